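## Length-bias-corrected gene-set enrichment. Long transcripts are more
## likely to end up in "interesting" gene lists for purely technical
## reasons; the correction fits a monotone probability-weighting
## function (PWF) of selection on gene length, converts it to an odds
## ratio per GO category, and tests over-representation under the
## Wallenius noncentral hypergeometric distribution instead of the
## central one.

#' Fit the probability weighting function (PWF)
#'
#' Genes are sorted by length and split into equal-count bins; the
#' per-bin selection proportion is isotonically regressed on the bin
#' mean length (pool-adjacent-violators), giving a monotone
#' non-decreasing selection weight per gene. Weights are floored at a
#' small positive value and rescaled to mean 1 over the universe.
#'
#' @param selected character vector of selected gene ids (subset of the
#'   universe, non-empty, not the whole universe).
#' @param universe character vector of background gene ids.
#' @param lengths data.frame(gene_id, length) or named numeric vector;
#'   genes with missing length get the median length (counted).
#' @param nBins number of equal-count length bins (default 40; reduced
#'   when the universe is small).
#' @return data.frame (class \code{Pwf}) with gene_id, length, weight;
#'   attributes \code{nImputed}, \code{degenerate}.
#' @export
fitPwf <- function(selected, universe, lengths, nBins = 40L) {
  universe <- unique(as.character(universe))
  selected <- unique(as.character(selected))
  if (length(selected) == 0L) stop("selected gene set is empty")
  if (!all(selected %in% universe))
    stop("selected must be a subset of the universe")
  if (length(selected) == length(universe))
    stop("selected equals the universe; enrichment is undefined")
  if (is.data.frame(lengths)) {
    len <- lengths$length
    names(len) <- lengths$gene_id
  } else len <- lengths
  l <- len[universe]
  nImputed <- sum(is.na(l))
  l[is.na(l)] <- stats::median(l, na.rm = TRUE)
  sel <- as.numeric(universe %in% selected)

  n <- length(universe)
  nBins <- max(2L, min(nBins, floor(n / 5)))
  ord <- order(l)
  bin <- ceiling(seq_len(n) / (n / nBins))
  bin <- pmin(bin, nBins)
  binMeanLen <- tapply(l[ord], bin, mean)
  binProp <- tapply(sel[ord], bin, mean)

  degenerate <- FALSE
  if (length(unique(binMeanLen)) < 2L || stats::sd(binProp) == 0) {
    warning("degenerate length distribution; using constant weights")
    w <- rep(1, n)
    degenerate <- TRUE
  } else {
    iso <- stats::isoreg(binMeanLen, binProp)
    fitted <- iso$yf[order(order(binMeanLen))]  # yf is in x-sorted order
    wBin <- fitted
    floorVal <- max(min(wBin[wBin > 0], na.rm = TRUE) / 2, 1e-8)
    wBin[wBin <= 0] <- floorVal
    w <- numeric(n)
    w[ord] <- wBin[bin]
  }
  w <- w / mean(w)
  out <- data.frame(gene_id = universe, length = as.numeric(l),
                    weight = w, stringsAsFactors = FALSE)
  attr(out, "nImputed") <- nImputed
  attr(out, "degenerate") <- degenerate
  class(out) <- c("Pwf", "data.frame")
  out
}

## Exact pmf of the two-weight-class Wallenius noncentral hypergeometric
## distribution by forward recursion over draws: at each draw, the
## probability of taking a category gene is odds*(m1-x) / (odds*(m1-x) +
## (m2-(d-x))). Exact for the urn with one weight inside the category
## and one outside, which is the setting the mean-weight odds reduces to.
walleniusPmf <- function(m1, m2, n, odds) {
  stopifnot(n <= m1 + m2, odds > 0)
  xmax <- min(n, m1)
  p <- c(1, rep(0, xmax))          # p[x+1] = P(X = x after d draws)
  if (n == 0L) return(p)
  for (d in 0:(n - 1L)) {
    x <- 0:xmax
    remT <- pmax(m1 - x, 0)
    remO <- pmax(m2 - (d - x), 0)
    wT <- odds * remT
    tot <- wT + remO
    pTake <- ifelse(tot > 0, wT / tot, 0)
    ## drawing more than the remaining pool is impossible; those states
    ## have probability 0 anyway
    pNew <- p * (1 - pTake)
    pNew <- pNew + c(0, (p * pTake)[seq_len(xmax)])
    p <- pNew
  }
  p
}

#' Wallenius noncentral hypergeometric enrichment test
#'
#' Tests over-representation of a gene category in a selected set,
#' weighting draws by the PWF: the odds ratio is the mean PWF weight
#' inside the category divided by the mean weight outside, and the
#' upper-tail p-value P(X >= overlap) is computed under the Wallenius
#' noncentral hypergeometric distribution (population = universe size,
#' successes = category size, draws = selected size). With odds 1 this
#' is exactly the central hypergeometric (Fisher) upper tail.
#'
#' @param termGenes gene ids of the category.
#' @param selected selected gene ids.
#' @param universe background gene ids.
#' @param pwf a \code{Pwf} from [fitPwf()], or NULL for constant
#'   weights (odds 1).
#' @return data.frame (one row) with term columns n_in_set,
#'   n_in_category, n_overlap, odds, p_over, flag.
#' @export
walleniusTest <- function(termGenes, selected, universe, pwf = NULL) {
  universe <- unique(as.character(universe))
  term <- intersect(unique(as.character(termGenes)), universe)
  selected <- intersect(unique(as.character(selected)), universe)
  if (length(term) == 0L) stop("term has no genes in the universe")
  N <- length(universe)
  m1 <- length(term)
  n <- length(selected)
  k <- length(intersect(term, selected))
  flag <- ""
  if (m1 == N) {
    out <- data.frame(n_in_set = n, n_in_category = m1, n_overlap = k,
                      odds = NA_real_, p_over = 1, flag = "all-genes-in-term",
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(pwf)) {
    odds <- 1
  } else {
    w <- pwf$weight[match(universe, pwf$gene_id)]
    if (anyNA(w)) stop("pwf is missing weights for some universe genes")
    inTerm <- universe %in% term
    odds <- mean(w[inTerm]) / mean(w[!inTerm])
  }
  if (k == 0L) {
    p <- 1
  } else {
    pmf <- walleniusPmf(m1, N - m1, n, odds)
    p <- sum(pmf[(k + 1L):length(pmf)])
    p <- min(1, max(p, 0))
  }
  data.frame(n_in_set = n, n_in_category = m1, n_overlap = k,
             odds = odds, p_over = p, flag = flag, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Step-up adjusted q-values.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Benjamini-Yekutieli adjusted p-values (valid under dependency)
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted q-values with the harmonic-sum inflation factor.
#' @export
byFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Enrichment of one or many gene sets over a GO map
#'
#' Runs [walleniusTest()] for every term with at least one universe
#' gene, for each selected gene set (e.g. each co-expression module),
#' fitting the PWF per set. Emits BH and BY FDR columns per set, rows
#' in deterministic term order.
#'
#' @param geneSets named list of selected gene sets, a single character
#'   vector, or a \code{ModuleAssignment} (each cluster becomes a set).
#' @param goMap data.frame(gene_id, term_id) annotations.
#' @param universe background gene ids (the genes expressed in the
#'   relevant compartment).
#' @param lengths gene lengths (see [fitPwf()]); NULL disables the
#'   length correction (constant weights).
#' @param nBins PWF bins, see [fitPwf()].
#' @return data.frame with columns set, term_id, n_in_set,
#'   n_in_category, n_overlap, odds, p_over, fdr_bh, fdr_by, flag.
#' @export
enrichAll <- function(geneSets, goMap, universe, lengths = NULL,
                      nBins = 40L) {
  if (inherits(geneSets, "ModuleAssignment")) {
    labs <- geneSets$labels
    geneSets <- lapply(sort(unique(labs[labs > 0])), function(cl)
      names(labs)[labs == cl])
    names(geneSets) <- paste0("cluster", sort(unique(labs[labs > 0])))
  }
  if (!is.list(geneSets)) geneSets <- list(set1 = geneSets)
  if (is.null(names(geneSets)))
    names(geneSets) <- paste0("set", seq_along(geneSets))
  universe <- unique(as.character(universe))
  goMap <- goMap[goMap$gene_id %in% universe, , drop = FALSE]
  if (nrow(goMap) == 0L)
    return(data.frame(set = character(0), term_id = character(0),
                      n_in_set = integer(0), n_in_category = integer(0),
                      n_overlap = integer(0), odds = numeric(0),
                      p_over = numeric(0), fdr_bh = numeric(0),
                      fdr_by = numeric(0), flag = character(0)))
  termList <- split(goMap$gene_id, goMap$term_id)
  termIds <- sort(names(termList))
  res <- lapply(names(geneSets), function(sn) {
    sel <- intersect(geneSets[[sn]], universe)
    if (length(sel) == 0L) return(NULL)
    pwf <- if (is.null(lengths)) NULL else
      fitPwf(sel, universe, lengths, nBins)
    rows <- lapply(termIds, function(tid)
      cbind(set = sn, term_id = tid,
            walleniusTest(termList[[tid]], sel, universe, pwf),
            stringsAsFactors = FALSE))
    tab <- do.call(rbind, rows)
    tab$fdr_bh <- bhFdr(tab$p_over)
    tab$fdr_by <- byFdr(tab$p_over)
    tab
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(set = character(0), term_id = character(0),
                      n_in_set = integer(0), n_in_category = integer(0),
                      n_overlap = integer(0), odds = numeric(0),
                      p_over = numeric(0), fdr_bh = numeric(0),
                      fdr_by = numeric(0), flag = character(0))
  rownames(out) <- NULL
  out
}
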