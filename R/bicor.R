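## Biweight midcorrelation and the cross-compartment permutation
## empirical FDR. The correlation down-weights observations far from
## the median (in units of 9 * MAD) with Tukey biweights, so single
## aberrant COCs cannot create spurious gene-pair correlations; the
## eFDR is estimated by breaking the COC linkage between the two
## compartments (permuting which oocyte goes with which cumulus sample)
## and counting how often the null exceeds each correlation threshold.

## Transform one vector to its normalized biweight coordinates so that
## bicor(x, y) = sum(transform(x) * transform(y)).
## Returns list(t = coords, fallback = used Pearson, bad = constant).
bicorTransformVector <- function(x, fallback = c("pearson", "strict")) {
  fallback <- match.arg(fallback)
  d <- x - stats::median(x)
  m <- stats::median(abs(d))
  if (m == 0) {
    if (fallback == "strict")
      return(list(t = rep(NA_real_, length(x)), fallback = TRUE, bad = TRUE))
    dc <- x - mean(x)
    den <- sqrt(sum(dc^2))
    if (den == 0)
      return(list(t = rep(NA_real_, length(x)), fallback = TRUE, bad = TRUE))
    return(list(t = dc / den, fallback = TRUE, bad = FALSE))
  }
  u <- d / (9 * m)
  a <- (1 - u^2)^2 * (abs(u) < 1)
  w <- d * a
  den <- sqrt(sum(w^2))
  if (den == 0)
    return(list(t = rep(NA_real_, length(x)), fallback = TRUE, bad = TRUE))
  list(t = w / den, fallback = FALSE, bad = FALSE)
}

## Row-wise biweight transform of a genes x samples matrix.
bicorTransformRows <- function(m, fallback = c("pearson", "strict")) {
  fallback <- match.arg(fallback)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  fb <- logical(nrow(m))
  bad <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    tr <- bicorTransformVector(m[i, ], fallback)
    out[i, ] <- tr$t
    fb[i] <- tr$fallback
    bad[i] <- tr$bad
  }
  list(t = out, fallback = fb, bad = bad)
}

#' Biweight midcorrelation of two vectors
#'
#' Robust correlation using Tukey biweights: with \eqn{d_i = x_i -
#' \mathrm{median}(x)} and \eqn{u_i = d_i / (9\,\mathrm{MAD}(x))} (MAD =
#' unscaled median absolute deviation), the weight is \eqn{a_i = (1 -
#' u_i^2)^2} for \eqn{|u_i| < 1} and 0 otherwise; the transformed
#' coordinates \eqn{\tilde x_i = d_i a_i / \sqrt{\sum_j (d_j a_j)^2}}
#' give \eqn{\mathrm{bicor}(x, y) = \sum_i \tilde x_i \tilde y_i}.
#' Observations beyond 9 MAD from the median get zero weight, so a
#' single outlying sample cannot dominate the coefficient.
#'
#' If a vector has MAD 0 the biweight is undefined; by default the
#' Pearson standardization is used for that vector and the result is
#' flagged (attribute \code{"fallback"}); in strict mode the result is
#' NA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param fallback \code{"pearson"} (default) or \code{"strict"}.
#' @return The correlation in [-1, 1], with logical attribute
#'   \code{"fallback"}.
#' @examples
#' bicor(1:10, 1:10)                       # 1
#' bicor(1:10, -(1:10))                    # -1
#' bicor(c(1, 2, 3, 4, 100), c(1, 2, 3, 4, 5))  # outlier down-weighted
#' @export
bicor <- function(x, y, fallback = c("pearson", "strict")) {
  fallback <- match.arg(fallback)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  tx <- bicorTransformVector(x, fallback)
  ty <- bicorTransformVector(y, fallback)
  if (tx$bad || ty$bad) {
    r <- NA_real_
  } else {
    r <- sum(tx$t * ty$t)
    r <- min(1, max(-1, r))
  }
  attr(r, "fallback") <- tx$fallback || ty$fallback
  r
}

#' Cross-compartment biweight midcorrelation matrix
#'
#' Computes bicor between every gene of compartment A and every gene of
#' compartment B across the shared COC index: entry (k, l) correlates
#' the expression of A-gene k with B-gene l over the J complexes.
#' Within-compartment pairs are not formed.
#'
#' @param pair a [LinkedCompartmentPair-class] (log2(FPKM+1),
#'   presence-filtered, J >= 3 COCs).
#' @param fallback zero-MAD handling, see [bicor()]. In strict mode the
#'   affected gene's whole row/column is NA.
#' @return A [BicorResult-class].
#' @export
crossCompartmentBicor <- function(pair, fallback = c("pearson", "strict")) {
  fallback <- match.arg(fallback)
  if (!is(pair, "LinkedCompartmentPair"))
    stop("pair must be a LinkedCompartmentPair")
  if (nCocs(pair) < 3L) stop("need J >= 3 COCs")
  ta <- bicorTransformRows(pair@a, fallback)
  tb <- bicorTransformRows(pair@b, fallback)
  v <- bicorCrossProduct(ta$t, tb$t)
  new("BicorResult", values = v, fallbackA = ta$fallback,
      fallbackB = tb$fallback, nCocs = nCocs(pair),
      compartments = pair@compartments)
}

## Cross-product of transformed rows with NA rows propagated and
## rounding clamped into [-1, 1].
bicorCrossProduct <- function(ta, tb) {
  badA <- !stats::complete.cases(ta)
  badB <- !stats::complete.cases(tb)
  ta0 <- ta; ta0[badA, ] <- 0
  tb0 <- tb; tb0[badB, ] <- 0
  v <- tcrossprod(ta0, tb0)
  v[v > 1] <- 1
  v[v < -1] <- -1
  if (any(badA)) v[badA, ] <- NA_real_
  if (any(badB)) v[, badB] <- NA_real_
  v
}

## All permutations of 1..n (n small), as a matrix with one permutation
## per row. Used for exhaustive enumeration of the null when J! - 1 <= B.
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Permutation null for cross-compartment correlations
#'
#' Breaks the COC linkage by permuting the COC index of the
#' compartment-A samples: for each of B draws, a uniformly random
#' non-identity permutation of the columns of matrix A is applied and
#' all K = |A genes| x |B genes| correlations recomputed. When
#' \eqn{J! - 1 \le B} the sampler switches to exhaustive enumeration of
#' all non-identity permutations.
#'
#' @param pair a [LinkedCompartmentPair-class].
#' @param B number of permutations (>= 1).
#' @param seed integer seed for the permutation draws.
#' @param fallback zero-MAD handling, see [bicor()].
#' @return An object of class \code{BicorNull}: a list with the
#'   permutation matrix (\code{B} rows), the cached biweight transforms,
#'   \code{mode} ("sampled" or "exhaustive") and \code{B}. Use
#'   [nullBicorValues()] to materialize the b-th null matrix.
#' @export
permutedNullBicor <- function(pair, B, seed = 1L,
                              fallback = c("pearson", "strict")) {
  fallback <- match.arg(fallback)
  if (!is(pair, "LinkedCompartmentPair"))
    stop("pair must be a LinkedCompartmentPair")
  if (B < 1L) stop("B must be >= 1")
  J <- nCocs(pair)
  ta <- bicorTransformRows(pair@a, fallback)
  tb <- bicorTransformRows(pair@b, fallback)
  nPerm <- factorial(J) - 1
  if (nPerm <= B) {
    perms <- allPermutations(J)
    ident <- apply(perms, 1L, function(p) all(p == seq_len(J)))
    perms <- perms[!ident, , drop = FALSE]
    ## canonical order for reproducibility regardless of enumeration order
    perms <- perms[do.call(order, as.data.frame(perms)), , drop = FALSE]
    mode <- "exhaustive"
    B <- nrow(perms)
  } else {
    set.seed(seed)
    perms <- matrix(0L, B, J)
    for (b in seq_len(B)) {
      repeat {
        p <- sample.int(J)
        if (!all(p == seq_len(J))) break
      }
      perms[b, ] <- p
    }
    mode <- "sampled"
  }
  structure(list(permutations = perms, ta = ta, tb = tb, B = B,
                 mode = mode, seed = seed, J = J),
            class = "BicorNull")
}

#' @describeIn permutedNullBicor materialize the b-th permuted
#'   correlation matrix.
#' @param nullObj a \code{BicorNull}.
#' @param b permutation index in 1..B.
#' @export
nullBicorValues <- function(nullObj, b) {
  stopifnot(inherits(nullObj, "BicorNull"), b >= 1, b <= nullObj$B)
  perm <- nullObj$permutations[b, ]
  bicorCrossProduct(nullObj$ta$t[, perm, drop = FALSE], nullObj$tb$t)
}

#' @export
print.BicorNull <- function(x, ...) {
  cat(sprintf("BicorNull: %d %s permutation(s) of J = %d COCs\n",
              x$B, x$mode, x$J))
  invisible(x)
}

#' Empirical FDR over a grid of correlation thresholds
#'
#' For each threshold t the estimator is
#' \deqn{eFDR(t) = \sum_{b=1}^{B} \frac{\#\{pairs: |bicor^{0b}| \ge t\} + 1}{K B + 1}}
#' where the count runs over all K gene pairs and bicor^{0b} are the
#' b-th permutation's null correlations; values above 1 are capped at 1.
#' The observed pair count reported alongside uses the strict selection
#' convention (|bicor| > t).
#'
#' @param observed a [BicorResult-class].
#' @param nullObj a \code{BicorNull} from [permutedNullBicor()].
#' @param thresholds absolute-correlation grid in (0, 1); default 0.50
#'   to 0.95 in steps of 0.05 (includes 0.85).
#' @return data.frame (class \code{EfdrTable}) with columns threshold,
#'   observed_count, permuted_exceed_total, efdr; attributes B, K, mode,
#'   seed.
#' @export
efdrAtThresholds <- function(observed, nullObj,
                             thresholds = seq(0.50, 0.95, by = 0.05)) {
  if (!is(observed, "BicorResult")) stop("observed must be a BicorResult")
  if (!inherits(nullObj, "BicorNull")) stop("nullObj must be a BicorNull")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  thresholds <- sort(thresholds)
  obs <- abs(bicorValues(observed))
  finite <- is.finite(obs)
  K <- sum(finite)
  if (K == 0L) stop("observed correlation matrix is empty")
  B <- nullObj$B
  exceed <- numeric(length(thresholds))
  for (b in seq_len(B)) {
    nv <- abs(nullBicorValues(nullObj, b))
    nv <- nv[is.finite(nv)]
    ## counts for all grid thresholds in one pass
    exceed <- exceed + vapply(thresholds, function(t) sum(nv >= t), 0)
  }
  efdr <- pmin(1, (exceed + B) / (K * B + 1))
  out <- data.frame(threshold = thresholds,
                    observed_count = vapply(thresholds,
                                            function(t) sum(obs[finite] > t), 0L),
                    permuted_exceed_total = exceed,
                    efdr = efdr)
  attr(out, "B") <- B
  attr(out, "K") <- K
  attr(out, "mode") <- nullObj$mode
  attr(out, "seed") <- nullObj$seed
  class(out) <- c("EfdrTable", "data.frame")
  out
}

#' Select significant cross-compartment gene pairs
#'
#' Keeps the gene pairs with |bicor| strictly greater than
#' \code{bicorMin}, provided the empirical FDR at that grid threshold is
#' below \code{efdrMax}; otherwise no pair is selected. \code{bicorMin}
#' must be one of the thresholds at which the eFDR table was computed
#' (no interpolation).
#'
#' @param observed a [BicorResult-class].
#' @param efdrTable an \code{EfdrTable} from [efdrAtThresholds()].
#' @param bicorMin absolute-correlation selection threshold
#'   (default 0.85).
#' @param efdrMax maximum admissible eFDR at \code{bicorMin}.
#' @return data.frame (gene_a, gene_b, bicor, passes) ordered by gene_a
#'   then gene_b; zero rows if the eFDR gate fails. Attribute
#'   \code{"efdr"} holds the eFDR at the threshold.
#' @export
selectSignificantPairs <- function(observed, efdrTable, bicorMin = 0.85,
                                   efdrMax = 0.001) {
  if (!is(observed, "BicorResult")) stop("observed must be a BicorResult")
  hit <- which(abs(efdrTable$threshold - bicorMin) < 1e-9)
  if (length(hit) != 1L)
    stop(sprintf("bicorMin = %g is not on the eFDR threshold grid", bicorMin))
  efdr <- efdrTable$efdr[hit]
  v <- bicorValues(observed)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      bicor = numeric(0), passes = logical(0))
  if (efdr >= efdrMax) {
    attr(empty, "efdr") <- efdr
    return(empty)
  }
  idx <- which(is.finite(v) & abs(v) > bicorMin, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    attr(empty, "efdr") <- efdr
    return(empty)
  }
  out <- data.frame(gene_a = rownames(v)[idx[, 1L]],
                    gene_b = colnames(v)[idx[, 2L]],
                    bicor = v[idx],
                    passes = TRUE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "efdr") <- efdr
  out
}
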