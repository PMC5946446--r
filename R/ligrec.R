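## Ligand-receptor road map: merge PPI sources through homology into
## one gene-level edge set, designate receptors by GO annotation,
## overlay per-compartment expression presence to classify each pair as
## autocrine / paracrine / either, and summarize the network topology
## (scale-free fit, hub coverage).

#' Integrate PPI edge tables through a homology map
#'
#' Foreign gene ids (species other than \code{targetSpecies}) are
#' expanded to all their homology-mapped target ids (one edge per
#' combination); target-species ids pass through unchanged. Edges are
#' canonicalized as unordered pairs and deduplicated across sources,
#' with provenance (source databases and species) unioned. Edges with
#' an unmapped endpoint, and self-edges arising after mapping, are
#' dropped and counted.
#'
#' @param edges data.frame from [readPpiEdges()] (columns id_a, id_b,
#'   source_db, species).
#' @param homologyMap data.frame(foreign_id, target_id) from
#'   [readHomologyMap()]; may map one foreign id to several targets.
#' @param targetSpecies species whose ids are already in the target
#'   namespace (default "cow").
#' @param allowSelf keep self-edges (default FALSE).
#' @return A [PPIEdgeSet-class].
#' @export
integratePpi <- function(edges, homologyMap, targetSpecies = "cow",
                         allowSelf = FALSE) {
  mapOne <- function(id, species) {
    if (species == targetSpecies) return(id)
    homologyMap$target_id[homologyMap$foreign_id == id]
  }
  if (nrow(edges) > 0L && nrow(homologyMap) == 0L &&
      !all(edges$species == targetSpecies))
    warning("empty homology map: all foreign-species edges will be dropped")
  rows <- vector("list", nrow(edges))
  droppedUnmapped <- 0L
  for (i in seq_len(nrow(edges))) {
    ta <- mapOne(edges$id_a[i], edges$species[i])
    tb <- mapOne(edges$id_b[i], edges$species[i])
    if (length(ta) == 0L || length(tb) == 0L) {
      droppedUnmapped <- droppedUnmapped + 1L
      next
    }
    combos <- expand.grid(a = ta, b = tb, stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(gene_a = pmin(combos$a, combos$b),
                            gene_b = pmax(combos$a, combos$b),
                            source_db = edges$source_db[i],
                            species = edges$species[i],
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(df))
    df <- data.frame(gene_a = character(0), gene_b = character(0),
                     source_db = character(0), species = character(0))
  droppedSelf <- 0L
  if (!allowSelf) {
    self <- df$gene_a == df$gene_b
    droppedSelf <- length(unique(paste(df$gene_a[self], df$gene_b[self])))
    df <- df[!self, , drop = FALSE]
  }
  key <- paste(df$gene_a, df$gene_b, sep = "\r")
  agg <- function(v) paste(sort(unique(v)), collapse = ",")
  uniq <- !duplicated(key)
  edgesOut <- df[uniq, c("gene_a", "gene_b"), drop = FALSE]
  dbByKey <- split(df$source_db, key)
  spByKey <- split(df$species, key)
  edgesOut$sources <- vapply(dbByKey[key[uniq]], agg, "", USE.NAMES = FALSE)
  edgesOut$species <- vapply(spByKey[key[uniq]], agg, "", USE.NAMES = FALSE)
  edgesOut$n_sources <- vapply(strsplit(edgesOut$sources, ","), length, 0L)
  edgesOut <- edgesOut[order(edgesOut$gene_a, edgesOut$gene_b), ,
                       drop = FALSE]
  rownames(edgesOut) <- NULL
  new("PPIEdgeSet", edges = edgesOut,
      droppedUnmapped = droppedUnmapped, droppedSelf = as.integer(droppedSelf))
}

#' Designate ligand and receptor roles on PPI edges
#'
#' A gene is a receptor if it carries one of the receptor GO terms
#' ("receptor activity" or "receptor complex" by default, matched by
#' exact term id or term name, no ontology propagation). Edges with at
#' least one receptor endpoint become candidate pairs: the non-receptor
#' endpoint is the ligand; edges between two receptors yield both
#' orientations, flagged receptor-receptor.
#'
#' @param ppi a [PPIEdgeSet-class].
#' @param go data.frame(gene_id, term_id[, term_name]) from
#'   [readGoAnnotations()].
#' @param receptorTerms terms marking receptors.
#' @return data.frame(ligand, receptor, receptor_receptor, sources).
#' @export
designateRoles <- function(ppi, go,
                           receptorTerms = c("receptor activity",
                                             "receptor complex")) {
  hits <- go$term_id %in% receptorTerms
  if ("term_name" %in% colnames(go))
    hits <- hits | go$term_name %in% receptorTerms
  receptors <- unique(go$gene_id[hits])
  e <- ppiEdges(ppi)
  isRecA <- e$gene_a %in% receptors
  isRecB <- e$gene_b %in% receptors
  one <- xor(isRecA, isRecB)
  both <- isRecA & isRecB
  out <- rbind(
    data.frame(ligand = ifelse(isRecA[one], e$gene_b[one], e$gene_a[one]),
               receptor = ifelse(isRecA[one], e$gene_a[one], e$gene_b[one]),
               receptor_receptor = rep(FALSE, sum(one)),
               sources = e$sources[one], stringsAsFactors = FALSE),
    data.frame(ligand = e$gene_a[both], receptor = e$gene_b[both],
               receptor_receptor = rep(TRUE, sum(both)),
               sources = e$sources[both], stringsAsFactors = FALSE),
    data.frame(ligand = e$gene_b[both], receptor = e$gene_a[both],
               receptor_receptor = rep(TRUE, sum(both)),
               sources = e$sources[both], stringsAsFactors = FALSE))
  out <- out[order(out$ligand, out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

presenceCategory <- function(genes, oocyteSet, ccSet) {
  inO <- genes %in% oocyteSet
  inC <- genes %in% ccSet
  out <- rep(NA_character_, length(genes))
  out[inO & inC] <- "both"
  out[inO & !inC] <- "oocyte-only"
  out[!inO & inC] <- "CC-only"
  out
}

classifyOne <- function(lig, rec) {
  ## lig, rec in {oocyte-only, CC-only, both}
  if (lig == "both" || rec == "both") return(c("autocrine_or_paracrine", ""))
  if (lig == rec) return(c("autocrine", sub("-only", "", lig)))
  if (lig == "oocyte-only") return(c("paracrine", "oocyte->CC"))
  c("paracrine", "CC->oocyte")
}

#' Classify candidate ligand-receptor pairs by signaling mode
#'
#' Each gene's presence category is one of oocyte-only, CC-only or both
#' (cumulus presence pools innerCC and outerCC by default). A pair is
#' autocrine when ligand and receptor are confined to the same
#' compartment, paracrine when confined to different compartments
#' (direction recorded), and autocrine-or-paracrine when either gene is
#' expressed on both sides. Pairs whose ligand or receptor is expressed
#' nowhere are dropped; receptor-receptor candidates are excluded from
#' classification counts unless requested.
#'
#' @param candidates data.frame from [designateRoles()].
#' @param presence named list of expressed gene sets per compartment
#'   (from [filterExpressed()]); names among oocyte, innerCC, outerCC,
#'   or directly \code{oocyte}/\code{CC}.
#' @param includeReceptorReceptor also classify receptor-receptor
#'   orientations (default FALSE).
#' @return list(pairs = classified data.frame, summary = per-category
#'   counts, geneCounts = expressed ligand/receptor gene counts per
#'   presence category).
#' @export
classifySignaling <- function(candidates, presence,
                              includeReceptorReceptor = FALSE) {
  known <- c("oocyte", "innerCC", "outerCC", "CC")
  bad <- setdiff(names(presence), known)
  if (length(bad))
    stop(sprintf("unknown compartment(s) in presence sets: %s",
                 paste(bad, collapse = ", ")))
  oocyteSet <- presence$oocyte
  ccSet <- if (!is.null(presence$CC)) presence$CC else
    unique(c(presence$innerCC, presence$outerCC))
  if (is.null(oocyteSet) || is.null(ccSet))
    stop("presence must provide 'oocyte' and cumulus ('CC' or innerCC/outerCC) sets")
  cand <- candidates
  if (!includeReceptorReceptor)
    cand <- cand[!cand$receptor_receptor, , drop = FALSE]
  ligCat <- presenceCategory(cand$ligand, oocyteSet, ccSet)
  recCat <- presenceCategory(cand$receptor, oocyteSet, ccSet)
  keep <- !is.na(ligCat) & !is.na(recCat)
  cand <- cand[keep, , drop = FALSE]
  ligCat <- ligCat[keep]; recCat <- recCat[keep]
  cls <- t(mapply(classifyOne, ligCat, recCat))
  cand$ligand_presence <- ligCat
  cand$receptor_presence <- recCat
  cand$category <- if (nrow(cand)) cls[, 1L] else character(0)
  cand$direction <- if (nrow(cand)) cls[, 2L] else character(0)
  rownames(cand) <- NULL
  summary <- as.data.frame(table(category = factor(cand$category,
    levels = c("autocrine", "paracrine", "autocrine_or_paracrine"))),
    stringsAsFactors = FALSE)
  names(summary) <- c("category", "n_pairs")
  genes <- unique(c(cand$ligand, cand$receptor))
  geneCounts <- data.frame(
    role = rep(c("ligand", "receptor"), each = 3L),
    presence = rep(c("oocyte-only", "CC-only", "both"), 2L),
    n_genes = c(vapply(c("oocyte-only", "CC-only", "both"), function(p)
                  length(unique(cand$ligand[cand$ligand_presence == p])), 0L),
                vapply(c("oocyte-only", "CC-only", "both"), function(p)
                  length(unique(cand$receptor[cand$receptor_presence == p])), 0L)))
  list(pairs = cand, summary = summary, geneCounts = geneCounts)
}

degreeTable <- function(edges) {
  if (is(edges, "PPIEdgeSet")) edges <- ppiEdges(edges)
  tab <- table(c(edges$gene_a, edges$gene_b))
  sort(tab, decreasing = TRUE)
}

scaleFreeR2 <- function(degrees) {
  tab <- table(degrees[degrees > 0])
  if (length(tab) < 2L) return(NA_real_)
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  stats::cor(x, y)^2
}

#' Scale-free fit of the degree distribution
#'
#' Tabulates the frequency f(d) of each observed node degree and
#' regresses log10 f(d) on log10 d (ordinary least squares, raw
#' frequencies, no binning); R-squared measures how power-law-like the
#' degree distribution is. The p-value compares the observed R-squared
#' with those of Erdos-Renyi random graphs with the same node and edge
#' counts: p = (#{null R^2 >= observed} + 1) / (nBootstrap + 1).
#'
#' @param edges a [PPIEdgeSet-class] or its edge data.frame (already
#'   restricted to expressed genes by the caller).
#' @param nBootstrap number of null graphs (default 1000).
#' @param seed integer seed.
#' @return list (class \code{DegreeFit}): degrees, rSquared, slope,
#'   pValue, nBootstrap.
#' @export
fitScaleFree <- function(edges, nBootstrap = 1000L, seed = 1L) {
  if (is(edges, "PPIEdgeSet")) edges <- ppiEdges(edges)
  deg <- degreeTable(edges)
  if (length(deg) < 10L)
    stop("need at least 10 nodes with degree >= 1")
  degrees <- as.integer(deg)
  tab <- table(degrees)
  if (length(tab) < 2L) stop("degenerate degree distribution")
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- stats::cor(x, y)^2
  nNodes <- length(degrees)
  nEdges <- nrow(edges)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(nBootstrap)) {
    g <- igraph::sample_gnm(nNodes, nEdges)
    r2b <- scaleFreeR2(igraph::degree(g))
    if (!is.na(r2b) && r2b >= r2) exceed <- exceed + 1L
  }
  structure(list(degrees = degrees, rSquared = r2, slope = fit$coefficients[2L],
                 pValue = (exceed + 1) / (nBootstrap + 1),
                 nBootstrap = as.integer(nBootstrap)),
            class = "DegreeFit")
}

#' @export
print.DegreeFit <- function(x, ...) {
  cat(sprintf("DegreeFit: %d nodes, R^2 = %.3f (slope %.2f), P = %.4g (%d bootstraps)\n",
              length(x$degrees), x$rSquared, x$slope, x$pValue, x$nBootstrap))
  invisible(x)
}

#' Hub genes and their edge coverage
#'
#' Ranks genes by degree (ties broken lexicographically) and reports
#' what fraction of all edges touch at least one of the top-n genes.
#'
#' @param edges a [PPIEdgeSet-class] or edge data.frame.
#' @param topN number of hubs (default 10; capped at the node count).
#' @return list(hubs = character vector, fraction = numeric in [0, 1]).
#' @export
hubSummary <- function(edges, topN = 10L) {
  if (is(edges, "PPIEdgeSet")) edges <- ppiEdges(edges)
  if (nrow(edges) == 0L) stop("empty edge set")
  deg <- table(c(edges$gene_a, edges$gene_b))
  ord <- order(-as.numeric(deg), names(deg))
  hubs <- names(deg)[ord][seq_len(min(topN, length(deg)))]
  incident <- edges$gene_a %in% hubs | edges$gene_b %in% hubs
  list(hubs = hubs, fraction = sum(incident) / nrow(edges))
}
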