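## Within-compartment signed co-expression networks (adjacency -> TOM ->
## average-linkage clusters) and two-dimensional clustering of the
## significant cross-compartment pairs on 1 - bicor.

#' Signed co-expression adjacency
#'
#' \eqn{a_{ij} = ((1 + \mathrm{bicor}(g_i, g_j)) / 2)^\beta}: the signed
#' map sends correlation -1 to 0 and +1 to 1, so strongly
#' anti-correlated genes are disconnected rather than connected, and the
#' soft power beta suppresses weak correlations.
#'
#' @param expr genes x samples matrix of log2(FPKM+1) values (>= 3
#'   samples), or a single-compartment log-scale [COCExperiment-class].
#' @param beta positive integer soft-threshold power (default 12).
#' @param fallback zero-MAD handling, see [bicor()].
#' @return Symmetric adjacency matrix in [0, 1] with unit diagonal
#'   (attribute \code{"beta"}).
#' @export
signedAdjacency <- function(expr, beta = 12L, fallback = c("pearson", "strict")) {
  fallback <- match.arg(fallback)
  if (is(expr, "COCExperiment")) {
    if (exprScale(expr) != "log2") stop("expr must be on the log2 scale")
    expr <- exprValues(expr)
  }
  if (!is.matrix(expr) || ncol(expr) < 3L)
    stop("expr must be a genes x samples matrix with >= 3 samples")
  if (beta < 1 || beta != round(beta)) stop("beta must be a positive integer")
  tr <- bicorTransformRows(expr, fallback)
  r <- bicorCrossProduct(tr$t, tr$t)
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  attr(a, "beta") <- as.integer(beta)
  a
}

#' Topological overlap similarity
#'
#' \eqn{TOM_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' for \eqn{i \ne j}, with \eqn{\ell_{ij} = \sum_{u \ne i,j} a_{iu}
#' a_{uj}} (shared-neighbor strength) and \eqn{k_i = \sum_{u \ne i}
#' a_{iu}} (connectivity); \eqn{TOM_{ii} = 1}. Two genes overlap
#' topologically when they are connected to each other and to the same
#' neighbors; 1 - TOM is the clustering dissimilarity.
#'
#' @param A symmetric adjacency matrix in [0, 1] with unit diagonal.
#' @return Symmetric TOM matrix in [0, 1] with unit diagonal.
#' @export
tomSimilarity <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be square")
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-10,
                        check.attributes = FALSE)))
    stop("A must be symmetric")
  if (any(A < 0 | A > 1)) stop("adjacency values must lie in [0, 1]")
  diag(A) <- 1
  n <- nrow(A)
  k <- colSums(A) - 1              # excludes the unit diagonal
  AA <- A %*% A
  ## remove the u = i and u = j terms from the path sum
  L <- AA - 2 * A                  # diag(A) = 1, so a_ii*a_ij + a_ij*a_jj = 2 a_ij
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(A)
  tom
}

relabelBySize <- function(labels, geneIds, minSize) {
  ## clusters below minSize -> 0; remaining renumbered 1..k by
  ## decreasing size, ties broken by the lexicographically first member
  keep <- table(labels)
  keep <- names(keep)[keep >= minSize]
  out <- integer(length(labels))
  names(out) <- geneIds
  if (!length(keep)) return(out)
  firstMember <- vapply(keep, function(cl) min(geneIds[labels == cl]), "")
  sizes <- vapply(keep, function(cl) sum(labels == cl), 0L)
  ord <- keep[order(-sizes, firstMember)]
  for (i in seq_along(ord)) out[labels == ord[i]] <- i
  out
}

#' Hierarchical co-expression modules from a dissimilarity matrix
#'
#' Average-linkage agglomerative clustering of a dissimilarity (e.g.
#' 1 - TOM), cut at one or more heights. Clusters smaller than
#' \code{minSize} are relabeled 0 (unassigned); assigned clusters are
#' numbered by decreasing size, ties broken by first gene id, so labels
#' do not depend on input gene order.
#'
#' @param D square symmetric dissimilarity with zero diagonal, gene ids
#'   as dimnames.
#' @param cutHeights numeric vector of tree-cut heights (>= 0; negative
#'   heights yield a warning and an all-unassigned result).
#' @param minSize minimum cluster size (default 10).
#' @param method \code{"direct"} (default) treats \code{D} itself as the
#'   clustering dissimilarity; \code{"euclidean"} clusters on the
#'   Euclidean distance between rows of \code{D}.
#' @return Named list (one element per height) of \code{ModuleAssignment}
#'   objects: list(labels = named integer vector, cutHeight, minSize).
#' @export
hierarchicalModules <- function(D, cutHeights, minSize = 10L,
                                method = c("direct", "euclidean")) {
  method <- match.arg(method)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (is.null(rownames(D))) stop("D needs gene ids as dimnames")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-10,
                        check.attributes = FALSE)))
    stop("D must be symmetric")
  genes <- rownames(D)
  d <- if (method == "direct") stats::as.dist(D) else stats::dist(D)
  hc <- stats::hclust(d, method = "average")
  out <- lapply(cutHeights, function(h) {
    if (h < 0) {
      warning(sprintf("cut height %g is below 0; empty assignment", h))
      labels <- integer(length(genes))
      names(labels) <- genes
    } else {
      raw <- stats::cutree(hc, h = h)
      labels <- relabelBySize(raw, genes, minSize)
    }
    structure(list(labels = labels, cutHeight = h, minSize = minSize),
              class = "ModuleAssignment")
  })
  names(out) <- as.character(cutHeights)
  out
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  tab <- table(x$labels[x$labels > 0])
  cat(sprintf("ModuleAssignment: %d gene(s), %d cluster(s) at height %g (min size %d)\n",
              length(x$labels), length(tab), x$cutHeight, x$minSize))
  if (length(tab))
    cat("  sizes:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Two-dimensional clustering of significant cross-compartment pairs
#'
#' Restricts the cross-compartment correlation matrix to the genes that
#' appear in significant pairs and clusters the two dimensions
#' independently: compartment-A genes on the Euclidean distance between
#' rows of the 1 - bicor matrix, compartment-B genes on the distance
#' between its columns (average linkage). For every (A cluster, B
#' cluster) block it reports the mean correlation — the signed summary
#' of how the two gene groups co-vary across complexes.
#'
#' @param pairs data.frame from [selectSignificantPairs()] (non-empty).
#' @param observed the [BicorResult-class] the pairs came from.
#' @param cutHeightA,cutHeightB tree-cut heights; \code{NULL} (default)
#'   cuts at 70% of the tree height of that dimension.
#' @param minSize minimum cluster size per dimension (default 10). A
#'   dimension with fewer than \code{minSize} genes forms one cluster,
#'   flagged sub-minimum.
#' @return list(modulesA, modulesB (ModuleAssignment),
#'   blocks = data.frame(cluster_a, cluster_b, mean_bicor, n_pairs,
#'   n_cells)).
#' @export
crossCompartmentClusters <- function(pairs, observed, cutHeightA = NULL,
                                     cutHeightB = NULL, minSize = 10L) {
  if (nrow(pairs) == 0L) stop("no significant pairs to cluster")
  v <- bicorValues(observed)
  genesA <- sort(unique(pairs$gene_a))
  genesB <- sort(unique(pairs$gene_b))
  sub <- v[genesA, genesB, drop = FALSE]
  D <- 1 - sub

  clusterDim <- function(M, cutHeight, genes) {
    if (nrow(M) < 2L || nrow(M) < minSize) {
      labels <- rep(1L, nrow(M))
      names(labels) <- genes
      return(structure(list(labels = labels, cutHeight = NA_real_,
                            minSize = minSize, subMinimum = TRUE),
                       class = "ModuleAssignment"))
    }
    d <- stats::dist(M)
    hc <- stats::hclust(d, method = "average")
    if (is.null(cutHeight)) cutHeight <- 0.7 * max(hc$height)
    raw <- stats::cutree(hc, h = max(0, cutHeight))
    labels <- relabelBySize(raw, genes, minSize)
    structure(list(labels = labels, cutHeight = cutHeight,
                   minSize = minSize, subMinimum = FALSE),
              class = "ModuleAssignment")
  }

  modA <- clusterDim(D, cutHeightA, genesA)
  modB <- clusterDim(t(D), cutHeightB, genesB)

  pairKey <- paste(pairs$gene_a, pairs$gene_b, sep = "\r")
  blocks <- list()
  for (ca in sort(unique(modA$labels[modA$labels > 0]))) {
    gA <- genesA[modA$labels == ca]
    for (cb in sort(unique(modB$labels[modB$labels > 0]))) {
      gB <- genesB[modB$labels == cb]
      cell <- sub[gA, gB, drop = FALSE]
      inBlock <- sum(paste(rep(gA, times = length(gB)),
                           rep(gB, each = length(gA)),
                           sep = "\r") %in% pairKey)
      blocks[[length(blocks) + 1L]] <-
        data.frame(cluster_a = ca, cluster_b = cb,
                   mean_bicor = mean(cell, na.rm = TRUE),
                   n_pairs = inBlock,
                   n_cells = length(cell))
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(cluster_a = integer(0), cluster_b = integer(0),
               mean_bicor = numeric(0), n_pairs = integer(0),
               n_cells = integer(0))
  list(modulesA = modA, modulesB = modB, blocks = blocks)
}
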