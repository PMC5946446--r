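#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

COC_COMPARTMENTS <- c("oocyte", "innerCC", "outerCC")

#' COCExperiment: expression data for cumulus-oocyte complexes
#'
#' A \linkS4class{SummarizedExperiment} whose columns are the dissected
#' samples of cumulus-oocyte complexes (COCs). Each column carries a
#' \code{coc_id} (which complex it came from) and a \code{compartment}
#' (one of \code{oocyte}, \code{innerCC}, \code{outerCC}) in
#' \code{colData}. The single assay holds non-negative expression values,
#' FPKM by default; \code{metadata(x)$scale} records whether values are
#' raw FPKM (\code{"fpkm"}) or log2(FPKM+1) (\code{"log2"}).
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @seealso [COCExperiment()] for construction, [filterExpressed()],
#'   [logTransform()], [linkCompartments()]
#' @export
setClass("COCExperiment", contains = "SummarizedExperiment")

setValidity("COCExperiment", function(object) {
  msg <- character(0)
  cd <- colData(object)
  if (!all(c("coc_id", "compartment") %in% colnames(cd)))
    return("colData must contain 'coc_id' and 'compartment'")
  comp <- as.character(cd$compartment)
  if (!all(comp %in% COC_COMPARTMENTS))
    msg <- c(msg, sprintf("unknown compartment label(s): %s",
                          paste(unique(setdiff(comp, COC_COMPARTMENTS)),
                                collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  key <- paste(cd$coc_id, comp, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "more than one sample for the same (coc_id, compartment)")
  v <- assay(object, 1L)
  if (anyNA(v))
    msg <- c(msg, "missing values are not supported; encode absence as 0")
  else if (any(v < 0))
    msg <- c(msg, "expression values must be non-negative")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("fpkm", "log2"))
    msg <- c(msg, "metadata(x)$scale must be 'fpkm' or 'log2'")
  if (length(msg)) msg else TRUE
})

#' Construct a COCExperiment
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); non-negative FPKM.
#' @param sampleSheet data.frame with columns \code{sample_id},
#'   \code{coc_id}, \code{compartment}; every column of \code{values}
#'   must appear exactly once.
#' @param scale \code{"fpkm"} (default) or \code{"log2"}.
#' @return A [COCExperiment-class] object.
#' @examples
#' v <- matrix(c(1, 0, 2.5, 3, 0.2, 0), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     coc_id = c("coc1", "coc1"),
#'                     compartment = c("oocyte", "outerCC"))
#' COCExperiment(v, sheet)
#' @export
COCExperiment <- function(values, sampleSheet, scale = "fpkm") {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene ids as rownames and sample ids as colnames")
  need <- c("sample_id", "coc_id", "compartment")
  if (!all(need %in% colnames(sampleSheet)))
    stop("sample sheet must have columns sample_id, coc_id, compartment")
  sampleSheet <- as.data.frame(sampleSheet, stringsAsFactors = FALSE)
  if (anyDuplicated(sampleSheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  missing <- setdiff(colnames(values), sampleSheet$sample_id)
  if (length(missing))
    stop(sprintf("sample(s) missing from sample sheet: %s",
                 paste(missing, collapse = ", ")))
  idx <- match(colnames(values), sampleSheet$sample_id)
  cd <- DataFrame(coc_id = as.character(sampleSheet$coc_id[idx]),
                  compartment = as.character(sampleSheet$compartment[idx]),
                  row.names = colnames(values))
  se <- SummarizedExperiment(assays = list(expr = values), colData = cd)
  metadata(se)$scale <- scale
  new("COCExperiment", se)
}

#' @describeIn COCExperiment COC identifier of each sample.
#' @param x a COCExperiment
#' @export
cocId <- function(x) as.character(colData(x)$coc_id)

#' @describeIn COCExperiment compartment label of each sample.
#' @export
compartmentOf <- function(x) as.character(colData(x)$compartment)

#' @describeIn COCExperiment the expression matrix (genes x samples).
#' @export
exprValues <- function(x) assay(x, 1L)

#' @describeIn COCExperiment the value scale, "fpkm" or "log2".
#' @export
exprScale <- function(x) metadata(x)$scale

setMethod("show", "COCExperiment", function(object) {
  cat(sprintf("COCExperiment: %d genes x %d samples (%s scale)\n",
              nrow(object), ncol(object), exprScale(object)))
  tab <- table(compartmentOf(object))
  cat("  compartments:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  COCs: %d\n", length(unique(cocId(object)))))
})

#' LinkedCompartmentPair: two compartments aligned on the COC index
#'
#' Holds two gene x COC expression matrices (log2(FPKM+1)) from two
#' different compartments of the same complexes, with columns aligned so
#' that column j of each matrix comes from the same COC. This is the
#' unit on which cross-compartment correlation and its permutation null
#' are computed.
#'
#' @slot a numeric matrix, genes (compartment A) x COCs.
#' @slot b numeric matrix, genes (compartment B) x COCs.
#' @slot cocIds character, shared ordered COC identifiers.
#' @slot compartments character(2), the compartment labels of a and b.
#' @seealso [linkCompartments()], [crossCompartmentBicor()]
#' @export
setClass("LinkedCompartmentPair",
         representation(a = "matrix", b = "matrix",
                        cocIds = "character", compartments = "character"))

setValidity("LinkedCompartmentPair", function(object) {
  msg <- character(0)
  J <- length(object@cocIds)
  if (ncol(object@a) != J || ncol(object@b) != J)
    msg <- c(msg, "both matrices must have one column per COC")
  if (!identical(colnames(object@a), object@cocIds) ||
      !identical(colnames(object@b), object@cocIds))
    msg <- c(msg, "matrix columns must be named by and ordered as cocIds")
  if (length(object@compartments) != 2L)
    msg <- c(msg, "exactly two compartment labels required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LinkedCompartmentPair", function(object) {
  cat(sprintf("LinkedCompartmentPair: %s (%d genes) vs %s (%d genes), J = %d COCs\n",
              object@compartments[1], nrow(object@a),
              object@compartments[2], nrow(object@b),
              length(object@cocIds)))
})

#' @describeIn LinkedCompartmentPair number of shared COCs.
#' @param x a LinkedCompartmentPair
#' @export
nCocs <- function(x) length(x@cocIds)

#' BicorResult: cross-compartment biweight midcorrelation matrix
#'
#' Gene-pair biweight midcorrelations between two compartments. Rows are
#' compartment-A genes, columns compartment-B genes. \code{fallbackA}/
#' \code{fallbackB} flag genes whose median absolute deviation was zero,
#' for which the Pearson fallback was used (default mode) or the whole
#' row/column set to NA (strict mode).
#'
#' @slot values numeric matrix in [-1, 1] (NA where excluded).
#' @slot fallbackA,fallbackB logical per-gene flags.
#' @slot nCocs integer, number of COCs the correlations are based on.
#' @slot compartments character(2).
#' @export
setClass("BicorResult",
         representation(values = "matrix", fallbackA = "logical",
                        fallbackB = "logical", nCocs = "integer",
                        compartments = "character"))

setMethod("show", "BicorResult", function(object) {
  v <- object@values
  cat(sprintf("BicorResult: %d x %d gene pairs over %d COCs (%s vs %s)\n",
              nrow(v), ncol(v), object@nCocs,
              object@compartments[1], object@compartments[2]))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  |bicor| > 0.85: %d pairs; range [%.3f, %.3f]\n",
                sum(abs(fin) > 0.85), min(fin), max(fin)))
  nf <- sum(object@fallbackA) + sum(object@fallbackB)
  if (nf) cat(sprintf("  %d gene(s) used the zero-MAD fallback\n", nf))
})

#' @describeIn BicorResult the correlation matrix.
#' @param x a BicorResult
#' @export
bicorValues <- function(x) x@values

#' PPIEdgeSet: deduplicated protein-protein interaction edges
#'
#' Unordered gene-level interaction edges in the target-species gene
#' namespace, with provenance (source databases and species) retained
#' per edge.
#'
#' @slot edges data.frame with columns gene_a, gene_b (gene_a <= gene_b
#'   lexicographically), sources, species, n_sources.
#' @slot droppedUnmapped integer, raw rows dropped because an endpoint
#'   had no homology mapping.
#' @slot droppedSelf integer, self-edges dropped after mapping.
#' @export
setClass("PPIEdgeSet",
         representation(edges = "data.frame", droppedUnmapped = "integer",
                        droppedSelf = "integer"))

setMethod("show", "PPIEdgeSet", function(object) {
  cat(sprintf("PPIEdgeSet: %d unique edges over %d genes\n",
              nrow(object@edges),
              length(unique(c(object@edges$gene_a, object@edges$gene_b)))))
  cat(sprintf("  dropped: %d unmapped, %d self-edges\n",
              object@droppedUnmapped, object@droppedSelf))
})

#' @describeIn PPIEdgeSet the edge table.
#' @param x a PPIEdgeSet
#' @export
ppiEdges <- function(x) x@edges
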