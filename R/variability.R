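## Highly-variable-gene detection via the log-normal coefficient of
## variation: CV = sqrt(exp(x^2) - 1), where x is the per-gene sample
## standard deviation of log2(FPKM+1). The formula is the log-normal CV
## identity evaluated, as printed convention here, directly on the
## log2-scale SD; `naturalLog = TRUE` rescales x by ln(2) first.

#' Genes detected in every sample of a compartment
#'
#' @param x a [COCExperiment-class] on the FPKM scale.
#' @param compartment compartment label.
#' @param minFpkm detection threshold; the default 0 means any non-zero
#'   FPKM counts as detected (strict inequality).
#' @return The compartment submatrix restricted to genes with
#'   FPKM > minFpkm in every sample.
#' @export
detectedInAll <- function(x, compartment, minFpkm = 0) {
  sub <- subsetCompartment(x, compartment)
  v <- exprValues(sub)
  sub[rowSums(v > minFpkm) == ncol(sub), ]
}

#' Per-gene coefficient of variation on the log scale
#'
#' For each gene, \code{sd_log} is the sample standard deviation (n - 1
#' denominator) of log2(FPKM+1) and \eqn{CV = \sqrt{e^{x^2} - 1}} with
#' x = sd_log. Requires every value to be strictly positive ("detected
#' in all samples"); use [detectedInAll()] first.
#'
#' @param x FPKM matrix (genes x samples of one compartment) or a
#'   single-compartment FPKM-scale [COCExperiment-class].
#' @param naturalLog if TRUE, convert x to the natural-log scale
#'   (multiply by ln 2) before applying the identity; default FALSE.
#' @return data.frame (class \code{CvTable}) with gene_id, sd_log, cv,
#'   percentile_rank (in [0, 100]).
#' @examples
#' m <- matrix(2^rnorm(80, 3), 5, 16,
#'             dimnames = list(paste0("g", 1:5), NULL))
#' perGeneCv(m)
#' @export
perGeneCv <- function(x, naturalLog = FALSE) {
  if (is(x, "COCExperiment")) {
    if (exprScale(x) != "fpkm") stop("x must be on the FPKM scale")
    x <- exprValues(x)
  }
  if (!is.matrix(x) || ncol(x) < 2L)
    stop("x must be a genes x samples matrix with >= 2 samples")
  if (any(x <= 0))
    stop("perGeneCv requires FPKM > 0 in every sample; restrict with detectedInAll()")
  lg <- log2(x + 1)
  sdLog <- apply(lg, 1L, stats::sd)
  xx <- if (naturalLog) sdLog * log(2) else sdLog
  cv <- sqrt(exp(xx^2) - 1)
  pr <- 100 * rank(cv, ties.method = "max") / length(cv)
  out <- data.frame(gene_id = rownames(x), sd_log = sdLog, cv = cv,
                    percentile_rank = pr, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("CvTable", "data.frame")
  out
}

#' Top variable genes above a CV percentile
#'
#' The cutoff is the nearest-rank percentile of the CV distribution
#' (sorted CV at index ceiling(p/100 * n)); genes with CV strictly
#' above the cutoff are selected, so when all CVs tie the selection is
#' empty.
#'
#' @param cvTable a \code{CvTable} from [perGeneCv()].
#' @param percentile percentile in (0, 100), e.g. 90 or 95.
#' @return list(genes = character vector, cutoff = the CV cutoff value).
#' @export
topVariableGenes <- function(cvTable, percentile = 90) {
  if (nrow(cvTable) == 0L) stop("empty CV table")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  cv <- sort(cvTable$cv)
  idx <- ceiling(percentile / 100 * length(cv))
  cutoff <- cv[idx]
  list(genes = cvTable$gene_id[cvTable$cv > cutoff], cutoff = cutoff)
}
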