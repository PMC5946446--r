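## Readers, writers and the expression-presence filter shared by all
## downstream stages. All tabular formats are tab-delimited UTF-8 with a
## header row; files are written with deterministic row order.

readTsvChecked <- function(path, requiredCols, colClasses = NA) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) stop(sprintf("empty file (no header): %s", path))
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("malformed row in %s at line %d: expected %d fields, found %d",
                 path, bad[1L], nf[1L], nf[bad[1L]]))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = colClasses)
  miss <- setdiff(requiredCols, colnames(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  df
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an FPKM expression matrix and its sample sheet
#'
#' The matrix file is TSV with gene ids in the first column and one
#' column per sample; the sample sheet is TSV with columns
#' \code{sample_id}, \code{coc_id}, \code{compartment}. Duplicate gene
#' or sample ids, samples absent from the sheet, unknown compartment
#' labels and negative values are hard errors.
#'
#' @param path path to the expression TSV.
#' @param sampleSheetPath path to the sample sheet TSV.
#' @return A [COCExperiment-class].
#' @export
readExpressionMatrix <- function(path, sampleSheetPath) {
  df <- readTsvChecked(path, character(0))
  if (ncol(df) < 2L) stop("expression matrix needs a gene id column and >= 1 sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric or missing expression values")
  rownames(m) <- genes
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id(s) in expression matrix header")
  sheet <- readTsvChecked(sampleSheetPath,
                          c("sample_id", "coc_id", "compartment"),
                          colClasses = "character")
  COCExperiment(m, sheet)
}

#' Write a COCExperiment to TSV
#'
#' Writes the expression matrix (genes in lexicographic order) and the
#' sample sheet as two TSV files that [readExpressionMatrix()] reads
#' back.
#'
#' @param x a [COCExperiment-class].
#' @param path expression matrix output path.
#' @param sampleSheetPath sample sheet output path.
#' @return Invisibly, \code{c(path, sampleSheetPath)}.
#' @export
writeExpressionMatrix <- function(x, path, sampleSheetPath) {
  m <- exprValues(x)
  m <- m[order(rownames(m)), , drop = FALSE]
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
  sheet <- data.frame(sample_id = colnames(x), coc_id = cocId(x),
                      compartment = compartmentOf(x),
                      stringsAsFactors = FALSE)
  writeTsv(sheet, sampleSheetPath)
  invisible(c(path, sampleSheetPath))
}

#' Restrict a COCExperiment to one compartment
#'
#' @param x a [COCExperiment-class].
#' @param compartment one of \code{"oocyte"}, \code{"innerCC"},
#'   \code{"outerCC"}.
#' @return The subset with only that compartment's samples.
#' @export
subsetCompartment <- function(x, compartment) {
  compartment <- match.arg(compartment, COC_COMPARTMENTS)
  keep <- compartmentOf(x) == compartment
  if (!any(keep)) stop(sprintf("no samples in compartment '%s'", compartment))
  x[, keep]
}

#' Presence filter: genes expressed above a threshold in enough samples
#'
#' Retains genes whose FPKM is strictly greater than \code{minFpkm} in
#' at least \code{minSamples} samples of one compartment (the rule used
#' to call a gene "expressed" in that compartment). The threshold is
#' strict: a value of exactly \code{minFpkm} does not count.
#'
#' @param x a [COCExperiment-class] on the FPKM scale.
#' @param compartment compartment to filter in; may be omitted if
#'   \code{x} already contains a single compartment.
#' @param minFpkm FPKM presence threshold (default 0.5, strict).
#' @param minSamples minimum number of samples above threshold
#'   (default 8).
#' @return A list with \code{experiment} (the retained submatrix,
#'   restricted to the compartment) and \code{genes} (character vector
#'   of expressed gene ids).
#' @examples
#' sim <- simulateCocDataset(cocSimConfig(nGenes = 30, seed = 1))
#' fe <- filterExpressed(sim$experiment, "oocyte")
#' length(fe$genes)
#' @export
filterExpressed <- function(x, compartment = NULL, minFpkm = 0.5,
                            minSamples = 8L) {
  if (!is(x, "COCExperiment")) stop("x must be a COCExperiment")
  if (exprScale(x) != "fpkm")
    stop("presence filtering is defined on the FPKM scale; filter before logTransform")
  if (is.null(compartment)) {
    comps <- unique(compartmentOf(x))
    if (length(comps) != 1L)
      stop("x spans several compartments; supply `compartment`")
    compartment <- comps
  }
  sub <- subsetCompartment(x, compartment)
  if (minSamples > ncol(sub))
    stop(sprintf("minSamples (%d) exceeds the %d samples in compartment '%s'",
                 minSamples, ncol(sub), compartment))
  v <- exprValues(sub)
  keep <- rowSums(v > minFpkm) >= minSamples
  list(experiment = sub[keep, ], genes = rownames(sub)[keep])
}

#' log2(FPKM + 1) transform
#'
#' @param x a [COCExperiment-class] on the FPKM scale.
#' @return The same object with values log2(v + 1) and scale "log2".
#' @export
logTransform <- function(x) {
  if (!is(x, "COCExperiment")) stop("x must be a COCExperiment")
  if (exprScale(x) != "fpkm") stop("already log-transformed")
  assay(x, 1L) <- log2(exprValues(x) + 1)
  metadata(x)$scale <- "log2"
  validObject(x)
  x
}

#' Align two compartments of the same COCs for cross-correlation
#'
#' Applies the presence filter in each compartment, log-transforms, and
#' aligns the two matrices column-wise on the COCs present in both
#' compartments.
#'
#' @param x a [COCExperiment-class] (FPKM scale) covering both
#'   compartments.
#' @param compartmentA,compartmentB the two compartments.
#' @param minFpkm,minSamples presence-filter parameters (see
#'   [filterExpressed()]).
#' @return A [LinkedCompartmentPair-class].
#' @export
linkCompartments <- function(x, compartmentA, compartmentB,
                             minFpkm = 0.5, minSamples = 8L) {
  if (compartmentA == compartmentB)
    stop("the two compartments must differ")
  fa <- filterExpressed(x, compartmentA, minFpkm, minSamples)
  fb <- filterExpressed(x, compartmentB, minFpkm, minSamples)
  la <- logTransform(fa$experiment)
  lb <- logTransform(fb$experiment)
  shared <- intersect(cocId(la), cocId(lb))
  if (length(shared) < 3L)
    stop("fewer than 3 COCs shared between the two compartments")
  shared <- sort(shared)
  ma <- exprValues(la)[, match(shared, cocId(la)), drop = FALSE]
  mb <- exprValues(lb)[, match(shared, cocId(lb)), drop = FALSE]
  colnames(ma) <- colnames(mb) <- shared
  new("LinkedCompartmentPair", a = ma, b = mb, cocIds = shared,
      compartments = c(compartmentA, compartmentB))
}

#' Read protein-protein interaction edge lists
#'
#' Each file is TSV with columns \code{id_a}, \code{id_b},
#' \code{source_db}, \code{species}; one edge per row. Edges are
#' unordered: the canonical key pairs the lexicographically smaller id
#' first.
#'
#' @param paths character vector of file paths.
#' @return data.frame with columns id_a, id_b, source_db, species,
#'   key_a, key_b (canonical unordered key).
#' @export
readPpiEdges <- function(paths) {
  tabs <- lapply(paths, function(p)
    readTsvChecked(p, c("id_a", "id_b", "source_db", "species"),
                   colClasses = "character"))
  df <- do.call(rbind, tabs)
  if (is.null(df))
    df <- data.frame(id_a = character(0), id_b = character(0),
                     source_db = character(0), species = character(0))
  df$key_a <- pmin(df$id_a, df$id_b)
  df$key_b <- pmax(df$id_a, df$id_b)
  df
}

#' Read a homology (ortholog) mapping table
#'
#' TSV with columns \code{foreign_id}, \code{target_id}. A foreign id
#' may map to several target ids; all rows are retained (one-to-many
#' expansion happens in [integratePpi()]).
#'
#' @param path file path.
#' @return data.frame(foreign_id, target_id), duplicates removed.
#' @export
readHomologyMap <- function(path) {
  df <- readTsvChecked(path, c("foreign_id", "target_id"),
                       colClasses = "character")
  unique(df[, c("foreign_id", "target_id")])
}

#' Read gene-to-GO-term annotations
#'
#' TSV with columns \code{gene_id}, \code{term_id}. A \code{term_name}
#' column is carried through if present.
#'
#' @param path file path.
#' @return data.frame of annotations, duplicates removed.
#' @export
readGoAnnotations <- function(path) {
  df <- readTsvChecked(path, c("gene_id", "term_id"),
                       colClasses = "character")
  unique(df)
}

#' Read gene lengths
#'
#' TSV with columns \code{gene_id}, \code{length} (bp, positive
#' integers).
#'
#' @param path file path.
#' @return data.frame(gene_id, length).
#' @export
readGeneLengths <- function(path) {
  df <- readTsvChecked(path, c("gene_id", "length"))
  df$gene_id <- as.character(df$gene_id)
  df$length <- as.numeric(df$length)
  if (anyNA(df$length) || any(df$length <= 0))
    stop("gene lengths must be positive numbers")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in lengths table")
  df[, c("gene_id", "length")]
}
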