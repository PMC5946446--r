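## Synthetic cumulus-oocyte-complex data with known planted structure:
## a Gaussian copula on latent per-gene normals gives log2(FPKM+1)
## values whose cross-compartment correlations and within-compartment
## modules are planted by construction; a preferential-attachment graph
## with GO-flagged receptors emulates the PPI road map; a length-biased
## selection emulates the bias the Wallenius enrichment corrects.

## Child seeds: one global seed expands deterministically per stage so
## stages are independently reproducible.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Configuration for the synthetic COC dataset
#'
#' Defaults emulate the study conditions: 16 COCs, three compartments
#' per COC, log2(FPKM+1) marginals with per-gene mean and SD, random
#' per-compartment presence, and optional planted cross-compartment
#' pairs and within-compartment modules.
#'
#' @param nCocs number of COCs (>= 3; default 16).
#' @param nGenes number of genes in the shared universe (default 300).
#' @param plantedPairs data.frame(gene_a, compartment_a, gene_b,
#'   compartment_b, rho) of latent cross-compartment correlations
#'   (|rho| <= 1), or NULL.
#' @param plantedModules list of list(compartment, genes, r) planted
#'   co-expression modules (within-module latent correlation r), or
#'   NULL.
#' @param presenceProb probability a gene is present in a compartment:
#'   a single number, or one value per compartment (oocyte, innerCC,
#'   outerCC). The default (0.52, 0.31, 0.53) mirrors the detection
#'   fractions typical of single-COC transcriptomes, where the inner
#'   cumulus layer yields the sparsest profiles. Genes referenced by
#'   planted structure are forced present in the relevant compartment.
#' @param muRange,sdRange ranges of the per-gene mean and SD of
#'   log2(FPKM+1). Defaults (2-6 and 0.4-1.0) put typical genes well
#'   above the presence threshold with log-scale dispersion giving
#'   median coefficients of variation near the 0.7-0.8 seen in
#'   single-COC data.
#' @param seed global integer seed.
#' @return list of class \code{cocSimConfig}.
#' @export
cocSimConfig <- function(nCocs = 16L, nGenes = 300L, plantedPairs = NULL,
                         plantedModules = NULL,
                         presenceProb = c(0.52, 0.31, 0.53),
                         muRange = c(2, 6), sdRange = c(0.4, 1.0),
                         seed = 1L) {
  if (nCocs < 3L) stop("nCocs must be >= 3")
  if (!length(presenceProb) %in% c(1L, 3L))
    stop("presenceProb must have length 1 or 3")
  if (length(presenceProb) == 1L) presenceProb <- rep(presenceProb, 3L)
  if (any(presenceProb < 0 | presenceProb > 1))
    stop("presenceProb must lie in [0, 1]")
  if (!is.null(plantedPairs)) {
    need <- c("gene_a", "compartment_a", "gene_b", "compartment_b", "rho")
    if (!all(need %in% colnames(plantedPairs)))
      stop("plantedPairs needs columns ", paste(need, collapse = ", "))
    if (any(abs(plantedPairs$rho) > 1)) stop("|rho| must be <= 1")
  }
  structure(list(nCocs = as.integer(nCocs), nGenes = as.integer(nGenes),
                 plantedPairs = plantedPairs,
                 plantedModules = plantedModules,
                 presenceProb = presenceProb, muRange = muRange,
                 sdRange = sdRange, seed = as.integer(seed)),
            class = "cocSimConfig")
}

#' Simulate a COC triplet dataset with planted structure
#'
#' Latent standard normals per (gene, compartment) across the COC index
#' carry the planted correlations: a planted pair's compartment-B gene
#' is \eqn{z_b = \rho z_a + \sqrt{1-\rho^2}\,\epsilon}; a planted
#' module's members share a common factor at the stated within-module
#' correlation. log2(FPKM+1) values are \eqn{\mu_g + \sigma_g z}
#' (floored at 0), back-transformed to FPKM via \eqn{2^v - 1}. Genes
#' absent in a compartment are 0 in all its samples. Fixed seed gives
#' bit-identical output.
#'
#' @param config a [cocSimConfig()].
#' @return list(experiment = [COCExperiment-class] covering the three
#'   compartments, truth = list(plantedPairs, modules, presence, mu,
#'   sigma)).
#' @examples
#' pp <- data.frame(gene_a = "g0001", compartment_a = "oocyte",
#'                  gene_b = "g0002", compartment_b = "outerCC",
#'                  rho = 0.95)
#' sim <- simulateCocDataset(cocSimConfig(nGenes = 50, plantedPairs = pp,
#'                                        seed = 7))
#' sim$experiment
#' @export
simulateCocDataset <- function(config) {
  stopifnot(inherits(config, "cocSimConfig"))
  J <- config$nCocs
  G <- config$nGenes
  genes <- sprintf("g%04d", seq_len(G))
  comps <- COC_COMPARTMENTS

  set.seed(childSeed(config$seed, 1L))
  presence <- matrix(stats::runif(G * 3), G, 3,
                     dimnames = list(genes, comps))
  presence <- sweep(presence, 2L, config$presenceProb, `<`)
  pp <- config$plantedPairs
  if (!is.null(pp)) {
    for (i in seq_len(nrow(pp))) {
      for (side in c("a", "b")) {
        g <- pp[[paste0("gene_", side)]][i]
        cmp <- pp[[paste0("compartment_", side)]][i]
        if (!g %in% genes)
          stop(sprintf("planted pair references unknown gene %s", g))
        if (!cmp %in% comps)
          stop(sprintf("unknown compartment %s in planted pair", cmp))
        presence[g, cmp] <- TRUE
      }
    }
  }
  for (mod in config$plantedModules) {
    if (!all(mod$genes %in% genes))
      stop("planted module references unknown gene(s)")
    presence[mod$genes, mod$compartment] <- TRUE
  }

  set.seed(childSeed(config$seed, 2L))
  mu <- stats::runif(G, config$muRange[1], config$muRange[2])
  sigma <- stats::runif(G, config$sdRange[1], config$sdRange[2])
  names(mu) <- names(sigma) <- genes

  ## latent normals per compartment: genes x J
  set.seed(childSeed(config$seed, 3L))
  z <- lapply(comps, function(cmp)
    matrix(stats::rnorm(G * J), G, J, dimnames = list(genes, NULL)))
  names(z) <- comps

  ## planted modules: shared factor within a compartment
  for (mod in config$plantedModules) {
    r <- mod$r
    f <- stats::rnorm(J)
    for (g in mod$genes)
      z[[mod$compartment]][g, ] <- sqrt(r) * f +
        sqrt(1 - r) * stats::rnorm(J)
  }
  ## planted cross-compartment pairs: B regressed on A
  if (!is.null(pp)) {
    for (i in seq_len(nrow(pp))) {
      za <- z[[pp$compartment_a[i]]][pp$gene_a[i], ]
      rho <- pp$rho[i]
      z[[pp$compartment_b[i]]][pp$gene_b[i], ] <-
        rho * za + sqrt(1 - rho^2) * stats::rnorm(J)
    }
  }

  cocIds <- sprintf("coc%02d", seq_len(J))
  mats <- lapply(comps, function(cmp) {
    lg <- sweep(z[[cmp]], 1L, sigma, `*`)
    lg <- sweep(lg, 1L, mu, `+`)
    lg[lg < 0] <- 0
    fpkm <- 2^lg - 1
    fpkm[!presence[, cmp], ] <- 0
    colnames(fpkm) <- paste(cocIds, cmp, sep = "_")
    fpkm
  })
  names(mats) <- comps
  values <- do.call(cbind, mats)
  sheet <- data.frame(sample_id = colnames(values),
                      coc_id = rep(cocIds, times = 3L),
                      compartment = rep(comps, each = J),
                      stringsAsFactors = FALSE)
  experiment <- COCExperiment(values, sheet)
  truth <- list(plantedPairs = pp, modules = config$plantedModules,
                presence = presence, mu = mu, sigma = sigma,
                seed = config$seed)
  list(experiment = experiment, truth = truth)
}

#' Simulate a preferential-attachment PPI network with receptors
#'
#' Grows an undirected Barabasi-Albert graph (each new node attaches
#' \code{edgesPerNewNode} edges preferentially to high-degree nodes),
#' whose degree distribution is approximately scale-free. A fraction of
#' nodes is annotated with the GO term "receptor activity"; the rest
#' get decoy terms.
#'
#' @param nNodes number of genes (>= edgesPerNewNode + 1).
#' @param edgesPerNewNode edges added per new node (default 2).
#' @param receptorFraction fraction of genes flagged as receptors.
#' @param nDecoyTerms decoy GO terms spread over non-receptor genes.
#' @param genes optional character vector of gene ids to build the
#'   network on (length >= nNodes; first nNodes used), so the PPI graph
#'   can share the expression data's gene universe. Default: its own
#'   \code{p0001...} namespace.
#' @param seed integer seed.
#' @return list(edges = data.frame(id_a, id_b, source_db, species),
#'   receptors = character, go = data.frame(gene_id, term_id)).
#' @export
simulatePpiNetwork <- function(nNodes, edgesPerNewNode = 2L,
                               receptorFraction = 0.1, nDecoyTerms = 5L,
                               genes = NULL, seed = 1L) {
  if (nNodes < edgesPerNewNode + 1L)
    stop("nNodes must be >= edgesPerNewNode + 1")
  if (receptorFraction < 0 || receptorFraction > 1)
    stop("receptorFraction must lie in [0, 1]")
  set.seed(childSeed(seed, 11L))
  g <- igraph::sample_pa(nNodes, m = edgesPerNewNode, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (is.null(genes)) {
    genes <- sprintf("p%04d", seq_len(nNodes))
  } else {
    if (length(genes) < nNodes) stop("need at least nNodes gene ids")
    genes <- genes[seq_len(nNodes)]
  }
  edges <- data.frame(id_a = genes[el[, 1L]], id_b = genes[el[, 2L]],
                      source_db = "simdb", species = "cow",
                      stringsAsFactors = FALSE)
  nRec <- round(receptorFraction * nNodes)
  receptors <- if (nRec > 0) sort(sample(genes, nRec)) else character(0)
  others <- setdiff(genes, receptors)
  go <- rbind(
    if (length(receptors))
      data.frame(gene_id = receptors, term_id = "receptor activity",
                 stringsAsFactors = FALSE),
    if (length(others))
      data.frame(gene_id = others,
                 term_id = sprintf("decoy_term_%02d",
                                   sample.int(nDecoyTerms, length(others),
                                              replace = TRUE)),
                 stringsAsFactors = FALSE))
  list(edges = edges, receptors = receptors, go = go)
}

#' Simulate a GO universe with a planted enriched term and length bias
#'
#' Genes receive lognormal lengths and random term memberships; an
#' "interesting" set is drawn with per-gene selection probability
#' increased (on the log-odds scale) for members of the enriched terms
#' and, with slope \code{lengthBias}, for long genes — the technical
#' artifact the PWF correction removes.
#'
#' @param nGenes number of genes.
#' @param nTerms number of GO terms.
#' @param enrichedTerms character vector of term ids (subset of the
#'   generated terms \code{term_01..}) to enrich; may be empty.
#' @param lengthBias log-odds slope per SD of log length (>= 0).
#' @param oddsRatio selection odds multiplier for enriched-term members
#'   (default 1 = no enrichment).
#' @param termSize genes per term (default 50).
#' @param baseProb baseline selection probability (default 0.1).
#' @param seed integer seed.
#' @return list(annotation = data.frame(gene_id, term_id),
#'   lengths = data.frame(gene_id, length), interesting = character,
#'   enriched = character).
#' @export
simulateGoUniverse <- function(nGenes, nTerms, enrichedTerms = character(0),
                               lengthBias = 0, oddsRatio = 1,
                               termSize = 50L, baseProb = 0.1, seed = 1L) {
  terms <- sprintf("term_%02d", seq_len(nTerms))
  if (!all(enrichedTerms %in% terms))
    stop("enrichedTerms must be among the generated term ids")
  set.seed(childSeed(seed, 21L))
  genes <- sprintf("g%05d", seq_len(nGenes))
  len <- round(exp(stats::rnorm(nGenes, mean = 7.3, sd = 0.6)))
  len[len < 100] <- 100
  annotation <- do.call(rbind, lapply(terms, function(t)
    data.frame(gene_id = sample(genes, min(termSize, nGenes)),
               term_id = t, stringsAsFactors = FALSE)))
  inEnriched <- genes %in% annotation$gene_id[annotation$term_id %in%
                                                enrichedTerms]
  lz <- as.numeric(scale(log(len)))
  eta <- stats::qlogis(baseProb) + log(oddsRatio) * inEnriched +
    lengthBias * lz
  p <- stats::plogis(eta)
  interesting <- genes[stats::runif(nGenes) < p]
  list(annotation = annotation,
       lengths = data.frame(gene_id = genes, length = len,
                            stringsAsFactors = FALSE),
       interesting = interesting, enriched = enrichedTerms)
}
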