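## End-to-end orchestration: presence filter -> CV -> cross-compartment
## bicor + eFDR -> two-dimensional clustering -> within-compartment TOM
## modules -> ligand-receptor road map -> enrichment, from one config,
## with per-stage child seeds and a JSON run manifest.

#' Pipeline configuration
#'
#' Validates the full-run parameters before any computation.
#'
#' @param seed global integer seed.
#' @param simulate a [cocSimConfig()] for synthetic input, or NULL when
#'   \code{expressionPath}/\code{sampleSheetPath} are given.
#' @param expressionPath,sampleSheetPath input TSVs (ignored when
#'   \code{simulate} is set).
#' @param minFpkm,minSamples presence-filter parameters.
#' @param B permutation count for the eFDR (>= 1).
#' @param thresholds eFDR threshold grid.
#' @param bicorMin,efdrMax pair-selection gate.
#' @param beta soft power for within-compartment adjacency.
#' @param cutHeights tree-cut heights for within-compartment modules.
#' @param minModuleSize minimum module size.
#' @param cvPercentile top-variable-gene percentile.
#' @param nBootstrap scale-free bootstrap count.
#' @param ppi optional list(edges, go) for the road-map stage (e.g.
#'   from [simulatePpiNetwork()]); NULL skips that stage.
#' @param goUniverse optional list(annotation, lengths) for enrichment
#'   of modules; NULL skips enrichment.
#' @param maxGenesPerCompartment cap on genes entering the
#'   within-compartment network stage (highest-variance genes kept).
#' @return list of class \code{cocRunConfig}.
#' @export
cocRunConfig <- function(seed = 1L, simulate = NULL, expressionPath = NULL,
                         sampleSheetPath = NULL, minFpkm = 0.5,
                         minSamples = 8L, B = 1000L,
                         thresholds = seq(0.5, 0.95, by = 0.05),
                         bicorMin = 0.85, efdrMax = 0.001, beta = 12L,
                         cutHeights = NULL, minModuleSize = 10L,
                         cvPercentile = 90, nBootstrap = 200L,
                         ppi = NULL, goUniverse = NULL,
                         maxGenesPerCompartment = 500L) {
  if (B < 1L) stop("B must be >= 1")
  if (is.null(simulate) &&
      (is.null(expressionPath) || is.null(sampleSheetPath)))
    stop("either `simulate` or expression/sample-sheet paths are required")
  if (!is.null(expressionPath) && !is.null(sampleSheetPath) &&
      is.null(simulate)) {
    for (p in c(expressionPath, sampleSheetPath))
      if (!file.exists(p)) stop(sprintf("input path does not exist: %s", p))
  }
  if (!any(abs(thresholds - bicorMin) < 1e-9))
    stop("bicorMin must be on the eFDR threshold grid")
  structure(as.list(environment()), class = "cocRunConfig")
}

stageMessage <- function(stage, seed, fmt, ...) {
  message(sprintf("[%s seed=%d] %s", stage, seed, sprintf(fmt, ...)))
}

#' Run the whole analysis from a configuration
#'
#' Executes simulate/read -> filter -> CV -> cross-compartment bicor +
#' eFDR + pair selection + two-dimensional clustering (oocyte-innerCC
#' and oocyte-outerCC independently) -> within-compartment TOM modules
#' -> ligand-receptor classification and topology -> module enrichment,
#' writing every stage's table under \code{outDir} and a manifest JSON
#' with seeds, parameters and file checksums. A stage failure aborts
#' with the stage name; tables already written persist.
#'
#' @param config a [cocRunConfig()].
#' @param outDir output directory (created if needed).
#' @return The manifest, invisibly also written to
#'   \code{outDir/manifest.json}.
#' @export
runCocPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "cocRunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- "init"
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    writeTsv(df, p)
    outputs <<- c(outputs, p)
    p
  }
  res <- tryCatch({
    stage <- "input"
    sd0 <- childSeed(config$seed, 100L)
    if (!is.null(config$simulate)) {
      simCfg <- config$simulate
      simCfg$seed <- childSeed(config$seed, 101L)
      sim <- simulateCocDataset(simCfg)
      x <- sim$experiment
      stageMessage(stage, sd0, "simulated %d genes x %d samples",
                   nrow(x), ncol(x))
    } else {
      x <- readExpressionMatrix(config$expressionPath,
                                config$sampleSheetPath)
      stageMessage(stage, sd0, "read %d genes x %d samples",
                   nrow(x), ncol(x))
    }

    stage <- "filter"
    comps <- intersect(COC_COMPARTMENTS, unique(compartmentOf(x)))
    filtered <- lapply(comps, function(cmp)
      filterExpressed(x, cmp, config$minFpkm, config$minSamples))
    names(filtered) <- comps
    expressed <- lapply(filtered, `[[`, "genes")
    emit(data.frame(compartment = rep(comps, lengths(expressed)),
                    gene_id = unlist(expressed, use.names = FALSE)),
         "expressed_genes.tsv")
    stageMessage(stage, sd0, "expressed genes: %s",
                 paste(sprintf("%s=%d", comps, lengths(expressed)),
                       collapse = ", "))

    stage <- "cv"
    cvTables <- list()
    for (cmp in intersect(c("oocyte", "outerCC"), comps)) {
      det <- detectedInAll(x, cmp)
      if (nrow(det) < 2L) next
      ct <- perGeneCv(det)
      cvTables[[cmp]] <- ct
      emit(ct, sprintf("cv_%s.tsv", cmp))
      tv <- topVariableGenes(ct, config$cvPercentile)
      emit(data.frame(gene_id = tv$genes, cutoff = tv$cutoff),
           sprintf("top_variable_%s.tsv", cmp))
      stageMessage(stage, sd0, "%s: %d genes detected in all, median CV %.3f",
                   cmp, nrow(ct), stats::median(ct$cv))
    }

    stage <- "bicor"
    pairings <- list(c("oocyte", "innerCC"), c("oocyte", "outerCC"))
    pairings <- Filter(function(p) all(p %in% comps), pairings)
    crossResults <- list()
    for (i in seq_along(pairings)) {
      pr <- pairings[[i]]
      key <- paste(pr, collapse = "_")
      lp <- linkCompartments(x, pr[1], pr[2], config$minFpkm,
                             config$minSamples)
      obs <- crossCompartmentBicor(lp)
      nullObj <- permutedNullBicor(lp, config$B,
                                   seed = childSeed(config$seed, 200L + i))
      efdr <- efdrAtThresholds(obs, nullObj, config$thresholds)
      emit(efdr, sprintf("efdr_%s.tsv", key))
      pairsTab <- selectSignificantPairs(obs, efdr, config$bicorMin,
                                         config$efdrMax)
      emit(pairsTab, sprintf("pairs_%s.tsv", key))
      stageMessage(stage, nullObj$seed,
                   "%s: %d significant pairs at |bicor| > %.2f (eFDR %.3g)",
                   key, nrow(pairsTab), config$bicorMin,
                   attr(pairsTab, "efdr"))
      crossResults[[key]] <- list(pair = lp, observed = obs, efdr = efdr,
                                  pairs = pairsTab)
      stage <- "cross_clusters"
      if (nrow(pairsTab) > 0L) {
        cc <- crossCompartmentClusters(pairsTab, obs,
                                       minSize = config$minModuleSize)
        emit(cc$blocks, sprintf("blocks_%s.tsv", key))
        emit(data.frame(gene_id = names(cc$modulesA$labels),
                        cluster = cc$modulesA$labels),
             sprintf("clusters_%s_%s.tsv", key, pr[1]))
        emit(data.frame(gene_id = names(cc$modulesB$labels),
                        cluster = cc$modulesB$labels),
             sprintf("clusters_%s_%s.tsv", key, pr[2]))
        crossResults[[key]]$clusters <- cc
      }
      stage <- "bicor"
    }

    stage <- "modules"
    moduleResults <- list()
    for (cmp in comps) {
      fx <- filtered[[cmp]]$experiment
      if (nrow(fx) < 3L) next
      lx <- logTransform(fx)
      v <- exprValues(lx)
      if (nrow(v) > config$maxGenesPerCompartment) {
        vr <- apply(v, 1L, stats::var)
        v <- v[order(-vr)[seq_len(config$maxGenesPerCompartment)], ,
               drop = FALSE]
      }
      A <- signedAdjacency(v, config$beta)
      tom <- tomSimilarity(A)
      D <- 1 - tom
      heights <- config$cutHeights
      if (is.null(heights)) heights <- stats::quantile(D[upper.tri(D)], 0.25)
      mods <- hierarchicalModules(D, heights, config$minModuleSize)
      m1 <- mods[[1L]]
      emit(data.frame(gene_id = names(m1$labels), cluster = m1$labels,
                      cut_height = m1$cutHeight),
           sprintf("modules_%s.tsv", cmp))
      moduleResults[[cmp]] <- m1
      stageMessage(stage, sd0, "%s: %d modules at height %.3f", cmp,
                   length(unique(m1$labels[m1$labels > 0])), m1$cutHeight)
    }

    stage <- "ligrec"
    ligrecResult <- NULL
    if (!is.null(config$ppi)) {
      emptyHom <- data.frame(foreign_id = character(0),
                             target_id = character(0))
      raw <- config$ppi$edges
      raw$key_a <- pmin(raw$id_a, raw$id_b)
      raw$key_b <- pmax(raw$id_a, raw$id_b)
      ppiSet <- integratePpi(raw, emptyHom)
      cand <- designateRoles(ppiSet, config$ppi$go)
      pres <- list(oocyte = expressed$oocyte,
                   CC = unique(c(expressed$innerCC, expressed$outerCC)))
      cls <- classifySignaling(cand, pres)
      emit(cls$pairs, "ligrec_pairs.tsv")
      emit(cls$summary, "ligrec_summary.tsv")
      exprGenes <- unique(c(pres$oocyte, pres$CC))
      e <- ppiEdges(ppiSet)
      eExpr <- e[e$gene_a %in% exprGenes & e$gene_b %in% exprGenes, ,
                 drop = FALSE]
      if (length(unique(c(eExpr$gene_a, eExpr$gene_b))) < 10L)
        eExpr <- e
      fitSeed <- childSeed(config$seed, 300L)
      fit <- fitScaleFree(eExpr, config$nBootstrap, seed = fitSeed)
      hubs <- hubSummary(eExpr)
      emit(data.frame(r_squared = fit$rSquared, slope = fit$slope,
                      p_value = fit$pValue, n_bootstrap = fit$nBootstrap,
                      hub_fraction = hubs$fraction),
           "ligrec_topology.tsv")
      ligrecResult <- list(ppi = ppiSet, candidates = cand,
                           classified = cls, fit = fit, hubs = hubs)
      stageMessage(stage, fitSeed,
                   "%d LR pairs; scale-free R^2 = %.2f (P = %.3g)",
                   nrow(cls$pairs), fit$rSquared, fit$pValue)
    }

    stage <- "enrichment"
    enrichment <- NULL
    if (!is.null(config$goUniverse) && length(moduleResults)) {
      cmp <- names(moduleResults)[1L]
      enrichment <- enrichAll(moduleResults[[cmp]],
                              config$goUniverse$annotation,
                              universe = expressed[[cmp]],
                              lengths = config$goUniverse$lengths)
      emit(enrichment, "module_enrichment.tsv")
      stageMessage(stage, sd0, "%d enrichment rows", nrow(enrichment))
    }

    list(filtered = filtered, cv = cvTables, cross = crossResults,
         modules = moduleResults, ligrec = ligrecResult,
         enrichment = enrichment)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  stage <- "manifest"
  manifest <- list(
    package = "cocnet",
    version = as.character(utils::packageVersion("cocnet")),
    seed = config$seed,
    parameters = list(minFpkm = config$minFpkm,
                      minSamples = config$minSamples, B = config$B,
                      thresholds = config$thresholds,
                      bicorMin = config$bicorMin, efdrMax = config$efdrMax,
                      beta = config$beta,
                      cvPercentile = config$cvPercentile,
                      nBootstrap = config$nBootstrap),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = res))
}
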