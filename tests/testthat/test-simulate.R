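test_that("same seed gives bit-identical simulated data", {
  cfg <- cocSimConfig(nGenes = 40, seed = 123)
  s1 <- simulateCocDataset(cfg)
  s2 <- simulateCocDataset(cfg)
  expect_identical(exprValues(s1$experiment), exprValues(s2$experiment))
  expect_identical(s1$truth$presence, s2$truth$presence)
  s3 <- simulateCocDataset(cocSimConfig(nGenes = 40, seed = 124))
  expect_false(identical(exprValues(s1$experiment),
                         exprValues(s3$experiment)))
})

test_that("simulated values respect presence flags and non-negativity", {
  sim <- simulateCocDataset(cocSimConfig(nGenes = 60, seed = 2,
                                         presenceProb = 0.5))
  v <- exprValues(sim$experiment)
  expect_true(all(v >= 0))
  for (cmp in c("oocyte", "innerCC", "outerCC")) {
    cols <- compartmentOf(sim$experiment) == cmp
    absent <- !sim$truth$presence[, cmp]
    expect_true(all(v[absent, cols] == 0))
  }
})

test_that("presence flags match the expression filter at high means", {
  sim <- simulateCocDataset(cocSimConfig(nGenes = 80, seed = 8,
                                         muRange = c(4, 6)))
  for (cmp in c("oocyte", "innerCC", "outerCC")) {
    fe <- filterExpressed(sim$experiment, cmp)
    expect_setequal(fe$genes,
                    rownames(sim$truth$presence)[sim$truth$presence[, cmp]])
  }
})

test_that("planted correlations carry through the copula back-transform", {
  # rho = 1: sample bicor only distorted by the monotone transform
  pp1 <- data.frame(gene_a = "g0001", compartment_a = "oocyte",
                    gene_b = "g0002", compartment_b = "outerCC", rho = 1)
  vals <- vapply(1:200, function(s) {
    sim <- simulateCocDataset(cocSimConfig(nGenes = 5, plantedPairs = pp1,
                                           seed = s, muRange = c(4, 6),
                                           presenceProb = 1))
    lp <- linkCompartments(sim$experiment, "oocyte", "outerCC")
    bicorValues(crossCompartmentBicor(lp))["g0001", "g0002"]
  }, 0)
  expect_true(all(vals > 0.95))

  # rank correlation converges to the planted value at large J
  pp2 <- data.frame(gene_a = "g0001", compartment_a = "oocyte",
                    gene_b = "g0002", compartment_b = "innerCC", rho = 0.8)
  sim <- simulateCocDataset(cocSimConfig(nCocs = 500, nGenes = 5,
                                         plantedPairs = pp2, seed = 4,
                                         muRange = c(4, 6),
                                         presenceProb = 1))
  lp <- linkCompartments(sim$experiment, "oocyte", "innerCC",
                         minSamples = 8)
  rs <- cor(lp@a["g0001", ], lp@b["g0002", ], method = "spearman")
  # Gaussian copula: rank rho = (6/pi) asin(rho/2)
  expect_lt(abs(rs - 6 / pi * asin(0.8 / 2)), 0.05)

  # planting a pair on a gene absent from its compartment is an error
  ppBad <- data.frame(gene_a = "g9999", compartment_a = "oocyte",
                      gene_b = "g0002", compartment_b = "outerCC",
                      rho = 0.5)
  expect_error(simulateCocDataset(cocSimConfig(nGenes = 5,
                                               plantedPairs = ppBad)),
               "unknown gene")
})

test_that("null data produce null-scale correlation tails", {
  # with nothing planted, the observed |bicor| > 0.85 rate over many
  # null pairs agrees with the permutation-null tail estimate
  sim <- simulateCocDataset(cocSimConfig(nGenes = 70, seed = 31,
                                         muRange = c(4, 6),
                                         presenceProb = 1))
  lp <- linkCompartments(sim$experiment, "oocyte", "outerCC")
  lp@a <- lp@a[1:25, ]; lp@b <- lp@b[26:65, ]  # 1000 disjoint null pairs
  obs <- crossCompartmentBicor(lp)
  no <- permutedNullBicor(lp, B = 100, seed = 7)
  obsRate <- mean(abs(bicorValues(obs)) > 0.85)
  nullRate <- mean(vapply(1:100, function(b)
    mean(abs(nullBicorValues(no, b)) >= 0.85), 0))
  K <- 1000
  se <- sqrt(nullRate * (1 - nullRate) / K)
  expect_lte(abs(obsRate - nullRate), max(3 * se, 3 / K))
})

test_that("observed and permuted null maxima are exchangeable on null data", {
  # distribution of the observed max |bicor| across simulated null
  # datasets vs the permuted max |bicor| within one dataset
  obsMax <- vapply(1:30, function(s) {
    sim <- simulateCocDataset(cocSimConfig(nGenes = 30, seed = 400 + s,
                                           muRange = c(4, 6),
                                           presenceProb = 1))
    lp <- linkCompartments(sim$experiment, "oocyte", "innerCC")
    lp@a <- lp@a[1:12, ]; lp@b <- lp@b[13:24, ]
    max(abs(bicorValues(crossCompartmentBicor(lp))))
  }, 0)
  sim <- simulateCocDataset(cocSimConfig(nGenes = 30, seed = 499,
                                         muRange = c(4, 6),
                                         presenceProb = 1))
  lp <- linkCompartments(sim$experiment, "oocyte", "innerCC")
  lp@a <- lp@a[1:12, ]; lp@b <- lp@b[13:24, ]
  no <- permutedNullBicor(lp, B = 30, seed = 6)
  permMax <- vapply(1:30, function(b) max(abs(nullBicorValues(no, b))), 0)
  ks <- suppressWarnings(ks.test(obsMax, permMax))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated PPI networks are deterministic and scale-free-ish", {
  n1 <- simulatePpiNetwork(200, 2, seed = 5)
  n2 <- simulatePpiNetwork(200, 2, seed = 5)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$receptors, n2$receptors)
  expect_equal(nrow(n1$edges), 2 * 200 - 3)  # m edges per new node
  expect_error(simulatePpiNetwork(2, 2), "nNodes")
  expect_error(simulatePpiNetwork(10, 2, receptorFraction = 1.5),
               "receptorFraction")
  # receptors all carry the receptor term
  expect_true(all(n1$go$term_id[n1$go$gene_id %in% n1$receptors] ==
                    "receptor activity"))
})

test_that("GO universe nulls are calibrated and saturated terms give p = 1", {
  # no planted enrichment: about 5% of term p-values below 0.05
  frac <- vapply(1:30, function(s) {
    gu <- simulateGoUniverse(1500, 15, lengthBias = 0, oddsRatio = 1,
                             baseProb = 0.1, seed = s + 40)
    res <- enrichAll(gu$interesting, gu$annotation, gu$lengths$gene_id,
                     gu$lengths)
    mean(res$p_over < 0.05)
  }, 0)
  expect_lte(mean(frac), 0.07)
  # a single term containing every gene
  gu <- simulateGoUniverse(50, 1, termSize = 50, seed = 3)
  res <- enrichAll(gu$interesting, gu$annotation, gu$lengths$gene_id)
  expect_equal(res$p_over, 1)
})
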