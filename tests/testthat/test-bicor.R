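test_that("bicor matches a literal transcription of the formula", {
  set.seed(101)
  for (i in 1:200) {
    x <- rnorm(16); y <- rnorm(16)
    expect_equal(as.numeric(bicor(x, y)), refBicor(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(as.numeric(bicor(1:10, 1:10)), 1)
  expect_equal(as.numeric(bicor(1:10, -(1:10))), -1)
})

test_that("bicor down-weights outliers relative to Pearson", {
  x <- c(1, 2, 3, 4, 100); y <- 1:5
  b <- as.numeric(bicor(x, y))
  expect_equal(b, refBicor(x, y), tolerance = 1e-12)
  expect_gt(abs(b - cor(x, y)), 0.05)
  expect_gt(b, cor(x, y))  # robust coefficient closer to the bulk trend
})

test_that("bicor is symmetric and affine-invariant", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(as.numeric(bicor(x, y)), as.numeric(bicor(y, x)),
                 tolerance = 1e-12)
    expect_equal(as.numeric(bicor(3 * x + 5, y)),
                 as.numeric(bicor(x, y)), tolerance = 1e-12)
  }
})

test_that("bicor equals Pearson exactly on balanced two-valued vectors", {
  # all |deviations| equal and median = mean, so every biweight is the
  # same constant and the midcorrelation collapses to Pearson
  set.seed(11)
  for (i in 1:20) {
    x <- sample(rep(c(0, 1), 8))
    y <- sample(rep(c(2, 7), 8))
    expect_equal(as.numeric(bicor(x, y)), cor(x, y), tolerance = 1e-12)
  }
})

test_that("zero-MAD vectors fall back to Pearson or are excluded", {
  x <- c(rep(0, 9), 5)  # median 0, MAD 0, but not constant
  y <- 1:10
  b <- bicor(x, y)
  expect_true(attr(b, "fallback"))
  # the fallback is per vector: x uses the Pearson standardization, y
  # keeps its biweights (hybrid oracle written out literally)
  px <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  dy <- y - median(y); uy <- dy / (9 * median(abs(dy)))
  wy <- dy * (1 - uy^2)^2 * (abs(uy) < 1)
  expect_equal(as.numeric(b), sum(px * wy / sqrt(sum(wy^2))),
               tolerance = 1e-12)
  # both vectors degenerate: plain Pearson
  x2 <- c(rep(0, 9), 5); y2 <- c(5, rep(1, 9))
  expect_equal(as.numeric(bicor(x2, y2)), cor(x2, y2), tolerance = 1e-12)
  expect_true(is.na(bicor(x, y, fallback = "strict")))

  # strict mode marks the whole row of a degenerate gene as excluded
  a <- rbind(g1 = c(rep(0, 7), 1), g2 = rnorm(8))
  bb <- matrix(rnorm(24), 3, 8, dimnames = list(paste0("h", 1:3), NULL))
  pr <- makePair(a, bb)
  res <- crossCompartmentBicor(pr, fallback = "strict")
  expect_true(all(is.na(bicorValues(res)["g1", ])))
  expect_true(all(is.finite(bicorValues(res)["g2", ])))
})

test_that("cross-compartment matrix reproduces pairwise bicor", {
  set.seed(3)
  a <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("a", 1:5), NULL))
  pr <- makePair(a, a)
  v <- bicorValues(crossCompartmentBicor(pr))
  expect_equal(unname(diag(v)), rep(1, 5), tolerance = 1e-12)
  for (k in 1:5) for (l in 1:5)
    expect_equal(v[k, l], refBicor(a[k, ], a[l, ]), tolerance = 1e-12)
  expect_error(crossCompartmentBicor(makePair(a[, 1:2], a[, 1:2])), "J >= 3")
})

test_that("planted pairs survive the copula and the robust correlation", {
  pp <- data.frame(gene_a = "g0001", compartment_a = "oocyte",
                   gene_b = "g0002", compartment_b = "outerCC",
                   rho = 0.98)
  hits <- 0; n <- 100
  for (s in seq_len(n)) {
    sim <- simulateCocDataset(cocSimConfig(nGenes = 10, plantedPairs = pp,
                                           seed = s, muRange = c(4, 6),
                                           presenceProb = 1))
    lp <- linkCompartments(sim$experiment, "oocyte", "outerCC")
    b <- bicorValues(crossCompartmentBicor(lp))["g0001", "g0002"]
    hits <- hits + (abs(b) > 0.85)
  }
  expect_gte(hits / n, 0.8)
})

test_that("permutation null excludes the identity and enumerates small J", {
  a <- matrix(rnorm(2 * 3), 2, 3); b <- matrix(rnorm(2 * 3), 2, 3)
  rownames(a) <- c("a1", "a2"); rownames(b) <- c("b1", "b2")
  no <- permutedNullBicor(makePair(a, b), B = 100, seed = 1)
  expect_equal(no$mode, "exhaustive")
  expect_equal(no$B, 5)  # 3! - 1
  expect_false(any(apply(no$permutations, 1, function(p) all(p == 1:3))))
  expect_equal(nrow(unique(as.data.frame(no$permutations))), 5)

  # fixed seed reproduces the sampled permutation sequence
  a <- matrix(rnorm(2 * 10), 2, 10); b <- matrix(rnorm(2 * 10), 2, 10)
  rownames(a) <- c("a1", "a2"); rownames(b) <- c("b1", "b2")
  n1 <- permutedNullBicor(makePair(a, b), B = 50, seed = 42)
  n2 <- permutedNullBicor(makePair(a, b), B = 50, seed = 42)
  expect_identical(n1$permutations, n2$permutations)
  expect_equal(n1$mode, "sampled")
  expect_false(any(apply(n1$permutations, 1, function(p) all(p == 1:10))))
})

test_that("null permutation values equal direct recomputation", {
  set.seed(5)
  a <- matrix(rnorm(3 * 6), 3, 6, dimnames = list(paste0("a", 1:3), NULL))
  b <- matrix(rnorm(2 * 6), 2, 6, dimnames = list(paste0("b", 1:2), NULL))
  pr <- makePair(a, b)
  no <- permutedNullBicor(pr, B = 10, seed = 2)
  for (bb in 1:5) {
    perm <- no$permutations[bb, ]
    v <- nullBicorValues(no, bb)
    for (k in 1:3) for (l in 1:2)
      expect_equal(v[k, l], refBicor(a[k, perm], b[l, ]),
                   tolerance = 1e-12)
  }
})

test_that("eFDR matches exhaustive brute force on a toy problem", {
  set.seed(12)
  a <- matrix(rnorm(2 * 4), 2, 4, dimnames = list(c("a1", "a2"), NULL))
  b <- matrix(rnorm(2 * 4), 2, 4, dimnames = list(c("b1", "b2"), NULL))
  pr <- makePair(a, b)
  obs <- crossCompartmentBicor(pr)
  no <- permutedNullBicor(pr, B = 10000, seed = 1)  # forces exhaustive
  expect_equal(no$B, 23)
  grid <- seq(0.5, 0.95, by = 0.05)
  ef <- efdrAtThresholds(obs, no, grid)

  # independent enumeration of the printed estimator
  perms <- refPermutations(4)
  perms <- perms[rowSums(perms == matrix(1:4, 24, 4, byrow = TRUE)) < 4, ]
  K <- 4; B <- nrow(perms)
  for (ti in seq_along(grid)) {
    t <- grid[ti]
    total <- 0
    for (r in seq_len(B)) {
      cnt <- 0
      for (k in 1:2) for (l in 1:2)
        cnt <- cnt + (abs(refBicor(a[k, perms[r, ]], b[l, ])) >= t)
      total <- total + cnt + 1
    }
    expect_equal(ef$efdr[ti], min(1, total / (K * B + 1)), tolerance = 1e-12)
  }
  # monotone non-increasing in the threshold
  expect_true(all(diff(ef$efdr) <= 1e-12))
})

test_that("eFDR floor and cap follow the printed formula", {
  # weak correlations, high threshold: no permuted exceedance, so the
  # "+1 per permutation" terms alone set the floor B/(K*B+1)
  set.seed(21)
  a <- matrix(rnorm(2 * 12), 2, 12, dimnames = list(c("a1", "a2"), NULL))
  b <- matrix(rnorm(2 * 12), 2, 12, dimnames = list(c("b1", "b2"), NULL))
  pr <- makePair(a, b)
  obs <- crossCompartmentBicor(pr)
  no <- permutedNullBicor(pr, B = 50, seed = 3)
  ef <- efdrAtThresholds(obs, no, c(0.5, 0.99))
  hi <- ef[ef$threshold == 0.99, ]
  expect_equal(hi$permuted_exceed_total, 0)
  expect_equal(hi$efdr, 50 / (4 * 50 + 1), tolerance = 1e-12)

  # saturated exceedance exceeds 1 before capping
  aa <- matrix(c(1, 2, 3, 2, 4, 6), 2, 3, byrow = TRUE,
               dimnames = list(c("a1", "a2"), NULL))
  prs <- makePair(aa, aa)
  obs2 <- crossCompartmentBicor(prs)
  no2 <- permutedNullBicor(prs, B = 5, seed = 1)
  # J = 3 permutations of collinear genes give |bicor| in {0.5, 1}, so
  # every permuted value clears a 0.45 threshold
  ef2 <- efdrAtThresholds(obs2, no2, 0.45)
  expect_equal(ef2$permuted_exceed_total, 4 * no2$B)
  expect_equal(ef2$efdr, 1)  # raw B(K+1)/(KB+1) > 1, capped
})

test_that("pair selection gates on the eFDR and uses strict thresholds", {
  v <- matrix(c(0.9, 0.2, -0.86, 0.85), 2, 2,
              dimnames = list(c("a1", "a2"), c("b1", "b2")))
  obs <- new("BicorResult", values = v, fallbackA = c(FALSE, FALSE),
             fallbackB = c(FALSE, FALSE), nCocs = 16L,
             compartments = c("oocyte", "outerCC"))
  ef <- data.frame(threshold = c(0.5, 0.85), observed_count = c(3L, 2L),
                   permuted_exceed_total = c(10, 0),
                   efdr = c(0.5, 1e-4))
  sel <- selectSignificantPairs(obs, ef, 0.85, efdrMax = 0.001)
  # bicor exactly 0.85 is excluded; 0.9 and -0.86 pass
  expect_equal(nrow(sel), 2)
  expect_setequal(paste(sel$gene_a, sel$gene_b),
                  c("a1 b1", "a1 b2"))
  # failing gate empties the selection regardless of values
  sel2 <- selectSignificantPairs(obs, ef, 0.85, efdrMax = 1e-5)
  expect_equal(nrow(sel2), 0)
  # off-grid threshold is an error, not an interpolation
  expect_error(selectSignificantPairs(obs, ef, 0.8), "grid")
})

test_that("gene relabeling permutes outputs consistently", {
  set.seed(30)
  a <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(paste0("a", 1:4), NULL))
  b <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(paste0("b", 1:3), NULL))
  v1 <- bicorValues(crossCompartmentBicor(makePair(a, b)))
  ord <- c(3, 1, 4, 2)
  v2 <- bicorValues(crossCompartmentBicor(makePair(a[ord, ], b)))
  expect_equal(v2, v1[ord, ], tolerance = 1e-12)
})
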