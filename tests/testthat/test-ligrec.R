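mkEdges <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$key_a <- pmin(df$id_a, df$id_b)
  df$key_b <- pmax(df$id_a, df$id_b)
  df
}

test_that("PPI integration deduplicates, expands homology and counts drops", {
  hom <- data.frame(foreign_id = c("h1", "h1", "h2"),
                    target_id = c("c1", "c2", "c3"))
  edges <- mkEdges(id_a = c("A", "B", "h1", "h9"),
                   id_b = c("B", "A", "h2", "h2"),
                   source_db = c("db1", "db2", "db1", "db1"),
                   species = c("cow", "cow", "human", "human"))
  ppi <- integratePpi(edges, hom)
  e <- ppiEdges(ppi)
  # same interaction from two databases merged with both provenance tags
  ab <- e[e$gene_a == "A" & e$gene_b == "B", ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$sources, "db1,db2")
  # one-to-two homology expansion: (h1,h2) -> (c1,c3), (c2,c3)
  expanded <- e[e$gene_b == "c3" | e$gene_a == "c3", ]
  expect_equal(nrow(expanded), 2)
  expect_setequal(paste(expanded$gene_a, expanded$gene_b),
                  c("c1 c3", "c2 c3"))
  # unmapped endpoint dropped and counted
  expect_equal(ppi@droppedUnmapped, 1L)
})

test_that("PPI integration is invariant to input row order", {
  hom <- data.frame(foreign_id = "h1", target_id = "c9")
  edges <- mkEdges(id_a = c("A", "C", "h1"), id_b = c("B", "A", "A"),
                   source_db = c("x", "y", "z"),
                   species = c("cow", "cow", "mouse"))
  e1 <- ppiEdges(integratePpi(edges, hom))
  e2 <- ppiEdges(integratePpi(edges[c(3, 1, 2), ], hom))
  rownames(e1) <- rownames(e2) <- NULL
  expect_equal(e1, e2)
})

test_that("role designation follows the receptor-annotation rule", {
  edges <- mkEdges(id_a = c("L1", "R1", "X1"),
                   id_b = c("R1", "R2", "X2"),
                   source_db = "db", species = "cow")
  ppi <- integratePpi(edges, data.frame(foreign_id = character(0),
                                        target_id = character(0)))
  go <- data.frame(gene_id = c("R1", "R2", "X1"),
                   term_id = c("receptor activity", "receptor complex",
                               "decoy"))
  cand <- designateRoles(ppi, go)
  # one receptor endpoint: the other is the ligand
  lr <- cand[!cand$receptor_receptor, ]
  expect_equal(nrow(lr), 1)
  expect_equal(lr$ligand, "L1")
  expect_equal(lr$receptor, "R1")
  # both receptors: two orientations, flagged
  rr <- cand[cand$receptor_receptor, ]
  expect_equal(nrow(rr), 2)
  expect_setequal(paste(rr$ligand, rr$receptor), c("R1 R2", "R2 R1"))
  # edge with no receptor endpoint discarded
  expect_false(any(cand$ligand %in% c("X1", "X2") &
                     cand$receptor %in% c("X1", "X2")))
})

test_that("signaling classification covers the 3x3 presence truth table", {
  cats <- c("oocyte-only", "CC-only", "both")
  sets <- list(`oocyte-only` = "oocyte", `CC-only` = "CC", both = "both")
  mkGene <- function(cat, id) id  # presence injected via the sets below
  rows <- expand.grid(lig = cats, rec = cats, stringsAsFactors = FALSE)
  cand <- data.frame(ligand = paste0("L", seq_len(nrow(rows))),
                     receptor = paste0("R", seq_len(nrow(rows))),
                     receptor_receptor = FALSE, sources = "db")
  oocyteSet <- c(paste0("L", which(rows$lig != "CC-only")),
                 paste0("R", which(rows$rec != "CC-only")))
  ccSet <- c(paste0("L", which(rows$lig != "oocyte-only")),
             paste0("R", which(rows$rec != "oocyte-only")))
  cls <- classifySignaling(cand, list(oocyte = oocyteSet, CC = ccSet))
  tab <- table(cls$pairs$category)
  expect_equal(unname(tab["autocrine"]), 2L)
  expect_equal(unname(tab["paracrine"]), 2L)
  expect_equal(unname(tab["autocrine_or_paracrine"]), 5L)
  expect_equal(sum(cls$summary$n_pairs), nrow(cls$pairs))
  # paracrine directions recorded
  par <- cls$pairs[cls$pairs$category == "paracrine", ]
  expect_setequal(par$direction, c("oocyte->CC", "CC->oocyte"))
  # gene expressed nowhere drops the pair
  cand2 <- rbind(cand, data.frame(ligand = "Lnone", receptor = "R1",
                                  receptor_receptor = FALSE, sources = "db"))
  cls2 <- classifySignaling(cand2, list(oocyte = oocyteSet, CC = ccSet))
  expect_equal(nrow(cls2$pairs), nrow(cls$pairs))
  expect_error(classifySignaling(cand, list(oocyte = "a", zona = "b")),
               "unknown compartment")
})

test_that("scale-free fit calibrates on generated graphs", {
  # preferential attachment: strong log-log fit
  net <- simulatePpiNetwork(500, 2, seed = 3)
  e <- data.frame(gene_a = net$edges$id_a, gene_b = net$edges$id_b)
  fit <- fitScaleFree(e, nBootstrap = 100, seed = 1)
  expect_gt(fit$rSquared, 0.7)
  expect_lt(fit$pValue, 0.05)
  expect_gte(fit$pValue, 1 / 101)
  expect_lt(fit$slope, 0)
  # 4-node star: two distinct degrees, two-point fit, R^2 = 1
  star <- data.frame(gene_a = "hub", gene_b = c("s1", "s2", "s3"))
  star <- rbind(star, data.frame(gene_a = paste0("t", 1:7),
                                 gene_b = paste0("u", 1:7)))
  fitS <- fitScaleFree(star, nBootstrap = 10, seed = 1)
  expect_equal(fitS$rSquared, 1, tolerance = 1e-12)
  # all-equal degrees are degenerate
  ring <- data.frame(gene_a = paste0("n", 1:12),
                     gene_b = paste0("n", c(2:12, 1)))
  expect_error(fitScaleFree(ring, nBootstrap = 5), "degenerate")
})

test_that("hub summary matches brute-force incidence counting", {
  # star: the hub covers everything
  star <- data.frame(gene_a = rep("hub", 5), gene_b = paste0("s", 1:5))
  hs <- hubSummary(star, topN = 1)
  expect_equal(hs$hubs, "hub")
  expect_equal(hs$fraction, 1)
  # perfect matching of 20 nodes paired consecutively: the ten
  # lexicographically first nodes are the endpoints of five edges
  pm <- data.frame(gene_a = sprintf("n%02d", seq(1, 19, 2)),
                   gene_b = sprintf("n%02d", seq(2, 20, 2)))
  expect_equal(hubSummary(pm, topN = 10)$fraction, 0.5)
  # random graph vs brute force
  set.seed(55)
  rg <- unique(data.frame(gene_a = sprintf("n%02d", sample(30, 60, TRUE)),
                          gene_b = sprintf("n%02d", sample(30, 60, TRUE))))
  rg <- rg[rg$gene_a != rg$gene_b, ]
  hs <- hubSummary(rg, topN = 5)
  brute <- mean(apply(rg, 1, function(r) any(r %in% hs$hubs)))
  expect_equal(hs$fraction, brute)
  # topN beyond the node count covers everything
  expect_equal(hubSummary(pm, topN = 100)$fraction, 1)
})

test_that("zero receptor fraction yields no ligand-receptor pairs", {
  net <- simulatePpiNetwork(50, 1, receptorFraction = 0, seed = 2)
  expect_length(net$receptors, 0)
  edges <- data.frame(id_a = net$edges$id_a, id_b = net$edges$id_b,
                      source_db = "simdb", species = "cow")
  edges$key_a <- pmin(edges$id_a, edges$id_b)
  edges$key_b <- pmax(edges$id_a, edges$id_b)
  ppi <- integratePpi(edges, data.frame(foreign_id = character(0),
                                        target_id = character(0)))
  cand <- designateRoles(ppi, net$go)
  expect_equal(nrow(cand), 0)
  # minimal construction: n = 3, m = 1 gives exactly 2 edges
  tiny <- simulatePpiNetwork(3, 1, seed = 1)
  expect_equal(nrow(tiny$edges), 2)
})
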