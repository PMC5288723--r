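test_that("single-gene deletion respects AND/OR semantics", {
  net <- chainNetwork(gpr = list(R1 = "g1", R2 = "g1 or g2"))
  # deleting g1 disables R1 (sole gene) and blocks the whole chain
  k1 <- deleteGeneBlocked(net, "g1")
  expect_true(all(c("R1", "R2", "Rin", "Rout") %in% k1))
  # deleting g2 leaves R2 enabled through the OR alternative
  expect_length(deleteGeneBlocked(net, "g2"), 0)
  expect_error(deleteGeneBlocked(net, "nope"), "unknown gene")
})

test_that("an obligate two-gene chain is fully gene-coupled", {
  net <- chainNetwork(gpr = list(R1 = "g1", R2 = "g2"))
  gg <- geneCouplingGraph(net)
  expect_identical(gg@fullyCoupled$g1, "g1")
  expect_identical(gg@fullyCoupled$g2, "g2")
})

test_that("the worked two-pathway example separates gene from reaction coupling", {
  net <- makeFig1Network()
  ct <- couplingTable(net)
  expect_identical(couplingOf(ct, "R04", "R05")$relation, "fully")
  expect_identical(couplingOf(ct, "R07", "R10")$relation, "fully")
  gg <- geneCouplingGraph(net)
  pairKey <- paste(gg@fullyCoupled$g1, gg@fullyCoupled$g2)
  expect_false("G1 G2" %in% pairKey)       # G1 also drives R07
  coupKey <- paste(gg@coupled$g1, gg@coupled$g2)
  expect_false("G3 G1" %in% coupKey)       # OR rule on R10: G3 alone
  expect_false("G4 G1" %in% coupKey)       #   (or G4 alone) is dispensable
  k2 <- deleteGeneBlocked(net, "G2")
  expect_true("R05" %in% k2)
  expect_false("R07" %in% k2)
  # OR semantics on R10: deleting G3 alone leaves R10 active
  expect_false("R10" %in% deleteGeneBlocked(net, "G3"))
})

test_that("pearson table matches direct computation and flags undefined pairs", {
  expr <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(1, 1, 1),
                d = c(3, 1, 2))
  colnames(expr) <- paste0("s", 1:3)
  tab <- pearsonTable(expr)
  expect_equal(correlationOf(tab, "a", "b"), 1)
  expect_true(is.na(correlationOf(tab, "a", "c")))   # zero variance
  expect_equal(correlationOf(tab, "a", "d"), -0.5)
  expect_equal(correlationOf(tab, "d", "a"), -0.5)   # symmetric lookup
  # cross-check every defined entry against stats::cor
  for (k in seq_len(nrow(tab@r))) {
    r <- tab@r[k, ]
    if (!is.na(r$r))
      expect_equal(r$r, cor(expr[r$gene_a, ], expr[r$gene_b, ]))
  }
  # fewer than 3 shared conditions is undefined
  expr2 <- rbind(a = c(1, 2, NA), b = c(2, NA, 6))
  colnames(expr2) <- paste0("s", 1:3)
  expect_true(is.na(correlationOf(pearsonTable(expr2), "a", "b")))
})

test_that("inconsistency sets follow the planted correlation labels", {
  net <- chainNetwork(gpr = list(R1 = "g1", R2 = "g2"))
  ct <- couplingTable(net)
  gg <- geneCouplingGraph(net)
  mkCorr <- function(r) new("CorrelationTable",
    r = data.frame(gene_a = "g1", gene_b = "g2", r = r))
  incLow <- buildInconsistency(net, ct, gg, mkCorr(0.05))
  expect_equal(nrow(incLow@L), 1)
  expect_identical(incLow@L$i, "R1")
  expect_equal(incLow@L$ratio, 1)
  expect_equal(nrow(incLow@H), 0)
  # dead zone between thresholds: neither set
  incMid <- buildInconsistency(net, ct, gg, mkCorr(0.5))
  expect_equal(nrow(incMid@L) + nrow(incMid@H), 0)
  incHigh <- buildInconsistency(net, ct, gg, mkCorr(0.9))
  expect_equal(nrow(incHigh@H), 1)
  # absolute correlation: r = -0.9 is "highly correlated"
  incNeg <- buildInconsistency(net, ct, gg, mkCorr(-0.9))
  expect_equal(nrow(incNeg@H), 1)
  # undefined correlation enters neither set
  incNA <- buildInconsistency(net, ct, gg, mkCorr(NA_real_))
  expect_equal(nrow(incNA@L) + nrow(incNA@H), 0)
  expect_error(buildInconsistency(net, ct, gg, mkCorr(0), low = 0.9,
                                  high = 0.2), "thresholds")
})

test_that("threshold moves are monotone for L and H", {
  sim <- makeRandomNetwork(syntheticSpec(planted_r = c(0.1, 0.3, 0.85),
                                         n_decoys = 1, seed = 42))
  ct <- couplingTable(sim$net)
  gg <- geneCouplingGraph(sim$net)
  corr <- pearsonTable(sim$expression)
  base <- buildInconsistency(sim$net, ct, gg, corr, low = 0.2, high = 0.8)
  tighterL <- buildInconsistency(sim$net, ct, gg, corr, low = 0.05,
                                 high = 0.8)
  expect_true(nrow(tighterL@L) <= nrow(base@L))
  tighterH <- buildInconsistency(sim$net, ct, gg, corr, low = 0.2,
                                 high = 0.95)
  expect_true(nrow(tighterH@H) <= nrow(base@H))
  looser <- buildInconsistency(sim$net, ct, gg, corr, low = 0.35,
                               high = 0.7)
  expect_true(nrow(looser@L) >= nrow(base@L))
  expect_true(nrow(looser@H) >= nrow(base@H))
  # deterministic lexicographic ordering
  again <- buildInconsistency(sim$net, ct, gg, corr, low = 0.2, high = 0.8)
  expect_identical(base@L, again@L)
  expect_identical(base@L$i, sort(base@L$i))
})

test_that("conflicting labels exclude a reaction pair from both sets", {
  # two fully coupled gene pairs reach the same reaction pair: (g1,g2) with
  # low r through (R1,R2), and (g3,g4) with high r through the same
  # reactions (OR'd into the rules)
  net <- chainNetwork(gpr = list(R1 = "g1 or g3", R2 = "g2 or g4"))
  ct <- couplingTable(net)
  # hand-build the gene graph: both pairs fully coupled
  gg <- new("GeneCouplingGraph",
    coupled = data.frame(g1 = c("g1", "g2", "g3", "g4"),
                         g2 = c("g2", "g1", "g4", "g3")),
    fullyCoupled = data.frame(g1 = c("g1", "g3"), g2 = c("g2", "g4")))
  corr <- new("CorrelationTable",
    r = data.frame(gene_a = c("g1", "g3"), gene_b = c("g2", "g4"),
                   r = c(0.05, 0.95)))
  inc <- buildInconsistency(net, ct, gg, corr)
  expect_equal(nrow(inc@L), 0)
  expect_equal(nrow(inc@H), 0)
  expect_true(nrow(inc@conflicts) >= 1)
  expect_true(any(inc@conflicts$i == "R1" & inc@conflicts$j == "R2"))
})
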