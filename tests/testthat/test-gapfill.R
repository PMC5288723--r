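# The two-step repair program, checked against the subset brute-force
# oracle and post-hoc coupling verification throughout.

test_that("a two-candidate bypass resolves a chain pair with N* = 2", {
  net <- chainNetwork()                       # -> A -> B -> C ->
  # bypass in series: A -> G, G -> B gives B a second producer
  us <- handUniversal(net, list(u1 = c(A = -1, G = 1), u2 = c(G = -1, B = 1)),
                      extraMets = "G")
  inc <- handInstance(L = list(c("R1", "R2")))
  s1 <- solveStep1(net, us, inc)
  expect_equal(s1$ZStar, 1)
  s2 <- solveStep2(net, us, inc, s1$ZStar)
  expect_equal(s2@NStar, 2)
  expect_setequal(names(s2@b)[s2@b > 0.5], c("u1", "u2"))
  expect_equal(sum(s2@h), 0)
  # the oracle agrees and the repaired network decouples the pair
  oracle <- bruteForceRepair(net, us, inc)
  expect_equal(oracle$ZStar, 1)
  expect_equal(oracle$NStar, 2)
  v <- verifySolution(net, us, inc, s2)
  expect_true(v$clean)
})

test_that("no candidates and no exchange freedom means Z* = 0", {
  net <- chainNetwork()
  inc <- handInstance(L = list(c("R1", "R2")))
  s1 <- solveStep1(net, emptyUniversal(net), inc)
  expect_equal(s1$ZStar, 0)  # reversibility relaxation alone cannot help
  s2 <- solveStep2(net, emptyUniversal(net), inc, 0)
  expect_equal(s2@NStar, 0)
  expect_error(solveStep1(net, emptyUniversal(net, "exchange"), inc),
               "does not match")
})

test_that("a bypass that would break a protected pair stays unused", {
  # chain -> A -> B -> C -> ; L = (R1, R2), H = (R1, Rout).
  # the only candidate exports B, which breaks the protected ratio too
  net <- chainNetwork()
  us <- handUniversal(net, list(u1 = c(B = -1)))
  inc <- handInstance(L = list(c("R1", "R2")), H = list(c("R1", "Rout")))
  s1 <- solveStep1(net, us, inc)
  expect_equal(s1$ZStar, 0)
  s2 <- solveStep2(net, us, inc, 0)
  expect_equal(sum(s2@b), 0)
  oracle <- bruteForceRepair(net, us, inc)
  expect_equal(oracle$ZStar, 0)
  # without the protection the same candidate resolves the pair
  incFree <- handInstance(L = list(c("R1", "R2")))
  expect_equal(solveStep1(net, us, incFree)$ZStar, 1)
})

test_that("pure irreversibility relaxation is found and counted as one move", {
  net <- reversibilityFixture()
  inc <- handInstance(L = list(c("R1", "R2")))
  us <- emptyUniversal(net)
  s1 <- solveStep1(net, us, inc)
  expect_equal(s1$ZStar, 1)
  s2 <- solveStep2(net, us, inc, 1)
  expect_equal(s2@NStar, 1)
  expect_equal(sum(s2@b), 0)
  expect_equal(sum(s2@h > 0.5), 1)
  # two symmetric one-relaxation repairs exist: reverse Rb (E -> B runs
  # B -> E) or reverse the E export (E becomes importable, feeding Rb)
  chosen <- names(s2@h)[s2@h > 0.5]
  expect_true(chosen %in% c("Rb", "RoutE"))
  expect_true(s2@v[[chosen]] < 0)             # runs backward in the witness
  oracle <- bruteForceRepair(net, us, inc)
  expect_equal(oracle$NStar, 1)
  expect_identical(lapply(oracle$optima, `[[`, "h"),
                   list("Rb", "RoutE"))
  expect_true(verifySolution(net, us, inc, s2)$clean)
  # in exchange mode irreversibilities are kept: nothing can be resolved
  cfgE <- milpConfig(mode = "exchange")
  expect_equal(solveStep1(net, emptyUniversal(net, "exchange"), inc,
                          cfgE)$ZStar, 0)
})

test_that("global repair beats per-pair repair on the shared-route example", {
  f2 <- makeFig2Network()
  cfg <- milpConfig()
  s1 <- solveStep1(f2$net, f2$universal, f2$inc, cfg)
  expect_equal(s1$ZStar, 2)
  s2 <- solveStep2(f2$net, f2$universal, f2$inc, s1$ZStar, cfg)
  expect_equal(s2@NStar, 3)
  expect_setequal(names(s2@b)[s2@b > 0.5], c("c7", "c8", "c9"))
  perPair <- lapply(1:2, function(k) {
    sub <- new("InconsistencyInstance", L = f2$inc@L[k, , drop = FALSE],
               H = f2$inc@H, low = 0.2, high = 0.8,
               conflicts = f2$inc@conflicts)
    z <- solveStep1(f2$net, f2$universal, sub, cfg)$ZStar
    solveStep2(f2$net, f2$universal, sub, z, cfg)
  })
  expect_setequal(names(perPair[[1]]@b)[perPair[[1]]@b > 0.5], c("c5", "c6"))
  expect_setequal(names(perPair[[2]]@b)[perPair[[2]]@b > 0.5],
                  c("c10", "c11"))
  # the Fig-2 property: 3 modifications at once vs 2 + 2 one at a time
  expect_lt(s2@NStar, sum(vapply(perPair, function(s) s@NStar, numeric(1))))
  expect_true(verifySolution(f2$net, f2$universal, f2$inc, s2)$clean)
})

test_that("integer cuts enumerate exactly the optimal solution pool", {
  net <- chainNetwork()
  inc <- handInstance(L = list(c("R1", "R2")))
  # two interchangeable single-candidate bypasses
  us2 <- handUniversal(net, list(e1 = c(B = -1), e2 = c(B = -1)))
  alts <- enumerateAlternatives(net, us2, inc, 1, 1)
  expect_length(alts, 2)
  sets <- lapply(alts, function(s) names(s@b)[s@b > 0.5])
  expect_setequal(unlist(sets), c("e1", "e2"))
  oracle <- bruteForceRepair(net, us2, inc)
  expect_identical(lapply(oracle$optima, `[[`, "b"),
                   lapply(sets[order(unlist(sets))], identity))
  # three interchangeable candidates -> three pairwise different sets
  us3 <- handUniversal(net, list(e1 = c(B = -1), e2 = c(B = -1),
                                 e3 = c(B = 1)))   # import works too
  alts3 <- enumerateAlternatives(net, us3, inc, 1, 1)
  expect_length(alts3, 3)
  expect_equal(length(unique(vapply(alts3, function(s)
    paste(names(s@b)[s@b > 0.5], collapse = ","), character(1)))), 3)
  expect_length(bruteForceRepair(net, us3, inc)$optima, 3)
  # unique optimum -> exactly one solution
  us1 <- handUniversal(net, list(e1 = c(B = -1)))
  alts1 <- enumerateAlternatives(net, us1, inc, 1, 1)
  expect_length(alts1, 1)
  expect_false(attr(alts1, "capped"))
})

test_that("the enumeration cap is honoured and flagged", {
  net <- chainNetwork()
  inc <- handInstance(L = list(c("R1", "R2")))
  us <- handUniversal(net, list(e1 = c(B = -1), e2 = c(B = -1),
                                e3 = c(B = -1)))
  cfg <- milpConfig(maxAlternatives = 2)
  alts <- enumerateAlternatives(net, us, inc, 1, 1, cfg)
  expect_length(alts, 2)
  expect_true(attr(alts, "capped"))
})

test_that("staged fallback attributes pairs to the right repair route", {
  fx <- fallbackFixture()
  res <- solveWithFallback(fx$net, fx$kegg, fx$exch, fx$inc)
  counts <- table(factor(res$provenance$status,
                         levels = c("kegg_reaction", "reversibility_change",
                                    "exchange", "unresolved")))
  expect_equal(as.vector(counts), c(2, 0, 1, 1))
  expect_identical(res$provenance$status[res$provenance$i == "c3_a"],
                   "exchange")
  expect_identical(res$provenance$status[res$provenance$i == "c4_a"],
                   "unresolved")
  # all pairs resolvable in phase 1 -> phase 2 skipped
  net <- chainNetwork()
  us <- handUniversal(net, list(u1 = c(B = -1)))
  inc <- handInstance(L = list(c("R1", "R2")))
  res2 <- solveWithFallback(net, us, buildExchangeUniversal(net), inc)
  expect_identical(res2$provenance$status, "kegg_reaction")
  expect_null(res2$solutions$exchange)
})

test_that("a reversibility-driven repair is attributed as such", {
  net <- reversibilityFixture()
  inc <- handInstance(L = list(c("R1", "R2")))
  # exchange fallback exists (B has no boundary reaction) but phase 1
  # already resolves the pair by relaxing Rb
  res <- solveWithFallback(net, emptyUniversal(net),
                           buildExchangeUniversal(net), inc)
  expect_identical(res$provenance$status, "reversibility_change")
})

test_that("one-by-one resolution re-instantiates the program per pair", {
  f2 <- makeFig2Network()
  cfg <- milpConfig(resolution = "one_by_one")
  res <- solveWithFallback(f2$net, f2$universal,
                           buildExchangeUniversal(f2$net), f2$inc, cfg)
  expect_length(res$perPair, 2)
  adds <- lapply(res$perPair, function(p)
    names(p$solutions$kegg@b)[p$solutions$kegg@b > 0.5])
  expect_setequal(adds[[1]], c("c5", "c6"))
  expect_setequal(adds[[2]], c("c10", "c11"))
  expect_equal(sum(lengths(adds)), 4)
})

test_that("verification flags a protected pair decoupled by the modification", {
  net <- chainNetwork()
  us <- handUniversal(net, list(u1 = c(B = -1)))
  inc <- handInstance(L = list(), H = list(c("R1", "R2")))
  # a hand-made "solution" whose witness keeps the protected ratio but whose
  # structural change decouples it
  sol <- new("GapFillSolution",
             v = setNames(rep(1, 4), reactionIds(net)),
             y = c(u1 = 0), d = numeric(0), e = numeric(0), f = numeric(0),
             b = c(u1 = 1), h = setNames(numeric(0), character(0)),
             ZStar = 0, NStar = 1, mode = "kegg")
  v <- verifySolution(net, us, inc, sol)
  expect_false(v$clean)
  expect_identical(v$report$set, "H")
  # the empty solution on the untouched network is vacuously clean
  sol0 <- new("GapFillSolution",
              v = setNames(rep(0, 4), reactionIds(net)),
              y = c(u1 = 0), d = numeric(0), e = numeric(0), f = numeric(0),
              b = c(u1 = 0), h = setNames(numeric(0), character(0)),
              ZStar = 0, NStar = 0, mode = "kegg")
  v0 <- verifySolution(net, us, inc, sol0)
  expect_true(v0$clean)
})

test_that("Z* is monotone in the universal set and in epsilon", {
  net <- chainNetwork()
  inc <- handInstance(L = list(c("R1", "R2")))
  usSmall <- emptyUniversal(net)
  usBig <- handUniversal(net, list(u1 = c(B = -1)))
  zSmall <- solveStep1(net, usSmall, inc)$ZStar
  zBig <- solveStep1(net, usBig, inc)$ZStar
  expect_true(zBig >= zSmall)
  zHalfEps <- solveStep1(net, usBig, inc, milpConfig(epsilon = 5e-7))$ZStar
  expect_true(zHalfEps >= zBig)
})
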