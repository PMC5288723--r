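test_that("GPR strings parse to the expected expression trees", {
  tree <- parseGpr("(g1 and g2) or g3")
  expect_identical(tree$op, "or")
  expect_identical(tree$args[[1]]$op, "and")
  expect_identical(gprToString(tree), "(g1 and g2) or g3")
  expect_setequal(gprGenes(tree), c("g1", "g2", "g3"))
  expect_true(gprEval(tree, "g3"))
  expect_true(gprEval(tree, c("g1", "g2")))
  expect_false(gprEval(tree, "g1"))
  expect_true(gprEval(NULL, character(0)))   # no rule = never disabled
  expect_error(parseGpr("g1 and (g2 or"), "unbalanced|malformed")
  # synonym operators and case-insensitivity
  expect_identical(gprToString(parseGpr("G1 AND g2 && g3")), "G1 and g2 and g3")
})

test_that("COBRA JSON and SBML round trips preserve S, bounds and GPRs", {
  net <- chainNetwork(gpr = list(R1 = "gA", R2 = "(gB and gC) or gD"))
  for (ext in c("json", "xml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    writeMetabolicModel(net, path)
    back <- readMetabolicModel(path)
    expect_identical(reactionIds(back), reactionIds(net))
    expect_identical(metaboliteIds(back), metaboliteIds(net))
    expect_equal(as.matrix(stoichMatrix(back)), as.matrix(stoichMatrix(net)))
    expect_equal(unname(lowerBounds(back)), unname(lowerBounds(net)))
    expect_equal(unname(upperBounds(back)), unname(upperBounds(net)))
    expect_identical(lapply(gprRules(back), gprToString),
                     lapply(gprRules(net), gprToString))
  }
})

test_that("readers flag malformed models with the offending element", {
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A", compartment = "c")),
    reactions = list(list(id = "R1", metabolites = list(ZZZ = 1),
                          lower_bound = 0, upper_bound = 10)),
    genes = list()), bad, auto_unbox = TRUE)
  expect_error(readMetabolicModel(bad), "R1.*ZZZ")
  bad2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A", compartment = "c")),
    reactions = list(list(id = "R1", metabolites = list(A = 1),
                          lower_bound = 5, upper_bound = 1)),
    genes = list()), bad2, auto_unbox = TRUE)
  expect_error(readMetabolicModel(bad2), "lower bound exceeds")
})

test_that("a minimal 1-reaction model with wide bounds has no irreversible set", {
  S <- matrix(1, 1, 1, dimnames = list("A", "R1"))
  net <- metabolicNetwork(S, lb = -1000, ub = 1000)
  expect_length(irreversibleReactions(net), 0)
  expect_identical(reactionIds(net), "R1")
})

test_that("biomass removal exports exactly the non-exportable precursors", {
  # biomass consumes M1 and M2, neither exportable -> 2 exporters
  mets <- c("M1", "M2")
  S <- matrix(0, 2, 3, dimnames = list(mets, c("in1", "in2", "biomass")))
  S["M1", "in1"] <- 1; S["M2", "in2"] <- 1
  S["M1", "biomass"] <- -1; S["M2", "biomass"] <- -0.5
  net <- metabolicNetwork(S, lb = rep(0, 3), ub = rep(1000, 3))
  out <- preprocessBiomass(net, "biomass")
  expect_false("biomass" %in% reactionIds(out))
  expect_setequal(setdiff(reactionIds(out), reactionIds(net)),
                  c("EX_M1_bm", "EX_M2_bm"))
  # surviving original reactions keep their stoichiometry
  expect_equal(as.matrix(stoichMatrix(out))[mets, c("in1", "in2")],
               as.matrix(stoichMatrix(net))[mets, c("in1", "in2")])

  # M3 already has an exchange -> 0 exporters
  S2 <- matrix(0, 1, 3, dimnames = list("M3", c("in3", "ex3", "biomass")))
  S2["M3", "in3"] <- 1; S2["M3", "ex3"] <- -1; S2["M3", "biomass"] <- -1
  net2 <- metabolicNetwork(S2, lb = rep(0, 3), ub = rep(1000, 3))
  out2 <- preprocessBiomass(net2, "biomass")
  expect_identical(sort(reactionIds(out2)), c("ex3", "in3"))
})

test_that("exporter count is the set difference of consumed and exportable", {
  # 5 consumed precursors, 2 already exportable -> 3 exporters added
  mets <- paste0("P", 1:5)
  rxns <- c(paste0("in", 1:5), "exP1", "exP2", "biomass")
  S <- matrix(0, 5, length(rxns), dimnames = list(mets, rxns))
  for (k in 1:5) S[k, k] <- 1
  S["P1", "exP1"] <- -1; S["P2", "exP2"] <- -1
  S[, "biomass"] <- -1
  net <- metabolicNetwork(S, lb = rep(0, ncol(S)), ub = rep(1000, ncol(S)))
  out <- preprocessBiomass(net, "biomass")
  added <- setdiff(reactionIds(out), reactionIds(net))
  expect_length(added, 3)
  expect_setequal(added, paste0("EX_P", 3:5, "_bm"))
  expect_error(preprocessBiomass(net, "nope"), "not found")
})

test_that("universal table filters work in order and are idempotent", {
  net <- chainNetwork()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\treversibility",
               "u1\tA + Q -> Q + W\tfalse",     # same metabolite both sides
               "u2\tA -> W\tfalse",
               "u3\t1 A -> W\tfalse",           # canonical duplicate of u2
               "u4\ta  ->  w\tfalse",           # case/space duplicate of u2
               "u5\tA -> B\tfalse",             # identical to model R1
               "u6\tW <=> Z\ttrue"),            # reversible: split
             tmp)
  us <- loadUniversal(tmp, net)
  expect_identical(us@mode, "kegg")
  expect_setequal(unique(us@sourceId), c("u2", "u6"))
  expect_setequal(colnames(us@U), c("u2", "u6__f", "u6__r"))
  expect_equal(nCandidates(us), 2)
  # candidate-only metabolites got their own rows
  expect_true(all(c("W", "Z") %in% rownames(us@U)))
  # split columns are sign flips of each other
  expect_equal(as.numeric(us@U[, "u6__f"]), -as.numeric(us@U[, "u6__r"]))
  # idempotence: re-filter the serialized survivors -> nothing else removed
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeUniversal(us, tmp2)
  us2 <- loadUniversal(tmp2, chainNetwork(mets = c("AA", "BB")))
  expect_equal(nCandidates(us2), nCandidates(us))

  expect_error(loadUniversal(withr::local_tempfile(lines =
    "id\tequation\treversibility"), net), "empty")
  bad <- withr::local_tempfile(lines = c("id\tequation\treversibility",
                                         "u9\tA B C\tfalse"))
  expect_error(loadUniversal(bad, net), "row 1")
})

test_that("exchange universal covers exactly the non-exchanged metabolites", {
  # chain: A has import, C has export, B has neither
  net <- chainNetwork()
  us <- buildExchangeUniversal(net)
  expect_identical(us@mode, "exchange")
  expect_identical(unique(us@sourceId), "EX_B")
  expect_equal(nCandidates(us), 1)
  nz <- Matrix::colSums(us@U != 0)
  expect_true(all(nz == 1))

  # no exchanges at all -> one candidate per metabolite
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  net2 <- metabolicNetwork(S, lb = 0, ub = 10)
  expect_equal(nCandidates(buildExchangeUniversal(net2)), 2)

  # count identity on a random network: metabolites minus already-exchanged
  set.seed(5)
  net3 <- randomToyNetwork()
  exch <- sum(vapply(metaboliteIds(net3), function(m)
    length(fluxgap:::boundaryReactionsOf(net3, m)) > 0, logical(1)))
  expect_equal(nCandidates(buildExchangeUniversal(net3)),
               length(metaboliteIds(net3)) - exch)
})
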