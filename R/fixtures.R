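# Self-certifying synthetic fixtures: figure-style worked examples, random
# toy networks for oracle equivalence testing, planted-correlation synthetic
# studies, and the GPR-ablation robustness utility.  Every generated fixture
# verifies its own defining properties before being returned.

#' Worked example: gene coupling differs from reaction coupling
#'
#' A ten-reaction network with two linear pathways.  (R4, R5) and (R7, R10)
#' are fully coupled reaction pairs, yet the associated genes are not fully
#' coupled: G1 drives both R4 and R7, so its function survives deletion of
#' G2; and R10 is enabled by "G3 or G4", so deleting either gene alone
#' leaves R10 active and G1 is not coupled to G3 or G4.  The construction is
#' verified at generation time by running the coupling and gene-coupling
#' analyses.
#'
#' @return a \code{MetabolicNetwork}.
#' @export
makeFig1Network <- function() {
  mets <- c("A", "C", "M", "P", "D", "N", "Q")
  rxns <- c("R01", "R02", "R03", "R04", "R05", "R06", "R07", "R08",
            "R09", "R10")
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  S["A", "R01"] <- 1                       # import A
  S["A", "R02"] <- -1; S["C", "R02"] <- 1  # branch keeps R01/R04 uncoupled
  S["C", "R03"] <- -1                      # export C
  S["A", "R04"] <- -1; S["M", "R04"] <- 1  # G1
  S["M", "R05"] <- -1; S["P", "R05"] <- 1  # G2
  S["P", "R06"] <- -1                      # export P
  S["D", "R08"] <- 1                       # import D
  S["D", "R07"] <- -1; S["N", "R07"] <- 1  # G1 again
  S["N", "R10"] <- -1; S["Q", "R10"] <- 1  # G3 or G4
  S["Q", "R09"] <- -1                      # export Q
  net <- metabolicNetwork(S, lb = rep(0, length(rxns)),
                          ub = rep(1000, length(rxns)),
                          gpr = list(R04 = "G1", R05 = "G2", R07 = "G1",
                                     R10 = "G3 or G4"))
  ct <- couplingTable(net)
  ok <- couplingOf(ct, "R04", "R05")$relation == "fully" &&
        couplingOf(ct, "R07", "R10")$relation == "fully"
  gg <- geneCouplingGraph(net)
  keyFull <- paste(gg@fullyCoupled$g1, gg@fullyCoupled$g2)
  keyCoup <- paste(gg@coupled$g1, gg@coupled$g2)
  ok <- ok && !("G1 G2" %in% keyFull) &&
        !("G3 G1" %in% keyCoup) && !("G4 G1" %in% keyCoup)
  kG2 <- deleteGeneBlocked(net, "G2")
  ok <- ok && ("R05" %in% kG2) && !("R07" %in% kG2)
  if (!ok) stop("fixture self-check failed: caption properties violated")
  net
}

#' Worked example: global versus per-pair repair optima
#'
#' Two independent fully coupled pathway pairs, (R1, R2) and (R3, R4), form
#' the inconsistency set.  Candidate reactions c5..c11 are arranged so each
#' pair alone is repaired cheapest by a dedicated two-candidate bypass
#' ({c5, c6}, respectively {c10, c11}), while repairing both at once is
#' cheapest through the shared three-candidate route {c7, c8, c9} linking
#' the two pathways.  Verified at generation time against the subset
#' brute-force oracle.
#'
#' @return list with \code{net}, \code{universal} (mode \code{"kegg"}) and
#'   \code{inc} (an \code{InconsistencyInstance}; gene columns are NA since
#'   the example is purely structural).
#' @export
makeFig2Network <- function() {
  mets <- c("A", "B", "C", "D", "E", "F")
  rxns <- c("Rin1", "R1", "R2", "Rout1", "Rin2", "R3", "R4", "Rout2")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["A", "Rin1"] <- 1
  S["A", "R1"] <- -1; S["B", "R1"] <- 1
  S["B", "R2"] <- -1; S["C", "R2"] <- 1
  S["C", "Rout1"] <- -1
  S["D", "Rin2"] <- 1
  S["D", "R3"] <- -1; S["E", "R3"] <- 1
  S["E", "R4"] <- -1; S["F", "R4"] <- 1
  S["F", "Rout2"] <- -1
  net <- metabolicNetwork(S, lb = rep(0, length(rxns)),
                          ub = rep(1000, length(rxns)))
  candMets <- c(mets, "G", "X", "Y", "HH")
  cand <- list(
    c5  = c(A = -1, G = 1),
    c6  = c(G = -1, B = 1),
    c7  = c(B = -1, X = 1),
    c8  = c(X = -1, E = 1, Y = 1),
    c9  = c(Y = -1),
    c10 = c(E = -1, HH = 1),
    c11 = c(HH = -1, F = 1))
  U <- Matrix::Matrix(0, length(candMets), length(cand), sparse = TRUE,
                      dimnames = list(candMets, names(cand)))
  for (k in seq_along(cand)) U[names(cand[[k]]), k] <- cand[[k]]
  universal <- new("UniversalSet", U = U, sourceId = names(cand),
                   sourceReversible = rep(FALSE, length(cand)),
                   mode = "kegg")
  Ldf <- data.frame(i = c("R1", "R3"), j = c("R2", "R4"), ratio = c(1, 1),
                    gene_a = NA_character_, gene_b = NA_character_,
                    r = NA_real_, stringsAsFactors = FALSE)
  inc <- new("InconsistencyInstance", L = Ldf, H = Ldf[0, , drop = FALSE],
             low = 0.2, high = 0.8, conflicts = Ldf[0, , drop = FALSE])
  # self-certification against the coupling analysis and the subset oracle
  ct <- couplingTable(net)
  if (couplingOf(ct, "R1", "R2")$relation != "fully" ||
      couplingOf(ct, "R3", "R4")$relation != "fully")
    stop("fixture self-check failed: planted pairs are not fully coupled")
  oracle <- bruteForceRepair(net, universal, inc, milpConfig())
  want <- list(c("c7", "c8", "c9"))
  if (oracle$ZStar != 2 || oracle$NStar != 3 ||
      !identical(lapply(oracle$optima, function(o) sort(o$b)), want))
    stop("fixture self-check failed: global optimum is not {c7,c8,c9}")
  list(net = net, universal = universal, inc = inc)
}

#' Random toy network for oracle-equivalence testing
#'
#' Small random networks mixing imports, exports, internal conversions and
#' occasional reversible reactions; intended for exhaustive comparison of
#' the LP-probe coupling classifier with the vertex-enumeration oracle.
#' Uses the current RNG state (seed at the call site).
#'
#' @param n_mets,n_rxns network size (defaults 4 metabolites, 8 reactions).
#' @return a \code{MetabolicNetwork}.
#' @export
randomToyNetwork <- function(n_mets = 4, n_rxns = 8) {
  mets <- paste0("m", seq_len(n_mets))
  rxns <- paste0("r", seq_len(n_rxns))
  S <- matrix(0, n_mets, n_rxns, dimnames = list(mets, rxns))
  rev <- logical(n_rxns)
  for (j in seq_len(n_rxns)) {
    kind <- sample(c("import", "export", "convert"), 1,
                   prob = c(0.2, 0.2, 0.6))
    if (kind == "import") {
      S[sample(n_mets, 1), j] <- sample(c(1, 2), 1)
    } else if (kind == "export") {
      S[sample(n_mets, 1), j] <- -sample(c(1, 2), 1)
    } else {
      ns <- sample(1:2, 1)
      np <- sample(1:2, 1)
      subs <- sample(n_mets, ns)
      prods <- sample(setdiff(seq_len(n_mets), subs),
                      min(np, n_mets - ns))
      S[subs, j] <- -sample(c(1, 1, 2), length(subs), replace = TRUE)
      if (length(prods))
        S[prods, j] <- sample(c(1, 1, 2), length(prods), replace = TRUE)
    }
    rev[j] <- stats::runif(1) < 0.25
  }
  metabolicNetwork(S, lb = ifelse(rev, -1000, 0), ub = rep(1000, n_rxns))
}

#' Specification for a planted synthetic study
#'
#' @param planted_r target Pearson correlations, one per planted fully
#'   coupled gene/reaction pair chain.
#' @param n_decoys number of uncoupled decoy branch motifs.
#' @param gpr_density fraction of assigned GPRs that are kept.
#' @param conditions expression conditions (>= 3; default 50, enough for the
#'   empirical correlation to be controlled exactly by construction).
#' @param seed random seed; generation is byte-reproducible per seed.
#' @return validated spec (plain list).
#' @export
syntheticSpec <- function(planted_r = c(0.05, 0.9), n_decoys = 2,
                          gpr_density = 1, conditions = 50, seed = 1) {
  stopifnot(length(planted_r) >= 1, all(abs(planted_r) <= 1),
            n_decoys >= 0, gpr_density >= 0, gpr_density <= 1,
            conditions >= 3)
  list(planted_r = planted_r, n_decoys = n_decoys,
       gpr_density = gpr_density, conditions = conditions, seed = seed)
}

# two vectors with exact sample correlation r (Gaussian-copula style draw,
# then orthogonalized so the empirical r matches the target exactly)
exactCorrelationPair <- function(n, r) {
  repeat {
    x <- stats::rnorm(n)
    z <- stats::rnorm(n)
    xs <- as.numeric(scale(x))
    zr <- stats::residuals(stats::lm(z ~ xs))
    if (stats::sd(zr) > 1e-8 && stats::sd(xs) > 1e-8) {
      y <- r * xs + sqrt(1 - r^2) * as.numeric(scale(zr))
      return(list(x = x, y = as.numeric(y)))
    }
  }
}

#' Generate a synthetic network with planted co-expression structure
#'
#' Each planted entry becomes an isolated linear pathway of two gene-bearing
#' reactions (hence an obligately fully coupled reaction pair and a fully
#' coupled gene pair) whose two genes receive expression profiles with the
#' target sample correlation, exactly.  Decoy motifs are branched pathways
#' whose genes are never fully coupled; their expression is independent
#' noise.  Planted pairs are verified fully coupled at generation time.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return list with \code{net}, \code{expression} (genes x conditions
#'   matrix), and \code{planted} (data.frame: genes, reactions, target r).
#' @export
makeRandomNetwork <- function(spec = syntheticSpec()) {
  set.seed(spec$seed)
  nP <- length(spec$planted_r)
  mets <- character(0); rxnDefs <- list(); gpr <- list()
  planted <- list()
  for (k in seq_len(nP)) {
    a <- sprintf("pA%d", k); b <- sprintf("pB%d", k); c3 <- sprintf("pC%d", k)
    g1 <- sprintf("gP%d_1", k); g2 <- sprintf("gP%d_2", k)
    r1 <- sprintf("P%d_in", k); r2 <- sprintf("P%d_a", k)
    r3 <- sprintf("P%d_b", k); r4 <- sprintf("P%d_out", k)
    mets <- c(mets, a, b, c3)
    rxnDefs[[r1]] <- stats::setNames(1, a)
    rxnDefs[[r2]] <- stats::setNames(c(-1, 1), c(a, b))
    rxnDefs[[r3]] <- stats::setNames(c(-1, 1), c(b, c3))
    rxnDefs[[r4]] <- stats::setNames(-1, c3)
    gpr[[r2]] <- g1; gpr[[r3]] <- g2
    planted[[k]] <- data.frame(gene_a = g1, gene_b = g2, i = r2, j = r3,
                               target_r = spec$planted_r[k],
                               stringsAsFactors = FALSE)
  }
  for (k in seq_len(spec$n_decoys)) {
    a <- sprintf("dA%d", k); b <- sprintf("dB%d", k); c3 <- sprintf("dC%d", k)
    g1 <- sprintf("gD%d_1", k); g2 <- sprintf("gD%d_2", k)
    mets <- c(mets, a, b, c3)
    rxnDefs[[sprintf("D%d_in", k)]] <- stats::setNames(1, a)
    rxnDefs[[sprintf("D%d_b1", k)]] <- stats::setNames(c(-1, 1), c(a, b))
    rxnDefs[[sprintf("D%d_b2", k)]] <- stats::setNames(c(-1, 1), c(a, c3))
    rxnDefs[[sprintf("D%d_o1", k)]] <- stats::setNames(-1, b)
    rxnDefs[[sprintf("D%d_o2", k)]] <- stats::setNames(-1, c3)
    gpr[[sprintf("D%d_b1", k)]] <- g1
    gpr[[sprintf("D%d_b2", k)]] <- g2
  }
  if (spec$gpr_density < 1) {
    keep <- stats::runif(length(gpr)) < spec$gpr_density
    gpr <- gpr[keep]
  }
  rxns <- names(rxnDefs)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxnDefs)) S[names(rxnDefs[[j]]), j] <- rxnDefs[[j]]
  net <- metabolicNetwork(S, lb = rep(0, length(rxns)),
                          ub = rep(1000, length(rxns)), gpr = gpr)
  plantedDf <- do.call(rbind, planted)
  if (spec$gpr_density >= 1) {
    ct <- couplingTable(net)
    for (k in seq_len(nrow(plantedDf)))
      if (couplingOf(ct, plantedDf$i[k], plantedDf$j[k])$relation != "fully")
        stop("fixture self-check failed: planted pair not fully coupled")
  }
  genes <- geneIds(net)
  allGenes <- unique(c(genes, unlist(plantedDf[, c("gene_a", "gene_b")])))
  expr <- matrix(stats::rnorm(length(allGenes) * spec$conditions),
                 nrow = length(allGenes),
                 dimnames = list(allGenes, paste0("cond", seq_len(spec$conditions))))
  for (k in seq_len(nrow(plantedDf))) {
    pr <- exactCorrelationPair(spec$conditions, plantedDf$target_r[k])
    expr[plantedDf$gene_a[k], ] <- pr$x
    expr[plantedDf$gene_b[k], ] <- pr$y
  }
  list(net = net, expression = expr, planted = plantedDf)
}

#' Randomly remove GPR rules
#'
#' Strips the GPR from \code{floor(fraction * n)} of the \code{n} reactions
#' that carry one, chosen uniformly; stoichiometry is untouched.  Used for
#' robustness experiments on the sensitivity of gene-coupling-driven gap
#' finding to incomplete gene annotations.
#'
#' @param net a \code{MetabolicNetwork}.
#' @param fraction in [0, 1].
#' @param seed random seed.
#' @return the ablated network.
#' @export
ablateGprs <- function(net, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  withGpr <- names(net@gpr)
  nDrop <- floor(fraction * length(withGpr))
  if (nDrop == 0) return(net)
  set.seed(seed)
  drop <- sample(withGpr, nDrop)
  metabolicNetwork(net@S, lb = net@lb, ub = net@ub,
                   gpr = net@gpr[setdiff(withGpr, drop)],
                   compartments = net@compartments)
}
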