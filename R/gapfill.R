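# Two-step mixed-integer repair of coupling/co-expression inconsistencies.
#
# Step 1 maximizes the number of low-correlation fully coupled pairs whose
# flux ratio is broken in a single steady-state witness, subject to mass
# balance over all metabolites (model + candidates) and exact ratio
# preservation for every high-correlation pair.  Step 2 fixes that optimum
# and minimizes the number of modifications: candidates added (b) plus
# originally irreversible reactions run backward (h).  Alternate optima are
# enumerated with integer cuts.

#' Configuration for the repair program
#'
#' @param epsilon strict-inequality margin separating "ratio broken" from
#'   numerical noise (default 1e-6).
#' @param bigM big-M constant; must be at least the flux bound magnitude
#'   (default 1000, matching the conventional bounds).
#' @param mode \code{"kegg"} (database candidates, irreversibility
#'   relaxation active) or \code{"exchange"} (exchange candidates only,
#'   original irreversibilities kept).
#' @param resolution \code{"all_at_once"} or \code{"one_by_one"}.
#' @param maxAlternatives cap on enumerated alternate optima.
#' @param nodeLimit branch-and-bound node budget per solve.
#' @return a \code{\linkS4class{MilpConfig}}.
#' @export
milpConfig <- function(epsilon = 1e-6, bigM = 1000, mode = "kegg",
                       resolution = "all_at_once", maxAlternatives = 100,
                       nodeLimit = 200000) {
  new("MilpConfig", epsilon = epsilon, bigM = bigM, mode = mode,
      resolution = resolution, maxAlternatives = maxAlternatives,
      nodeLimit = nodeLimit)
}

# Assemble the constraint system shared by both steps.  Variable layout:
#   v (model reactions) | y (candidate columns) | d | e | f  [ | b | h ]
buildRepairProgram <- function(net, universal, inc, cfg, step,
                               ZStar = NULL, cuts = list()) {
  rxns <- reactionIds(net)
  nv <- length(rxns)
  U <- universal@U
  candIds <- colnames(U)
  ny <- length(candIds)
  L <- inc@L; H <- inc@H
  nL <- nrow(L)
  irr <- if (cfg@mode == "kegg") irreversibleReactions(net) else character(0)
  nh <- if (step == 2) length(irr) else 0L
  nb <- if (step == 2) ny else 0L

  iv <- seq_len(nv)
  iy <- nv + seq_len(ny)
  id <- nv + ny + seq_len(nL)
  ie <- nv + ny + nL + seq_len(nL)
  iff <- nv + ny + 2 * nL + seq_len(nL)
  ib <- if (nb) nv + ny + 3 * nL + seq_len(nb) else integer(0)
  ih <- if (nh) nv + ny + 3 * nL + nb + seq_len(nh) else integer(0)
  ntot <- nv + ny + 3 * nL + nb + nh

  # mass balance over the union metabolite set
  mets <- rownames(U)
  stopifnot(all(metaboliteIds(net) %in% mets))
  Sfull <- matrix(0, length(mets), ntot)
  Sv <- as.matrix(net@S)
  Sfull[match(metaboliteIds(net), mets), iv] <- Sv
  if (ny) Sfull[, iy] <- as.matrix(U)
  A <- Sfull
  sense <- rep("=", length(mets))
  rhs <- rep(0, length(mets))

  addRow <- function(coefIdx, coefVal, s, r) {
    row <- numeric(ntot)
    row[coefIdx] <- coefVal
    A <<- rbind(A, row)
    sense <<- c(sense, s)
    rhs <<- c(rhs, r)
  }

  eps <- cfg@epsilon
  for (k in seq_len(nL)) {
    ri <- match(L$i[k], rxns); rj <- match(L$j[k], rxns)
    lam <- L$ratio[k]
    Mi <- (1 + abs(lam)) * cfg@bigM
    # e_k = 1 demands u - lambda w >= eps ; f_k = 1 demands lambda w - u >= eps
    addRow(c(ri, rj, ie[k]), c(1, -lam, -(Mi + eps)), ">=", eps - (Mi + eps))
    addRow(c(ri, rj, iff[k]), c(-1, lam, -(Mi + eps)), ">=", eps - (Mi + eps))
    addRow(c(ie[k], iff[k]), c(1, 1), "<=", 1)
    addRow(c(id[k], ie[k], iff[k]), c(1, -1, -1), "<=", 0)
  }
  for (k in seq_len(nrow(H))) {
    ri <- match(H$i[k], rxns); rj <- match(H$j[k], rxns)
    addRow(c(ri, rj), c(1, -H$ratio[k]), "=", 0)
  }
  if (step == 2) {
    for (k in seq_len(ny))
      addRow(c(iy[k], ib[k]), c(1, -cfg@bigM), "<=", 0)
    if (nh) {
      irrIdx <- match(irr, rxns)
      for (k in seq_len(nh)) {
        addRow(c(irrIdx[k], ih[k]), c(1, cfg@bigM), ">=", 0)
        addRow(c(irrIdx[k], ih[k]), c(1, cfg@bigM + eps), "<=", cfg@bigM)
      }
    }
    addRow(id, rep(1, nL), "=", ZStar)
    for (cut in cuts) {
      sel <- c(ib[match(cut$b, candIds)], ih[match(cut$h, irr)])
      if (length(sel))
        addRow(sel, rep(1, length(sel)), "<=", length(sel) - 1)
    }
  }

  lb <- numeric(ntot); ub <- numeric(ntot)
  lb[iv] <- if (cfg@mode == "kegg") rep(-cfg@bigM, nv) else net@lb
  ub[iv] <- net@ub
  if (ny) { lb[iy] <- 0; ub[iy] <- cfg@bigM }
  bins <- c(id, ie, iff, ib, ih)
  lb[bins] <- 0; ub[bins] <- 1

  obj <- numeric(ntot)
  if (step == 1) obj[id] <- 1 else obj[c(ib, ih)] <- 1

  list(A = A, sense = sense, rhs = rhs, lb = lb, ub = ub, obj = obj,
       binaries = bins, iv = iv, iy = iy, id = id, ie = ie, iff = iff,
       ib = ib, ih = ih, rxns = rxns, candIds = candIds, irr = irr,
       maximize = (step == 1))
}

solutionFromVector <- function(prog, x, ZStar, NStar, mode) {
  pick <- function(idx, nms) stats::setNames(round(x[idx], 9), nms)
  bin <- function(idx, nms) stats::setNames(round(x[idx]), nms)
  Lnames <- paste(seq_along(prog$id))
  new("GapFillSolution",
      v = pick(prog$iv, prog$rxns),
      y = pick(prog$iy, prog$candIds),
      d = bin(prog$id, Lnames), e = bin(prog$ie, Lnames),
      f = bin(prog$iff, Lnames),
      b = if (length(prog$ib)) bin(prog$ib, prog$candIds)
          else stats::setNames(numeric(0), character(0)),
      h = if (length(prog$ih)) bin(prog$ih, prog$irr)
          else stats::setNames(numeric(0), character(0)),
      ZStar = ZStar, NStar = NStar, mode = mode)
}

#' Step 1: maximum number of resolvable inconsistencies
#'
#' @param net the preprocessed \code{MetabolicNetwork}.
#' @param universal a \code{UniversalSet}; its mode must match \code{cfg}.
#' @param inc an \code{InconsistencyInstance} with non-empty L.
#' @param cfg a \code{MilpConfig}.
#' @return list with \code{ZStar} (count) and \code{solution} (a witness
#'   \code{GapFillSolution}; modification indicators are not yet minimized).
#' @export
solveStep1 <- function(net, universal, inc, cfg = milpConfig()) {
  if (nrow(inc@L) == 0) stop("inconsistency set L is empty")
  if (universal@mode != cfg@mode)
    stop("universal set mode '", universal@mode,
         "' does not match config mode '", cfg@mode, "'")
  prog <- buildRepairProgram(net, universal, inc, cfg, step = 1)
  res <- solveMixedIntegerProgram(prog$obj, prog$A, prog$sense, prog$rhs,
                                  prog$lb, prog$ub, prog$binaries,
                                  maximize = TRUE,
                                  node_limit = cfg@nodeLimit)
  if (res$status != "optimal")
    stop("step-1 program unexpectedly infeasible")
  ZStar <- round(res$objective)
  list(ZStar = ZStar,
       solution = solutionFromVector(prog, res$x, ZStar, NA_real_, cfg@mode))
}

#' Step 2: minimum number of modifications achieving the step-1 optimum
#'
#' @inheritParams solveStep1
#' @param ZStar step-1 optimum on identical inputs.
#' @param cuts list of integer cuts (internal; used by
#'   \code{\link{enumerateAlternatives}}), each \code{list(b = , h = )}.
#' @return a \code{GapFillSolution} with \code{NStar} set, or \code{NULL}
#'   when cuts have exhausted the solution pool.
#' @export
solveStep2 <- function(net, universal, inc, ZStar, cfg = milpConfig(),
                       cuts = list()) {
  prog <- buildRepairProgram(net, universal, inc, cfg, step = 2,
                             ZStar = ZStar, cuts = cuts)
  res <- solveMixedIntegerProgram(prog$obj, prog$A, prog$sense, prog$rhs,
                                  prog$lb, prog$ub, prog$binaries,
                                  maximize = FALSE,
                                  node_limit = cfg@nodeLimit)
  if (res$status != "optimal") {
    if (length(cuts) > 0) return(NULL)
    stop("step-2 program infeasible at Z* = ", ZStar,
         "; inconsistent inputs")
  }
  solutionFromVector(prog, res$x, ZStar, round(res$objective), cfg@mode)
}

selectedSet <- function(sol) {
  list(b = names(sol@b)[sol@b > 0.5], h = names(sol@h)[sol@h > 0.5])
}

#' Enumerate all alternate optima of step 2 by integer cuts
#'
#' Re-solves step 2, each time excluding every previously found selected set
#' (added candidates plus reversed reactions) through a cut demanding at
#' least one element differ.  Stops when the objective exceeds \code{NStar}
#' or the enumeration cap is reached (flagged via the \code{capped}
#' attribute).
#'
#' @inheritParams solveStep2
#' @param NStar step-2 optimum.
#' @return list of \code{GapFillSolution}, canonically ordered.
#' @export
enumerateAlternatives <- function(net, universal, inc, ZStar, NStar,
                                  cfg = milpConfig()) {
  sols <- list()
  cuts <- list()
  capped <- FALSE
  repeat {
    sol <- solveStep2(net, universal, inc, ZStar, cfg, cuts = cuts)
    if (is.null(sol) || sol@NStar > NStar + 0.5) break
    sols[[length(sols) + 1L]] <- sol
    sel <- selectedSet(sol)
    if (length(sel$b) + length(sel$h) == 0) break  # empty set: unique optimum
    cuts[[length(cuts) + 1L]] <- sel
    if (length(sols) >= cfg@maxAlternatives) { capped <- TRUE; break }
  }
  keys <- vapply(sols, function(s) {
    sel <- selectedSet(s)
    paste(paste(sort(sel$b), collapse = ","),
          paste(sort(sel$h), collapse = ","), sep = "|")
  }, character(1))
  sols <- sols[order(keys)]
  attr(sols, "capped") <- capped
  sols
}

#' Apply a solution to the network
#'
#' Selected candidate columns are appended as irreversible reactions in
#' their stated direction; reactions with \code{h = 1} are made reversible.
#' All other bounds are the original ones.
#'
#' @param net the original (preprocessed) network.
#' @param universal the \code{UniversalSet} the solution drew from.
#' @param sol a \code{GapFillSolution}.
#' @return an augmented \code{MetabolicNetwork}.
#' @export
applySolution <- function(net, universal, sol) {
  lb <- net@lb
  rev <- names(sol@h)[sol@h > 0.5]
  lb[match(rev, reactionIds(net))] <- -DEFAULT_BOUND
  out <- metabolicNetwork(net@S, lb = lb, ub = net@ub, gpr = net@gpr,
                          compartments = net@compartments)
  add <- names(sol@b)[sol@b > 0.5]
  if (length(add)) {
    jj <- match(add, colnames(universal@U))
    cols <- lapply(jj, function(j) {
      col <- universal@U[, j]
      nz <- which(col != 0)
      stats::setNames(as.numeric(col[nz]), rownames(universal@U)[nz])
    })
    newMets <- setdiff(unique(unlist(lapply(cols, names))),
                       metaboliteIds(out))
    out <- appendReactions(out, add, cols, lb = rep(0, length(add)),
                           ub = rep(DEFAULT_BOUND, length(add)),
                           newMets = newMets)
  }
  out
}

#' Verify a solution by re-running coupling analysis
#'
#' The witness flux vector certifies broken ratios only pointwise; this
#' check builds the actually modified network and recomputes the full
#' coupling table: every pair claimed resolved must no longer be fully
#' coupled (re-coupling at a new ratio counts as a mismatch), and every
#' high-correlation pair must remain fully coupled at its original ratio.
#'
#' @inheritParams applySolution
#' @param inc the \code{InconsistencyInstance} the solution addressed.
#' @return list with \code{clean} (logical) and \code{report} (data.frame:
#'   pair, set, claim, observed relation, ok).  Mismatches are data, not
#'   errors.
#' @export
verifySolution <- function(net, universal, inc, sol) {
  aug <- applySolution(net, universal, sol)
  ct <- couplingTable(aug)
  rows <- list()
  for (k in seq_len(nrow(inc@L))) {
    if (sol@d[k] < 0.5) next
    cp <- couplingOf(ct, inc@L$i[k], inc@L$j[k])
    rows[[length(rows) + 1L]] <- data.frame(
      i = inc@L$i[k], j = inc@L$j[k], set = "L", claim = "not fully coupled",
      observed = cp$relation, ok = cp$relation != "fully",
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(inc@H))) {
    cp <- couplingOf(ct, inc@H$i[k], inc@H$j[k])
    okRatio <- cp$relation == "fully" && !is.na(cp$ratio) &&
      abs(cp$ratio - inc@H$ratio[k]) <= 1e-6 * max(1, abs(inc@H$ratio[k]))
    rows[[length(rows) + 1L]] <- data.frame(
      i = inc@H$i[k], j = inc@H$j[k], set = "H", claim = "fully coupled",
      observed = cp$relation, ok = okRatio, stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = character(0), j = character(0), set = character(0),
               claim = character(0), observed = character(0), ok = logical(0))
  list(clean = all(report$ok), report = report)
}

# kegg / reversibility attribution: is the pair broken with only the added
# candidates, original bounds (no reversibility change)?
attributePhase1 <- function(net, universal, sol, i, j) {
  solNoH <- sol
  solNoH@h[] <- 0
  aug <- applySolution(net, universal, solNoH)
  cp <- couplingOf(couplingTable(aug), i, j)
  if (cp$relation != "fully") "kegg_reaction" else "reversibility_change"
}

#' Staged repair: database candidates first, then exchange reactions
#'
#' Phase 1 runs the two-step program in \code{"kegg"} mode (irreversibility
#' relaxation active).  Pairs left unresolved feed phase 2 in
#' \code{"exchange"} mode, where irreversible reactions keep their zero
#' lower bounds and only exchange candidates are available.  Each pair is
#' annotated with how it was resolved: \code{kegg_reaction},
#' \code{reversibility_change}, \code{exchange}, or \code{unresolved}.
#' With \code{resolution = "one_by_one"} the full staged procedure is
#' re-instantiated per inconsistent pair (all H constraints retained).
#'
#' @param net the preprocessed \code{MetabolicNetwork}.
#' @param keggUniversal \code{UniversalSet} with \code{mode = "kegg"}
#'   (may have zero candidates).
#' @param exchUniversal \code{UniversalSet} with \code{mode = "exchange"}.
#' @param inc an \code{InconsistencyInstance}.
#' @param cfg a \code{MilpConfig}; its \code{mode} is managed internally.
#' @return list with \code{provenance} (data.frame pair -> status),
#'   \code{solutions} (named list: \code{kegg}, \code{exchange}; entries may
#'   be \code{NULL}), and for one-by-one resolution \code{perPair}, a list
#'   of per-pair staged results.
#' @export
solveWithFallback <- function(net, keggUniversal, exchUniversal, inc,
                              cfg = milpConfig()) {
  if (cfg@resolution == "one_by_one") {
    per <- list()
    prov <- list()
    cfg1 <- cfg; cfg1@resolution <- "all_at_once"
    for (k in seq_len(nrow(inc@L))) {
      sub <- new("InconsistencyInstance", L = inc@L[k, , drop = FALSE],
                 H = inc@H, low = inc@low, high = inc@high,
                 conflicts = inc@conflicts[0, , drop = FALSE])
      res <- solveWithFallback(net, keggUniversal, exchUniversal, sub, cfg1)
      per[[k]] <- res
      prov[[k]] <- res$provenance
    }
    return(list(provenance = do.call(rbind, prov), solutions = NULL,
                perPair = per))
  }

  L <- inc@L
  status <- rep("unresolved", nrow(L))
  solKegg <- NULL; solExch <- NULL

  cfgK <- cfg; cfgK@mode <- "kegg"
  if (nrow(L) > 0) {
    s1 <- solveStep1(net, keggUniversal, inc, cfgK)
    if (s1$ZStar > 0) {
      solKegg <- solveStep2(net, keggUniversal, inc, s1$ZStar, cfgK)
      resolved <- which(solKegg@d > 0.5)
      for (k in resolved)
        status[k] <- attributePhase1(net, keggUniversal, solKegg,
                                     L$i[k], L$j[k])
    }
  }

  left <- which(status == "unresolved")
  if (length(left) > 0 && ncol(exchUniversal@U) > 0) {
    sub <- new("InconsistencyInstance", L = L[left, , drop = FALSE],
               H = inc@H, low = inc@low, high = inc@high,
               conflicts = inc@conflicts[0, , drop = FALSE])
    cfgE <- cfg; cfgE@mode <- "exchange"
    s1e <- solveStep1(net, exchUniversal, sub, cfgE)
    if (s1e$ZStar > 0) {
      solExch <- solveStep2(net, exchUniversal, sub, s1e$ZStar, cfgE)
      status[left[solExch@d > 0.5]] <- "exchange"
    }
  }

  list(provenance = data.frame(i = L$i, j = L$j, status = status,
                               stringsAsFactors = FALSE),
       solutions = list(kegg = solKegg, exchange = solExch))
}
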