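# Flux coupling analysis by linear-programming probes, plus an exhaustive
# oracle over the vertices of the steady-state polytope for small networks.
#
# Classification contract (pair i, j; i < j lexicographically):
#   fully               v_i = lambda * v_j in every feasible steady state
#   directional_i_to_j  v_i = 0 forces v_j = 0 (but not conversely)
#   directional_j_to_i  v_j = 0 forces v_i = 0 (but not conversely)
#   partial             each zero flux forces the other, but no constant ratio
#   uncoupled           neither forces the other
# Blocked reactions never appear in a pair.

ZERO_TOL <- 1e-9     # forced-zero / blocked decisions
RATIO_TOL <- 1e-6    # relative tolerance for ratio equality

#' Reactions that cannot carry steady-state flux
#'
#' A reaction is blocked when both its maximum and minimum achievable flux
#' over \{v : S v = 0, lb <= v <= ub\} lie within the zero tolerance of 0.
#'
#' @param net a \code{MetabolicNetwork}.
#' @param zero_tol absolute tolerance for "cannot carry flux".
#' @return character vector of blocked reaction identifiers.
#' @export
findBlocked <- function(net, zero_tol = ZERO_TOL) {
  forced <- forcedZeroSet(net, zero_tol = zero_tol)
  reactionIds(net)[forced]
}

# Indices of reactions forced to zero flux, optionally with some fluxes
# pinned to zero.  Two generic-objective probes clear most reactions that
# can carry flux in one solve each; the survivors get targeted max/min
# probes.  Exact: a reaction is returned iff its flux is zero in every
# feasible steady state of the constrained system.
forcedZeroSet <- function(net, fixedIdx = integer(0), zero_tol = ZERO_TOL) {
  S <- as.matrix(net@S)
  n <- ncol(S)
  extraA <- NULL; extraRhs <- NULL; extraSense <- NULL
  if (length(fixedIdx)) {
    extraA <- matrix(0, length(fixedIdx), n)
    for (k in seq_along(fixedIdx)) extraA[k, fixedIdx[k]] <- 1
    extraRhs <- rep(0, length(fixedIdx))
    extraSense <- rep("=", length(fixedIdx))
  }
  probe <- function(obj, maximize) {
    res <- fluxOptimum(S, net@lb, net@ub, obj, maximize = maximize,
                       extraA = extraA, extraRhs = extraRhs,
                       extraSense = extraSense)
    if (res$status != "optimal")
      stop("steady-state flux system unexpectedly infeasible")
    res
  }
  nonzero <- logical(n)
  w <- sin(seq_len(n) * 2.399963)   # deterministic generic objective
  for (sgn in c(1, -1)) {
    x <- probe(sgn * w, maximize = TRUE)$x
    nonzero[abs(x) > zero_tol] <- TRUE
  }
  for (j in seq_len(n)) {
    if (nonzero[j] || j %in% fixedIdx) next
    obj <- numeric(n); obj[j] <- 1
    x <- probe(obj, maximize = TRUE)$x
    nonzero[abs(x) > zero_tol] <- TRUE
    if (!nonzero[j]) {
      x <- probe(obj, maximize = FALSE)$x
      nonzero[abs(x) > zero_tol] <- TRUE
    }
  }
  which(!nonzero)
}

# min and max of flux j, optionally with one flux pinned to a value
fluxRange <- function(net, j, fixedIdx = NULL, fixedValue = 0) {
  S <- as.matrix(net@S)
  n <- ncol(S)
  extraA <- NULL; extraRhs <- NULL; extraSense <- NULL
  if (!is.null(fixedIdx)) {
    extraA <- matrix(0, 1, n); extraA[1, fixedIdx] <- 1
    extraRhs <- fixedValue; extraSense <- "="
  }
  obj <- numeric(n); obj[j] <- 1
  up <- fluxOptimum(S, net@lb, net@ub, obj, maximize = TRUE,
                    extraA = extraA, extraRhs = extraRhs,
                    extraSense = extraSense)
  lo <- fluxOptimum(S, net@lb, net@ub, obj, maximize = FALSE,
                    extraA = extraA, extraRhs = extraRhs,
                    extraSense = extraSense)
  if (up$status != "optimal" || lo$status != "optimal")
    stop("steady-state flux system unexpectedly infeasible")
  c(min = lo$objective, max = up$objective)
}

#' Pairwise flux coupling classification
#'
#' Coupling is decided by linear-programming probes: directional coupling by
#' fixing one flux to zero and maximizing the magnitude of the other; full
#' coupling by equality of the minimum and maximum of \code{v_i} subject to
#' \code{v_j} fixed at a feasible nonzero level (both signs are probed when
#' the reference reaction can run in both directions).  Ratios of fully
#' coupled pairs are stored signed: antiparallel reversible pairs get a
#' negative ratio.
#'
#' @param net a preprocessed \code{MetabolicNetwork} (biomass removed, see
#'   \code{\link{preprocessBiomass}}).
#' @param zero_tol absolute tolerance for forced-zero decisions.
#' @param ratio_tol relative tolerance for ratio equality.
#' @return a \code{\linkS4class{CouplingTable}}.
#' @export
couplingTable <- function(net, zero_tol = ZERO_TOL, ratio_tol = RATIO_TOL) {
  rxns <- reactionIds(net)
  n <- length(rxns)
  blockedIdx <- forcedZeroSet(net, zero_tol = zero_tol)
  live <- setdiff(seq_len(n), blockedIdx)

  # forces[a, b]: does v_a = 0 force v_b = 0?
  forces <- matrix(FALSE, n, n)
  for (a in live) {
    fz <- forcedZeroSet(net, fixedIdx = a, zero_tol = zero_tol)
    forces[a, intersect(fz, live)] <- TRUE
    forces[a, a] <- FALSE
  }

  rangeCache <- list()
  liveRange <- function(j) {
    key <- as.character(j)
    if (is.null(rangeCache[[key]]))
      rangeCache[[key]] <<- fluxRange(net, j)
    rangeCache[[key]]
  }
  ratioProbe <- function(i, j, t) {
    rng <- fluxRange(net, i, fixedIdx = j, fixedValue = t)
    c(rng[["min"]] / t, rng[["max"]] / t)
  }
  rows <- list()
  if (length(live) >= 2) {
    ord <- live[order(rxns[live])]
    for (ai in seq_len(length(ord) - 1)) {
      for (bi in (ai + 1):length(ord)) {
        i <- ord[ai]; j <- ord[bi]
        fij <- forces[i, j]; fji <- forces[j, i]
        rel <- "uncoupled"; ratio <- NA_real_
        if (fij && !fji) rel <- "directional_i_to_j"
        if (fji && !fij) rel <- "directional_j_to_i"
        if (fij && fji) {
          rng <- liveRange(j)
          probes <- list()
          if (rng[["max"]] > zero_tol)
            probes <- c(probes, rng[["max"]] / 2)
          if (rng[["min"]] < -zero_tol)
            probes <- c(probes, rng[["min"]] / 2)
          lams <- unlist(lapply(probes, function(t) ratioProbe(i, j, t)))
          spread <- max(lams) - min(lams)
          if (spread <= ratio_tol * max(1, max(abs(lams)))) {
            rel <- "fully"; ratio <- mean(lams)
          } else rel <- "partial"
        }
        rows[[length(rows) + 1L]] <-
          data.frame(i = rxns[i], j = rxns[j], relation = rel, ratio = ratio,
                     stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = character(0), j = character(0),
               relation = character(0), ratio = numeric(0))
  new("CouplingTable", blocked = rxns[blockedIdx], pairs = pairs)
}

#' Brute-force coupling oracle by polytope vertex enumeration
#'
#' Enumerates every vertex of the steady-state polytope (and of each
#' zero-flux slice) and reads the coupling relations directly off the vertex
#' set.  Identical contract to \code{\link{couplingTable}} but computed by a
#' completely different route; restricted to small networks.
#'
#' @param net a \code{MetabolicNetwork} with at most \code{cap} reactions.
#' @param cap refusal threshold (default 12 reactions).
#' @param zero_tol,ratio_tol tolerances, as in \code{\link{couplingTable}}.
#' @return a \code{\linkS4class{CouplingTable}}.
#' @export
oracleCoupling <- function(net, cap = 12L, zero_tol = ZERO_TOL,
                           ratio_tol = RATIO_TOL) {
  rxns <- reactionIds(net)
  n <- length(rxns)
  if (n > cap) stop("oracleCoupling refuses networks with more than ",
                    cap, " reactions")
  S <- as.matrix(net@S)
  V <- enumeratePolytopeVertices(S, rep(0, nrow(S)), net@lb, net@ub)
  if (nrow(V) == 0) stop("steady-state polytope has no vertices")
  vmax <- apply(abs(V), 2, max)
  blockedIdx <- which(vmax <= 1e-6)
  live <- setdiff(seq_len(n), blockedIdx)

  forces <- matrix(FALSE, n, n)
  for (a in live) {
    Sa <- rbind(S, as.numeric(seq_len(n) == a))
    Va <- enumeratePolytopeVertices(Sa, rep(0, nrow(Sa)), net@lb, net@ub)
    mx <- if (nrow(Va)) apply(abs(Va), 2, max) else rep(0, n)
    forces[a, live] <- mx[live] <= 1e-6
    forces[a, a] <- FALSE
  }

  rows <- list()
  if (length(live) >= 2) {
    ord <- live[order(rxns[live])]
    for (ai in seq_len(length(ord) - 1)) {
      for (bi in (ai + 1):length(ord)) {
        i <- ord[ai]; j <- ord[bi]
        fij <- forces[i, j]; fji <- forces[j, i]
        rel <- "uncoupled"; ratio <- NA_real_
        if (fij && !fji) rel <- "directional_i_to_j"
        if (fji && !fij) rel <- "directional_j_to_i"
        if (fij && fji) {
          nzv <- V[abs(V[, j]) > 1e-6, , drop = FALSE]
          lams <- nzv[, i] / nzv[, j]
          spread <- if (length(lams)) max(lams) - min(lams) else 0
          if (length(lams) && spread <= ratio_tol * max(1, max(abs(lams)))) {
            rel <- "fully"; ratio <- mean(lams)
          } else rel <- "partial"
        }
        rows[[length(rows) + 1L]] <-
          data.frame(i = rxns[i], j = rxns[j], relation = rel, ratio = ratio,
                     stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = character(0), j = character(0),
               relation = character(0), ratio = numeric(0))
  new("CouplingTable", blocked = rxns[blockedIdx], pairs = pairs)
}

#' Look up the coupling relation of a reaction pair
#'
#' @param tab a \code{CouplingTable}.
#' @param a,b reaction identifiers (order-free; directional relations are
#'   reoriented to the requested order).
#' @return list with \code{relation} and \code{ratio} (ratio = v_a / v_b for
#'   fully coupled pairs).
#' @export
couplingOf <- function(tab, a, b) {
  p <- tab@pairs
  hit <- which((p$i == a & p$j == b) | (p$i == b & p$j == a))
  if (length(hit) == 0) return(list(relation = "absent", ratio = NA_real_))
  row <- p[hit[1], ]
  rel <- row$relation; ratio <- row$ratio
  if (row$i != a) {  # reorient
    if (rel == "directional_i_to_j") rel <- "directional_j_to_i"
    else if (rel == "directional_j_to_i") rel <- "directional_i_to_j"
    if (!is.na(ratio) && abs(ratio) > 0) ratio <- 1 / ratio
  }
  list(relation = rel, ratio = ratio)
}

#' Fully coupled pairs of a coupling table
#' @param tab a \code{CouplingTable}.
#' @return data.frame (\code{i}, \code{j}, \code{ratio}).
#' @export
fullyCoupledPairs <- function(tab) {
  p <- tab@pairs[tab@pairs$relation == "fully", c("i", "j", "ratio")]
  rownames(p) <- NULL
  p
}

#' Serialize a coupling table to TSV
#' @param tab a \code{CouplingTable}.
#' @param path output path.
#' @export
writeCouplingTable <- function(tab, path) {
  utils::write.table(tab@pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
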