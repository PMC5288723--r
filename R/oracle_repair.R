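# Brute-force oracle for the repair program: exhaustive search over subsets
# of candidate columns and irreversibility relaxations, with "coupling
# broken" decided by vertex enumeration of the resulting steady-state
# polytope.  Completely independent of the simplex / branch-and-bound route.

# Can each low-correlation pair deviate from its ratio somewhere in the
# polytope of the network augmented with the selected candidates and
# relaxations (high-correlation ratios enforced as equality rows)?
oracleBreakablePairs <- function(net, universal, inc, candSel, revSel,
                                 bigM = 1000, tol = 1e-5) {
  rxns <- reactionIds(net)
  S <- as.matrix(net@S)
  lb <- net@lb; ub <- net@ub
  lb[match(revSel, rxns)] <- -bigM
  if (length(candSel)) {
    Usub <- as.matrix(universal@U[, candSel, drop = FALSE])
    Usub <- Usub[rowSums(Usub != 0) > 0, , drop = FALSE]
    allMets <- union(rownames(S), rownames(Usub))
    Sx <- matrix(0, length(allMets), ncol(S) + ncol(Usub),
                 dimnames = list(allMets, c(colnames(S), candSel)))
    Sx[rownames(S), seq_len(ncol(S))] <- S
    Sx[rownames(Usub), ncol(S) + seq_len(ncol(Usub))] <- Usub
    S <- Sx
    lb <- c(lb, rep(0, length(candSel)))
    ub <- c(ub, rep(bigM, length(candSel)))
  }
  n <- ncol(S)
  H <- inc@H
  for (k in seq_len(nrow(H))) {
    row <- numeric(n)
    row[match(H$i[k], colnames(S))] <- 1
    row[match(H$j[k], colnames(S))] <- -H$ratio[k]
    S <- rbind(S, row)
  }
  V <- enumeratePolytopeVertices(S, rep(0, nrow(S)), lb, ub)
  L <- inc@L
  vapply(seq_len(nrow(L)), function(k) {
    ui <- match(L$i[k], colnames(S)); wj <- match(L$j[k], colnames(S))
    dev <- abs(V[, ui] - L$ratio[k] * V[, wj])
    any(dev > tol)
  }, logical(1))
}

#' Exhaustive subset oracle for the two-step repair program
#'
#' Searches all subsets of candidate columns and (in kegg mode)
#' irreversibility relaxations in order of increasing size, deciding for
#' each whether the selected modifications let every still-targeted pair
#' deviate from its coupling ratio.  Returns the maximum number of
#' resolvable pairs, the minimum modification count achieving it, and every
#' optimal selected set.  Exponential; intended for fixtures with at most a
#' dozen candidates.
#'
#' @param net preprocessed \code{MetabolicNetwork}.
#' @param universal a \code{UniversalSet}.
#' @param inc an \code{InconsistencyInstance}.
#' @param cfg a \code{MilpConfig} (mode decides whether relaxations are
#'   searched).
#' @param maxSize largest modification count searched before giving up.
#' @return list with \code{ZStar}, \code{NStar} and \code{optima} (list of
#'   \code{list(b=, h=)}), sorted canonically.
#' @export
bruteForceRepair <- function(net, universal, inc, cfg = milpConfig(),
                             maxSize = 6L) {
  cands <- colnames(universal@U)
  if (is.null(cands)) cands <- character(0)
  revs <- if (cfg@mode == "kegg") irreversibleReactions(net) else character(0)
  if (length(cands) > 12)
    stop("subset oracle refuses more than 12 candidate columns")
  # step-1 ceiling: every candidate in, every irreversibility relaxed
  ZStar <- sum(oracleBreakablePairs(net, universal, inc, cands, revs,
                                    bigM = cfg@bigM))
  if (ZStar == 0)
    return(list(ZStar = 0, NStar = 0,
                optima = list(list(b = character(0), h = character(0)))))
  items <- c(if (length(cands)) paste0("b:", cands),
             if (length(revs)) paste0("h:", revs))
  for (size in 0:maxSize) {
    hits <- list()
    if (size == 0) {
      combos <- list(integer(0))
    } else if (size <= length(items)) {
      cm <- utils::combn(length(items), size)
      combos <- lapply(seq_len(ncol(cm)), function(j) cm[, j])
    } else combos <- list()
    for (sel in combos) {
      tags <- items[sel]
      bSel <- sub("^b:", "", tags[startsWith(tags, "b:")])
      hSel <- sub("^h:", "", tags[startsWith(tags, "h:")])
      broken <- oracleBreakablePairs(net, universal, inc, bSel, hSel,
                                     bigM = cfg@bigM)
      if (sum(broken) == ZStar)
        hits[[length(hits) + 1L]] <- list(b = sort(bSel), h = sort(hSel))
    }
    if (length(hits)) {
      keys <- vapply(hits, function(o)
        paste(paste(o$b, collapse = ","), paste(o$h, collapse = ","),
              sep = "|"), character(1))
      return(list(ZStar = ZStar, NStar = size, optima = hits[order(keys)]))
    }
  }
  stop("subset oracle exhausted maxSize without matching the ceiling")
}
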