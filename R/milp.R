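# Branch-and-bound mixed-integer solver over the bounded simplex.
#
# Depth-first search with most-fractional branching; for maximization the
# "variable = 1" child is explored first (solutions here switch indicators
# on).  With an integral objective the bound can be rounded, which prunes
# aggressively.  Everything is deterministic: no randomized tie-breaking.

#' @keywords internal
#' @noRd
solveMixedIntegerProgram <- function(obj, A, sense, rhs, lower, upper,
                                     binary, maximize = FALSE,
                                     integral_objective = TRUE,
                                     node_limit = 200000L, tol = 1e-6) {
  stopifnot(all(binary %in% seq_along(obj)))
  lower[binary] <- pmax(lower[binary], 0)
  upper[binary] <- pmin(upper[binary], 1)

  best <- list(x = NULL, objective = if (maximize) -Inf else Inf)
  nodes <- 0L
  sgn <- if (maximize) 1 else -1   # compare in "maximize sgn*obj" space

  bnd_value <- function(z) sgn * z

  recurse <- function(lo, up) {
    nodes <<- nodes + 1L
    if (nodes > node_limit) stop("branch-and-bound node limit exceeded")
    rel <- solveLinearProgram(obj, A, sense, rhs, lo, up, maximize = maximize)
    if (rel$status != "optimal") return(invisible(NULL))
    bound <- bnd_value(rel$objective)
    incumbent <- bnd_value(best$objective)
    if (is.finite(incumbent)) {
      bnd_eff <- if (integral_objective) floor(bound + 1e-7) else bound
      if (bnd_eff <= incumbent + 1e-7) return(invisible(NULL))
    }
    tryIncumbent <- function() {
      lo2 <- lo; up2 <- up
      lo2[binary] <- round(rel$x[binary]); up2[binary] <- lo2[binary]
      fix <- solveLinearProgram(obj, A, sense, rhs, lo2, up2,
                                maximize = maximize)
      if (fix$status != "optimal") return(NA_real_)
      if (bnd_value(fix$objective) > bnd_value(best$objective) + 1e-9)
        best <<- list(x = fix$x, objective = fix$objective)
      fix$objective
    }
    # Only binaries not yet pinned by branching are branchable.  Rounding is
    # a heuristic, never a proof: an indicator can sit at 1 - eps/bigM,
    # numerically a hair from integral yet genuinely fractional, so a node
    # is closed by rounding only when the rounded solution attains the LP
    # bound; otherwise any nonzero fractionality is branched away.
    unpinned <- binary[lo[binary] < up[binary] - 0.5]
    frac <- abs(rel$x[unpinned] - round(rel$x[unpinned]))
    if (length(unpinned) == 0L) { tryIncumbent(); return(invisible(NULL)) }
    if (max(frac) <= tol) {
      fixobj <- tryIncumbent()
      if (!is.na(fixobj) && bnd_value(fixobj) >= bound - 1e-7)
        return(invisible(NULL))               # node solved at its bound
      if (max(frac) <= 1e-12) return(invisible(NULL))
    }
    j <- unpinned[which.max(frac)]
    first_up <- maximize
    for (side in if (first_up) c("up", "down") else c("down", "up")) {
      lo2 <- lo; up2 <- up
      if (side == "up") lo2[j] <- 1 else up2[j] <- 0
      recurse(lo2, up2)
    }
    invisible(NULL)
  }
  recurse(lower, upper)
  if (is.null(best$x))
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                nodes = nodes))
  list(status = "optimal", x = best$x, objective = best$objective,
       nodes = nodes)
}
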