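# Exhaustive vertex enumeration for small flux polytopes.
#
# The steady-state flux space {v : A v = b, lb <= v <= ub} is a bounded
# polytope; every vertex has at least n - rank(A) coordinates pinned to a
# bound.  Enumerating all choices of pinned coordinates and bound sides gives
# the complete (possibly degenerate) vertex set.  This is exponential and is
# only ever applied to networks of a dozen reactions or fewer, where it acts
# as a brute-force oracle that is entirely independent of the simplex code.

#' @keywords internal
#' @noRd
enumeratePolytopeVertices <- function(A, b, lb, ub, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)),
            all(is.finite(ub)), nrow(A) == length(b))
  qa <- qr(A)
  r <- qa$rank
  k <- n - r
  verts <- list()
  push <- function(v) {
    if (all(v >= lb - tol) && all(v <= ub + tol) &&
        max(abs(A %*% v - b)) <= tol * max(1, max(abs(b)), max(abs(v))))
      verts[[length(verts) + 1L]] <<- pmin(pmax(v, lb), ub)
  }
  if (k == 0L) {
    v <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (!is.null(v)) push(v)
  } else {
    subsets <- utils::combn(n, k)
    for (s in seq_len(ncol(subsets))) {
      Fidx <- subsets[, s]
      Arest <- A[, -Fidx, drop = FALSE]
      qr_rest <- qr(Arest)
      if (qr_rest$rank < n - k) next  # pinned set does not determine a point
      for (mask in 0:(2^k - 1)) {
        side <- bitwAnd(rep(mask, k), bitwShiftL(1L, seq_len(k) - 1L)) > 0
        vF <- ifelse(side, ub[Fidx], lb[Fidx])
        if (any(side & abs(ub[Fidx] - lb[Fidx]) < tol)) next  # same point twice
        rhs <- b - as.vector(A[, Fidx, drop = FALSE] %*% vF)
        vR <- tryCatch(qr.coef(qr_rest, rhs), error = function(e) NULL)
        if (is.null(vR) || anyNA(vR)) next
        if (max(abs(Arest %*% vR - rhs)) > tol * max(1, max(abs(rhs)))) next
        v <- numeric(n)
        v[Fidx] <- vF
        v[-Fidx] <- vR
        push(v)
      }
    }
  }
  if (length(verts) == 0L) return(matrix(numeric(0), nrow = 0, ncol = n))
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}
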