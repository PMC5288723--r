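# Dense bounded-variable two-phase simplex.
#
# Solves   optimize  c'x   s.t.  A x {<=,=,>=} rhs,   lower <= x <= upper.
#
# All structural variables must have finite bounds (every flux in this package
# is box-constrained, so nothing of generality is lost); slack variables are
# [0, Inf). Bland's rule is used for both the entering and the leaving
# variable, which guarantees termination at the price of speed -- the linear
# programs solved here are tiny (tens of rows), so robustness wins.

#' @keywords internal
#' @noRd
solveLinearProgram <- function(obj, A, sense, rhs, lower, upper,
                               maximize = FALSE, tol = 1e-9,
                               max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(sense) == m, length(rhs) == m,
            length(lower) == n, length(upper) == n,
            all(sense %in% c("<=", ">=", "=")))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("all variable bounds must be finite")
  if (any(lower > upper + 1e-12))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))

  cc <- if (maximize) -obj else obj

  # slack columns turn every row into an equality
  n_le <- sum(sense == "<=")
  n_ge <- sum(sense == ">=")
  n_sl <- n_le + n_ge
  Afull <- cbind(A, matrix(0, m, n_sl))
  sl_of_row <- integer(m)
  k <- n
  for (i in seq_len(m)) {
    if (sense[i] == "<=") { k <- k + 1L; Afull[i, k] <-  1; sl_of_row[i] <- k }
    if (sense[i] == ">=") { k <- k + 1L; Afull[i, k] <- -1; sl_of_row[i] <- k }
  }
  lo <- c(lower, rep(0, n_sl))
  up <- c(upper, rep(Inf, n_sl))
  cost <- c(cc, rep(0, n_sl))
  ntot <- n + n_sl

  # initial nonbasic point: structurals at lower bound, slacks at 0
  x <- lo
  x[!is.finite(x)] <- 0
  resid <- rhs - as.vector(Afull %*% x)

  # artificial columns sign-matched to the residual so their value is >= 0
  Aart <- matrix(0, m, m)
  for (i in seq_len(m)) Aart[i, i] <- if (resid[i] >= 0) 1 else -1
  Afull <- cbind(Afull, Aart)
  lo <- c(lo, rep(0, m))
  up <- c(up, rep(Inf, m))
  cost <- c(cost, rep(0, m))
  x <- c(x, abs(resid))
  art_idx <- ntot + seq_len(m)

  basis <- art_idx
  at_upper <- rep(FALSE, ntot + m)   # meaningful for nonbasic only
  Binv <- diag(1 / ifelse(resid >= 0, 1, -1), m, m)

  run_phase <- function(phase_cost, basis, x, at_upper, Binv, iter0) {
    it <- iter0
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit exceeded")
      if (it %% 60L == 0L) {  # periodic refactorization for numerical hygiene
        B <- Afull[, basis, drop = FALSE]
        Binv <- tryCatch(solve(B), error = function(e) NULL)
        if (is.null(Binv)) stop("singular basis during refactorization")
        nb <- setdiff(seq_along(x), basis)
        xn <- x
        x[basis] <- as.vector(Binv %*% (rhs - Afull[, nb, drop = FALSE] %*% xn[nb]))
      }
      yrow <- crossprod(phase_cost[basis], Binv)            # 1 x m
      rc <- phase_cost - as.vector(yrow %*% Afull)
      isb <- logical(length(x)); isb[basis] <- TRUE
      elig <- which(!isb & ((!at_upper & rc < -tol) | (at_upper & rc > tol)))
      if (length(elig) == 0L)
        return(list(basis = basis, x = x, at_upper = at_upper,
                    Binv = Binv, iter = it, optimal = TRUE))
      q <- min(elig)                                        # Bland: entering
      dir <- if (at_upper[q]) -1 else 1
      w <- as.vector(Binv %*% Afull[, q])
      xb <- x[basis]
      dw <- dir * w
      tlim <- rep(Inf, m)
      pos <- dw > tol
      neg <- dw < -tol
      tlim[pos] <- (xb[pos] - lo[basis][pos]) / dw[pos]
      ubb <- up[basis]
      fin_neg <- neg & is.finite(ubb)
      tlim[fin_neg] <- (ubb[fin_neg] - xb[fin_neg]) / (-dw[fin_neg])
      tlim[tlim < 0] <- 0   # basic value drifted a hair past its bound
      range_q <- up[q] - lo[q]
      minlim <- min(tlim)                  # Inf when no basic var limits
      if (!is.finite(minlim) && !is.finite(range_q))
        stop("unbounded linear program")
      if (is.finite(range_q) && range_q < minlim - tol) {
        # entering variable runs to its opposite bound; basis unchanged
        x[basis] <- xb - dw * range_q
        x[q] <- if (at_upper[q]) lo[q] else up[q]
        at_upper[q] <- !at_upper[q]
        next
      }
      # on a tie, pivot: it places the leaving variable on its bound exactly,
      # a flip would overshoot by up to tol * |column| in row space.  The tie
      # window is kept at rounding scale: a looser window lets the step
      # overshoot the true minimum ratio by window * |column|, driving
      # another basic variable out of its bound.
      tstar <- minlim
      cand <- which(tlim <= tstar + 1e-12 * (1 + abs(tstar)))
      r <- cand[which.min(basis[cand])]                     # Bland: leaving
      leave <- basis[r]
      x[basis] <- xb - dw * tstar
      x[q] <- x[q] + dir * tstar
      # the leaving variable sits on whichever of its bounds it hit
      x[leave] <- if (dw[r] > 0) lo[leave] else up[leave]
      at_upper[leave] <- dw[r] <= 0
      basis[r] <- q
      piv <- w[r]
      Binv[r, ] <- Binv[r, ] / piv
      other <- setdiff(seq_len(m), r)
      if (length(other))
        Binv[other, ] <- Binv[other, ] - outer(w[other], Binv[r, ])
    }
  }

  if (m > 0L) {
    p1cost <- rep(0, length(x)); p1cost[art_idx] <- 1
    ph1 <- run_phase(p1cost, basis, x, at_upper, Binv, 0L)
    if (sum(ph1$x[art_idx]) > 1e-7)
      return(list(status = "infeasible", x = NULL, objective = NA_real_))
    # freeze artificials at zero for phase 2
    up[art_idx] <- 0
    ph1$x[art_idx] <- pmin(ph1$x[art_idx], 0)
    p2cost <- c(cost)
    ph2 <- run_phase(p2cost, ph1$basis, ph1$x, ph1$at_upper, ph1$Binv,
                     ph1$iter)
    # final hygiene: recompute the basic values from a fresh factorization
    # and audit feasibility of the returned point
    B <- Afull[, ph2$basis, drop = FALSE]
    Binv2 <- tryCatch(solve(B), error = function(e) NULL)
    if (!is.null(Binv2)) {
      nb <- setdiff(seq_along(ph2$x), ph2$basis)
      ph2$x[ph2$basis] <- as.vector(
        Binv2 %*% (rhs - Afull[, nb, drop = FALSE] %*% ph2$x[nb]))
    }
    viol <- max(abs(Afull %*% ph2$x - rhs))
    scale <- max(1, max(abs(rhs)))
    bviol <- max(c(0, lo - ph2$x, ph2$x - pmin(up, Inf))[is.finite(
      c(0, lo - ph2$x, ph2$x - pmin(up, Inf)))])
    if (viol > 1e-6 * scale || bviol > 1e-6)
      stop("simplex returned an infeasible point (residual ",
           format(max(viol, bviol)), "); numerical failure")
    xs <- ph2$x[seq_len(n)]
  } else {
    xs <- ifelse(cc >= 0, lower, upper)
  }
  objective <- sum(obj * xs)
  list(status = "optimal", x = xs, objective = objective)
}

# Convenience wrapper for flux problems: optimize c'v over
# {v : S v = 0 (optionally extra rows), lb <= v <= ub}.
#' @keywords internal
#' @noRd
fluxOptimum <- function(S, lb, ub, obj, maximize = TRUE,
                        extraA = NULL, extraRhs = NULL, extraSense = NULL) {
  A <- as.matrix(S)
  sense <- rep("=", nrow(A))
  rhs <- rep(0, nrow(A))
  if (!is.null(extraA)) {
    A <- rbind(A, extraA)
    rhs <- c(rhs, extraRhs)
    sense <- c(sense, extraSense)
  }
  solveLinearProgram(obj, A, sense, rhs, lb, ub, maximize = maximize)
}
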