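# Dense two-phase simplex. No LP backend is assumed to be available at run
# time, so the package carries its own solver; problem sizes here (tens to a
# few hundred variables) are well within reach of a dense tableau method.
# Bland's rule is used throughout: deterministic and cycle-free.

#' Large finite stand-in for an infinite flux bound
#'
#' LP/QP solvers require finite bounds; this value is substituted for
#' `Inf`/`-Inf` when a model is handed to a solver. It is far above any
#' attainable flux in the models this package targets (uptake bounds are
#' typically O(10) mmol/gDW/h).
#' @keywords internal
GEM_BIG <- 1e6

# Objective magnitudes at or beyond this fraction of GEM_BIG are reported as
# "unbounded": the optimum is pinned against the artificial finite bound.
.unbounded_frac <- 0.01

#' Solve a bounded linear program
#'
#' Minimizes or maximizes `obj %*% v` subject to `Aeq %*% v == beq` and
#' `lower <= v <= upper`. Infinite bounds are replaced by `+/-big`.
#'
#' @param obj numeric objective coefficients, length n.
#' @param Aeq equality constraint matrix (m x n); may have zero rows.
#' @param beq equality right-hand side, length m.
#' @param lower,upper bounds on `v`; `Inf`/`-Inf` allowed.
#' @param sense `"max"` or `"min"`.
#' @param big finite stand-in for infinite bounds.
#' @param tol pivot / feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution in the original variable space) and `objval`.
#' @keywords internal
lp_solve <- function(obj, Aeq, beq, lower, upper, sense = c("max", "min"),
                     big = GEM_BIG, tol = 1e-9) {
  sense <- match.arg(sense)
  n <- length(obj)
  Aeq <- matrix(as.numeric(Aeq), nrow = length(beq), ncol = n)
  lower <- pmax(lower, -big)
  upper <- pmin(upper, big)
  if (any(lower > upper + tol)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  }
  rng <- upper - lower
  m_eq <- length(beq)
  b2 <- as.numeric(beq - Aeq %*% lower)

  # standard form: columns = [x (n) | s (n, ub slacks) | a (m_eq artificials)]
  # rows = m_eq equality rows then n upper-bound rows (x_j + s_j = rng_j)
  flip <- b2 < 0
  Aeq[flip, ] <- -Aeq[flip, , drop = FALSE]
  b2[flip] <- -b2[flip]

  m <- m_eq + n
  N <- 2L * n + m_eq
  A <- matrix(0, m, N)
  A[seq_len(m_eq), seq_len(n)] <- Aeq
  if (m_eq > 0) A[cbind(seq_len(m_eq), 2L * n + seq_len(m_eq))] <- 1
  ubr <- m_eq + seq_len(n)
  A[cbind(ubr, seq_len(n))] <- 1
  A[cbind(ubr, n + seq_len(n))] <- 1
  b <- c(b2, rng)
  basis <- c(if (m_eq > 0) 2L * n + seq_len(m_eq), n + seq_len(n))

  # phase 1: drive artificials to zero
  if (m_eq > 0) {
    cost1 <- c(rep(0, 2L * n), rep(1, m_eq))
    ph1 <- .simplex_iterate(cost1, A, b, basis, tol)
    if (ph1$status != "optimal") {
      return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
    }
    A <- ph1$A; b <- ph1$b; basis <- ph1$basis
    if (sum(b[basis > 2L * n]) > 1e-7) {
      return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
    }
    # pivot lingering degenerate artificials out of the basis (or drop rows)
    keep <- rep(TRUE, length(b))
    for (r in which(basis > 2L * n)) {
      j <- which(abs(A[r, seq_len(2L * n)]) > tol)
      if (length(j)) {
        piv <- .pivot(A, b, basis, r, j[1L])
        A <- piv$A; b <- piv$b; basis <- piv$basis
      } else {
        keep[r] <- FALSE
      }
    }
    A <- A[keep, c(seq_len(2L * n)), drop = FALSE]
    b <- b[keep]
    basis <- basis[keep]
  } else {
    A <- A[, seq_len(2L * n), drop = FALSE]
  }

  cost2 <- c(if (sense == "max") -obj else obj, rep(0, n))
  ph2 <- .simplex_iterate(cost2, A, b, basis, tol)
  if (ph2$status == "unbounded") {
    # cannot occur while every variable carries an upper-bound row
    return(list(status = "unbounded", x = rep(NA_real_, n), objval = NA_real_))
  }
  xfull <- numeric(2L * n)
  xfull[ph2$basis] <- ph2$b
  v <- xfull[seq_len(n)] + lower
  objval <- sum(obj * v)
  status <- "optimal"
  if (abs(objval) >= .unbounded_frac * big) status <- "unbounded"
  list(status = status, x = v, objval = objval)
}

# One simplex phase on a tableau already canonical w.r.t. `basis`, b >= 0.
.simplex_iterate <- function(cost, A, b, basis, tol = 1e-9,
                             max_iter = 200000L) {
  m <- nrow(A)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("simplex: iteration limit reached")
    red <- cost - as.vector(crossprod(A, cost[basis]))
    red[basis] <- 0
    enter <- which(red < -tol)
    if (!length(enter)) {
      return(list(status = "optimal", A = A, b = b, basis = basis))
    }
    j <- enter[1L]                      # Bland: lowest entering index
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", A = A, b = b, basis = basis))
    }
    ratio <- b[pos] / col[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    r <- cand[which.min(basis[cand])]   # Bland: lowest leaving basic index
    piv <- .pivot(A, b, basis, r, j)
    A <- piv$A; b <- piv$b; basis <- piv$basis
  }
}

.pivot <- function(A, b, basis, r, j) {
  pv <- A[r, j]
  A[r, ] <- A[r, ] / pv
  b[r] <- b[r] / pv
  f <- A[, j]
  f[r] <- 0
  nz <- which(f != 0)
  if (length(nz)) {
    A[nz, ] <- A[nz, , drop = FALSE] - outer(f[nz], A[r, ])
    b[nz] <- b[nz] - f[nz] * b[r]
  }
  b[b < 0 & b > -1e-7] <- 0             # clip tiny negative round-off
  basis[r] <- j
  list(A = A, b = b, basis = basis)
}
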