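# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# The FBA linear programs here are small (a few hundred columns after adding
# slack variables), so a plain tableau method is fast enough and, with
# Bland's rule, guaranteed to terminate. Standard form:
#
#   min cost' x   s.t.  A x = b,  x >= 0,  b >= 0
#
# Phase 1 minimizes the sum of artificial variables; phase 2 re-prices with
# the true cost while artificial columns are barred from entering.

simplex_pivot <- function(T, basis, cost, allowed, tol = 1e-9) {
  m <- nrow(T)
  ncols <- ncol(T) - 1L
  it <- 0L
  max_it <- 50L * (m + ncols)
  repeat {
    it <- it + 1L
    if (it > max_it) return(list(T = T, basis = basis, status = "iteration_limit"))
    y <- cost[basis]
    red <- cost - as.numeric(crossprod(T[, seq_len(ncols), drop = FALSE], y))
    # Bland: smallest-index entering column with negative reduced cost
    cand <- which(allowed & red < -tol)
    if (!length(cand)) return(list(T = T, basis = basis, status = "optimal"))
    j <- cand[1L]
    col <- T[, j]
    rows <- which(col > tol)
    if (!length(rows)) return(list(T = T, basis = basis, status = "unbounded"))
    ratios <- T[rows, ncols + 1L] / col[rows]
    rmin <- min(ratios)
    ties <- rows[ratios <= rmin + tol]
    i <- ties[which.min(basis[ties])]  # Bland tie-break on leaving index
    # pivot on (i, j)
    piv <- T[i, ] / T[i, j]
    T <- T - outer(T[, j], piv)
    T[i, ] <- piv
    basis[i] <- j
  }
}

# Maximize cc'x subject to Aeq x = beq and 0 <= x <= ubx (ubx finite).
# Returns list(status, x, value).
simplex_box_lp <- function(cc, Aeq, beq, ubx, tol = 1e-9) {
  n <- length(cc)
  m1 <- nrow(Aeq)
  # flip equality rows so the rhs is non-negative
  flip <- beq < 0
  Aeq[flip, ] <- -Aeq[flip, , drop = FALSE]
  beq[flip] <- -beq[flip]
  # slack rows for the upper bounds: x_j + s_j = ub_j
  m <- m1 + n
  A <- rbind(cbind(Aeq, matrix(0, m1, n)), cbind(diag(n), diag(n)))
  b <- c(beq, ubx)
  ncols <- 2L * n
  # artificials for the equality rows only (slack rows start basic)
  A <- cbind(A, rbind(diag(m1), matrix(0, n, m1)))
  T <- cbind(A, b)
  basis <- c(ncols + seq_len(m1), n + seq_len(n))
  cost1 <- c(rep(0, ncols), rep(1, m1))
  allowed <- rep(TRUE, ncols + m1)
  res <- simplex_pivot(T, basis, cost1, allowed, tol)
  if (res$status != "optimal") return(list(status = "error"))
  obj1 <- sum(cost1[res$basis] * res$T[, ncols + m1 + 1L])
  if (obj1 > 1e-7) return(list(status = "infeasible"))
  # drive any zero-valued basic artificial out of the basis (else it could
  # drift positive during phase 2); an all-zero row is redundant and dropped
  T <- res$T; basis <- res$basis
  art <- which(basis > ncols)
  drop_rows <- integer(0)
  for (i in art) {
    entry <- which(abs(T[i, seq_len(ncols)]) > tol)
    if (length(entry)) {
      j <- entry[1L]
      piv <- T[i, ] / T[i, j]
      T <- T - outer(T[, j], piv)
      T[i, ] <- piv
      basis[i] <- j
    } else {
      drop_rows <- c(drop_rows, i)
    }
  }
  if (length(drop_rows)) {
    T <- T[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  # phase 2 on the true cost, artificial columns removed
  T <- T[, c(seq_len(ncols), ncols + m1 + 1L), drop = FALSE]
  cost2 <- c(-cc, rep(0, n))
  res <- simplex_pivot(T, basis, cost2, rep(TRUE, ncols), tol)
  if (res$status == "unbounded") return(list(status = "unbounded"))
  if (res$status != "optimal") return(list(status = "error"))
  x <- numeric(ncols)
  x[res$basis] <- res$T[, ncols + 1L]
  x <- pmin(pmax(x[seq_len(n)], 0), ubx)
  list(status = "optimal", x = x, value = sum(cc * x))
}
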