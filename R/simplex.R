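# Dense two-phase primal simplex used for the Frank-Wolfe linear subproblems.
#
# The subproblems maximize a linear functional over
#   { M : Aeq vec(M) = beq,  Ain vec(M) >= 0 },
# a bounded polytope whose inequality right-hand sides are all zero.  That
# makes every basic feasible solution heavily primal-degenerate, a regime in
# which textbook pivoting cycles or produces singular bases.  Pivoting here is
# Dantzig's rule with an automatic, permanent switch to Bland's rule once the
# objective stalls, which guarantees finite termination.

#' @noRd
lp_vertex <- function(obj, Aeq, beq, Ain, tol = 1e-9, max_iter = NULL) {
  nv <- length(obj)
  n_in <- nrow(Ain)
  n_eq <- nrow(Aeq)
  n_rows <- n_in + n_eq

  # free variables x = xp - xm; inequality rows are negated so the slack
  # enters with coefficient +1 and forms part of the initial identity basis
  sgn <- ifelse(beq < 0, -1, 1)
  A <- rbind(
    cbind(-Ain, Ain, diag(n_in), matrix(0, n_in, n_eq)),
    cbind(sgn * Aeq, -sgn * Aeq, matrix(0, n_eq, n_in), diag(n_eq))
  )
  b <- c(rep(0, n_in), sgn * beq)
  n_cols <- ncol(A)
  art_cols <- (2 * nv + n_in + 1):n_cols
  basis <- c(2 * nv + seq_len(n_in), art_cols)

  if (is.null(max_iter)) max_iter <- 200L * (n_rows + n_cols)

  pivot <- function(state, pr, pc) {
    pv <- state$A[pr, pc]
    state$A[pr, ] <- state$A[pr, ] / pv
    state$b[pr] <- state$b[pr] / pv
    fac <- state$A[, pc]
    fac[pr] <- 0
    hit <- which(fac != 0)
    if (length(hit)) {
      state$A[hit, ] <- state$A[hit, ] - tcrossprod(fac[hit], state$A[pr, ])
      state$b[hit] <- state$b[hit] - fac[hit] * state$b[pr]
    }
    state$basis[pr] <- pc
    state$b[state$b < 0 & state$b > -tol] <- 0
    state
  }

  run_phase <- function(state, cost, blocked) {
    red <- cost - crossprod(state$A, cost[state$basis])[, 1L]
    red[blocked] <- Inf
    bland <- FALSE
    stall <- 0L
    for (it in seq_len(max_iter)) {
      enter_ok <- which(red < -tol)
      if (!length(enter_ok)) {
        state$value <- sum(cost[state$basis] * state$b)
        state$status <- "optimal"
        return(state)
      }
      pc <- if (bland) enter_ok[1L] else enter_ok[which.min(red[enter_ok])]
      col <- state$A[, pc]
      pos <- which(col > tol)
      if (!length(pos)) {
        state$status <- "unbounded"
        return(state)
      }
      ratio <- state$b[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol * (1 + abs(rmin))]
      # leaving-variable tie break: smallest basis label (Bland-compatible)
      pr <- cand[which.min(state$basis[cand])]
      if (rmin <= tol) stall <- stall + 1L else stall <- 0L
      if (stall > 2L * length(state$b)) bland <- TRUE
      fac <- red[pc]
      state <- pivot(state, pr, pc)
      red <- red - fac * state$A[pr, ]
      red[pc] <- 0
      red[blocked] <- Inf
    }
    state$status <- "maxiter"
    state
  }

  state <- list(A = A, b = b, basis = basis)

  # Phase I: drive the artificials to zero
  cost1 <- c(rep(0, n_cols - n_eq), rep(1, n_eq))
  state <- run_phase(state, cost1, blocked = integer(0))
  if (state$status != "optimal" || state$value > 1e-7) {
    stop("LP phase I failed (status ", state$status, "): infeasible subproblem")
  }

  # Artificials can remain basic at zero on degenerate equality rows; pivot
  # them out (a zero-step pivot) or drop the row as redundant, otherwise
  # later pivots could silently reintroduce an equality violation.
  struct_cols <- seq_len(2 * nv + n_in)
  art_rows <- which(state$basis > 2 * nv + n_in)
  if (length(art_rows)) {
    keep <- rep(TRUE, length(state$b))
    for (r in art_rows) {
      j <- which(abs(state$A[r, struct_cols]) > tol)[1L]
      if (is.na(j)) {
        keep[r] <- FALSE
      } else {
        state <- pivot(state, r, j)
      }
    }
    state$A <- state$A[keep, , drop = FALSE]
    state$b <- state$b[keep]
    state$basis <- state$basis[keep]
  }

  # Phase II: original objective, artificials barred from entering
  cost2 <- c(-obj, obj, rep(0, n_in + n_eq))
  state <- run_phase(state, cost2, blocked = art_cols)
  if (state$status == "unbounded") {
    stop("LP unbounded: constraint polytope is not bounded")
  }
  if (state$status != "optimal") {
    stop("LP did not converge (status ", state$status, ")")
  }

  x_all <- numeric(n_cols)
  x_all[state$basis] <- state$b
  x <- x_all[seq_len(nv)] - x_all[nv + seq_len(nv)]
  list(x = x, value = sum(obj * x), status = "optimal")
}
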