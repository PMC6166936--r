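#' Search parameters for the multi-start Frank-Wolfe solver
#'
#' @param n_restarts number of seeded restarts; default `32 * m` (resolved at
#'   solve time when `NULL`).
#' @param max_fw_iters cap on Frank-Wolfe iterations per restart.
#' @param tol_obj objective-improvement stopping tolerance.
#' @param tol_feas feasibility tolerance for the linear constraints.
#' @param seed integer seed controlling all restart randomness.
#' @param reduce_constraints use the exact constraint-row reduction (unique
#'   rows, and the convex hull of the ratio rows for m <= 3); the returned
#'   solution is always re-verified against the full constraint set.
#' @return A list of class `"lapmix_search"`.
#' @export
search_params <- function(n_restarts = NULL, max_fw_iters = 100L,
                          tol_obj = 1e-10, tol_feas = 1e-9, seed = 1L,
                          reduce_constraints = TRUE) {
  stopifnot(max_fw_iters >= 1, tol_obj > 0, tol_feas > 0)
  structure(list(n_restarts = n_restarts, max_fw_iters = as.integer(max_fw_iters),
                 tol_obj = tol_obj, tol_feas = tol_feas, seed = as.integer(seed),
                 reduce_constraints = isTRUE(reduce_constraints)),
            class = "lapmix_search")
}

#' Model loss of a transform matrix
#'
#' The expected squared error (fuzziness) of the partition of unity induced by
#' the expansion-coefficient matrix `M`: `1 - ||M||_F^2`.  Zero exactly for
#' binary (crisp) partitions; `1 - 1/m` at the uniform partition.
#'
#' @param M square numeric matrix of eigenbasis expansion coefficients.
#' @return Scalar loss.
#' @export
lapmix_loss <- function(M) 1 - sum(M^2)

#' Feasibility of a transform matrix
#'
#' Checks the two linear constraint families defining the model polytope: the
#' column-sum constraint `t(M) %*% e = e_1` and nonnegativity of the induced
#' conditional probabilities at every data point.
#'
#' @param M `m x m` transform matrix.
#' @param basis a `"lapmix_basis"`.
#' @param tol feasibility tolerance.
#' @return List with `feasible` (logical) and `max_violation`.
#' @export
check_feasible <- function(M, basis, tol = 1e-9) {
  m <- basis$m
  stopifnot(is.matrix(M), nrow(M) == m, ncol(M) == m)
  eq <- max(abs(colSums(M) - c(1, rep(0, m - 1))))
  P <- basis$ratios %*% t(M)
  ineq <- max(0, -min(P))
  viol <- max(eq, ineq)
  list(feasible = viol <= tol, max_violation = viol)
}

uniform_transform <- function(m) {
  M <- matrix(0, m, m)
  M[, 1] <- 1 / m
  M
}

reduce_ratio_rows <- function(om) {
  m <- ncol(om)
  if (m == 2) {
    idx <- c(which.min(om[, 2]), which.max(om[, 2]))
  } else if (m == 3) {
    idx <- grDevices::chull(om[, 2], om[, 3])
  } else {
    idx <- which(!duplicated(signif(om, 10)))
  }
  unique(idx)
}

lp_structure <- function(basis, params) {
  om <- basis$ratios
  m <- basis$m
  idx <- if (params$reduce_constraints) reduce_ratio_rows(om) else seq_len(nrow(om))
  om_red <- om[idx, , drop = FALSE]
  list(m = m,
       omega = om,
       omega_red = om_red,
       Aeq = kronecker(diag(m), matrix(1, 1, m)),
       beq = c(1, rep(0, m - 1)),
       Ain = kronecker(om_red, diag(m)))
}

fw_local <- function(M0, str, params, keep_iterates = FALSE) {
  m <- str$m
  M <- M0
  obj <- sum(M^2)
  iters <- 0L
  iterates <- list()
  repeat {
    iters <- iters + 1L
    sol <- lp_vertex(as.vector(M), str$Aeq, str$beq, str$Ain)
    V <- matrix(sol$x, m, m)
    if (sol$value <= obj + params$tol_obj) break  # no improving vertex
    M <- V
    if (keep_iterates) iterates[[length(iterates) + 1]] <- V
    newobj <- sum(M^2)
    if (newobj <= obj + params$tol_obj) { obj <- max(obj, newobj); break }
    obj <- newobj
    if (iters >= params$max_fw_iters) break
  }
  list(M = M, iters = iters, iterates = iterates)
}

#' One local run of the modified Frank-Wolfe heuristic
#'
#' Starting from a feasible transform matrix, repeatedly maximizes the
#' linearization `tr(t(M_t) %*% M)` of the (concave-minimization) objective
#' over the constraint polytope; each step is a linear program whose optimum
#' is a polytope vertex.  The loss is non-increasing across iterations and the
#' returned matrix is a vertex that no linearization step can improve.
#'
#' @param M0 feasible starting transform matrix.
#' @param basis a `"lapmix_basis"`.
#' @param params a [search_params()] list.
#' @return The locally optimal transform matrix.
#' @export
frank_wolfe_local <- function(M0, basis, params = search_params()) {
  chk <- check_feasible(M0, basis, tol = 1e-6)
  if (!chk$feasible) {
    stop("M0 is infeasible (max violation ", format(chk$max_violation), ")")
  }
  str <- lp_structure(basis, params)
  fw_local(M0, str, params)$M
}

farthest_point_anchors <- function(rows, m) {
  n <- nrow(rows)
  first <- sample.int(n, 1)
  anchors <- first
  if (m > 1) {
    d2 <- rowSums((rows - rows[rep(first, n), , drop = FALSE])^2)
    for (k in seq_len(m - 1)) {
      nxt <- which.max(d2 + stats::runif(n, 0, 1e-9 * (max(d2) + 1)))
      anchors <- c(anchors, nxt)
      d2 <- pmin(d2, rowSums((rows - rows[rep(nxt, n), , drop = FALSE])^2))
    }
  }
  anchors
}

anchor_direction <- function(str) {
  # search direction pointing at the polytope corner where each of m
  # farthest-point-sampled ratio rows gets its own component
  m <- str$m
  rows <- str$omega_red
  if (nrow(rows) >= m) {
    anchors <- farthest_point_anchors(rows, m)
    W <- rows[anchors, , drop = FALSE]
    Mtry <- tryCatch(t(solve(W)), error = function(e) NULL)
    if (!is.null(Mtry) && all(is.finite(Mtry))) return(Mtry)
  }
  matrix(stats::rnorm(m^2), m, m)
}

make_restart <- function(str, r) {
  m <- str$m
  M <- anchor_direction(str)
  # project onto the equality constraint, then shrink toward the uniform
  # (interior) matrix until the nonnegativity constraints hold
  M <- M - matrix((colSums(M) - c(1, rep(0, m - 1))) / m, m, m, byrow = TRUE)
  Mu <- uniform_transform(m)
  P <- str$omega %*% t(M)
  pmin_ <- min(P)
  if (pmin_ < 0) {
    # entrywise: (1-theta) p + theta/m >= 0 for all p < 0
    th <- max(pmin_ / (pmin_ - 1 / m))
    th <- min(1, th + 1e-10 + 1e-6 * th)
    M <- (1 - th) * M + th * Mu
    if (min(str$omega %*% t(M)) < -1e-12) M <- Mu
  }
  M
}

assess_candidate <- function(M, str, tol_feas) {
  # degeneracy check: a candidate whose hard labels leave some component
  # empty is assigned infinite loss
  P <- str$omega %*% t(M)
  labels <- max.col(P, ties.method = "first")
  counts <- tabulate(labels, str$m)
  eqviol <- max(abs(colSums(M) - str$beq))
  viol <- max(eqviol, max(0, -min(P)))
  degenerate <- any(counts == 0)
  list(loss = if (degenerate || viol > 10 * tol_feas) Inf else lapmix_loss(M),
       degenerate = degenerate, violation = viol, labels = labels,
       counts = counts, p = P)
}

#' Globally optimized Laplacian mixture transform
#'
#' Runs the seeded multi-start modified Frank-Wolfe procedure: each restart
#' starts from a feasible matrix built by farthest-point anchor sampling in
#' the eigenvector-ratio row space, descends to a polytope vertex, and is then
#' subjected to the degeneracy check (candidates whose hard-thresholded labels
#' leave a component empty get infinite loss).  The minimum-loss nondegenerate
#' candidate wins.
#'
#' @param basis a `"lapmix_basis"`.
#' @param params a [search_params()] list.
#' @return A list with `M`, `loss`, `p` (N x m partition-of-unity matrix,
#'   unclipped), `labels`, `status` (`"ok"`, `"degenerate"` when no
#'   m-component solution was found, or `"trivial"` for m = 1) and `restarts`,
#'   a per-restart data frame (loss, degeneracy flag, iterations).
#' @export
lapmix_solve <- function(basis, params = search_params()) {
  m <- basis$m
  if (m == 1) {
    return(list(M = matrix(1, 1, 1), loss = 0,
                p = matrix(1, basis$n, 1), labels = rep(1L, basis$n),
                status = "trivial",
                restarts = data.frame(restart = integer(0), loss = numeric(0),
                                      degenerate = logical(0), iters = integer(0))))
  }
  if (is.null(params$n_restarts)) params$n_restarts <- 32L * m
  str <- lp_structure(basis, params)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(params$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  best <- NULL
  best_loss <- Inf
  rep_rows <- vector("list", params$n_restarts)
  for (r in seq_len(params$n_restarts)) {
    # alternate anchor-corner and isotropic search directions; the first
    # vertex maximizes the direction, then Frank-Wolfe descends from it
    G <- if (r %% 2 == 1) anchor_direction(str) else
      matrix(stats::rnorm(m^2), m, m)
    run <- tryCatch({
      v0 <- lp_vertex(as.vector(G), str$Aeq, str$beq, str$Ain)
      V0 <- matrix(v0$x, m, m)
      fw <- fw_local(V0, str, params, keep_iterates = TRUE)
      list(iterates = c(list(V0), fw$iterates), iters = fw$iters)
    }, error = function(e) {
      warning("restart ", r, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(run)) {
      rep_rows[[r]] <- data.frame(restart = r, loss = NA_real_,
                                  degenerate = NA, iters = NA_integer_)
      next
    }
    # every LP iterate is a polytope vertex and a model candidate; Algorithm
    # semantics: degeneracy-check each, keep the minimum-loss survivor
    r_loss <- Inf
    r_degen <- TRUE
    for (V in run$iterates) {
      cand <- assess_candidate(V, str, params$tol_feas)
      if (cand$loss < r_loss) r_loss <- cand$loss
      if (!cand$degenerate) r_degen <- FALSE
      if (cand$loss < best_loss) {
        best_loss <- cand$loss
        best <- list(M = V, cand = cand)
      }
    }
    rep_rows[[r]] <- data.frame(restart = r, loss = r_loss,
                                degenerate = r_degen, iters = run$iters)
  }
  restarts <- do.call(rbind, rep_rows)
  if (is.null(best) || !is.finite(best_loss)) {
    return(list(M = NULL, loss = Inf, p = NULL, labels = NULL,
                status = "degenerate", restarts = restarts))
  }
  list(M = best$M, loss = best_loss, p = best$cand$p,
       labels = best$cand$labels, status = "ok", restarts = restarts)
}
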