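# Independent oracles and small fixture generators used across the suite.

# dense random connected weighted graph (all pairs weighted, so connected)
rand_dense_graph <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# sparse-ish random graph guaranteed connected by a backbone cycle
rand_sparse_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  mask <- matrix(stats::runif(n * n) < p, n)
  A[mask] <- stats::runif(sum(mask))
  A <- pmax(A, t(A))
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, j] <- A[j, i] <- max(A[i, j], stats::runif(1, 0.2, 1))
  }
  diag(A) <- 0
  A
}

# brute-force connected-component count by depth-first search (no igraph)
dfs_component_count <- function(A, tol = 0) {
  n <- nrow(A)
  seen <- logical(n)
  count <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    count <- count + 1
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      nb <- which(A[v, ] > tol & !seen)
      stack <- c(stack, nb)
    }
  }
  count
}

# exhaustive vertex enumeration of the m = 2 constraint polytope:
# { M : t(M) e = e1, Omega t(M) >= 0 }.  The feasible set is 2-dimensional,
# so every vertex is the intersection of two inequality facets.
enumerate_m2_optimum <- function(omega, tol = 1e-9) {
  m <- 2
  Aeq <- kronecker(diag(m), matrix(1, 1, m))
  beq <- c(1, 0)
  Ain <- kronecker(omega, diag(m))
  n_in <- nrow(Ain)
  best <- -Inf
  verts <- list()
  combs <- utils::combn(n_in, 2)
  for (ci in seq_len(ncol(combs))) {
    Asys <- rbind(Aeq, Ain[combs[, ci], , drop = FALSE])
    x <- tryCatch(solve(Asys, c(beq, 0, 0)), error = function(e) NULL)
    if (is.null(x)) next
    if (min(Ain %*% x) >= -tol) {
      # same nondegeneracy rule as the solver: every component must win the
      # argmax on at least one point
      P <- omega %*% t(matrix(x, 2, 2))
      labs <- max.col(P, ties.method = "first")
      if (length(unique(labs)) < 2) next
      verts[[length(verts) + 1]] <- x
      nrm <- sum(x^2)
      if (nrm > best) best <- nrm
    }
  }
  list(min_loss = 1 - best, n_vertices = length(verts))
}

# map a target partition matrix into the transform-matrix parametrization
transform_from_partition <- function(p, basis) {
  t(qr.solve(basis$ratios, p))
}

# basis with the degenerate eigenspace (columns 2..m) randomly rotated
rotate_degenerate_basis <- function(basis, seed) {
  set.seed(seed)
  m <- basis$m
  R <- qr.Q(qr(matrix(stats::rnorm((m - 1)^2), m - 1)))
  V <- basis$vectors
  V[, -1] <- V[, -1, drop = FALSE] %*% R
  basis$vectors <- V
  basis$ratios <- V / V[, 1]
  basis$ratios[, 1] <- 1
  basis
}

expect_partition_of_unity <- function(p, tol_sum = 1e-8, tol_neg = 1e-9) {
  expect_lte(max(abs(rowSums(p) - 1)), tol_sum)
  expect_gte(min(p), -tol_neg)
}
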