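test_that("graph Laplacian is D - A with zero row sums", {
  expect_equal(as.matrix(graph_laplacian(matrix(0, 2, 2))$matrix),
               matrix(0, 2, 2))

  L2 <- as.matrix(graph_laplacian(matrix(c(0, 1, 1, 0), 2))$matrix)
  expect_equal(L2, matrix(c(1, -1, -1, 1), 2))

  # complete graph on 4 vertices: spectrum {0, N, N, N}
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  ev <- eigen(as.matrix(graph_laplacian(K4)$matrix), symmetric = TRUE)$values
  expect_equal(sort(ev), c(0, 4, 4, 4), tolerance = 1e-12)

  for (seed in 1:5) {
    A <- rand_sparse_graph(20, seed = seed)
    L <- graph_laplacian(A)$matrix
    expect_lte(max(abs(Matrix::rowSums(L))), 1e-12 * max(Matrix::diag(L)))
  }
})

test_that("invalid adjacency input is rejected with a pointed diagnostic", {
  A <- matrix(c(0, 1, 0.5, 0), 2)
  expect_error(graph_laplacian(A), "not symmetric.*w\\(1,2\\)|w\\(2,1\\)")
  B <- matrix(c(0, -0.2, -0.2, 0), 2)
  expect_error(graph_laplacian(B), "negative edge weight")
})

test_that("detailed-balance symmetrization preserves spectra and handles the symmetric case", {
  # symmetric rates + uniform stationary: identity conjugation
  Q <- matrix(c(0, 2, 2, 0), 2)
  sys <- symmetrize_detailed_balance(Q, c(0.5, 0.5))
  expect_equal(as.matrix(sys$matrix), matrix(c(2, -2, -2, 2), 2))

  # 2-state chain: q(1<-2) = 2, q(2<-1) = 1, stationary (2,1)/3
  Q <- matrix(c(0, 1, 2, 0), 2)  # Q[1,2] = 2, Q[2,1] = 1
  sys <- symmetrize_detailed_balance(Q, c(2, 1) / 3)
  expect_equal(as.matrix(sys$matrix)[1, 2], -sqrt(2), tolerance = 1e-12)

  # eigenvalues match the unsymmetrized generator on random reversible chains
  for (seed in 1:5) {
    set.seed(seed)
    n <- 6
    pi_ <- stats::runif(n, 0.2, 1); pi_ <- pi_ / sum(pi_)
    C <- matrix(stats::runif(n * n), n); C <- (C + t(C)) / 2; diag(C) <- 0
    Q <- C * sqrt(outer(pi_, pi_, "/"))   # Q_ij = C_ij sqrt(pi_i / pi_j)
    sys <- symmetrize_detailed_balance(Q, pi_)
    D <- diag(colSums(Q))
    ev_orig <- sort(Re(eigen(D - Q)$values))
    ev_sym <- sort(eigen(as.matrix(sys$matrix), symmetric = TRUE)$values)
    expect_equal(ev_sym, ev_orig, tolerance = 1e-10)
  }

  # violating detailed balance is an error
  Qbad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(symmetrize_detailed_balance(Qbad, c(0.5, 0.5)),
               "detailed balance")
})

test_that("similarity graph pipeline handles degenerate and clean geometries", {
  # two identical items: one edge of weight 1 after row normalization
  g <- similarity_graph(matrix(c(1, 1, 2, 2), 2, byrow = TRUE), k_nn = 1)
  expect_equal(as.matrix(g), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)

  # no sparsification: dense symmetric graph
  set.seed(42)
  x <- matrix(stats::rnorm(20), 10, 2)
  g <- similarity_graph(x, k_nn = 9, k_min = 0, min_weight_quantile = NULL)
  gm <- as.matrix(g)
  expect_true(all(gm[upper.tri(gm)] > 0))
  expect_equal(gm, t(gm))

  # three well-separated clouds come out as three components
  set.seed(7)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  x <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(stats::rnorm(40, sd = 0.1), 20, 2), 2, centers[k, ], "+")
  }))
  g <- suppressWarnings(
    similarity_graph(x, k_nn = 5, k_min = 0, min_weight_quantile = NULL))
  expect_equal(dfs_component_count(as.matrix(g), tol = 1e-12), 3)
})

test_that("adjacency preprocessing is shape-preserving and idempotent", {
  # an already row-stochastic symmetric matrix passes through unchanged
  A <- matrix(c(0, 1, 1, 0), 2)
  out <- adjacency_preprocess(A, k_nn = 1, k_min = 0,
                              min_weight_quantile = NULL)
  expect_equal(as.matrix(out), A)

  # star graph, k_nn = 1: hub keeps its strongest spoke, but max-symmetrization
  # restores every spoke from the leaves' side
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- c(0.9, 0.5, 0.4, 0.3); star[2:5, 1] <- star[1, 2:5]
  out <- as.matrix(adjacency_preprocess(star, k_nn = 1, k_min = 0,
                                        min_weight_quantile = NULL))
  expect_true(all(out[1, 2:5] > 0))          # all spokes survive
  expect_equal(which.max(out[1, ]), 2L)      # strongest spoke dominates

  for (seed in 1:4) {
    A <- rand_sparse_graph(15, seed = seed)
    out <- as.matrix(adjacency_preprocess(A, k_nn = 6, k_min = 2,
                                          min_weight_quantile = 0.9))
    expect_equal(out, t(out))
    expect_true(all(out >= 0 & out <= 1))
    # deterministic: the same input and configuration give the same graph
    out_again <- as.matrix(adjacency_preprocess(A, k_nn = 6, k_min = 2,
                                                min_weight_quantile = 0.9))
    expect_identical(out_again, out)
  }
})

test_that("largest connected component extraction returns the right subgraph", {
  A <- rand_dense_graph(6, seed = 1)
  lcc <- largest_connected_component(A)
  expect_equal(lcc$index, 1:6)

  # two blocks of sizes 5 and 3
  B <- matrix(0, 8, 8)
  B[1:5, 1:5] <- 1; B[6:8, 6:8] <- 1; diag(B) <- 0
  lcc <- largest_connected_component(B)
  expect_equal(lcc$index, 1:5)
  expect_equal(dim(lcc$graph), c(5, 5))
})

test_that("Smoluchowski lattice operator has the prescribed rates and kernel", {
  # constant density: the symmetrized operator is the lattice graph Laplacian
  sys <- smoluchowski_laplacian(density_grid(rep(2, 6), shape = c(3, 2)),
                                beta = 1.7)
  lat <- matrix(0, 6, 6)
  pr <- lapmix:::grid_neighbor_pairs(c(3L, 2L))
  lat[pr] <- 1; lat <- pmax(lat, t(lat))
  expect_equal(as.matrix(sys$matrix),
               as.matrix(graph_laplacian(lat)$matrix), tolerance = 1e-12)

  # free-diffusion limit: rates approach 1 as beta -> 0
  f <- c(1, 3, 0.5, 2)
  sys <- smoluchowski_laplacian(density_grid(f), beta = 1e-9)
  off <- as.matrix(sys$matrix); diag(off) <- 0
  expect_equal(abs(off[off != 0]), rep(1, sum(off != 0)), tolerance = 1e-6)

  # two-point grid, f = (1, 4), beta = 2: hand-computed symmetrization
  sys <- smoluchowski_laplacian(density_grid(c(1, 4)), beta = 2)
  expect_equal(as.matrix(sys$matrix),
               matrix(c(4, -1, -1, 0.25), 2), tolerance = 1e-12)
  expect_equal(as.vector(sys$matrix %*% c(1, 4)), c(0, 0), tolerance = 1e-12)

  # the symmetrized operator annihilates f^(beta/2) on random positive grids
  for (seed in 1:5) {
    set.seed(seed)
    f <- stats::runif(60, 0.1, 5)
    beta <- stats::runif(1, 0.3, 4)
    sys <- smoluchowski_laplacian(density_grid(f, shape = c(12, 5)), beta)
    v <- f^(beta / 2)
    expect_lte(sqrt(sum((as.vector(sys$matrix %*% v))^2)),
               1e-8 * sqrt(sum(v^2)))
  }

  expect_error(smoluchowski_laplacian(density_grid(c(1, 0, 2)), beta = 1),
               "grid index 2")
})
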