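test_that("interpolating cluster graphs interpolate between cluster and complete graphs", {
  sizes <- c(2, 3)
  B1 <- interpolating_cluster_graph(sizes, epsilon = 1)
  expect_equal(unname(B1[1:2, 3:5]), matrix(0, 2, 3))     # pure cluster graph
  expect_equal(B1[1, 2], 1)

  B0 <- interpolating_cluster_graph(sizes, epsilon = 0)   # complete graph
  expect_equal(unname(B0), matrix(1, 5, 5) - diag(5), ignore_attr = TRUE)

  B <- interpolating_cluster_graph(c(2, 2), epsilon = 0.5)
  expect_equal(unname(B), rbind(c(0, 1, 0.5, 0.5), c(1, 0, 0.5, 0.5),
                                c(0.5, 0.5, 0, 1), c(0.5, 0.5, 1, 0)),
               ignore_attr = TRUE)
})

test_that("closed-form eigenvectors carry eigenvalue N(1-eps) and sum to zero", {
  specs <- list(list(sizes = c(2, 2), eps = 0.5),
                list(sizes = c(3, 4, 5), eps = 0.5),
                list(sizes = c(2, 7), eps = 0.1),
                list(sizes = c(4, 4, 4, 4), eps = 0.9),
                list(sizes = c(1, 5, 9), eps = 0.3))
  for (sp in specs) {
    phi <- cluster_graph_eigenvectors(sp$sizes, sp$eps)
    n <- sum(sp$sizes)
    lam <- attr(phi, "eigenvalue")
    expect_equal(lam, n * (1 - sp$eps))
    L <- as.matrix(graph_laplacian(interpolating_cluster_graph(sp$sizes, sp$eps))$matrix)
    res <- L %*% phi[, -1, drop = FALSE] - lam * phi[, -1, drop = FALSE]
    expect_lte(max(abs(res)), 1e-10 * max(1, lam))
    expect_equal(colSums(phi[, -1, drop = FALSE]), rep(0, length(sp$sizes) - 1),
                 tolerance = 1e-12)
  }
  expect_equal(cluster_graph_eigenvectors(c(2, 2), 0.5)[, 2], c(1, 1, -1, -1))
})

test_that("the closed-form solution is the zero-loss binary indicator", {
  expect_equal(cluster_graph_solution(c(2, 2)),
               rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)))
  for (sp in list(c(3, 4, 5), c(2, 9), c(1, 2, 3, 4))) {
    p <- cluster_graph_solution(sp)
    expect_true(all(p %in% c(0, 1)))
    expect_equal(rowSums(p), rep(1, sum(sp)))
    expect_equal(colSums(p), sp)
    # loss through the transform-matrix parametrization is exactly zero
    basis <- laplacian_eigenbasis(
      graph_laplacian(interpolating_cluster_graph(sp, 0.5)), m = length(sp))
    M <- transform_from_partition(p, basis)
    expect_lte(abs(lapmix_loss(M)), 1e-9)
  }
})

test_that("uniform edge noise is symmetric, bounded, seeded, and convex", {
  B <- interpolating_cluster_graph(c(3, 3), 0.5)
  expect_equal(add_graph_noise(B, alpha = 0, n_out = 0), unname(B),
               ignore_attr = TRUE)

  N1 <- add_graph_noise(B, alpha = 0.3, seed = 4)
  expect_equal(N1, t(N1))
  expect_true(all(N1 >= 0 & N1 <= 1))
  expect_equal(N1, add_graph_noise(B, alpha = 0.3, seed = 4))  # reproducible

  # alpha = 1 wipes out the input entirely
  B2 <- interpolating_cluster_graph(c(3, 3), 0.9)
  expect_equal(add_graph_noise(B, 1, seed = 9), add_graph_noise(B2, 1, seed = 9))

  # outliers are appended as fully connected U(0,1) vertices
  N2 <- add_graph_noise(B, alpha = 0, n_out = 2, seed = 5)
  expect_equal(dim(N2), c(8, 8))
  expect_equal(N2[1:6, 1:6], unname(B), ignore_attr = TRUE)
  expect_true(all(N2[7:8, -(7:8)] > 0))
})

test_that("radial mixture densities return normalized truth and reproduce the mixture", {
  # a single isotropic Gaussian component is that Gaussian, normalized
  out <- radial_mixture_density(profiles = "gaussian", lower = -6, upper = 6,
                                shape = 121, n_basis = 1,
                                centers = list(matrix(0, 1, 1)),
                                scales = c(1, 1), seed = 2)
  x <- out$points[, 1]
  g <- exp(-x^2 / 2); g <- g / (sum(g) * out$grid$spacing)
  expect_equal(out$grid$values / sum(out$grid$values) / out$grid$spacing,
               g, tolerance = 1e-10)

  # three components on the 200 x 200 grid layout over [-10, 10]^2
  out <- radial_mixture_density(shape = c(200, 200), lower = -10, upper = 10,
                                seed = 3)
  expect_equal(length(out$grid$values), 40000L)
  expect_true(all(out$grid$values > 0))
  expect_equal(as.vector(out$components %*% out$weights), out$grid$values,
               tolerance = 1e-12)
  expect_equal(colSums(out$components) * prod(out$grid$spacing), rep(1, 3),
               tolerance = 1e-10)
})
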