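test_that("conditional probabilities follow p = M omega with unit row sums", {
  A <- rand_dense_graph(9, seed = 12)
  basis <- laplacian_eigenbasis(graph_laplacian(A), m = 3)
  Mu <- lapmix:::uniform_transform(3)
  P <- conditional_probabilities(Mu, basis)
  expect_equal(P, matrix(1 / 3, 9, 3), tolerance = 1e-9)

  # any feasible M yields unit row sums (column constraint + omega_0 = 1)
  set.seed(5)
  str <- lapmix:::lp_structure(basis, search_params())
  for (r in 1:4) {
    M <- lapmix:::make_restart(str, r)
    P <- conditional_probabilities(M, basis)
    expect_equal(rowSums(P), rep(1, 9), tolerance = 1e-9)
  }

  # the analytic cluster-graph transform reproduces the binary indicator
  sizes <- c(2, 2)
  B <- interpolating_cluster_graph(sizes, 0.5)
  basis <- laplacian_eigenbasis(graph_laplacian(B), m = 2)
  M <- transform_from_partition(cluster_graph_solution(sizes), basis)
  expect_equal(conditional_probabilities(M, basis, tol = 1e-7),
               cluster_graph_solution(sizes), tolerance = 1e-8)

  expect_error(conditional_probabilities(diag(3),
                                         laplacian_eigenbasis(graph_laplacian(A), m = 3)),
               "infeasible")
})

test_that("component weights integrate p against the stationary weight", {
  p <- matrix(1 / 3, 12, 3)
  expect_equal(component_weights(p, rep(1, 12)), rep(1 / 3, 3))

  p <- cluster_graph_solution(c(2, 2))
  expect_equal(component_weights(p, rep(0.25, 4)), c(0.5, 0.5))

  p <- cluster_graph_solution(c(3, 4, 5))
  expect_equal(component_weights(p, rep(1 / 12, 12)), c(0.25, 1 / 3, 5 / 12))
})

test_that("component densities renormalize and reconstruct the mixture", {
  # m = 1 returns the (normalized) input density
  f <- c(1, 2, 3, 4)
  out <- mixture_components(matrix(1, 4, 1), f = f, spacing = 1)
  expect_equal(out$components[, 1], f / sum(f))

  # a binary split yields renormalized restrictions and exact reconstruction
  p <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  out <- mixture_components(p, f = f, spacing = 0.5)
  expect_equal(out$components[, 1], c(1 / 3, 2 / 3, 0, 0) / 0.5)
  recon <- out$components %*% out$weights
  expect_equal(as.vector(recon) * 0.5, f / sum(f), tolerance = 1e-12)

  # reconstruction identity for a fitted density model
  set.seed(3)
  f <- stats::runif(30, 0.5, 2)
  fit <- lapmix(density_grid(f), m = 2, type = "density", beta = 1,
                params = search_params(n_restarts = 16, seed = 1))
  out <- mixture_components(fit)
  recon <- as.vector(out$components %*% out$weights)
  expect_equal(recon, f / sum(f), tolerance = 1e-10)
})

test_that("hard thresholding is argmax with lowest-index tie breaking", {
  expect_equal(hard_threshold(cluster_graph_solution(c(2, 3))),
               c(1L, 1L, 2L, 2L, 2L))
  expect_equal(hard_threshold(matrix(1 / 3, 4, 3)), rep(1L, 4))
  expect_equal(hard_threshold(matrix(c(0.2, 0.5, 0.3), 1)), 2L)
})

test_that("component losses vanish exactly on binary components", {
  p <- cluster_graph_solution(c(3, 4, 5))
  w <- rep(1 / 12, 12)
  expect_equal(component_losses(p, w), c(0, 0, 0))

  expect_equal(component_losses(matrix(1 / 4, 10, 4), rep(0.1, 10)),
               rep(3 / 4, 4))

  # fuzzy nondegenerate models give per-component losses strictly inside (0, 1)
  fit <- lapmix(add_graph_noise(interpolating_cluster_graph(c(5, 5, 6), 0.5),
                                alpha = 0.3, seed = 55), m = 3)
  expect_true(all(fit$component_losses > 0 & fit$component_losses < 1))

  # an empty component reports loss 1
  p_empty <- cbind(rep(1, 5), rep(0, 5))
  expect_equal(component_losses(p_empty, rep(0.2, 5)), c(0, 1))
})

test_that("model object methods expose the fit coherently", {
  B <- interpolating_cluster_graph(c(4, 4), 0.4)
  fit <- lapmix(B, m = 2)
  expect_s3_class(fit, "lapmix")
  expect_identical(coef(fit), fit$M)
  expect_identical(fitted(fit), fit$p)
  expect_identical(labels(fit), fit$labels)
  expect_output(print(fit), "Laplacian mixture model")
  expect_output(print(summary(fit)), "Per-component summary")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
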