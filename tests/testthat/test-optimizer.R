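test_that("loss and feasibility behave as the constraint algebra dictates", {
  m <- 2
  Mu <- lapmix:::uniform_transform(m)
  expect_equal(lapmix_loss(Mu), 0.5)

  A <- rand_dense_graph(10, seed = 4)
  basis <- laplacian_eigenbasis(graph_laplacian(A), m = 2)
  chk <- check_feasible(Mu, basis)
  expect_true(chk$feasible)
  expect_equal(conditional_probabilities(Mu, basis),
               matrix(0.5, 10, 2), tolerance = 1e-9)

  expect_false(check_feasible(diag(2), basis)$feasible)

  # the analytic cluster-graph optimum maps to a feasible zero-loss vertex
  sizes <- c(3, 4, 5)
  B <- interpolating_cluster_graph(sizes, epsilon = 0.5)
  basis <- laplacian_eigenbasis(graph_laplacian(B), m = 3)
  p_true <- cluster_graph_solution(sizes)
  M <- transform_from_partition(p_true, basis)
  expect_lte(check_feasible(M, basis, tol = 1e-8)$max_violation, 1e-8)
  expect_lte(abs(lapmix_loss(M)), 1e-10)
})

test_that("Frank-Wolfe descends monotonically and stops at vertices", {
  A <- rand_dense_graph(15, seed = 8)
  basis <- laplacian_eigenbasis(graph_laplacian(A), m = 3)
  params <- search_params(seed = 2)
  str <- lapmix:::lp_structure(basis, params)
  set.seed(99)
  for (r in 1:6) {
    M0 <- lapmix:::make_restart(str, r)
    out <- frank_wolfe_local(M0, basis, params)
    expect_lte(lapmix_loss(out), lapmix_loss(M0) + 1e-12)
    # a local optimum is a fixed point of another run
    again <- frank_wolfe_local(out, basis, params)
    expect_equal(lapmix_loss(again), lapmix_loss(out), tolerance = 1e-9)
  }
  expect_error(frank_wolfe_local(diag(3), basis, params), "infeasible")
})

test_that("solver recovers interpolating cluster graphs exactly", {
  sizes <- c(3, 4, 5)
  B <- interpolating_cluster_graph(sizes, epsilon = 0.5)
  fit <- lapmix(B, m = 3)
  expect_equal(fit$status, "ok")
  expect_lte(fit$loss, 1e-6)
  expect_equal(labeling_errors(labels(fit), attr(B, "blocks")), 0L)
  expect_equal(fit$p[cbind(seq_len(12), matched_labels(labels(fit), attr(B, "blocks")))],
               rep(1, 12), tolerance = 1e-6)
})

test_that("solved models satisfy the partition-of-unity constraints and the loss identity", {
  cases <- list(
    lapmix(rand_dense_graph(14, seed = 21), m = 2),
    lapmix(add_graph_noise(interpolating_cluster_graph(c(6, 7, 7), 0.5),
                           alpha = 0.25, seed = 22), m = 3),
    lapmix(interpolating_cluster_graph(c(4, 6), 0.3), m = 2))
  for (fit in cases) {
    expect_equal(fit$status, "ok")
    expect_partition_of_unity(fit$p)
    direct <- 1 - sum(fit$basis$weight * rowSums(fit$p^2))
    expect_lte(abs(fit$loss - direct), 1e-10)
    expect_gte(fit$loss, 0)
    expect_lt(fit$loss, 1)
  }
})

test_that("a constructed degenerate candidate is assigned infinite loss", {
  A <- rand_dense_graph(10, seed = 31)
  basis <- laplacian_eigenbasis(graph_laplacian(A), m = 2)
  str <- lapmix:::lp_structure(basis, search_params())
  Mdeg <- matrix(c(1, 0, 0, 0), 2)  # p_1 = 1 everywhere, p_2 empty
  expect_true(check_feasible(Mdeg, basis)$feasible)
  cand <- lapmix:::assess_candidate(Mdeg, str, 1e-9)
  expect_true(cand$degenerate)
  expect_identical(cand$loss, Inf)
  # the uniform candidate is also degenerate: argmax ties resolve to the
  # lowest component index, leaving the others empty
  cand_u <- lapmix:::assess_candidate(lapmix:::uniform_transform(2), str, 1e-9)
  expect_true(cand_u$degenerate)
  # a candidate whose hard labels populate every component keeps its loss
  sizes <- c(2, 3)
  bas2 <- laplacian_eigenbasis(
    graph_laplacian(interpolating_cluster_graph(sizes, 0.5)), m = 2)
  str2 <- lapmix:::lp_structure(bas2, search_params())
  Mok <- transform_from_partition(cluster_graph_solution(sizes), bas2)
  cand2 <- lapmix:::assess_candidate(Mok, str2, 1e-9)
  expect_false(cand2$degenerate)
  expect_lte(abs(cand2$loss), 1e-9)
})

test_that("m = 2 solver matches exhaustive vertex enumeration on small graphs", {
  for (seed in 1:6) {
    n <- 4 + (seed %% 5)
    A <- rand_dense_graph(n, seed = 100 + seed)
    basis <- laplacian_eigenbasis(graph_laplacian(A), m = 2)
    oracle <- enumerate_m2_optimum(basis$ratios)
    sol <- lapmix_solve(basis, search_params(seed = seed))
    expect_equal(sol$loss, oracle$min_loss, tolerance = 1e-7)
  }
})

test_that("solutions are invariant to rotations of the degenerate eigenspace", {
  sizes <- c(3, 4, 5)
  B <- interpolating_cluster_graph(sizes, epsilon = 0.5)
  basis <- laplacian_eigenbasis(graph_laplacian(B), m = 3)
  ref <- lapmix_solve(basis, search_params(seed = 1))
  rot <- rotate_degenerate_basis(basis, seed = 123)
  alt <- lapmix_solve(rot, search_params(seed = 1))
  expect_lte(abs(ref$loss - alt$loss), 1e-6)
  expect_equal(labeling_errors(alt$labels, ref$labels), 0L)
})

test_that("m = 1 is the trivial flagged model", {
  fit <- lapmix(rand_dense_graph(8, seed = 77), m = 1)
  expect_equal(fit$status, "trivial")
  expect_equal(fit$loss, 0)
  expect_equal(fit$p, matrix(1, 8, 1))
})
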