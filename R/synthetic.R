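# Synthetic inputs with known ground truth: interpolating cluster graphs and
# their closed-form eigenstructure and optimal model, uniform edge noise, and
# randomized radial-basis mixture densities.

#' Interpolating cluster graph
#'
#' The convex interpolation between a cluster graph (disjoint union of
#' complete blocks, `epsilon = 1`) and the complete graph (`epsilon = 0`):
#' within-block edge weights are 1 and cross-block weights `1 - epsilon`.
#' The diagonal is zero (simple graph).
#'
#' @param sizes integer vector of block sizes (`K = length(sizes)` blocks).
#' @param epsilon separation parameter in `[0, 1]`.
#' @return Dense `N x N` adjacency matrix with a `"blocks"` attribute giving
#'   the true block label of each vertex.
#' @examples
#' interpolating_cluster_graph(c(2, 2), epsilon = 0.5)
#' @export
interpolating_cluster_graph <- function(sizes, epsilon) {
  stopifnot(length(sizes) >= 1, all(sizes >= 1), epsilon >= 0, epsilon <= 1)
  blocks <- rep(seq_along(sizes), sizes)
  n <- sum(sizes)
  within <- outer(blocks, blocks, "==")
  B <- matrix(1 - epsilon, n, n)
  B[within] <- 1
  diag(B) <- 0
  attr(B, "blocks") <- blocks
  B
}

#' Closed-form eigenvectors of an interpolating cluster graph
#'
#' For `epsilon < 1` the Laplacian of the interpolating cluster graph has the
#' constant vector at eigenvalue 0 and a degenerate eigenvalue
#' `N (1 - epsilon)` of multiplicity `K - 1`.  A convenient (non-orthogonal)
#' basis of that eigenspace takes the value 1 on block 1, `-N_1 / N_j` on
#' block `j`, and 0 elsewhere; each such column sums to zero.  The eigenvector
#' property is verified numerically at construction.
#'
#' @param sizes block sizes.
#' @param epsilon separation parameter, `< 1`.
#' @return `N x K` matrix: column 1 is the all-ones vector, columns `2..K`
#'   the block-contrast eigenvectors, with eigenvalue `N (1 - epsilon)`
#'   attached as attribute `"eigenvalue"`.
#' @export
cluster_graph_eigenvectors <- function(sizes, epsilon) {
  stopifnot(epsilon < 1)
  K <- length(sizes)
  n <- sum(sizes)
  blocks <- rep(seq_len(K), sizes)
  phi <- matrix(0, n, K)
  phi[, 1] <- 1
  for (j in seq_len(K - 1)) {
    phi[blocks == 1, j + 1] <- 1
    phi[blocks == j + 1, j + 1] <- -sizes[1] / sizes[j + 1]
  }
  lam <- n * (1 - epsilon)
  L <- as.matrix(graph_laplacian(interpolating_cluster_graph(sizes, epsilon))$matrix)
  if (K > 1) {
    res <- L %*% phi[, -1, drop = FALSE] - lam * phi[, -1, drop = FALSE]
    if (max(abs(res)) > 1e-8 * max(1, lam)) {
      stop("internal consistency failure: eigenvector residual ", max(abs(res)))
    }
  }
  attr(phi, "eigenvalue") <- lam
  phi
}

#' Closed-form optimal partition of an interpolating cluster graph
#'
#' Combines the analytic eigenvectors into the exact optimizer of the model:
#' `p_1 = (1/N) sum_i N_i phi_{i-1}` and
#' `p_j = (N_j / N_1) (p_1 - phi_{j-1})` for the remaining components.  The
#' result is the binary block-indicator matrix, whose loss is exactly zero;
#' binarity is verified at construction.
#'
#' @param sizes block sizes.
#' @param epsilon separation parameter, `< 1` (enters only through the
#'   consistency check of the eigenvectors).
#' @return `N x K` binary indicator matrix of block membership.
#' @export
cluster_graph_solution <- function(sizes, epsilon = 0.5) {
  K <- length(sizes)
  n <- sum(sizes)
  phi <- cluster_graph_eigenvectors(sizes, epsilon)
  p1 <- as.vector(phi %*% sizes) / n
  p <- matrix(0, n, K)
  p[, 1] <- p1
  for (j in seq_len(K - 1)) {
    p[, j + 1] <- sizes[j + 1] / sizes[1] * (p1 - phi[, j + 1])
  }
  if (max(abs(p - round(p))) > 1e-10 || !all(round(p) %in% c(0, 1))) {
    stop("internal consistency failure: analytic solution is not binary")
  }
  round(p)
}

#' Add uniform edge noise (and optional outlier vertices) to a graph
#'
#' First appends `n_out` outlier vertices connected to every other vertex
#' with i.i.d. `U(0, 1)` weights, then replaces every off-diagonal weight by
#' the convex combination `(1 - alpha) b_ij + alpha u` with a fresh uniform
#' draw per unordered pair.  All weights stay in `[0, 1]` and the result is
#' symmetric with zero diagonal.
#'
#' @param graph adjacency matrix.
#' @param alpha uniform-noise level in `[0, 1]`.
#' @param n_out number of outlier vertices appended.
#' @param seed integer seed (reproducible noise).
#' @return Dense noisy adjacency matrix.
#' @export
add_graph_noise <- function(graph, alpha, n_out = 0, seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, n_out >= 0)
  B <- as.matrix(as_weighted_graph(graph))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  n0 <- nrow(B)
  if (n_out > 0) {
    n <- n0 + n_out
    Bx <- matrix(0, n, n)
    Bx[seq_len(n0), seq_len(n0)] <- B
    for (v in (n0 + 1):n) {
      w <- stats::runif(n - 1)
      Bx[v, -v] <- w
      Bx[-v, v] <- w
    }
    Bx <- (Bx + t(Bx)) / 2
    diag(Bx) <- 0
    B <- Bx
  }
  if (alpha > 0) {
    n <- nrow(B)
    ut <- upper.tri(B)
    u <- stats::runif(sum(ut))
    B[ut] <- (1 - alpha) * B[ut] + alpha * u
    B[lower.tri(B)] <- t(B)[lower.tri(B)]
  }
  diag(B) <- 0
  B
}

radial_profile <- function(profile) {
  switch(profile,
         gaussian = function(r) exp(-r^2 / 2),
         laplace = function(r) exp(-r),
         sech = function(r) 2 / (exp(r) + exp(-r)),
         stop("unknown radial profile: ", profile))
}

#' Randomized radial-basis mixture density on a grid
#'
#' Builds a nonnegative mixture density with known ground-truth components.
#' Each component is a normalized sum of `n_basis` anisotropic radial basis
#' functions of a single profile (Gaussian, Laplace, or hyperbolic secant)
#' with randomized centers and covariance transforms; the mixture is their
#' equal-weight superposition, evaluated on a regular Cartesian grid.
#'
#' @param profiles character vector of per-component radial profiles; its
#'   length sets the number of components.
#' @param lower,upper domain bounds per axis (recycled).
#' @param shape per-axis grid point counts (recycled).
#' @param n_basis radial basis functions per component.
#' @param centers optional list of `n_basis x d` center matrices per
#'   component; randomized inside the middle 60% of the domain when `NULL`.
#' @param scales range of the random axis scalings of the covariance
#'   transforms.
#' @param seed integer seed.
#' @return List with `grid` (a [density_grid()] of the mixture `f`),
#'   `components` (`N x m` matrix of normalized true component densities),
#'   `weights` (equal mixing proportions) and `points` (`N x d` grid
#'   coordinates).  The mixture satisfies `f = sum_k weights_k components_k`
#'   up to normalization by construction.
#' @export
radial_mixture_density <- function(profiles = c("gaussian", "laplace", "sech"),
                                   lower = -10, upper = 10, shape = 200,
                                   n_basis = 3, centers = NULL,
                                   scales = c(0.8, 2.5), seed = 1L) {
  m <- length(profiles)
  d <- max(length(lower), length(upper), length(shape))
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  shape <- rep_len(as.integer(shape), d)
  axes <- lapply(seq_len(d), function(k) seq(lower[k], upper[k], length.out = shape[k]))
  spacing <- vapply(axes, function(a) if (length(a) > 1) a[2] - a[1] else 1, numeric(1))
  pts <- as.matrix(expand.grid(axes))
  colnames(pts) <- NULL
  n <- nrow(pts)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  vol <- prod(spacing)
  comp <- matrix(0, n, m)
  for (k in seq_len(m)) {
    g <- radial_profile(profiles[k])
    ctr <- if (!is.null(centers)) as.matrix(centers[[k]]) else {
      span <- upper - lower
      matrix(stats::runif(n_basis * d, lower + 0.2 * span, upper - 0.2 * span),
             n_basis, d, byrow = FALSE)
    }
    fk <- numeric(n)
    for (b in seq_len(nrow(ctr))) {
      # random covariance transform: rotation times axis scaling
      Tm <- diag(1 / stats::runif(d, scales[1], scales[2]), d)
      if (d > 1) {
        rot <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
        Tm <- Tm %*% rot
      }
      z <- sweep(pts, 2, ctr[b, ]) %*% t(Tm)
      fk <- fk + g(sqrt(rowSums(z^2)))
    }
    tot <- sum(fk) * vol
    if (tot <= 0) stop("grid too coarse: component ", k, " vanishes on the grid")
    comp[, k] <- fk / tot
  }
  w <- rep(1 / m, m)
  f <- as.vector(comp %*% w)
  if (any(f <= 0)) stop("grid too coarse: mixture density vanishes at some grid point")
  list(grid = density_grid(f, shape = shape, spacing = spacing),
       components = comp, weights = w, points = pts)
}
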