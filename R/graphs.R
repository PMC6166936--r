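#' Validate and canonicalize a weighted graph adjacency matrix
#'
#' Checks that `x` is a square, finite, symmetric, nonnegative matrix with
#' weights in `[0, 1]`, zeroes the diagonal (simple graphs only), and returns
#' it as a sparse symmetric `Matrix`.
#'
#' @param x square numeric matrix or `Matrix` of edge weights.
#' @param tol tolerance for the symmetry check.
#' @return A sparse symmetric adjacency matrix (class `"dsCMatrix"`).
#' @export
as_weighted_graph <- function(x, tol = 1e-12) {
  x <- methods::as(methods::as(Matrix::Matrix(x), "generalMatrix"), "CsparseMatrix")
  if (nrow(x) != ncol(x)) stop("adjacency matrix must be square")
  if (length(x@x) && any(!is.finite(x@x))) {
    stop("adjacency matrix contains non-finite entries")
  }
  trip <- Matrix::summary(x)
  neg <- which(trip$x < 0)
  if (length(neg)) {
    k <- neg[1]
    stop(sprintf("negative edge weight at (%d, %d): %g",
                 trip$i[k], trip$j[k], trip$x[k]))
  }
  if (length(x@x) && any(x@x > 1 + 1e-9)) stop("edge weights must lie in [0, 1]")
  asym <- Matrix::drop0(abs(x - Matrix::t(x)))
  scale <- max(abs(x@x), 1)
  atrip <- Matrix::summary(asym)
  bad <- which(atrip$x > tol * scale)
  if (length(bad)) {
    i <- atrip$i[bad[1]]; j <- atrip$j[bad[1]]
    stop(sprintf("adjacency matrix is not symmetric: w(%d,%d)=%g but w(%d,%d)=%g",
                 i, j, as.numeric(x[i, j]), j, i, as.numeric(x[j, i])))
  }
  Matrix::diag(x) <- 0
  Matrix::forceSymmetric(Matrix::drop0((x + Matrix::t(x)) / 2))
}

new_laplacian_system <- function(matrix, degree, sym_scaling = NULL,
                                 source = "graph", grid = NULL) {
  structure(list(matrix = matrix, degree = degree, sym_scaling = sym_scaling,
                 source = source, grid = grid),
            class = "lapmix_laplacian")
}

#' @export
print.lapmix_laplacian <- function(x, ...) {
  cat(sprintf("Laplacian system: %d vertices, source = %s%s\n",
              nrow(x$matrix), x$source,
              if (!is.null(x$sym_scaling)) ", detailed-balance symmetrized" else ""))
  invisible(x)
}

#' Weighted graph Laplacian
#'
#' Builds the combinatorial Laplacian `D - A` of a weighted undirected graph,
#' where `D` is the diagonal matrix of weighted vertex degrees.  Row sums of
#' the result are zero, so the constant vector is the Perron-Frobenius
#' eigenvector with eigenvalue zero on connected graphs.
#'
#' @param graph adjacency matrix (validated by [as_weighted_graph()]).
#' @return A `"lapmix_laplacian"` system (sparse symmetric Laplacian, degrees).
#' @examples
#' graph_laplacian(matrix(c(0, 1, 1, 0), 2))
#' @export
graph_laplacian <- function(graph) {
  A <- as_weighted_graph(graph)
  d <- Matrix::rowSums(A)
  L <- Matrix::forceSymmetric(Matrix::Diagonal(x = d) - A)
  new_laplacian_system(L, d, source = "graph")
}

#' Symmetrize a detailed-balance rate matrix by diagonal conjugation
#'
#' Given nonnegative off-diagonal transition rates `Q` (entry `(i, j)` is the
#' rate from state `j` into state `i`) in detailed balance with a stationary
#' distribution `pi`, returns the symmetric operator
#' `S^-1 (D - Q) S` with `S = diag(sqrt(pi))` and `D` the diagonal of column
#' sums of `Q`.  The conjugation preserves the eigenvalues of the
#' unsymmetrized generator, and the symmetrized operator annihilates
#' `sqrt(pi)`.
#'
#' @param rates square matrix of nonnegative off-diagonal rates.
#' @param stationary strictly positive stationary probability vector.
#' @param tol relative tolerance for the detailed-balance check.
#' @param source source tag stored on the returned system.
#' @param grid optional density-grid metadata carried along.
#' @return A `"lapmix_laplacian"` system with `sym_scaling = sqrt(pi)`.
#' @export
symmetrize_detailed_balance <- function(rates, stationary, tol = 1e-8,
                                        source = "graph", grid = NULL) {
  Q <- methods::as(methods::as(Matrix::Matrix(rates), "generalMatrix"), "CsparseMatrix")
  n <- nrow(Q)
  if (length(stationary) != n) stop("stationary vector length must match rates")
  if (any(stationary <= 0)) stop("stationary distribution must be strictly positive")
  Matrix::diag(Q) <- 0
  Q <- Matrix::drop0(Q)
  if (any(Q@x < 0)) stop("off-diagonal rates must be nonnegative")
  pi_ <- stationary / sum(stationary)
  flow <- Q %*% Matrix::Diagonal(x = pi_)      # flow[i, j] = q(i <- j) * pi_j
  db <- abs(flow - Matrix::t(flow))
  scale <- max(abs(flow@x), .Machine$double.xmin)
  if (max(db) > tol * scale) {
    stop(sprintf("rates violate detailed balance: max relative violation %.3g",
                 max(db) / scale))
  }
  d <- Matrix::colSums(Q)
  s <- sqrt(pi_)
  L <- Matrix::Diagonal(x = 1 / s) %*% (Matrix::Diagonal(x = d) - Q) %*%
    Matrix::Diagonal(x = s)
  rel <- max(abs(L - Matrix::t(L))) / max(max(abs(L)), .Machine$double.xmin)
  if (rel > 1e-10) stop("symmetrization failed: residual asymmetry ", rel)
  L <- Matrix::forceSymmetric((L + Matrix::t(L)) / 2)
  new_laplacian_system(L, d, sym_scaling = s, source = source, grid = grid)
}

row_topk_keep <- function(S, k) {
  # keep each row's k largest entries, tie-inclusive: everything tied with
  # the k-th largest value survives, so the cutoff is deterministic and does
  # not split exactly equal similarities (ties have measure zero for
  # continuous weights)
  n <- nrow(S)
  for (i in seq_len(n)) {
    row <- S[i, ]
    if (sum(row > 0) > k) {
      kth <- sort(row, decreasing = TRUE)[k]
      row[row < kth] <- 0
      S[i, ] <- row
    }
  }
  S
}

#' Sparse similarity graph from feature vectors
#'
#' Converts an items-by-features numeric matrix into a weighted undirected
#' graph through a fixed pipeline: (1) pairwise similarity from Euclidean
#' distance through a decaying kernel; (2) a per-item similarity floor at the
#' `min_weight_quantile` value over all pairs, so no item is left essentially
#' disconnected; (3) strengthening of each item's top `k_min` similarities to
#' at least that quantile value; (4) a `k_nn` nearest-neighbour cutoff per
#' item; (5) row normalization to unit sum; (6) symmetrization by elementwise
#' maximum; (7) zero diagonal.
#'
#' @param x numeric matrix, items in rows, feature dimensions in columns.
#' @param k_nn nearest-neighbour cutoff (at most `nrow(x) - 1`).
#' @param k_min number of top connections per item strengthened to the
#'   quantile value (outlier-removal parameter).
#' @param min_weight_quantile quantile in `[0, 1]` used by steps (2) and (3),
#'   or `NULL` to disable both.
#' @param kernel `"gaussian"` for `exp(-d^2 / (2 s^2))` or `"invquad"` for
#'   the unbounded inverse quadratic `1 / (1 + (d/s)^2)`.
#' @param kernel_scale positive bandwidth `s`, or `"auto"` for the median
#'   distance to the `k_nn`-th nearest neighbour.
#' @return A sparse symmetric adjacency matrix.  If the result is
#'   disconnected a warning reports the component sizes.
#' @export
similarity_graph <- function(x, k_nn, k_min = 0, min_weight_quantile = 0.99,
                             kernel = c("gaussian", "invquad"),
                             kernel_scale = "auto") {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 items")
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values")
  n <- nrow(x)
  if (k_nn < 1 || k_nn > n - 1) stop("k_nn must be in [1, n_items - 1]")
  if (k_min > k_nn) stop("k_min must not exceed k_nn")
  D <- as.matrix(stats::dist(x))
  if (identical(kernel_scale, "auto")) {
    knd <- apply(D, 1, function(r) sort(r[-which.min(r)])[k_nn])
    s <- stats::median(knd)
    if (!is.finite(s) || s <= 0) s <- 1
  } else {
    s <- as.numeric(kernel_scale)
    if (s <= 0) stop("kernel_scale must be positive")
  }
  S <- switch(kernel,
              gaussian = exp(-(D / s)^2 / 2),
              invquad = 1 / (1 + (D / s)^2))
  diag(S) <- 0
  q <- if (is.null(min_weight_quantile)) NULL else
    stats::quantile(S[upper.tri(S)], min_weight_quantile, names = FALSE)
  if (!is.null(q)) {
    # per-item floor: lift the max similarity of weakly connected items
    for (i in seq_len(n)) {
      if (max(S[i, ]) < q) S[i, which.max(S[i, ])] <- q
    }
  }
  finish_adjacency(S, k_nn, k_min, q)
}

finish_adjacency <- function(S, k_nn, k_min, q) {
  n <- nrow(S)
  if (k_min > 0 && !is.null(q)) {
    for (i in seq_len(n)) {
      pos <- which(S[i, ] > 0)
      if (!length(pos)) next
      top <- pos[order(S[i, pos], decreasing = TRUE)][seq_len(min(k_min, length(pos)))]
      S[i, top] <- pmax(S[i, top], q)
    }
  }
  if (k_nn < n - 1) S <- row_topk_keep(S, k_nn)
  rs <- rowSums(S)
  zero_deg <- which(rs == 0)
  if (length(zero_deg)) {
    message("isolated vertices (zero degree) kept: ",
            paste(utils::head(zero_deg, 10), collapse = ", "),
            if (length(zero_deg) > 10) ", ..." else "")
    rs[zero_deg] <- 1
  }
  S <- S / rs
  W <- pmax(S, t(S))
  diag(W) <- 0
  g <- as_weighted_graph(W)
  comp <- graph_components(g)
  if (comp$no > 1) {
    warning(sprintf("similarity graph is disconnected: %d components with sizes %s",
                    comp$no, paste(sort(comp$csize, decreasing = TRUE), collapse = ", ")))
  }
  g
}

#' Preprocess an existing weighted adjacency matrix
#'
#' Applies the tail of the [similarity_graph()] pipeline to a graph given
#' directly as a weighted adjacency matrix (the network-analysis input path):
#' strengthening of the top `k_min` connections to the `min_weight_quantile`
#' value over all edge weights, `k_nn` nearest-neighbour cutoff, row
#' normalization to unit sum, symmetrization by elementwise maximum, and zero
#' diagonal.
#'
#' @param graph adjacency matrix.
#' @param k_nn nearest-neighbour cutoff; `NULL` keeps all edges.
#' @param k_min number of top connections strengthened per vertex.
#' @param min_weight_quantile quantile over all positive edge weights used for
#'   strengthening, or `NULL` to disable.
#' @return A sparse symmetric adjacency matrix; zero-degree vertices are
#'   reported and kept isolated (use [largest_connected_component()]).
#' @export
adjacency_preprocess <- function(graph, k_nn = NULL, k_min = 0,
                                 min_weight_quantile = 0.99) {
  A <- as.matrix(as_weighted_graph(graph))
  n <- nrow(A)
  if (is.null(k_nn)) k_nn <- n - 1
  if (k_nn < 1 || k_nn > n - 1) stop("k_nn must be in [1, n_vertices - 1]")
  q <- if (is.null(min_weight_quantile)) NULL else {
    w <- A[A > 0]
    if (length(w)) stats::quantile(w, min_weight_quantile, names = FALSE) else NULL
  }
  finish_adjacency(A, k_nn, k_min, q)
}

graph_components <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(graph, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::components(g)
}

#' Largest connected component of a weighted graph
#'
#' @param graph adjacency matrix.
#' @return A list with `graph`, the vertex-induced adjacency matrix of the
#'   largest component, and `index`, the original indices of its vertices
#'   (old-to-new mapping: new vertex `k` is old vertex `index[k]`).
#' @export
largest_connected_component <- function(graph) {
  g <- as_weighted_graph(graph)
  comp <- graph_components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  list(graph = g[keep, keep, drop = FALSE], index = keep)
}

#' Nonnegative density values on a regular Cartesian grid
#'
#' @param values nonnegative density values; an array, or a vector laid out in
#'   column-major (R array) order when `shape` is given.
#' @param shape integer vector of per-axis point counts; defaults to
#'   `dim(values)` (or the length, for plain vectors).
#' @param spacing per-axis grid step (recycled).
#' @return A `"lapmix_grid"` object.
#' @export
density_grid <- function(values, shape = NULL, spacing = 1) {
  v <- as.numeric(values)
  if (is.null(shape)) shape <- if (!is.null(dim(values))) dim(values) else length(v)
  shape <- as.integer(shape)
  if (prod(shape) != length(v)) stop("prod(shape) must equal length(values)")
  if (any(!is.finite(v)) || any(v < 0)) stop("density values must be finite and >= 0")
  if (!any(v > 0)) stop("density must be strictly positive somewhere")
  spacing <- rep_len(as.numeric(spacing), length(shape))
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(values = v, shape = shape, spacing = spacing),
            class = "lapmix_grid")
}

grid_neighbor_pairs <- function(shape) {
  # von Neumann stencil with reflecting boundaries: ordered pairs along each
  # axis, no wraparound (edge nodes simply have fewer neighbours)
  n <- prod(shape)
  coords <- arrayInd(seq_len(n), shape)
  from <- integer(0); to <- integer(0)
  stride <- cumprod(c(1L, shape[-length(shape)]))
  for (d in seq_along(shape)) {
    sel <- which(coords[, d] < shape[d])
    from <- c(from, sel)
    to <- c(to, sel + stride[d])
  }
  cbind(from = from, to = to)
}

#' Lattice Smoluchowski operator for a sampled density
#'
#' Discretizes the drift-diffusion (Smoluchowski) generator whose stationary
#' distribution is `f^beta` on a regular grid: nearest lattice neighbours `i`,
#' `j` get the hopping rate `q(i <- j) = (f(x_i) / f(x_j))^(beta / 2)`, the
#' diagonal conserves probability, and boundaries are reflecting.  The
#' returned operator is symmetrized by diagonal conjugation
#' ([symmetrize_detailed_balance()]), so it annihilates `f^(beta/2)` and its
#' squared Perron-Frobenius eigenvector is proportional to `f^beta`.
#'
#' @param grid a [density_grid()] (or values coercible to one); values must be
#'   strictly positive everywhere.
#' @param beta positive inverse-temperature scaling parameter.
#' @param ... passed to [density_grid()] when `grid` is a plain vector/array.
#' @return A `"lapmix_laplacian"` system with source `"density"`.
#' @export
smoluchowski_laplacian <- function(grid, beta, ...) {
  if (!inherits(grid, "lapmix_grid")) grid <- density_grid(grid, ...)
  if (beta <= 0) stop("beta must be positive")
  bad <- which(grid$values <= 0)
  if (length(bad)) {
    stop(sprintf("density must be strictly positive on the grid; first zero/negative value at grid index %d",
                 bad[1]))
  }
  lf <- log(grid$values)
  pr <- grid_neighbor_pairs(grid$shape)
  n <- prod(grid$shape)
  rate_fwd <- exp(beta / 2 * (lf[pr[, "from"]] - lf[pr[, "to"]]))  # q(from <- to)
  rate_bwd <- exp(beta / 2 * (lf[pr[, "to"]] - lf[pr[, "from"]]))  # q(to <- from)
  Q <- Matrix::sparseMatrix(i = c(pr[, "from"], pr[, "to"]),
                            j = c(pr[, "to"], pr[, "from"]),
                            x = c(rate_fwd, rate_bwd), dims = c(n, n))
  lpi <- beta * lf
  stationary <- exp(lpi - max(lpi))
  symmetrize_detailed_balance(Q, stationary / sum(stationary),
                              source = "density", grid = grid)
}
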