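#' Fit a Laplacian mixture model
#'
#' Fits a soft (probabilistic) spectral decomposition: the first `m`
#' eigenvectors of a graph Laplacian are combined, through a globally
#' optimized expansion-coefficient matrix, into a partition of unity — `m`
#' nonnegative conditional probabilities summing to one at every vertex.  The
#' optimizer minimizes the expected squared classifier error
#' `L = 1 - sum_k <p_k^2>`, equivalently `1 - ||M||_F^2` over the
#' linearly-constrained matrix `M`, a concave quadratic program attacked by a
#' seeded multi-start modified Frank-Wolfe procedure with a degeneracy check.
#'
#' Three input types are supported.  Graphs enter as weighted adjacency
#' matrices through the combinatorial Laplacian `D - A`.  Feature tables
#' (items in rows) are first converted to a sparse k-nearest-neighbour
#' similarity graph.  Densities sampled on a regular grid are discretized into
#' a detailed-balance Smoluchowski (drift-diffusion) operator whose stationary
#' distribution is `f^beta`.
#'
#' @param x adjacency matrix, items-by-features numeric matrix,
#'   [density_grid()] (or array of density values), or a precomputed
#'   `"lapmix_laplacian"` / `"lapmix_basis"`.
#' @param m number of mixture components (>= 1).
#' @param type input interpretation; `"auto"` takes square symmetric
#'   zero-diagonal matrices as graphs, `"lapmix_grid"` objects and arrays as
#'   densities, and other matrices as feature tables.
#' @param k_nn,k_min,min_weight_quantile,kernel,kernel_scale similarity-graph
#'   parameters, see [similarity_graph()] (feature path only; `k_nn` defaults
#'   to `min(125, n - 1)`).
#' @param beta inverse-temperature scaling of the density-path operator.
#' @param spacing grid spacing for plain-array density input.
#' @param params a [search_params()] list; its `seed` drives all restart
#'   randomness.
#' @param dense_cutoff passed to [laplacian_eigenbasis()].
#' @return An object of class `"lapmix"`: a list with elements `p` (N x m
#'   partition-of-unity matrix, clipped to `[0, 1]`), `M` (optimal transform),
#'   `loss`, `component_losses`, `weights` (mixing proportions), `labels`
#'   (hard argmax assignments), `m`, `status`, `basis`, `restarts`, `clip`
#'   (largest clipping applied to `p`), and the matched `call`.  When no
#'   nondegenerate solution exists, `status` is `"degenerate"` and `p` is
#'   `NULL`.
#' @examples
#' B <- interpolating_cluster_graph(c(3, 4, 5), epsilon = 0.5)
#' fit <- lapmix(B, m = 3)
#' fit
#' table(labels(fit))
#' @export
lapmix <- function(x, m = 2,
                   type = c("auto", "graph", "features", "density"),
                   k_nn = NULL, k_min = 0, min_weight_quantile = 0.99,
                   kernel = "gaussian", kernel_scale = "auto",
                   beta = 1, spacing = 1,
                   params = search_params(), dense_cutoff = 1200) {
  type <- match.arg(type)
  cl <- match.call()

  basis <- if (inherits(x, "lapmix_basis")) {
    if (x$m < m) stop("precomputed basis has fewer than m eigenvectors")
    x
  } else {
    system <- if (inherits(x, "lapmix_laplacian")) {
      x
    } else {
      if (type == "auto") type <- guess_input_type(x)
      switch(type,
        graph = graph_laplacian(x),
        features = {
          n <- nrow(as.matrix(x))
          if (is.null(k_nn)) k_nn <- min(125L, n - 1L)
          g <- similarity_graph(x, k_nn = k_nn, k_min = k_min,
                                min_weight_quantile = min_weight_quantile,
                                kernel = kernel, kernel_scale = kernel_scale)
          graph_laplacian(g)
        },
        density = smoluchowski_laplacian(x, beta = beta, spacing = spacing))
    }
    laplacian_eigenbasis(system, m = max(m, 2), dense_cutoff = dense_cutoff)
  }
  if (m > 1 && basis$m > m) basis <- trim_basis(basis, m)

  sol <- if (m == 1) {
    list(M = matrix(1, 1, 1), loss = 0, p = matrix(1, basis$n, 1),
         labels = rep(1L, basis$n), status = "trivial",
         restarts = data.frame())
  } else {
    lapmix_solve(basis, params)
  }

  if (sol$status == "degenerate") {
    out <- structure(list(p = NULL, M = NULL, loss = Inf,
                          component_losses = NULL, weights = NULL,
                          labels = NULL, m = m, status = "degenerate",
                          basis = basis, restarts = sol$restarts, clip = NA,
                          seed = params$seed, call = cl),
                     class = "lapmix")
    return(out)
  }

  p_raw <- sol$p
  clip <- max(0, max(-p_raw, p_raw - 1, 0))
  p <- pmin(pmax(p_raw, 0), 1)
  w <- basis$weight
  structure(list(p = p, M = sol$M, loss = sol$loss,
                 component_losses = component_losses(p, w),
                 weights = component_weights(p, w),
                 labels = sol$labels, m = m, status = sol$status,
                 basis = basis, restarts = sol$restarts, clip = clip,
                 seed = params$seed, call = cl),
            class = "lapmix")
}

guess_input_type <- function(x) {
  if (inherits(x, "lapmix_grid")) return("density")
  if (is.array(x) && length(dim(x)) > 2) return("density")
  if (is.null(dim(x))) return("density")
  xm <- as.matrix(x)
  if (nrow(xm) == ncol(xm) &&
      max(abs(xm - t(xm))) <= 1e-12 * max(abs(xm), 1) &&
      all(xm >= 0) && all(abs(diag(xm)) <= 1e-12)) {
    return("graph")
  }
  "features"
}

trim_basis <- function(basis, m) {
  basis$vectors <- basis$vectors[, seq_len(m), drop = FALSE]
  basis$values <- basis$values[seq_len(m)]
  basis$ratios <- basis$ratios[, seq_len(m), drop = FALSE]
  basis$m <- m
  basis
}

#' Conditional probabilities induced by a transform matrix
#'
#' Evaluates the partition of unity `p(x) = M omega(x)` at every data point.
#' Feasible `M` guarantees nonnegative entries with unit row sums.
#'
#' @param M feasible `m x m` transform matrix.
#' @param basis a `"lapmix_basis"`.
#' @param tol feasibility tolerance; infeasible `M` is rejected.
#' @return `N x m` matrix of conditional probabilities.
#' @export
conditional_probabilities <- function(M, basis, tol = 1e-6) {
  chk <- check_feasible(M, basis, tol = tol)
  if (!chk$feasible) {
    stop("transform matrix is infeasible (max violation ",
         format(chk$max_violation), ")")
  }
  basis$ratios %*% t(M)
}

#' Mixture weights of a partition of unity
#'
#' `a_k = sum_x p_k(x) w(x)` for a stationary weight `w` summing to one; the
#' weights sum to one.
#'
#' @param p `N x m` partition-of-unity matrix.
#' @param weight length-N nonnegative stationary weight vector.
#' @return Length-m numeric vector of mixing proportions.
#' @export
component_weights <- function(p, weight) {
  weight <- weight / sum(weight)
  as.vector(crossprod(p, weight))
}

#' Per-component fuzziness losses
#'
#' `c_k = 1 - <p_k^2>_w / <p_k>_w`, the natural per-component normalization of
#' the model's squared-error objective: it lies in `[0, 1)`, vanishes exactly
#' for binary components, and equals `1 - 1/m` for the uniform partition.
#' Empty components (`<p_k>_w = 0`) are reported as 1.
#'
#' @inheritParams component_weights
#' @return Length-m numeric vector.
#' @export
component_losses <- function(p, weight) {
  weight <- weight / sum(weight)
  num <- as.vector(crossprod(p^2, weight))
  den <- as.vector(crossprod(p, weight))
  out <- rep(1, ncol(p))
  pos <- den > 1e-12
  out[pos] <- 1 - num[pos] / den[pos]
  out
}

#' Hard cluster labels from conditional probabilities
#'
#' Per-item argmax over the components; ties are broken toward the lowest
#' component index.
#'
#' @param p `N x m` partition-of-unity matrix.
#' @return Integer vector of labels in `1..m`.
#' @export
hard_threshold <- function(p) {
  max.col(as.matrix(p), ties.method = "first")
}

#' Mixture-component densities of a density-path model
#'
#' Reconstructs the component densities `f_k = p_k f / a_k` with weights
#' `a_k = sum_x p_k(x) f(x) / sum_x f(x)`; each component integrates to one
#' over the grid and the weighted sum reproduces the input mixture exactly.
#'
#' @param fit a `"lapmix"` model fitted on the density path, or an `N x m`
#'   partition matrix.
#' @param f input density values; defaults to the grid stored on the fit.
#' @param spacing grid spacing (for normalization); defaults likewise.
#' @return List with `components` (N x m matrix of normalized densities),
#'   `weights`, and `empty` (indices of components with vanishing weight).
#' @export
mixture_components <- function(fit, f = NULL, spacing = NULL) {
  if (inherits(fit, "lapmix")) {
    p <- fit$p
    if (is.null(f)) {
      if (is.null(fit$basis$grid)) {
        stop("fit carries no density grid; supply f explicitly")
      }
      f <- fit$basis$grid$values
      spacing <- fit$basis$grid$spacing
    }
  } else {
    p <- as.matrix(fit)
  }
  if (is.null(spacing)) spacing <- 1
  if (any(f < 0)) stop("density values must be nonnegative")
  vol <- prod(spacing)
  fn <- f / sum(f)
  a <- as.vector(crossprod(p, fn))
  empty <- which(a < 1e-12)
  comp <- matrix(0, nrow(p), ncol(p))
  ok <- setdiff(seq_len(ncol(p)), empty)
  for (k in ok) comp[, k] <- p[, k] * fn / (a[k] * vol)
  list(components = comp, weights = a, empty = empty)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.lapmix <- function(x, ...) {
  cat("Laplacian mixture model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  if (x$status == "degenerate") {
    cat(sprintf("No nondegenerate %d-component solution was found.\n", x$m))
    return(invisible(x))
  }
  cat(sprintf("Components: %d   Loss: %.6g   Vertices: %d\n",
              x$m, x$loss, nrow(x$p)))
  cat("Mixing weights: ", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  cat("Hard cluster sizes: ",
      paste(sort(tabulate(x$labels, x$m), decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.lapmix <- function(object, ...) {
  structure(list(fit = object), class = "summary.lapmix")
}

#' @export
print.summary.lapmix <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (fit$status == "degenerate") return(invisible(x))
  tab <- data.frame(component = seq_len(fit$m),
                    weight = fit$weights,
                    loss = fit$component_losses,
                    size = tabulate(fit$labels, fit$m))
  cat("\nPer-component summary:\n")
  print(tab, row.names = FALSE, digits = 4)
  if (nrow(fit$restarts)) {
    nd <- sum(!fit$restarts$degenerate, na.rm = TRUE)
    cat(sprintf("\nRestarts: %d (%d nondegenerate); best loss found %d time(s)\n",
                nrow(fit$restarts), nd,
                sum(abs(fit$restarts$loss - fit$loss) < 1e-8, na.rm = TRUE)))
  }
  if (!is.na(fit$clip) && fit$clip > 0) {
    cat(sprintf("Largest probability clipping applied: %.3g\n", fit$clip))
  }
  invisible(x)
}

#' @export
coef.lapmix <- function(object, ...) object$M

#' @export
fitted.lapmix <- function(object, ...) object$p

#' @export
labels.lapmix <- function(object, ...) object$labels

#' @export
plot.lapmix <- function(x, sort_by_label = TRUE, ...) {
  if (x$status == "degenerate") stop("nothing to plot: degenerate fit")
  p <- x$p
  ord <- if (sort_by_label) order(x$labels, -p[cbind(seq_len(nrow(p)), x$labels)])
         else seq_len(nrow(p))
  graphics::matplot(p[ord, , drop = FALSE], type = "l", lty = 1,
                    xlab = "items (sorted by hard label)",
                    ylab = "conditional probability", ...)
  invisible(x)
}

#' Fit a sequence of models over a range of component counts
#'
#' Fits `m = m_min, ..., m_max` and truncates at the first `m` for which no
#' nondegenerate solution is found (the remaining orders are not attempted).
#'
#' @inheritParams lapmix
#' @param m_min,m_max inclusive model-order range.
#' @param ... passed to [lapmix()].
#' @return A `"lapmix_sequence"`: list with `fits` (list of `"lapmix"`),
#'   `m` (orders attempted), `status` (per-order `"ok"`/`"degenerate"`).
#' @export
lapmix_sequence <- function(x, m_min = 2, m_max = 8, ...) {
  fits <- list()
  status <- character(0)
  ms <- integer(0)
  for (m in seq(m_min, m_max)) {
    fit <- lapmix(x, m = m, ...)
    fits[[length(fits) + 1]] <- fit
    ms <- c(ms, m)
    status <- c(status, fit$status)
    if (fit$status == "degenerate") break
  }
  structure(list(fits = fits, m = ms, status = status),
            class = "lapmix_sequence")
}

#' @export
print.lapmix_sequence <- function(x, ...) {
  cat("Laplacian mixture model sequence\n")
  losses <- vapply(x$fits, function(f) f$loss, numeric(1))
  tab <- data.frame(m = x$m, status = x$status, loss = losses)
  print(tab, row.names = FALSE, digits = 5)
  if (utils::tail(x$status, 1) == "degenerate") {
    cat(sprintf("Search truncated: no %d-component solution found.\n",
                utils::tail(x$m, 1)))
  }
  invisible(x)
}
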