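# Evaluation and model/parameter selection: labeling error under optimal
# component matching, relative unmixing error, silhouette profiles,
# robust-fit model selection, and the beta / k-NN grid searches.

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Labeling errors under optimal component matching
#'
#' Minimum Hamming distance between two labelings over all one-to-one
#' assignments of inferred components to true clusters (exhaustive matching on
#' the confusion matrix for up to 8 classes, greedy beyond).  Invariant under
#' permutation of component identities; the labelings need not use the same
#' number of distinct values.
#'
#' @param labels integer vector of inferred labels.
#' @param truth integer vector of true labels (same length).
#' @return Integer error count.
#' @export
labeling_errors <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  lu <- sort(unique(labels)); tu <- sort(unique(truth))
  conf <- table(factor(labels, levels = lu), factor(truth, levels = tu))
  k <- max(length(lu), length(tu))
  C <- matrix(0, k, k)
  C[seq_along(lu), seq_along(tu)] <- conf
  n <- length(labels)
  if (k <= 8) {
    best <- 0
    for (p in all_permutations(k)) {
      agree <- sum(C[cbind(seq_len(k), p)])
      if (agree > best) best <- agree
    }
  } else {
    # greedy fallback for many classes
    best <- 0
    Cw <- C
    for (i in seq_len(k)) {
      idx <- arrayInd(which.max(Cw), dim(Cw))
      best <- best + Cw[idx]
      Cw[idx[1], ] <- -1
      Cw[, idx[2]] <- -1
    }
  }
  as.integer(n - best)
}

#' Relabel inferred components by their optimal match to a reference
#'
#' Applies the component-to-cluster assignment found by the optimal matching
#' of [labeling_errors()] and returns the relabeled vector, so that
#' disagreements with `truth` can be localized (e.g. counted per true
#' cluster).
#'
#' @inheritParams labeling_errors
#' @return Integer vector of relabeled inferred labels.
#' @export
matched_labels <- function(labels, truth) {
  lu <- sort(unique(labels)); tu <- sort(unique(truth))
  conf <- table(factor(labels, levels = lu), factor(truth, levels = tu))
  k <- max(length(lu), length(tu))
  C <- matrix(0, k, k)
  C[seq_along(lu), seq_along(tu)] <- conf
  vals <- c(tu, rep(NA_integer_, k - length(tu)))
  if (k <= 8) {
    best <- -1; bestp <- seq_len(k)
    for (p in all_permutations(k)) {
      agree <- sum(C[cbind(seq_len(k), p)])
      if (agree > best) { best <- agree; bestp <- p }
    }
  } else {
    bestp <- integer(k); Cw <- C
    for (i in seq_len(k)) {
      idx <- arrayInd(which.max(Cw), dim(Cw))
      bestp[idx[1]] <- idx[2]
      Cw[idx[1], ] <- -1
      Cw[, idx[2]] <- -1
    }
  }
  map <- stats::setNames(vals[bestp[seq_along(lu)]], lu)
  unname(map[as.character(labels)])
}

#' Relative unmixing error of estimated component densities
#'
#' After optimal one-to-one matching of estimated to true components
#' (exhaustive for m <= 8), either the mean of the per-component relative
#' 2-norm errors `||est_k - true_k|| / ||true_k||` (`aggregate = "mean"`) or
#' the relative error of the stacked vectors (`aggregate = "stacked"`).
#'
#' @param estimated `N x m` matrix of estimated component densities.
#' @param truth `N x m` matrix of true component densities.
#' @param aggregate aggregation rule.
#' @return Scalar relative error (permutation invariant).
#' @export
relative_error <- function(estimated, truth, aggregate = c("mean", "stacked")) {
  aggregate <- match.arg(aggregate)
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  stopifnot(all(dim(estimated) == dim(truth)))
  m <- ncol(truth)
  score <- function(perm) {
    if (aggregate == "mean") {
      mean(vapply(seq_len(m), function(k) {
        sqrt(sum((estimated[, k] - truth[, perm[k]])^2)) /
          sqrt(sum(truth[, perm[k]]^2))
      }, numeric(1)))
    } else {
      sqrt(sum((estimated - truth[, perm, drop = FALSE])^2)) / sqrt(sum(truth^2))
    }
  }
  if (m <= 8) {
    min(vapply(all_permutations(m), score, numeric(1)))
  } else {
    score(seq_len(m))
  }
}

#' Grid search over the inverse-temperature parameter beta
#'
#' Fits a density-path model for every `beta` and scores it by the relative
#' unmixing error against the true components when available, otherwise by
#' the model loss.  Betas for which no nondegenerate model exists are
#' excluded from the arg-min and flagged in the returned curve.
#'
#' @param grid a [density_grid()].
#' @param m number of components.
#' @param betas positive beta values to scan.
#' @param truth optional `N x m` matrix of true component densities.
#' @param params a [search_params()] list.
#' @param ... passed to [lapmix()].
#' @return List with `best_beta`, `curve` (data frame of beta, score, status),
#'   and `fits` (per-beta models).
#' @export
beta_search <- function(grid, m, betas, truth = NULL,
                        params = search_params(), ...) {
  stopifnot(all(betas > 0))
  fits <- vector("list", length(betas))
  score <- rep(NA_real_, length(betas))
  status <- character(length(betas))
  for (i in seq_along(betas)) {
    fit <- lapmix(grid, m = m, type = "density", beta = betas[i],
                  params = params, ...)
    fits[[i]] <- fit
    status[i] <- fit$status
    if (fit$status != "degenerate") {
      score[i] <- if (is.null(truth)) fit$loss else {
        est <- mixture_components(fit)$components
        relative_error(est, truth)
      }
    }
  }
  curve <- data.frame(beta = betas, score = score, status = status)
  ok <- which(is.finite(score))
  if (!length(ok)) {
    warning("no nondegenerate model at any beta")
    return(list(best_beta = NA_real_, curve = curve, fits = fits))
  }
  list(best_beta = betas[ok[which.min(score[ok])]], curve = curve, fits = fits)
}

#' Subsampled silhouette score of a hard labeling
#'
#' Mean Euclidean silhouette width of the hard cluster labels, averaged over
#' seeded random subsamples of the items (the full sample is used when
#' `subsample_size >= N`).  Subsamples containing fewer than two distinct
#' labels are redrawn (bounded retries).
#'
#' @param labels integer labels, or a `"lapmix"` fit.
#' @param x items-by-features numeric matrix the silhouette is computed in.
#' @param n_subsamples number of random subsamples.
#' @param subsample_size items per subsample.
#' @param seed integer seed.
#' @return Mean silhouette score.
#' @export
silhouette_profile <- function(labels, x, n_subsamples = 10,
                               subsample_size = 2000, seed = 1L) {
  if (inherits(labels, "lapmix")) labels <- labels$labels
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2) stop("silhouette needs at least 2 distinct labels")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  if (subsample_size >= n) {
    sil <- cluster::silhouette(labels, stats::dist(x))
    return(mean(sil[, "sil_width"]))
  }
  scores <- numeric(n_subsamples)
  for (s in seq_len(n_subsamples)) {
    for (try in 1:20) {
      idx <- sample.int(n, subsample_size)
      if (length(unique(labels[idx])) >= 2) break
      if (try == 20) stop("could not draw a subsample with 2 distinct labels")
    }
    sil <- cluster::silhouette(labels[idx], stats::dist(x[idx, , drop = FALSE]))
    scores[s] <- mean(sil[, "sil_width"])
  }
  mean(scores)
}

#' Robust-fit model selection over a model sequence
#'
#' Fits a robust line (iteratively reweighted least squares with bisquare
#' weights) of the per-order quality scores against the optimal objective
#' values, and selects the highest-dimensional model whose residual is
#' positive, i.e. the largest model that beats the overall score-vs-loss
#' trend.  When no residual is positive the smallest model is returned with a
#' warning.
#'
#' @param sequence a `"lapmix_sequence"`, or an integer vector of model
#'   orders.
#' @param scores per-order quality scores (e.g. silhouette profiles).
#' @param losses per-order optimal objective values (taken from `sequence`
#'   when it is a `"lapmix_sequence"`).
#' @param tol residuals must exceed this to count as positive (guards against
#'   reading numerical noise on collinear scores as structure).
#' @return The chosen model order, with the fitted residuals attached as
#'   attribute `"residuals"`.
#' @export
select_model <- function(sequence, scores, losses = NULL, tol = 1e-8) {
  if (inherits(sequence, "lapmix_sequence")) {
    ok <- sequence$status != "degenerate"
    ms <- sequence$m[ok]
    if (is.null(losses)) {
      losses <- vapply(sequence$fits[ok], function(f) f$loss, numeric(1))
    }
    scores <- scores[ok]
  } else {
    ms <- as.integer(sequence)
  }
  if (length(ms) < 3) stop("need at least 3 scored models")
  rfit <- MASS::rlm(scores ~ losses, psi = MASS::psi.bisquare, maxit = 100)
  res <- stats::residuals(rfit)
  pos <- which(res > tol)
  choice <- if (length(pos)) max(ms[pos]) else {
    warning("no model has a positive residual; falling back to the smallest")
    min(ms)
  }
  attr(choice, "residuals") <- stats::setNames(res, ms)
  choice
}

#' Grid search over the k-NN sparsification parameters
#'
#' For every `(k_min, k_nn)` pair: preprocess the adjacency matrix, keep the
#' largest connected component, fit an `m`-component model, and record the
#' hard-threshold cluster size distribution (the largest and second-largest
#' sizes are the usual selection criterion).
#'
#' @param graph weighted adjacency matrix.
#' @param k_min_range,k_nn_range integer vectors to scan.
#' @param m number of components.
#' @param params a [search_params()] list.
#' @param min_weight_quantile passed to [adjacency_preprocess()].
#' @return Data frame with one row per grid cell: `k_min`, `k_nn`, `status`,
#'   `n_used`, `largest`, `second`, and `sizes` (all sizes, comma separated,
#'   decreasing).
#' @export
knn_grid_search <- function(graph, k_min_range, k_nn_range, m = 5,
                            params = search_params(),
                            min_weight_quantile = 0.99) {
  rows <- list()
  for (k_min in k_min_range) {
    for (k_nn in k_nn_range) {
      g <- suppressWarnings(
        adjacency_preprocess(graph, k_nn = k_nn, k_min = k_min,
                             min_weight_quantile = min_weight_quantile))
      lcc <- largest_connected_component(g)
      row <- data.frame(k_min = k_min, k_nn = k_nn, status = "degenerate",
                        n_used = length(lcc$index), largest = NA_integer_,
                        second = NA_integer_, sizes = NA_character_)
      if (length(lcc$index) >= m) {
        fit <- tryCatch(lapmix(lcc$graph, m = m, type = "graph", params = params),
                        error = function(e) NULL)
        if (!is.null(fit) && fit$status != "degenerate") {
          sz <- sort(tabulate(fit$labels, m), decreasing = TRUE)
          row$status <- "solved"
          row$largest <- sz[1]
          row$second <- if (m >= 2) sz[2] else NA_integer_
          row$sizes <- paste(sz, collapse = ",")
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
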