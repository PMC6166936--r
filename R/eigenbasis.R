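#' Leading Laplacian eigenbasis
#'
#' Computes the first `m` eigenpairs of a symmetric Laplacian system, ordered
#' by ascending eigenvalue magnitude, together with the derived quantities the
#' optimizer works with: the stationary weight `w = phi_0^2` (entrywise square
#' of the Perron-Frobenius eigenvector, summing to one) and the ratio matrix
#' `omega` with columns `phi_k / phi_0` (column one identically 1).
#'
#' Small systems are decomposed densely; larger ones use the ARPACK sparse
#' iterative solver (through \pkg{igraph}) on the spectrally shifted operator
#' `cI - L` so that the small-magnitude end of the spectrum converges quickly.
#'
#' @param system a `"lapmix_laplacian"` from [graph_laplacian()],
#'   [symmetrize_detailed_balance()] or [smoluchowski_laplacian()].
#' @param m number of eigenvectors (>= 2).
#' @param dense_cutoff below this many vertices the dense solver is used.
#' @return A `"lapmix_basis"` object with fields `vectors` (N x m, orthonormal
#'   columns), `values`, `weight`, `ratios`, `n`, `m`, `sym_scaling`,
#'   `source`.
#' @export
laplacian_eigenbasis <- function(system, m, dense_cutoff = 1200) {
  stopifnot(inherits(system, "lapmix_laplacian"))
  L <- system$matrix
  n <- nrow(L)
  if (m < 2) stop("m must be at least 2")
  if (m > n) stop("m cannot exceed the number of vertices")

  if (n <= dense_cutoff) {
    es <- eigen(as.matrix(L), symmetric = TRUE)
    idx <- seq(n, n - m + 1)
    vectors <- es$vectors[, idx, drop = FALSE]
    values <- es$values[idx]
  } else {
    # largest eigenpairs of the shifted operator c*I - L; c from Gershgorin
    cshift <- max(Matrix::rowSums(abs(L))) + 1
    res <- tryCatch(
      igraph::arpack(function(x, extra) cshift * x - as.vector(L %*% x),
                     sym = TRUE,
                     options = list(n = n, nev = m,
                                    ncv = min(n, max(4 * m + 1, 25)),
                                    which = "LA", maxiter = 5000)),
      error = function(e) NULL)
    if (is.null(res)) {
      if (n <= 5000) {
        es <- eigen(as.matrix(L), symmetric = TRUE)
        idx <- seq(n, n - m + 1)
        vectors <- es$vectors[, idx, drop = FALSE]
        values <- es$values[idx]
      } else {
        stop("sparse eigensolver did not converge and the system is too large for the dense fallback")
      }
    } else {
      values <- cshift - res$values
      ord <- order(abs(values))
      values <- values[ord][seq_len(m)]
      vectors <- res$vectors[, ord, drop = FALSE][, seq_len(m), drop = FALSE]
    }
  }

  ord <- order(abs(values))
  values <- values[ord]
  vectors <- vectors[, ord, drop = FALSE]

  # deterministic sign fixing
  phi0 <- vectors[, 1]
  if (sum(phi0) < 0) phi0 <- -phi0
  if (min(phi0) < -1e-8 * max(abs(phi0))) {
    stop("Perron-Frobenius eigenvector has negative entries: the graph appears ",
         "disconnected (or the zero eigenvalue is not simple)")
  }
  phi0 <- abs(phi0)
  vectors[, 1] <- phi0
  for (k in seq_len(m)[-1]) {
    v <- vectors[, k]
    if (v[which.max(abs(v))] < 0) vectors[, k] <- -v
  }

  dmax <- max(Matrix::diag(L))
  if (m >= 2 && values[1] > 1e-8 * max(abs(values)) && values[1] > 1e-12 * dmax) {
    warning(sprintf("lowest eigenvalue %.3g is not negligible against the spectrum scale %.3g; is the graph connected?",
                    values[1], max(abs(values))))
  }

  weight <- phi0^2
  weight <- weight / sum(weight)

  basis <- structure(list(vectors = vectors, values = values, weight = weight,
                          n = n, m = m, sym_scaling = system$sym_scaling,
                          source = system$source, grid = system$grid),
                     class = "lapmix_basis")
  basis$ratios <- basis_ratios(basis)
  basis
}

#' Eigenvector ratio matrix
#'
#' Returns the `N x m` matrix `omega` with entries
#' `omega[i, k] = phi_k(i) / phi_0(i)`; its first column is identically one.
#' Entries of `phi_0` below `1e-12 * max(phi_0)` signal near-disconnection and
#' raise an error naming the vertex.
#'
#' @param basis a `"lapmix_basis"`.
#' @return Numeric `N x m` matrix.
#' @export
basis_ratios <- function(basis) {
  stopifnot(inherits(basis, "lapmix_basis"))
  phi0 <- basis$vectors[, 1]
  eps_div <- 1e-12 * max(phi0)
  bad <- which(phi0 < eps_div)
  if (length(bad)) {
    stop(sprintf("phi_0 is numerically zero at vertex %d: graph is (nearly) disconnected",
                 bad[1]))
  }
  om <- basis$vectors / phi0
  om[, 1] <- 1
  om
}

#' @export
print.lapmix_basis <- function(x, ...) {
  cat(sprintf("Laplacian eigenbasis: %d vertices, m = %d, source = %s\n",
              x$n, x$m, x$source))
  cat("eigenvalues:", format(x$values, digits = 4), "\n")
  invisible(x)
}

#' Write / read an eigenbasis cache as delimited text
#'
#' Allows the (possibly expensive) eigendecomposition to be reused across
#' model orders once the similarity matrix has been released.
#'
#' @param basis a `"lapmix_basis"`.
#' @param path file path.
#' @rdname eigenbasis_cache
#' @export
write_eigenbasis <- function(basis, path) {
  hdr <- sprintf("# lapmix eigenbasis n=%d m=%d source=%s", basis$n, basis$m,
                 basis$source)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(format(basis$values, digits = 17), collapse = "\t"), con)
  utils::write.table(format(basis$vectors, digits = 17), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param system the Laplacian system the cache belongs to (restores the
#'   symmetrization scaling and source tag).
#' @rdname eigenbasis_cache
#' @export
read_eigenbasis <- function(path, system = NULL) {
  lines <- readLines(path)
  meta <- strsplit(sub("^# lapmix eigenbasis ", "", lines[1]), " ")[[1]]
  kv <- do.call(rbind, strsplit(meta, "="))
  values <- as.numeric(strsplit(lines[2], "\t")[[1]])
  vectors <- as.matrix(utils::read.table(text = lines[-(1:2)], sep = "\t"))
  dimnames(vectors) <- NULL
  basis <- structure(list(vectors = vectors, values = values,
                          weight = vectors[, 1]^2 / sum(vectors[, 1]^2),
                          n = nrow(vectors), m = ncol(vectors),
                          sym_scaling = if (!is.null(system)) system$sym_scaling,
                          source = kv[kv[, 1] == "source", 2],
                          grid = if (!is.null(system)) system$grid),
                     class = "lapmix_basis")
  basis$ratios <- basis_ratios(basis)
  basis
}
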