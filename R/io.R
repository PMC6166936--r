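# Readers/writers for the supported on-disk formats and the configuration
# driven pipeline.  Internal vertex indexing is 0-free (R's 1-based); edge
# lists on disk default to 0-based indices, Matrix Market is 1-based.

#' Read a weighted graph
#'
#' Supports Matrix Market coordinate files (1-based indices; symmetric or
#' general — general input must be symmetric and is rejected otherwise) and
#' whitespace/tab-delimited edge lists with columns `src dst weight`
#' (0-based by default).  An index-base mismatch in edge lists is detected
#' heuristically (a 0 index under `index_base = 1`, or a suspicious dense
#' max index) and reported.
#'
#' @param path input file.
#' @param format `"auto"` (by extension: `.mtx` vs anything else), `"mtx"`,
#'   or `"edgelist"`.
#' @param index_base 0 or 1; edge-list vertex index base.
#' @param n_vertices optional vertex count (edge lists; defaults to the
#'   maximum index seen).
#' @return Sparse symmetric adjacency matrix.
#' @export
read_graph <- function(path, format = c("auto", "mtx", "edgelist"),
                       index_base = 0, n_vertices = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "edgelist"
  }
  if (format == "mtx") {
    A <- Matrix::readMM(path)
    A <- methods::as(A, "CsparseMatrix")
    return(as_weighted_graph(A))
  }
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("src", "dst", "weight"))
  if (index_base == 1 && any(df$src == 0 | df$dst == 0)) {
    stop("edge list declared 1-based but contains index 0; set index_base = 0")
  }
  i <- df$src + (1 - index_base)
  j <- df$dst + (1 - index_base)
  n <- if (is.null(n_vertices)) max(i, j) else n_vertices
  if (index_base == 0 && !is.null(n_vertices) && max(df$src, df$dst) == n_vertices) {
    stop("edge list declared 0-based but its maximum index equals n_vertices; ",
         "it looks 1-based")
  }
  A <- Matrix::sparseMatrix(i = i, j = j, x = df$weight, dims = c(n, n))
  At <- Matrix::t(A)
  both <- (A != 0) * (At != 0)
  bad <- Matrix::drop0((A - At) * both)
  if (length(bad@x) && max(abs(bad@x)) > 1e-12) {
    stop("edge list provides both directions of an edge with different weights")
  }
  as_weighted_graph((A + At + abs(A - At)) / 2)
}

#' Write a weighted graph
#'
#' @param graph adjacency matrix.
#' @param path output file.
#' @param format `"mtx"` or `"edgelist"`.
#' @param index_base edge-list index base on disk.
#' @export
write_graph <- function(graph, path, format = c("mtx", "edgelist"),
                        index_base = 0) {
  format <- match.arg(format)
  g <- as_weighted_graph(graph)
  if (format == "mtx") {
    Matrix::writeMM(g, path)
  } else {
    trip <- Matrix::summary(methods::as(g, "generalMatrix"))
    trip <- trip[trip$i < trip$j, , drop = FALSE]
    utils::write.table(
      data.frame(src = trip$i - (1 - index_base),
                 dst = trip$j - (1 - index_base),
                 weight = trip$x),
      path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a delimited feature table
#'
#' @param path delimited text file with a header row.
#' @param sep field separator (default: any whitespace).
#' @return Numeric matrix.
#' @export
read_features <- function(path, sep = "") {
  as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                              check.names = FALSE))
}

#' Read density values with grid metadata
#'
#' Values come from a delimited text file (one value per line or
#' whitespace-separated, in column-major grid order); `shape` and `spacing`
#' come either from arguments or from a JSON sidecar `<path>.json` with those
#' fields.
#'
#' @param path values file.
#' @param shape,spacing grid metadata (override the sidecar).
#' @return A [density_grid()].
#' @export
read_density <- function(path, shape = NULL, spacing = NULL) {
  vals <- scan(path, quiet = TRUE)
  sidecar <- paste0(path, ".json")
  if ((is.null(shape) || is.null(spacing)) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(shape)) shape <- meta$shape
    if (is.null(spacing)) spacing <- meta$spacing
  }
  if (is.null(spacing)) spacing <- 1
  density_grid(vals, shape = shape, spacing = spacing)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a fitted model to a directory
#'
#' Writes the partition-of-unity table (`model_p.tsv`: item id, `p_1..p_m`,
#' hard label) and JSON metadata (`model_meta.json`: m, loss, per-component
#' losses, weights, seed, configuration hash).
#'
#' @param fit a `"lapmix"` model.
#' @param dir output directory (created).
#' @param config optional configuration list recorded in the metadata hash.
#' @return `dir`, invisibly.
#' @export
write_model <- function(fit, dir, config = NULL) {
  stopifnot(inherits(fit, "lapmix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (fit$status == "degenerate") {
    jsonlite::write_json(list(m = fit$m, status = "degenerate",
                              seed = fit$seed),
                         file.path(dir, "model_meta.json"), auto_unbox = TRUE)
    return(invisible(dir))
  }
  tab <- data.frame(item = seq_len(nrow(fit$p)), fit$p, label = fit$labels)
  names(tab) <- c("item", paste0("p_", seq_len(fit$m)), "label")
  utils::write.table(tab, file.path(dir, "model_p.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(m = fit$m, loss = fit$loss,
               component_losses = fit$component_losses,
               weights = fit$weights, status = fit$status, seed = fit$seed,
               config_hash = if (!is.null(config)) config_hash(config))
  jsonlite::write_json(meta, file.path(dir, "model_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(fit$restarts, file.path(dir, "restarts.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Run the full pipeline from a configuration
#'
#' Executes input reading, input-specific preprocessing, Laplacian and
#' eigenbasis construction, model fitting for each requested order (stopping
#' at the first degenerate order), and writes model files plus a solver
#' report under `config$output`.  Deterministic for a fixed seed.
#'
#' @param config a list (or path to a JSON file) with fields `input` (path,
#'   or an in-memory object), `type` (`graph`/`features`/`density`), `m`
#'   (scalar or vector of orders), `output` (directory), and optionally
#'   `seed`, `beta`, `shape`, `spacing`, `k_nn`, `k_min`,
#'   `min_weight_quantile`, `kernel`, `n_restarts`.
#' @return A `"lapmix_sequence"` (invisibly); artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (field in c("input", "type", "m", "output")) {
    if (is.null(config[[field]])) stop("config is missing required field '", field, "'")
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- search_params(n_restarts = config$n_restarts, seed = seed)
  x <- config$input
  if (is.character(x)) {
    x <- switch(config$type,
                graph = read_graph(x),
                features = read_features(x),
                density = read_density(x, shape = config$shape,
                                       spacing = config$spacing),
                stop("config$type must be graph, features or density"))
  }
  if (config$type == "graph" &&
      (!is.null(config$k_nn) || !is.null(config$k_min))) {
    x <- adjacency_preprocess(
      x, k_nn = config$k_nn,
      k_min = if (is.null(config$k_min)) 0 else config$k_min,
      min_weight_quantile = if (is.null(config$min_weight_quantile)) 0.99
                            else config$min_weight_quantile)
    x <- largest_connected_component(x)$graph
  }
  args <- list(x = x, type = config$type, params = params)
  for (f in c("k_nn", "k_min", "min_weight_quantile", "kernel", "beta",
              "spacing")) {
    if (!is.null(config[[f]])) args[[f]] <- config[[f]]
  }
  ms <- sort(unique(as.integer(config$m)))
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)
  fits <- list(); status <- character(0)
  for (m in ms) {
    fit <- do.call(lapmix, c(args, list(m = m)))
    fits[[length(fits) + 1]] <- fit
    status <- c(status, fit$status)
    write_model(fit, file.path(config$output, sprintf("m%02d", m)),
                config = config)
    if (fit$status == "degenerate") break
  }
  seq_ <- structure(list(fits = fits, m = ms[seq_along(fits)], status = status),
                    class = "lapmix_sequence")
  jsonlite::write_json(
    list(m = seq_[["m"]], status = status, seed = seed,
         loss = vapply(fits, function(f) f$loss, numeric(1)),
         config_hash = config_hash(config[setdiff(names(config), "input")])),
    file.path(config$output, "run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(seq_)
}
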