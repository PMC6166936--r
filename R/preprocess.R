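# Normalizations for expression-style feature tables (items in columns,
# features in rows, as in cells-by-genes single-cell matrices).

#' Denoised unit-max normalization
#'
#' Per item (column): subtract the column median (offset/additive noise),
#' divide by the maximum of the centered column (gain/multiplicative noise),
#' then remove outlier values — entries that are negative or exactly one after
#' scaling — by setting them to zero.  Columns whose maximum equals their
#' median (constant columns, including all-zero items) are dropped, and
#' duplicate feature rows of the normalized table are removed.
#'
#' @param x numeric matrix, features in rows, items in columns.
#' @return List with `values` (the normalized, denoised matrix), and `report`:
#'   counts of dropped all-zero and constant columns, zeroed outlier cells,
#'   and removed duplicate rows, plus the dropped column indices.
#' @export
denoised_unit_max <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("feature table contains non-finite values")
  med <- apply(x, 2, stats::median)
  mx <- apply(x, 2, max)
  all_zero <- which(apply(x, 2, function(col) all(col == 0)))
  constant <- setdiff(which(mx <= med), all_zero)
  drop_cols <- sort(c(all_zero, constant))
  keep <- setdiff(seq_len(ncol(x)), drop_cols)
  y <- sweep(x[, keep, drop = FALSE], 2, med[keep])
  y <- sweep(y, 2, apply(y, 2, max), "/")
  out_mask <- y < 0 | y == 1
  n_outlier <- sum(out_mask)
  y[out_mask] <- 0
  dup <- duplicated(y)
  n_dup <- sum(dup)
  y <- y[!dup, , drop = FALSE]
  list(values = y,
       report = list(n_zero_cols = length(all_zero),
                     n_constant_cols = length(constant),
                     n_outlier_cells = n_outlier,
                     n_duplicate_rows = n_dup,
                     dropped_cols = unname(drop_cols)))
}

#' Unit-median normalization
#'
#' Divides every column by the median of its nonzero values; intended to be
#' applied after [denoised_unit_max()].  All-zero columns are dropped.
#'
#' @param x numeric matrix, features in rows, items in columns.
#' @return The rescaled matrix (possibly with fewer columns); dropped column
#'   indices are attached as attribute `"dropped_cols"`.
#' @export
unit_median <- function(x) {
  x <- as.matrix(x)
  nzmed <- apply(x, 2, function(col) {
    nz <- col[col != 0]
    if (length(nz)) stats::median(nz) else NA_real_
  })
  drop_cols <- which(is.na(nzmed))
  keep <- setdiff(seq_len(ncol(x)), drop_cols)
  y <- sweep(x[, keep, drop = FALSE], 2, nzmed[keep], "/")
  attr(y, "dropped_cols") <- drop_cols
  y
}
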