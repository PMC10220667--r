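#' Masked data block
#'
#' A `masked_matrix` couples a channels-by-samples block of signal values
#' (conventionally microvolts) with a logical mask of the same shape.
#' `TRUE` mask entries are observed (usable) values; `FALSE` entries are
#' corrupted and are the target of matrix completion.
#'
#' @param values Numeric matrix, channels x samples.
#' @param mask Logical matrix of the same shape; `TRUE` = observed.
#'   Defaults to fully observed.
#' @return An object of class `masked_matrix` with elements `values` and
#'   `mask`.
#' @examples
#' m <- masked_matrix(matrix(rnorm(20), 4, 5))
#' severity(m)
#' @export
masked_matrix <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(mask))
    mask <- matrix(TRUE, nrow(values), ncol(values))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values)))
    stop("'values' and 'mask' must have identical dimensions")
  if (!is.logical(mask))
    storage.mode(mask) <- "logical"
  if (anyNA(mask))
    stop("'mask' must not contain NA")
  structure(list(values = values, mask = mask), class = "masked_matrix")
}

#' @export
print.masked_matrix <- function(x, ...) {
  cat(sprintf("<masked_matrix> %d x %d, severity %.2f%%\n",
              nrow(x$values), ncol(x$values), severity(x)))
  invisible(x)
}

#' @export
dim.masked_matrix <- function(x) dim(x$values)

#' Artifact severity of a block
#'
#' Percentage of entries of a block (or of a logical mask) that are
#' corrupted, i.e. `100 * #FALSE / (C * Tk)`.
#'
#' @param x A `masked_matrix`, or a logical mask matrix (`TRUE` = observed).
#' @return A percentage in `[0, 100]`.
#' @export
severity <- function(x) {
  mask <- if (inherits(x, "masked_matrix")) x$mask else x
  100 * sum(!mask) / length(mask)
}

#' Rows and columns with no observed entry
#'
#' A block is completable only if every row and every column retains at
#' least one observed entry; all-missing lines cannot be recovered by any
#' completion and must be handled upstream (channel/timepoint rejection).
#'
#' @param block A `masked_matrix`.
#' @return List with integer vectors `rows` and `cols` of all-missing lines.
#' @export
infeasible_lines <- function(block) {
  stopifnot(inherits(block, "masked_matrix"))
  list(rows = which(rowSums(block$mask) == 0L),
       cols = which(colSums(block$mask) == 0L))
}

#' Is a block completable?
#'
#' @param block A `masked_matrix`.
#' @return `TRUE` when every row and column has at least one observed entry.
#' @export
is_completable <- function(block) {
  bad <- infeasible_lines(block)
  length(bad$rows) == 0L && length(bad$cols) == 0L
}

#' Zero-fill a masked block
#'
#' Returns the block values with every corrupted entry replaced by zero --
#' the matrix whose truncated SVD seeds the completion.
#'
#' @param block A `masked_matrix`.
#' @return Numeric matrix of the same shape.
#' @export
zero_fill <- function(block) {
  stopifnot(inherits(block, "masked_matrix"))
  out <- block$values
  out[!block$mask] <- 0
  out
}

#' Trim over-represented rows and columns
#'
#' Rows (columns) whose observed-entry count exceeds `degree_factor` times
#' the mean observed row (column) count are zeroed out and marked
#' unobserved in a copy of the block.  Trimming equalizes the influence of
#' lines on the spectral initialization; the iterative refinement is then
#' run against the untrimmed mask.
#'
#' @param block A `masked_matrix`.
#' @param degree_factor Positive multiplier of the mean degree above which
#'   a line counts as over-represented (default 2).
#' @return A new `masked_matrix` with over-represented lines blanked.
#' @export
trim_block <- function(block, degree_factor = 2) {
  stopifnot(inherits(block, "masked_matrix"), degree_factor > 0)
  mask <- block$mask
  row_deg <- rowSums(mask)
  col_deg <- colSums(mask)
  heavy_rows <- row_deg > degree_factor * mean(row_deg)
  heavy_cols <- col_deg > degree_factor * mean(col_deg)
  values <- block$values
  values[heavy_rows, ] <- 0
  values[, heavy_cols] <- 0
  mask[heavy_rows, ] <- FALSE
  mask[, heavy_cols] <- FALSE
  masked_matrix(values, mask)
}
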