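#' Continuous multichannel recording
#'
#' Container for a channels-by-samples data matrix with its sampling rate,
#' channel labels, an observed/corrupted mask, and rejection metadata.
#' The mask uses the same convention as [masked_matrix()]: `TRUE` =
#' observed (usable), `FALSE` = corrupted.
#'
#' @param data Numeric matrix, channels x samples (microvolts by
#'   convention; thresholds in [repair_config()] scale linearly if another
#'   unit is used).
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels (default
#'   `"ch1", ...`).
#' @param mask Logical matrix like `data`; default fully observed.
#' @return Object of class `recording` with elements `data`, `fs`,
#'   `channels`, `mask`, `rejected_channels`, `rejected_timepoints`.
#' @export
recording <- function(data, fs, channels = NULL, mask = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0)
  C <- nrow(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(C))
  stopifnot(length(channels) == C)
  if (is.null(mask)) mask <- matrix(TRUE, C, ncol(data))
  stopifnot(identical(dim(mask), dim(data)), is.logical(mask))
  structure(list(data = data, fs = fs, channels = as.character(channels),
                 mask = mask, rejected_channels = integer(0),
                 rejected_timepoints = integer(0)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channels x %d samples @ %g Hz, %.2f%% corrupted\n",
    nrow(x$data), ncol(x$data), x$fs, severity(x$mask)))
  if (length(x$rejected_channels))
    cat(" rejected channels:", paste(x$channels[x$rejected_channels],
                                     collapse = ", "), "\n")
  if (length(x$rejected_timepoints))
    cat(sprintf(" rejected timepoints: %d\n", length(x$rejected_timepoints)))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

#' Write / read a recording as delimited text
#'
#' The data matrix is stored channels x samples as tab-separated values
#' with a leading `channel` column of labels; the mask (if any corrupted
#' entries exist) goes to a sibling file of 0/1 values with the same
#' layout.  `read_recording()` reverses the operation.
#'
#' @param rec A `recording`.
#' @param path Output file for the data matrix.
#' @param mask_path Optional path for the 0/1 mask matrix (1 = observed);
#'   default `paste0(path, ".mask")` when the mask has corrupted entries.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `recording`.
#' @export
write_recording <- function(rec, path, mask_path = NULL) {
  stopifnot(inherits(rec, "recording"))
  df <- data.frame(channel = rec$channels, rec$data, check.names = FALSE)
  colnames(df) <- c("channel", seq_len(ncol(rec$data)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (is.null(mask_path) && any(!rec$mask))
    mask_path <- paste0(path, ".mask")
  if (!is.null(mask_path)) {
    mdf <- data.frame(channel = rec$channels, rec$mask + 0L,
                      check.names = FALSE)
    colnames(mdf) <- colnames(df)
    utils::write.table(mdf, mask_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_recording
#' @param fs Sampling rate in Hz (not stored in the text container).
#' @export
read_recording <- function(path, fs, mask_path = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  channels <- as.character(df[[1]])
  data <- as.matrix(df[, -1, drop = FALSE])
  dimnames(data) <- NULL
  mask <- NULL
  if (is.null(mask_path) && file.exists(paste0(path, ".mask")))
    mask_path <- paste0(path, ".mask")
  if (!is.null(mask_path)) {
    mdf <- utils::read.table(mask_path, sep = "\t", header = TRUE,
                             check.names = FALSE)
    mask <- as.matrix(mdf[, -1, drop = FALSE]) != 0
    dimnames(mask) <- NULL
  }
  recording(data, fs, channels, mask)
}

#' Read interval artifact annotations
#'
#' Annotations are a CSV of `channel_label, start_sample, end_sample`
#' rows with 0-based, half-open sample intervals; `channel_label = "*"`
#' applies to every channel.
#'
#' @param path CSV file path.
#' @return Data frame with columns `channel_label`, `start_sample`,
#'   `end_sample`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_label", "start_sample", "end_sample")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns ",
         paste(need, collapse = ", "))
  ann
}

#' Convert interval annotations to a bad-entry mask
#'
#' @param rec A `recording`.
#' @param annotations Data frame as returned by [read_annotations()].
#' @return Logical C x T matrix, `TRUE` = annotated bad.
#' @export
annotations_to_bad <- function(rec, annotations) {
  bad <- matrix(FALSE, nrow(rec$data), ncol(rec$data))
  if (is.null(annotations) || nrow(annotations) == 0L) return(bad)
  T_len <- ncol(rec$data)
  for (k in seq_len(nrow(annotations))) {
    lab <- annotations$channel_label[k]
    rows <- if (identical(lab, "*")) seq_len(nrow(bad))
            else match(lab, rec$channels)
    if (anyNA(rows))
      stop(sprintf("unknown channel label '%s' in annotations", lab))
    # 0-based half-open [start, end)
    cols <- seq.int(annotations$start_sample[k] + 1L,
                    min(annotations$end_sample[k], T_len))
    bad[rows, cols] <- TRUE
  }
  bad
}
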