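#' Repair-pipeline configuration
#'
#' Bundles the hyperparameters of the artifact-marking rules and of the
#' blockwise completion.  Defaults follow standard practice for
#' high-density infant EEG at 250 Hz: 250 uV sample-to-sample jump
#' threshold, 150 uV fast/slow moving-average deviation threshold, 10-SD
#' global outlier threshold, 70% / 75% / 50% channel / timepoint / trial
#' rejection fractions, 120-sample completion blocks, and a 0.5-20 Hz
#' band-pass applied after completion.
#'
#' @param block_size Completion epoch length Tk in samples (>= 2).
#' @param rank Completion rank r for every block.
#' @param jump_threshold Sample-to-sample jump marking threshold (uV).
#' @param deviation_threshold Fast-vs-slow moving-average deviation
#'   threshold (uV).
#' @param sd_threshold Global outlier threshold in multiples of the
#'   overall SD.
#' @param channel_reject_frac Channels with a bad fraction strictly above
#'   this are rejected for the whole recording.
#' @param timepoint_reject_frac Timepoints bad on strictly more than this
#'   fraction of channels are rejected for all channels.
#' @param trial_reject_frac Trials with strictly more than this fraction
#'   of corrupted entries are dropped.
#' @param replace_observed If `TRUE` (default) a completed block replaces
#'   observed entries by the low-rank model too; if `FALSE` only corrupted
#'   entries are filled.
#' @param bandpass Length-2 numeric `(low, high)` in Hz, or `NULL` to skip
#'   filtering.
#' @param fast_window,slow_window Moving-average windows for the deviation
#'   rule, in seconds.
#' @return Object of class `repair_config`.
#' @export
repair_config <- function(block_size = 120, rank = 12,
                          jump_threshold = 250, deviation_threshold = 150,
                          sd_threshold = 10,
                          channel_reject_frac = 0.70,
                          timepoint_reject_frac = 0.75,
                          trial_reject_frac = 0.50,
                          replace_observed = TRUE,
                          bandpass = c(0.5, 20),
                          fast_window = 0.02, slow_window = 0.5) {
  stopifnot(block_size >= 2, rank >= 1,
            jump_threshold > 0, deviation_threshold > 0, sd_threshold > 0,
            channel_reject_frac > 0, channel_reject_frac <= 1,
            timepoint_reject_frac > 0, timepoint_reject_frac <= 1,
            trial_reject_frac > 0, trial_reject_frac <= 1,
            fast_window > 0, slow_window > fast_window)
  structure(list(block_size = block_size, rank = rank,
                 jump_threshold = jump_threshold,
                 deviation_threshold = deviation_threshold,
                 sd_threshold = sd_threshold,
                 channel_reject_frac = channel_reject_frac,
                 timepoint_reject_frac = timepoint_reject_frac,
                 trial_reject_frac = trial_reject_frac,
                 replace_observed = replace_observed,
                 bandpass = bandpass,
                 fast_window = fast_window, slow_window = slow_window),
            class = "repair_config")
}

# centered moving mean with shrinking windows at the edges
moving_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- width %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Threshold-based artifact marking
#'
#' Marks an entry bad when any of three rules fires: (a) the
#' sample-to-sample jump flanking it exceeds `jump_threshold`; (b) the
#' absolute difference between a fast and a slow centered moving average
#' of its channel exceeds `deviation_threshold`; (c) its value deviates
#' from the overall (whole-matrix) mean by more than `sd_threshold` times
#' the overall SD.  Non-finite samples are always marked bad.  Manual
#' annotations, if given, are OR-ed in.
#'
#' @param rec A `recording`.
#' @param cfg A `repair_config`.
#' @param annotations Optional annotation data frame
#'   (see [read_annotations()]).
#' @return Logical C x T matrix, `TRUE` = marked bad.
#' @export
mark_artifacts <- function(rec, cfg = repair_config(), annotations = NULL) {
  stopifnot(inherits(rec, "recording"), inherits(cfg, "repair_config"))
  D <- rec$data
  C <- nrow(D); T_len <- ncol(D)
  bad <- !is.finite(D)
  Dz <- D
  Dz[bad] <- 0
  # (a) sample-to-sample jumps: mark the two flanking samples
  if (T_len >= 2) {
    jumps <- abs(Dz[, -1, drop = FALSE] - Dz[, -T_len, drop = FALSE]) >
      cfg$jump_threshold
    bad[, -T_len] <- bad[, -T_len] | jumps
    bad[, -1] <- bad[, -1] | jumps
  }
  # (b) fast vs slow moving-average deviation
  wf <- max(1L, round(cfg$fast_window * rec$fs))
  ws <- max(wf + 1L, round(cfg$slow_window * rec$fs))
  for (i in seq_len(C)) {
    dev <- abs(moving_mean(Dz[i, ], wf) - moving_mean(Dz[i, ], ws))
    bad[i, dev > cfg$deviation_threshold] <- TRUE
  }
  # (c) global z-score outliers against the overall voltage mean/SD
  fin <- is.finite(D)
  mu <- mean(D[fin])
  sdev <- stats::sd(D[fin])
  if (is.finite(sdev) && sdev > 0)
    bad <- bad | (abs(Dz - mu) > cfg$sd_threshold * sdev)
  if (!is.null(annotations))
    bad <- bad | annotations_to_bad(rec, annotations)
  bad
}

#' Apply a bad-entry mask to a recording
#'
#' @param rec A `recording`.
#' @param bad Logical C x T matrix, `TRUE` = bad (as from
#'   [mark_artifacts()]).
#' @return The recording with `mask` set to `!bad`.
#' @export
set_artifacts <- function(rec, bad) {
  stopifnot(inherits(rec, "recording"), identical(dim(bad), dim(rec$data)))
  rec$mask <- !bad
  rec
}

#' Reject channels with too many bad timepoints
#'
#' Channels whose fraction of corrupted entries is strictly greater than
#' `frac` are rejected for the entire recording.
#'
#' @param mask Logical observed-mask matrix (`TRUE` = observed) or a
#'   `recording`.
#' @param frac Rejection fraction (default 0.70).
#' @return Integer vector of rejected channel indices.
#' @export
reject_channels <- function(mask, frac = 0.70) {
  if (inherits(mask, "recording")) mask <- mask$mask
  which(rowMeans(!mask) > frac)
}

#' Reject timepoints bad across too many channels
#'
#' Timepoints corrupted on strictly more than `frac` of the channels are
#' rejected for all channels.
#'
#' @param mask Logical observed-mask matrix or a `recording`.
#' @param frac Rejection fraction (default 0.75).
#' @return Integer vector of rejected timepoint indices.
#' @export
reject_timepoints <- function(mask, frac = 0.75) {
  if (inherits(mask, "recording")) mask <- mask$mask
  which(colMeans(!mask) > frac)
}

#' Split a recording into nonoverlapping completion blocks
#'
#' Consecutive, stimulus-agnostic blocks of `block_size` columns covering
#' the recording; the final block carries the remainder.  When the
#' remainder is shorter than `min_remainder` columns it is merged into the
#' previous block to avoid degenerate least-squares systems.  Block
#' boundaries are recorded so reassembly is exact.
#'
#' @param rec A `recording`.
#' @param block_size Tk in samples (>= 2).
#' @param min_remainder Minimum width of a standalone remainder block
#'   (default 2).
#' @return List of `masked_matrix` blocks, each with attributes `start`
#'   and `end` (column indices into the recording).
#' @export
epoch_recording <- function(rec, block_size, min_remainder = 2) {
  stopifnot(inherits(rec, "recording"), block_size >= 2)
  T_len <- ncol(rec$data)
  starts <- seq.int(1L, T_len, by = block_size)
  ends <- pmin(starts + block_size - 1L, T_len)
  n <- length(starts)
  if (n > 1L && (ends[n] - starts[n] + 1L) < min_remainder) {
    ends[n - 1L] <- ends[n]
    starts <- starts[-n]; ends <- ends[-n]
    n <- n - 1L
  }
  lapply(seq_len(n), function(k) {
    idx <- starts[k]:ends[k]
    blk <- masked_matrix(rec$data[, idx, drop = FALSE],
                         rec$mask[, idx, drop = FALSE])
    attr(blk, "start") <- starts[k]
    attr(blk, "end") <- ends[k]
    blk
  })
}

#' Repair a recording by blockwise low-rank completion
#'
#' Runs the full per-block repair: globally rejected channels are excluded
#' from every fit, each block's remaining all-missing rows/columns are
#' excluded and reported, the feasible submatrix is completed at rank
#' `cfg$rank`, and the result is written back.  With
#' `cfg$replace_observed = TRUE` the whole block is replaced by the
#' low-rank model; otherwise observed entries are kept bitwise and only
#' corrupted entries are filled.  Per-block failures are recorded in the
#' report, never abort the recording.
#'
#' @param rec A `recording` whose `mask` is already populated (see
#'   [mark_artifacts()] / [set_artifacts()]).
#' @param cfg A `repair_config`.
#' @param reject If `TRUE` (default) run channel/timepoint rejection first
#'   and exclude the rejected lines from completion.
#' @return List with `recording` (repaired) and `report` (one row per
#'   block: `block`, `start`, `end`, `severity`, `iterations`,
#'   `final_cost`, `converged`, `n_infeasible_rows`, `n_infeasible_cols`,
#'   `status`).
#' @export
repair_recording <- function(rec, cfg = repair_config(), reject = TRUE) {
  stopifnot(inherits(rec, "recording"), inherits(cfg, "repair_config"))
  if (reject) {
    rec$rejected_channels <- reject_channels(rec$mask,
                                             cfg$channel_reject_frac)
    rec$rejected_timepoints <- reject_timepoints(rec$mask,
                                                 cfg$timepoint_reject_frac)
  }
  keep_ch <- setdiff(seq_len(nrow(rec$data)), rec$rejected_channels)
  bad_tp <- rec$rejected_timepoints
  blocks <- epoch_recording(rec, cfg$block_size,
                            min_remainder = 2 * cfg$rank)
  out <- rec$data
  rep_rows <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    blk <- blocks[[k]]
    cols_abs <- attr(blk, "start"):attr(blk, "end")
    keep_tp <- which(!(cols_abs %in% bad_tp))
    sub <- masked_matrix(blk$values[keep_ch, keep_tp, drop = FALSE],
                         blk$mask[keep_ch, keep_tp, drop = FALSE])
    sev <- severity(sub)
    row <- data.frame(block = k, start = attr(blk, "start"),
                      end = attr(blk, "end"), severity = sev,
                      iterations = NA_integer_, final_cost = NA_real_,
                      converged = NA, n_infeasible_rows = 0L,
                      n_infeasible_cols = 0L, status = "ok",
                      stringsAsFactors = FALSE)
    bad_lines <- infeasible_lines(sub)
    row$n_infeasible_rows <- length(bad_lines$rows)
    row$n_infeasible_cols <- length(bad_lines$cols)
    fit_rows <- setdiff(seq_len(nrow(sub$values)), bad_lines$rows)
    fit_cols <- setdiff(seq_len(ncol(sub$values)), bad_lines$cols)
    r_eff <- min(cfg$rank, length(fit_rows), length(fit_cols))
    if (length(fit_rows) == 0L || length(fit_cols) == 0L || r_eff < 1L) {
      row$status <- "irrecoverable"
    } else {
      fit <- tryCatch(
        complete_block(masked_matrix(
          sub$values[fit_rows, fit_cols, drop = FALSE],
          sub$mask[fit_rows, fit_cols, drop = FALSE]),
          rank = r_eff, block_index = k),
        error = function(e) e)
      if (inherits(fit, "error")) {
        row$status <- paste("failed:", conditionMessage(fit))
      } else {
        row$iterations <- fit$iterations
        row$final_cost <- fit$final_cost
        row$converged <- fit$converged
        patch <- sub$values
        patch[fit_rows, fit_cols] <- fit$completed
        if (!cfg$replace_observed)
          patch[sub$mask] <- sub$values[sub$mask]
        # never write into lines the fit could not see
        patch[bad_lines$rows, ] <- sub$values[bad_lines$rows, ]
        patch[, bad_lines$cols] <- sub$values[, bad_lines$cols]
        out[keep_ch, cols_abs[keep_tp]] <- patch
      }
    }
    rep_rows[[k]] <- row
  }
  repaired <- rec
  repaired$data <- out
  # completed entries are usable downstream; rejected lines stay corrupted
  mask_new <- rec$mask
  report <- do.call(rbind, rep_rows)
  for (k in which(report$status == "ok")) {
    cols_abs <- report$start[k]:report$end[k]
    keep_tp <- cols_abs[!(cols_abs %in% bad_tp)]
    mask_new[keep_ch, keep_tp] <- TRUE
  }
  mask_new[rec$rejected_channels, ] <- FALSE
  mask_new[, bad_tp] <- FALSE
  # entries inside infeasible lines of a block were not completed
  for (k in which(report$n_infeasible_rows > 0 | report$n_infeasible_cols > 0)) {
    cols_abs <- report$start[k]:report$end[k]
    keep_tp <- cols_abs[!(cols_abs %in% bad_tp)]
    sub_mask <- rec$mask[keep_ch, keep_tp, drop = FALSE]
    bad_lines <- infeasible_lines(masked_matrix(
      rec$data[keep_ch, keep_tp, drop = FALSE], sub_mask))
    m <- mask_new[keep_ch, keep_tp, drop = FALSE]
    m[bad_lines$rows, ] <- sub_mask[bad_lines$rows, ]
    m[, bad_lines$cols] <- sub_mask[, bad_lines$cols]
    mask_new[keep_ch, keep_tp] <- m
  }
  repaired$mask <- mask_new
  list(recording = repaired, report = report)
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`) to every channel, so ERP latencies are not
#' shifted.  In the recommended pipeline order, completion runs first on
#' the unfiltered data and filtering comes after.
#'
#' @param rec A `recording`.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order per band edge (default 4).
#' @return The filtered `recording`.
#' @export
bandpass_recording <- function(rec, low, high, order = 4) {
  stopifnot(inherits(rec, "recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("invalid band: need 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  for (i in seq_len(nrow(rec$data)))
    rec$data[i, ] <- signal::filtfilt(bf, rec$data[i, ])
  rec
}

#' Reject peristimulus trials by corrupted fraction
#'
#' A trial is dropped when strictly more than `frac` of its entries are
#' corrupted.  Peristimulus trials are distinct from completion blocks;
#' this rule is applied when selecting trials for ERP-style averaging.
#'
#' @param trial_masks List of logical channel x time observed-masks, one
#'   per trial (`TRUE` = observed).
#' @param frac Rejection fraction (default 0.50).
#' @return Integer vector of kept trial indices.
#' @export
reject_trials <- function(trial_masks, frac = 0.50) {
  bad_frac <- vapply(trial_masks, function(m) mean(!m), numeric(1))
  which(bad_frac <= frac)
}
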