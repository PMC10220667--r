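#' Set of peristimulus trials
#'
#' @param trials List of channel x time numeric matrices, all the same
#'   shape, aligned so that time zero is stimulus onset.
#' @param fs Sampling rate (Hz).
#' @param times Numeric vector of peristimulus times in ms (length =
#'   number of samples); default built from `fs` with onset at sample
#'   `onset`.
#' @param onset Stimulus-onset sample used to build `times` when not
#'   given (default 1: epoch starts at onset).
#' @param condition,subject,age Optional metadata (condition label,
#'   subject id, age in weeks).
#' @return Object of class `trial_set`.
#' @export
trial_set <- function(trials, fs, times = NULL, onset = 1L,
                      condition = NA_character_, subject = NA_character_,
                      age = NA_real_) {
  stopifnot(is.list(trials), length(trials) >= 1, fs > 0)
  d <- dim(trials[[1]])
  ok <- vapply(trials, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("all trials must share the same shape")
  if (is.null(times))
    times <- (seq_len(d[2]) - onset) / fs * 1000
  stopifnot(length(times) == d[2])
  structure(list(trials = trials, fs = fs, times = times,
                 condition = condition, subject = subject, age = age),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials of %d x %d @ %g Hz\n",
              length(x$trials), nrow(x$trials[[1]]),
              ncol(x$trials[[1]]), x$fs))
  invisible(x)
}

#' Baseline correction, average reference and GFP normalization
#'
#' Per trial: (1) subtract from each channel its mean over the baseline
#' window; (2) re-reference to the across-channel average at each time
#' point; (3) normalize each time point by the global field power (GFP),
#' the across-channel standard deviation at that instant.  GFP values
#' below an epsilon floor are clamped (and counted) to avoid division by
#' ~zero.  The result is scale-invariant: scaling a trial leaves it
#' unchanged.
#'
#' @param ts A `trial_set`.
#' @param baseline_window Length-2 numeric, baseline window in ms
#'   (inclusive); default everything at or before 0 ms.
#' @param gfp_floor Relative epsilon floor for the GFP (default 1e-10 of
#'   the largest GFP in the trial).
#' @return The preprocessed `trial_set`, with attribute `n_gfp_floored`.
#' @export
preprocess_trials <- function(ts, baseline_window = NULL,
                              gfp_floor = 1e-10) {
  stopifnot(inherits(ts, "trial_set"))
  if (is.null(baseline_window))
    baseline_window <- c(min(ts$times), 0)
  sel <- ts$times >= baseline_window[1] & ts$times <= baseline_window[2]
  if (!any(sel)) stop("baseline window outside the epoch")
  floored <- 0L
  ts$trials <- lapply(ts$trials, function(m) {
    m <- m - rowMeans(m[, sel, drop = FALSE])
    m <- sweep(m, 2, colMeans(m))
    gfp <- apply(m, 2, stats::sd)
    floor_val <- gfp_floor * max(gfp, 1e-300)
    low <- gfp < floor_val
    floored <<- floored + sum(low)
    gfp[low] <- floor_val
    sweep(m, 2, gfp, `/`)
  })
  attr(ts, "n_gfp_floored") <- floored
  ts
}

#' Event-related potential with SEM
#'
#' Averages each trial over a channel cluster, then across trials,
#' returning the mean waveform with its per-timepoint standard error of
#' the mean.  Subject-level curves can be averaged again into a grand
#' average with across-subject SEM via [grand_average()].
#'
#' @param ts A `trial_set` with at least 2 trials.
#' @param channel_cluster Integer indices of the channels to average
#'   (nonempty).
#' @return List with `mean`, `sem` (numeric vectors over time), `n`
#'   (number of trials) and `times`.
#' @export
erp <- function(ts, channel_cluster) {
  stopifnot(inherits(ts, "trial_set"), length(ts$trials) >= 2)
  if (length(channel_cluster) == 0L) stop("empty channel cluster")
  curves <- vapply(ts$trials, function(m)
    colMeans(m[channel_cluster, , drop = FALSE]),
    numeric(ncol(ts$trials[[1]])))
  n <- length(ts$trials)
  list(mean = rowMeans(curves),
       sem = apply(curves, 1, stats::sd) / sqrt(n),
       n = n, times = ts$times)
}

#' Grand average across subject-level ERP curves
#'
#' @param erps List of [erp()] results with common time axes.
#' @return List with `mean`, `sem` (across subjects), `n`, `times`.
#' @export
grand_average <- function(erps) {
  stopifnot(length(erps) >= 2)
  curves <- vapply(erps, `[[`, numeric(length(erps[[1]]$mean)), "mean")
  list(mean = rowMeans(curves),
       sem = apply(curves, 1, stats::sd) / sqrt(length(erps)),
       n = length(erps), times = erps[[1]]$times)
}

#' Between-trial variability in a time window
#'
#' At each time point in the window, each trial is represented by its
#' across-channel vector; the distance between two trials is one minus
#' the Pearson correlation of those vectors.  Distances are averaged over
#' all unordered trial pairs, then over the window, giving one score per
#' trial set (subject).  Pairs with a constant vector (undefined
#' correlation) are skipped and counted in attribute `n_skipped_pairs`.
#'
#' @param ts A `trial_set` with at least 3 trials.
#' @param window_ms Length-2 numeric window in ms (default
#'   `c(400, 600)`, the P400 neighborhood).
#' @return Scalar variability score with attribute `n_skipped_pairs`.
#' @export
between_trial_variability <- function(ts, window_ms = c(400, 600)) {
  stopifnot(inherits(ts, "trial_set"), length(ts$trials) >= 3)
  sel <- which(ts$times >= window_ms[1] & ts$times <= window_ms[2])
  if (length(sel) == 0L) stop("variability window outside the epoch")
  n <- length(ts$trials)
  skipped <- 0L
  t_means <- numeric(length(sel))
  for (w in seq_along(sel)) {
    j <- sel[w]
    V <- vapply(ts$trials, function(m) m[, j], numeric(nrow(ts$trials[[1]])))
    dists <- c()
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      r <- safe_cor(V[, a], V[, b])
      if (is.na(r)) skipped <- skipped + 1L
      else dists <- c(dists, 1 - r)
    }
    t_means[w] <- if (length(dists)) mean(dists) else NA_real_
  }
  out <- mean(t_means, na.rm = TRUE)
  attr(out, "n_skipped_pairs") <- skipped
  out
}

#' Z-score subject scores across a cohort
#'
#' The reference population is the full set of scores passed in (all
#' analyzed subjects pooled across groups).
#'
#' @param scores Numeric vector of per-subject scores.
#' @return Z-scored vector.
#' @export
zscore_cohort <- function(scores) {
  (scores - mean(scores)) / stats::sd(scores)
}

#' Compare two groups of subject scores
#'
#' Two-sided Wilcoxon rank-sum test for equality of medians.
#'
#' @param scores_a,scores_b Nonempty numeric vectors.
#' @return List with `statistic` (rank-sum W) and `p.value`.
#' @export
compare_groups <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) > 0, length(scores_b) > 0)
  wt <- stats::wilcox.test(scores_a, scores_b, exact = FALSE,
                           correct = TRUE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Window-mean condition contrast F statistic
#'
#' Per subject, the contrast is the mean over the window of the
#' difference between two condition ERPs (cluster-averaged).  A one-sample
#' test across subjects of mean zero yields `F = t^2` with `(1, n - 1)`
#' degrees of freedom; larger F means a more reliably detected effect.
#'
#' @param contrasts Numeric vector of per-subject window-mean contrasts.
#' @return List with `F`, `df`, `p.value`.
#' @export
contrast_f_test <- function(contrasts) {
  n <- length(contrasts)
  stopifnot(n >= 2)
  tt <- stats::t.test(contrasts)
  Fv <- unname(tt$statistic)^2
  list(F = Fv, df = c(1, n - 1),
       p.value = stats::pf(Fv, 1, n - 1, lower.tail = FALSE))
}
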