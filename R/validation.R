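#' Paired ERP pipeline comparison on a synthetic cohort
#'
#' Runs the two repair pipelines the package is built to compare on the
#' same corrupted cohort and extracts the downstream ERP statistics:
#'
#' * **completion**: every trial is repaired by blockwise low-rank
#'   completion; the trial is retained when the fraction of entries that
#'   remain corrupted after completion (infeasible lines) is at most
#'   `trial_reject_frac`; channels still corrupted in a retained trial
#'   are then rebuilt by spherical-spline interpolation so no artifact
#'   values leak into the averages.
#' * **spline**: the conventional pipeline; a trial is retained when its
#'   raw corrupted fraction is at most `trial_reject_frac`, and every
#'   channel containing an artifact is rebuilt entirely by
#'   spherical-spline interpolation.
#'
#' Retained trials are baseline-corrected, average-referenced and
#' GFP-normalized; cluster ERPs are averaged per subject and condition;
#' the per-subject window-mean contrast between the two conditions is
#' tested across subjects ([contrast_f_test()]); and the grand-average
#' SEM and peak latency are measured in the contrast window.
#'
#' @param coh A `cohort` from [generate_trialset()].
#' @param rank Maximum completion rank per trial.  The rank actually used
#'   for a trial is adapted to its corruption level -- heavily corrupted
#'   trials are completed at lower rank so the observed entries still
#'   overdetermine the factor model (the fixed-rank mode remains
#'   available through [repair_recording()]).
#' @param contrast_window Window (ms) for the condition contrast
#'   (default `c(250, 450)`).
#' @param baseline_window Baseline window (ms) for
#'   [preprocess_trials()].
#' @param trial_reject_frac Trial rejection fraction (default 0.5).
#' @param mont Montage for the spline steps (default
#'   [ideal_montage()] of the cohort's channel count).
#' @return List with one element per pipeline, each carrying `retained`
#'   (total retained trials), `F`, `p.value` (window-contrast test),
#'   `sem` (mean grand-average SEM in the window), `peak_ms`
#'   (grand-average peak latency), and `erps` (per-subject ERP lists).
#' @export
compare_erp_pipelines <- function(coh, rank = 12,
                                  contrast_window = c(250, 450),
                                  baseline_window = c(-200, 0),
                                  trial_reject_frac = 0.5,
                                  mont = NULL) {
  stopifnot(inherits(coh, "cohort"))
  sp <- coh$spec
  C <- sp$C
  if (is.null(mont)) mont <- ideal_montage(C)
  cfg <- repair_config(block_size = sp$trial_len, rank = rank,
                       trial_reject_frac = trial_reject_frac)
  # repair and select trials under both pipelines
  fixed <- list()
  retained <- c(completion = 0L, spline = 0L)
  for (pipe in c("completion", "spline")) {
    fixed[[pipe]] <- lapply(coh$subjects, function(subj) {
      out_s <- list()
      for (cond in sp$conditions) {
        kept <- list()
        for (i in seq_along(subj$trials[[cond]]$trials)) {
          res <- repair_trial(subj$trials[[cond]]$trials[[i]],
                              subj$masks[[cond]][[i]], pipe, cfg, sp$fs,
                              mont, trial_reject_frac)
          if (!is.null(res)) kept[[length(kept) + 1L]] <- res
        }
        retained[pipe] <<- retained[pipe] + length(kept)
        out_s[[cond]] <- kept
      }
      out_s
    })
  }
  # subjects with too few usable trials under either pipeline are
  # excluded from the ERP comparison (but still counted in retention)
  usable <- vapply(seq_along(coh$subjects), function(s)
    all(vapply(c("completion", "spline"), function(p)
      all(lengths(fixed[[p]][[s]]) >= 2), logical(1))), logical(1))
  if (sum(usable) < 2)
    stop("fewer than 2 subjects with enough retained trials in both pipelines")
  out <- list()
  for (pipe in c("completion", "spline")) {
    erps_all <- lapply(which(usable), function(s) {
      lapply(fixed[[pipe]][[s]], function(kept) {
        ts <- trial_set(kept, sp$fs, onset = sp$trial_onset)
        ts <- preprocess_trials(ts, baseline_window = baseline_window)
        erp(ts, coh$cluster)
      })
    })
    win <- function(e) which(e$times >= contrast_window[1] &
                               e$times <= contrast_window[2])
    contr <- vapply(erps_all, function(e)
      mean(e[[sp$conditions[1]]]$mean[win(e[[sp$conditions[1]]])] -
             e[[sp$conditions[2]]]$mean[win(e[[sp$conditions[2]]])]),
      numeric(1))
    ga <- grand_average(lapply(erps_all, `[[`, sp$conditions[1]))
    wsel <- win(ga)
    ft <- contrast_f_test(contr)
    # peak latency on a 20 ms smoothed curve, standard for ERP latencies
    smoothed <- moving_mean(ga$mean, max(1L, round(0.02 * sp$fs)))
    out[[pipe]] <- list(
      retained = unname(retained[pipe]), F = ft$F, p.value = ft$p.value,
      sem = mean(ga$sem[wsel]),
      peak_ms = ga$times[wsel][which.max(abs(smoothed[wsel]))],
      n_subjects = sum(usable), erps = erps_all)
  }
  out
}

# repair one trial under the given pipeline; NULL when the trial is
# rejected. Retained trials are guaranteed artifact-free.
repair_trial <- function(trial, mask, pipe, cfg, fs, mont,
                         trial_reject_frac) {
  C <- nrow(trial)
  if (pipe == "completion") {
    # rank adapted to the corruption level: keep the observed entries
    # comfortably above the factor-model degrees of freedom, without
    # truncating so hard that genuine evoked components are dropped
    r_adapt <- max(1L, min(cfg$rank,
                           floor(sum(mask) / (1.2 * (C + ncol(trial))))))
    cfg$rank <- r_adapt
    rr <- repair_recording(recording(trial, fs, mask = mask), cfg,
                           reject = FALSE)
    post <- rr$recording$mask
    if (mean(!post) > trial_reject_frac) return(NULL)
    dat <- rr$recording$data
    bad_ch <- which(rowSums(!post) > 0L)
    if (length(bad_ch) > 0L) {
      if (length(bad_ch) > C - 4L) return(NULL)
      dat <- spline_repair_block(masked_matrix(dat, post), mont)
    }
    dat
  } else {
    if (mean(!mask) > trial_reject_frac) return(NULL)
    bad_ch <- which(rowSums(!mask) > 0L)
    if (length(bad_ch) == 0L) return(trial)
    if (length(bad_ch) > C - 4L) return(NULL)
    spline_repair_block(masked_matrix(trial, mask), mont)
  }
}
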