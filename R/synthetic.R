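#' Specification for the synthetic-data generator
#'
#' Collects every knob of the seeded generator used to test the repair
#' method: dimensions, latent low-rank signal structure, sensor and line
#' noise, bursty artifact-mask statistics, and the trial/cohort layout
#' for the downstream analyses.  Everything downstream is a pure function
#' of `(spec, seed)`.
#'
#' Defaults emulate the study conditions of a high-density infant EEG
#' setting: 128 channels at 250 Hz, a rank-8 latent signal mixing 4-12 Hz
#' oscillations with band-limited smoothed noise at ~20 uV scale, a few
#' uV of sensor noise, and artifact masks dominated by channel bursts so
#' that block-severity distributions come out right-skewed.
#'
#' @param C Channels. @param T_samples Total samples.
#' @param fs Sampling rate (Hz).
#' @param latent_rank Rank of the noiseless signal (`<= C`).
#' @param osc_band Frequency band (Hz) for oscillatory sources.
#' @param phase_drift SD of the per-sample random phase drift (radians).
#' @param smooth_width Moving-average width (samples) of smoothed-noise
#'   sources.
#' @param signal_amp Mixing amplitude scale (uV).
#' @param noise_sd Sensor noise SD (uV).
#' @param line_amp Amplitude of a common power-line component (uV); when
#'   positive the line sinusoid replaces the last latent source so the
#'   noiseless rank stays `latent_rank`.
#' @param line_freq Line frequency (Hz, default 50).
#' @param speckle_rate Uniform corruption probability per entry.
#' @param chan_burst_rate Per-channel burst-start probability per sample.
#' @param chan_burst_mean Mean single-channel burst duration (samples,
#'   geometric).
#' @param global_burst_rate All-channel burst-start probability per
#'   sample.
#' @param global_burst_mean Mean all-channel burst duration (samples).
#' @param multi_burst_rate Start probability per sample of movement-like
#'   bursts hitting a random subset of channels; these produce the
#'   severe-but-completable blocks (tens of percent corrupted) that
#'   populate the top severity class.
#' @param multi_burst_mean Mean multichannel burst duration (samples).
#' @param multi_burst_coverage Range of the channel fraction covered by a
#'   multichannel burst.
#' @param artifact_amp Amplitude (uV) of the junk waveform written into
#'   corrupted entries by [corrupt_recording()].
#' @param n_trials Trials per subject and condition.
#' @param trial_len Samples per peristimulus trial.
#' @param trial_onset Stimulus-onset sample within a trial.
#' @param conditions Two condition labels; the first carries the evoked
#'   effect.
#' @param effect_window_ms Window of the condition effect (ms).
#' @param effect_size Amplitude of the condition-specific evoked bump in
#'   normalized field units.
#' @param effect_sigma_ms Gaussian SD (ms) of the evoked bump envelope;
#'   sharp enough that the grand-average peak latency is well defined.
#' @param cluster_size Channels in the evoked spatial cluster.
#' @param group_btv Named per-group target between-trial distances
#'   (`1 - r`) inside the variability window; the default 2:1 ratio
#'   emulates the developmental increase of event-related variability.
#' @param n_subjects Subjects per group.
#' @param group_ages Named list of age ranges (weeks) per group.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(C = 128, T_samples = 15000, fs = 250,
                           latent_rank = 8, osc_band = c(4, 12),
                           phase_drift = 0.05, smooth_width = 25,
                           signal_amp = 20, noise_sd = 6,
                           line_amp = 0, line_freq = 50,
                           speckle_rate = 1e-6,
                           chan_burst_rate = 1e-6, chan_burst_mean = 50,
                           global_burst_rate = 1e-4, global_burst_mean = 100,
                           multi_burst_rate = 2e-3, multi_burst_mean = 100,
                           multi_burst_coverage = c(0.02, 0.95),
                           artifact_amp = 400,
                           n_trials = 20, trial_len = 250, trial_onset = 51,
                           conditions = c("left", "right"),
                           effect_window_ms = c(250, 450),
                           effect_size = 2.5, effect_sigma_ms = 35,
                           cluster_size = 8,
                           group_btv = c(young = 0.3, older = 0.6),
                           n_subjects = 20,
                           group_ages = list(young = c(5, 12),
                                             older = c(16, 24))) {
  stopifnot(latent_rank >= 1, latent_rank <= C,
            speckle_rate >= 0, chan_burst_rate >= 0, global_burst_rate >= 0,
            all(group_btv > 0), all(group_btv < 1),
            length(conditions) == 2)
  structure(as.list(environment()), class = "generator_spec")
}

# r latent source time courses: drifting-phase oscillations + smoothed noise
make_sources <- function(spec, T_len) {
  r <- spec$latent_rank
  n_osc <- ceiling(r / 2)
  src <- matrix(0, r, T_len)
  tt <- seq_len(T_len) / spec$fs
  for (k in seq_len(n_osc)) {
    f <- stats::runif(1, spec$osc_band[1], spec$osc_band[2])
    drift <- cumsum(stats::rnorm(T_len, 0, spec$phase_drift))
    src[k, ] <- sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi) + drift)
  }
  if (r > n_osc) for (k in (n_osc + 1):r) {
    x <- stats::rnorm(T_len + 2 * spec$smooth_width)
    x <- moving_mean(x, spec$smooth_width)
    src[k, ] <- x[spec$smooth_width + seq_len(T_len)]
  }
  # unit-variance sources
  src / pmax(apply(src, 1, stats::sd), 1e-12)
}

#' Generate a low-rank multichannel recording
#'
#' `data = mixing (C x r) . sources (r x T) + sensor noise`, with
#' oscillatory and smoothed-noise latent sources.  When
#' `spec$line_amp > 0`, the last latent source is a common power-line
#' sinusoid, so the numerical rank of the noiseless part always equals
#' `spec$latent_rank`.
#'
#' @param spec A `generator_spec`.
#' @param seed Integer seed.
#' @return List with `recording` (a [recording()], mask fully observed)
#'   and `truth` (the noiseless C x T signal matrix).
#' @export
generate_recording <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  withr_seed(seed)
  C <- spec$C; T_len <- spec$T_samples
  src <- make_sources(spec, T_len)
  mix <- matrix(stats::rnorm(C * spec$latent_rank, sd = spec$signal_amp),
                C, spec$latent_rank)
  if (spec$line_amp > 0) {
    tt <- seq_len(T_len) / spec$fs
    src[spec$latent_rank, ] <- sin(2 * pi * spec$line_freq * tt)
    mix[, spec$latent_rank] <-
      spec$line_amp * (0.5 + abs(stats::rnorm(C, sd = 0.5)))
  }
  truth <- mix %*% src
  data <- truth + matrix(stats::rnorm(C * T_len, sd = spec$noise_sd),
                         C, T_len)
  list(recording = recording(data, spec$fs), truth = truth)
}

#' Generate a bursty artifact mask
#'
#' Union of bursty corruption processes: uniform speckle, single-channel
#' bursts with geometric durations, movement-like bursts covering a
#' random subset of channels, and all-channel bursts.  With
#' burst-dominated settings the distribution of block severities is
#' right-skewed with a heavy tail reaching tens of percent, as bursty
#' artifacts produce in real recordings.
#'
#' @param spec A `generator_spec`.
#' @param seed Integer seed.
#' @param C,T_samples Optional dimension overrides (default from `spec`).
#' @return Logical C x T matrix, `TRUE` = observed; attribute `severity`
#'   carries the realized corruption percentage.
#' @export
generate_mask <- function(spec, seed = 1, C = spec$C,
                          T_samples = spec$T_samples) {
  stopifnot(inherits(spec, "generator_spec"))
  withr_seed(seed)
  bad <- matrix(stats::runif(C * T_samples) < spec$speckle_rate,
                C, T_samples)
  if (spec$chan_burst_rate > 0) {
    for (i in seq_len(C)) {
      starts <- which(stats::runif(T_samples) < spec$chan_burst_rate)
      for (s in starts) {
        len <- 1L + stats::rgeom(1, 1 / spec$chan_burst_mean)
        bad[i, s:min(T_samples, s + len - 1L)] <- TRUE
      }
    }
  }
  if (spec$multi_burst_rate > 0) {
    starts <- which(stats::runif(T_samples) < spec$multi_burst_rate)
    for (s in starts) {
      len <- 1L + stats::rgeom(1, 1 / spec$multi_burst_mean)
      # most events touch few channels, rare ones are near-global:
      # left-skewed coverage keeps block severities power-law-like
      cov <- spec$multi_burst_coverage[1] +
        diff(spec$multi_burst_coverage) * stats::rbeta(1, 0.5, 1.5)
      ch <- sample.int(C, max(1L, round(cov * C)))
      bad[ch, s:min(T_samples, s + len - 1L)] <- TRUE
    }
  }
  if (spec$global_burst_rate > 0) {
    starts <- which(stats::runif(T_samples) < spec$global_burst_rate)
    for (s in starts) {
      len <- 1L + stats::rgeom(1, 1 / spec$global_burst_mean)
      bad[, s:min(T_samples, s + len - 1L)] <- TRUE
    }
  }
  mask <- !bad
  attr(mask, "severity") <- severity(mask)
  mask
}

#' Write artifact waveforms into the corrupted entries of a recording
#'
#' Corrupted entries of real recordings do not hold clean signal -- they
#' hold high-amplitude junk.  This overlays a large slow oscillation plus
#' noise (amplitude `spec$artifact_amp`) on every corrupted entry and
#' installs the mask, so that order-of-operations effects (e.g. filtering
#' smearing artifacts into good samples) are reproduced honestly.
#'
#' @param rec A `recording`.
#' @param mask Logical observed-mask (`TRUE` = observed).
#' @param spec A `generator_spec` (for `artifact_amp` and `fs`).
#' @param seed Integer seed.
#' @return The corrupted `recording` with `mask` installed.
#' @export
corrupt_recording <- function(rec, mask, spec, seed = 1) {
  stopifnot(inherits(rec, "recording"), identical(dim(mask), dim(rec$data)))
  withr_seed(seed)
  C <- nrow(rec$data); T_len <- ncol(rec$data)
  tt <- seq_len(T_len) / rec$fs
  junk <- outer(stats::runif(C, 0.5, 1),
                sin(2 * pi * stats::runif(1, 1, 3) * tt)) *
    spec$artifact_amp +
    matrix(stats::rnorm(C * T_len, sd = spec$artifact_amp / 4), C, T_len)
  rec$data[!mask] <- junk[!mask]
  rec$mask <- mask
  rec
}

# one subject's trials for one condition; d = target between-trial distance
make_subject_trials <- function(spec, d, with_effect, cluster) {
  C <- spec$C; T_len <- spec$trial_len
  tt_ms <- (seq_len(T_len) - spec$trial_onset) / spec$fs * 1000
  # shared evoked trajectory, normalized per timepoint across channels
  s <- normalize_field(t(make_sources(spec, T_len)[
    seq_len(min(4, spec$latent_rank)), , drop = FALSE]) %*%
      matrix(stats::rnorm(min(4, spec$latent_rank) * C), ncol = C))
  env <- exp(-((tt_ms - mean(spec$effect_window_ms)) /
                 spec$effect_sigma_ms)^2 / 2)
  pattern <- numeric(C)
  pattern[cluster] <- 1
  trials <- lapply(seq_len(spec$n_trials), function(i) {
    eps <- normalize_field(t(make_sources(spec, T_len)[
      seq_len(min(4, spec$latent_rank)), , drop = FALSE]) %*%
        matrix(stats::rnorm(min(4, spec$latent_rank) * C), ncol = C))
    v <- sqrt(1 - d) * s + sqrt(d) * eps  # T x C
    if (with_effect)
      v <- v + spec$effect_size * outer(env, pattern)
    t(v) * spec$signal_amp  # C x T
  })
  trials
}

# zero-mean, unit-SD across channels at each timepoint (rows = time)
normalize_field <- function(m) {
  m <- m - rowMeans(m)
  sdv <- pmax(sqrt(rowSums(m^2) / (ncol(m) - 1)), 1e-12)
  m / sdv
}

#' Generate a synthetic two-group, two-condition trial cohort
#'
#' Each subject receives `n_trials` peristimulus trials per condition:
#' ongoing low-rank activity around a shared evoked trajectory, with the
#' between-trial distance (one minus the expected pairwise trial
#' correlation) set to the subject's group target `spec$group_btv`, and a
#' condition-specific evoked bump on a channel cluster inside the effect
#' window for the first condition.  Bursty artifact masks are applied per
#' trial and junk written into corrupted entries; the clean trials are
#' retained as ground truth.
#'
#' @param spec A `generator_spec`.
#' @param seed Integer seed.
#' @return Object of class `cohort`: list with `subjects` (each carrying
#'   `subject`, `group`, `age`, and per-condition `trials`
#'   ([trial_set()], corrupted), `masks`, `truth`), plus `cluster`
#'   (evoked channel indices) and `spec`.
#' @export
generate_trialset <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "generator_spec"))
  withr_seed(seed)
  groups <- names(spec$group_btv)
  cluster <- seq_len(min(spec$cluster_size, spec$C))
  subjects <- list()
  sid <- 0L
  for (g in groups) {
    for (k in seq_len(spec$n_subjects)) {
      sid <- sid + 1L
      age <- stats::runif(1, spec$group_ages[[g]][1], spec$group_ages[[g]][2])
      subj <- list(subject = sprintf("S%02d", sid), group = g, age = age)
      for (cond in spec$conditions) {
        clean <- make_subject_trials(spec, spec$group_btv[[g]],
                                     with_effect = cond == spec$conditions[1],
                                     cluster = cluster)
        masks <- lapply(seq_along(clean), function(i)
          generate_mask(spec, seed = seed + 1000L * sid +
                          10L * i + match(cond, spec$conditions),
                        C = spec$C, T_samples = spec$trial_len))
        corrupted <- lapply(seq_along(clean), function(i) {
          rec <- corrupt_recording(
            recording(clean[[i]], spec$fs), masks[[i]], spec,
            seed = seed + 1000L * sid + 10L * i + 7L)
          rec$data
        })
        subj$trials[[cond]] <- trial_set(corrupted, spec$fs,
                                         onset = spec$trial_onset,
                                         condition = cond,
                                         subject = subj$subject, age = age)
        subj$masks[[cond]] <- masks
        subj$truth[[cond]] <- clean
      }
      subjects[[sid]] <- subj
    }
  }
  structure(list(subjects = subjects, cluster = cluster, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d conditions x %d trials\n",
              length(x$subjects), length(x$spec$conditions),
              x$spec$n_trials))
  invisible(x)
}
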