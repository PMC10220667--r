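test_that("noiseless recordings have exactly the configured rank", {
  sp <- generator_spec(C = 20, T_samples = 400, latent_rank = 3,
                       noise_sd = 0)
  g <- generate_recording(sp, seed = 1)
  sv <- svd(g$recording$data)$d
  expect_lt(sv[4] / sv[3], 1e-10)
  expect_equal(g$recording$data, g$truth)
  # with line noise the common component is part of the latent rank
  spl <- generator_spec(C = 20, T_samples = 400, latent_rank = 3,
                        noise_sd = 0, line_amp = 10)
  gl <- generate_recording(spl, seed = 1)
  expect_lt(svd(gl$truth)$d[4] / svd(gl$truth)$d[3], 1e-10)
})

test_that("generation is a pure function of (spec, seed)", {
  sp <- generator_spec(C = 10, T_samples = 300, latent_rank = 2)
  expect_identical(generate_recording(sp, seed = 7),
                   generate_recording(sp, seed = 7))
  expect_identical(generate_mask(sp, seed = 7), generate_mask(sp, seed = 7))
  expect_false(identical(generate_mask(sp, seed = 7),
                         generate_mask(sp, seed = 8)))
})

test_that("oscillatory sources peak at frequencies inside the band", {
  sp <- generator_spec(C = 4, T_samples = 2048, latent_rank = 2,
                       noise_sd = 0, osc_band = c(8, 10),
                       phase_drift = 0.01)
  g <- generate_recording(sp, seed = 3)
  spec_est <- spec.pgram(ts(g$recording$data[1, ], frequency = 250),
                         plot = FALSE, spans = 5)
  f_peak <- spec_est$freq[which.max(spec_est$spec)]
  expect_gt(f_peak, 6)
  expect_lt(f_peak, 12)
})

test_that("mask processes follow their configured rates", {
  sp0 <- generator_spec(C = 10, T_samples = 500, speckle_rate = 0,
                        chan_burst_rate = 0, global_burst_rate = 0,
                        multi_burst_rate = 0)
  expect_true(all(generate_mask(sp0, seed = 1)))
  # speckle only: bad fraction within 3 binomial SDs of the rate
  p <- 0.02
  sp1 <- generator_spec(C = 50, T_samples = 2000, speckle_rate = p,
                        chan_burst_rate = 0, global_burst_rate = 0,
                        multi_burst_rate = 0)
  m <- generate_mask(sp1, seed = 2)
  n <- length(m)
  expect_lt(abs(mean(!m) - p), 3 * sqrt(p * (1 - p) / n))
  # all-channel bursts corrupt entire columns
  sp2 <- generator_spec(C = 10, T_samples = 2000, speckle_rate = 0,
                        chan_burst_rate = 0, multi_burst_rate = 0,
                        global_burst_rate = 5e-3)
  m2 <- generate_mask(sp2, seed = 3)
  bad_cols <- colSums(!m2)
  expect_true(all(bad_cols %in% c(0L, 10L)))
  expect_gt(sum(bad_cols == 10L), 0)
})

test_that("corrupt_recording writes junk only into corrupted entries", {
  sp <- generator_spec(C = 8, T_samples = 200, latent_rank = 2)
  g <- generate_recording(sp, seed = 4)
  mask <- generate_mask(sp, seed = 5)
  rec <- corrupt_recording(g$recording, mask, sp, seed = 6)
  expect_identical(rec$data[mask], g$recording$data[mask])
  expect_identical(rec$mask, mask)
  if (any(!mask))
    expect_gt(max(abs(rec$data[!mask])), 3 * max(abs(g$recording$data)))
})

test_that("cohorts are reproducible and carry the group structure", {
  sp <- generator_spec(C = 12, T_samples = 100, trial_len = 100,
                       trial_onset = 21, n_subjects = 2, n_trials = 4)
  coh <- generate_trialset(sp, seed = 5)
  coh2 <- generate_trialset(sp, seed = 5)
  expect_identical(coh$subjects[[1]]$trials[["left"]]$trials,
                   coh2$subjects[[1]]$trials[["left"]]$trials)
  expect_equal(length(coh$subjects), 4)
  groups <- vapply(coh$subjects, `[[`, character(1), "group")
  expect_equal(as.vector(table(groups)), c(2L, 2L))
  ages <- vapply(coh$subjects, `[[`, numeric(1), "age")
  expect_true(all(ages[groups == "young"] <= 12))
  expect_true(all(ages[groups == "older"] >= 16))
})

test_that("the evoked effect is confined to the first condition", {
  sp <- generator_spec(C = 16, T_samples = 150, trial_len = 150,
                       trial_onset = 26, n_subjects = 2, n_trials = 12,
                       effect_size = 3, cluster_size = 4,
                       speckle_rate = 0, chan_burst_rate = 0,
                       global_burst_rate = 0, multi_burst_rate = 0)
  coh <- generate_trialset(sp, seed = 6)
  win_mean <- function(subj, cond) {
    ts <- trial_set(subj$truth[[cond]], sp$fs, onset = sp$trial_onset)
    e <- erp(ts, coh$cluster)
    mean(e$mean[e$times >= 250 & e$times <= 450])
  }
  effect <- mean(sapply(coh$subjects, win_mean, cond = "left")) -
    mean(sapply(coh$subjects, win_mean, cond = "right"))
  expect_gt(effect, 1)
  # zero effect size makes the conditions statistically alike
  sp0 <- generator_spec(C = 16, T_samples = 150, trial_len = 150,
                        trial_onset = 26, n_subjects = 2, n_trials = 12,
                        effect_size = 0, cluster_size = 4,
                        speckle_rate = 0, chan_burst_rate = 0,
                        global_burst_rate = 0, multi_burst_rate = 0)
  coh0 <- generate_trialset(sp0, seed = 6)
  effect0 <- mean(sapply(coh0$subjects, win_mean, cond = "left")) -
    mean(sapply(coh0$subjects, win_mean, cond = "right"))
  expect_lt(abs(effect0), abs(effect) / 4)
})
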