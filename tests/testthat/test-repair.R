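test_that("artifact marking reproduces hand-computed threshold outcomes", {
  fs <- 250
  T_len <- 1000
  data <- matrix(0, 4, T_len)
  data[1, ] <- 7                      # constant channel: nothing marked
  data[2, 500:T_len] <- 300           # +300 uV step at sample 500
  set.seed(3)
  data[3, ] <- rnorm(T_len, sd = 5)   # white noise ...
  rec <- recording(data, fs)
  cfg <- repair_config()
  # place one sample of channel 3 at 12 global SDs (rule c), recomputed
  mu <- mean(rec$data); sdev <- sd(rec$data)
  rec$data[3, 700] <- mu + 12 * sdev
  bad <- mark_artifacts(rec, cfg)
  expect_false(any(bad[1, ]))
  # rule (a): the 300 uV jump marks its two flanking samples
  expect_true(bad[2, 499] && bad[2, 500])
  # rule (c): direct z-score against overall mean/SD
  z <- abs(rec$data - mean(rec$data)) / sd(rec$data)
  expect_true(bad[3, 700])
  expect_true(all(bad[3, which(z[3, ] > 10)]))
  # rule (b): sustained 200 uV deviation from the slow mean
  rec2 <- recording(matrix(0, 4, T_len), fs)
  rec2$data[4, 400:410] <- 200
  bad2 <- mark_artifacts(rec2, cfg)
  expect_true(any(bad2[4, 400:410]))
  expect_false(any(bad2[1:3, ]))
})

test_that("channel and timepoint rejection use strict fractions", {
  mask <- matrix(TRUE, 10, 100)
  mask[1, 1:71] <- FALSE  # 71% bad: rejected
  mask[2, 1:70] <- FALSE  # exactly 70%: kept (strict 'more than')
  expect_equal(reject_channels(mask, 0.70), 1L)
  tmask <- matrix(TRUE, 128, 10)
  tmask[1:97, 1] <- FALSE  # 97/128 = 75.8% of electrodes: rejected
  tmask[1:96, 2] <- FALSE  # exactly 75%: kept
  expect_equal(reject_timepoints(tmask, 0.75), 1L)
  expect_length(reject_channels(matrix(TRUE, 5, 5)), 0)
  expect_length(reject_timepoints(matrix(TRUE, 5, 5)), 0)
  # random mask agrees with independent counting
  set.seed(7)
  rmask <- matrix(runif(2000) > 0.3, 20, 100)
  expect_equal(reject_channels(rmask, 0.25),
               which(sapply(1:20, function(i) mean(!rmask[i, ]) > 0.25)))
})

test_that("epoching is exact and the remainder rule is applied", {
  rec <- recording(matrix(as.numeric(seq_len(3000)), 3, 1000), 250)
  blocks <- epoch_recording(rec, 120)
  expect_length(blocks, 9)
  widths <- vapply(blocks, function(b) ncol(b$values), integer(1))
  expect_equal(widths, c(rep(120L, 8), 40L))
  # remainder shorter than min_remainder merges into the previous block
  blocks2 <- epoch_recording(rec, 120, min_remainder = 50)
  expect_length(blocks2, 8)
  expect_equal(ncol(blocks2[[8]]$values), 160L)
  # single block when Tk = T
  expect_length(epoch_recording(rec, 1000), 1)
  # round trip is the identity
  reassembled <- matrix(NA_real_, 3, 1000)
  for (b in blocks) reassembled[, attr(b, "start"):attr(b, "end")] <- b$values
  expect_identical(reassembled, rec$data)
})

test_that("repair fills punched gaps in a low-rank recording", {
  sp <- generator_spec(C = 24, T_samples = 720, latent_rank = 4,
                       noise_sd = 0.5)
  g <- generate_recording(sp, seed = 5)
  mask <- uniform_mask(24, 720, 0.08)
  rec <- g$recording
  rec$mask <- mask
  out <- repair_recording(rec, repair_config(block_size = 120, rank = 4))
  hid <- !mask
  expect_gt(cor(out$recording$data[hid], g$truth[hid]), 0.9)
  expect_equal(nrow(out$report), 6)
  expect_true(all(out$report$status == "ok"))
  expect_true(all(out$recording$mask))
})

test_that("repair with replace_observed = FALSE keeps observed data bitwise", {
  sp <- generator_spec(C = 16, T_samples = 360, latent_rank = 3)
  g <- generate_recording(sp, seed = 9)
  rec <- g$recording
  rec$mask <- uniform_mask(16, 360, 0.05)
  cfg <- repair_config(block_size = 120, rank = 3, replace_observed = FALSE)
  out <- repair_recording(rec, cfg)
  expect_identical(out$recording$data[rec$mask], rec$data[rec$mask])
  # artifact-free recording passes through bit-for-bit
  clean <- g$recording
  out2 <- repair_recording(clean, cfg)
  expect_identical(out2$recording$data, clean$data)
})

test_that("blocks with all-missing lines are reported, not fatal", {
  sp <- generator_spec(C = 12, T_samples = 240, latent_rank = 3)
  g <- generate_recording(sp, seed = 13)
  rec <- g$recording
  rec$mask[5, 1:120] <- FALSE  # channel fully missing in block 1
  out <- repair_recording(rec, repair_config(block_size = 120, rank = 3),
                          reject = FALSE)
  expect_equal(out$report$n_infeasible_rows, c(1L, 0L))
  expect_true(all(out$report$status == "ok"))
  # the infeasible line was not overwritten by the model
  expect_identical(out$recording$data[5, 1:120], rec$data[5, 1:120])
  expect_true(all(!out$recording$mask[5, 1:120]))
})

test_that("band-pass is zero-phase with the expected frequency response", {
  fs <- 250
  tt <- seq_len(5 * fs) / fs
  rec50 <- recording(matrix(sin(2 * pi * 50 * tt), 1), fs)
  out50 <- bandpass_recording(rec50, 0.5, 20)
  mid <- 250:1000
  atten <- 20 * log10(sd(out50$data[1, mid]) / sd(rec50$data[1, mid]))
  expect_lt(atten, -20)
  rec10 <- recording(matrix(sin(2 * pi * 10 * tt), 1), fs)
  out10 <- bandpass_recording(rec10, 0.5, 20)
  expect_equal(sd(out10$data[1, mid]), sd(rec10$data[1, mid]),
               tolerance = 0.05)
  # zero in, zero out; invalid bands rejected
  expect_equal(bandpass_recording(recording(matrix(0, 2, 500), fs),
                                  0.5, 20)$data,
               matrix(0, 2, 500))
  expect_error(bandpass_recording(rec10, 20, 0.5), "invalid band")
  expect_error(bandpass_recording(rec10, 0.5, 200), "invalid band")
})

test_that("trial rejection keeps trials at exactly the threshold", {
  m_clean <- matrix(TRUE, 4, 10)
  m_half <- m_clean; m_half[1:2, ] <- FALSE            # exactly 50%
  m_51 <- m_clean; m_51[1:2, ] <- FALSE; m_51[3, 1:4] <- FALSE
  expect_equal(reject_trials(list(m_clean, m_half, m_51), 0.5), c(1L, 2L))
})

test_that("repair can only improve trial retention", {
  sp <- generator_spec(C = 16, T_samples = 240, latent_rank = 3,
                       multi_burst_rate = 2e-3)
  for (seed in 1:5) {
    g <- generate_recording(sp, seed = seed)
    rec <- g$recording
    rec$mask <- generate_mask(sp, seed = 100 + seed)
    out <- repair_recording(rec, repair_config(block_size = 80, rank = 3),
                            reject = FALSE)
    split_cols <- function(m) lapply(seq(1, 240, 80), function(s)
      m[, s:(s + 79)])
    before <- reject_trials(split_cols(rec$mask))
    after <- reject_trials(split_cols(out$recording$mask))
    expect_true(all(before %in% after))
  }
})

test_that("recording text round trip preserves data, labels and mask", {
  sp <- generator_spec(C = 6, T_samples = 50, latent_rank = 2)
  rec <- generate_recording(sp, seed = 2)$recording
  rec$mask[2, 5:9] <- FALSE
  path <- tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path, fs = 250)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_identical(back$mask, rec$mask)
  expect_identical(back$channels, rec$channels)
  unlink(c(path, paste0(path, ".mask")))
})

test_that("interval annotations translate to bad entries (0-based, half-open)", {
  rec <- recording(matrix(0, 3, 20), 250, channels = c("A", "B", "C"))
  ann <- data.frame(channel_label = c("B", "*"),
                    start_sample = c(0L, 10L), end_sample = c(3L, 12L))
  bad <- annotations_to_bad(rec, ann)
  expect_true(all(bad[2, 1:3]))
  expect_false(any(bad[c(1, 3), 1:3]))
  expect_true(all(bad[, 11:12]))
  expect_false(any(bad[, 13]))
  expect_error(annotations_to_bad(rec, data.frame(channel_label = "Z",
                                                  start_sample = 0,
                                                  end_sample = 1)),
               "unknown channel")
})
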