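test_that("RR intervals honor mean, CV and the regular-rhythm edge case", {
  cfg0 <- synth_ecg_config(duration = 10, mean_hr = 60, rr_cv = 0, seed = 1)
  rr0 <- generate_rr_intervals(cfg0)
  expect_true(all(rr0 == 1.0))
  expect_equal(stats::var(rr0), 0)

  cfg <- synth_ecg_config(duration = 10, mean_hr = 80, rr_cv = 0.05, seed = 9)
  rr <- generate_rr_intervals(cfg, n = 1000)
  expect_lt(abs(mean(rr) - 0.75) / 0.75, 0.02)
  expect_lt(abs(stats::sd(rr) / mean(rr) - 0.05), 0.01)
  expect_true(all(rr > 0.2))
})

test_that("regular 60 bpm minute contains exactly 60 beats 1 s apart", {
  cfg <- synth_ecg_config(duration = 60, mean_hr = 60, rr_cv = 0, seed = 5)
  ann <- generate_ecg(cfg)
  expect_equal(length(ann$record), 60 * 360)
  expect_equal(length(ann$truth), 60L)
  expect_equal(unique(diff(ann$truth$r_indices)), 360)
})

test_that("beat count equals the RR interval count and truth is valid", {
  for (seed in 1:5) {
    cfg <- synth_ecg_config(duration = 30, mean_hr = 75, rr_cv = 0.1,
                            premature_prob = 0.1, seed = seed)
    ann <- generate_ecg(cfg)
    rr <- generate_rr_intervals(cfg)
    expect_equal(length(ann$truth), length(rr))
    expect_true(all(diff(ann$truth$r_indices) > 0))
    expect_true(all(ann$truth$r_indices >= 0 &
                      ann$truth$r_indices < length(ann$record)))
  }
})

test_that("identical config and seed reproduce the signal bit for bit", {
  cfg <- synth_ecg_config(duration = 15, noise_white_sd = 0.05,
                          baseline_amp = 0.3, seed = 77)
  a <- generate_ecg(cfg)
  b <- generate_ecg(cfg)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth$r_indices, b$truth$r_indices)
})

test_that("noise-free signal at each truth index matches the analytic sum", {
  cfg <- synth_ecg_config(duration = 20, mean_hr = 60, rr_cv = 0, seed = 2)
  ann <- generate_ecg(cfg)
  rr <- generate_rr_intervals(cfg)
  beat_times <- rr[1] / 2 + c(0, cumsum(rr[-1]))
  t_truth <- ann$truth$r_indices / cfg$fs
  expected <- vapply(t_truth, analytic_beat_sum, numeric(1),
                     beat_times = beat_times,
                     wave_params = cfg$wave_params)
  got <- ann$record$samples[ann$truth$r_indices + 1]
  expect_equal(got, expected, tolerance = 1e-10)
  # Gaussian-sum cross-talk (mostly the T-wave tail) keeps the value near
  # the configured 1 mV R amplitude; the oracle puts it at ~1.011 mV
  expect_true(all(abs(got - 1.0) < 0.015))
})

test_that("add_noise is the identity when all amplitudes are zero", {
  ann <- clean_record()
  cfg <- synth_ecg_config(duration = 60, mean_hr = 75, rr_cv = 0.05,
                          seed = 101L)
  expect_identical(add_noise(ann, cfg)$record$samples, ann$record$samples)
})

test_that("white-noise variance and baseline spectral peak match config", {
  cfg_clean <- synth_ecg_config(duration = 60, seed = 8)
  clean <- generate_ecg(cfg_clean)

  cfg_white <- synth_ecg_config(duration = 60, noise_white_sd = 0.2, seed = 8)
  noisy <- add_noise(clean, cfg_white)
  resid <- noisy$record$samples - clean$record$samples
  expect_lt(abs(stats::var(resid) - 0.04) / 0.04, 0.05)
  expect_identical(noisy$truth$r_indices, clean$truth$r_indices)

  cfg_bw <- synth_ecg_config(duration = 60, baseline_amp = 0.5,
                             baseline_freq = 0.3, seed = 8)
  wander <- add_noise(clean, cfg_bw)$record$samples - clean$record$samples
  spec <- stats::spec.pgram(stats::ts(wander, frequency = 360),
                            plot = FALSE, taper = 0)
  expect_lt(abs(spec$freq[which.max(spec$spec)] - 0.3), 0.05)
})

test_that("tall-T and premature-beat regimes are expressible", {
  tall <- tall_t_record()
  # T amplitude >= 0.8x R present in the waveform: value ~0.8 mV at
  # +300 ms from each R peak
  idx <- tall$truth$r_indices[5] + round(0.3 * 360)
  expect_gt(tall$record$samples[idx + 1], 0.6)

  cfg <- synth_ecg_config(duration = 60, mean_hr = 75, rr_cv = 0,
                          premature_prob = 0.2, seed = 31)
  rr <- generate_rr_intervals(cfg)
  expect_true(any(abs(rr - 0.8 * 0.6) < 1e-9))   # shortened beats
  expect_true(any(abs(rr - 0.8 * 1.4) < 1e-9))   # compensatory pauses
})

test_that("configs that cannot yield a beat or resolve a wave are rejected", {
  expect_error(synth_ecg_config(duration = 0.2, mean_hr = 60), "one beat")
  expect_error(synth_ecg_config(duration = -1), "duration")
  expect_error(synth_ecg_config(rr_cv = -0.1), "rr_cv")
  expect_error(synth_ecg_config(fs = 20), "resolve")
})
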