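test_that("anti-alias design: passthrough at 1, cutoff 1/K, band behavior", {
  expect_equal(design_antialias_filter(1, 360)$kind, "passthrough")
  spec <- design_antialias_filter(6, 360)
  expect_equal(spec$normalized_cutoff, 1 / 6)  # 30 Hz at 360 Hz
  # frequency-response probe: flat at half the cutoff, deep at 1.5x
  H <- function(f, fs = 360) {
    abs(sum(spec$b * exp(-1i * 2 * pi * f / fs * (seq_along(spec$b) - 1))))
  }
  expect_gt(20 * log10(H(15)), -1)
  expect_lt(20 * log10(H(45)), -40)
  expect_error(design_antialias_filter(0), ">= 1")
})

test_that("decimation is the identity at factor 1 and scales rate/length", {
  ann <- clean_record()
  c1 <- decimate_by_factor(ann$record, 1)
  expect_identical(c1$samples, ann$record$samples)
  expect_equal(c1$fs_out, 360)
  c6 <- decimate_by_factor(ann$record, 6)
  expect_equal(c6$fs_out, 60)
  expect_equal(length(c6$samples), ceiling(length(ann$record) / 6))
})

test_that("a 5 Hz tone survives decimation by 6 with its amplitude intact", {
  fs <- 360
  t <- (0:3599) / fs
  x <- sin(2 * pi * 5 * t)
  comp <- decimate_by_factor(ecg_record(x, fs), 6)
  trans <- ceiling(length(comp$filter$b) / 6)
  interior <- comp$samples[(trans + 1):(length(comp$samples) - trans)]
  amp <- fitted_tone_amplitude(comp$samples, 60, 5)
  expect_lt(abs(amp - 1), 0.02)
  # and it is still a 5 Hz sine: compare against the analytic tone
  t6 <- (seq_along(comp$samples) - 1) / 60
  expect_lt(max(abs(interior - sin(2 * pi * 5 * t6)[(trans + 1):
                                     (length(comp$samples) - trans)])), 0.02)
})

test_that("decimation equals the literal convolve-then-subsample oracle", {
  set.seed(123)
  x <- rnorm(2000)
  rec <- ecg_record(x, 360)
  for (k in 1:8) {
    spec <- design_antialias_filter(k, 360)
    expect_equal(decimate_by_factor(rec, k)$samples,
                 brute_force_decimate(x, spec$b, k),
                 tolerance = 1e-9, label = paste("k =", k))
  }
})

test_that("aliasing band is suppressed and passband preserved after decimation", {
  fs <- 360
  t <- (0:7199) / fs
  for (k in c(4L, 6L)) {
    nyq_out <- fs / k / 2
    rec_hi <- ecg_record(sin(2 * pi * (1.5 * nyq_out) * t), fs)
    comp_hi <- decimate_by_factor(rec_hi, k)
    trans <- ceiling(length(comp_hi$filter$b) / k)
    interior <- comp_hi$samples[(trans + 1):(length(comp_hi$samples) - trans)]
    atten_db <- 20 * log10(sqrt(mean(interior^2)) / sqrt(0.5))
    expect_lt(atten_db, -40)

    rec_lo <- ecg_record(sin(2 * pi * (0.8 * nyq_out) * t), fs)
    comp_lo <- decimate_by_factor(rec_lo, k)
    amp <- fitted_tone_amplitude(comp_lo$samples, fs / k, 0.8 * nyq_out)
    expect_lt(abs(amp - 1), 0.02)
  }
})

test_that("B/K resampling hits the target rate and the 4.5x ratio", {
  ann <- clean_record()
  comp <- resample_b_over_k(ann$record, B = 390, K = 80)
  expect_equal(comp$fs_out, 80)
  expect_equal(comp$fs_in / comp$fs_out, 4.5)
  expect_equal(comp$method, "II")
  # identity configuration
  ident <- resample_b_over_k(ann$record, B = 360, K = 360)
  expect_equal(ident$samples, ann$record$samples, tolerance = 1e-12)
  expect_error(resample_b_over_k(ann$record, B = -1, K = 80), "> 0")
})

test_that("B/K resampling passes 10 Hz and rejects 45 Hz at K = 80", {
  fs <- 360
  t <- (0:7199) / fs
  c10 <- resample_b_over_k(ecg_record(sin(2 * pi * 10 * t), fs), 390, 80)
  amp <- fitted_tone_amplitude(c10$samples, 80, 10)
  expect_lt(abs(amp - 1), 0.02)
  c45 <- resample_b_over_k(ecg_record(sin(2 * pi * 45 * t), fs), 390, 80)
  edge <- 40L  # half a second at 80 Hz: clear of both stage transients
  interior <- c45$samples[(edge + 1):(length(c45$samples) - edge)]
  expect_lt(20 * log10(sqrt(mean(interior^2)) / sqrt(0.5)), -40)
})

test_that("linear prediction: exact cases and cold start", {
  const <- predict_error(rep(3, 50), order_m = 1, mode = "fixed",
                         coefficients = 1)
  expect_equal(const$error[-1], rep(0, 49))
  expect_equal(const$error[1], 3)

  ramp <- predict_error(as.numeric(0:49), order_m = 2, mode = "fixed",
                        coefficients = c(2, -1))
  expect_equal(ramp$error[-(1:2)], rep(0, 48))
  expect_equal(ramp$error[1:2], c(0, 1))

  expect_error(predict_error(1:5, order_m = 5), "smaller")
  expect_error(predict_error(1:5, order_m = 0), ">= 1")
})

test_that("adaptive prediction error concentrates energy inside the QRS", {
  ann <- clean_record()
  pred <- predict_error(ann$record, order_m = 4, mode = "lms_adaptive")
  e2 <- pred$error^2
  fs <- ann$record$fs
  qrs_mask <- logical(length(e2))
  for (r in ann$truth$r_indices) {
    lo <- max(1, r + 1 - round(0.06 * fs))
    hi <- min(length(e2), r + 1 + round(0.06 * fs))
    qrs_mask[lo:hi] <- TRUE
  }
  # skip the adaptation warm-up second
  warm <- seq_len(fs)
  qrs_mask[warm] <- NA
  inside <- mean(e2[which(qrs_mask)])
  outside <- mean(e2[which(!qrs_mask)])
  expect_gt(inside / outside, 5)
})

test_that("reconstruction restores length and band-limited content", {
  fs <- 360
  t <- (0:7199) / fs
  x <- sin(2 * pi * 5 * t)
  rec <- ecg_record(x, fs)
  for (k in 1:8) {
    comp <- decimate_by_factor(rec, k)
    xhat <- reconstruct(comp)
    expect_length(xhat, length(x))
    if (k == 1) expect_identical(xhat, comp$samples)
  }
  comp6 <- decimate_by_factor(rec, 6)
  expect_lt(compute_prd(x, reconstruct(comp6)), 2)
})

test_that("PRD: exact zero, hand value, scale invariance, guards", {
  x <- c(1, 0)
  expect_equal(compute_prd(x, x), 0)
  expect_equal(compute_prd(x, c(0, 0)), 100)
  set.seed(4)
  a <- rnorm(100)
  b <- a + rnorm(100, sd = 0.1)
  expect_equal(compute_prd(3 * a, 3 * b), compute_prd(a, b))
  expect_error(compute_prd(c(0, 0), c(1, 0)), "zero energy")
  expect_error(compute_prd(1:3, 1:4), "equal length")
})

test_that("BCR arithmetic", {
  expect_equal(compute_bcr(600, 11, 100, 11), 6)
  expect_equal(compute_bcr(100, 11, 100, 11), 1)
  expect_equal(compute_bcr(1000, 11, 250, 11), 4)
  expect_error(compute_bcr(0, 11, 10, 11), "positive")
})

test_that("max_factor applies the strict normalized-cutoff rule", {
  expect_equal(max_factor(360, 20), 8L)
  # brute-force scan oracle at an unrelated rate
  brute <- function(fs, f2) {
    k <- 1L
    while (f2 < (fs / (k + 1)) / 2) k <- k + 1L
    k
  }
  expect_equal(max_factor(1000, 20), 24L)
  expect_equal(max_factor(1000, 20), brute(1000, 20))
  for (fs in c(250, 500, 512)) {
    expect_equal(max_factor(fs, 20), brute(fs, 20))
  }
  expect_error(max_factor(40, 20), "exceed")
})

test_that("Hz-style targets map to integer factors with clamping", {
  expect_equal(k_from_target_rate(360, 60), 6L)
  expect_equal(k_from_target_rate(360, 51), 7L)
  expect_equal(k_from_target_rate(360, 360), 1L)
  expect_equal(k_from_target_rate(360, 40), 8L)  # clamped to max_factor
  expect_error(k_from_target_rate(360, 400), "target_hz")
})

test_that("compressed power spectrum keeps its mass in the QRS band", {
  ann <- clean_record()
  comp <- decimate_by_factor(ann$record, 6)
  sp <- stats::spec.pgram(stats::ts(comp$samples, frequency = 60),
                          plot = FALSE, taper = 0, spans = 5)
  band <- function(lo, hi) sum(sp$spec[sp$freq >= lo & sp$freq < hi])
  # above the heart-rate fundamentals, the dominant mass sits in the
  # 10-18 Hz QRS band rather than above it
  expect_gt(band(10, 18), band(18, 30))
})
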