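# Shared fixtures and independent brute-force oracles.

# fixture cache so expensive synthetic records are built once per run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

clean_record <- function() {
  fixture("clean", function() {
    generate_ecg(synth_ecg_config(duration = 60, mean_hr = 75, rr_cv = 0.05,
                                  seed = 101L))
  })
}

tall_t_record <- function() {
  # T amplitude at 0.8x R, the large-T regime that fools amplitude-only
  # detectors
  fixture("tall_t", function() {
    wp <- default_wave_params()
    wp$amp[wp$wave == "T"] <- 0.8
    generate_ecg(synth_ecg_config(duration = 60, mean_hr = 75, rr_cv = 0.05,
                                  wave_params = wp, seed = 202L))
  })
}

stress_record <- function() {
  # white noise + severe baseline drift + powerline, irregular rhythm
  fixture("stress", function() {
    generate_ecg(synth_ecg_config(duration = 60, mean_hr = 75, rr_cv = 0.1,
                                  noise_white_sd = 0.1, baseline_amp = 0.5,
                                  baseline_freq = 0.3, powerline_amp = 0.05,
                                  powerline_freq = 60,
                                  premature_prob = 0.1, seed = 303L))
  })
}

# least-squares amplitude of a sinusoid of frequency f in x sampled at fs
fitted_tone_amplitude <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
}

# Eq.-8-literal decimation: direct O(n*taps) convolution of the zero-phase
# (group-delay-compensated) FIR with the zero-padded signal, then every
# k-th sample
brute_force_decimate <- function(x, b, k) {
  gd <- (length(b) - 1L) %/% 2L
  pad <- length(b)
  xpad <- c(rep(0, pad), x, rep(0, pad))
  j <- vapply(seq_along(x), function(i) {
    idx <- i + gd - (seq_along(b) - 1L)
    sum(b * xpad[idx + pad])
  }, numeric(1L))
  j[seq(1L, length(x), by = k)]
}

# O(n*w) centered moving mean with shrinking edge windows
brute_force_moving_average <- function(y, w) {
  h <- (w - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - h):min(n, i + h)])
  }, numeric(1L))
}

# exhaustive maximum-cardinality one-to-one matching within tol (samples)
brute_force_max_matching <- function(det, ref, tol) {
  n_det <- length(det)
  best <- 0L
  recurse <- function(i, used) {
    if (i > n_det) return(0L)
    # skip detection i
    top <- recurse(i + 1L, used)
    for (j in seq_along(ref)) {
      if (!used[j] && abs(ref[j] - det[i]) <= tol) {
        used2 <- used
        used2[j] <- TRUE
        top <- max(top, 1L + recurse(i + 1L, used2))
      }
    }
    top
  }
  recurse(1L, logical(length(ref)))
}

# analytic Gaussian-sum evaluation of the synthetic model at time t (s)
analytic_beat_sum <- function(t, beat_times, wave_params) {
  out <- 0
  for (bt in beat_times) {
    for (j in seq_len(nrow(wave_params))) {
      mu <- bt + wave_params$offset_ms[j] / 1000
      sdv <- wave_params$width_ms[j] / 1000
      out <- out + wave_params$amp[j] * exp(-(t - mu)^2 / (2 * sdv^2))
    }
  }
  out
}
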