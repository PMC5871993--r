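#' Compressed ECG signal
#'
#' Result of a lossy compressor: the compressed sample sequence together
#' with the factor, input/output rates, method label and the filter that
#' produced it. Created by [decimate_by_factor()] and
#' [resample_b_over_k()], not usually by hand.
#'
#' @param samples Compressed sample sequence.
#' @param factor_k Integer decimation factor (1 for Method II, where the
#'   rate change is rational).
#' @param fs_in,fs_out Input and output sampling rates (Hz).
#' @param method `"I"`, `"II"` or `"III"`.
#' @param filter The `filter_spec` used (provenance).
#' @param n_in Length of the original signal (needed for exact-length
#'   reconstruction).
#' @param record_id Identifier inherited from the source record.
#' @param adc_bits Bit width inherited from the source record.
#' @return An object of class `compressed_signal`.
#' @export
compressed_signal <- function(samples, factor_k, fs_in, fs_out, method,
                              filter, n_in, record_id = "record",
                              adc_bits = NA_integer_) {
  if (fs_out <= 0) stop("`fs_out` must be > 0", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), factor_k = as.integer(factor_k),
         fs_in = fs_in, fs_out = fs_out, method = method, filter = filter,
         n_in = as.integer(n_in), record_id = as.character(record_id),
         adc_bits = adc_bits),
    class = "compressed_signal"
  )
}

#' @export
print.compressed_signal <- function(x, ...) {
  cat(sprintf(
    "<compressed_signal> %s: Method %s, %d -> %d samples (%g -> %g Hz)\n",
    x$record_id, x$method, x$n_in, length(x$samples), x$fs_in, x$fs_out))
  invisible(x)
}

#' Convert a compressed signal to an ECG record
#'
#' The compressed samples live on their own timeline at `fs_out`; this
#' view lets the QRS detector (and the I/O writers) treat them as an
#' ordinary record.
#'
#' @param c A [compressed_signal()].
#' @return An [ecg_record()] at the compressed rate.
#' @export
as_ecg_record <- function(c) {
  stopifnot(inherits(c, "compressed_signal"))
  ecg_record(c$samples, fs = c$fs_out, record_id = c$record_id,
             adc_bits = c$adc_bits)
}

#' Compress by anti-aliased decimation (Method III)
#'
#' The core compressor: a low-pass filter confines the signal to the new
#' Nyquist band `(fs/K)/2`, then every `K`-th filtered sample is kept,
#' `y[m] = J[mK]`. Output length is `ceil(n/K)` and the output rate is
#' `fs/K`, so with unchanged bit width the bit compression ratio equals
#' `K`.
#'
#' @param x An [ecg_record()].
#' @param factor_k Integer decimation factor (>= 1).
#' @param filter Optional `filter_spec` from [design_antialias_filter()];
#'   designed automatically when `NULL`.
#' @param kind Filter family passed to [design_antialias_filter()] when
#'   `filter` is `NULL`.
#' @param detector_f2 Upper bandpass edge (Hz) of the downstream QRS
#'   detector; factors beyond [max_factor()] for this edge trigger a
#'   warning (the detector itself enforces the constraint).
#' @return A [compressed_signal()].
#' @examples
#' rec <- generate_ecg(synth_ecg_config(duration = 10))
#' decimate_by_factor(rec$record, 6)
#' @export
decimate_by_factor <- function(x, factor_k, filter = NULL,
                               kind = c("fir_lowpass",
                                        "butterworth_lowpass"),
                               detector_f2 = 20) {
  stopifnot(inherits(x, "ecg_record"))
  kind <- match.arg(kind)
  factor_k <- as.integer(factor_k)
  if (is.na(factor_k) || factor_k < 1L) {
    stop("`factor_k` must be an integer >= 1", call. = FALSE)
  }
  if (is.null(filter)) filter <- design_antialias_filter(factor_k, x$fs, kind)
  if (length(x$samples) <= length(filter$b)) {
    stop("record shorter than the filter transient", call. = FALSE)
  }
  if (!is.null(detector_f2) && x$fs > 2 * detector_f2 &&
      factor_k > max_factor(x$fs, detector_f2)) {
    warning(sprintf(
      "factor %d exceeds max_factor(%g, %g) = %d; QRS detection at %g Hz will fail",
      factor_k, x$fs, detector_f2, max_factor(x$fs, detector_f2),
      x$fs / factor_k))
  }
  j <- apply_filter(x$samples, filter)
  y <- j[seq(1L, length(j), by = factor_k)]   # 0-based indices m*K
  compressed_signal(y, factor_k, fs_in = x$fs, fs_out = x$fs / factor_k,
                    method = "III", filter = filter,
                    n_in = length(x$samples), record_id = x$record_id,
                    adc_bits = x$adc_bits)
}

#' Compress by rational-rate resampling (Method II benchmark)
#'
#' Converts the sampling rate from `fs` to `K` Hz through the intermediate
#' rate `B` Hz: interpolation to `B` (zero insertion + low-pass) followed
#' by decimation to `K` (low-pass + downsampling). Each stage is a
#' rational-rate resampler with up/down factors from the continued-
#' fraction approximation of the rate ratio (max denominator 1000).
#'
#' @param x An [ecg_record()].
#' @param B Intermediate (interpolation) rate in Hz.
#' @param K Output rate in Hz.
#' @return A [compressed_signal()] with `method = "II"` and
#'   `fs_out = K` (up to the rational approximation).
#' @examples
#' rec <- generate_ecg(synth_ecg_config(duration = 10))
#' resample_b_over_k(rec$record, B = 390, K = 80)
#' @export
resample_b_over_k <- function(x, B, K) {
  stopifnot(inherits(x, "ecg_record"))
  if (B <= 0 || K <= 0) stop("`B` and `K` must be > 0", call. = FALSE)
  r1 <- unname(rational_approx(B / x$fs))
  y1 <- resample_rational(x$samples, r1[1L], r1[2L])
  fs_mid <- x$fs * r1[1L] / r1[2L]
  r2 <- unname(rational_approx(K / fs_mid))
  y2 <- resample_rational(y1, r2[1L], r2[2L])
  fs_out <- fs_mid * r2[1L] / r2[2L]
  spec <- filter_spec("fir_lowpass", 30L * max(r2),
                      min(1 / r2[1L], 1 / r2[2L]),
                      b = NA_real_)  # provenance only; stages design their own
  compressed_signal(y2, factor_k = 1L, fs_in = x$fs, fs_out = fs_out,
                    method = "II", filter = spec, n_in = length(x$samples),
                    record_id = x$record_id, adc_bits = x$adc_bits)
}

#' Adaptive linear-prediction error (Method I benchmark)
#'
#' Predicts each sample from its past `order_m` samples,
#' `xhat[n] = sum_k h_k x[n-k]`, and returns the prediction error
#' `e[n] = x[n] - xhat[n]`. The first `order_m` error samples are defined
#' as `x[n]` (cold start, no history). In `"fixed"` mode the coefficient
#' vector is supplied; in `"lms_adaptive"` mode the coefficients are
#' updated per sample by normalized least-mean-squares,
#' `h <- h + step * e[n] * xvec / (||xvec||^2 + eps)`.
#'
#' @param x An [ecg_record()] or numeric vector.
#' @param order_m Predictor order (>= 1).
#' @param mode `"fixed"` or `"lms_adaptive"`.
#' @param coefficients Coefficient vector `h_1..h_m` for `"fixed"` mode
#'   (also the initial value for adaptive mode; defaults to zeros).
#' @param step NLMS adaptation rate (> 0).
#' @return An object of class `predictor_output` with fields `order_m`,
#'   `coefficients` (final values), `error` and `estimate`.
#' @export
predict_error <- function(x, order_m, mode = c("fixed", "lms_adaptive"),
                          coefficients = NULL, step = 0.05) {
  mode <- match.arg(mode)
  sig <- if (inherits(x, "ecg_record")) x$samples else as.numeric(x)
  order_m <- as.integer(order_m)
  if (order_m < 1L) stop("`order_m` must be >= 1", call. = FALSE)
  n <- length(sig)
  if (order_m >= n) {
    stop("`order_m` must be smaller than the signal length", call. = FALSE)
  }
  if (mode == "fixed") {
    if (is.null(coefficients) || length(coefficients) != order_m) {
      stop("`fixed` mode needs `coefficients` of length `order_m`",
           call. = FALSE)
    }
    h <- as.numeric(coefficients)
    xhat <- numeric(n)
    for (k in seq_len(order_m)) {
      idx <- (order_m + 1L):n
      xhat[idx] <- xhat[idx] + h[k] * sig[idx - k]
    }
    e <- sig - xhat
    e[seq_len(order_m)] <- sig[seq_len(order_m)]
    xhat[seq_len(order_m)] <- 0
  } else {
    if (step <= 0) stop("`step` must be > 0 for adaptive mode", call. = FALSE)
    h <- if (is.null(coefficients)) numeric(order_m) else {
      stopifnot(length(coefficients) == order_m)
      as.numeric(coefficients)
    }
    xhat <- numeric(n)
    e <- numeric(n)
    e[seq_len(order_m)] <- sig[seq_len(order_m)]
    eps <- 1e-8
    for (i in (order_m + 1L):n) {
      past <- sig[(i - 1L):(i - order_m)]
      xhat[i] <- sum(h * past)
      e[i] <- sig[i] - xhat[i]
      h <- h + step * e[i] * past / (sum(past^2) + eps)
    }
  }
  structure(list(order_m = order_m, coefficients = h, error = e,
                 estimate = xhat),
            class = "predictor_output")
}

#' @export
print.predictor_output <- function(x, ...) {
  cat(sprintf("<predictor_output> order %d, %d samples, RMS error %.4g\n",
              x$order_m, length(x$error),
              sqrt(mean(x$error[-seq_len(x$order_m)]^2))))
  invisible(x)
}

#' Reconstruct a compressed signal at the original rate
#'
#' Dual of [decimate_by_factor()], used to measure distortion (PRD): the
#' compressed samples are upsampled by zero insertion, interpolated with
#' the same anti-alias FIR family (cutoff `1/K` of the original Nyquist,
#' gain `K`), and trimmed or zero-padded to the original length. Method II
#' signals are resampled back rationally.
#'
#' @param c A [compressed_signal()].
#' @param fs_target Target rate; must equal `c$fs_in` (the default).
#' @return Numeric vector of length `c$n_in`.
#' @export
reconstruct <- function(c, fs_target = c$fs_in) {
  stopifnot(inherits(c, "compressed_signal"))
  if (!isTRUE(all.equal(fs_target, c$fs_in))) {
    stop("reconstruction is only supported at the original rate",
         call. = FALSE)
  }
  if (c$method == "III") {
    k <- c$factor_k
    if (k == 1L) return(pad_or_trim(c$samples, c$n_in))
    y <- resample_rational(c$samples, up = k, down = 1L)
  } else {
    r <- unname(rational_approx(c$fs_in / c$fs_out))
    y <- resample_rational(c$samples, r[1L], r[2L])
  }
  pad_or_trim(y, c$n_in)
}

pad_or_trim <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
}

#' Percentage root-mean-square difference (PRD)
#'
#' `100 * sqrt(sum((x - xhat)^2) / sum(x^2))`. This is the non-normalized
#' variant (no mean subtraction); published PRD figures are sensitive to
#' this choice, so the mean-subtracted variant (often called PRDN) is
#' available via `normalized = TRUE`. PRD is invariant to a common
#' rescaling of both arguments and zero iff they are identical.
#'
#' @param x Reference sequence (not all zero).
#' @param xhat Reconstructed sequence of the same length.
#' @param normalized If `TRUE`, subtract `mean(x)` from the denominator
#'   energy (PRDN).
#' @return PRD in percent.
#' @examples
#' compute_prd(c(1, 0), c(0, 0))  # 100
#' @export
compute_prd <- function(x, xhat, normalized = FALSE) {
  x <- as.numeric(x); xhat <- as.numeric(xhat)
  if (length(x) != length(xhat) || length(x) < 1L) {
    stop("`x` and `xhat` must have equal length >= 1", call. = FALSE)
  }
  denom <- if (normalized) sum((x - mean(x))^2) else sum(x^2)
  if (denom == 0) {
    stop("reference signal has zero energy; PRD undefined", call. = FALSE)
  }
  100 * sqrt(sum((x - xhat)^2) / denom)
}

#' Bit compression ratio (BCR)
#'
#' Ratio of total uncompressed to compressed bits,
#' `(n_u * bits_u) / (n_c * bits_c)`. With unchanged per-sample bit width
#' (no re-quantization, the package default) this reduces to the sample
#' count ratio, so Method III at factor `K` scores exactly `K`.
#'
#' @param n_uncompressed,n_compressed Sample counts.
#' @param bits_uncompressed,bits_compressed Bits per sample.
#' @return The ratio.
#' @export
compute_bcr <- function(n_uncompressed, bits_uncompressed,
                        n_compressed, bits_compressed) {
  args <- c(n_uncompressed, bits_uncompressed, n_compressed,
            bits_compressed)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("all BCR arguments must be positive", call. = FALSE)
  }
  (n_uncompressed * bits_uncompressed) / (n_compressed * bits_compressed)
}

#' Maximum usable decimation factor for a given detector band
#'
#' The QRS detector's bandpass needs its upper edge `F2` strictly below
#' the compressed Nyquist `(fs/K)/2`: at equality the normalized cutoff is
#' exactly 1 and the filter cannot be realized. This returns the largest
#' integer factor satisfying the strict inequality; at 360 Hz with
#' `F2 = 20` Hz that is 8 (factor 9 would leave a 40 Hz rate and a cutoff
#' of exactly one).
#'
#' @param fs Input sampling rate in Hz.
#' @param detector_f2 Upper bandpass edge of the detector in Hz.
#' @return Integer factor.
#' @examples
#' max_factor(360, 20)  # 8
#' @export
max_factor <- function(fs, detector_f2) {
  if (!(fs > 2 * detector_f2)) {
    stop("`fs` must exceed 2 * detector_f2 for any factor to be usable",
         call. = FALSE)
  }
  k <- 1L
  while (detector_f2 < (fs / (k + 1L)) / 2) k <- k + 1L
  k
}

#' Map a target output rate in Hz to an integer decimation factor
#'
#' Compression grids are often quoted as output rates (360, 180, 120, 90,
#' 72, 60, 51, 45 Hz for a 360 Hz input); internally the decimator takes
#' an integer factor. The mapping is `round(fs/target)`, clamped to
#' `[1, max_factor(fs, detector_f2)]`.
#'
#' @param fs Input sampling rate in Hz.
#' @param target_hz Desired output rate, `0 < target_hz <= fs`.
#' @param detector_f2 Upper detector band edge used for the clamp; `NULL`
#'   disables the upper clamp.
#' @return Integer factor.
#' @examples
#' k_from_target_rate(360, 60)  # 6
#' @export
k_from_target_rate <- function(fs, target_hz, detector_f2 = 20) {
  if (target_hz <= 0 || target_hz > fs) {
    stop("`target_hz` must be in (0, fs]", call. = FALSE)
  }
  k <- as.integer(round(fs / target_hz))
  k <- max(1L, k)
  if (!is.null(detector_f2)) k <- min(k, max_factor(fs, detector_f2))
  k
}
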