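# Filter specs and zero-phase application. Linear-phase FIR is the default
# anti-alias family: R-peak timing must survive compression, and the
# evaluation metrics hinge on it.

filter_spec <- function(kind, order, normalized_cutoff, b, a = 1) {
  structure(
    list(kind = kind, order = as.integer(order),
         normalized_cutoff = normalized_cutoff,
         b = as.numeric(b), a = as.numeric(a)),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s, order %d, cutoff %.4g x Nyquist\n",
              x$kind, x$order, x$normalized_cutoff))
  invisible(x)
}

#' Design the anti-alias low-pass filter for decimation by K
#'
#' For an integer decimation factor `K` the usable band of the output is
#' `(fs/K)/2`, i.e. a fraction `1/K` of the input Nyquist; the filter's
#' cutoff is placed there. The default realization is a Hamming-windowed
#' sinc FIR of order `30*K` (linear phase, applied with its group delay
#' compensated so the net phase is zero); `kind = "butterworth_lowpass"`
#' gives a 4th-order Butterworth applied forward-backward instead.
#' `factor_k = 1` returns a passthrough (unity) filter.
#'
#' @param factor_k Integer decimation factor (>= 1).
#' @param fs Input sampling rate in Hz (only used to report the cutoff).
#' @param kind `"fir_lowpass"` (default) or `"butterworth_lowpass"`.
#' @return A `filter_spec`.
#' @examples
#' design_antialias_filter(6, 360)  # cutoff at 30 Hz
#' @export
design_antialias_filter <- function(factor_k, fs = NULL,
                                    kind = c("fir_lowpass",
                                             "butterworth_lowpass")) {
  kind <- match.arg(kind)
  factor_k <- as.integer(factor_k)
  if (is.na(factor_k) || factor_k < 1L) {
    stop("`factor_k` must be an integer >= 1", call. = FALSE)
  }
  if (factor_k == 1L) {
    return(filter_spec("passthrough", 0L, 1, b = 1))
  }
  if (kind == "fir_lowpass") {
    order <- 30L * factor_k  # even, so the group delay is an integer
    b <- signal::fir1(order, 1 / factor_k)
    filter_spec("fir_lowpass", order, 1 / factor_k, b = as.numeric(b))
  } else {
    bt <- signal::butter(4, 1 / factor_k, type = "low")
    filter_spec("butterworth_lowpass", 4L, 1 / factor_k,
                b = bt$b, a = bt$a)
  }
}

# zero-phase application: FIR filters are linear phase, so full convolution
# shifted back by the group delay is exact zero-phase; IIR filters are run
# forward-backward (filtfilt)
apply_filter <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  switch(spec$kind,
    passthrough = x,
    fir_lowpass = fir_zero_phase(x, spec$b),
    butterworth_lowpass =
      as.numeric(signal::filtfilt(signal::Arma(b = spec$b, a = spec$a), x)),
    stop("unknown filter kind: ", spec$kind, call. = FALSE)
  )
}

fir_zero_phase <- function(x, b) {
  gd <- (length(b) - 1L) %/% 2L
  full <- stats::convolve(x, rev(b), type = "open")
  full[gd + seq_along(x)]
}

# continued-fraction rational approximation p/q of x with q <= max_den
rational_approx <- function(x, max_den = 1000L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r - a < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p = as.integer(round(p1)), q = as.integer(round(q1)))
}

# rational-rate resampler: zero-insertion by `up`, zero-phase FIR low-pass
# with cutoff min(1/up, 1/down) of the intermediate Nyquist and gain `up`,
# then keep every `down`-th sample
resample_rational <- function(x, up, down) {
  up <- as.integer(up); down <- as.integer(down)
  stopifnot(up >= 1L, down >= 1L)
  if (up == 1L && down == 1L) return(x)
  n <- length(x)
  z <- numeric(n * up)
  z[seq(1L, by = up, length.out = n)] <- x
  order <- 30L * max(up, down)
  b <- up * as.numeric(signal::fir1(order, min(1 / up, 1 / down)))
  p <- fir_zero_phase(z, b)
  p[seq(1L, length(p), by = down)]
}
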