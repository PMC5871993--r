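#' Single-lead ECG record
#'
#' Container for a single-lead ECG signal in physical units (mV) with its
#' sampling metadata. Sample indices are 0-based throughout the package, so
#' the sample at time `t` seconds is index `round(t * fs)`.
#'
#' @param samples Numeric vector of finite amplitudes (mV).
#' @param fs Sampling rate in Hz (> 0).
#' @param record_id Identifier string.
#' @param adc_bits Integer bit width of the original quantization
#'   (e.g. 11 for the MIT-BIH Arrhythmia Database), or `NA` if unknown.
#' @param gain ADC units per mV, or `NA` when the signal was never
#'   digitized (synthetic data).
#' @return An object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 5 * (0:719) / 360), fs = 360)
#' rec
#' @export
ecg_record <- function(samples, fs, record_id = "record", adc_bits = NA_integer_,
                       gain = NA_real_) {
  samples <- as.numeric(samples)
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all `samples` must be finite", call. = FALSE)
  }
  if (!is.na(adc_bits)) {
    adc_bits <- as.integer(adc_bits)
    if (adc_bits < 1L) stop("`adc_bits` must be >= 1", call. = FALSE)
  }
  if (!is.na(gain) && gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  structure(
    list(record_id = as.character(record_id), fs = fs, samples = samples,
         adc_bits = adc_bits, gain = as.numeric(gain)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.1f s)",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  if (!is.na(x$adc_bits)) cat(sprintf(", %d-bit ADC", x$adc_bits))
  cat("\n")
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)

#' R-peak annotations on a record's timeline
#'
#' Ground-truth or detected R-peak positions as strictly increasing 0-based
#' sample indices, tied to the sampling rate `fs` of the timeline they live
#' on (a record decimated by `k` has annotations at `fs/k`).
#'
#' @param r_indices Integer-valued vector of 0-based sample indices,
#'   strictly increasing.
#' @param fs Sampling rate in Hz of the timeline.
#' @param record_id Identifier of the record the beats belong to.
#' @param n_samples Optional record length; when given, indices are checked
#'   to lie in `[0, n_samples)`.
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(r_indices, fs, record_id = "record",
                             n_samples = NULL) {
  r_indices <- as.numeric(r_indices)
  if (length(r_indices) && any(r_indices != round(r_indices))) {
    stop("`r_indices` must be integer-valued sample indices", call. = FALSE)
  }
  if (length(r_indices) > 1L && any(diff(r_indices) <= 0)) {
    stop("`r_indices` must be strictly increasing", call. = FALSE)
  }
  if (length(r_indices) && r_indices[1L] < 0) {
    stop("`r_indices` must be >= 0", call. = FALSE)
  }
  if (!is.null(n_samples) && length(r_indices) &&
      r_indices[length(r_indices)] >= n_samples) {
    stop(sprintf("annotation index %d out of record range [0, %d)",
                 r_indices[length(r_indices)], n_samples), call. = FALSE)
  }
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(record_id = as.character(record_id), r_indices = r_indices,
         fs = as.numeric(fs)),
    class = "beat_annotations"
  )
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %s: %d beats @ %g Hz\n",
              x$record_id, length(x$r_indices), x$fs))
  invisible(x)
}

#' @export
length.beat_annotations <- function(x) length(x$r_indices)

#' Annotated record (signal + ground-truth beats)
#'
#' Pairs an [ecg_record()] with the [beat_annotations()] that serve as its
#' reference, as produced by [generate_ecg()] or assembled from files.
#'
#' @param record An `ecg_record`.
#' @param truth A `beat_annotations` on the same timeline (`fs` must match).
#' @return An object of class `annotated_record`.
#' @export
annotated_record <- function(record, truth) {
  stopifnot(inherits(record, "ecg_record"), inherits(truth, "beat_annotations"))
  if (!isTRUE(all.equal(record$fs, truth$fs))) {
    stop("record and annotations must share the same sampling rate", call. = FALSE)
  }
  if (length(truth$r_indices) &&
      truth$r_indices[length(truth$r_indices)] >= length(record$samples)) {
    stop("annotation indices exceed record length", call. = FALSE)
  }
  structure(list(record = record, truth = truth), class = "annotated_record")
}

#' @export
print.annotated_record <- function(x, ...) {
  print(x$record)
  cat(sprintf("  with %d reference beats\n", length(x$truth$r_indices)))
  invisible(x)
}
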