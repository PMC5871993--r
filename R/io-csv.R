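#' Read an ECG record from file
#'
#' Reads a WFDB record (header + format-212 signal file) or a plain CSV
#' record into an [ecg_record()] in physical units (mV).
#'
#' The CSV dialect is deliberately minimal so fixtures stay diffable:
#' optional `key=value` header lines (`fs=360`, `adc_bits=11`, `gain=200`),
#' then one sample per row. For WFDB, `path` is the `.hea` file or the
#' record name without extension; amplitudes are converted with
#' `(adc - baseline) / gain`.
#'
#' Multi-signal WFDB records: only one channel is returned,
#' `channel = 1` (the first) by default.
#'
#' @param path Path to the file (`.csv`, or WFDB `.hea` / record name).
#' @param format `"csv"` or `"wfdb"`; guessed from the extension by default.
#' @param fs Sampling rate in Hz, required for CSV files that carry no
#'   `fs=` header line; ignored for WFDB.
#' @param channel 1-based signal channel to extract from multi-lead WFDB
#'   records.
#' @return An [ecg_record()].
#' @seealso [write_record()], [read_annotations()]
#' @export
read_record <- function(path, format = c("auto", "csv", "wfdb"), fs = NULL,
                        channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    read_record_csv(path, fs = fs)
  } else {
    read_record_wfdb(path, channel = channel)
  }
}

#' Write an ECG record to file
#'
#' Inverse of [read_record()]. CSV output stores samples at full double
#' precision so the round trip is exact; WFDB output re-quantizes to
#' format 212 (12-bit), so the round trip is exact only to one
#' quantization step (`1/gain` mV).
#'
#' @param record An [ecg_record()].
#' @param path Output path (`.csv`, or WFDB record name / `.hea` path).
#' @param format `"csv"` or `"wfdb"`; guessed from the extension by default.
#' @param gain ADC units per mV used when quantizing to WFDB format 212;
#'   defaults to the record's own gain, or 200 when unknown.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("auto", "csv", "wfdb"),
                         gain = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") {
    write_record_csv(record, path)
  } else {
    write_record_wfdb(record, path, gain = gain)
  }
  invisible(path)
}

#' Read beat annotations from file
#'
#' Reads R-peak annotations from a WFDB annotation file (e.g. `.atr`) or a
#' CSV file (one 0-based sample index per row; comma-separated values on a
#' line are also accepted). WFDB non-beat annotation symbols are dropped
#' according to `keep_codes`.
#'
#' @param path Path to the annotation file.
#' @param format `"csv"` or `"wfdb"`; guessed from the extension by default.
#' @param fs Sampling rate (Hz) of the timeline the indices live on
#'   (required for CSV; for WFDB taken from the sibling `.hea` when
#'   present, otherwise required).
#' @param record_id Identifier; defaults to the file stem.
#' @param n_samples Optional record length for range validation.
#' @param keep_codes Integer WFDB annotation type codes treated as beats
#'   (default: the standard beat codes 1--13, 25, 34, 35, 38).
#' @param lenient If `TRUE`, unsorted CSV indices are sorted instead of
#'   raising an error.
#' @return A [beat_annotations()].
#' @export
read_annotations <- function(path, format = c("auto", "csv", "wfdb"),
                             fs = NULL, record_id = NULL, n_samples = NULL,
                             keep_codes = wfdb_beat_codes(), lenient = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    if (is.null(fs)) stop("`fs` is required for CSV annotations", call. = FALSE)
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    idx <- as.numeric(unlist(strsplit(lines, ",")))
    if (anyNA(idx)) stop("non-numeric annotation entry in ", path, call. = FALSE)
    if (length(idx) > 1L && any(diff(idx) <= 0)) {
      if (!lenient) {
        stop("annotation indices are not strictly increasing ",
             "(use `lenient = TRUE` to sort)", call. = FALSE)
      }
      idx <- sort(unique(idx))
    }
    beat_annotations(idx, fs = fs, record_id = record_id, n_samples = n_samples)
  } else {
    read_annotations_wfdb(path, fs = fs, record_id = record_id,
                          n_samples = n_samples, keep_codes = keep_codes)
  }
}

#' Write beat annotations to file
#'
#' Inverse of [read_annotations()]. CSV output is one 0-based index per
#' row; WFDB output writes MIT-format annotations with beat type code 1
#' (normal), which the matching reader restores exactly.
#'
#' @param ann A [beat_annotations()].
#' @param path Output path.
#' @param format `"csv"` or `"wfdb"`; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, format = c("auto", "csv", "wfdb")) {
  stopifnot(inherits(ann, "beat_annotations"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (format == "csv") {
    writeLines(format(ann$r_indices, scientific = FALSE, trim = TRUE), path)
  } else {
    write_annotations_wfdb(ann, path)
  }
  invisible(path)
}

read_record_csv <- function(path, fs = NULL) {
  lines <- readLines(path)
  meta <- list(fs = fs, adc_bits = NA_integer_, gain = NA_real_)
  n_header <- 0L
  for (ln in lines) {
    if (grepl("^[A-Za-z_]+ *=", ln)) {
      n_header <- n_header + 1L
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      val <- trimws(kv[2L])
      if (key == "fs") meta$fs <- as.numeric(val)
      else if (key == "adc_bits") meta$adc_bits <- as.integer(val)
      else if (key == "gain") meta$gain <- as.numeric(val)
      else stop("unknown CSV header field: ", key, call. = FALSE)
    } else break
  }
  if (is.null(meta$fs) || is.na(meta$fs)) {
    stop("sampling rate unknown: no `fs=` header line in ", path,
         " and no `fs` argument given", call. = FALSE)
  }
  body <- lines[seq.int(n_header + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  samples <- as.numeric(body)
  if (anyNA(samples)) stop("non-numeric sample in ", path, call. = FALSE)
  ecg_record(samples, fs = meta$fs,
             record_id = sub("\\.[^.]*$", "", basename(path)),
             adc_bits = meta$adc_bits, gain = meta$gain)
}

write_record_csv <- function(record, path) {
  header <- sprintf("fs=%s", format(record$fs, scientific = FALSE, trim = TRUE))
  if (!is.na(record$adc_bits)) {
    header <- c(header, sprintf("adc_bits=%d", record$adc_bits))
  }
  if (!is.na(record$gain)) {
    header <- c(header, sprintf("gain=%s",
                                format(record$gain, scientific = FALSE,
                                       trim = TRUE)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(format(record$samples, scientific = FALSE, trim = TRUE,
                    digits = 17), con)
}
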