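# Minimal WFDB I/O: header parsing, format-212 signals, MIT annotations.
# Covers the subset needed for MIT-BIH / QT style records: it is not a
# general WFDB implementation (no multi-segment records, no skew/offset,
# signal format 212 only). Conformance is established by round-trip
# property tests rather than against an external reader.

#' WFDB beat annotation type codes
#'
#' The standard set of annotation type codes that denote beats (normal,
#' bundle-branch block, premature, escape, paced and fusion beats);
#' everything else (rhythm changes, noise, comments) is dropped by
#' [read_annotations()] unless the keep-list says otherwise.
#'
#' @return Integer vector of type codes.
#' @export
wfdb_beat_codes <- function() {
  c(1:13, 25L, 34L, 35L, 38L)
}

wfdb_paths <- function(path) {
  stem <- sub("\\.(hea|dat|atr)$", "", path)
  list(stem = stem, hea = paste0(stem, ".hea"), dat = paste0(stem, ".dat"))
}

parse_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) {
    stop("WFDB header not found: ", hea_path, call. = FALSE)
  }
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(head_tok) < 2L) {
    stop("malformed WFDB header line (record name / signal count): ",
         lines[1L], call. = FALSE)
  }
  record_name <- head_tok[1L]
  nsig <- suppressWarnings(as.integer(head_tok[2L]))
  if (is.na(nsig) || nsig < 1L) {
    stop("malformed WFDB header: bad signal count field '", head_tok[2L],
         "'", call. = FALSE)
  }
  fs <- 250
  if (length(head_tok) >= 3L) {
    fs <- suppressWarnings(as.numeric(sub("/.*$", "", head_tok[3L])))
    if (is.na(fs) || fs <= 0) {
      stop("malformed WFDB header: bad sampling frequency field '",
           head_tok[3L], "'", call. = FALSE)
    }
  }
  nsamples <- if (length(head_tok) >= 4L) {
    suppressWarnings(as.integer(head_tok[4L]))
  } else NA_integer_
  if (length(lines) < 1L + nsig) {
    stop("malformed WFDB header: expected ", nsig, " signal lines",
         call. = FALSE)
  }
  signals <- lapply(seq_len(nsig), function(i) {
    tok <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    fmt <- sub("[x:+].*$", "", tok[2L])
    gain_field <- if (length(tok) >= 3L) tok[3L] else "0"
    units <- sub("^[^/]*/?", "", gain_field)
    gain_core <- sub("/.*$", "", gain_field)
    baseline <- NA_integer_
    if (grepl("\\(", gain_core)) {
      baseline <- as.integer(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_core))
      gain_core <- sub("\\(.*$", "", gain_core)
    }
    gain <- suppressWarnings(as.numeric(gain_core))
    if (is.na(gain)) {
      stop("malformed WFDB header: bad gain field '", gain_field, "'",
           call. = FALSE)
    }
    adcres <- if (length(tok) >= 4L) as.integer(tok[4L]) else 12L
    adczero <- if (length(tok) >= 5L) as.integer(tok[5L]) else 0L
    if (is.na(baseline)) baseline <- adczero
    list(file = tok[1L], format = fmt, gain = gain, baseline = baseline,
         adcres = adcres, adczero = adczero,
         units = if (nzchar(units)) units else "mV")
  })
  list(record_name = record_name, nsig = nsig, fs = fs, nsamples = nsamples,
       signals = signals)
}

decode_212 <- function(raw_bytes, n_values) {
  b <- as.integer(raw_bytes)
  n_groups <- length(b) %/% 3L
  b1 <- b[seq(1L, by = 3L, length.out = n_groups)]
  b2 <- b[seq(2L, by = 3L, length.out = n_groups)]
  b3 <- b[seq(3L, by = 3L, length.out = n_groups)]
  a <- bitwOr(bitwShiftL(bitwAnd(b2, 0x0FL), 8L), b1)
  d <- bitwOr(bitwShiftL(bitwAnd(b2, 0xF0L), 4L), b3)
  a <- ifelse(a > 2047L, a - 4096L, a)
  d <- ifelse(d > 2047L, d - 4096L, d)
  out <- as.vector(rbind(a, d))
  out[seq_len(n_values)]
}

encode_212 <- function(values) {
  v <- as.integer(values)
  if (any(v < -2048L | v > 2047L)) {
    stop("sample out of 12-bit range for WFDB format 212", call. = FALSE)
  }
  if (length(v) %% 2L == 1L) v <- c(v, 0L)
  v <- ifelse(v < 0L, v + 4096L, v)
  a <- v[seq(1L, length(v), by = 2L)]
  d <- v[seq(2L, length(v), by = 2L)]
  b1 <- bitwAnd(a, 0xFFL)
  b2 <- bitwOr(bitwShiftR(a, 8L), bitwShiftL(bitwShiftR(d, 8L), 4L))
  b3 <- bitwAnd(d, 0xFFL)
  as.raw(as.vector(rbind(b1, b2, b3)))
}

read_record_wfdb <- function(path, channel = 1L) {
  p <- wfdb_paths(path)
  hdr <- parse_wfdb_header(p$hea)
  if (channel < 1L || channel > hdr$nsig) {
    stop("record has ", hdr$nsig, " signal(s); channel ", channel,
         " requested", call. = FALSE)
  }
  sig <- hdr$signals[[channel]]
  if (sig$format != "212") {
    stop("unsupported WFDB signal format '", sig$format,
         "' (only 212 is supported)", call. = FALSE)
  }
  dat_path <- file.path(dirname(p$hea), sig$file)
  if (!file.exists(dat_path)) {
    stop("WFDB signal file not found: ", dat_path, call. = FALSE)
  }
  raw_bytes <- readBin(dat_path, "raw", n = file.size(dat_path))
  total <- hdr$nsamples * hdr$nsig
  need_bytes <- 3L * ((total + 1L) %/% 2L)
  if (length(raw_bytes) < need_bytes) {
    stop("WFDB signal file shorter than header sample count: expected >= ",
         need_bytes, " bytes, found ", length(raw_bytes), call. = FALSE)
  }
  adc <- decode_212(raw_bytes, total)
  # format 212 interleaves the signals sample by sample
  adc <- adc[seq(channel, by = hdr$nsig, length.out = hdr$nsamples)]
  gain <- if (sig$gain > 0) sig$gain else 200
  samples <- (adc - sig$baseline) / gain
  ecg_record(samples, fs = hdr$fs, record_id = hdr$record_name,
             adc_bits = sig$adcres, gain = gain)
}

write_record_wfdb <- function(record, path, gain = NULL) {
  p <- wfdb_paths(path)
  if (is.null(gain)) gain <- if (!is.na(record$gain)) record$gain else 200
  adc <- as.integer(round(record$samples * gain))
  if (any(adc < -2048L | adc > 2047L)) {
    stop("signal exceeds the 12-bit range of WFDB format 212 at gain ",
         gain, "; lower `gain`", call. = FALSE)
  }
  n <- length(adc)
  name <- basename(p$stem)
  adcres <- if (!is.na(record$adc_bits)) record$adc_bits else 12L
  hdr <- c(
    sprintf("%s 1 %s %d", name,
            format(record$fs, scientific = FALSE, trim = TRUE), n),
    sprintf("%s.dat 212 %s(0)/mV %d 0 %d 0 0 ECG", name,
            format(gain, scientific = FALSE, trim = TRUE), adcres, adc[1L])
  )
  writeLines(hdr, p$hea)
  writeBin(encode_212(adc), paste0(p$stem, ".dat"))
  invisible(p$stem)
}

# MIT annotation format: 16-bit little-endian words, type code in the high
# 6 bits, time increment in the low 10 bits; SKIP (59) carries a 4-byte
# long interval (high word first), AUX (63) carries a padded byte string.
read_annotations_wfdb <- function(path, fs = NULL, record_id = NULL,
                                  n_samples = NULL,
                                  keep_codes = wfdb_beat_codes()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(fs)) {
    hea <- wfdb_paths(path)$hea
    if (file.exists(hea)) {
      fs <- parse_wfdb_header(hea)$fs
    } else {
      stop("`fs` is required (no sibling .hea header found)", call. = FALSE)
    }
  }
  b <- as.integer(readBin(path, "raw", n = file.size(path)))
  i <- 1L
  t <- 0
  times <- numeric(0)
  codes <- integer(0)
  while (i + 1L <= length(b)) {
    word <- b[i] + 256L * b[i + 1L]
    i <- i + 2L
    typ <- word %/% 1024L
    delta <- word %% 1024L
    if (typ == 0L && delta == 0L) break            # EOF
    if (typ == 59L) {                              # SKIP: 4-byte interval
      if (delta == 0L) {
        hi <- b[i] + 256L * b[i + 1L]
        lo <- b[i + 2L] + 256L * b[i + 3L]
        i <- i + 4L
        long_delta <- hi * 65536 + lo
        if (long_delta >= 2^31) long_delta <- long_delta - 2^32
        t <- t + long_delta
      }
    } else if (typ == 63L) {                       # AUX: skip payload
      i <- i + delta + (delta %% 2L)
    } else if (typ %in% c(60L, 61L, 62L)) {        # NUM/SUB/CHN: no time
      # value carried in delta; ignored
    } else {
      t <- t + delta
      times <- c(times, t)
      codes <- c(codes, typ)
    }
  }
  keep <- codes %in% keep_codes
  beat_annotations(times[keep], fs = fs,
                   record_id = if (is.null(record_id)) "record" else record_id,
                   n_samples = n_samples)
}

write_annotations_wfdb <- function(ann, path, code = 1L) {
  idx <- ann$r_indices
  words <- integer(0)
  prev <- 0
  for (t in idx) {
    delta <- t - prev
    if (delta > 1023) {
      words <- c(words, 59L * 1024L,                       # SKIP, delta 0
                 delta %/% 65536, delta %% 65536)          # hi word, lo word
      delta <- 0
    }
    words <- c(words, code * 1024L + delta)
    prev <- t
  }
  words <- c(words, 0L)                                    # EOF
  bytes <- as.raw(as.vector(rbind(words %% 256L, words %/% 256L)))
  writeBin(bytes, path)
  invisible(path)
}
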