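#' Detection count triple
#'
#' True positives, false positives and false negatives of a beat-matching
#' run. `tp + fn` equals the number of reference beats and `tp + fp` the
#' number of detections.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return An object of class `detection_counts`.
#' @export
detection_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn)),
            class = "detection_counts")
}

#' @export
print.detection_counts <- function(x, ...) {
  cat(sprintf("<detection_counts> TP %g, FP %g, FN %g\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Match detected beats against reference annotations
#'
#' One-to-one matching of detections to reference beats within a
#' `tolerance_ms` window, on a shared timeline (same `fs`; map compressed
#' detections up with [map_to_original_timeline()] first). Both sequences
#' are sorted, so each detection's admissible references form a
#' contiguous run; matching each detection in order to the earliest
#' unmatched admissible reference is then a maximum-cardinality matching
#' (the classic greedy for convex bipartite graphs). Unmatched references
#' count as FN, unmatched detections as FP.
#'
#' The default window of 150 ms is the ANSI/AAMI EC57 convention; it is
#' the single most results-sensitive free choice in the whole evaluation
#' and is therefore exposed everywhere.
#'
#' @param detected,reference [beat_annotations()] on the same timeline.
#' @param tolerance_ms Matching half-window in ms.
#' @return A [detection_counts()].
#' @export
match_beats <- function(detected, reference, tolerance_ms = 150) {
  stopifnot(inherits(detected, "beat_annotations"),
            inherits(reference, "beat_annotations"))
  if (!isTRUE(all.equal(detected$fs, reference$fs))) {
    stop("`detected` and `reference` must share a timeline (same fs); ",
         "use map_to_original_timeline() first", call. = FALSE)
  }
  tol <- tolerance_ms / 1000 * reference$fs
  det <- detected$r_indices
  ref <- reference$r_indices
  used <- logical(length(ref))
  tp <- 0L
  j <- 1L  # earliest reference that can still match
  for (d in det) {
    while (j <= length(ref) && (used[j] || ref[j] < d - tol)) j <- j + 1L
    if (j <= length(ref) && abs(ref[j] - d) <= tol) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  detection_counts(tp, fp = length(det) - tp, fn = length(ref) - tp)
}

#' Map annotations from a decimated timeline back to the original
#'
#' A beat detected at index `i` on a record decimated by `K` corresponds
#' to index `i * K` at the original rate; the timeline rate scales the
#' same way.
#'
#' @param ann A [beat_annotations()] at the compressed rate.
#' @param factor_k Integer decimation factor (>= 1).
#' @return A [beat_annotations()] at `fs * factor_k`.
#' @export
map_to_original_timeline <- function(ann, factor_k) {
  stopifnot(inherits(ann, "beat_annotations"))
  factor_k <- as.integer(factor_k)
  if (factor_k < 1L) stop("`factor_k` must be >= 1", call. = FALSE)
  if (factor_k == 1L) return(ann)
  beat_annotations(ann$r_indices * factor_k, fs = ann$fs * factor_k,
                   record_id = ann$record_id)
}

#' Sensitivity (SE)
#'
#' `100 * TP / (TP + FN)`: the fraction of true beats that were detected.
#'
#' @param c A [detection_counts()].
#' @return Percentage.
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "detection_counts"))
  if (c$tp + c$fn == 0) {
    stop("sensitivity undefined: no reference beats (tp + fn = 0)",
         call. = FALSE)
  }
  100 * c$tp / (c$tp + c$fn)
}

#' Positive predictivity (+P)
#'
#' `100 * TP / (TP + FP)`: the fraction of detections that are true beats.
#'
#' @param c A [detection_counts()].
#' @return Percentage.
#' @export
positive_predictivity <- function(c) {
  stopifnot(inherits(c, "detection_counts"))
  if (c$tp + c$fp == 0) {
    stop("positive predictivity undefined: no detections (tp + fp = 0)",
         call. = FALSE)
  }
  100 * c$tp / (c$tp + c$fp)
}

#' F-score g
#'
#' `100 * 2*TP / (2*TP + FP + FN)`, the harmonic mean of sensitivity and
#' positive predictivity. This is the objective the decimation-factor
#' grid search maximizes.
#'
#' @param c A [detection_counts()].
#' @return Percentage.
#' @export
f_score <- function(c) {
  stopifnot(inherits(c, "detection_counts"))
  if (2 * c$tp + c$fp + c$fn == 0) {
    stop("F-score undefined: no beats and no detections", call. = FALSE)
  }
  100 * 2 * c$tp / (2 * c$tp + c$fp + c$fn)
}

#' Evaluation result for one record (or a pooled set)
#'
#' @param record_id Identifier.
#' @param factor_k Decimation factor evaluated.
#' @param counts A [detection_counts()].
#' @param bcr Bit compression ratio.
#' @param prd PRD in percent, or `NA` when not computed.
#' @param fs_out Output rate in Hz (for reporting the Hz-style grid).
#' @return An object of class `evaluation_result`; `se`, `pp` and `g` are
#'   computed from the counts (and are `NA` when undefined).
#' @export
evaluation_result <- function(record_id, factor_k, counts, bcr = NA_real_,
                              prd = NA_real_, fs_out = NA_real_) {
  stopifnot(inherits(counts, "detection_counts"))
  se <- if (counts$tp + counts$fn > 0) sensitivity(counts) else NA_real_
  pp <- if (counts$tp + counts$fp > 0) positive_predictivity(counts) else NA_real_
  g <- if (2 * counts$tp + counts$fp + counts$fn > 0) f_score(counts) else NA_real_
  structure(
    list(record_id = record_id, factor_k = factor_k, counts = counts,
         se = se, pp = pp, g = g, bcr = bcr, prd = prd, fs_out = fs_out),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> %s (K=%s): TP %g FP %g FN %g | SE %.2f%% +P %.2f%% g %.2f%%",
    x$record_id, x$factor_k, x$counts$tp, x$counts$fp, x$counts$fn,
    x$se, x$pp, x$g))
  if (!is.na(x$bcr)) cat(sprintf(" | BCR %.2f", x$bcr))
  if (!is.na(x$prd)) cat(sprintf(" | PRD %.2f%%", x$prd))
  cat("\n")
  invisible(x)
}

#' Evaluate compression quality on one annotated record
#'
#' The validation pipeline: decimate the record by `factor_k`, run the
#' QRS detector at the compressed rate, map the detections back to the
#' original timeline, match them against the reference beats and compute
#' SE, +P, g and BCR (and PRD against the reconstruction when
#' `compute_prd_flag` is set).
#'
#' @param annotated An [annotated_record()].
#' @param factor_k Integer decimation factor.
#' @param detector_params A [terma_params()].
#' @param tolerance_ms Beat-matching window in ms.
#' @param filter_kind Anti-alias family for [decimate_by_factor()].
#' @param compute_prd_flag If `TRUE`, also reconstruct and report PRD.
#' @return An [evaluation_result()].
#' @examples
#' ann <- generate_ecg(synth_ecg_config(duration = 30))
#' evaluate_record(ann, factor_k = 6)
#' @export
evaluate_record <- function(annotated, factor_k, detector_params = terma_params(),
                            tolerance_ms = 150,
                            filter_kind = c("fir_lowpass",
                                            "butterworth_lowpass"),
                            compute_prd_flag = FALSE) {
  stopifnot(inherits(annotated, "annotated_record"))
  filter_kind <- match.arg(filter_kind)
  rec <- annotated$record
  comp <- decimate_by_factor(rec, factor_k, kind = filter_kind,
                             detector_f2 = detector_params$f2)
  det <- detect_qrs(as_ecg_record(comp), detector_params)
  det_orig <- map_to_original_timeline(det, factor_k)
  counts <- match_beats(det_orig, annotated$truth, tolerance_ms)
  stopifnot(counts$tp + counts$fn == length(annotated$truth$r_indices),
            counts$tp + counts$fp == length(det$r_indices))
  bits <- if (!is.na(rec$adc_bits)) rec$adc_bits else 11L
  bcr <- compute_bcr(length(rec$samples), bits, length(comp$samples), bits)
  prd <- if (compute_prd_flag) {
    compute_prd(rec$samples, reconstruct(comp))
  } else NA_real_
  evaluation_result(rec$record_id, factor_k, counts, bcr = bcr, prd = prd,
                    fs_out = comp$fs_out)
}

#' Pool evaluation results
#'
#' Sums TP/FP/FN across records and recomputes SE, +P and g from the
#' pooled counts — not by averaging per-record percentages, which weights
#' records equally regardless of beat count and gives different answers.
#' BCR and PRD are averaged across the records that report them (BCR is
#' identical across records at a fixed factor anyway).
#'
#' @param results Non-empty list of [evaluation_result()]s.
#' @return A pooled [evaluation_result()] with `record_id = "pooled"`.
#' @export
pool_results <- function(results) {
  if (length(results) == 0L) stop("`results` must be non-empty", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1L), "evaluation_result")))
  tp <- sum(vapply(results, function(r) r$counts$tp, numeric(1L)))
  fp <- sum(vapply(results, function(r) r$counts$fp, numeric(1L)))
  fn <- sum(vapply(results, function(r) r$counts$fn, numeric(1L)))
  bcrs <- vapply(results, function(r) r$bcr, numeric(1L))
  prds <- vapply(results, function(r) r$prd, numeric(1L))
  ks <- unique(vapply(results, function(r) r$factor_k, numeric(1L)))
  fso <- unique(vapply(results, function(r) r$fs_out, numeric(1L)))
  evaluation_result(
    "pooled", if (length(ks) == 1L) ks else NA_real_,
    detection_counts(tp, fp, fn),
    bcr = if (all(is.na(bcrs))) NA_real_ else mean(bcrs, na.rm = TRUE),
    prd = if (all(is.na(prds))) NA_real_ else mean(prds, na.rm = TRUE),
    fs_out = if (length(fso) == 1L) fso else NA_real_
  )
}
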