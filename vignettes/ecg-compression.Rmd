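---
title: "Decimation-based ECG compression and its QRS-detection validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decimation-based ECG compression and its QRS-detection validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgcompress)
```

## The problem

Continuous single-lead ECG at 360 Hz and 11 bits produces ~4 kbit/s per
patient — too much for battery-powered sensors that must transmit for
days. Lossless predictive coders compress 2–2.5x at real cost in
computation; but if the clinical consumer of the stream is beat detection
and rhythm analysis, fidelity far above the QRS band is wasted. The
package's premise is that the cheapest useful compressor is sampling-rate
reduction, judged not by waveform error alone but by whether a QRS
detector still finds every beat afterwards.

## The compressor and its benchmarks

**Method III (core): decimation by an integer factor K.** A low-pass
filter limits the signal to `(Fs/K)/2` (normalized cutoff `1/K`,
i.e. `π/K` in radian frequency), then every K-th filtered sample is
kept: `J[n] = Σ h[l]·x[n−l]`, `y[m] = J[mK]`. Output rate `Fs/K`, output
length `ceil(n/K)`; with unchanged bit width the bit compression ratio
`BCR = (n_u·BW_u)/(n_c·BW_c)` is exactly K.

**Method II (benchmark): rational-rate resampling via B.** The signal is
interpolated to an intermediate rate B Hz (zero insertion + low-pass)
and then decimated to K Hz. Each stage is a rational resampler whose
up/down factors come from a continued-fraction approximation of the rate
ratio (max denominator 1000). At 360 Hz with the benchmark optimum
B = 390 Hz, K = 80 Hz the effective ratio is 360/80 = 4.5.

**Method I (benchmark): adaptive linear prediction.** A forward
predictor `x̂[n] = Σ_{k=1..m} h_k·x[n−k]` leaves an error signal
`e[n] = x[n] − x̂[n]` that is near zero between beats and peaks inside
the QRS, which makes it both compressible (entropy coding is out of
scope here) and usable for detection. The adaptation rule is normalized
LMS, `h ← h + μ·e[n]·x_past/(‖x_past‖² + ε)` with `μ = 0.05` by default;
the first `m` error samples are the cold-start `x[n]` itself. The
literature this method descends from treats its QRS post-detector
(Savitzky–Golay smoothing with window/order parameters defined
elsewhere) as a separate component; it is not reimplemented here, and
Method I is validated only through the error-energy localization
property.

## The TERMA detector

Detection runs *on the compressed timeline*: bandpass (third-order
Butterworth, 8–20 Hz, applied forward-backward so it is zero-phase) →
squaring → two centered moving averages with windows `W1 = 97` ms
(QRS scale) and `W2 = 611` ms (beat scale) → blocks of interest where
`MA_QRS > MA_beat + THR_offset` → one R peak per block at the argmax of
the absolute bandpassed signal. Detected indices are mapped back to the
original timeline by multiplying by K.

Numerical conventions that make results bit-reproducible:

* window sizes are the nearest odd sample count to `W·Fs/1000`
  (ties rounded up): 35 samples for 97 ms at 360 Hz, 5 at 60 Hz;
* edges use shrinking windows (the mean over what fits);
* blocks shorter than the `W1` window are rejected as spurious;
* blocks with onsets closer than 200 ms — the physiological minimum RR
  interval — are merged before peak picking, preventing double-fire on
  wide QRS complexes;
* ties in the peak argmax break to the earliest index.

**The β parameter.** The published optimum for this detector quotes
β = 8 with no accompanying formula, while the detector's source
literature uses a small fractional offset. This package interprets β as
a *percentage of the mean squared bandpassed energy*:
`THR_offset = (β/100)·mean(y²)`. That reading makes β = 8 a mild
offset consistent with the near-perfect detection the parameter set is
known for. It is an explicit assumption; `terma_params(beta_mode =
"absolute")` switches to an absolute offset for sensitivity analyses.

**Why the band edge caps K.** The bandpass needs `F2/(Fs′/2) < 1`
strictly. At `Fs = 360` Hz and `F2 = 20` Hz, factor 9 gives `Fs′ = 40`
Hz and a normalized cutoff of exactly 1, which no realizable filter
accepts — hence `max_factor(360, 20) = 8` and the grid 360, 180, 120,
90, 72, 60, 51, 45 Hz (`round(360/k)`, k = 1..8).

## Evaluation protocol

Detections and reference beats are matched one-to-one within ±150 ms
(the ANSI/AAMI EC57 window — the single most results-sensitive free
choice in the protocol, therefore configurable everywhere). Both
sequences are sorted, so matching each detection in order to the
earliest unmatched in-window reference attains maximum-cardinality
matching (the convex-bipartite greedy); the test suite checks this
against exhaustive assignment. From `TP/FP/FN`:
`SE = 100·TP/(TP+FN)`, `+P = 100·TP/(TP+FP)`,
`g = 100·2TP/(2TP+FP+FN)` (the harmonic mean of SE and +P).

Multi-record results are pooled by **summing counts** and recomputing
the percentages, never by averaging per-record percentages — pooling
weights records by their beat count and is the convention the published
summary rows follow. Degenerate records (no beats, no detections) report
metrics as undefined rather than 100%.

**PRD.** The package uses the non-normalized definition
`100·sqrt(Σ(x−x̂)²/Σx²)`; the mean-subtracted variant (PRDN) is
available behind a flag. Published PRD figures are sensitive to this
choice, which is why it is called out loudly. Reconstruction for PRD is
the simplest dual of the decimator: zero insertion by K, the same FIR
family with cutoff `1/K` and gain K, trimmed to the original length.

## The K grid search

`optimize_k()` runs the full compress–detect–match pipeline per factor,
pools counts over the dataset and maximizes g. Selection rule: among
factors with pooled g within ε = 0.05 percentage points of the maximum,
the **largest** factor wins — at comparable detection quality, more
compression is strictly better, and published optima follow this
preference (a 60 Hz selection despite marginally higher g at 360/180
Hz). ε is configurable; the detector parameters stay fixed during the
search (their joint optimization belongs to the detector's own
literature).

## Filter realizations

The anti-alias filter is a Hamming-windowed-sinc FIR of order `30·K`
with cutoff `1/K` of Nyquist. Linear phase matters: R-peak *timing* is
what the evaluation measures, and a linear-phase FIR applied with its
group delay compensated is exactly zero-phase, so compression shifts no
peaks. Measured on the order-180 (K = 6) design: ≤0.01 dB at half the
cutoff, −71 dB at 1.5× the cutoff, comfortably beyond the 40 dB
anti-aliasing requirement the tests assert. A 4th-order Butterworth
applied forward-backward is available as the low-cost alternative. The
detector's own bandpass is Butterworth by construction (order 3), also
run forward-backward.

Edge handling: zero-phase convolution assumes zeros outside the record,
so one filter length at each end is transient; the tone-preservation
and attenuation tests measure interior segments. Records shorter than
the filter are rejected.

## The synthetic generator

`generate_ecg()` is the package's study bench: each beat is a sum of
five Gaussians (P, Q, R, S, T) with configurable amplitude, width
(Gaussian sd) and offset from R; defaults are R = 1.0 mV / 25 ms,
T = 0.3 mV / 120 ms at +300 ms, P = 0.15 mV / 55 ms at −200 ms, and
small negative Q/S — chosen to put realistic QRS energy in the 8–20 Hz
detector band at a 75 bpm default rate. RR intervals are truncated-
normal (floor 0.2 s) with configurable CV; a premature-beat option
shortens an interval to 0.6× with a 1.4× compensatory pause. Stress
regimes add white noise, sinusoidal baseline wander (default 0.3 Hz)
and powerline interference. Ground truth is the sample nearest each
R-wave center, defined on the clean signal and invariant under added
noise; Gaussian cross-talk (mostly the T tail) places the clean signal
value at the truth index within ~1.1% of the configured R amplitude,
and the tests check the exact analytic sum.

What the generator does *not* emulate: measured morphology variability
between leads and patients, non-stationary noise bursts, electrode
motion artifacts, true arrhythmia dynamics. Passing the synthetic suite
therefore demonstrates the pipeline's signal-processing correctness and
its behavior under the intended stress axes, not clinical-grade
performance; per-record results on the standard arrhythmia databases
require obtaining those recordings (the WFDB reader ingests them
directly).

## Problem sizes and determinism

The test fixtures are 60-second records at 360 Hz (one clean, one
tall-T with T = 0.8× R, one noisy/irregular), which are long enough to
hold ~75 beats and short enough that the full suite, including the 8-
point grid search, runs in seconds. Every stochastic component draws
from an explicit seed (config seed for the generator, private RNG
scope), so identical configs are bit-identical and all suite results
are reproducible.

## Known limitations

* Method I is compression-only here: no entropy coder, no validated QRS
  stage (its defining parameters are not public in sufficient detail).
* WFDB support covers format 212 and MIT beat annotations — enough for
  the classic arrhythmia databases — not the full format zoo.
* β's percentage interpretation is an assumption (above); deployments
  against other detector implementations should verify thresholds on a
  labelled segment.
* PRD depends on the reconstruction filter; the reported figures are
  specific to the interpolation dual described here.
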