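---
title: "Methods: rare-event peak detection and cascaded classification in backscatter flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-event peak detection and cascaded classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcascade)
```

## The problem

Circulating tumor cell clusters (CTCCs) are aggregates of two or more tumor
cells in the bloodstream. They are orders of magnitude rarer than single
circulating tumor cells — literature concentrations span roughly 0.4 to 10
clusters per millilitre of blood — but carry far higher metastatic
potential, which makes their label-free enumeration a clinically important
and statistically brutal problem: a detector must find a handful of true
events among hundreds of thousands of background peaks produced by white
blood cells, debris and instrument noise.

`peakcascade` implements a two-stage detector for multi-channel backscatter
flow cytometry (BSFC) voltage traces. Blood flows through a 30 × 30 µm²
microfluidic channel across a 5 µm illumination slit; elastically
backscattered light is recorded at 405, 488 and 633 nm at 60 kHz, together
with a green exogenous-fluorescence channel (525 ± 25 nm) that sees only
GFP-labelled spiked clusters — the ground truth used to train and evaluate
the label-free scatter-only detector — and a red autofluorescence channel
(670 ± 20 nm).

## Stage one: anomaly-based region-of-interest detection

Recordings are processed in 90 s segments. Each segment passes through:

1. **Clot screening and correction.** Whole blood occasionally carries a
   clot that raises the baseline. The cumulative scatter signal (the sum of
   the three scatter channels, expected baseline variance
   0.169 + 0.452 + 0.511 ≈ 1.132 V²) is screened against a 1.75 V standard
   deviation threshold — three standard deviations above the expected
   cumulative baseline. When the variance exceeds 3.06 V² (= 1.75²), a
   centred 500-sample moving average is subtracted from each scatter
   channel and the channel's original mean is added back, repeating until
   the standard deviation drops below 1.75 V or three iterations have run;
   the cap exists because noisy segments need not converge. The corrected
   channels preserve their global means exactly (the residual is recentred
   before the mean is restored), which the tests assert to 10⁻⁶ V.
2. **Band-pass filtering.** A second-order Butterworth filter, 50–10 000 Hz.
   It is applied forward and backward (zero phase) so peak positions are
   not shifted — downstream feature windows are centred on peak locations,
   so phase distortion would leak label information out of the ±49-sample
   window. The magnitude response of the round trip is the squared
   single-pass response, which the tests check against the analytic
   Butterworth magnitude at bilinear-prewarped frequencies.
3. **Normalization.** Each scatter channel is divided by an optional
   per-day laser-power factor and min–max mapped onto [0, 1] within the
   segment, so day-to-day power drift cannot masquerade as signal.
4. **Hotelling T² anomaly trace.** Each time sample is a 3-vector of
   normalized scatter values. Principal components are estimated from the
   segment's own samples (blood background dominates, so the centroid and
   covariance describe the background), and each sample is scored
   `T² = Σ_k score_k² / λ_k` over the retained components. With all three
   components this is exactly the squared Mahalanobis distance from the
   centroid — the oracle the test suite checks against `stats::mahalanobis`
   to 10⁻⁸ — and with the default two components it is the distance within
   the dominant-variance plane. Samples with T² > 10 are anomalies;
   contiguous supra-threshold runs become candidate events, and a run
   containing several local maxima is kept as one (cluster) event at its
   tallest peak.
5. **Shoulder-equalized FWHM and the width gate.** Real cluster peaks often
   carry lower-amplitude shoulder sub-peaks that truncate a naive
   full-width-at-half-maximum. Geometric height equalization rescales every
   local maximum of the event to 1 and divides intermediate samples by the
   straight line joining the original peak heights; FWHM is then measured
   at 0.5 with sub-sample linear interpolation and rounded half-up. The
   multicellular gate removes events narrower than 17 samples: a large
   single cell (12–15 µm) crossing the 5 µm slit at 55.6 mm/s spans
   (15 + 5) µm / 55.6 mm s⁻¹ × 60 kHz ≈ 21.6 → at most 22 samples, and
   0.75 × 22 rounds to 17. The gate is inclusive (FWHM ≥ 17 survives).

## Stage two: cascaded convolutional classification

Surviving events become 297-point feature vectors: each raw scatter channel
is z-scored over its segment, the ±49 samples around the peak are extracted
(edge-padded at segment boundaries), and the three 99-sample windows are
concatenated in 405/488/633 order. Ground-truth labels come from the green
channel: a scatter event is a CTCC when a green region overlaps it and
either its own FWHM or the green region's FWHM strictly exceeds 17 samples.
Note the deliberate asymmetry: detection retains FWHM = 17 but the label
rule is strict, so an event at exactly 17 with an equally narrow green
partner is retained yet labelled NC. Splits are always by acquisition day,
never by event, so no recording session leaks between training, validation
and test.

The classifier is a small 1-D CNN — six convolution + max-pool blocks, one
extra max-pool, one fully connected sigmoid output — trained with Adam at
10⁻³ for at most 15 epochs with early stopping after 7 epochs without
validation improvement (monitored on validation F1, ties broken by lower
validation loss). Class imbalance is handled in the loss, not by
resampling: the training loss is an equal mix of weighted binary
cross-entropy (positive weight = negatives/positives, recomputed per
stage) and the focal Tversky loss `(1 − TI)^γ` with
`TI = TP/(TP + α·FN + β·FP)` on soft scores, α = 0.7, β = 0.3, γ = 0.75 —
the conventional defaults of the focal Tversky literature; the kernel size
(3) and channel widths (8–16–32–32–32–32) are likewise defaults of the
package since the architecture's source publication leaves them open, and
all are configurable.

Purity is then raised by a **cascade** of up to ten such networks. Stage
k + 1 trains on stage k's training-set true positives, false positives and
false negatives — the confidently rejected true negatives are dropped — so
each successive network faces a smaller, positive-enriched set of hard
examples. At prediction time every event enters stage 1 and only predicted
positives advance; the final positives are those accepted by every stage.
The predicted-positive set therefore shrinks weakly with depth: false
positives and sensitivity can only fall, purity tends to rise. This is the
mechanism behind the depth trade-off (high-sensitivity/low-purity shallow
cascades versus low-sensitivity/high-purity deep ones), and the test suite
asserts it directionally on synthetic data. The CNN, its backpropagation
and the Adam updates are implemented in base R with an im2col forward pass;
a finite-difference gradient check in the test suite pins the backward pass
to the forward pass at 10⁻⁵ relative tolerance.

## Rare-event statistics

With net sensitivity `p` (the product of detection and classification
sensitivities, e.g. 0.851 × 0.415 = 0.353), detecting an expected `x`
events requires `n = x/p` events in the sample; at 0.4–0.5 clusters/mL and
the 3 µL/min throughput of the 30 × 30 µm² channel (cross-section × flow
speed), one detection needs roughly 5.7–7.1 mL and 27–39 hours of
processing. Counting reproducibility is assessed with the coefficient of
variation: Poisson counting alone gives `%CV = 100/√µ`, and the
fixed-count subsampling procedure (take the event-stream prefix up to the
k-th ground-truth cluster, keeping all earlier NC events) yields replicate
counts whose observed %CV can be compared with theory; a volume-variability
term enters through the sum of variances
`σ²_{x+y} = σ²_x + σ²_y + 2·Cov(x, y)`, with the covariance term's sign
carried by the covariance itself. The volume term is estimated as the
empirical variance of per-replicate NC counts rescaled to the cluster rate,
since NC events are an internal proxy for processed volume. An ideal
detector run over Poisson replicates shows no excess variance (tested with
a variance-ratio test at α = 0.01) — the statistical statement that the
pipeline adds no variability beyond rare-event counting itself.

## The synthetic trace generator

No public BSFC recordings exist, so the package ships a simulator that
emulates the acquisition statistically and carries exact ground truth;
every stage of the pipeline is tested against it.

* **Baselines** are Gaussian with the nominal per-channel variances
  (0.169/0.452/0.511 V²); fluorescence channels use a 0.05 V baseline.
* **Transit physics.** An object of length L crossing the slit produces a
  pulse of base width (L + slit)/speed × rate samples. The pulse shape is a
  raised cosine with exponent 0.65, chosen once for two properties: the
  voltage pulse's own FWHM/base ratio is 0.78 (below the 0.75-derived gate
  arithmetic's conservative bound), and because the anomaly trace is
  approximately quadratic in the pulse, the measured T²-trace FWHM/base
  ratio is ≈ 0.60 — so a 26 µm two-cell cluster measures ≈ 20 samples
  (above the gate) while a 15 µm single cell measures ≈ 13 (below it),
  reproducing the intended single-cell/multicellular separation.
* **Events.** Poisson counts per kind: single cells (8–15 µm, default
  30/min), clusters (size classes 2 / 3–6 / 6+ cells mapped to 24–28 /
  30–55 / 55–80 µm, default 2/min, always with a co-located green pulse),
  optional wide autofluorescent confounders with no green signal (default
  off), and clots (default 2/h) as a low-frequency random-walk drift scaled
  to push the cumulative standard deviation past 1.75 V. Cluster peaks
  carry a 20% chance of a 30–50% amplitude shoulder, exercising the
  equalization path. Amplitudes are per-channel means (405 nm carrying the
  highest signal-to-background) with a common log-normal event factor;
  they are free parameters of the package — chosen once so the T²
  threshold of 10 separates events from baseline at realistic
  signal-to-noise — because no amplitude statistics are published for this
  instrument class.
* **Day effects** are a per-day multiplicative power factor on the scatter
  channels (default degenerate at 1; enabling it motivates the
  normalization step).

What the simulator deliberately does not model: red-blood-cell-resolved
scattering, optics and point-spread functions, flow-speed dispersion across
the channel cross-section, cluster orientation (a two-cell cluster tilted
along the flow axis shortens its transit length), and real-instrument
non-Gaussian noise. Passing tests therefore demonstrate algorithmic
correctness and statistical behaviour under the stated model, not
instrument-grade performance on real blood; the published real-data
figures (purity, net sensitivity, false-alarm rate on 34 days of
recordings) are not reproducible from synthetic data and are not claimed.

## Numerical and design choices

* Indices are 1-based with inclusive ranges throughout (documented in every
  exported CSV header); thresholds are strict (`> 1.75 V`, `> 3.06 V²`,
  `T² > 10`) except the width gate, which is inclusive at 17 because
  narrower-than-17 events are what gets removed.
* Rounding of derived integer thresholds is half-up (`floor(x + 0.5)`),
  not banker's; the gate derivation ceilings the 21.6-sample transit to 22
  before applying the 0.75 fraction, matching the conservative published
  arithmetic.
* A local maximum is strictly greater than both neighbours; an interior
  plateau counts once at its leftmost sample. FWHM crossings use sub-sample
  linear interpolation; an event whose half-maximum never crosses inside
  its range reports the range length with a flag.
* T² is computed per segment (centroid and covariance from that segment's
  own samples); two principal components are retained by default, and the
  all-components variant — exactly the squared Mahalanobis distance — is the
  oracle-checked mode. Zero-variance components are excluded with a
  warning.
* The green ground-truth channel is thresholded at 5 baseline standard
  deviations of the filtered channel (configurable). An amplitude threshold
  replaces T² there because T² is defined on the three-channel scatter set;
  5σ sits in the 3–5σ range of classical intensity thresholding and keeps
  ground-truth regions free of noise runs, which matters because labels
  inherit any ground-truth false positive.
* Whether z-scoring for features uses the whole recording or one segment is
  an open choice; the package z-scores per segment for locality. Evaluation
  re-scores events from features at every cascade stage rather than passing
  scores forward, and all stages share one decision threshold of 0.5.
* `make_splits` holds out a fixed test fraction of days, then draws each
  fold's validation days independently (about the reference 5-of-23
  fraction); at the reference 34-day scale every fold gets exactly 18
  training and 5 validation days. Fold validation sets are not forced to
  partition the non-test days — with 23 days and 5 folds of 5 they cannot.

## Problem sizes used in the shipped tests

The unit tests run on 5–30 s segments at the full 60 kHz (or a reduced rate
where only counting statistics matter). The end-to-end acceptance test
simulates ten 90 s acquisition days across a spike ladder of 2–16
clusters/min with harder, cluster-like confounders (8/min), trains a
two-stage cascade on six days with two validation days, and evaluates
detection recovery (≥ 95% of injected clusters), the zero-false-ROI
property on event-free segments, the detected-versus-true count correlation
(r > 0.9) and the cascade's monotone depth behaviour. The
coefficient-of-variation study uses 250 Poisson replicates at spike targets
{5, 10, 30, 50, 100}. These sizes were chosen as the smallest at which the
statistical assertions are stable.

## Known limitations

* The cascade's depth trade-off is reproduced directionally, not at the
  published operating points, which are bound to unreleased instrument
  data.
* The T² threshold of 10 is treated as an absolute dimensionless constant,
  as published; no per-segment recalibration procedure is defined.
* Training is CPU-only and desk-scale by design; the base-R CNN is
  adequate for hundreds to thousands of 297-point events, not for
  million-event corpora.
* The superseded variance-threshold ROI detector from earlier work is not
  a supported path; only the anomaly-trace detector is implemented.
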