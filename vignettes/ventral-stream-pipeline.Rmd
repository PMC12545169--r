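---
title: "Models and methods of the ventral-stream analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the ventral-stream analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vstream)
```

This vignette documents the statistical models behind each stage of the
pipeline, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and
the numerical conventions adopted where the procedures admit more than
one reading.

## Geometry and windows

All positions are in degrees of visual field on a monitor subtending
±54° azimuth × ±38° elevation, screen centre at (0, 0), azimuth positive
rightward, elevation positive upward. Stimuli are presented at 3 Hz
(167 ms image, 167 ms grey screen); sparse-noise frames last 100 ms.
The evoked-response window is 0–100 ms after onset and the baseline
window −50–0 ms; both are arguments everywhere they are used. The
baseline expectation is rescaled by the window-length ratio before
comparison.

## Responsiveness, stability, latency

A unit is responsive to a stimulus class when the mean evoked count
exceeds the baseline Poisson expectation λ̂ by at least 5 SD, with the SD
of a mean of N Poisson windows taken as √(λ̂/N). A subtlety worth
recording: because λ̂ is estimated from the same N trials, the null
variance of (mean evoked − λ̂) is about 3λ/N rather than λ/N, so the
realized false-positive rate of the 5-SD rule under a pure Poisson null
is ≈ 0.2–0.5 %, not the 5-SD Gaussian tail. That is still far below any
plausible signal and is verified by Monte-Carlo calibration in the test
suite. Silent units floor λ̂ at 0.5/N so the statistic is always finite.

The stability filter for long blocked runs follows the amplitude rule:
per block, the waveform amplitude is the mean per-spike amplitude (a
deliberate proxy — sorted outputs rarely ship full waveforms, so the
peak-to-peak amplitude of the mean waveform is approximated by the mean
spike amplitude); the threshold is 0.6 × the third-largest per-block
amplitude; blocks whose suprathreshold spike count falls more than 2 SD
below the across-block mean are excluded. With fewer than three blocks
the third-largest amplitude does not exist and the filter is skipped
with a warning.

Half-peak latency uses a 5-ms, unsmoothed PSTH of trial-summed counts
(bin width configurable; no standard value exists, and
5 ms resolves the 30–100 ms latencies of interest without starving the
bins). The peak must exceed the 99.75th percentile of the Poisson count
predicted from baseline; the latency is the left edge of the first bin
at or above (r_baseline + r_peak)/2. Note that the peak test is a
maximum over ~50 bins, so its family-wise null rate is 1 − 0.9975⁵⁰ ≈
12 %, not 0.25 % — the tests calibrate it against the correct bound. The
percentile is applied to the trial-summed count (the per-trial-mean
convention differs only through the Poisson quantile's discreteness).

## Receptive fields

ON and OFF histograms are accumulated independently from white-dot and
black-dot frames. Because every frame shows one dot per scheduling cell
(12 dots), each spike in the response window credits *all* dot locations
of its frame; the pseudo-random decorrelated placement cancels the
off-field credits in the average, which is the design rationale of the
stimulus itself. The response window for crediting defaults to
50–150 ms after frame onset, covering the 30–100 ms latency range plus
the 100-ms frame.

The per-location mean count is fitted with a circular 2D Gaussian plus
constant baseline by bounded Levenberg–Marquardt (σ ∈ [1°, 40°], centre
within the monitor + 10°), multi-started from the three largest
histogram peaks. Quality is Q = (O − E)/√E over locations within 10° of
the fitted centre, with E the fitted baseline times the presentations
there; Q > 5 declares a field. RF size defaults to the FWHM diameter
2√(2 ln 2)·σ (the size convention is not standardized; "2σ" is
available).

The placement lattice defaults to 32 × 18 = 576 candidate positions
inside the 4 × 3 scheduling grid — 576 locations spaced ~3.4° × 4.2°
across the monitor — and is configurable; all downstream fits are
lattice-agnostic.

## Tuning and texture

Orientation tuning is the modified Von Mises curve
R(θ) = B + A·exp(κ(cos 2(θ − θ_pref) − 1)) with 0–180° as the full
period; spatial-frequency tuning is Gaussian in log frequency. Both are
bounded least-squares fits multi-started at every tested level; a cell
counts as tuned when the fitted amplitude is at least half its mean
grating-evoked rate. Spatial-frequency peaks landing on the tested range
edge (monotone cells) are clamped and flagged `unbounded`. Orientation
errors are always measured circularly modulo 180°.

Variance explained by a categorical variable is
100·(V_total − V_residual)/V_total with *population* variances (divide
by n) for both terms, so the ratio is invariant to affine response
transforms; the n-vs-(n−1) choice is not dictated by the formula and is
recorded here once. Area scope sums total and residual variances across
cells before normalizing — the percentage of all variance in the area,
not the mean of per-cell percentages.

Texture-versus-noise divergence compares, per 10-ms bin, each cell's
mean response to textures against its spectrally matched noise partners
with a paired two-tailed t-test across cells; the divergence latency is
the first bin below α = 0.01 with no multiplicity correction (matching
the per-bin convention of the source analyses). An optional
`consecutive` argument requires a run of significant bins; the package's
own recovery tests use `consecutive = 3` because with ~25 independent
bins a single per-bin α = 0.01 hit occurs in roughly one run in five
under the null.

## The axis model

The preferred axis is operationalized as the unit-normalized OLS
coefficient vector of per-image mean responses on the 50 PC scores —
the unique direction whose 1-D linear projection maximizes explained
variance. Scores are kept in eigenvalue scale (not whitened; a whitening
toggle would change the estimand, not just the estimator). Estimation is
10-fold cross-validated over images; fold axes are sign-aligned to fold
1 (ties toward a positive first coordinate) and averaged, and every
image's projection comes from the fold that excluded it. `ev_cv` is the
squared Pearson correlation between held-out projections and responses.
Rank-deficient folds fall back to ridge with penalty 1e−6 × trace(XᵀX).

Split-half reliability uses the odd/even repeat split by default
(deterministic; a seeded random split is available) and the
Spearman–Brown correction 2ρ/(1+ρ), clamped to [0, 1] with the raw value
retained. Whether per-image responses are baseline-subtracted before
axis fitting is left as a toggle; raw window counts are the default.

Tuning curves rescale projections so the 1st and 99th nearest-rank
percentiles map to −1 and +1 ([−1, 1] then covers 98 % of stimuli up to
rank discreteness), use 16 equal-width bins, and report empty bins as
missing. The principal orthogonal axis is the first PC direction
projected off the preferred axis; when the two are numerically parallel
the second PC is used. Flat tuning along this control axis is an
*isotropy-dependent* prediction: with strongly anisotropic score
covariance, Euclidean orthogonality does not imply decorrelation, which
is why the generator's recovery tests use near-isotropic scores for that
specific property.

A practical accuracy note: the OLS axis error per component scales like
σ²/(n·λ_j), so recovery degrades along trailing PCs when the eigenvalue
spectrum is steep. The recovery suite uses a mild geometric spectrum
(ratio 0.97 per component over 50 PCs, ~1593 images), under which a
cosine similarity above 0.9 is attainable at split-half reliability
around 0.5.

## Decoding and reconstruction

PC decoding repeatedly samples 100 cells without replacement, regresses
each PC on the sampled response matrix with 10-fold cross-validation
over images, and reports held-out R² (capped at 1 by construction;
negative values are reported raw — they are informative about
overfitting, whose expected size is ≈ −n_cells/n_train under the null).
Reconstruction maps decoded scores back to feature space through the
pseudoinverse of the orthonormal loading matrix (= its transpose), then
retrieves the nearest auxiliary image by Euclidean distance in full
feature space, ties broken toward the lowest image id.

The normalized decoding distance divides |v_recon − v_original| by
|v_best − v_original| where v_best is the auxiliary vector nearest to
the *original* — the reading of "best possible reconstruction" as the
best achievable retrieval; the alternative (nearest to the decoded
vector) is exposed via `best_by = "recon"` since the phrase admits both.
Distances are computed in full feature space, matching the defining
equation. The score is 1 when retrieval is as good as the bank allows
and 0 under perfect decoding; banks must be disjoint from the presented
set or the denominator vanishes (an error instructs accordingly).
Reconstruction summaries use cross-validated held-out predictions for
every image. Synthetic runs default to auxiliary banks of a few hundred
to a few thousand images; the real-data analogue uses ~16k.

## Selectivity, identity, invariance

Face selectivity is the Welch t score across per-image mean responses
(faces vs everything else) plus the FSI; t > 5 flags face cells, t ≥ 15
highly selective ones. Identity decoding trains per-class independent
Gaussians (variance floored at 1e−6 to avoid degenerate zero-variance
classes) on all but one repeat per image and classifies the held-out
repeat, resampling neurons and train/test splits; the reference protocol
is 500 × 200 resamples, and reduced counts (20 × 20) are used in tests
where only calibration, not precision, matters. Reports always carry
n_classes next to accuracy because 100-class and 201-class variants are
both in circulation; the default is 201 with chance 1/201. The
view-invariance index averages Pearson correlations between frontal and
non-frontal population vectors over views, then identities, skipping
constant vectors.

The 13 low-level indices (documented set v1: mean luminance, RMS and
Michelson contrast, foreground area/perimeter/compactness, bounding-box
aspect ratio, centroid x/y, spectral centroid and bandwidth, orientation
anisotropy, edge density) are package-defined — the canonical set is not
enumerated anywhere authoritative — and versioned so replacements are
auditable. The RF-windowed control weights image pixels by the fitted
Gaussian RF profile with the image covering 20° centred on the RF.

## What the generator emulates, and what it does not

The generator reproduces the *statistical structure* the analyses
assume: Poisson spiking with per-unit baseline and latency; circular
Gaussian ON/OFF receptive fields on the sparse-noise lattice; Von Mises
× log-Gaussian grating tuning; a rectified-ramp axis drive in the
feature principal subspace (the ramp's rectification is configurable to
linear — the shape of axis tuning is reported, not assumed, by the
analyses); a texture-versus-noise offset with per-family weights; and
slow multiplicative waveform-amplitude drift across blocks. Image banks
are procedural: texture families share oriented band-pass Fourier
recipes with cross-scale phase alignment; noise partners are exact
phase-scrambles (amplitude spectra preserved to machine precision, with
a shared affine normalization per pair); faces are a distinct oval +
parts recipe so that face clustering in feature space — and hence face
selectivity — is *emergent*, not injected into labels.

It does not emulate photorealistic texture statistics, eye movements,
adaptation, correlated (non-Poisson) spiking, or cross-neuron noise
correlations. Passing recovery and calibration tests therefore shows
the estimators are correct and calibrated under the stated model — not
that real cortex satisfies the model. The feature extractor is a
deterministic Gabor + seeded-random-readout stack with layer-wise
pooling (receptive fields doubling per layer), not a trained network; a
trained DNN can be plugged in through `extractor_fun` without touching
any analysis code.

## Problem sizes and determinism

Every generator and resampling routine takes an explicit seed and is
bit-reproducible; `run_pipeline()` derives per-stage seeds from one
master seed, and identical configs yield byte-identical artifacts. The
shipped tests and the acceptance script run on deliberately moderate
problem sizes — e.g. 60-run recovery batches, 1000-unit null
calibrations, 20 × 20 decoding resamples, 32-px image rasters — chosen
so the full suite completes in about a minute while keeping Monte-Carlo
margins well inside the asserted tolerances; all sizes are arguments, so
full-scale runs (1,593 images × 10 repeats, 500 × 200 resamples,
4096-D features) use the same code paths.

## Known limitations

- The spike-crediting scheme for sparse noise relies on decorrelated dot
  placement; with few frames the off-field credits raise the fitted
  baseline and shrink the apparent σ slightly.
- Held-out R² in decoding is biased downward by overfitting when the
  sampled population is large relative to the image count; warnings are
  emitted when images < 2 × cells.
- The divergence latency inherits the per-bin α convention: without the
  `consecutive` option it has a ~20 % family-wise false-alarm rate over
  a 250-ms window under the null.
- GNB identity decoding assumes conditional independence across units;
  correlated noise (not simulated) would change absolute accuracies,
  though not the chance calibration.
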