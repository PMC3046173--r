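---
title: "HRV features and risk classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRV features and risk classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `hrvrisk`: the models each
stage assumes, the tunable parameters and their defaults, the numerical
conventions the tests rely on, and the design choices made where several
defensible options existed. It states no empirical numbers beyond what
the package's test suite and `scripts/acceptance.R` themselves compute.

## The signal model

Heart period data enter as an ordered series of normal-to-normal (NN)
intervals in milliseconds. Autonomic control imprints two oscillations on
this series: a low-frequency (LF, ~0.1 Hz) component associated with
baroreflex/sympathetic dynamics, and a high-frequency (HF) component at
the breathing rate — respiratory sinus arrhythmia, ~0.2 Hz at the
12 breaths/min protocol rate. Cardiovascular risk expresses itself
predominantly as *reduced* variability (occasionally as erratic,
excessive variability). Every stage below either recovers the NN series
from raw ECG, cleans it, or condenses it into features sensitive to that
signature.

## R-peak detection

`detect_r_peaks()` combines a wavelet detail pre-filter with the
Pan-Tompkins detector. The combination is deliberately sequential: the
ECG is decomposed with the Haar wavelet to `level` (default 4) and
reconstructed from the detail coefficients only. Discarding the deepest
approximation removes baseline wander and very-low-frequency drift while
keeping QRS energy; shallower levels keep more high-frequency noise bands,
which is why false positives fall as the level grows — the behavior the
level sweep in the test suite exercises. The reconstruction feeds the
classic Pan-Tompkins chain:

* zero-phase Butterworth band-pass, 5–15 Hz (QRS energy band), order 2;
* centered five-point derivative, squaring;
* 150 ms moving-window integration (centered, so no group delay);
* adaptive dual threshold on the integrated signal with a 200 ms
  refractory period, exponential signal/noise level tracking, and a
  search-back pass at half threshold when a gap exceeds 1.66× the running
  RR average;
* refinement of each fiducial to the raw-signal extremum within ±50 ms.

Sampling rates below 40 Hz cannot support the band-pass and are rejected.
Detection is scored by greedy one-to-one matching within ±50 ms (a
conventional beat-matching window; none is prescribed by the protocol),
with sensitivity `Se = 100·TP/(TP+FN)` and accuracy
`Ac = 100·TP/(TP+FN+FP)`.

## Ectopic-interval removal

Isolated ectopic beats produce extreme intervals that corrupt every
downstream feature; removing them outright is preferred to interpolation,
which manufactures spurious regularity. `rosner_filter()` implements the
generalized extreme studentized deviate (ESD) procedure: iteratively
remove the most extreme point (largest `|x − x̄|/s`, sample-sd
convention, which is what the published critical values assume), and
compare each statistic against
`λ_i = (n_i − 1) t_{1−α/(2 n_i), n_i−2} / sqrt((n_i − 2 + t²) n_i)`,
`n_i = n − i + 1`. The declared outlier count is the *largest* step whose
statistic exceeds its critical value — this look-ahead is what makes the
procedure robust to masking. Defaults: `alpha = 0.05` and
`k_max = ceiling(0.05 n)`, a conservative ectopic-rate budget for sinus
rhythm records; both are configurable. A zero-dispersion sample stops the
iteration (the statistic is undefined; nothing is removed). Because the
statistic and removal order depend only on values, the declared set is
invariant under permutations of the input, and shrinking `alpha` can only
shrink the declared set.

## Time-domain indexes

Seven classical short-term statistics (`time_domain_features()`): meanNN,
SDNN (sample sd), RMSSD, pNN50, MIRR (Q3 − Q1), MDARR (median absolute
successive difference) and SDSD (sample sd of successive differences).
Two conventions worth stating explicitly:

* **pNN50** counts successive differences *strictly* greater than 50 ms
  and divides by the number of successive differences (N − 1), the
  Task-Force convention, even though "divided by the total of all NN
  intervals" is sometimes written; with hundreds of beats the two differ
  negligibly, but the convention is fixed for determinism.
* **Quartiles** use linear interpolation of the empirical CDF
  (`quantile` type 7), one of several common definitions, fixed so MIRR
  is reproducible.

These indexes obey exact invariances — dispersion measures are unchanged
by adding a constant and scale linearly with the data — which the suite
checks as properties.

## Spectral analysis

The NN series is an irregularly sampled point process, so
`resample_rr()` first interpolates it onto an even 4 Hz grid with a cubic
spline (4 Hz is comfortably above twice the 0.4 Hz band edge).
`detrend_sp()` then removes the slow trend by regularized least squares
with a second-difference penalty (`trend = (I + λ² D₂ᵀD₂)⁻¹ z`); the
smoother's frequency response is a high-pass whose cutoff is set by `λ`,
and the default `λ = 500` at 4 Hz attenuates essentially everything below
~0.04 Hz while passing the 0.1 Hz LF oscillation nearly unchanged — the
properties the test suite measures on ramps and sinusoids. The penalty
formulation is solved sparsely (banded system), so detrending a 5-minute
tachogram is effectively free.

`ar_psd()` fits an AR(16) model by the covariance (least-squares) method:
regress `x_t` on its `p` predecessors over all fully interior windows.
Parametric estimation is the right tool for 300-sample records, where the
periodogram's variance is prohibitive; the periodogram appears only as a
test oracle (the AR spectrum's integral must match the signal variance).
The one-sided spectrum is evaluated on 1024 grid points as

    P(f) = 2 σ² / fs / |1 + Σ_k a_k e^(−i 2π f k / fs)|²,

with σ² the innovation (residual) variance. The normalization is chosen so
that the integral over `[0, fs/2]` approximates the series variance; order
16 is the conventional compromise between resolution of the three HRV
bands and variance of the estimate for ~1200-sample tachograms.

`band_powers()` integrates by trapezoid over VLF `[0, 0.04]`, LF
`[0.04, 0.15]` and HF `[0.15, 0.4]` Hz with the edge values interpolated
onto both adjacent bands, so the three band powers add *exactly* to the
total integral over `[0, 0.4]`. Normalized powers exclude VLF:
`NLF = 100·LF/(LF+HF)`, `NHF = 100 − NLF` (sums to 100 by construction);
`LF/HF` indexes sympathovagal balance and is reported missing when HF is
zero.

## Wavelet-packet features

`wp_features()` grows the full wavelet-packet tree of the mean-subtracted
NN series to level 5 with the Daubechies-4 (8-tap) filter pair — 62 nodes
over levels 1..5, 32 leaves. Per node it emits the mean coefficient
energy and the Shannon entropy of the node's normalized coefficient
energies (`0·log 0 ≡ 0`, natural logarithm; the base only rescales).
Numerical conventions that matter:

* **Periodic extension, zero-padded.** The series is zero-padded to a
  multiple of 2⁵ before analysis. Zero padding leaves the squared norm
  unchanged, and an even length at every split keeps the periodized
  orthogonal transform exactly energy-preserving — which turns energy
  conservation per level into a sharp (1e−6 relative) test of the filter
  bank rather than an approximate one.
* **Aggregation granularity.** Energy and entropy are computed per node
  (per "group of coefficients"), giving 124 named features
  `wpE_L{level}N{index}` / `wpS_L{level}N{index}` in natural filter-bank
  order.
* **Input domain.** The transform runs on the raw (index-domain) NN
  series, not the resampled tachogram; the beat index is the natural
  sampling of the process and resampling would smear energy across
  nodes. No wavelet package ships in this package's dependency set, so
  the periodized filter bank is implemented here and validated by the
  orthogonality/energy tests.

Because adjacent nodes carry redundant information, `fit_pca()` /
`pca_project()` offer a centered covariance PCA of the wavelet block with
a deterministic sign convention (largest-magnitude loading positive) and
components sorted by explained variance. Both the per-node and the
projected representations are exposed; the default pipeline screens the
per-node features directly, since projection mixes features and tends to
dilute per-feature statistical significance.

## Nonlinear features

The Poincaré map plots each interval against its successor. After the
π/4 rotation `u = (x_{n+1} + x_n)/√2`, `v = (x_{n+1} − x_n)/√2`, SD1
(population sd of `v`) captures beat-to-beat dispersion and SD2
(population sd of `u`) long-range dispersion. The population-sd
convention is deliberate: it makes `SD1² = ½·SDSD_pop²` exact, and
`SD2² = 2·SDNN_lag² − ½·SDSD_pop²` exact when `SDNN_lag²` is the mean of
the population variances of the two lagged coordinate sets (for the usual
full-series SDNN the identity holds only to O(1/n)). The three histogram
widths (NN intervals, `v`, `u`) are ranges rounded up to a whole number
of bins of width 7.8125 ms = 1/128 s, the conventional HRV histogram
resolution.

Approximate entropy (`apen()`) is the Pincus statistic
`Φ^m − Φ^{m+1}` with Chebyshev template distance and self-matches
included; sample entropy (`smen()`) is the Richman–Moorman estimator
`−log(A/B)` over the first `n − m` template positions with self-matches
excluded. Tolerance defaults to `r = 0.2·SD` — the upper end of the
recommended 0.1–0.2 range, which stabilizes match counts on ~350-beat
records — and the embedding sweep `m = 1..4` is emitted as eight features.
At `m = 4` on 5-minute data SmEn can run out of template matches; the
value is then reported as missing (with a warning), not as an error, and
downstream selection treats such features as unselectable. Both measures
are exactly invariant to shifting the data and, because `r` tracks the
SD, to rescaling it.

## Feature screening

HRV features are grossly non-Gaussian (the package's normality screen —
Pearson chi-square against a fitted Normal with equal-probability bins of
expected count ≥ 5, plus a one-sample KS test — demonstrates this on real
features), so group comparison uses the distribution-free two-sample KS
test: `D = sup |ECDF_N − ECDF_R|`, p-value from the asymptotic Kolmogorov
distribution at effective size `n_a n_b/(n_a + n_b)`. Exact small-sample
p-values are unnecessary at 45 records per group. Two thresholds are
used: `alpha_significant = 0.05` for reporting and a stricter
`alpha_select = 0.01` for admission to the classifier pool. No
multiple-testing correction is applied — the screen is a ranking device,
not an inferential claim — though that choice is stated rather than
hidden.

MinMax normalization maps each feature through bounds learned on the
*training split only*; normalizing before splitting leaks test
information, so the leak-free protocol is the default and the
all-samples variant exists only as an explicit compatibility choice.

## Classifiers and evaluation

All three schemes consume the top-k KS-ranked, MinMax-normalized
features, with cardiovascular risk as the positive class and a 0.5
decision threshold (0 for the SVM margin).

* **MLP** (default 5–200–1): tanh hidden units and a logistic output
  (which pins outputs to (0, 1)), trained by Levenberg–Marquardt on the
  squared error. The damped step is solved through the SVD of the
  Jacobian, which costs O(n²p) rather than O(p³) — the training sets here
  have n ≈ 48 rows against p ≈ 1400 weights, so this is the difference
  between milliseconds and seconds per iteration. Up to 200 iterations,
  early stopping on a stratified 20% validation holdout after 6
  non-improving checks, two random restarts; everything is a
  deterministic function of the seed.
* **RBF network** (default 5–3–1): k-means positions the hidden centers
  (run to stabilization); each unit's Gaussian width is its influence
  radius, realized as the distance to the nearest other center (a mean
  pairwise alternative sits behind `width_rule`); the linear output layer
  is ordinary least squares. Empty clusters are re-seeded from the
  farthest points.
* **SVM**: libsvm soft-margin machines with linear, polynomial and RBF
  kernels. The linear machine defaults to `C = 1`; for the nonlinear
  kernels the "heuristic" parameter choice is made concrete as a small
  grid (`C ∈ {0.1, 1, 10, 100}` × degree `{2, 3}` or γ
  `{0.01, 0.1, 1}`) scored by stratified 3-fold CV on the training split.
  The support-vector count is reported.

Evaluation follows the stratified 2/3–1/3 protocol: a balanced 45+45
cohort gives 30+30 training and 15+15 test records. `cross_validate()`
runs one split per repeat (the single-random-split protocol), with
repeats available for mean ± sd reporting; both selection and
normalization are re-fitted inside each training split. Reports carry the
confusion matrix, Se/Sp/Pp/Np/Ac, the ROC curve from a full threshold
sweep, and the AUC — which equals the normalized Mann–Whitney U
statistic, an identity the tests verify against an independent rank-based
oracle. Inside `cross_validate()` the selection threshold defaults to 1
(pure top-k ranking): the protocol must be able to fit a model even when
no feature is individually significant — the null-cohort calibration
depends on it — while the standalone `select_features()` keeps the
stricter 0.01 default.

## The synthetic cohort: what it does and does not emulate

`generate_rr()` samples
`RR_n = base + A_LF sin(2π·0.1·t_n + φ₁) + A_HF sin(2π·0.2·t_n + φ₂) + ε_n`
at the cumulative beat times, clipped to the physiological 300–2000 ms.
Defaults — base 850 ms, LF 30 ms, HF 20 ms (RSA at 12 breaths/min), noise
SD 12 ms, 300 s — place the normal class at ~71 bpm with SDNN in the
normal short-term range and an LF-dominant spectrum. The risk class
multiplies both amplitudes and the noise by `risk_scaling = 0.5` by
default (reduced variability); the `"excessive"` mode instead inflates
noise and injects ectopic-like halved/doubled intervals, exercising the
ESD filter. Per-record seeds are `seed + record index`, so cohorts are
bit-reproducible. `generate_ecg()` renders a Gaussian-bump PQRST template
at beat times snapped to the sample grid (default 250 Hz — a realistic
clinical rate; extreme oversampling adds nothing at these wavelet levels)
and returns exact apex indices, plus optional noise, 0.3 Hz baseline
wander and a sinusoidal respiration channel.

What the generator does *not* model: true 1/f fractal scaling,
nonstationary autonomic shifts within a record, arrhythmic morphology,
realistic ECG noise (muscle artifact, electrode motion), or inter-subject
covariance structure between features. Passing the recovery experiments
therefore demonstrates that the pipeline's machinery is correct and
sensitive to the planted effect — not that the classifiers would reach
comparable accuracy on clinical data, where class overlap is far larger.
With the default effect size (`risk_scaling = 0.5`) the classes are
widely separated by construction, and near-ceiling held-out accuracy is
the *expected* outcome of a correct implementation.

## Breathing-rate validity check

Because RSA moves with breathing frequency, comparisons across records
assume a steady rate near the 12 breaths/min protocol figure.
`breathing_check()` takes the dominant spectral frequency of the
respiration channel within 0.05–0.7 Hz; a record is valid when the rate
is within ±3 breaths/min of target and its 60-s windowed rate has
SD ≤ 2 breaths/min ("relatively constant" made concrete — the protocol
itself quantifies neither). Invalid records are flagged advisory-only;
they are never silently excluded, since validity concerns
interpretation, not computability.

## Problem sizes and numerical tolerances

The test suite and acceptance script choose problem sizes that keep every
statement sharp at desk scale: 60-s ECG records for the detection
round-trip (the detector's behavior is rate- and morphology-driven, not
duration-driven), full 300-s records for cohort experiments, 5–10 seeded
cohorts per recovery claim, and 200 label shuffles for the type-I
calibration. Exact-identity checks (entropies vs brute-force counting,
KS vs ECDF scan, AUC vs rank statistic) are asserted at 1e−12 or bitwise;
linear-algebra identities (energy conservation, PCA orthonormality,
SD1/SD2) at 1e−6 to 1e−9 relative; stochastic calibrations at the widths
their sampling variance dictates (e.g. ±50% relative on a 0.05 type-I
rate over 200 shuffles). The KS calibration is checked at the 0.05
reporting level: at 45-per-group effective sample sizes the asymptotic
p-value is mildly conservative, and at 0.01 the expected count of
selections per shuffle (~0.5) would make a ±50% band mostly a test of
shot noise.

## Known limitations

* The AR covariance method does not guarantee a stable all-pole model;
  gross instability surfaces as a conditioning error naming the record
  rather than silently corrupted band powers.
* The asymptotic KS p-value is conservative below ~20 effective samples;
  selection *ranks* are unaffected, which is what the pipeline consumes.
* SmEn at m = 4 is frequently undefined on 5-minute records — an honest
  property of the estimator at this data length, handled as a missing
  value.
* The MLP's LM trainer fits interpolating networks (p ≫ n) by design;
  its generalization on real cohorts should be controlled through the
  validation holdout and feature count, not taken from the synthetic
  ceiling.
* `read_ecg()` handles delimited text only; vendor binary formats and
  WFDB/EDF are out of scope.
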