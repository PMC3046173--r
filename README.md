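# hrvrisk

Short-term heart rate variability (HRV) analysis for cardiovascular risk
screening: an R implementation of the full chain from raw single-lead ECG
to a binary normal-vs-risk prognosis.

Reduced (or grossly distorted) beat-to-beat variability of the
normal-to-normal (NN) heartbeat intervals is a well-established marker of
cardiovascular risk. `hrvrisk` turns a 5-minute ECG or NN series into a
risk call in five stages:

1. **R-peak detection** — the ECG is reconstructed from its Haar wavelet
   detail coefficients at levels 1..4 (dropping the lowpass branch that
   carries baseline wander) and passed to the Pan-Tompkins algorithm
   (5–15 Hz band-pass, derivative, squaring, 150 ms moving-window
   integration, adaptive dual threshold with 200 ms refractory period and
   search-back), with a final ±50 ms refinement to the raw-signal
   extremum.
2. **Ectopic-interval removal** — the generalized extreme studentized
   deviate (Rosner) test iteratively removes up to `k_max` outlying
   intervals, comparing each statistic `R_i = max |x − x̄|/s` against its
   t-distribution critical value.
3. **Feature extraction**, four families (150 features):
   * *statistical*: meanNN, SDNN, RMSSD, pNN50, MIRR (interquartile
     range), MDARR (median absolute successive difference), SDSD;
   * *spectral*: the tachogram is cubic-spline resampled at 4 Hz,
     detrended with a smoothness-priors smoother, modeled as an AR(16)
     process fitted by the covariance (least-squares) method, and
     integrated over VLF (0–0.04 Hz), LF (0.04–0.15 Hz) and HF
     (0.15–0.4 Hz), with normalized powers NLF/NHF and the LF/HF ratio;
   * *wavelet-packet*: full DB4 tree to level 5 (62 nodes), per-node mean
     coefficient energy and Shannon entropy of the normalized coefficient
     energies, with an optional PCA compression of the block;
   * *nonlinear*: Poincaré-map SD1/SD2 and the three histogram widths,
     plus approximate and sample entropy for embedding lengths m = 1..4
     at tolerance r = 0.2·SD.
4. **Feature screening** — per-feature two-sample Kolmogorov–Smirnov tests
   between the groups, ranked by p-value (plus chi-square / one-sample KS
   normality checks that motivate the distribution-free screen).
5. **Classification** — a 5–200–1 multilayer perceptron trained by
   Levenberg–Marquardt least squares, a 5–3–1 RBF network (k-means
   centers, nearest-center influence radii, least-squares output), and
   linear/polynomial/RBF soft-margin SVMs, evaluated on stratified
   2/3–1/3 splits with training-split MinMax normalization, reported as
   Se/Sp/Pp/Np/Ac, ROC and AUC.

Because no public ECG database accompanies this design, the package ships
a first-class synthetic cohort generator: 5-minute NN series with a
0.1 Hz low-frequency oscillation, respiratory sinus arrhythmia at 0.2 Hz
(12 breaths/min), Gaussian beat-to-beat noise, and a risk class whose
variability is scaled down (or, alternatively, inflated with ectopic-like
spikes). A matching PQRST ECG synthesizer returns exact ground-truth
R-peak positions. A respiration channel, when present, is screened for a
steady ~12 breaths/min rate; off-protocol records are flagged advisory,
never silently dropped.

## Worked example

```r
library(hrvrisk)

rr <- generate_rr(seed = 1)          # one synthetic 5-minute NN series
rr
#> <rr_series 'synthetic': 353 intervals, mean 849.9 ms>

feats <- extract_features(rr)        # all four families, 150 features
round(feats[c("meanNN", "SDNN", "RMSSD", "pNN50", "NLF", "LFHF",
              "SD1", "SD2", "ApEn_m2", "SmEn_m2")], 3)
#>  meanNN    SDNN   RMSSD   pNN50     NLF    LFHF     SD1     SD2 ApEn_m2 SmEn_m2
#> 849.920  27.778  24.870   0.043  67.808   2.106  17.585  34.963   1.208   1.813
```

The mean interval of ~850 ms is a resting heart rate of ~71 bpm; SDNN
~28 ms is normal short-term variability; NLF ≈ 68 with LF/HF ≈ 2.1 says
most oscillatory power sits in the low-frequency band, as built into the
generator (LF amplitude 30 ms vs HF 20 ms).

The full two-class experiment — 45 normal + 45 risk records, risk
variability halved:

```r
cohort <- generate_cohort(cohort_spec(n_per_class = 45,
                                      risk_scaling = 0.5, seed = 1))
tab <- cohort_features(cohort)       # Rosner cleaning + extraction
select_features(tab, alpha_select = 0.01, top_k = 5)
#> <selection_report: 150 features tested, 5 selected at p < 0.01>
#>    SDNN, RMSSD, pNN50, MIRR, MDARR

cross_validate(tab, scheme = "mlp", top_k = 5, seed = 1, repeats = 3)
#> <cv_result: mlp, 3 repeat(s)>
#>   metric mean sd
#> 1     Se  100  0
#> 2     Sp  100  0
#> ...
#> 6    AUC    1  0
```

The KS screen puts the dispersion indexes at the top — exactly the
quantities the risk class perturbs — and with the default effect size the
held-out 15+15 test records are classified perfectly.

A thin command-line front end wraps the same functions:

```sh
hrvrisk detect --ecg rec.csv --fs 250 --level 4 --out rr.txt
hrvrisk clean  --rr rr.txt --alpha 0.05 --out nn.txt --report esd.json
hrvrisk synth  --n 45 --risk-scaling 0.5 --seed 1 --out cohort/
hrvrisk run    --config cfg.yaml
```

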