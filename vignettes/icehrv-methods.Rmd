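---
title: "Methods: frequency-domain HRV and longitudinal inference in icehrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-domain HRV and longitudinal inference in icehrv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icehrv)
```

## What the package computes

`icehrv` analyses the time course of cardiac autonomic modulation in small
longitudinal cohorts measured repeatedly under isolation and confinement —
the motivating setting is an Antarctic overwintering crew of 25 subjects
(15 men, 10 women) recorded supine for 10 minutes once before departure
(baseline) and monthly from February to October. The pipeline has four
stages, each usable on its own:

1. **NN preprocessing** (`preprocess_rr()`): raw beat-to-beat RR intervals
   are screened for premature beats and artifacts, edited, and whole
   series are discarded when editing touches more than 5% of beats.
2. **Spectral indices** (`compute_indices()`): Welch-periodogram band
   powers (VLF 0–0.04, LF 0.04–0.15, HF 0.15–0.40 Hz), normalized units,
   the LF/HF ratio, base-10 log transforms, mean HR, and the HF peak
   frequency.
3. **Outlier screening** (`screen_outliers()`): per-subject Tukey fences
   on the monthly log HF values; flagged recordings are removed entirely.
4. **Longitudinal inference** (`hrv_lmm()` and its contrast functions):
   a REML random-intercept mixed model per HRV index with pre-planned
   polynomial and trimester contrasts under Satterthwaite degrees of
   freedom.

## Beat editing as a reproducible algorithm

Manual, visual beat editing is not reproducible, so the package replaces
it with a local-median rule: beat $i$ is abnormal when
$|RR_i - m_i|/m_i > 0.20$, with $m_i$ the median of the 11-beat window
centred on $i$ (shrunk at the series edges). Both parameters are exposed
(`rel_threshold`, `window`); 20% deviation catches halved (premature) and
doubled (missed-beat) intervals while tolerating respiratory sinus
arrhythmia, and an 11-beat window keeps the local median insensitive to
bursts of up to five consecutive artifacts.

Flagged beats are *replaced* by cubic interpolation over beat index rather
than deleted: deletion would shift every later beat time and distort the
spectrum, while replacement keeps the tachogram's time base continuous.
The edited fraction feeds the discard rule, which is strict: a series is
discarded only when the fraction *exceeds* 5% — exactly 5% is retained.

## Spectral estimation

NN intervals are an unevenly sampled series, so the tachogram is
cubic-spline interpolated and resampled at 4 Hz (each interval attached to
the time of the beat that opens it) before Fourier analysis. The PSD is a
Welch estimate: 150-s Hann-tapered segments with 50% overlap, each
linearly detrended, one-sided and normalized so the integral over
frequency equals the analysed signal power. The 150-s segment gives a
frequency resolution of 1/150 ≈ 0.0067 Hz, comfortably separating the
0.04 Hz VLF/LF boundary; at 600 s this averages 7 segments. These choices
are conventional for short-term HRV; all of them are configurable because
commercial analysis software rarely documents its exact settings.

Band powers are trapezoidal integrals of the piecewise-linear PSD with
interpolated band edges, so the VLF/LF/HF bands tile 0–0.40 Hz without
double counting. **Total power is the band-limited integral over
0–0.40 Hz**, i.e. exactly VLF + LF + HF. This choice is forced by the
normalized-unit definitions
$$LF_{nu} = \frac{LF}{total - VLF} \times 100, \qquad
  HF_{nu} = \frac{HF}{total - VLF} \times 100,$$
which sum to 100 identically only under the band-limited total; it also
matches the band-limited convention of the common HRV analysis packages.
Log transforms are base 10, consistent with log HF values of ~2.5–2.8 for
HF powers of a few hundred ms². A spectrum with zero LF or HF power (e.g.
a constant series) raises a classed "degenerate spectrum" error rather
than producing silent -Inf logs; cohort batch processing flags such
sessions.

## Outlier screening

Vagal indices are sensitive to breathing irregularities and lack of a
steady state, and in-expedition recordings are self-administered, so each
subject's monthly log HF values (never the supervised baseline) are
screened once with Tukey fences: $Q_1 - 1.5\,IQR$ and $Q_3 + 1.5\,IQR$,
strict inequalities, quartiles by linear interpolation of order statistics
(R type 7; configurable, since Tukey's original hinges differ slightly at
n = 9). A flagged log HF removes the whole recording from every
downstream variable. Screening is single-pass: fences are not recomputed
after removals.

Two operating characteristics of this rule are worth knowing. First, with
only 9 values per subject the quartiles are noisy, and the per-value
false-positive rate for Gaussian data is about 4–5% — a scale-invariant
property of the fences, not of the data spread. Second, a genuine monthly
trend widens the within-subject spread, which widens the fences: under
the package's default study conditions a −1.5 log-unit shift is caught in
roughly four of five cases at a ~3% false-positive rate. The test suite
measures both numbers; they are properties of Tukey's method at n = 9,
not of the implementation.

## The longitudinal model

Each HRV index is analysed separately with the REML mixed model
$$y_{ij} = \mu + \text{month}_j + \text{sex}_i +
  (\text{month} \times \text{sex})_{ij} + \beta\,b_i + u_i +
  \varepsilon_{ij},$$
where $b_i$ is the subject's baseline value of the same index
(mean-centred internally; adjusted means are invariant to the centring)
and $u_i$ a subject random intercept — intercept only, deliberately, as
random slopes are not identifiable with 9 sessions per subject at this
cohort size. Month enters as a 9-level unordered factor (hence 8
numerator df for the Time effect); trend shapes are assessed afterwards
on the adjusted means, not by a continuous-time fit. Fitting is delegated
to `lme4`; unbalanced data from discarded or screened sessions are
handled by the likelihood, with no imputation.

### Satterthwaite degrees of freedom

Inference uses Satterthwaite's approximation, implemented in the
variance-component parameterization $\theta = (\sigma_b^2,
\sigma_e^2)$:
$$\nu(c) = \frac{2\,[c'V_\beta c]^2}{g'\,A\,g}, \qquad
  g_k = u'\frac{\partial V}{\partial\theta_k}u, \quad
  u = V^{-1}XV_\beta c,$$
with $A$ the inverse REML information
$\tfrac12\,\mathrm{tr}(P\,\partial_k V\,P\,\partial_l V)$. At a singular
fit ($\hat\sigma_b^2 = 0$) the intercept-variance direction is inactive
and the formula reduces to the ordinary-least-squares residual df, which
is also the behaviour of the standard mixed-model testing packages at the
boundary. Multi-df F tests diagonalize the term's covariance block, give
each component its own $\nu_m$, and combine them as
$df_2 = 2E/(E-q)$ with $E = \sum_m \nu_m/(\nu_m-2)$. The test suite
cross-checks both the 1-df and multi-df paths against independent
implementations.

### Contrasts and conventions

Adjusted means are model predictions per (month, sex) cell at the grand
mean of the baseline covariate. Pre-planned contrasts are computed on
these means:

* **Polynomial trends** use orthonormal (unit Euclidean norm)
  linear/quadratic/cubic coefficients over the 9 equally spaced months,
  so a reported linear estimate equals (slope per month) × √60. Published
  tables in this field often use unstated coefficient scalings; the
  orthonormal convention is recorded in the output metadata, and t, df
  and p are invariant to the scaling in any case.
* **Trimester contrasts** average the month means within T1 (Feb–Apr),
  T2 (May–Jul), T3 (Aug–Oct) and report earlier-minus-later differences
  (T1–T2, T2–T3, T1–T3), so a declining index gives positive T1–T3.
* **Sex differences** of any contrast are men minus women, uniformly.
  (Published tables sometimes flip this convention between tables; a
  single documented direction was chosen instead.)
* No multiplicity correction is applied, matching the pre-planned,
  exploratory character of the contrast set at two-sided α = 0.05.

Baseline sex comparisons use unpaired t tests; Welch's unequal-variance
form is the default (the pooled form is one flag away) because the two
sexes' baseline spreads differ noticeably at this cohort size.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions with known ground
truth. At the index level, each session's value is drawn from exactly the
mixed model above: per-sex intercepts (log HF 2.824/2.534 and log LF/HF
0.004/0.334 for women/men, HR 70.3/64.2 bpm — the baseline sex means of
the motivating cohort), per-sex month trends, subject intercept SD 0.3,
residual SD 0.2. Trends are specified as coefficients on the orthonormal
polynomial contrasts so the injected coefficient *is* the expected
contrast estimate; the defaults encode a linear log HF decline in both
sexes (−0.775, i.e. −0.10 per month) and a women-only log LF/HF rise
(linear +0.19, cubic −0.18, matching the t statistics of the motivating
study at this design size). Outlier sessions (3% rate, −1.5 log HF
shift) emulate out-of-steady-state recordings.

At the signal level the same targets are mapped to sinusoid amplitudes,
$A_{HF} = \sqrt{2 \cdot 10^{\log HF}}$ (and likewise for LF through
log LF = log LF/HF + log HF), and full RR series are generated by the
modulated-interval iteration $t_{k+1} = t_k + NN(t_k)/1000$ with 3 ms
beat noise, closing the loop through file IO, editing and the spectral
stage. The generator writes the same plain-text RR files and manifest
that `load_cohort()` reads, plus a ground-truth JSON sidecar.

What the generator does **not** emulate: real respiratory-frequency
drift and nonstationarity within a recording, 1/f-like broadband VLF
structure, circadian variation, mission/crew effects (supported as a
sensitivity option but off by default, as the analysis model omits them),
and correlated missingness. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
every feature of field recordings.

A note on the baseline covariate: by default the generated baseline
shares the subject's random intercept, as a repeated measurement of the
same physiology would. Conditioning on such a baseline shrinks the
*conditional* between-subject variance below the marginal 0.3² — this is
a property of the design, not a bug. Variance-recovery experiments
therefore set `baseline_from_intercept = FALSE`, making the fitted
conditional model coincide with the generating model.

## Numerical choices and degenerate inputs

* Quartiles: type 7; configurable 1–9.
* Welch normalization is checked against an exact per-segment Parseval
  reference carried on the estimate (`segment_power`).
* Spline resampling uses the classic cubic interpolation of R's
  `splinefun(method = "fmm")`; interpolation error for
  respiratory-band oscillations at ~1 s beat spacing is ≈1–2 ms in the
  interior and up to ~5 ms in the first/last two seconds (edge
  extrapolation), negligible against typical HF amplitudes.
* Editing a series in which every beat is flagged, resampling fewer than
  4 beats, Welch on less than one segment, zero LF/HF power, missing
  baseline rows, and fewer than 4 values for fences all raise classed
  errors or logged warnings rather than silent results.
* Ties in the HF peak search resolve to the lowest frequency
  (`which.max`), deterministic by construction.

## Problem sizes used in the checks

The packaged verification experiments run at the study's design size
(25 subjects × 9 months): 1000 replicates for the null calibration of
the 18 pre-planned contrasts, 200 for variance-component recovery, 50
cohorts for the outlier-screen operating characteristics, and 20
signal-level cohorts (250 ten-minute recordings each) for end-to-end
trend-sign recovery. These sizes give Monte-Carlo standard errors well
inside the asserted tolerances (e.g. ±0.7% on a 5% rejection rate at
n = 1000).

## Known limitations

* The editing rule is a documented proxy for manual editing; on real
  data its agreement with an expert reviewer is unquantified.
* Satterthwaite df in the variance parameterization can differ from
  finite-difference implementations by a few percent in small samples;
  exact agreement is not a design goal (the cross-check tests allow 2%).
* The band-limited total power excludes >0.40 Hz content by design;
  recordings with substantial supra-0.40 Hz power (fast breathers) will
  show a lower total than a Nyquist-wide integral would.
* Time-domain (SDNN, RMSSD) and nonlinear HRV indices, Lomb–Scargle
  spectra, random slopes, autoregressive residuals and Kenward–Roger df
  are out of scope.
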