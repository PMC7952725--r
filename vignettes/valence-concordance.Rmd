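---
title: "Assessing subjective valence from facial EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing subjective valence from facial EMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgvalence)
```

## The problem

Facial electromyography (EMG) over the corrugator supercilii (CS, the
"frowning" brow muscle) and the zygomatic major (ZM, the "smiling" cheek
muscle) tracks the valence dimension of emotional experience: CS activity
rises with unpleasant states, ZM activity with pleasant ones. `emgvalence`
implements a complete, testable pipeline for quantifying the *concordance*
between a continuously rated subjective valence trace (a nine-point scale
sampled at 1 Hz, 5 = neutral) and the EMG amplitude envelope of each
muscle, for two recording set-ups:

* a **wired** laboratory amplifier sampling at 1000 Hz with an on-line
  20--400 Hz band-pass, and
* a **wearable** glasses-type device sampling at 500 Hz, conditioned
  off-line.

Two session types are modelled end to end by the synthetic-data generator:
a film-viewing session (15 participants x 5 emotional films of 138--205 s,
each preceded by a 10-s rest baseline, both devices recording) and a
motion-game session (23 participants x ~10 min of game frames of mean
26.7 s, wearable only, no usable baselines, with annotated movement
artifacts).

## Signal conditioning and envelope extraction

For every recording and channel the pipeline applies, in order:

1. **20 Hz low-cut filter** -- a 4th-order Butterworth high-pass applied
   forward--backward (`signal::filtfilt`), i.e. zero-phase, so the envelope
   is not shifted in time relative to the rating trace. The realization is
   a design choice (the conditioning is specified only as a 20 Hz low-cut);
   zero phase is what keeps 1-s alignment between signals meaningful.
2. **51-point moving-average subtraction** (wearable path only) -- removes
   residual baseline wander. Edge samples use symmetrically truncated
   windows so the output length is preserved.
3. **Rectification** -- elementwise absolute value.
4. **Epoching and 1000-ms binning** -- bins are aligned to stimulus onset;
   a trailing partial bin is dropped (the 1 Hz series length is the whole
   number of seconds in the window). Samples inside annotated artifact
   intervals are excluded before averaging and a bin with more than 50% of
   its samples excluded is marked missing. The machine-readable artifact
   annotations replace what is, in practice, a manual video review.
5. **Baseline correction** (film sessions only) -- each trial's bins minus
   the mean rectified signal over the 10-s pre-stimulus window. Game
   sessions skip this step: free play has no clean rest window.
6. **Within-individual standardization** -- all of a participant's trials
   (per muscle and device) are concatenated and z-scored. The sample
   (n - 1) SD is used; any consistent convention gives identical downstream
   t statistics, the constant being absorbed by the model, but the
   convention must be fixed and declared, and this one matches R's `sd()`.

Two consequences are load-bearing and tested: the pipeline output is
exactly invariant to positive rescaling of the raw recording (every step is
either linear or scale-equivariant and the z-score removes the scale), so
the generator's arbitrary microvolt amplitudes cannot matter downstream;
and trials are processed independently, so processing order cannot leak
information across trials.

## The concordance model

Concordance is estimated with a two-level linear mixed model with the 1 Hz
valence rating \(x_{ij}\) (participant \(j\), second \(i\)) predicting the
standardized envelope \(y_{ij}\):

\[ y_{ij} = \gamma_{00} + \gamma_{10} x_{ij} + u_{0j} + u_{1j} x_{ij} +
\varepsilon_{ij}, \qquad (u_{0j}, u_{1j}) \sim N(0, \Psi), \quad
\varepsilon_{ij} \sim N(0, \sigma^2). \]

\(\gamma_{10}\) is the population concordance slope (z-units of envelope
per valence-scale unit). The fit is full **maximum likelihood** (not
REML), written from scratch in this package:

* \(\Psi/\sigma^2\) is parameterized by its log-Cholesky factor, which
  guarantees a positive-semidefinite covariance at every iterate;
* the fixed effects and \(\sigma^2\) are profiled out of the deviance in
  closed form (GLS step), leaving a 3-parameter optimization solved by
  `nlminb` (relative tolerance 1e-12) from two fixed starting points
  (relative SDs 0.5 and 0.05), the better optimum being kept;
* per-participant sufficient statistics (cross-products of
  \([1, x, y]\)) make each deviance evaluation O(participants) via 2x2
  Woodbury identities, so a fit takes milliseconds regardless of the
  number of 1 Hz observations;
* internally the predictor is centered -- an equivalent reparameterization
  (\(u_{0j}' = u_{0j} + c\,u_{1j}\)) that the slope, its standard error and
  the likelihood are invariant to -- because the uncentered problem is
  severely ill-conditioned (the rating scale's origin is far outside the
  data). Intercept-side quantities are transformed back for reporting.

Non-convergence is flagged, never silent; the slope test refuses a
non-converged fit. Fits with a variance at the boundary are reported as
singular. A boundary intercept variance is in fact *expected* here:
within-individual standardization forces every participant's mean envelope
to zero, leaving almost no between-participant intercept variation.

Standard errors come from the ML information matrix,
\(\widehat{\mathrm{cov}}(\hat\gamma) = \hat\sigma^2 (\sum_j X_j'
V_j^{*-1} X_j)^{-1}\). The slope is tested one-tailed in the direction
fixed a priori per muscle -- negative for CS, positive for ZM -- with
**m - l - 1 degrees of freedom** (participants minus level-2 predictors
minus one): 14 for the 15-participant film design, 22 for the
23-participant game design.

### Outlier handling

Standardized residuals are conditional residuals (response minus fixed
part minus predicted random part, using the BLUPs) divided by
\(\hat\sigma\); a marginal variant is also implemented, the conditional
one being the default. Observations with |residual| > 3 are removed and
the model is refitted with the *same* degrees of freedom (the participant
count is unchanged). If removal would leave a participant with fewer than
3 observations, that participant's outliers are retained with a warning.
The outlier fraction is reported as a percentage next to the main
statistics.

### Lag choice and group summaries

The analysis pairs ratings and envelopes at a lag of zero;
`cross_correlation()` is provided to verify on any dataset that the
zero-lag correlation is the maximum over integer-second lags. For
group-level description, `group_summary()` averages both series across
participants per time point and fits an ordinary least-squares line
through the group means (the scatterplot-with-regression-line view), and
the pipeline emits a second-by-second mean +/- SE time course, truncated
for variable-length game frames at the end point covering 90% of frames.

## Rating-side analyses

* **Overall ratings vs neutral**: two-tailed one-sample t-tests against
  the scale midpoint 5, Bonferroni-corrected by the family size (10 for
  the film design: 5 conditions x 2 scales), with the corrected p clipped
  at 1.
* **On-line vs cued-recall validation**: per participant x condition
  Pearson correlation between the two traces, then per-condition
  one-sample t-tests of the correlations against zero
  (Bonferroni-corrected, two-tailed). Correlations are tested
  untransformed; a Fisher-z step was considered and left out because the
  two-step procedure being emulated tests raw coefficients. Pairs with a
  constant trace have an undefined correlation and are excluded with a
  logged count.
* **Sample-size search**: the smallest n whose one-sample t-test power,
  computed exactly under a noncentral t with noncentrality \(d\sqrt{n}\),
  reaches the target -- found by direct integer scan (n <= 1000) rather
  than a closed-form approximation; exactness is cheap at this scale.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions and are not adjusted per analysis.

* **Latent valence** is a discretized Ornstein--Uhlenbeck process at 1 Hz
  around a condition-specific mean, clipped to [1, 9]; correlation time
  20 s, stationary SD 1.5. The process is smooth, bounded and has tunable
  autocorrelation -- the features that matter for a rating-dial trace; no
  generative model is implied by the measured ratings themselves, so this
  is a declared design choice.
* **Coupling** is linear on the standardized-envelope scale (matching the
  linearity assumption of the analysis model): envelope
  \(= u_{0j} + (\gamma_{10} + u_{1j})(x - 5) + \varepsilon\) with defaults
  \(\gamma_{10}\) = -0.2 (CS) / +0.15 (ZM) for the film preset and
  -0.03 / +0.03 for the game preset (the magnitudes of the reference
  tables), random intercept SD 0.3, random slope SD 0.1 (film) / 0.05
  (game), residual SD 0.95 -- chosen so the envelope has roughly unit
  variance and the empirical within-individual standardization is close
  to an identity in expectation.
* **Raw EMG** is amplitude-modulated band-limited Gaussian noise: a
  20--400 Hz carrier (truncated below the Nyquist frequency for the 500 Hz
  device), multiplied by a softplus-floored linear map of the envelope to
  microvolts (the softplus keeps amplitudes positive while staying linear
  over the operating range). Amplitude modulation of band-limited noise is
  standard surface-EMG phenomenology and makes the rectified mean the
  right envelope estimator. Slow drift (a low-passed random walk, SD
  20 uV, corner 0.5 Hz) and, for the game preset, broadband high-amplitude
  artifact bursts (2/min x 2 s, about 6.5% of stimulus time -- the
  fraction excised in the reference analysis) are added, the latter
  annotated in the event table.
* **Overall ratings** are drawn around each trial's realized mean trace
  valence (SD 0.7, rounded, clipped), so their direction relative to 5 is
  consistent with the condition by construction.
* Everything is reproducible from a single integer seed; identical
  configuration and seed give byte-identical on-disk datasets.

`simulate_paired_series()` is the generator's envelope-level fast path: it
skips carrier synthesis and returns exactly the 1 Hz paired series the
model sees after preprocessing. The repeated-simulation studies (oracle
equivalence over 20 datasets, parameter recovery over 100) run at this
level; the raw path (carrier, drift, filtering, binning) is exercised by
the end-to-end preset runs and the envelope-fidelity and scale-invariance
tests. This split keeps the 100-replicate study to seconds without
changing the statistical structure being recovered.

What the generator does *not* emulate: muscle cross-talk, electrode
impedance and placement effects, device noise floors, sweating, or any
nonlinearity in the valence--EMG link. Passing recovery tests therefore
show that the pipeline correctly inverts its own (field-standard) forward
model -- not that real recordings satisfy that model.

## Numerical conventions and degenerate inputs

* Standardization uses the sample (n - 1) SD; missing bins are excluded
  from the moments and stay missing; zero-variance or nearly-empty
  individuals are rejected with the participant named.
* A participant with constant ratings contributes to intercept terms only
  (warned, not dropped); a dataset where *every* participant is constant
  is rejected.
* Perfectly linear data drive \(\hat\sigma^2\) to the boundary; the fit is
  returned with the exact coefficients and flagged singular.
* The Bonferroni-corrected p never exceeds 1 and never falls below the raw
  p; a zero-variance rating set at the null mean reports t = 0, p = 1.
* Problem sizes used in the shipped test-suite studies: 20 datasets for
  the lme4 oracle-equivalence check, 100 for slope recovery, 200 for the
  covariate null calibration, 5000 replicates for rating-test calibration,
  and one full raw run of each preset for the end-to-end pattern check.

## Known limitations

* Degrees of freedom are m - l - 1 only; Satterthwaite or Kenward--Roger
  approximations are out of scope, as are REML, crossed random effects and
  nonlinear (machine-learning) decoders.
* The sex-covariate sensitivity analysis is meaningful on the
  *unstandardized* envelope; after within-individual standardization a
  level-2 covariate has almost nothing left to explain and its p-value is
  conservative by construction.
* Artifact handling assumes intervals are annotated; no automatic artifact
  detection is attempted.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config("exp1", seed = 1, outdir = tempfile())
out <- run_full(cfg)
out$results    # device x muscle: beta, se, t, df, one-tailed p, refit
out$ratings    # overall ratings vs neutral, Bonferroni-corrected
```
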