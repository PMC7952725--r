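# emgvalence

Facial EMG preprocessing and subjective-valence concordance modelling.

Surface EMG over the corrugator supercilii (CS, brow/frowning) and
zygomatic major (ZM, cheek/smiling) muscles tracks the valence of
emotional experience: CS activity increases with unpleasant states, ZM
with pleasant ones. `emgvalence` is for psychophysiologists who want to
quantify, per recording device and muscle, how well a continuously rated
valence trace (nine-point scale, 1 Hz, 5 = neutral) is reflected in the
EMG amplitude envelope — and who want the whole chain, from raw
microvolt samples to the slope test, reproducible and tested.

The package implements:

* **Device-specific conditioning** — zero-phase 4th-order Butterworth
  20 Hz high-pass; for the 500 Hz wearable device an additional 51-point
  moving-average subtraction; rectification; per-trial 1000-ms binning
  with artifact-interval excision (> 50%-excluded bins are missing);
  baseline correction against the 10-s pre-stimulus mean where baselines
  exist; within-individual z-standardization of the concatenated trials.
* **A from-scratch maximum-likelihood linear mixed model** of the
  standardized envelope on the valence rating with random by-participant
  slopes and intercepts,

  y_ij = γ00 + γ10·x_ij + u0j + u1j·x_ij + ε_ij,  (u0j, u1j) ~ N(0, Ψ),

  fitted by profiled ML with a log-Cholesky covariance parameterization.
  The slope γ10 is tested one-tailed (CS negative, ZM positive, fixed a
  priori) with **m − l − 1** degrees of freedom (participants −
  level-2 predictors − 1). Standardized-residual outliers (|r| > 3 SD)
  are reported and the model refitted without them. `lme4` is used only
  as an independent cross-check in the test suite.
* **Rating analyses** — one-sample t-tests of overall ratings against
  the neutral midpoint with Bonferroni correction, on-line vs cued-recall
  trace validation via per-pair Pearson correlations, and an exact
  noncentral-t sample-size search.
* **A synthetic-data generator** with known ground-truth coupling that
  emulates a film-viewing experiment (15 participants × 5 films of
  138–205 s, 10-s baselines, wired 1000 Hz + wearable 500 Hz) and a
  motion-game experiment (23 participants × ~10 min of ~27-s frames,
  wearable only, annotated movement artifacts), down to raw
  amplitude-modulated band-limited EMG.

See `vignettes/valence-concordance.Rmd` for the model, conventions and
design rationale.

## Worked example

```r
library(emgvalence)
cfg <- run_config("exp1", seed = 1, outdir = tempfile())
out <- run_full(cfg)
out$results
```

simulates the film experiment at its default ground truth (CS slope
−0.2, ZM slope +0.15 on the standardized-envelope scale), runs the full
preprocessing chain on the raw recordings of both devices, and fits one
concordance model per device × muscle:

```
    device muscle   beta     se      t df p_one_tailed outlier_pct beta_refit t_refit  p_refit
1    wired     cs -0.210 0.0164 -12.85 14     1.94e-09       0.292     -0.211  -12.96 1.74e-09
2    wired     zm  0.176 0.0221   7.96 14     7.22e-07       0.323      0.177    8.13 5.66e-07
3 wearable     cs -0.206 0.0169 -12.24 14     3.64e-09       0.315     -0.206  -12.32 3.33e-09
4 wearable     zm  0.173 0.0222   7.79 14     9.35e-07       0.277      0.174    7.93 7.58e-07
```

Each row is one device × muscle concordance model: `beta` is the fixed
valence slope recovered from the raw synthetic EMG (close to the
generating ±0.2/0.15), `t` and `p_one_tailed` test it in the a-priori
direction on 14 = 15 − 0 − 1 degrees of freedom, `outlier_pct` is the
percentage of |standardized residual| > 3 observations, and the `_refit`
columns repeat the test after removing them. `out$ratings` holds the
overall-rating tests (e.g. the anger films rate mean 2.27 on the valence
scale, t(14) = −15.0, Bonferroni-corrected p = 4.9e-9), and
`out$timecourse` the second-by-second group means.

A thin command-line wrapper over the same functions ships at
`inst/cli/emgvalence`:

```sh
Rscript inst/cli/emgvalence run-all --preset exp1 --seed 7 --outdir run7
```

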