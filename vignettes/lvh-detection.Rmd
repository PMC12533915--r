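---
title: "Detecting echocardiographic LVH from ECG and synthesized vectorcardiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting echocardiographic LVH from ECG and synthesized vectorcardiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcglvh)
```

## The problem

Left ventricular hypertrophy diagnosed on echocardiography (Echo-LVH, LV
mass index > 115 g/m2 in men, > 95 g/m2 in women) is a strong predictor of
cardiovascular events, but the classical electrocardiographic voltage
criteria that screen for it — Cornell voltage, Sokolow-Lyon, Peguero-Lo
Presti and their kin — are specific yet insensitive, typically catching
fewer than a third of hypertrophied ventricles. This package implements a
pipeline that augments the scalar ECG measurements with the geometry of the
*vectorcardiogram* (VCG): the 3-D trajectory swept by the heart's electrical
vector, synthesized from the ordinary 12-lead recording by a linear
transform. Loop-geometry features and classical criteria feed interpretable
decision-tree classifiers whose rules a clinician can read directly.

## Pipeline and models

1. **Median beats.** One averaged cardiac cycle per patient, 12 leads in
   microvolts with a declared sampling rate. Wave windows (P, QRS, T) are
   0-based half-open sample intervals; when they are not supplied they are
   detected by spatial-velocity thresholding on the Kors VCG (the QRS is the
   run of samples above 10% of the peak spatial velocity, and the same rule
   delimits P and T in the flanking windows, floored above each window's
   noise level). Supplied fiducials always take precedence.
2. **VCG synthesis.** `xyz(t) = M leads8(t)` with `leads8 = (I, II, V1..V6)`;
   the four 3 x 8 coefficient sets (inverse Dower, Kors regression, and the
   QLSV/PLSV least-squares pair) ship as editable plain-text files. The
   inverse Dower and Kors matrices are transcriptions of their primary
   sources; the QLSV/PLSV files are *synthetic stand-ins* derived as
   wave-weighted pseudo-inverses of the Dower forward matrix, because the
   original data-fitted coefficients are not printed in an accessible
   source. A test pins the inverse Dower transcription to the pseudo-inverse
   of the forward matrix.
3. **Loop features.** Per wave and method (optionally after truncated-Fourier
   smoothing with 8 harmonics per wave window — the harmonic count is a
   declared default, chosen to keep QRS morphology at 500 Hz while
   suppressing noise): per-decile magnitude, velocity and orbital frequency,
   plus the global features (normalized vector area GAV, rotation-angle
   range in the least-squares plane, velocity extrema, terminal-vector
   magnitude over the last 40 ms of the QRS). Deciles are temporal tenths by
   sample index, not arc length. Angles are computed in radians and the
   angle range is reported in degrees, matching how such features are
   conventionally printed. The exact published formulas for GAV, orbital
   frequency and angle range live in companion software that is not
   publicly specified, so this package's definitions are declared stand-ins
   with matching units: GAV is normalized by the squared maximum loop
   magnitude to be dimensionless (the raw uV^2 vector area is also
   emitted), orbital frequency counts revolutions about the loop centroid
   per millisecond, and the terminal window is the conventional 40 ms.
4. **Classical criteria.** A declarative 23-item registry (semicolon-separated
   text, editable without code change) evaluates each criterion's continuous
   value, comparator and sex-specific threshold, plus voltage-duration
   products for every mV criterion. Cornell voltage (> 2.8 / > 2.0 mV,
   strict) and Peguero-Lo Presti (>= 2.8 / >= 2.3 mV, non-strict) are
   hard-pinned; the Romhilt-Estes score is the standard six-component
   implementation with strain defined as T polarity opposite the dominant
   QRS deflection in V5/V6.
5. **Preprocessing and pruning.** Missing features are imputed by the mean
   when roughly symmetric and by the median otherwise; |skewness| <= 1 is
   the declared cut for "symmetric" since the rule is usually stated
   without a number. Columns are z-scored by training-split statistics.
   Each signal family (VCG, ECG) is pruned separately by L1-penalized
   logistic regression with the penalty maximizing 5-fold cross-validated
   AUC (glmnet; seeded folds).
6. **Tree induction.** A gain-ratio threshold tree in the C4.5/C5.0 lineage,
   authored in this package: binary midpoint splits, growth until purity or
   `2 * minCases`, bottom-up pessimistic pruning (binomial upper confidence
   bound, confidence factor 0.25), optional winnowing of zero-gain
   predictors, Laplace-smoothed leaf probabilities and a fixed 0.5
   probability threshold. Trees are fit on the z-scored data but report
   split thresholds in original units (the gain ratio is invariant under
   monotone rescaling, which a test asserts by comparing topologies).
   Two design choices are worth spelling out. First, when no candidate
   split has positive gain at an impure node the learner falls back to the
   best zero-gain split: a symmetric XOR configuration is invisible to any
   depth-1 entropy criterion, yet its children are perfectly separable, and
   pruning removes such splits when they lead nowhere. A depth cap of 30
   bounds the degenerate chains this could otherwise produce. Second,
   misclassification costs enter only the leaf class frequencies — the
   Laplace probability becomes `(pos + 1) / (pos + cost_fp * neg + 2)` —
   while split selection and pruning stay cost-blind. The tree structure is
   therefore identical at every cost and raising the false-positive cost
   can only flip calls from positive to negative, which makes the
   advertised monotonicity properties (training false positives never
   increase; specificity never decreases) hold exactly rather than merely
   on average.
7. **Model building.** Three criteria are produced: a VCG-only tree on the
   lasso-selected VCG features, a combined tree on the union of both
   selections, and a specificity-tuned variant whose false-positive cost is
   chosen by grid search (`minCases` in {2, 5, 10, 20}, winnowing on/off,
   cost in {1, 1.5, 2, 3} — the knobs are named in the source methodology
   but not the grid, so these ranges are package defaults) to maximize
   cross-validated specificity subject to sensitivity >= 0.55. A *pinned*
   mode bypasses selection and uses the published 5/6/6 predictor sets
   (`GAV_K`, `RangeAngR`, `PMagP2`, `POrbFrqD5`, `Vel_Min_Kf_T`;
   `Ang_Term_Num`, `T_AREA_DI`, `ECG21`, `QRSMagP1`, `TVelQ5`,
   `QRSMagPf9`). Published tree cut-offs are not reproduced node-for-node:
   the fidelity target is the predictor sets, tree form and performance
   behaviour, since the original cut-offs are only available as a figure.
8. **Evaluation.** Confusion metrics with exact Clopper-Pearson accuracy
   CIs (Wilson optional — the CI method is not named in the source
   methodology), hand-built DeLong comparison of correlated AUCs via
   placement values (pROC serves only as an independent oracle in the
   tests), McNemar with the exact binomial below 25 discordant pairs and
   the continuity-corrected chi-square above (the switch point is a package
   choice), Bonferroni adjustment truncated at 1, seeded k-fold
   cross-validation reporting both pooled and per-fold metrics (the source
   does not say which convention its CIs use, so both are available),
   stratified correct-classification tables, and the arcsine two-proportion
   power computation.

## The synthetic cohort generator

No clinical waveforms ship with the package; every pipeline stage is
exercised on synthetic median beats with analytic ground truth. A beat is a
sum of Gaussian wavelets per independent lead (P, Q/R/S, T) plus white
noise; the four dependent limb leads are derived from noisy I and II so the
Einthoven/Goldberger redundancy holds exactly, and the true wave windows
(+/- 3 sigma) are returned with the beat. A cohort draws labels at 42.8%
prevalence (n = 664 by default, the study scale) and applies to LVH beats a
lognormal QRS voltage gain (mean multiplier 1.5), a modest QRS widening
(x1.1), T-amplitude shrinkage (x0.7) and lateral T inversion ("strain")
with probability 0.35. Every patient also receives a lognormal beat-scale
jitter (sdlog 0.35) and wave-width jitter (sdlog 0.05): inter-individual
ECG voltage variability is large, and without it the classes separate
almost perfectly, which would make every downstream benchmark trivial.
These defaults were fixed once as the package's study conditions.

Covariates (sex, age, BMI, hypertension, IHD, LV geometry, severity) are
drawn from the study's marginal rates, independent of the waveform given
the label — the subgroup machinery only needs labels, so no confounding is
modelled. What passing tests on this generator demonstrate is that the
*pipeline* is correct and that injected voltage/repolarization effects
propagate end to end; they do not certify clinical performance, because
real beats differ in morphology variability, artefact structure, conduction
abnormalities and the correlation structure of features. Performance
numbers on the synthetic cohort are accordingly better than the clinical
figures reported for comparable pipelines.

## Numerical conventions and degenerate inputs

* Amplitudes are microvolts internally and criterion voltages millivolts;
  conversion happens only at module boundaries. The isoelectric baseline is
  the mean over the 20 ms before P onset (clamped to the record start) —
  a PR-segment baseline was rejected because P may abut QRS in fixtures.
* T-wave areas integrate the baseline-corrected signal by the trapezoid
  over the closed sample range of the T window, in Ashman units
  (1 AU = 40 ms x 0.1 mV); the closed range makes a 0.1 mV / 40 ms plateau
  exactly 1 AU.
* Loops are treated as closed (last point joined to first) for vector area,
  orbital frequency and the angle range's closing step; per-decile velocity
  drops the artificial closing step so constant-speed trajectories are flat
  across deciles. Degenerate loops (all points identical, or rank < 2 for
  the plane fit) yield zeros rather than errors.
* Gain-ratio ties break toward the first predictor and the smallest
  threshold, making retraining deterministic; all stochastic steps (splits,
  folds, generators) are seeded.
* Whole-beat linear transforms commute with segmentation, so the pipeline
  transforms first and segments after; Fourier smoothing does not commute
  and is applied per wave window, with the harmonic count clamped to the
  window length.

## Limitations

Records with bundle-branch block, paced rhythms and similar confounders are
out of scope, as is multi-beat averaging from rhythm strips. The QLSV/PLSV
coefficients are labelled synthetic until transcribed from their primary
sources; the 23-item registry follows standard literature definitions and
is designed to be reconciled against a reference catalogue by editing one
text file. Problem sizes in the test-suite simulations (cohorts of 664,
simulation counts of 100, bootstrap of 2000) match the package's declared
study conditions.
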