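# vcglvh

Electrovectorcardiographic detection of echocardiographic left ventricular
hypertrophy (Echo-LVH) in R.

Classical ECG voltage criteria for LVH — Cornell voltage
(R<sub>aVL</sub> + S<sub>V3</sub> > 2.8 mV men / 2.0 mV women), Sokolow-Lyon
(S<sub>V1</sub> + max(R<sub>V5</sub>, R<sub>V6</sub>) ≥ 3.5 mV),
Peguero-Lo Presti (S<sub>D</sub> + S<sub>V4</sub> ≥ 2.8/2.3 mV) and their
kin — are specific but miss most hypertrophied ventricles. This package
implements a pipeline that enriches them with the geometry of the
synthesized vectorcardiogram (VCG) and learns interpretable decision-tree
criteria:

* **12-lead median beats**: CSV I/O in µV/mV, validation, fiducial
  detection by spatial-velocity thresholding, per-lead R/S amplitudes, QRS
  duration, T-wave areas in Ashman units (1 AU = 40 ms × 0.1 mV).
* **VCG synthesis**: `xyz(t) = M · (I, II, V1…V6)(t)` with four editable
  3×8 coefficient sets (inverse Dower, Kors regression, QLSV/PLSV
  least-squares stand-ins) plus per-wave truncated-Fourier smoothing.
* **Loop features**: P/QRS/T loops reduced to per-decile magnitude,
  velocity and orbital frequency, and global features (normalized vector
  area GAV, rotation-angle range, velocity extrema, terminal-QRS vector).
* **23 classical criteria** in a declarative, editable registry with
  sex-specific cut-offs, voltage-duration products and the Romhilt-Estes
  point score.
* **Modeling**: skewness-guided imputation, training-split z-scaling,
  per-family lasso pruning (glmnet, CV-AUC), and an authored gain-ratio
  decision tree (C4.5/C5.0 lineage: midpoint threshold splits, pessimistic
  pruning, winnowing, false-positive cost weighting of leaf frequencies,
  Laplace probabilities, fixed 0.5 threshold, thresholds reported in
  original units). `build_lvh_models()` produces the VCG-only, combined
  VCG-ECG and specificity-tuned criteria; a pinned mode uses the published
  5/6/6 predictor sets.
* **Evaluation**: exact-CI confusion metrics, DeLong comparison of
  correlated ROC curves, McNemar with Bonferroni truncation, k-fold
  cross-validation, stratified correct-classification tables, and the
  arcsine two-proportion power computation
  (`h = 2·asin√p₂ − 2·asin√p₁`, `n = ⌈(z₁₋α/₂ + z_power)²/h²⌉`).
* **Synthetic data**: Gaussian-wavelet median beats with analytic ground
  truth and cohorts with an injected LVH voltage/repolarization effect, so
  the whole pipeline is testable without any recordings.

## Worked example

```r
library(vcglvh)

# one synthetic median beat with known ground truth
b <- make_beat(beat_spec(noise_sd = 2), seed = 42)
m <- measure_amplitudes(b, attr(b, "fiducials"))
cornell_voltage(m, "male")
#> cornell_voltage: 0.691 mV > 2.8 [male] -> negative
peguero_lo_presti(m, "male")
#> peguero_lo_presti: 1.205 mV >= 2.8 [male] -> negative

# a labeled cohort through the full pipeline
co <- make_cohort(cohort_spec(n = 240), seed = 7)
ft <- cohort_features(co)            # VCG + ECG feature table
ms <- build_lvh_models(ft, seed = 7) # lasso + grid search + three trees
model_performance(ms, "test")[, c("model", "accuracy", "sensitivity",
                                  "specificity", "f1", "auc")]
#>        model accuracy sensitivity specificity    f1   auc
#> 1        vcg     87.5        88.2        86.8 0.870 0.921
#> 2    vcg_ecg     93.1        91.2        94.7 0.925 0.934
#> 3 vcg_ecg_sp     93.1        91.2        94.7 0.925 0.934
```

The fitted trees print as readable rules (thresholds in original units),
e.g. the combined model's root here splits on a lateral T-wave area:

```r
print(ms$models$vcg_ecg)
#> Gain-ratio decision tree: 8 leaves, depth 6 (minCases=5, cost_fp=1)
#> T_AREA_V5 <= 4.172:
#>   -> LVH (n=34, LVH 34/34, p=0.972)
#> T_AREA_V5 >  4.172:
#>   ravl_voltage <= 0.3054: ...
```

Accuracy/sensitivity percentages above are test-split performance on the
*synthetic* cohort, whose injected effect makes the task easier than
clinical data; see the vignette (`vignettes/lvh-detection.Rmd`) for what
the generator does and does not emulate.

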