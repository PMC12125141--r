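# pshrisk

Early risk modelling of **paroxysmal sympathetic hyperactivity (PSH)**
after traumatic brain injury, from *transients* in the coupling between
autonomic-nervous-system activity and cerebral hemodynamics.

PSH (episodic tachycardia, hypertension, hyperthermia, sweating,
posturing) usually becomes clinically diagnosable only 1-2 weeks after
injury. This package implements, and validates on a synthetic cohort, a
pipeline that asks whether the *instability* of the relationship between
ANS metrics (heart rate HR, mean arterial pressure ABP, baroreflex
sensitivity BRS) and cerebral hemodynamics (intracranial pressure ICP,
pressure reactivity index PRx) during the first 72 h of neuromonitoring
predicts the at-risk label.

The core statistic is the **zero-crossing rate** of a rolling Pearson
correlation: for each of the six ANS × hemodynamics signal pairs, the
correlation is computed over sliding windows of W ∈ {3, 6, 12, 24} h on
the 60-s trend grid, and within each W-long time bin

```
ZCR = 1/(N-1) * Σ | sgn(corr[n]) − sgn(corr[n−1]) |      ∈ [0, 2]
```

counts how often the correlation changes sign (MEAN and STD of the
correlation values are the companion metrics). Risk is modelled with
L2-penalised logistic regression over three nested feature sets —
clinical metadata (level I); + 72-h neuromonitoring means (level II);
+ one variability metric per pair and bin (level III) — using stratified
five-fold cross-validation over a regularisation grid
{2N, N, 1, 1/N, 1/(2N)} × {balanced, unbalanced}, followed by
coefficient- and attribution-based importance and a temporal
significance profile over the time bins.

Because the patient monitoring data are not available, the package
includes a first-class synthetic cohort generator (41 patients, 14 at
risk, metadata matched to the published cohort's distributions) with a
controllable group difference: the at-risk group's HR–ICP and HR–PRx
couplings reverse sign at an elevated rate early in monitoring. The
pipeline must recover that injected effect end to end; see the methods
vignette (`vignettes/psh-risk-modelling.Rmd`) for the generator design
and its limits.

## Package layout

* `R/` — the implementation: synthetic cohort (`cohort_params`,
  `simulate_cohort`, `gen_waveform`), signal I/O and QC
  (`read_trend_csv`, `interpolate_gaps`, `qc_record`), waveform
  estimators (`estimate_hr_fft`, `detect_beats`, `estimate_brs_xcorr`,
  `compute_prx`), transients (`rolling_correlation`, `zcr`,
  `variability_metrics`), feature assembly (`build_feature_set`,
  `compare_groups`), the risk model (`fit_logistic`, `grid_search_cv`,
  `stratified_folds`), interpretability (`additive_attribution`,
  `importance_profile`, `temporal_profile`) and orchestration
  (`run_pipeline`).
* `analysis/01_simulate.R … 07_explain.R` — the numbered workflow
  drivers; each is a thin narrative script over the package functions
  that writes its tables under `results/`.
* `tests/testthat/` — unit, property and pipeline-level validation.
* `scripts/acceptance.R` — recomputes the headline quantities from
  scratch (below).

## Worked example

Running the workflow end to end (`Rscript analysis/01_simulate.R` …
`07_explain.R`) on the default seed prints, among other things:

```
Simulated 41 patients (14 at risk) under seed 1.
Group-separated variables at alpha = 0.05: wbc, ct_tsah
WBC medians (at risk / not): 18.8 / 15
41 of 41 records pass QC (worst residual missing 0.8%).

level I   best C = 41       (balanced): AUC 0.75 +/- 0.09, ACC 0.63 +/- 0.20
level II  best C = 1        (unbalanced): AUC 0.65 +/- 0.16, ACC 0.63 +/- 0.17
level III best C = 0.02439  (unbalanced): AUC 0.82 +/- 0.19, ACC 0.70 +/- 0.08

Pair ranking by aggregated coefficient importance:
    pair importance
  hr-icp      4.902
  hr-prx      4.431
 abp-prx      0.193
 ...
Influential bins (threshold 0.199): hours 0-3, ...
```

Reading this: the synthetic admission metadata separate the groups on
white-blood-cell count (as the emulated cohort does); adding the ZCR
transient features (level III) lifts cross-validated AUC above the
metadata-only model (level I), while the 72-h means alone (level II) add
nothing; the importance analysis correctly singles out the two pairs
carrying the injected effect (HR–ICP, HR–PRx) and the temporal profile
flags the first 3-h bin, where the effect was injected. Fold-to-fold
AUC spread is large at n = 41 — expected, and the reason the validation
properties are stated over seed ensembles rather than single runs.

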