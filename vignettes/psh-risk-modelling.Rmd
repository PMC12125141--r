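---
title: "Modelling PSH risk from transients between autonomic activity and cerebral hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PSH risk from transients between autonomic activity and cerebral hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Paroxysmal sympathetic hyperactivity (PSH) is an episodic storm of
sympathetic over-activation — tachycardia, hypertension, hyperthermia,
sweating, posturing — that affects a substantial fraction of patients
after severe traumatic brain injury (TBI). Clinical diagnosis typically
becomes possible only after the first symptomatic episodes, more than a
week post-injury. The hypothesis this package operationalises is that
*transient changes in the coupling between autonomic nervous system (ANS)
activity and cerebral hemodynamics during the first 72 h of
neuromonitoring* carry early information about which patients will later
be judged at risk of PSH.

The ANS side is proxied by heart rate (HR), mean arterial blood pressure
(ABP) and baroreflex sensitivity (BRS); the cerebral side by intracranial
pressure (ICP) and the pressure reactivity index (PRx). All five are
60-s-resolution trend series over 72 h. The coupling between an ANS
metric $x$ and a hemodynamic metric $y$ is summarised by a rolling
Pearson correlation over sliding windows of $W \in \{3, 6, 12, 24\}$
hours, advanced one 60-s sample at a time. From the correlation track
three variability metrics are extracted per time bin: the mean (MEAN),
the sample standard deviation (STD), and the zero-crossing rate

$$\mathrm{ZCR} = \frac{1}{N-1}\sum_{n=1}^{N-1}
  \bigl|\,\mathrm{sgn}(corr[n]) - \mathrm{sgn}(corr[n-1])\,\bigr|,$$

with $\mathrm{sgn}(0)=0$, which quantifies how often the correlation
changes sign; it lies in $[0,2]$, where a full sign flip contributes 2
and a transition through an exact zero contributes 1.

Risk is modelled by L2-penalised logistic regression over three nested
feature sets — clinical admission metadata (level I, 13 covariates);
plus the five 72-h channel means (level II, 18); plus one variability
metric for each of the six signal pairs and each time bin (level III) —
evaluated by stratified five-fold cross-validation over a regularisation
grid, with coefficient- and attribution-based importance analysis and a
temporal significance profile.

Because no patient monitoring data are distributed, the package pairs
the analysis pipeline with a synthetic cohort generator that reproduces
the *statistical structure the analysis assumes*. Everything the
generator does is a stand-in: it is explicitly not a reconstruction of
any patient data, and results on it validate the machinery, not the
clinical finding.

## Windowing: one recorded interpretation

The variability metrics are "extracted from the values within each
window and aggregated". Two readings are possible; this package fixes
the two-level interpretation: the rolling-correlation *window length* is
$W$, **and** the 72-h axis is divided into consecutive non-overlapping
*bins* of length $W$ (so 24 bins for $W=3$). Each correlation value is
labelled by its window start; a bin aggregates the values whose start
falls inside it. A time-resolved importance profile (which the temporal
analysis requires) is impossible without time-indexed features, which
forces some such two-level construction. Consequences:

* only windows fully inside the record are evaluated, so the last bin
  contains a single window start and its metrics are missing by the
  "fewer than 2 defined values" rule; missing features are imputed
  fold-locally at model time, never at assembly time;
* a bin-0 feature for $W=3$ summarises windows *starting* in hours 0-3,
  which extend over signal hours 0-6.

The rolling step is one 60-s sample (the finest available), and windows
require at least 90% pairwise-complete samples — the record-level 10%
missingness rule applied at window scale.

## Quality control and interpolation

Missing runs of up to 10 consecutive trend samples (10 min) with
observed anchors on both sides are filled linearly; longer and boundary
runs stay missing. A record passes QC when, after interpolation, every
channel retains at most 10% missing samples over the 72-h window.
Whether the original study assessed the 10% rule before or after
interpolation is not stated; this package evaluates it after, and the
QC report records per-channel residual missingness so the decision is
auditable. Failure of any channel fails the record, mirroring exclusion
of whole recordings for poor signal quality.

## Waveform-level estimators

For raw 200-Hz ABP/ICP segments the package derives the trend channels
as follows.

* **HR** — 60 × the frequency of the largest magnitude-spectrum peak of
  the linearly detrended 60-s segment within 0.67-2.33 Hz (40-140 bpm).
  The FFT window is tied to the 60-s trend bin; an in-band peak below
  25% of the global non-DC spectral maximum is treated as no credible
  cardiac peak and yields a missing value rather than a guess.
* **Beats** — local maxima of the baseline-removed (1-s moving average)
  pressure signal, with a 0.25-s refractory period and an acceptance
  threshold at half the 95th percentile of the detrended amplitude.
  Both parameters are exposed; nothing in the source material fixes
  them.
* **BRS** — the cross-correlation method: beat-wise systolic pressure
  and interbeat interval resampled to a 1-s grid; per 10-s segment, the
  lag in 0-5 s maximising the SBP-IBI correlation is selected and the
  regression slope of IBI on the lagged SBP is the segment estimate,
  averaged into the 60-s value. The maximising correlation must be
  *positive*: baroreflex physiology implies positive SBP-to-IBI
  coupling, and negative-only segments are emitted as missing rather
  than sign-flipped. Segments start only after `max(lags)` seconds of
  history so every lag is evaluable in every segment (an early segment
  with a truncated lag search would bias the average). A significance
  gate on the correlation is available (`min_corr`) but off by default,
  since it is not clearly part of the original construction.
* **PRx** — consecutive 10-s means of ABP and ICP; at each 10-s update,
  the Pearson correlation of the 30 most recent means (a 5-min window);
  averaged onto the 60-s grid. This is the standard construction
  jointly consistent with "5-min moving average window, updated every
  10 s".

Parameter recovery closes the loop: on noise-free generated waveforms
the estimators recover the configured pulse frequency to one FFT bin,
baroreflex gains of 3-12 ms/mmHg at delays 0-5 s to within a few
percent, and the sign and magnitude of the slow-wave coupling through
PRx essentially exactly (see `analysis/03_derive_indices.R` and the
test suite).

## The synthetic cohort

Defaults emulate the study conditions: 41 patients, 14 at risk, 72 h of
60-s data. Channel baselines and between-patient spreads follow the
published cohort medians and IQRs (ABP 84 mmHg, HR 78 bpm, BRS
6.8 ms/mmHg, ICP 11 mmHg, PRx 0.05). Within-patient minute-scale
fluctuation is AR(1) noise with lag-1 autocorrelation 0.6 — autocorrelated
enough to look like physiology, while leaving a 3-h window enough
effective samples that the rolling correlation tracks the latent
coupling rather than sampling noise.

Metadata families are matched to the published group medians/IQRs:
log-normal for the right-skewed WBC, age and ISS; normal for Hb;
discrete uniform over the printed IQR for the GCS sum score; Bernoulli
at the printed group rates for sex, trauma type and the six CT flags.
Only median and IQR are published, so any family matching them is
admissible; the family used is recorded here and in the generator
documentation. WBC is the one strongly group-separated admission
marker (population medians 20.3 vs 14.2 × 10³/µl); across simulated
cohorts the Mann-Whitney test flags it at α = 0.05 in roughly 90% of
seeds with a median p near 0.005.

### The injected coupling effect

Each hemodynamic channel's fluctuation is a mixture of the ANS channels'
fluctuations and an independent residual,
$e_\mathrm{hemo} = \sum_a \sigma_a(t)\,\rho_a\,e_a + \sqrt{1-\textstyle\sum_a
\rho_a^2}\,\eta$, so the short-horizon correlation of a pair tracks
$\sigma_a \rho_a$. The non-HR pairs carry *stable* weak couplings
(ABP-ICP 0.45, others 0.4) — slow-wave transmission that keeps their
correlation tracks clearly away from zero, as physiological
co-oscillation would. The HR-ICP and HR-PRx pairs carry the switching
coupling (±0.7) whose sign $\sigma(t)$ reverses as a *hardcore renewal
process*: consecutive reversals are separated by a refractory gap of
1.6 h plus an exponential at the configured rate.

The refractory gap is the load-bearing design choice. A sliding $W$-long
correlation window *averages* the latent sign, and two reversals closer
together than $W/2$ cancel inside the window: the windowed correlation
dips but never crosses zero, so a pure Poisson switching process
produces ZCR responses that saturate far below certainty regardless of
rate (direct simulation of the mechanism shows bin-0 sensitivity capped
near 0.5). With the refractory above $W/2 = 1.5$ h every latent reversal
is realisable as an actual zero crossing of the correlation track, the
induced ZCR remains monotone in the configured rate, and rate semantics
are preserved (mean gap = refractory + 1/rate).

Everyone switches at a baseline 0.02/h (a few reversals per 72 h). The
at-risk group additionally has an early unstable phase at 3/h over
signal hours 1.5-4.5. That interval is chosen so the induced zero
crossings — which occur when the sliding window is centred on a
reversal — fall exactly at window starts in hours 0-3, i.e. in the
first 3-h feature bin and only there. This is the generator's
controllable group difference: higher correlation-sign instability in
the at-risk group, concentrated in the earliest bin, matching the
direction of the positive ZCR coefficients the risk model is designed
to reward. The calibration (coupling magnitudes, rates, refractory,
AR(1) smoothness) was fixed from this mechanism-level reasoning during
generator design and then frozen.

### What the generator does not emulate

No artifacts, no treatment interventions or sedation changes, no
circadian structure, no correlated clinical covariates, no
heavy-tailed measurement noise, and independence between metadata and
signal dynamics (only the switching process differs by group). Passing
tests on this cohort demonstrate that the pipeline recovers the kind of
effect it is built to detect at the published cohort size; they say
nothing about effect sizes in real patients.

## The risk model

"Regularisation strength" values $\{2N, N, 1, 1/N, 1/(2N)\}$ (with
$N$ the full-cohort instance count, 41) are interpreted as *inverse*
penalty weights, the convention of the scikit-learn ecosystem, under
which strengths on the order of the instance count denote weak
penalisation; $N$ is the full cohort size, not the training-fold size,
which is what makes strengths of exactly 41 and 82 expressible by the
grid. The fit minimises
$\sum_i s_i\,\ell_i(\beta) + \lVert\beta\rVert^2/(2C)$ with an
unpenalised intercept. Balanced weighting sets $s_i = n/(2 n_{y_i})$.
The optimiser is a damped Newton iteration written directly so the
objective is exactly this expression; the test suite checks its
coefficients against an independent BFGS optimiser (agreement to 1e-6)
and, during development, against glmnet ridge (identical to numerical
precision).

Features are z-scored within training folds (coefficient-magnitude
importance across mixed units is meaningless otherwise); imputation uses
training-fold column medians. Both are strictly fold-local — a leakage
canary test (a feature equal to the label on one fold's validation rows)
and a permuted-label null calibration at n = 200 (mean best grid AUC
0.50) verify that nothing leaks through imputation, standardisation or
grid search. Accuracy uses a 0.5 probability threshold (unstated in the
source; documented default). AUC is computed with a fixed comparison
direction so chance-level models score near 0.5 rather than being
auto-flipped upward. The best configuration is the highest mean AUC,
ties resolving to the smaller strength.

Stratified folds are built by dealing each class's shuffled members to
the folds in rotation, which guarantees per-fold class counts within one
of each other (written directly rather than via a resampling package
because the balance guarantee is then by construction).

## Importance and the temporal profile

Coefficient importance is $|\beta_j|$ per fold. Additive attribution for
the linear model is exact and closed-form:
$\phi_{ij} = \beta_j (z_{ij} - z^{bg}_j)$ on the linear-predictor scale
with the training-fold means as background, so attributions plus base
value reconstruct every linear predictor to machine precision. Both are
aggregated by summing absolute values across folds (and validation
instances), then min-max normalised to $[0,1]$. The temporal profile
averages, per time bin, the normalised importance of that bin's six
pair features, min-max rescales the bin profile, and marks bins
*strictly* above the mean of the profile as influential (strictness
makes the all-equal case well-defined: an empty span).

Per-bin aggregation uses the mean across pairs (any positive multiple
gives the same influential set, since the threshold is the mean of the
same values). On well-behaved continuous standardised features the
coefficient and attribution rankings agree (Spearman ≥ 0.9 on the
level-II models). On level III the agreement degrades by construction:
most ZCR columns are near-constant zero with occasional spikes, so
z-scoring them is degenerate and the per-fold validation attribution
aggregate is dominated by whether a spike lands in the fold — a
limitation of spike-like sparse features, not of either importance
method (the attribution identity itself remains exact).

## Numerical choices and degenerate inputs

* Rolling correlation uses one-pass sums on globally mean-centred data;
  windows with complete fraction below 0.9 or variance below 1e-12 are
  missing; values are clamped to $[-1,1]$ against rounding.
* ZCR is evaluated literally with sgn(0) = 0; missing values drop out
  pairwise; fewer than 2 defined values gives a missing metric.
* Zero-variance feature columns are dropped from the fit with a warning
  and reported with coefficient 0 (all-missing bins imputed to a
  constant end up here).
* Degenerate min-max normalisation (all values equal) returns zeros
  with a warning.
* All randomness flows from a single integer seed through
  deterministic per-stage derived seeds; identical configuration and
  seed give byte-identical outputs.

## Problem sizes

The default study conditions are the published cohort scale: 41
patients × 72 h × 5 channels at 60 s, six signal pairs, four windows.
The Monte-Carlo validations use 25 cohort replicates for the
effect-recovery and null-calibration properties, 50 replicates per
configuration for baroreflex-gain recovery, and 1000 random sequences
for the ZCR oracle; these sizes give stable pass/fail behaviour for the
properties at the tolerances used.

## Known limitations

* The two-level windowing is a recorded interpretation, not the only
  possible reading of the aggregation.
* With 162 features and 41 patients, cross-validated AUC has large
  fold-to-fold spread (standard deviations of 0.1-0.2 are typical);
  single-seed comparisons between feature sets are noisy, which is why
  the validation properties are stated over seed ensembles.
* The BRS estimator assumes positive baroreflex coupling; genuinely
  inverted coupling is reported as missing, not estimated.
* EDH is present in only a few percent of patients, so its column is
  frequently near-degenerate at n = 41; it is kept as-is and simply
  gets dropped by the zero-variance rule in folds where it is constant.
* PSH-AM scoring itself is out of scope; the dichotomised risk label is
  an input.
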