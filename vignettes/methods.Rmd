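---
title: "Models and methods behind prepsaccade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prepsaccade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepsaccade)
```

# The scientific setting

A delayed saccade paradigm separates, in time, three neural events: a
symbolic cue that tells the participant *which kind* of eye movement to
prepare (a pro-saccade toward an upcoming target, or an anti-saccade away
from it), the appearance of the target and the outward saccade, and a
later return saccade to fixation. Because the preparation interval is long
and variable (6, 10 or 14 s) and the post-saccade hold and inter-trial
intervals are jittered, the BOLD responses of the three events are
separable by an event-related general linear model.

`prepsaccade` implements the full analysis chain for this paradigm —
design-matrix construction, per-voxel GLM, region-of-interest univariate
statistics, and multi-voxel pattern decoding — together with a generative
simulator, so that every estimator can be validated against known ground
truth and the qualitative scientific contrast (task-specific cortical
patterns versus amplitude-matched, pattern-free collicular responses) can
be demonstrated by parameter recovery.

# The forward model

Each voxel's time series in one run is

$$ y_v(t) \;=\; \sum_{e \in \text{events}} a(v, \mathrm{kind}_e)\,
   \tilde{x}_{\mathrm{kind}_e}(t) \;+\; \mu \;+\; d_v(t) \;+\;
   \varepsilon_v(t), $$

where $\tilde{x}_k$ is the unit-peak-scaled convolution of the kind's
0.5 s event boxcars with the hemodynamic response function, $\mu$ is the
baseline signal level, $d_v$ an optional low-frequency cosine drift and
$\varepsilon_v$ Gaussian noise (optionally AR(1)). Amplitudes are
expressed in the units of the unit-peak regressor; with zero noise and
drift the data are *exactly* the design matrix times the amplitudes, which
is what makes the end-to-end exactness test meaningful (GLM recovery to
numerical precision, not approximation).

The HRF is a difference of two gamma densities. With unit dispersion the
`dual_gamma` variant uses shapes 6 (response) and 16 (undershoot) with
undershoot ratio 1/6, peaking at 5.0 s — the field-standard
parameterisation of the dual-gamma form, adopted because the analysis this
package models cites the HRF only generically. The `early_peak` variant
re-parameterises the positive lobe to a 4.5 s mode (shape 5.5), leaving
the undershoot unchanged; the earlier peak suits collicular hemodynamics.

## Timing distributions

Preparation durations are drawn uniformly from {6, 10, 14} s. Hold and
inter-trial delays are integer seconds from a Poisson distribution
truncated to [2, 12] s. A Poisson with rate 4 truncated to that range has
mean ≈ 4.32, so the rate is calibrated by root search until the truncated
mean is exactly 4.0 s (`calibrate_delay_rate()` finds λ ≈ 3.595); the
stated mean governs design efficiency, so it is the quantity honoured.
Event onsets are not locked to the 1.5 s TR grid; regressors are built on
a 0.1 s grid (finer than every event-duration quantisation) and sampled at
volume times.

The total run length is emergent from the sampled durations rather than
forced to a target volume count, because the segment bookkeeping does not
uniquely determine a fixed length.

# Estimation choices

* **High-pass filtering** is projection onto the complement of a
  discrete-cosine drift basis: all DCT-II components with frequency below
  3 cycles/run, plus the mean. Projection (rather than recursive
  filtering) is idempotent and exactly testable; in the GLM the same basis
  enters as run-wise drift columns, which is equivalent and keeps the
  degrees of freedom explicit.
* **Univariate analysis** fits one GLM over the concatenated runs with
  direction-resolved execution regressors (6 task regressors plus the
  return saccade), run-wise drift and constants. The analysis unit is the
  hemisphere-ROI: with 6 participants the paired tests and the 2×2
  repeated-measures ANOVA run over 12 units, matching the 11 degrees of
  freedom that structure implies. Two-level factors need no sphericity
  correction.
* **Percent signal change** divides each unit's betas by its baseline
  level — the run-constant estimate averaged over the ROI — times 100,
  then removes residual between-unit gain by dividing each unit's values
  by that unit's grand mean across conditions and multiplying by the group
  grand mean. Whether the original analysis normalised percent signal
  change or raw betas is not recoverable; normalising the percent signal
  change is the package's choice and the operation is exposed directly so
  either input can be used.
* **ROI definition** intersects the thresholded execution-versus-baseline
  t-map (Benjamini–Hochberg FDR, the standard reading of "FDR(q)", or an
  uncorrected-p threshold — both are supported because both appear in the
  protocol) with an anatomical template label, standing in for manual
  identification of an activity patch at a known location. Anatomical
  definition (the template itself) is used where functional definition is
  impossible, e.g. for the null scenario.
* **"Scaling to unity"** of regressors is implemented as column-maximum
  = 1 (the unconvolved-peak alternative differs only by a constant per
  regressor and is absorbed by the amplitudes).

# MVPA decoding

Exemplars are per-run GLM betas under the direction-collapsed 5-regressor
scheme — one pro and one anti pattern per run, so 6 runs give 12
exemplars — estimated run by run so that leave-one-run-out folds are
statistically independent. Normalisation is two-stage: each participant's
feature block is scaled to root-mean-square 1 (removing between-participant
magnitude), then each class block within the participant is scaled to RMS
1 (removing between-class magnitude, so only spatial pattern can drive
decoding). "Normalised to 1.0" is ambiguous between RMS and maximum; RMS
is the default because it is gain-removing and insensitive to single
extreme voxels, and max-abs is available via `method = "max_abs"`.
Participants are then concatenated along the voxel axis, aligned by run
and class — the exemplar count stays 12 and the feature dimension grows,
which preserves fold independence (stacking exemplars instead would leak
runs across participants).

The classifier is a linear-kernel SVM with cost fixed at 1 on the
normalised features. An exemplar exactly on the decision boundary counts
as misclassified, and an all-constant training fold (no separating
direction) scores zero — both choices make degenerate cases deterministic.

## The permutation null

Significance uses the empirical 95th percentile of decoding accuracies
under label permutation. Two scheme decisions matter and both are
documented deviations from the most literal reading:

* **Within-run shuffling is the default.** Shuffling labels freely across
  all 12 exemplars leaves most training folds class-imbalanced; a
  soft-margin SVM then acquires a majority-class bias and, because the
  held-out run is skewed toward the *other* class, the null accuracy is
  biased below chance (≈ 41% rather than 50% in signal-free simulations).
  That contradicts the defining property of the null — chance-level
  accuracy with variance comparable to the true analysis. Shuffling within
  each run (flipping or keeping each run's pro/anti pair) preserves the
  design's balance in every fold and restores a chance-level null. Free
  shuffling remains available (`scheme = "free"`) for comparison.
* **Sampled nulls exclude the identity.** Within-run shuffling reaches
  only $2^{\text{runs}}$ assignments, two of which (the observed labeling
  and its global class swap) reproduce the true accuracy; leaving them in
  the sampled null occasionally drags the empirical 95th percentile up to
  the true accuracy itself. Random draws therefore use only genuinely
  different relabelings, consistent with the procedure's description;
  exhaustive enumeration (used by the oracle tests) keeps every
  assignment.

The accuracy-versus-sample-size curve draws, at each voxel count, fresh
random voxel subsets (20 by default), averages the true-label accuracies,
and computes a matching permutation percentile. The p-value-histogram
analysis draws a fresh subset and a fresh permutation per iteration and
compares the 6 true-label fold accuracies with the 6 permuted-label fold
accuracies by a two-sample t-test; the pairing of that t-test is
underdetermined in the source description, and the two-sample fold-accuracy
reading is the package's documented choice.

### A known miscalibration

The fold-accuracy t-test is anti-conservative under the null: the 6 fold
accuracies on each side are positively correlated (any two training sets
share 4 of 5 runs), so the t-test underestimates the variance of their
mean. In signal-free simulations with a fresh dataset and fresh labels per
draw, the fraction of p-values below 0.05 is about 0.10–0.11 rather than
0.05, for the pooled, Welch and paired variants alike. The package
implements the procedure as described and its acceptance suite asserts the
nominal binomial band, so that check fails by design and records the
miscalibration; the p-value histogram should be read as a descriptive
display (clustering at low values under genuine signal), not as a
calibrated test.

# The synthetic-data generator as study conditions

Scenarios encode the hypotheses under test, with per-voxel pattern values
drawn as Normal(1, 0.35) so voxels respond heterogeneously but mostly
positively:

| parameter | cortex_like | sc_like | null |
|---|---|---|---|
| preparation gain (pro / anti) | 0.8 / 1.3 | 1.0 / 1.0 | 0 |
| execution gain (both classes) | 2.0 | 2.0 | 0 |
| return-saccade gain | 0.8 | 0.5 | 0 |
| class patterns | independent per class | shared | — |

Execution responses are roughly twice the preparation responses, the
anti-saccade preparation gain exceeds the pro-saccade gain only in the
cortex-like scenario, and the collicular scenario's smaller return gain
reflects the weak return-saccade response there. Noise defaults to unit
Gaussian per volume (keeping OLS assumptions exact for the oracle tests;
AR(1) is available), drift to zero (so exactness tests are exact; cosine
drift below the high-pass cutoff is available), the baseline to 100
arbitrary units, and direction lateralisation to zero (no reliable
ipsi/contra amplitude difference is modelled). These values were fixed
once as the package's study conditions: strong enough that the
cortex-like contrast is detected reliably at desk-scale simulation sizes,
null by construction where the hypothesis says null.

What the generator does **not** emulate: eye-movement errors (none are
simulated; the modelled protocol discarded none), scanner artefacts
(spikes, motion, slice-timing), spatial autocorrelation between voxels,
and physiological noise structure beyond AR(1). Passing tests therefore
demonstrate correctness of the estimators and the internal consistency of
the inference chain under the stated generative model — not robustness to
real-scanner confounds.

# Problem sizes used by the test suite

The validation suite runs everything at reduced scale, chosen so the full
suite completes in minutes while keeping every statistical property
testable: oracle equivalence on 100 random small instances per estimator;
permutation-versus-enumeration on 4- and 6-exemplar miniatures; null
calibration of the decoding criterion over 50 signal-free replicates
(2 participants × 6 runs, 8-trial runs, 24 voxels, 160 permutations);
the cortex-versus-colliculus contrast over 50 univariate replicates
(6 participants × 4 runs, 12-trial runs) and 15 decoding replicates per
scenario (3 participants × 6 runs); and a rising decoding curve checked at
higher noise (so accuracy is not yet saturated over the tested sizes).
The acceptance script uses the full 20-trial run design.

# Numerical notes and degenerate inputs

* Convolution grid 0.1 s; HRF support 32 s; peak finding on a 1 ms grid.
* Rank-deficient designs are rejected naming the collinear columns; zero
  residual variance with a nonzero contrast yields a signed-infinity t.
* Effect sums of squares below $10^{-12}$ of the total SS report F = 0
  (they are rounding residue of an exactly-null effect).
* A paired test on exactly identical samples returns t = 0, p = 1;
  constant nonzero differences are an error (the statistic is undefined).
* All-zero exemplar blocks cannot be normalised and raise an error rather
  than propagating NaN.
* Seeds: `make_dataset()` and the pipeline derive named child seeds from
  one master seed (`child_seed()`), so adding a stage never perturbs the
  streams of earlier stages and every report is reproducible from config
  plus seed.

# Limitations

* The decoding significance criterion is the empirical 95th percentile of
  a finite permutation sample; with within-run shuffling the support has
  only $2^{\text{runs}}$ points, so the smallest achievable p-value is
  limited by the run count (with 6 runs, 1/32 after identity exclusion up
  to the swap symmetry).
* The fold-accuracy t-test of the p-value-histogram analysis is
  anti-conservative (see above).
* Real-data quantities that depend on the original scans — group
  statistics tables, peak decoding accuracies, histogram counts — are out
  of scope; no raw data are distributed, so the package validates the
  method, not the published point estimates.
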