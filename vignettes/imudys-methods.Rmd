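---
title: "Methods: severity estimation from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity estimation from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imudys)
```

## The problem

Dystonia in dyskinetic cerebral palsy is rated clinically on an ordinal
0–4 scale per limb per 5-second window, following the amplitude definition
of the Dyskinesia Impairment Scale. `imudys` treats each scored
(window, limb) pair as one supervised sample: the input is the 5-s block of
that limb's inertial sensor (free acceleration, angular velocity, Euler
angles at 60 Hz), the label is the median of three clinicians' integer
ratings, and the task is 5-class classification whose ordinal structure is
assessed afterwards through RMSE and adjacent-class error analysis rather
than built into the losses.

## The synthetic generative model

Clinical IMU recordings of this population are not freely available at
development scale, so the package ships a first-class simulator
(`cohort_config()`, `generate_cohort()`) whose outputs exercise every
pipeline contract. Its structure is the minimal one under which an
amplitude-based severity definition is learnable:

* **Severity dynamics.** Per limb, the true score follows a sticky
  first-order Markov chain over 0–4 (default: stay probability 0.6,
  remainder on adjacent scores; the chain starts from its stationary
  distribution). This mimics severity that fluctuates slowly across
  windows.
* **Movement signal.** Within a window, acceleration and angular-velocity
  channels carry baseline Gaussian sensor noise (sd 0.05 channel units)
  plus a sum of two sinusoids with frequencies uniform in 0.5–3 Hz —
  the band of slow dystonic movement — and random phases, with amplitude
  `amplitude_per_score[score] × subject_factor`. The default amplitudes
  `(0, 0.5, 1, 2, 4)` are spaced geometrically so neighbouring classes
  overlap under noise, which is what produces the realistic
  neighbouring-class confusion structure downstream. Orientation channels
  integrate the angular velocity (cumulative sum × dt) and wrap to
  [−180, 180)°.
* **Heterogeneity.** Subject factors are log-normal,
  `exp(N(0, subject_heterogeneity_sd))` (default sd 0.3): two subjects
  with the same clinical score move with different amplitudes, which is
  exactly what separates individual from generalized model performance.
* **Raters.** Each of three raters reports
  `round(true + N(0, rater_noise_sd))` clipped to 0–4 (default sd 0.3);
  the median is the label, so most label noise is one level and
  symmetric.
* **Artifacts.** Timestamps drop out independently (`missing_rate`),
  whole sensors fail by truncation at a uniform point
  (`sensor_failure_prob`), and some (window, limb) pairs are unscorable
  (`unscorable_rate`), emulating the data losses of home measurement.

What the simulator does *not* model: biomechanically realistic limb
kinematics, voluntary-activity confounds (eating, wheelchair driving…),
choreoathetic jerk profiles, or rater biases that differ systematically
between clinicians. Passing recovery tests on this cohort therefore
demonstrates that the pipeline's machinery is correct and leakage-free,
not that it attains any particular accuracy on clinical recordings.

All randomness flows from one master seed through named substreams (per
subject, recording and limb), so regenerating any subset of a cohort is
stable and two runs with one config are bit-identical.

## Ingest and synchronization

Sensors drop timestamps independently, so the four streams are aligned by
linear interpolation onto a uniform grid at the nominal rate over the
*intersection* of the four sensors' observed ranges. The uniform-grid
choice (rather than snapping to one master sensor's clock) keeps 5-s
windows at exactly 300 samples; it is noted as an interpretation point.
Decisions worth knowing:

* Euler angles are interpolated on the unwrapped scale and rewrapped, so
  a yaw crossing +179° → −179° interpolates near ±180°, never through 0.
* A grid point counts as "observed" if a raw timestamp lies within 1 ms;
  otherwise it is flagged interpolated, and `validate_recording()`
  reports per-sensor interpolated fractions.
* Duplicate raw timestamps are averaged with a warning; recordings with
  an empty four-sensor overlap are excluded and counted, not patched.
* Windows whose limb sensor is more than 50% interpolated are flagged
  (`high_interp`) but retained; the flag is carried in the metadata for
  sensitivity analyses.

Annotations referencing windows beyond a truncated recording are dropped
and counted by `align_labels(strict = FALSE)` (the pipeline default),
since sensor failure after video scoring is an expected data loss; strict
mode turns them into errors for curated datasets.

## Features

The ten feature classes are named but not defined in most clinical ML
reports, so the definitions are fixed here explicitly (n = 300 samples s):

| class | definition |
|---|---|
| absolute harmonic mean | n / Σ 1/max(\|s\|, ε) |
| absolute maximum | max \|s\| |
| bandpower | mean periodogram power over (0, Nyquist] of the mean-removed signal (FFT); equals mean AC power by Parseval |
| geometric mean | exp(mean log max(\|s\|, ε)) |
| maximum, median, minimum | order statistics |
| RMS / RSS | √(mean s²) / √(Σ s²) |
| Shannon entropy | −Σ s² ln s², with 0·ln 0 = 0 (signal-energy entropy) |

ε = 1e−12 channel units makes every class total. The energy form of the
entropy and the periodogram bandpower are deliberate choices among several
defensible readings; both are pinned by oracle tests (brute-force
re-implementations and the Parseval identity at 1e−9 relative tolerance).
Min–max normalization is fitted on training partitions only and clips
out-of-range test values to [0, 1]; constant training columns map to 0.
This leakage-free variant is the default even though a global scaling
would be marginally simpler, because fold-wise refitting is the variant
whose metrics are trustworthy.

## Selection, training and evaluation protocol

* **Screening** (`screen_feature_classes()`): one feature class × 11
  signals → 11-dimensional vectors, cross-validated with each algorithm
  family at defaults; a class passes if its best macro F1 ≥ 0.7. The
  shipped default catalogue is the ten-class post-screening set, so the
  screening harness is generic rather than re-run on every use.
* **SFS** (`sequential_forward_selection()`): greedy forward wrapper,
  inner-CV misclassification objective, budget of 20 candidate
  evaluations counted per scored candidate (the natural reading of an
  "objective evaluation" cap). Ties break to the lower column index for
  determinism. The baseline objective is the majority-class error, so a
  first feature must beat label frequency to be accepted.
* **Tuning** (`tune_hyperparameters()`): sequential model-based
  optimization — Latin-hypercube initial design, Gaussian-process
  surrogate (squared-exponential kernel, fixed length-scale 0.3 on the
  unit cube, nugget 1e−6), expected-improvement acquisition over a random
  candidate pool — spending exactly 15 objective evaluations and
  returning the best-observed configuration. Search spaces per family are
  bounded by what the underlying fitters expose: k for k-NN; minbucket
  and split criterion for trees; linear vs quadratic discriminant; cost
  and kernel scale for the RBF-SVM; the density floor for naive Bayes;
  tree count and mtry for the bagged ensemble.
* **First-fold protocol**: SFS lists and tuned hyperparameters are
  computed on fold 1's training partition and reused on the remaining
  folds. This mirrors the home-measurement study protocol exactly; it is
  statistically unusual (fold 1's artifacts see data that later folds
  treat as test), which is why validation-F1 — not test-F1 — drives model
  selection, and why ties prefer the simpler setting
  (ALL < SFS < ALL+HYP < SFS+HYP).
* **Oversampling** duplicates minority-class training rows to the
  majority count; it never touches validation or test partitions
  (asserted by provenance tests on normalization parameters and row
  identity).
* **Metrics**: macro averaging over classes present in the true labels,
  with zero-division precision/recall scored 0 and kept in the mean. The
  macro choice is recorded in every report (`averaging` field) because
  multi-class F1 conventions differ and materially affect sparse
  classes. RMSE treats labels as integers; `adjacent_error_fraction()`
  summarizes how often errors confuse neighbouring severities.

## Degenerate inputs and numerical choices

Single-class training data yields a constant predictor for every family;
quadratic discriminant falls back to linear and then to the majority class
when a fold is too small for its covariance estimates; zero-variance
columns are dropped for density-based fitters; k for k-NN is capped at the
training size. Feature extraction guards logs and reciprocals with ε, so
no feature is ever non-finite on finite input (a hard error names the
row/column otherwise).

## Problem sizes used in the shipped checks

The recovery experiments in the test suite use 12 simulated subjects with
3 recordings × 60 s each (36 windows per subject and limb, ≈70 upper-limb
samples per subject), rater noise sd 0.3, and the ALL-setting grid over
k-NN, decision tree and ensemble — sizes at which individual models, the
generalized model and the heterogeneity contrast are all comfortably
resolved on one CPU in about a minute. The heterogeneity contrast compares
`subject_heterogeneity_sd` 0 vs 0.8 at paired seeds. The worked example in
the README uses a 4-subject cohort for the same reason. These are the
package's chosen demonstration scales; nothing in the implementation is
specific to them.

## Known limitations

* The simulator's amplitude-only severity encoding means features beyond
  amplitude surrogates (e.g. entropy) carry little independent signal in
  synthetic cohorts; on clinical data their value may differ.
* The generalized-model experiments inherit the protocol's small-cohort
  limits: leave-two-subjects-out folds are few, and fold-to-fold variance
  is high.
* Ordinality is not modelled in training (classifiers treat scores as
  unordered); only the evaluation acknowledges scale structure.
* Feature definitions that the field leaves underspecified (entropy,
  bandpower) are fixed by explicit choice here; comparisons against other
  implementations should confirm conventions first.
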