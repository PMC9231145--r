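# imudys

Estimating the clinical severity of **dystonia** from body-worn inertial
sensors. Children and young adults with dyskinetic cerebral palsy show
involuntary postures and slow movements whose severity fluctuates over the
day; clinicians currently rate it from video on an ordinal 0–4 scale
(following the amplitude definition of the Dyskinesia Impairment Scale),
which is slow, subjective, and captures only a snapshot. `imudys`
implements a complete home-measurement analysis pipeline that learns to
reproduce those ratings from four limb-worn IMUs (left/right forearm,
left/right lower leg; 60 Hz free acceleration, angular velocity and Euler
angles), plus a synthetic-cohort simulator with known ground truth so every
stage is testable without clinical data.

## The method

For each recording, the four sensor streams are synchronized by linear
interpolation onto a common 60 Hz grid (Euler angles are interpolated on
the unwrapped scale), resultant channels

a_r = √(a_x² + a_y² + a_z²),  ω_r = √(ω_x² + ω_y² + ω_z²)

are derived so each sensor exposes 11 signals (44 across sensors), and the
recording is cut into non-overlapping 5-s windows of 300 samples — the same
windows three clinicians score per limb; the median of the three ratings is
the label. Per window and limb, 10 feature classes (absolute harmonic mean,
absolute maximum, FFT bandpower, geometric mean, maximum, median, minimum,
RMS, root-sum-of-squares, Shannon signal-energy entropy) are extracted from
each of the 11 signals, giving 110 features, min–max scaled to [0, 1] with
parameters fitted on training data only.

Six classifier families (decision tree, discriminant analysis, naive
Bayes, RBF-SVM, k-nearest neighbours, ensemble/bagged trees) are trained
under four settings — all features or sequential-forward-selected features
(SFS, misclassification-rate objective, 20-evaluation budget), each with or
without Bayesian hyperparameter tuning (Gaussian-process surrogate,
expected improvement, 15 evaluations on the first fold, reused on the
rest). Training partitions are randomly oversampled to equal class counts.
**Individual** models use a subject's own data under stratified 5-fold
cross-validation; **generalized** models use leave-two-subjects-out
cross-validation (6 folds for 12 subjects, 10 training subjects per fold).
Models are compared by macro precision / recall / F1 (Eqs. below), RMSE on
the 0–4 scale and 5×5 confusion matrices; the variant with the highest
validation F1 is each dataset's final model.

precision = TP/(TP+FP),  recall = TP/(TP+FN),  F1 = 2·P·R/(P+R)

## Worked example

```r
library(imudys)
cfg <- run_config(
  cohort = cohort_config(n_subjects = 4, recordings_per_subject = 2,
                         recording_seconds = 60, rater_noise_sd = 0.3,
                         subject_heterogeneity_sd = 0.3),
  extremity = "upper",
  experiment = experiment_config(algorithms = c("knn", "decision_tree", "ensemble"),
                                 settings = c("ALL", "SFS")),
  seed = 7)
run <- run_experiment(cfg)
run$leaderboard$individual
```

```
  subject dataset algorithm model f1_validation   f1_test precision_test recall_test
1     S01   upper  ensemble   ALL     0.9594366 1.0000000      1.0000000   1.0000000
2     S02   upper       knn   SFS     0.8720116 0.8997373      0.9464286   0.8904762
3     S03   upper  ensemble   ALL     1.0000000 1.0000000      1.0000000   1.0000000
4     S04   upper  ensemble   ALL     0.9575290 0.9035088      0.9750000   0.8750000
```

Each row is one subject's best individual model (picked by validation F1):
e.g. subject S02's winner is a k-NN on SFS-selected features whose pooled
held-out windows score macro F1 0.90. The generalized (cross-subject)
model and its error structure:

```r
gen <- run$results$upper$generalized
gen$best$variant$test
#> <evaluation_report> n=150  macro F1=0.949  precision=0.943  recall=0.956  RMSE=0.216
gen$best$variant$test$confusion
#>     predicted
#> true  0  1  2  3  4
#>    0 10  0  0  0  0
#>    1  1 34  0  0  0
#>    2  0  0 34  0  0
#>    3  0  0  0 45  3
#>    4  0  0  0  3 20
```

Every misclassification lands on a neighbouring severity level
(adjacent-error fraction 1.00) — the confusion structure expected when the
underlying scale is ordinal. With larger between-subject heterogeneity
(`subject_heterogeneity_sd = 0.8`) the generalized F1 drops sharply while
individual models stay accurate, reproducing the individual-vs-generalized
gap seen in home-measurement studies.

See the methods vignette (`vignettes/imudys-methods.Rmd`) for the
generative model, feature definitions, protocol choices and limitations.

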