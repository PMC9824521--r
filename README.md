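# hrvstress

Daily physical-stress estimation for elderly residents from two passive
data streams: smartwatch heart-rate samples and in-home activity-interval
logs. The package is aimed at digital-health researchers who want a fully
testable, end-to-end implementation of the Lorenz-plot / mixed-indicator
pipeline — including a synthetic-cohort generator, since studies of this
kind rarely deposit their raw data.

## What it computes

**Biometric features.** Heart-rate samples (bpm, nominally every 15 s) are
converted to R-R intervals, RRI = 60/bpm × 1000 ms. Consecutive pairs
(RRI(t), RRI(t+1)) form the Lorenz (Poincaré) plot; with u = (a+b)/√2 and
v = (a−b)/√2, the ellipse area

    S = π · δx · δ(−x),   δx = sd(u), δ(−x) = sd(v)

summarises short-term heart-rate variability, computed per analysis window
and per activity (pairs never bridge dropouts or activity boundaries).

**Gender-normalised indicators.** For subject *s* and activity *a*, the
activity indicator Ai divides the 24 h time-share Ar by its gender-group
mean; the biometric indicator Bi does the same with the per-activity
Lorenz area Br; and the mixed indicator is their product,

    Mixed[s,a] = Ai[s,a] × Bi[s,a],

combining how long an activity was performed with how stressful it
appears to have been.

**Classification.** Morning/night five-point Likert answers map to three
classes (bad / neutral / good). The classifier is an imbalance-aware
ensemble: SMOTE oversampling to fixed per-class targets (bad 100, neutral
100, good 200; k = 3, random state 0), then ten members, each a random
forest on a balanced with-replacement undersample (seeds 1..10), combined
by majority vote with ties resolved toward *bad*. Five nested feature
variants (`baseline1`, `baseline2`, `previous`, `proposed1`, `proposed2`)
are compared with stratified 3-fold cross-validation, accuracy and
per-class F1.

**Synthetic cohorts.** `simulate_cohort()` generates households with
gendered activity schedules, a latent daily AR(1) stress state that
shrinks within-activity RRI dispersion and tilts the day's time budget,
and questionnaire answers binned from that state — so every stage of the
pipeline is testable without access to private study data. See the
methods vignette (`vignettes/stress-estimation.Rmd`) for what the
generator does and does not emulate.

## Worked example

```r
library(hrvstress)

cfg     <- cohort_config(n_households = 3, n_days = 10, seed = 42)
cohort  <- simulate_cohort(cfg)
cohort
#> Synthetic stress cohort: 5 subjects in 3 households, 10 days
#>   heart-rate samples: 282187   activity intervals: 485   answers: 100

features <- build_dataset(cohort, variant = "proposed2")
cv <- evaluate_question(cohort, "proposed2", "NQ", features = features)
cv
#> 3-fold stratified CV (over_under_bagging): accuracy 0.820 on 50 rows
#>     class support recall precision    f1
#> 1     bad       9  0.889     0.800 0.842
#> 2 neutral      12  0.667     0.615 0.640
#> 3    good      29  0.862     0.926 0.893
```

The cohort holds five subjects over ten days, so the night question (NQ)
gives 50 rows. The ensemble reaches 0.82 accuracy against a
majority-class rate of 0.58 — the synthetic stress signal, coded into
per-activity RRI dispersion and durations, is recovered; the per-class F1
table shows the minority *bad* class is detected too, which is what the
resampling pipeline is for. `compare_methods(cohort)` runs all five
feature variants on both questions with shared fold splits and prints the
MQ/NQ/Mean accuracy table.

The four CSV schemas (subjects, heart rate, activity intervals, answers)
are documented in `load_subjects()`, `load_heart_rate()`,
`load_activity_log()` and `load_answers()`; `write_cohort()` /
`read_cohort()` round-trip a cohort through them. A thin command-line
wrapper over these functions is installed at
`inst/scripts/stress_pipeline.R`.

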