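# petlat

Lateralization of mesial temporal lobe epilepsy (TLE) from interictal
FDG-PET regional asymmetry indices.

In mesial TLE, the temporal lobe ipsilateral to the seizure focus is
typically hypometabolic on interictal FDG-PET. `petlat` quantifies this
with a regional **asymmetry index** over thirteen left/right homologous
regions (hippocampus, parahippocampal gyrus, amygdala, temporal gyri and
poles, insula, and perisylvian regions):

```
AI = 200 * (L - R) / (L + R)
```

The index is antisymmetric under hemisphere exchange, invariant to global
intensity scaling, and negative for left-sided hypometabolism. On top of
the AI vector the package trains and evaluates two interpretable
classifiers for Left-vs-Right lateralization:

* **`train_c45()`** — an entropy-based decision tree (C4.5 style):
  gain-ratio splits at midpoint thresholds, error-based pruning.
* **`train_lmt()`** — a logistic model tree: LogitBoost with simple linear
  base learners, iteration count chosen by internal cross-validation,
  producing antisymmetric per-class linear scores.

Evaluation tools include stratified train/test splits (`make_split()`),
stratified k-fold cross-validation (`cross_validate()`), correct
lateralization ratios that count non-calls as errors (`correct_ratio()`),
and Cohen's kappa with its null-hypothesis z statistic (`cohens_kappa()`).
A synthetic PET cohort generator (`generate_cohort()`,
`generate_feature_table()`) provides seeded, calibrated test data — no
patient data is included — and `published_rules()` ships the fixed
reference models for reproducibility.

## Worked example

The shipped reference rules, and the canonical false-lateralization case
they share — a subject with a definitive Left focus whose PET shows
relative right-sided hypometabolism:

```r
library(petlat)
rules <- published_rules()
rules$j48_test_model
#> <ai_tree> C4.5-style lateralization tree
#> AI[Hippocampus] <= 3.18: Left
#> AI[Hippocampus] > 3.18: Right

patient <- worked_example_features()
patient
#> # A tibble: 1 × 4
#>   subject_id label Hippocampus Temporal_Pole_Mid
#>   <chr>      <chr>       <dbl>             <dbl>
#> 1 patient12  Left         5.71              7.94

predict(rules$j48_test_model, patient)
#> [1] "Right"
linear_scores(rules$lmt_test_model, patient)
#> # A tibble: 1 × 3
#>   score_Left score_Right prediction
#>        <dbl>       <dbl> <chr>
#> 1     -0.635       0.635 Right
```

Training on a synthetic cohort at the study scale (49 subjects, 27:22
Left:Right, hippocampal deficit of 6%):

```r
tab <- generate_feature_table(cohort_config(seed = 1))
train_c45(tab)
#> <ai_tree> C4.5-style lateralization tree
#> AI[Hippocampus] <= -0.171158: Left
#> AI[Hippocampus] > -0.171158: Right

cross_validate(tab, k = 5, algo = "lmt", seed = 1)
#> <ai_cv> lmt, 5-fold: mean correct lateralization 49/49 (100%)
```

The full pipeline — simulate (optionally through NIfTI volumes), extract
features, split, train, predict, evaluate, cross-validate — is one call:

```r
run_pipeline(list(out_dir = "out", seed = 1, algorithm = "lmt"))
```

or, from the shell, via the thin CLI wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "petlat.R", package = "petlat"))')" run --out out --seed 1 --algo lmt
```

Tidyverse accessors are provided throughout: `tidy()` and `glance()` on
models, kappa and cross-validation objects, and `autoplot()` on feature
tables, linear models, and cross-validation results.

## Methods

See the methods vignette (`vignettes/methods.Rmd`) for the model, the
closed-form generator calibration, numerical conventions (midpoint
thresholds, tie-to-Right, pruning confidence, LogitBoost clamping), and
the generator's scope and limitations.
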