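---
title: "Methods: asymmetry-index lateralization of temporal lobe epilepsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asymmetry-index lateralization of temporal lobe epilepsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petlat)
```

## The problem and the model

In mesial temporal lobe epilepsy (TLE), interictal FDG-PET typically shows
hypometabolism in the temporal lobe ipsilateral to the seizure focus.
`petlat` turns that observation into a classifier. For each of thirteen
left/right homologous regions (hippocampus, parahippocampal gyrus, amygdala,
temporal gyri and poles, insula, and selected perisylvian regions — see
`region_pairs()`), the package computes a regional **asymmetry index**

$$ AI = 200 \cdot \frac{L - R}{L + R} $$

where $L$ and $R$ are the mean regional uptake values. The index is
dimensionless, antisymmetric under hemisphere exchange, invariant to any
global scaling of the image (injected dose, scanner calibration, global
metabolism), and bounded in $(-200, 200)$. Left-sided hypometabolism drives
$AI$ negative, so Left TLE subjects show negative indices in affected
regions.

Two classifiers map the 13-dimensional AI vector to a `"Left"`/`"Right"`
lateralization:

* **`train_c45()`** — an entropy-based decision tree in the C4.5 style:
  binary splits on `AI[region] <= threshold`, chosen by gain ratio, with
  error-based (pessimistic) pruning at confidence `cf = 0.25`.
* **`train_lmt()`** — a logistic model tree trained with LogitBoost using
  simple (one-variable) weighted least-squares base learners, yielding
  antisymmetric per-class linear scores over the AIs.

The package also ships fixed reference rules (`published_rules()`): a
single-node hippocampal tree (`AI[Hippocampus] <= 3.18: Left`) and a small
linear model over the hippocampal and mid temporal pole AIs, plus the
per-fold models from a five-run cross-validation analysis.

## Numerical and algorithmic choices

**Midpoint thresholds.** Candidate thresholds for tree splits are midpoints
between consecutive distinct observed values (`threshold_style =
"midpoint"`, the default). This places the cut inside the empirical gap
between classes and makes the rule robust to ties;
`threshold_style = "observed"` reproduces the convention of splitting at an
observed value instead.

**Ties resolve to `"Right"`.** Wherever a decision is exactly balanced — a
leaf with equal class counts, or a linear score of exactly zero — the
prediction is `"Right"` (the second class in `tle_classes()`). A fixed
deterministic convention keeps training and prediction reproducible; tests
assert it explicitly so it cannot drift silently.

**Gain ratio with a minimum-gain guard.** Splits must improve information
gain by more than `1e-12` before the gain ratio is evaluated, avoiding
division-by-near-zero artifacts on uninformative features. Both children of
a split must contain at least `min_leaf = 2` cases.

**Pessimistic pruning.** Subtrees are collapsed when the upper confidence
bound of the leaf error, `qbeta(1 - cf, E + 1, N - E)` scaled to counts,
does not exceed the summed bound of the subtree (plus a 0.1 tolerance, the
standard C4.5 convention).

**Root-only logistic model trees.** `train_lmt()` always fits the logistic
model at the root rather than growing a tree of logistic nodes. At the
cohort sizes this package targets (tens of subjects), the standard
minimum-split heuristic (`min_split = 15`) would almost never allow an
interior logistic node, and the reference analyses this package mirrors all
produced root-only models; the simpler estimator is therefore the honest
one. The LogitBoost iteration count is chosen by an internal stratified
5-fold cross-validation (ties go to the smaller count), with working
responses clamped at $|z| \le 3$ and weights floored at $10^{-24}$ for
numerical stability. Internal folds are constructed so that relabeling the
classes leaves the folds intact, which makes the fitted model exactly
antisymmetric under label exchange — a property the tests verify to
$10^{-10}$.

**Cohen's kappa.** `cohens_kappa()` reports the chance-corrected agreement
$\kappa = (p_o - p_e)/(1 - p_e)$ together with the null-hypothesis standard
error
$SE_0 = \sqrt{p_e + p_e^2 - \sum_i p_{i+} p_{+i}(p_{i+} + p_{+i})} \,/\,
((1 - p_e)\sqrt{n})$, the $z = \kappa / SE_0$ statistic, and its one-sided
p-value. On the fixed 18-subject reference cohort this reproduces
$\kappa = 0.775, z = 3.288$ (tree) and $\kappa = 0.889, z = 3.795$ (linear
model) exactly.

**Evaluation.** `make_split()` produces stratified train/test partitions by
largest-remainder allocation (a 49-subject, 27:22 cohort at fraction 31/49
yields the canonical 31/18 split with 17 Left + 14 Right in training).
`make_folds()` assigns classes round-robin with a continuing offset, so a
49-subject cohort at $k = 5$ gives fold sizes 10, 10, 10, 10, 9 with
per-fold class counts as even as the integers allow. `correct_ratio()`
counts non-calls (e.g. `"No lateralization"`) as incorrect.

## The synthetic cohort generator

No patient data ships with the package. `generate_cohort()` and the faster
`generate_feature_table()` produce synthetic cohorts whose defaults are the
study conditions the methods were designed for: `n_subjects = 49` with a
27:22 Left:Right composition, and a regional effect map in which the
ipsilateral region's uptake is reduced by a factor $(1 - \delta)$ (an
optional contralateral gain $(1 + g)$ defaults to $g = 0$), with $\delta$
ranging from 0.06 (hippocampus) down to 0.01 (supramarginal gyrus). Under
that construction the noise-free asymmetry index is, in closed form,

$$ AI = 200\,\frac{(1+g) - (1-\delta)}{(1-\delta) + (1+g)}
      = \frac{200\,(\delta + g)}{2 + g - \delta}, $$

where $g$ is the contralateral gain (`expected_ai(delta, gain)`, default
$g = 0$). For $\delta = 0.06$ this is $200 \cdot 0.06 / 1.94 =
`r round(expected_ai(0.06), 6)`$, negative for Left subjects. The generator is calibrated
against this formula: with vanishing noise the volume-level pipeline
(`generate_subject()` → `region_means()` → `compute_features()`) recovers
$-6.185567$ to $10^{-6}$.

The volume layer builds a mirror-symmetric block atlas
(`generate_atlas()`), draws per-pair baseline uptakes, applies the planted
effect, Gaussian voxel noise (`voxel_noise_sd = 5`), and a per-subject
global intensity scale drawn from `global_scale_range = c(0.8, 1.2)` —
which the asymmetry index must, and does, cancel.
`generate_feature_table()` skips the volumes and draws AIs directly as
$N(\pm$`expected_ai`$(\delta),$ `ai_noise_sd`$^2)$ with
`ai_noise_sd = 2`, matching the empirical magnitude of regional AIs of a
few percent.

**Scope and limits.** The generator models effect *magnitudes* and
*additive noise* only. It does not model inter-regional correlation of
uptake, partial-volume effects, registration error, bilateral or
extratemporal hypometabolism, or the non-lateralizing patterns that make
real cohorts hard. Accuracies on synthetic cohorts are therefore
upper bounds — they validate the estimators, not the clinical difficulty.

## Problem sizes

All development and testing uses cohorts of 10–600 subjects (49 is the
canonical size), 13 features, atlases up to $64 \times 64 \times 48$ voxels
at 2 mm, and $k \in \{5, 10\}$ folds. Five-fold cross-validation of either
classifier on a 49-subject table runs in well under a second.

## A worked example

```{r worked}
rules <- published_rules()
patient <- worked_example_features()
patient

predict(rules$j48_test_model, patient)
linear_scores(rules$lmt_test_model, patient)
```

This subject has a definitive *Left* focus but clearly positive temporal
AIs (relative *right*-sided hypometabolism on PET), so both fixed rules
lateralize to the Right — the canonical false lateralization case both
models share.

## Limitations

* The classifiers are binary (Left vs Right); bilateral, non-lateralizing,
  or extratemporal cases are out of scope, and `cohens_kappa()` refuses
  non-binary inputs unless they are filtered first.
* The reference rules were fit on a small cohort; they are shipped for
  reproducibility, not as clinical tools.
* Synthetic performance overstates clinical performance (see generator
  limits above).
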