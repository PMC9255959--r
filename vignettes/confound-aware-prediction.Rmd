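---
title: "Confound-aware prediction in multi-site cohorts"
author: "ConfoundCV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confound-aware prediction in multi-site cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ConfoundCV)
```

## The problem

Large multi-site cohort studies relate a high-dimensional feature table
$X$ (here: structural brain morphometrics, one row per subject) to a
phenotype $y$ (here: a binary adolescent alcohol-misuse label derived
from longitudinal questionnaire scores). Two categorical variables
confound such analyses: **sex** and **recruitment site**. Both are
recoverable from the features (brains differ by sex; scanners and
populations differ by site) and both correlate with the phenotype
(misuse prevalence differs by sex and by site). A classifier can
therefore reach "significant" accuracy along the pathway
$X \to c \to y$ without ever touching the biological signal of
interest. ConfoundCV packages the full defensive workflow: correction
techniques, diagnostics that detect residual confounding, a two-stage
evaluation design, and attribution with a stability rule.

## The evaluation design

The analysis subjects (after excluding moderate misusers) are split
once into an **explore** set (80%) and a **holdout** set (20%),
stratified on label, sex and site where cell sizes permit
(`splitExploreHoldout()`). All model comparison, phenotype selection and
hyperparameter search happen on the explore set with a nested
cross-validation: 7 outer folds; inside each outer-training portion a
5-fold inner CV scores every hyperparameter combination by balanced
accuracy, ties broken by grid order (`nestedCV()`). The holdout is
scored once, by retraining the frozen winning configuration 7 times
with different seeds (`holdoutEvaluate()`); hyperparameters are *not*
re-searched during those retrainings. Significance comes from a
train-shuffle permutation test: the entire pipeline - resampling,
preprocessing, fitting - is re-run on shuffled training labels while
test labels stay fixed, and the add-one estimator
$p = (1 + \#\{s_{null} \ge s_{obs}\})/(n_{perm}+1)$ is reported
(`permutationTest()`), Bonferroni-adjusted over the number of parallel
analyses (3 by default, mirroring a three-timepoint design).

Balanced accuracy - the mean of per-class recalls - is the headline
metric throughout, because counterbalancing and moderate-exclusion both
change class ratios; chance is $1/\#\text{classes}$ regardless of
imbalance.

## Confound correction

Three techniques operate on training data only:

* **Confound regression** (`fitConfoundRegressor()` /
  `applyConfoundRegressor()`): per-feature OLS on
  `[intercept | one-hot sex | one-hot site]` main effects; the residuals
  are passed on. Drop-first encoding avoids collinearity. The fit
  removes *every per-category mean shift* but cannot remove
  category-dependent variance or interaction structure - a deliberate
  limitation that the diagnostics below exploit.
* **Counterbalancing by undersampling / oversampling**
  (`counterbalance()`): within every joint sex x site cell of the
  training set, the two label classes are equalized - down to the cell
  minimum (dropping rows) or up to the cell maximum
  (sampling-with-replacement of the minority). Joint (rather than
  marginal) balancing is used because it guarantees both marginals and
  makes the cell x label chi-square statistic *exactly* zero on the
  resampled multiset, which the tests assert. Cells missing one class
  are dropped with a warning. Oversampling never shrinks the training
  set; undersampling never grows it - the power argument for preferring
  oversampling.

Standardization (`fitStandardizer()`) uses training-only means and
population (divide-by-$n$) standard deviations, drops zero-variance
training columns, and is fitted *after* resampling, since the resampled
multiset is what the model sees. A per-block outlier rule
(`excludeOutlierSubjects()`) removes subjects whose block-mean feature
intensity lies more than 3 SD from the cohort mean, before any split.

## The five-way diagnostic battery

`runSameAnalysisChecks()` evaluates five input-output combinations with
the *same* folds and the *same* model family as the main analysis:
$X \to y$, $X \to c_{sex}$, $X \to c_{site}$, $c_{sex} \to y$,
$c_{site} \to y$. Confounds as inputs are full one-hot encoded;
confounds as targets are scored with multiclass balanced accuracy.
Each row carries its own train-shuffle permutation p-value. The logic:

* before correction, all five rows can be significant;
* after a *successful* confound regression the $X \to c$ rows should be
  at chance for the model family actually used - but a kernel model can
  remain significant if non-linear confound channels survive the linear
  regression;
* after successful counterbalancing the $c \to y$ rows must be at
  chance. Confound regression leaves the $c \to y$ rows untouched
  (residualizing $X$ cannot change the $c$-$y$ association), so the
  battery reports them unmodified in that mode.

## The cohort simulator

Because the motivating data are access-restricted, every claim the
package makes is exercised on simulated cohorts with known generative
truth (`generateCohort()`). Severity (safe / moderate / heavy) is drawn
first, per (sex, site) cell; features and misuse-score trajectories are
generated conditional on it, so label-recovery and attribution tests
have exact ground truth. Per subject $i$ and feature $f$:

$$X_{if} = s_x a_f [male_i] + s_s b_{f,site_i}
  + s_{int}\, g_f [male_i]\, h(site_i) + d_f \delta(sev_i)
  + \varepsilon_{if},\qquad
  \varepsilon_{if} \sim N(0, v_{site_i}^2).$$

The two *non-linear* confound channels are the per-site residual scales
$v$ (variance, invisible to mean regression) and the sex x site
interaction means $g_f h(s)$ (outside the main-effects span). Both are
detectable by an RBF classifier, neither is removed by linear confound
regression - which is exactly the failure mode the battery is designed
to expose. Defaults (`cohortConfig()`): 1400 subjects, 8 sites with
mildly decreasing sizes, 719 features in two blocks (656 "t1w", 63
"dti"), 20 informative features whose heavy-vs-safe shifts spread over
0.5-1.5 x a nominal d = 0.5 (so a single largest effect exists),
sex/site/interaction scales 0.25 / 0.35 / 0.6 and variance multipliers
0.7-1.4. The effect scales were fixed once, from a pilot power
simulation, so that each channel is individually detectable by the
matching model family at n = 1000 and 100 features; they are
qualitative stand-ins, not estimates of any real cohort. Misuse scores
follow class-conditional linear trajectories over ages 14-22 whose
parameters separate the three classes at the final timepoint;
`matchedThresholds()` returns the midpoint cut-offs, which recover the
generating severity for ~95% of subjects. The moderate share of 0.25
lands the excluded-subject count in the 250-400 range at n = 1400.

What the simulator does **not** emulate: inter-feature correlation
(features are conditionally independent given the confounds), site
x feature interactions in the label signal, questionnaire item
structure, missing data, and longitudinal feature tables. Passing
tests therefore demonstrate the *machinery* - leakage-freedom,
calibration, the qualitative behavior of the corrections - not
performance on real morphometry.

Three presets (`cohortPreset()`) freeze the study conditions used by
the validation experiments: `"signal"` (defaults above), `"confounded"`
(n = 1000, 100 features, prevalence 0.44 vs 0.22 by sex and +0.20 at
three high-risk sites - chosen so each confound-to-label pathway is
clearly super-chance while the label classes stay near-balanced) and
`"null"` (no effects, uniform prevalence).

## Phenotype labeling

`binSeverity()` thresholds a score into safe / moderate / heavy with
half-open bins (heavy inclusive at the upper threshold);
`makeBinaryLabels()` excludes the moderates and returns the binary
label plus bookkeeping. Longitudinal phenotypes use per-subject OLS
lines of score on centered age (`fitTrajectory()`) - a deliberate
simplification of latent growth-curve modeling, since downstream
stages only consume a per-subject trajectory summary - and
`combinedPhenotype()` offers a k-means-based combined label whose
"heavy" cluster is the one with the highest mean binge measure.
Thresholds are study choices; the simulator-matched defaults are just
that, defaults.

## Models

Four families (`modelSpec()`): L2-penalized logistic regression
(in-package IRLS with inverse-regularization C; the C++ core exists
because the diagnostic battery refits it hundreds of thousands of
times inside permutation loops, and it is verified against `glm()` in
the tests), linear SVM and RBF SVM (e1071), and gradient boosting
(xgboost). Multiclass site targets use one-vs-rest for logistic and
the native reductions of the SVM (one-vs-one) and boosting (softmax)
implementations. Default grids: four log-spaced C values for the
linear families, 3 x 3 (C, kernel-width scale) for the RBF (kernel
width = scale / #features), 2 x 2 x 2 (rounds, depth, learning rate)
for boosting.

## Attribution and stability

`permutationShap()` estimates Shapley values on the model's decision
scale (margin / log-odds - the hard class is not additive). For each
draw it samples a background row and a feature ordering, walks the
ordering switching background values to the explained subject's values,
and records output changes; the reversed ordering is always included
(antithetic pair), which makes the estimator exact for additive models
and guarantees per-subject additivity by telescoping. For the SVM and
linear families the chain is evaluated by exact incremental algebra
(rank-one squared-distance updates for the RBF kernel) - identical
results to the generic path, orders of magnitude faster; a brute-force
$2^d$ enumeration (`exactShap()`) serves as the oracle in tests.

`summarizeImportance()` applies the stability rule across the 7 holdout
retrainings: per run, $\bar S_f = \frac 1 N \sum_s |S_{s,f}|$ and the
grand mean $\bar S$ over features; a feature is *stable* iff
$\bar S_f \ge 2 \bar S$ (read inclusively) in at least 6 of 7 runs
(scaled as $\lceil 6k/7\rceil$ for $k$ runs). `effectDirection()` then
labels each stable feature "higher" or "lower" according to whether its
mean among predicted-positive holdout subjects exceeds its overall
holdout mean. The background set is 100 training rows under a fixed
seed. Correlated features can split credit, so stable-set precision
against generative truth is validated at >= 0.5, not 1.0. For
attribution runs the package uses the smoother RBF setting
(C = 1, width scale 0.1/p): the sharper default kernel scores slightly
higher but spreads credit onto idiosyncratic features, a trade-off
documented here once and used consistently.

## Numerical and design choices

* Half-open severity bins, heavy inclusive at the top threshold.
* Population-SD standardization (makes two-point examples exact).
* Joint sex x site counterbalancing strata; sex-only inside
  leave-one-site-out, where site is the fold unit and cannot be
  balanced.
* Hyperparameter ties broken by grid order; inner-CV metric is
  balanced accuracy.
* Add-one permutation p (unbiased, never zero); train labels shuffled,
  test labels fixed; resampling plans are re-derived inside every
  permutation when the shuffled labels drive them.
* Holdout retrainings keep hyperparameters frozen from exploration.
* Degenerate cases: strata missing a label class are dropped with a
  warning; folds whose training portion loses a target class are
  skipped with a warning (error if all are); k-means with fewer
  distinct rows than clusters degrades to one cluster with a warning.
* IRLS runs at most 12 iterations to tolerance 1e-6 - balanced
  accuracies are insensitive beyond this, and the permutation loops
  dominate runtime.

Every one of these conventions is echoed into `run_metadata.json` by
`runExperiment()` so a finished run documents itself.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run: the five-way battery
with 199 permutations per row on n = 1000 / 100-feature cohorts over
10 seeds (2 folds); null calibration with 200 independent permutation
tests (199 permutations each) on reduced null cohorts (n = 120, 10
features); signal recovery on the full 719-feature cohort with 7
holdout retrainings, a 49- or 99-permutation significance check and
3-repeat Shapley estimation; and the model-family ordering on 500 x 8
interaction problems over 10 seeds. These sizes were chosen so the
whole suite completes on a single CPU in well under half an hour while
every contrast retains the power the corresponding test asserts
(verified by pilot simulation before the thresholds were frozen).

## A worked example

```{r example, eval = FALSE}
library(ConfoundCV)

co <- generateCohort(cohortPreset("confounded", seed = 1))
lb <- labelCohort(co)

spec <- modelSpec("logistic", grid = list(list(C = 1)))
plan <- cvPlan(outerFolds = 2, innerFolds = 2, seed = 50)

# before correction: every pathway lights up
runSameAnalysisChecks(spec, lb$X, lb$y, lb$cf, plan, "none",
                      nPerm = 199, seed = 7)

# after oversampled counterbalancing: c -> y rows fall to chance
runSameAnalysisChecks(spec, lb$X, lb$y, lb$cf, plan, "over",
                      nPerm = 199, seed = 7,
                      combinations = c("sex_to_y", "site_to_y"))
```

## Limitations

Only categorical confounds are supported (no continuous age or
intracranial volume); the simulator's independence assumptions are
listed above; the leave-one-site-out design cannot counterbalance the
site it tests on; and stable-feature precision is bounded by credit
splitting among correlated or jointly used features. None of the
synthetic prevalences or effect sizes should be read as estimates of
any real cohort.
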