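#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Configuration of the multi-site cohort simulator
#'
#' A \code{CohortConfig} fixes every generative choice of
#' \code{\link{generateCohort}}: cohort size, the site and sex composition,
#' the (sex x site)-conditional severity prevalences, the feature model
#' (block sizes, label signal, linear and non-linear confound channels) and
#' the class-conditional misuse-score trajectories. Build one with
#' \code{\link{cohortConfig}} rather than \code{new()}.
#'
#' @slot nSubjects integer, cohort size.
#' @slot nSites integer, number of recruitment sites.
#' @slot siteProbs numeric, site membership probabilities (sums to 1).
#' @slot pMaleBySite numeric, per-site probability that a subject is male.
#' @slot severityProbs numeric array \code{[2, nSites, 3]} of
#'   \{safe, moderate, heavy\} probabilities per (sex, site) cell; first
#'   margin is (female, male).
#' @slot blockSizes named integer vector of feature-block widths
#'   (default \code{c(t1w = 656, dti = 63)}).
#' @slot nInformative integer, number of label-informative features.
#' @slot effectSizeD numeric, nominal standardized heavy-vs-safe mean shift
#'   of informative features (per-feature shifts are spread uniformly over
#'   0.5x-1.5x this value so a single largest effect exists).
#' @slot sexShift numeric, scale of the per-feature linear sex effect.
#' @slot siteShift numeric, scale of the per-feature per-site mean offsets.
#' @slot siteVarRange numeric length 2, range of per-site residual-variance
#'   multipliers (a non-linear confound channel: invisible to main-effects
#'   regression).
#' @slot interactionScale numeric, scale of sex x site mean interactions
#'   (second non-linear channel).
#' @slot timepoints numeric, acquisition ages of the misuse scores.
#' @slot trajectoryParams named list (safe/moderate/heavy) of lists with
#'   \code{interceptMean, interceptSd, slopeMean, slopeSd, noiseSd} that
#'   define the class-conditional score trajectories (score units per year).
#' @slot seed integer, RNG seed; identical config implies a bit-identical
#'   cohort.
#'
#' @seealso \code{\link{cohortConfig}}, \code{\link{generateCohort}}
#' @exportClass CohortConfig
setClass("CohortConfig", representation(
  nSubjects = "integer",
  nSites = "integer",
  siteProbs = "numeric",
  pMaleBySite = "numeric",
  severityProbs = "array",
  blockSizes = "integer",
  nInformative = "integer",
  effectSizeD = "numeric",
  sexShift = "numeric",
  siteShift = "numeric",
  siteVarRange = "numeric",
  interactionScale = "numeric",
  timepoints = "numeric",
  trajectoryParams = "list",
  seed = "integer"
))

.validProbVec <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    return(sprintf("%s must be non-negative and sum to 1", what))
  NULL
}

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be positive")
  if (object@nSites < 1L) msg <- c(msg, "nSites must be positive")
  if (length(object@siteProbs) != object@nSites)
    msg <- c(msg, "siteProbs length must equal nSites")
  msg <- c(msg, .validProbVec(object@siteProbs, "siteProbs"))
  if (length(object@pMaleBySite) != object@nSites)
    msg <- c(msg, "pMaleBySite length must equal nSites")
  if (any(object@pMaleBySite < 0 | object@pMaleBySite > 1))
    msg <- c(msg, "pMaleBySite must lie in [0, 1]")
  d <- dim(object@severityProbs)
  if (length(d) != 3L || d[1] != 2L || d[2] != object@nSites || d[3] != 3L) {
    msg <- c(msg, "severityProbs must be a [2, nSites, 3] array")
  } else {
    for (s in 1:2) for (k in seq_len(d[2]))
      msg <- c(msg, .validProbVec(object@severityProbs[s, k, ],
                                  sprintf("severityProbs[%d,%d,]", s, k)))
  }
  if (any(object@blockSizes < 0L)) msg <- c(msg, "blockSizes must be >= 0")
  if (object@nInformative > sum(object@blockSizes))
    msg <- c(msg, "nInformative must not exceed the number of features")
  if (length(object@siteVarRange) != 2L || any(object@siteVarRange <= 0))
    msg <- c(msg, "siteVarRange must be two strictly positive values")
  if (length(object@timepoints) < 1L || is.unsorted(object@timepoints, strictly = TRUE))
    msg <- c(msg, "timepoints must be strictly increasing")
  need <- c("safe", "moderate", "heavy")
  if (!all(need %in% names(object@trajectoryParams)))
    msg <- c(msg, "trajectoryParams needs entries safe, moderate, heavy")
  if (length(msg)) msg else TRUE
})

#' Simulated multi-site cohort
#'
#' A \code{SimCohort} extends \code{SummarizedExperiment}: the single assay
#' \code{"features"} is the features x subjects matrix, \code{colData}
#' carries per-subject \code{sex}, \code{site}, \code{severity} and the
#' misuse-score matrix \code{scores}, and \code{rowData} tags each feature
#' with its block (\code{"t1w"}/\code{"dti"}), whether it is
#' label-informative and its true heavy-vs-safe shift. The full generative
#' truth (all effect parameters and the config) sits in
#' \code{metadata(x)$truth}.
#'
#' @seealso \code{\link{generateCohort}}, \code{\link{featureMatrix}},
#'   \code{\link{cohortTruth}}
#' @exportClass SimCohort
setClass("SimCohort", contains = "SummarizedExperiment")

setValidity("SimCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- character()
  for (col in c("sex", "site", "severity"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", col))
  if ("severity" %in% colnames(cd) &&
      !all(as.character(cd$severity) %in% c("safe", "moderate", "heavy")))
    msg <- c(msg, "severity must be one of safe/moderate/heavy")
  if (length(SummarizedExperiment::assays(object)) &&
      anyNA(SummarizedExperiment::assay(object)))
    msg <- c(msg, "feature matrix must not contain missing values")
  tr <- S4Vectors::metadata(object)$truth
  if (!is.null(tr$informative)) {
    if (anyDuplicated(tr$informative) ||
        any(tr$informative < 1L) || any(tr$informative > nrow(object)))
      msg <- c(msg, "truth$informative indices must be unique and in range")
  }
  if (length(msg)) msg else TRUE
})

#' Phenotype labels derived from misuse scores
#'
#' Severity (safe/moderate/heavy), the binary heavy-vs-safe label and the
#' inclusion mask after excluding moderate misusers. \code{label} is
#' \code{NA} exactly where \code{included} is \code{FALSE}.
#'
#' @slot severity factor with levels safe, moderate, heavy.
#' @slot label integer vector in \{0, 1, NA\}; 1 = heavy, 0 = safe.
#' @slot included logical mask, \code{FALSE} exactly for moderate subjects.
#' @slot excluded integer, number of excluded subjects.
#' @exportClass PhenotypeLabels
setClass("PhenotypeLabels", representation(
  severity = "factor", label = "integer", included = "logical",
  excluded = "integer"
))

setValidity("PhenotypeLabels", function(object) {
  msg <- character()
  n <- length(object@severity)
  if (length(object@label) != n || length(object@included) != n)
    msg <- c(msg, "severity, label and included must have equal length")
  if (!identical(which(!object@included),
                 which(object@severity == "moderate")))
    msg <- c(msg, "included must be FALSE exactly where severity is moderate")
  if (anyNA(object@label[object@included]))
    msg <- c(msg, "label must be defined for every included subject")
  if (object@excluded != sum(!object@included))
    msg <- c(msg, "excluded count disagrees with the inclusion mask")
  if (length(msg)) msg else TRUE
})

#' Categorical confound frame
#'
#' Holds the sex and site factors of a set of subjects with their category
#' sets fixed, so train-fitted objects can refuse unseen categories at
#' apply time. One-hot designs are derived via \code{\link{designMatrix}}.
#'
#' @slot sex factor (2 categories in the motivating study).
#' @slot site factor (8 categories in the motivating study).
#' @exportClass ConfoundFrame
setClass("ConfoundFrame",
         representation(sex = "factor", site = "factor"))

setValidity("ConfoundFrame", function(object) {
  if (length(object@sex) != length(object@site))
    "sex and site must have equal length"
  else if (anyNA(object@sex) || anyNA(object@site))
    "confounds must not contain missing values"
  else TRUE
})

#' Fitted linear confound regressor
#'
#' Per-feature ordinary-least-squares coefficients of the features on the
#' \code{[intercept | one-hot sex | one-hot site]} main-effects design,
#' fitted on training rows only.
#'
#' @slot coefficients design-columns x features coefficient matrix.
#' @slot columns character, design column names actually fitted.
#' @slot sexLevels,siteLevels category sets fixed at fit time.
#' @exportClass ConfoundRegressor
setClass("ConfoundRegressor", representation(
  coefficients = "matrix", columns = "character",
  sexLevels = "character", siteLevels = "character"
))

#' Counterbalancing resample plan
#'
#' The training-row index multiset that equalizes the two label classes
#' within every confound stratum, plus bookkeeping. Indices are relative to
#' the training rows the plan was built from, so rows outside them can
#' never enter.
#'
#' @slot mode "under" or "over".
#' @slot strata character, stratum id per training row.
#' @slot indices integer multiset of selected training-row positions.
#' @slot cellTable data.frame of per-(stratum x class) counts before/after.
#' @slot droppedRows integer, rows lost to strata missing one class.
#' @slot seed integer resampling seed.
#' @exportClass ResamplePlan
setClass("ResamplePlan", representation(
  mode = "character", strata = "character", indices = "integer",
  cellTable = "data.frame", droppedRows = "integer", seed = "integer"
))

setValidity("ResamplePlan", function(object) {
  msg <- character()
  if (!object@mode %in% c("under", "over"))
    msg <- c(msg, "mode must be 'under' or 'over'")
  n <- length(object@strata)
  if (length(object@indices) &&
      (min(object@indices) < 1L || max(object@indices) > n))
    msg <- c(msg, "indices out of training-row range")
  if (object@mode == "under" && anyDuplicated(object@indices))
    msg <- c(msg, "undersampling plan must not duplicate rows")
  if (length(msg)) msg else TRUE
})

#' Train-fitted feature standardizer
#'
#' Column means and population standard deviations estimated on training
#' rows only; zero-variance training columns are dropped.
#'
#' @slot keptColumns integer indices of retained columns.
#' @slot means,sds numeric, one value per kept column.
#' @slot nColumns integer, original column count (checked at apply time).
#' @exportClass Standardizer
setClass("Standardizer", representation(
  keptColumns = "integer", means = "numeric", sds = "numeric",
  nColumns = "integer"
))

setValidity("Standardizer", function(object) {
  msg <- character()
  k <- length(object@keptColumns)
  if (length(object@means) != k || length(object@sds) != k)
    msg <- c(msg, "keptColumns, means and sds must have equal length")
  if (any(object@sds <= 0)) msg <- c(msg, "sds must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Model family and hyperparameter grid
#'
#' @slot family one of "logistic", "linear-svm", "rbf-svm",
#'   "gradient-boosting".
#' @slot grid ordered list of named hyperparameter combinations; ties in
#'   inner-CV selection are broken by grid order.
#' @slot seed integer model seed.
#' @seealso \code{\link{modelSpec}}
#' @exportClass ModelSpec
setClass("ModelSpec", representation(
  family = "character", grid = "list", seed = "integer"
))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@family %in% c("logistic", "linear-svm", "rbf-svm",
                            "gradient-boosting"))
    msg <- c(msg, "unknown model family")
  if (!length(object@grid)) msg <- c(msg, "hyperparameter grid must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Cross-validation plan
#'
#' @slot outerFolds,innerFolds fold counts of the nested CV (defaults 7, 5).
#' @slot holdoutFraction proportion kept aside as the one-shot holdout set.
#' @slot seed integer partitioning seed.
#' @seealso \code{\link{cvPlan}}
#' @exportClass CVPlan
setClass("CVPlan", representation(
  outerFolds = "integer", innerFolds = "integer",
  holdoutFraction = "numeric", seed = "integer"
))

setValidity("CVPlan", function(object) {
  msg <- character()
  if (object@outerFolds < 2L || object@innerFolds < 2L)
    msg <- c(msg, "fold counts must be >= 2")
  if (object@holdoutFraction <= 0 || object@holdoutFraction >= 1)
    msg <- c(msg, "holdoutFraction must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Evaluation result
#'
#' Per-fold (nested CV, leave-one-site-out) or per-seed (holdout
#' retraining) balanced accuracies and AUCs, the hyperparameters chosen per
#' fold, and optionally a permutation null with raw and Bonferroni-adjusted
#' p-values.
#'
#' @slot scores numeric, balanced accuracy per fold/seed.
#' @slot auc numeric, AUC per fold/seed (NA for multiclass targets).
#' @slot chosen list of hyperparameter combinations per fold.
#' @slot nullScores numeric permutation-null scores (may be empty).
#' @slot pRaw,pBonferroni numeric p-values (NA until computed).
#' @slot info list of free-form metadata (correction mode, seeds, ...).
#' @exportClass EvalResult
setClass("EvalResult", representation(
  scores = "numeric", auc = "numeric", chosen = "list",
  nullScores = "numeric", pRaw = "numeric", pBonferroni = "numeric",
  info = "list"
), prototype(nullScores = numeric(), pRaw = NA_real_,
             pBonferroni = NA_real_, info = list()))

setValidity("EvalResult", function(object) {
  msg <- character()
  sc <- object@scores
  if (length(sc) && (any(sc < 0) || any(sc > 1)))
    msg <- c(msg, "balanced accuracies must lie in [0, 1]")
  p <- object@pRaw
  if (!is.na(p) && (p <= 0 || p > 1)) msg <- c(msg, "pRaw must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Five-way diagnostic check table
#'
#' One row per input-output combination (X->y, X->c_sex, X->c_site,
#' c_sex->y, c_site->y), all evaluated with the same folds and model family
#' under a chosen correction technique.
#'
#' @slot table data.frame with columns combination, meanBA, sdBA, chance,
#'   pValue, sig05, sig01.
#' @slot info list: correction mode, model family, fold count, nPerm, seed.
#' @exportClass CheckTable
setClass("CheckTable",
         representation(table = "data.frame", info = "list"))

setValidity("CheckTable", function(object) {
  tb <- object@table
  msg <- character()
  known <- c("x_to_y", "x_to_sex", "x_to_site", "sex_to_y", "site_to_y")
  if (nrow(tb) < 1L || nrow(tb) > 5L || !all(tb$combination %in% known))
    msg <- c(msg, "rows must be a non-empty subset of the five combinations")
  if (any(tb$meanBA < 0 | tb$meanBA > 1)) msg <- c(msg, "accuracies must lie in [0, 1]")
  if (any(tb$pValue <= 0 | tb$pValue > 1)) msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Per-run Shapley attribution matrix
#'
#' Subjects x features attribution values on the model's decision scale.
#' For every subject, \code{baseValue + rowSums(values)} reproduces the
#' model output (additivity).
#'
#' @slot values subjects x features matrix of attributions.
#' @slot baseValue numeric, mean model output over the background rows used.
#' @slot prediction numeric, model output per explained subject.
#' @slot seed integer estimator seed.
#' @exportClass AttributionMatrix
setClass("AttributionMatrix", representation(
  values = "matrix", baseValue = "numeric", prediction = "numeric",
  seed = "integer"
))

#' Cross-run feature-importance summary
#'
#' Mean absolute attribution per feature and run, the grand mean per run,
#' and the stable-feature set (features at least twice the grand mean in at
#' least six of seven runs, scaled for other run counts).
#'
#' @slot perFeatureMeanAbs runs x features matrix of mean |attribution|.
#' @slot grandMean numeric, per-run mean over features.
#' @slot qualifyingRuns integer, per feature: runs in which it passed 2x.
#' @slot stableSet integer feature indices deemed stable.
#' @slot direction character per stable feature: "higher", "lower" or
#'   "undefined" (empty until \code{\link{effectDirection}} fills it).
#' @slot requiredRuns integer threshold used for stability.
#' @exportClass ImportanceSummary
setClass("ImportanceSummary", representation(
  perFeatureMeanAbs = "matrix", grandMean = "numeric",
  qualifyingRuns = "integer", stableSet = "integer",
  direction = "character", requiredRuns = "integer"
), prototype(direction = character()))

setValidity("ImportanceSummary", function(object) {
  msg <- character()
  if (length(object@grandMean) != nrow(object@perFeatureMeanAbs))
    msg <- c(msg, "one grand mean per run required")
  if (length(object@stableSet) &&
      max(object@stableSet) > ncol(object@perFeatureMeanAbs))
    msg <- c(msg, "stableSet out of feature range")
  if (length(msg)) msg else TRUE
})
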