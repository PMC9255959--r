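#' Preset cohort configurations for the three study conditions
#'
#' Three canonical simulator settings used throughout the package's
#' validation experiments and examples:
#' \describe{
#'   \item{"signal"}{the default-signal cohort: full-size multi-site cohort
#'     (about 1000 analysis subjects after moderate exclusion, 719
#'     features, 20 informative features at nominal d = 0.5) with all
#'     confound channels on - the setting for holdout generalization and
#'     attribution-recovery experiments.}
#'   \item{"confounded"}{a deliberately strongly confounded cohort (n =
#'     1000, 100 features): sex and site mean shifts, per-site variance
#'     scaling, sex x site interactions, and heavy-misuse prevalence that
#'     differs sharply by sex (about 0.44 vs 0.22) and by site (+0.20 at
#'     three high-risk sites) - the setting for comparing confound
#'     correction techniques with the five-way check battery.}
#'   \item{"null"}{a global-null cohort: no label signal, no confound
#'     effects, uniform severity prevalence everywhere - the setting for
#'     type-I-error calibration.}
#' }
#'
#' @param name preset name.
#' @param seed integer RNG seed for the cohort draw.
#' @param nSubjects,nFeatures optional size overrides (the "null" preset
#'   defaults to a smaller cohort since calibration replicates it many
#'   times).
#' @return a \code{\linkS4class{CohortConfig}}.
#' @export
cohortPreset <- function(name = c("signal", "confounded", "null"), seed = 1L,
                         nSubjects = NULL, nFeatures = NULL) {
  name <- match.arg(name)
  switch(name,
    signal = cohortConfig(
      nSubjects = if (is.null(nSubjects)) 1340L else nSubjects,
      nFeatures = if (is.null(nFeatures)) 719L else nFeatures,
      seed = seed),
    confounded = cohortConfig(
      nSubjects = if (is.null(nSubjects)) 1000L else nSubjects,
      nFeatures = if (is.null(nFeatures)) 100L else nFeatures,
      severityProbs = defaultSeverityProbs(heavyFemale = 0.22,
                                           heavyMale = 0.44,
                                           highBonus = 0.20),
      seed = seed),
    null = cohortConfig(
      nSubjects = if (is.null(nSubjects)) 300L else nSubjects,
      nFeatures = if (is.null(nFeatures)) 20L else nFeatures,
      nInformative = 0L, effectSizeD = 0, sexShift = 0, siteShift = 0,
      interactionScale = 0, siteVarRange = c(1, 1),
      severityProbs = defaultSeverityProbs(heavyFemale = 0.375,
                                           heavyMale = 0.375,
                                           highBonus = 0),
      seed = seed))
}

#' Interaction-signal (XOR) classification problem
#'
#' A non-linear synthetic problem in which the label is the exclusive-or
#' of the signs of two latent features (with a configurable flip rate),
#' padded with noise features. Linear models are blind to this signal by
#' construction, while kernel and tree-ensemble models can recover it -
#' the canonical setting for checking the non-linear vs linear model
#' ordering.
#'
#' @param nSubjects number of subjects.
#' @param nFeatures total features (the first two carry the interaction).
#' @param flipRate label noise rate (default 0.1).
#' @param seed integer seed.
#' @return list with \code{X}, binary \code{y}, and a neutral \code{cf}
#'   (two sites and sexes drawn independently of everything).
#' @export
interactionProblem <- function(nSubjects = 500L, nFeatures = 8L,
                               flipRate = 0.1, seed = 1L) {
  withSeed(seed, {
    X <- matrix(rnorm(nSubjects * nFeatures), nSubjects, nFeatures)
    y <- as.integer(xor(X[, 1] > 0, X[, 2] > 0))
    flip <- stats::runif(nSubjects) < flipRate
    y[flip] <- 1L - y[flip]
    cf <- confoundFrame(sample(c("female", "male"), nSubjects, TRUE),
                        sample(c("siteA", "siteB"), nSubjects, TRUE))
    colnames(X) <- sprintf("x_%02d", seq_len(nFeatures))
    list(X = X, y = y, cf = cf)
  })
}

#' Label a simulated cohort with simulator-matched thresholds
#'
#' Convenience wrapper: bins the final-timepoint misuse score with
#' \code{\link{matchedThresholds}} and applies the moderate-user
#' exclusion, returning everything downstream stages need.
#'
#' @param cohort a \code{\linkS4class{SimCohort}}.
#' @return list with \code{labels} (\code{\linkS4class{PhenotypeLabels}}),
#'   and - restricted to included subjects - \code{X}, \code{y},
#'   \code{cf}, plus \code{included} (indices into the cohort).
#' @export
labelCohort <- function(cohort) {
  cfg <- cohortTruth(cohort)$config
  thr <- matchedThresholds(cfg)
  sc <- misuseScores(cohort)
  labels <- makeBinaryLabels(binSeverity(sc[, ncol(sc)], thr[1], thr[2]))
  inc <- which(includedSubjects(labels))
  list(labels = labels,
       X = featureMatrix(cohort)[inc, , drop = FALSE],
       y = phenotypeLabel(labels)[inc],
       cf = cohortConfounds(cohort)[inc],
       included = inc)
}
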