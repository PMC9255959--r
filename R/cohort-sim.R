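#' Build a cohort-simulator configuration
#'
#' Returns a validated \code{\linkS4class{CohortConfig}}. The defaults
#' emulate the structure of a large multi-site adolescent neuroimaging
#' cohort: about 1400 subjects over 8 unequally sized European sites,
#' 719 structural features in two blocks (656 T1w morphometrics, 63 DTI-FA
#' tract means), misuse scores at ages 14/16/19/22, heavy-misuse prevalence
#' that is higher for males and at three "high-risk" sites, and both linear
#' (mean-shift) and non-linear (per-site variance scaling, sex x site
#' interaction) confound channels in the features.
#'
#' @param nSubjects cohort size.
#' @param nSites number of recruitment sites.
#' @param siteProbs site membership probabilities; defaults to a mildly
#'   decreasing profile over sites.
#' @param pMaleBySite per-site male probability (default 0.5 everywhere).
#' @param severityProbs \code{[2, nSites, 3]} array of per-(sex, site)
#'   \{safe, moderate, heavy\} probabilities; default built by
#'   \code{\link{defaultSeverityProbs}}.
#' @param nFeatures total feature count; partitioned into blocks in the
#'   proportion 656:63 unless \code{blockSizes} is given.
#' @param blockSizes named integer vector of block widths.
#' @param nInformative number of label-informative features (default:
#'   20, capped at the feature count).
#' @param effectSizeD nominal heavy-vs-safe standardized shift (default 0.5).
#' @param sexShift,siteShift linear confound mean-shift scales.
#' @param siteVarRange range of per-site residual-sd multipliers.
#' @param interactionScale sex x site interaction mean scale.
#' @param timepoints acquisition ages.
#' @param trajectoryParams class-conditional trajectory parameters; see
#'   \code{\linkS4class{CohortConfig}}.
#' @param seed integer RNG seed.
#' @return a \code{CohortConfig}.
#' @examples
#' cfg <- cohortConfig(nSubjects = 200, nFeatures = 30, seed = 1)
#' cohort <- generateCohort(cfg)
#' @export
cohortConfig <- function(nSubjects = 1400L,
                         nSites = 8L,
                         siteProbs = NULL,
                         pMaleBySite = NULL,
                         severityProbs = NULL,
                         nFeatures = 719L,
                         blockSizes = NULL,
                         nInformative = NULL,
                         effectSizeD = 0.5,
                         sexShift = 0.25,
                         siteShift = 0.35,
                         siteVarRange = c(0.7, 1.4),
                         interactionScale = 0.6,
                         timepoints = c(14, 16, 19, 22),
                         trajectoryParams = defaultTrajectoryParams(),
                         seed = 1L) {
  nSites <- as.integer(nSites)
  if (is.null(siteProbs)) {
    siteProbs <- rev(seq_len(nSites)) + nSites / 2
    siteProbs <- siteProbs / sum(siteProbs)
  }
  if (is.null(pMaleBySite)) pMaleBySite <- rep(0.5, nSites)
  if (is.null(severityProbs)) severityProbs <- defaultSeverityProbs(nSites)
  if (is.null(blockSizes)) {
    t1w <- as.integer(round(as.integer(nFeatures) * 656 / 719))
    blockSizes <- c(t1w = t1w, dti = as.integer(nFeatures) - t1w)
  }
  if (is.null(nInformative)) nInformative <- min(20L, sum(blockSizes))
  new("CohortConfig",
      nSubjects = as.integer(nSubjects), nSites = nSites,
      siteProbs = as.numeric(siteProbs), pMaleBySite = as.numeric(pMaleBySite),
      severityProbs = severityProbs,
      blockSizes = setNames(as.integer(blockSizes), names(blockSizes)),
      nInformative = as.integer(nInformative),
      effectSizeD = effectSizeD, sexShift = sexShift, siteShift = siteShift,
      siteVarRange = as.numeric(siteVarRange),
      interactionScale = interactionScale,
      timepoints = as.numeric(timepoints),
      trajectoryParams = trajectoryParams, seed = as.integer(seed))
}

#' Default (sex x site) severity prevalences
#'
#' Heavy-misuse prevalence is higher for males than females and receives a
#' bonus at the first \code{nHigh} sites; the moderate share is constant.
#' These are qualitative stand-ins (higher male and high-risk-site rates),
#' not estimates of any real cohort.
#'
#' @param nSites number of sites.
#' @param pModerate moderate share per cell (default 0.25).
#' @param heavyFemale,heavyMale baseline heavy share by sex.
#' @param nHigh number of leading "high-risk" sites.
#' @param highBonus heavy-share bonus at high-risk sites.
#' @return \code{[2, nSites, 3]} probability array (female/male margin
#'   first, severity \{safe, moderate, heavy\} last).
#' @export
defaultSeverityProbs <- function(nSites = 8L, pModerate = 0.25,
                                 heavyFemale = 0.32, heavyMale = 0.44,
                                 nHigh = 3L, highBonus = 0.10) {
  out <- array(0, c(2L, nSites, 3L),
               dimnames = list(c("female", "male"), NULL,
                               c("safe", "moderate", "heavy")))
  for (s in 1:2) for (k in seq_len(nSites)) {
    heavy <- c(heavyFemale, heavyMale)[s] + if (k <= nHigh) highBonus else 0
    out[s, k, ] <- c(1 - pModerate - heavy, pModerate, heavy)
  }
  out
}

#' Default class-conditional misuse-score trajectory parameters
#'
#' Intercepts are at the first timepoint; slopes are in score units per
#' year. Heavy misusers start higher and escalate faster; the three class
#' distributions are separated enough that thresholding the final-timepoint
#' score recovers the generating class for the large majority of subjects.
#'
#' @return named list (safe, moderate, heavy) of parameter lists.
#' @export
defaultTrajectoryParams <- function() {
  list(
    safe     = list(interceptMean = 0.5, interceptSd = 0.5,
                    slopeMean = 0.10, slopeSd = 0.05, noiseSd = 0.5),
    moderate = list(interceptMean = 2.0, interceptSd = 0.7,
                    slopeMean = 0.35, slopeSd = 0.10, noiseSd = 0.5),
    heavy    = list(interceptMean = 4.0, interceptSd = 1.0,
                    slopeMean = 0.80, slopeSd = 0.15, noiseSd = 0.5)
  )
}

#' Severity thresholds matched to a simulator configuration
#'
#' Midpoints between the class-conditional means of the final-timepoint
#' score, usable as \code{tLow}/\code{tHigh} in \code{\link{binSeverity}}
#' to recover the generating severity up to trajectory noise.
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @return named numeric \code{c(tLow, tHigh)}.
#' @export
matchedThresholds <- function(config) {
  tp <- config@trajectoryParams
  dt <- max(config@timepoints) - config@timepoints[1]
  m <- vapply(tp[c("safe", "moderate", "heavy")],
              function(p) p$interceptMean + p$slopeMean * dt, numeric(1))
  c(tLow = mean(m[1:2]), tHigh = mean(m[2:3]))
}

#' Generate a synthetic multi-site cohort
#'
#' Draws severity first, conditional on the (sex, site) cell, then features
#' and misuse-score trajectories conditional on severity, so the generative
#' truth of every label-recovery and confound-detection test is known
#' exactly. Per subject \eqn{i} and feature \eqn{f},
#' \deqn{X_{if} = s_x a_f [male_i] + s_s b_{f,site_i} +
#'   s_{int} g_f [male_i] h(site_i) + d_f \delta(sev_i) + \epsilon_{if},}
#' with \eqn{\epsilon_{if} \sim N(0, v_{site_i}^2)}. The per-site residual
#' scales \eqn{v} and the sex x site interaction are the two non-linear
#' confound channels: neither moves any quantity a main-effects one-hot
#' regression can remove, yet both are detectable by a kernel classifier.
#' \eqn{\delta} is 1 for heavy, 1/2 for moderate and 0 for safe subjects;
#' \eqn{d_f} is non-zero only for the informative features, spread over
#' 0.5x-1.5x \code{effectSizeD}. Identical configs (including seed) give
#' bit-identical cohorts.
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @return a \code{\linkS4class{SimCohort}}.
#' @examples
#' cohort <- generateCohort(cohortConfig(nSubjects = 100, nFeatures = 20))
#' dim(featureMatrix(cohort))
#' @export
generateCohort <- function(config) {
  validObject(config)
  n <- config@nSubjects
  p <- sum(config@blockSizes)
  nS <- config@nSites
  withSeed(config@seed, {
    site <- sample.int(nS, n, replace = TRUE, prob = config@siteProbs)
    sex <- rbinom(n, 1L, config@pMaleBySite[site])  # 1 = male
    sev <- character(n)
    for (i in seq_len(n))
      sev[i] <- sample(c("safe", "moderate", "heavy"), 1L,
                       prob = config@severityProbs[sex[i] + 1L, site[i], ])
    sev <- factor(sev, levels = c("safe", "moderate", "heavy"))

    a <- rnorm(p)
    b <- matrix(rnorm(p * nS), p, nS)
    g <- rnorm(p)
    h <- if (nS > 1) seq(-1, 1, length.out = nS) else 0
    v <- if (nS > 1) seq(config@siteVarRange[1], config@siteVarRange[2],
                         length.out = nS) else mean(config@siteVarRange)
    informative <- sort(sample.int(p, config@nInformative))
    d <- numeric(p)
    if (config@nInformative > 0)
      d[informative] <- config@effectSizeD *
        seq(0.5, 1.5, length.out = config@nInformative)
    delta <- c(safe = 0, moderate = 0.5, heavy = 1)[as.character(sev)]

    mu <- config@sexShift * outer(sex, a) +
      config@siteShift * t(b[, site, drop = FALSE]) +
      config@interactionScale * outer(sex, g) * h[site] +
      outer(delta, d)
    X <- mu + matrix(rnorm(n * p), n, p) * v[site]

    tp <- config@timepoints
    pars <- config@trajectoryParams[as.character(sev)]
    alpha <- vapply(pars, function(q) rnorm(1, q$interceptMean, q$interceptSd),
                    numeric(1))
    beta <- vapply(pars, function(q) rnorm(1, q$slopeMean, q$slopeSd),
                   numeric(1))
    noiseSd <- vapply(pars, function(q) q$noiseSd, numeric(1))
    scores <- outer(alpha, rep(1, length(tp))) +
      outer(beta, tp - tp[1]) +
      matrix(rnorm(n * length(tp)), n) * noiseSd
    colnames(scores) <- paste0("score_t", seq_along(tp))

    featNames <- unlist(lapply(names(config@blockSizes), function(bl)
      sprintf("%s_%03d", bl, seq_len(config@blockSizes[[bl]]))),
      use.names = FALSE)
    colnames(X) <- featNames
    subj <- sprintf("sub_%04d", seq_len(n))
    rownames(X) <- subj

    cd <- S4Vectors::DataFrame(
      sex = factor(ifelse(sex == 1L, "male", "female"),
                   levels = c("female", "male")),
      site = factor(paste0("site", site), levels = paste0("site", seq_len(nS))),
      severity = sev,
      row.names = subj)
    cd$scores <- scores
    rd <- S4Vectors::DataFrame(
      block = rep(names(config@blockSizes), config@blockSizes),
      informative = seq_len(p) %in% informative,
      effect = d, row.names = featNames)
    truth <- list(informative = informative, effect = d, sexLoadings = a,
                  siteOffsets = b, interactionLoadings = g, siteScore = h,
                  siteSd = v, config = config)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(features = t(X)), colData = cd, rowData = rd,
      metadata = list(truth = truth))
    new("SimCohort", se)
  })
}

#' @describeIn SimCohort-accessors subjects x features numeric matrix.
#' @export
featureMatrix <- function(x) t(SummarizedExperiment::assay(x, "features"))

#' Accessors for SimCohort objects
#'
#' Small wrappers around the underlying \code{SummarizedExperiment}
#' so downstream code never touches slots directly.
#'
#' @param x a \code{\linkS4class{SimCohort}}.
#' @name SimCohort-accessors
NULL

#' @describeIn SimCohort-accessors subjects x timepoints misuse scores.
#' @export
misuseScores <- function(x) {
  sc <- SummarizedExperiment::colData(x)$scores
  as.matrix(sc)
}

#' @describeIn SimCohort-accessors generating severity factor.
#' @export
cohortSeverity <- function(x) SummarizedExperiment::colData(x)$severity

#' @describeIn SimCohort-accessors the generative truth record.
#' @export
cohortTruth <- function(x) S4Vectors::metadata(x)$truth

#' @describeIn SimCohort-accessors \code{\linkS4class{ConfoundFrame}} of
#'   sex and site.
#' @export
cohortConfounds <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  confoundFrame(cd$sex, cd$site)
}

#' Per-(sex x site) prevalence summary
#'
#' Cell counts and the proportion of heavy-severity subjects per cell,
#' the synthetic analogue of a risky-drinker prevalence breakdown across
#' sex and recruitment site.
#'
#' @param cohort a non-empty \code{\linkS4class{SimCohort}}.
#' @return data.frame with columns sex, site, n, nHeavy, propHeavy; cell
#'   counts sum to the cohort size.
#' @export
cohortSummary <- function(cohort) {
  stopIfNot(ncol(cohort) > 0, "cohort is empty")
  cd <- SummarizedExperiment::colData(cohort)
  cells <- expand.grid(sex = levels(cd$sex), site = levels(cd$site),
                       stringsAsFactors = FALSE)
  cells$n <- mapply(function(s, k) sum(cd$sex == s & cd$site == k),
                    cells$sex, cells$site)
  cells$nHeavy <- mapply(function(s, k)
    sum(cd$sex == s & cd$site == k & cd$severity == "heavy"),
    cells$sex, cells$site)
  cells$propHeavy <- ifelse(cells$n > 0, cells$nHeavy / cells$n, NA_real_)
  cells
}

setMethod("show", "SimCohort", function(object) {
  cat(sprintf("SimCohort: %d subjects x %d features\n",
              ncol(object), nrow(object)))
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("  sites: %d, severity: %s\n",
              nlevels(cd$site),
              paste(sprintf("%s=%d", levels(cd$severity),
                            as.integer(table(cd$severity))), collapse = " ")))
  tr <- cohortTruth(object)
  if (!is.null(tr))
    cat(sprintf("  informative features: %d\n", length(tr$informative)))
})
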