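#' Default experiment configuration
#'
#' Returns the configuration list \code{\link{runExperiment}} consumes,
#' with every field at its default. Either \code{simulate} (a list of
#' \code{\link{cohortConfig}} arguments) or \code{input} (paths readable
#' by \code{\link{readCohort}}) must be present - exactly one of the two.
#'
#' @param ... named overrides merged over the defaults (one level deep).
#' @return named list.
#' @export
experimentConfig <- function(...) {
  base <- list(
    simulate = list(nSubjects = 400L, nFeatures = 60L, seed = 11L),
    input = NULL,
    phenotype = list(mode = "binge", tLow = NULL, tHigh = NULL,
                     timepoint = NULL),
    correction = "over",
    model = list(families = c("logistic", "rbf-svm"), gridSize = "default"),
    cv = list(outerFolds = 7L, innerFolds = 5L, holdoutFraction = 0.2),
    nPerm = 199L,
    nHoldoutSeeds = 7L,
    nComparisons = 3L,
    shapRepeats = 10L,
    outlierSd = 3,
    seed = 1L,
    outDir = NULL,
    stages = c("simulate", "label", "explore", "checks", "holdout",
               "attribute")
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  # an explicit input source replaces the default simulation block
  if (!is.null(over$input) && is.null(over$simulate)) base["simulate"] <- list(NULL)
  base
}

validateConfig <- function(config) {
  hasSim <- !is.null(config$simulate)
  hasInput <- !is.null(config$input)
  if (hasSim == hasInput)
    stop("config must contain exactly one of 'simulate' and 'input'",
         call. = FALSE)
  if (hasInput) {
    files <- file.path(config$input,
                       c("features.csv", "confounds.csv", "phenotype.csv"))
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  if (!config$correction %in% c("none", "regression", "under", "over"))
    stop("unknown correction mode: ", config$correction, call. = FALSE)
  bad <- setdiff(config$model$families,
                 c("logistic", "linear-svm", "rbf-svm", "gradient-boosting"))
  if (length(bad)) stop("unknown model family: ", bad[1], call. = FALSE)
  if (is.null(config$outDir)) stop("config needs an outDir", call. = FALSE)
  invisible(config)
}

# Decisions and conventions baked into the pipeline, echoed into every
# run's metadata for auditability.
pipelineConventions <- function() {
  list(
    severityBins = "half-open [tLow, tHigh); heavy inclusive at tHigh",
    trajectories = "per-subject OLS line on centered age (no latent growth model)",
    standardization = "population SD; fitted on the (resampled) training rows only, after counterbalancing",
    outlierRule = "per-block subject mean beyond k SD of the cohort mean, applied before the explore/holdout split",
    counterbalanceStrata = "joint sex x site cells (sex-only inside leave-one-site-out)",
    oneHot = "drop-first + intercept for regression; full one-hot for confounds as model inputs",
    emptyStrata = "strata missing a label class are dropped with a warning",
    tieBreak = "hyperparameter ties broken by grid order",
    innerMetric = "balanced accuracy",
    permutationP = "add-one estimator, train labels shuffled, test labels fixed",
    holdoutRetraining = "hyperparameters frozen from exploration across the 7 reseeded retrainings",
    regressionAndCtoY = "confound regression leaves c->y rows unmodified in the check suite",
    shapThreshold = "inclusive >= 2x grand mean, in >= ceiling(6k/7) of k runs",
    shapBackground = "100 training rows sampled with a fixed seed",
    shapScale = "model decision function (margin / log-odds)"
  )
}

#' Run a configured end-to-end experiment
#'
#' Orchestrates simulate (or load) -> outlier exclusion -> label ->
#' explore (model x correction grid via nested CV) -> five-way checks ->
#' holdout generalization with permutation significance -> attribution
#' stability, writing plain-text artifacts (labels.csv, explore_grid.tsv,
#' checks.tsv, holdout_result.json, importance.tsv, run_metadata.json)
#' into the configured output directory. Identical config and seeds give
#' identical artifacts.
#'
#' @param config configuration list from \code{\link{experimentConfig}},
#'   or the path of a YAML file holding one.
#' @param outDir,seed optional overrides of the config fields.
#' @return (invisibly) a list with the in-memory results per stage and
#'   \code{dir}, the artifact directory.
#' @export
runExperiment <- function(config, outDir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- do.call(experimentConfig, config)
  if (!is.null(outDir)) config$outDir <- outDir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validateConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  results <- list(config = config, dir = config$outDir)
  writeManifest <- function(e) {
    jsonlite::write_json(list(error = conditionMessage(e),
                              completed = names(results)),
                         file.path(config$outDir, "error_manifest.json"),
                         auto_unbox = TRUE)
  }
  tryCatch({
    # ---- data ----
    if (!is.null(config$simulate)) {
      simArgs <- config$simulate
      if (is.null(simArgs$seed)) simArgs$seed <- childSeed(config$seed, 1L)
      cohortCfg <- do.call(cohortConfig, simArgs)
      cohort <- generateCohort(cohortCfg)
      data <- list(features = featureMatrix(cohort),
                   cf = cohortConfounds(cohort),
                   scores = misuseScores(cohort),
                   severity = cohortSeverity(cohort),
                   truth = cohortTruth(cohort))
      if ("simulate" %in% stages) writeCohort(cohort, file.path(config$outDir, "cohort"))
      results$cohortConfig <- cohortCfg
    } else {
      data <- readCohort(config$input)
      cohortCfg <- NULL
    }
    blocks <- sub("_.*$", "", colnames(data$features))
    keep <- rep(TRUE, nrow(data$features))
    for (bl in unique(blocks)) {
      xb <- data$features[, blocks == bl, drop = FALSE]
      if (ncol(xb) >= 1 && nrow(xb) >= 3)
        keep <- keep & !excludeOutlierSubjects(xb, config$outlierSd)
    }
    data <- list(features = data$features[keep, , drop = FALSE],
                 cf = data$cf[keep], scores = data$scores[keep, , drop = FALSE],
                 severity = if (!is.null(data$severity)) data$severity[keep],
                 truth = data$truth)
    results$nOutliers <- sum(!keep)

    # ---- label ----
    ph <- config$phenotype
    labels <- switch(ph$mode,
      binge = {
        tpIdx <- if (is.null(ph$timepoint)) ncol(data$scores) else ph$timepoint
        thr <- if (!is.null(cohortCfg)) matchedThresholds(cohortCfg)
               else c(tLow = stats::quantile(data$scores[, tpIdx], 1 / 3),
                      tHigh = stats::quantile(data$scores[, tpIdx], 2 / 3))
        tLow <- if (is.null(ph$tLow)) thr[[1]] else ph$tLow
        tHigh <- if (is.null(ph$tHigh)) thr[[2]] else ph$tHigh
        makeBinaryLabels(binSeverity(data$scores[, tpIdx], tLow, tHigh))
      },
      growth = {
        ages <- if (!is.null(cohortCfg)) cohortCfg@timepoints
                else seq_len(ncol(data$scores))
        tr <- fitTrajectory(data$scores, ages)
        qs <- stats::quantile(tr$slope, c(1 / 3, 2 / 3), na.rm = TRUE)
        makeBinaryLabels(binSeverity(tr$slope, qs[[1]], qs[[2]]))
      },
      combined = {
        ages <- if (!is.null(cohortCfg)) cohortCfg@timepoints
                else seq_len(ncol(data$scores))
        tr <- fitTrajectory(data$scores, ages)
        cp <- combinedPhenotype(cbind(final = data$scores[, ncol(data$scores)],
                                      slope = tr$slope),
                                k = 2L, seed = childSeed(config$seed, 3L))
        sev <- factor(ifelse(cp$label == 1L, "heavy", "safe"),
                      levels = c("safe", "moderate", "heavy"))
        makeBinaryLabels(sev)
      },
      stop("unknown phenotype mode: ", ph$mode, call. = FALSE))
    if ("label" %in% stages)
      writeLabels(labels, file.path(config$outDir, "labels.csv"),
                  rownames(data$features))
    results$labels <- labels

    inc <- which(includedSubjects(labels))
    Xinc <- data$features[inc, , drop = FALSE]
    yinc <- phenotypeLabel(labels)[inc]
    cfInc <- data$cf[inc]
    plan <- cvPlan(config$cv$outerFolds, config$cv$innerFolds,
                   config$cv$holdoutFraction, seed = childSeed(config$seed, 7L))
    split <- splitExploreHoldout(yinc, cfInc, plan)
    results$split <- split

    # ---- explore ----
    best <- NULL
    if ("explore" %in% stages) {
      rows <- list()
      for (family in config$model$families) {
        spec <- modelSpec(family, seed = childSeed(config$seed, 13L))
        ev <- nestedCV(spec, Xinc[split$explore, , drop = FALSE],
                       yinc[split$explore], cfInc[split$explore],
                       plan, config$correction)
        rows[[family]] <- data.frame(
          phenotype = ph$mode, family = family,
          meanBA = mean(evalScores(ev)), sdBA = stats::sd(evalScores(ev)),
          meanAUC = mean(evalAUC(ev), na.rm = TRUE))
        modal <- table(vapply(evalChosen(ev), function(p)
          paste(names(p), unlist(p), sep = "=", collapse = ";"), ""))
        rows[[family]]$chosen <- names(which.max(modal))
        if (is.null(best) || rows[[family]]$meanBA > best$meanBA)
          best <- list(family = family, meanBA = rows[[family]]$meanBA,
                       params = evalChosen(ev)[[which.max(evalScores(ev))]])
      }
      grid <- do.call(rbind, rows)
      utils::write.table(grid, file.path(config$outDir, "explore_grid.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$exploreGrid <- grid
    }
    if (is.null(best))
      best <- list(family = config$model$families[1],
                   params = modelSpec(config$model$families[1])@grid[[1]])

    # ---- checks ----
    if ("checks" %in% stages) {
      spec <- modelSpec(best$family, grid = list(best$params),
                        seed = childSeed(config$seed, 17L))
      ct <- runSameAnalysisChecks(
        spec, Xinc[split$explore, , drop = FALSE], yinc[split$explore],
        cfInc[split$explore], plan, config$correction,
        nPerm = config$nPerm, seed = childSeed(config$seed, 19L))
      writeCheckTable(ct, file.path(config$outDir, "checks.tsv"))
      results$checks <- ct
    }

    # ---- holdout ----
    if ("holdout" %in% stages) {
      spec <- modelSpec(best$family, grid = list(best$params),
                        seed = childSeed(config$seed, 23L))
      hv <- holdoutEvaluate(spec, best$params, Xinc, yinc, cfInc,
                            split$explore, split$holdout,
                            nSeeds = config$nHoldoutSeeds,
                            correction = config$correction,
                            keepFits = "attribute" %in% stages)
      runner <- function(yTrain) {
        y2 <- yinc; y2[split$explore] <- yTrain
        pipelineScore(Xinc, y2, cfInc, split$explore, split$holdout,
                      spec, best$params, config$correction,
                      seed = childSeed(spec@seed, 5001L))$ba
      }
      pt <- permutationTest(runner, yinc[split$explore],
                            nPerm = config$nPerm,
                            seed = childSeed(config$seed, 29L),
                            observed = mean(evalScores(hv)))
      hv@nullScores <- pt$nullScores
      hv@pRaw <- pt$p
      hv@pBonferroni <- bonferroniAdjust(pt$p, config$nComparisons)
      jsonlite::write_json(list(
        family = best$family, params = best$params,
        correction = config$correction,
        balancedAccuracy = evalScores(hv), auc = evalAUC(hv),
        meanBA = mean(evalScores(hv)), sdBA = stats::sd(evalScores(hv)),
        meanAUC = mean(evalAUC(hv), na.rm = TRUE),
        pRaw = hv@pRaw, pBonferroni = hv@pBonferroni,
        nPerm = config$nPerm
      ), file.path(config$outDir, "holdout_result.json"),
      auto_unbox = TRUE, digits = NA)
      results$holdout <- hv
    }

    # ---- attribute ----
    if ("attribute" %in% stages && !is.null(results$holdout) &&
        !is.null(evalInfo(results$holdout)$fits)) {
      fits <- evalInfo(results$holdout)$fits
      runs <- lapply(seq_along(fits), function(s) {
        ft <- fits[[s]]
        prep <- function(Z, idx) {
          if (!is.null(ft$reg)) Z <- applyConfoundRegressor(ft$reg, Z, cfInc[idx])
          applyStandardizer(ft$std, Z)
        }
        Xbg <- prep(Xinc[ft$rows, , drop = FALSE], ft$rows)
        nBg <- min(100L, nrow(Xbg))
        bg <- Xbg[withSeed(childSeed(config$seed, 31L),
                           sample(nrow(Xbg), nBg)), , drop = FALSE]
        Xho <- prep(Xinc[split$holdout, , drop = FALSE], split$holdout)
        permutationShap(function(Z) predictModel(ft$fit, Z, "decision"),
                        bg, Xho, nRepeats = config$shapRepeats,
                        seed = childSeed(config$seed, 37L + s))
      })
      imp <- summarizeImportance(runs)
      dirFlags <- NULL
      if (length(stableFeatures(imp))) {
        ft <- fits[[1]]
        prep <- function(Z, idx) {
          if (!is.null(ft$reg)) Z <- applyConfoundRegressor(ft$reg, Z, cfInc[idx])
          applyStandardizer(ft$std, Z)
        }
        Xho <- prep(Xinc[split$holdout, , drop = FALSE], split$holdout)
        pred <- as.integer(as.character(
          predictModel(ft$fit, Xho, "class")))
        if (any(pred == 1L))
          dirFlags <- effectDirection(Xho, pred, stableFeatures(imp))
      }
      writeImportance(imp, file.path(config$outDir, "importance.tsv"),
                      dirFlags)
      results$importance <- imp
      results$direction <- dirFlags
    }

    # ---- loso ----
    if ("loso" %in% stages) {
      spec <- modelSpec(best$family, grid = list(best$params),
                        seed = childSeed(config$seed, 41L))
      holdSite <- levels(confoundSite(cfInc))[
        which.max(table(confoundSite(cfInc)) > 0)]
      lo <- leaveOneSiteOut(spec, Xinc, yinc, cfInc, holdSite,
                            correction = if (config$correction %in%
                                             c("under", "over"))
                              config$correction else "none")
      results$loso <- lo
    }

    meta <- list(
      packageVersion = as.character(utils::packageVersion("ConfoundCV")),
      seed = config$seed,
      correction = config$correction,
      phenotypeMode = ph$mode,
      nPerm = config$nPerm,
      families = config$model$families,
      bestFamily = best$family,
      bestParams = best$params,
      nOutliersExcluded = results$nOutliers,
      nExcludedModerate = excludedCount(labels),
      nExplore = length(split$explore),
      nHoldout = length(split$holdout),
      decisions = pipelineConventions()
    )
    jsonlite::write_json(meta, file.path(config$outDir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    results$metadata <- meta
    invisible(results)
  }, error = function(e) {
    writeManifest(e)
    stop(e)
  })
}
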