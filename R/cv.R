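#' Balanced accuracy
#'
#' Mean of the per-class recalls (the model's accuracy within each observed
#' class), insensitive to class imbalance; chance level is 1/#classes.
#'
#' @param yTrue true class vector (factor or coercible); every class over
#'   which the metric is computed must be non-empty.
#' @param yPred predicted class vector of equal length.
#' @return numeric in [0, 1].
#' @examples
#' balancedAccuracy(c(1, 1, 0, 0), c(1, 0, 0, 0))  # (0.5 + 1) / 2
#' @export
balancedAccuracy <- function(yTrue, yPred) {
  stopIfNot(length(yTrue) == length(yPred), "inputs must have equal length")
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  classes <- unique(yTrue)
  stopIfNot(length(classes) >= 1 && !anyNA(yTrue), "empty or missing true classes")
  mean(vapply(classes, function(cl) mean(yPred[yTrue == cl] == cl), numeric(1)))
}

#' Construct a cross-validation plan
#'
#' @param outerFolds outer fold count (default 7).
#' @param innerFolds inner fold count for hyperparameter selection
#'   (default 5).
#' @param holdoutFraction fraction kept aside as the one-shot holdout set
#'   (default 0.20).
#' @param seed integer partitioning seed.
#' @return a \code{\linkS4class{CVPlan}}.
#' @export
cvPlan <- function(outerFolds = 7L, innerFolds = 5L, holdoutFraction = 0.2,
                   seed = 1L) {
  new("CVPlan", outerFolds = as.integer(outerFolds),
      innerFolds = as.integer(innerFolds),
      holdoutFraction = holdoutFraction, seed = as.integer(seed))
}

#' Split subjects into explore and holdout sets
#'
#' Random split stratified on the joint (label x sex x site) cell where
#' cell sizes permit (cells smaller than 4 are pooled within label), else
#' on the label alone. The two sets are disjoint and exhaustive; all model
#' and label selection is meant to happen on the explore set, with the
#' holdout scored once.
#'
#' @param labels binary label vector (no missing values; both classes
#'   present).
#' @param cf \code{\linkS4class{ConfoundFrame}} aligned with \code{labels}.
#' @param plan a \code{\linkS4class{CVPlan}} (its \code{holdoutFraction}
#'   and \code{seed} are used).
#' @return list with integer index vectors \code{explore} and
#'   \code{holdout}.
#' @export
splitExploreHoldout <- function(labels, cf, plan) {
  stopIfNot(!anyNA(labels), "labels must be defined on all indices")
  stopIfNot(length(unique(labels)) == 2, "both label classes must be present")
  stopIfNot(length(labels) == length(cf), "labels and confounds must align")
  cell <- paste(labels, confoundStrata(cf))
  small <- names(which(table(cell) < 4L))
  cell[cell %in% small] <- paste(labels[cell %in% small], "pooled")
  holdout <- integer(0)
  withSeed(plan@seed, {
    for (cl in unique(cell)) {
      idx <- which(cell == cl)
      nHold <- round(length(idx) * plan@holdoutFraction)
      if (nHold > 0) holdout <- c(holdout, sample(idx, nHold))
    }
  })
  holdout <- sort(holdout)
  list(explore = setdiff(seq_along(labels), holdout), holdout = holdout)
}

# ---- single train/test pipeline -----------------------------------------
# Fit correction + standardization + model on the training rows and score
# the test rows. `target` is what the model predicts; `cbLabels` are the
# binary labels driving counterbalancing (defaults to `target`), which is
# how the diagnostic checks resample on the analysis labels while
# predicting a confound. Returns balanced accuracy, optionally AUC, and
# the fitted pieces. Every fitted transform is a pure function of the
# training rows.
pipelineScore <- function(X, target, cf, trainIdx, testIdx, spec, params,
                          correction = c("none", "regression", "under", "over"),
                          cbLabels = NULL, seed = spec@seed,
                          cbStrata = "sex_site", standardize = TRUE,
                          wantAuc = FALSE, keepFit = FALSE) {
  correction <- match.arg(correction)
  stopIfNot(length(intersect(trainIdx, testIdx)) == 0,
            "train and test rows overlap")
  if (is.null(cbLabels)) cbLabels <- target
  rows <- trainIdx
  plan <- NULL
  if (correction %in% c("under", "over")) {
    plan <- counterbalance(as.integer(cbLabels[trainIdx]), cf[trainIdx],
                           mode = correction, seed = seed, strata = cbStrata)
    rows <- trainIdx[planIndices(plan)]
  }
  reg <- NULL
  Xtr <- X[rows, , drop = FALSE]
  Xte <- X[testIdx, , drop = FALSE]
  if (correction == "regression") {
    reg <- fitConfoundRegressor(X[trainIdx, , drop = FALSE], cf[trainIdx])
    Xtr <- applyConfoundRegressor(reg, Xtr, cf[rows])
    Xte <- applyConfoundRegressor(reg, Xte, cf[testIdx])
  }
  std <- NULL
  if (standardize) {
    std <- fitStandardizer(Xtr)
    Xtr <- applyStandardizer(std, Xtr)
    Xte <- applyStandardizer(std, Xte)
  }
  ytr <- droplevels(as.factor(target[rows]))
  if (nlevels(ytr) < 2)
    stop("degenerate target in training portion", call. = FALSE)
  fit <- fitModel(spec, params, Xtr, ytr, seed = seed)
  yte <- as.factor(target[testIdx])
  pred <- predictModel(fit, Xte, "class")
  ba <- balancedAccuracy(as.character(yte), as.character(pred))
  auc <- if (wantAuc && nlevels(ytr) == 2L)
    aucScore(yte, predictModel(fit, Xte, "decision")) else NA_real_
  out <- list(ba = ba, auc = auc)
  if (keepFit) out <- c(out, list(fit = fit, std = std, reg = reg,
                                  plan = plan, rows = rows))
  out
}

#' Nested cross-validation on the explore set
#'
#' For each outer fold, correction and preprocessing are fitted on the
#' outer-training portion, the hyperparameter grid is searched with an
#' inner CV scored by balanced accuracy (ties broken by grid order), the
#' winning combination is refitted on the full outer-training portion and
#' scored on the outer-test fold.
#'
#' @param spec a \code{\linkS4class{ModelSpec}}.
#' @param X subjects x features matrix (explore set only).
#' @param y binary 0/1 label vector.
#' @param cf \code{\linkS4class{ConfoundFrame}} aligned with \code{X}.
#' @param plan a \code{\linkS4class{CVPlan}}.
#' @param correction correction mode: none, regression, under, over.
#' @return an \code{\linkS4class{EvalResult}} with one balanced accuracy
#'   and AUC per outer fold and the chosen hyperparameters per fold.
#' @export
nestedCV <- function(spec, X, y, cf, plan = cvPlan(),
                     correction = c("none", "regression", "under", "over")) {
  correction <- match.arg(correction)
  X <- as.matrix(X)
  stopIfNot(nrow(X) == length(y) && length(y) == length(cf),
            "inputs must align")
  outer <- makeFolds(y, plan@outerFolds, childSeed(plan@seed, 101L))
  scores <- auc <- numeric(plan@outerFolds)
  chosen <- vector("list", plan@outerFolds)
  for (k in seq_len(plan@outerFolds)) {
    trainO <- which(outer != k)
    testO <- which(outer == k)
    if (length(spec@grid) > 1L) {
      inner <- makeFolds(y[trainO], plan@innerFolds,
                         childSeed(plan@seed, 200L + k))
      gridScore <- vapply(spec@grid, function(params) {
        mean(vapply(seq_len(plan@innerFolds), function(j) {
          pipelineScore(X, y, cf, trainO[inner != j], trainO[inner == j],
                        spec, params, correction,
                        seed = childSeed(spec@seed, 1000L * k + j))$ba
        }, numeric(1)))
      }, numeric(1))
      best <- which.max(gridScore)  # first maximum = grid-order tie-break
    } else best <- 1L
    chosen[[k]] <- spec@grid[[best]]
    res <- pipelineScore(X, y, cf, trainO, testO, spec, spec@grid[[best]],
                         correction, seed = childSeed(spec@seed, k),
                         wantAuc = TRUE)
    scores[k] <- res$ba
    auc[k] <- res$auc
  }
  new("EvalResult", scores = scores, auc = auc, chosen = chosen,
      info = list(kind = "nestedCV", correction = correction,
                  family = spec@family, plan = plan))
}

#' Repeated holdout generalization test
#'
#' Retrains the frozen (family, hyperparameter) pipeline on the explore set
#' \code{nSeeds} times with different random seeds (affecting resampling
#' and any model stochasticity) and re-evaluates on the untouched holdout
#' set, reporting per-seed balanced accuracy and AUC.
#'
#' @param spec a \code{\linkS4class{ModelSpec}}.
#' @param params the hyperparameter combination frozen from exploration.
#' @param X,y,cf full data (features, binary labels, confounds).
#' @param exploreIdx,holdoutIdx disjoint index vectors.
#' @param nSeeds number of retrainings (default 7).
#' @param correction correction mode.
#' @param keepFits keep the fitted pipelines (needed for attribution).
#' @return an \code{\linkS4class{EvalResult}}; if \code{keepFits}, the
#'   fitted pipelines are in \code{info$fits}.
#' @export
holdoutEvaluate <- function(spec, params, X, y, cf, exploreIdx, holdoutIdx,
                            nSeeds = 7L,
                            correction = c("none", "regression", "under", "over"),
                            keepFits = FALSE) {
  correction <- match.arg(correction)
  stopIfNot(length(intersect(exploreIdx, holdoutIdx)) == 0,
            "explore and holdout sets overlap")
  X <- as.matrix(X)
  scores <- auc <- numeric(nSeeds)
  fits <- vector("list", nSeeds)
  for (s in seq_len(nSeeds)) {
    res <- pipelineScore(X, y, cf, exploreIdx, holdoutIdx, spec, params,
                         correction, seed = childSeed(spec@seed, 5000L + s),
                         wantAuc = TRUE, keepFit = keepFits)
    scores[s] <- res$ba
    auc[s] <- res$auc
    if (keepFits) fits[[s]] <- res
  }
  new("EvalResult", scores = scores, auc = auc,
      chosen = rep(list(params), nSeeds),
      info = list(kind = "holdout", correction = correction,
                  family = spec@family, nSeeds = nSeeds,
                  fits = if (keepFits) fits else NULL))
}

#' Train-label permutation test
#'
#' Builds the null distribution by re-running the entire pipeline with the
#' training labels randomly shuffled while test labels stay fixed, and
#' returns the add-one p-value \eqn{p = (1 + \#\{null \ge obs\}) /
#' (nPerm + 1)}, which is unbiased and never zero.
#'
#' @param runner function taking a (permuted) training-label vector and
#'   returning the pipeline's test score; it must be the same pipeline
#'   (correction + preprocessing + fit) that produced the observed score.
#' @param trainLabels the unpermuted training labels.
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed for the shuffles.
#' @param observed observed score; computed as \code{runner(trainLabels)}
#'   when omitted.
#' @return list with \code{observed}, \code{nullScores} and \code{p}.
#' @export
permutationTest <- function(runner, trainLabels, nPerm = 1000L, seed = 1L,
                            observed = NULL) {
  stopIfNot(nPerm >= 1, "nPerm must be at least 1")
  if (is.null(observed)) observed <- runner(trainLabels)
  nullScores <- vapply(seq_len(nPerm), function(i) {
    perm <- withSeed(childSeed(seed, i), sample(trainLabels))
    runner(perm)
  }, numeric(1))
  list(observed = observed, nullScores = nullScores,
       p = (1 + sum(nullScores >= observed)) / (nPerm + 1))
}

#' Bonferroni adjustment
#'
#' @param pValues numeric p-values in (0, 1].
#' @param m number of simultaneous analyses (default: the number of
#'   p-values supplied; the motivating study uses m = 3 timepoint
#'   analyses).
#' @return adjusted p-values, capped at 1.
#' @examples
#' bonferroniAdjust(c(0.01, 0.04, 0.2))
#' @export
bonferroniAdjust <- function(pValues, m = length(pValues)) {
  stopIfNot(all(pValues > 0 & pValues <= 1), "p-values must lie in (0, 1]")
  pmin(pValues * m, 1)
}

#' Leave-one-site-out cross-validation
#'
#' One designated site is set aside as the geographic holdout; every other
#' site serves as one outer test fold while the model trains on the
#' remaining sites. Site cannot be counterbalanced in this design (each
#' test fold IS one site), so only sex is balanced; this is recorded in
#' the result metadata. Hyperparameters are selected by an inner CV on the
#' training sites unless a single-combination grid (or \code{params}) is
#' given.
#'
#' @param spec a \code{\linkS4class{ModelSpec}}.
#' @param X,y,cf features, binary labels and confounds.
#' @param holdoutSite site level to keep aside entirely.
#' @param correction "under", "over" (sex-only counterbalancing) or "none".
#' @param params optional frozen hyperparameter combination; grid search
#'   is skipped when given.
#' @param innerFolds inner folds for the grid search (default 5).
#' @return an \code{\linkS4class{EvalResult}} with one score per site fold
#'   (named), plus the holdout-site score in \code{info$holdout}.
#' @export
leaveOneSiteOut <- function(spec, X, y, cf, holdoutSite,
                            correction = c("over", "under", "none"),
                            params = NULL, innerFolds = 5L) {
  correction <- match.arg(correction)
  X <- as.matrix(X)
  site <- confoundSite(cf)
  sites <- names(which(table(site) > 0))
  stopIfNot(length(sites) >= 3, "need at least 3 sites")
  stopIfNot(holdoutSite %in% sites, "holdout site absent from the data")
  foldSites <- setdiff(sites, holdoutSite)
  inferIdx <- which(site != holdoutSite)
  cbStrata <- "sex"
  pickParams <- function(trainIdx) {
    if (!is.null(params)) return(params)
    if (length(spec@grid) == 1L) return(spec@grid[[1]])
    inner <- makeFolds(y[trainIdx], innerFolds, childSeed(spec@seed, 77L))
    gridScore <- vapply(spec@grid, function(pp) {
      mean(vapply(seq_len(innerFolds), function(j) {
        pipelineScore(X, y, cf, trainIdx[inner != j], trainIdx[inner == j],
                      spec, pp, correction, cbStrata = cbStrata,
                      seed = childSeed(spec@seed, 300L + j))$ba
      }, numeric(1)))
    }, numeric(1))
    spec@grid[[which.max(gridScore)]]
  }
  scores <- auc <- setNames(numeric(length(foldSites)), foldSites)
  chosen <- vector("list", length(foldSites))
  for (i in seq_along(foldSites)) {
    s <- foldSites[i]
    testIdx <- which(site == s)
    trainIdx <- setdiff(inferIdx, testIdx)
    pp <- pickParams(trainIdx)
    chosen[[i]] <- pp
    res <- pipelineScore(X, y, cf, trainIdx, testIdx, spec, pp, correction,
                         cbStrata = cbStrata, seed = childSeed(spec@seed, i),
                         wantAuc = TRUE)
    scores[i] <- res$ba
    auc[i] <- res$auc
  }
  holdIdx <- which(site == holdoutSite)
  ppH <- pickParams(inferIdx)
  hold <- pipelineScore(X, y, cf, inferIdx, holdIdx, spec, ppH, correction,
                        cbStrata = cbStrata,
                        seed = childSeed(spec@seed, 999L), wantAuc = TRUE)
  new("EvalResult", scores = unname(scores), auc = unname(auc),
      chosen = chosen,
      info = list(kind = "leaveOneSiteOut", foldSites = foldSites,
                  holdoutSite = holdoutSite,
                  holdout = list(ba = hold$ba, auc = hold$auc),
                  counterbalanced = "sex only (site is the fold unit)",
                  correction = correction))
}

#' @describeIn EvalResult-accessors per-fold/per-seed balanced accuracies.
#' @export
evalScores <- function(x) x@scores

#' Accessors for EvalResult
#' @param x an \code{\linkS4class{EvalResult}}.
#' @name EvalResult-accessors
NULL

#' @describeIn EvalResult-accessors per-fold/per-seed AUCs.
#' @export
evalAUC <- function(x) x@auc

#' @describeIn EvalResult-accessors chosen hyperparameters per fold.
#' @export
evalChosen <- function(x) x@chosen

#' @describeIn EvalResult-accessors metadata list.
#' @export
evalInfo <- function(x) x@info

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult (%s): balanced accuracy %.3f +/- %.3f over %d folds/seeds\n",
              if (length(object@info$kind)) object@info$kind else "?",
              mean(object@scores), stats::sd(object@scores),
              length(object@scores)))
  if (!is.na(object@pRaw))
    cat(sprintf("  permutation p = %.4g (Bonferroni: %.4g)\n",
                object@pRaw, object@pBonferroni))
})
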