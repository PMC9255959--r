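#' Five-way same-analysis diagnostic checks
#'
#' Evaluates the five input-output combinations X->y, X->c_sex, X->c_site,
#' c_sex->y and c_site->y under a chosen confound-correction technique,
#' all with the same cross-validation fold assignments and the same model
#' family as the main analysis, so that differences between rows are
#' attributable to the input/target swap rather than partition noise.
#' Confounds used as inputs are full one-hot encoded; confounds used as
#' targets are scored with multiclass balanced accuracy (chance =
#' 1/#classes). The correction is applied exactly as in the main analysis
#' before the X->. rows (regression residualizes the features;
#' counterbalancing resamples the training rows on the analysis labels
#' \code{y}), and label-driven resampling is applied before the c->y rows.
#' Under confound regression the c->y rows are reported unmodified, since
#' residualizing X leaves the c~y association untouched. Each row gets a
#' train-label permutation p-value.
#'
#' A healthy corrected analysis shows: X->y above chance (the signal of
#' interest), X->c rows at chance after a successful confound regression,
#' and c->y rows at chance after successful counterbalancing.
#'
#' @param spec a \code{\linkS4class{ModelSpec}}; its first grid entry is
#'   used (the checks run at fixed hyperparameters).
#' @param X subjects x features matrix (analysis subjects only).
#' @param y binary 0/1 label vector.
#' @param cf \code{\linkS4class{ConfoundFrame}} aligned with \code{X}.
#' @param plan a \code{\linkS4class{CVPlan}}; \code{outerFolds} and
#'   \code{seed} define the shared folds.
#' @param correction correction mode: none, regression, under, over.
#' @param nPerm permutations per row (default 199).
#' @param seed permutation seed.
#' @param combinations which of the five rows to evaluate (default: the
#'   full battery); restricting is useful when one pathway is probed under
#'   several model families.
#' @return a \code{\linkS4class{CheckTable}}.
#' @export
runSameAnalysisChecks <- function(spec, X, y, cf, plan = cvPlan(),
                                  correction = c("none", "regression",
                                                 "under", "over"),
                                  nPerm = 199L, seed = 1L,
                                  combinations = c("x_to_y", "x_to_sex",
                                                   "x_to_site", "sex_to_y",
                                                   "site_to_y")) {
  correction <- match.arg(correction)
  combinations <- match.arg(combinations, several.ok = TRUE)
  X <- as.matrix(X)
  y <- as.integer(y)
  stopIfNot(nrow(X) == length(y) && length(y) == length(cf),
            "inputs must align")
  k <- plan@outerFolds
  fold <- makeFolds(y, k, childSeed(plan@seed, 101L))
  params <- spec@grid[[1]]
  Cfull <- designMatrix(cf, "full")
  sexCols <- grep("^sex", colnames(Cfull))
  siteCols <- grep("^site", colnames(Cfull))

  resampling <- correction %in% c("under", "over")

  # Score one row. inputKind: "features" or "confound"; target: what the
  # model predicts; cbDriven: TRUE when the resampling labels are the
  # row's own target (X->y and c->y rows), so permutations must re-derive
  # the resample plan. For every other row the training rows - and hence
  # the fitted correction and standardization - do not depend on the
  # permuted target, so the per-fold corrected matrices are prepared once
  # and only the model is refitted per permutation.
  scoreRow <- function(inputKind, inputX, target, cbDriven, rowCorrection) {
    target <- as.factor(target)
    rowResample <- rowCorrection %in% c("under", "over")
    dynamic <- rowResample && cbDriven

    prepFold <- function(kk, cbLab) {
      trainIdx <- which(fold != kk)
      testIdx <- which(fold == kk)
      rows <- trainIdx
      if (rowResample) {
        cbv <- as.integer(as.character(cbLab[trainIdx]))
        pl <- counterbalance(cbv, cf[trainIdx], mode = rowCorrection,
                             seed = childSeed(plan@seed, 400L + kk))
        rows <- trainIdx[planIndices(pl)]
      }
      Xtr <- inputX[rows, , drop = FALSE]
      Xte <- inputX[testIdx, , drop = FALSE]
      if (rowCorrection == "regression") {
        reg <- fitConfoundRegressor(inputX[trainIdx, , drop = FALSE],
                                    cf[trainIdx])
        Xtr <- applyConfoundRegressor(reg, Xtr, cf[rows])
        Xte <- applyConfoundRegressor(reg, Xte, cf[testIdx])
      }
      if (inputKind == "features") {
        std <- fitStandardizer(Xtr)
        Xtr <- applyStandardizer(std, Xtr)
        Xte <- applyStandardizer(std, Xte)
      }
      list(trainIdx = trainIdx, testIdx = testIdx, rows = rows,
           Xtr = Xtr, Xte = Xte, kk = kk)
    }

    foldFit <- function(fd, tgt) {
      ytr <- droplevels(as.factor(tgt[fd$rows]))
      if (nlevels(ytr) < 2L) return(NA_real_)
      fit <- tryCatch(fitModel(spec, params, fd$Xtr, ytr,
                               seed = childSeed(plan@seed, 400L + fd$kk)),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      balancedAccuracy(as.character(target[fd$testIdx]),
                       as.character(predictModel(fit, fd$Xte, "class")))
    }

    meanScore <- function(sc, warn) {
      if (all(is.na(sc)))
        stop("all folds skipped: no fold retains both target classes",
             call. = FALSE)
      if (warn && anyNA(sc))
        warning("fold(s) lacking a target class were skipped", call. = FALSE)
      mean(sc, na.rm = TRUE)
    }

    if (!dynamic) {
      folds <- lapply(seq_len(k), prepFold, cbLab = y)
      perFold <- vapply(folds, foldFit, numeric(1), tgt = target)
      obs <- meanScore(perFold, warn = TRUE)
      nullScores <- vapply(seq_len(nPerm), function(i) {
        sc <- vapply(folds, function(fd) {
          tgt <- target
          tgt[fd$trainIdx] <- withSeed(childSeed(seed, i * 37L + fd$kk),
                                       sample(tgt[fd$trainIdx]))
          foldFit(fd, tgt)
        }, numeric(1))
        meanScore(sc, warn = FALSE)
      }, numeric(1))
    } else {
      # the permuted target drives the resampling: rebuild the plan (and
      # everything downstream of it) inside every permutation
      runFold <- function(kk, tgt) {
        fd <- tryCatch(prepFold(kk, cbLab = tgt), error = function(e) NULL)
        if (is.null(fd)) return(NA_real_)
        foldFit(fd, tgt)
      }
      perFold <- vapply(seq_len(k), runFold, numeric(1), tgt = target)
      obs <- meanScore(perFold, warn = TRUE)
      nullScores <- vapply(seq_len(nPerm), function(i) {
        sc <- vapply(seq_len(k), function(kk) {
          tgt <- target
          trainIdx <- which(fold != kk)
          tgt[trainIdx] <- withSeed(childSeed(seed, i * 37L + kk),
                                    sample(tgt[trainIdx]))
          runFold(kk, tgt)
        }, numeric(1))
        meanScore(sc, warn = FALSE)
      }, numeric(1))
    }
    p <- (1 + sum(nullScores >= obs, na.rm = TRUE)) / (nPerm + 1)
    list(mean = obs, sd = stats::sd(perFold, na.rm = TRUE), p = p,
         chance = 1 / nlevels(droplevels(target)))
  }

  xCorrection <- correction
  cCorrection <- if (resampling) correction else "none"
  rowDefs <- list(
    x_to_y = function() scoreRow("features", X, y, cbDriven = TRUE,
                                 rowCorrection = xCorrection),
    x_to_sex = function() scoreRow("features", X, confoundSex(cf),
                                   cbDriven = FALSE,
                                   rowCorrection = xCorrection),
    x_to_site = function() scoreRow("features", X, confoundSite(cf),
                                    cbDriven = FALSE,
                                    rowCorrection = xCorrection),
    sex_to_y = function() scoreRow("confound", Cfull[, sexCols, drop = FALSE],
                                   y, cbDriven = TRUE,
                                   rowCorrection = cCorrection),
    site_to_y = function() scoreRow("confound", Cfull[, siteCols, drop = FALSE],
                                    y, cbDriven = TRUE,
                                    rowCorrection = cCorrection)
  )
  rows <- lapply(rowDefs[names(rowDefs) %in% combinations], function(f) f())
  tb <- data.frame(
    combination = names(rows),
    meanBA = vapply(rows, `[[`, numeric(1), "mean"),
    sdBA = vapply(rows, `[[`, numeric(1), "sd"),
    chance = vapply(rows, `[[`, numeric(1), "chance"),
    pValue = vapply(rows, `[[`, numeric(1), "p"),
    row.names = NULL
  )
  tb$sig05 <- tb$pValue <= 0.05
  tb$sig01 <- tb$pValue <= 0.01
  new("CheckTable", table = tb,
      info = list(correction = correction, family = spec@family,
                  folds = k, nPerm = nPerm, seed = seed))
}

#' @describeIn runSameAnalysisChecks the underlying five-row data.frame.
#' @param x a \code{\linkS4class{CheckTable}}.
#' @export
checkTable <- function(x) x@table

setMethod("show", "CheckTable", function(object) {
  cat(sprintf("CheckTable (correction: %s, model: %s)\n",
              object@info$correction, object@info$family))
  tb <- object@table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-10s BA %.3f +/- %.3f (chance %.3f), p = %.4g%s\n",
                tb$combination[i], tb$meanBA[i], tb$sdBA[i], tb$chance[i],
                tb$pValue[i],
                if (tb$sig01[i]) " **" else if (tb$sig05[i]) " *" else ""))
})

#' Write a check table to TSV
#'
#' @param x a \code{\linkS4class{CheckTable}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCheckTable <- function(x, path) {
  utils::write.table(x@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
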