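#' Construct a confound frame
#'
#' @param sex,site factors (or coercible) of equal length; the level sets
#'   are fixed here and enforced whenever a fitted object is applied.
#' @return a \code{\linkS4class{ConfoundFrame}}.
#' @export
confoundFrame <- function(sex, site) {
  new("ConfoundFrame", sex = as.factor(sex), site = as.factor(site))
}

#' Subset a confound frame
#' @param x a \code{\linkS4class{ConfoundFrame}}.
#' @param i subject indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ConfoundFrame", function(x, i, j, ..., drop = FALSE) {
  # hot path inside permutation loops: skip re-validation of a subset
  S4Vectors::new2("ConfoundFrame", sex = x@sex[i, drop = FALSE],
                  site = x@site[i, drop = FALSE], check = FALSE)
})

setMethod("length", "ConfoundFrame", function(x) length(x@sex))

setMethod("show", "ConfoundFrame", function(object) {
  cat(sprintf("ConfoundFrame: %d subjects, sex levels [%s], site levels [%s]\n",
              length(object@sex), paste(levels(object@sex), collapse = ", "),
              paste(levels(object@site), collapse = ", ")))
})

#' @describeIn confoundFrame sex factor accessor.
#' @param x a \code{ConfoundFrame}.
#' @export
confoundSex <- function(x) x@sex

#' @describeIn confoundFrame site factor accessor.
#' @export
confoundSite <- function(x) x@site

#' @describeIn confoundFrame joint (sex x site) stratum id per subject.
#' @export
confoundStrata <- function(x) paste(x@sex, x@site, sep = ":")

#' One-hot design matrix for confounds
#'
#' Categorical confounds are one-hot encoded so that no false ordinal
#' relationship is implied. Two encodings are used in the package:
#' drop-first with an intercept (for OLS confound regression, avoiding
#' collinearity) and full one-hot without intercept (when confounds serve
#' as classifier inputs in the diagnostic checks).
#'
#' @param cf a \code{\linkS4class{ConfoundFrame}}.
#' @param encoding "regression" (intercept + drop-first) or "full".
#' @return numeric design matrix with named columns.
#' @export
designMatrix <- function(cf, encoding = c("regression", "full")) {
  encoding <- match.arg(encoding)
  oneHot <- function(f, name, dropFirst) {
    lv <- levels(f)
    if (dropFirst) lv <- lv[-1]
    cols <- vapply(lv, function(l) as.numeric(f == l),
                   numeric(length(f)))
    cols <- matrix(cols, nrow = length(f),
                   dimnames = list(NULL, paste0(name, lv)))
    cols
  }
  if (encoding == "regression") {
    cbind(`(Intercept)` = 1,
          oneHot(cf@sex, "sex", TRUE), oneHot(cf@site, "site", TRUE))
  } else {
    cbind(oneHot(cf@sex, "sex", FALSE), oneHot(cf@site, "site", FALSE))
  }
}

#' Fit a linear confound regressor on training data
#'
#' Per-feature OLS of the features on the main-effects one-hot design
#' (intercept, sex, site). Design columns whose category is absent from
#' the training rows are dropped with a warning. Because the design only
#' carries main effects, the fit removes every per-category mean shift but
#' leaves per-category variance differences and sex x site interaction
#' structure untouched - which is exactly what the diagnostic check suite
#' probes with a kernel model.
#'
#' @param xTrain training feature matrix (rows = subjects).
#' @param cfTrain \code{\linkS4class{ConfoundFrame}} of the training rows.
#' @return a \code{\linkS4class{ConfoundRegressor}}.
#' @export
fitConfoundRegressor <- function(xTrain, cfTrain) {
  xTrain <- as.matrix(xTrain)
  stopIfNot(nrow(xTrain) == length(cfTrain),
            "features and confounds must align")
  cells <- unique(confoundStrata(cfTrain))
  stopIfNot(length(cells) >= 2,
            "need at least 2 distinct confound cells in the training data")
  D <- designMatrix(cfTrain, "regression")
  present <- colSums(abs(D)) > 0
  if (!all(present)) {
    warning(sprintf("dropping empty design column(s): %s",
                    paste(colnames(D)[!present], collapse = ", ")),
            call. = FALSE)
    D <- D[, present, drop = FALSE]
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    warning("rank-deficient confound design; dropping aliased column(s)",
            call. = FALSE)
    D <- D[, sort(keep), drop = FALSE]
    qrD <- qr(D)
  }
  coefs <- qr.coef(qrD, xTrain)
  coefs[is.na(coefs)] <- 0
  new("ConfoundRegressor", coefficients = coefs, columns = colnames(D),
      sexLevels = levels(confoundSex(cfTrain)),
      siteLevels = levels(confoundSite(cfTrain)))
}

#' Residualize features with a fitted confound regressor
#'
#' Subtracts the train-fitted design effects from any data (training or
#' test); coefficients are never refitted at apply time.
#'
#' @param reg a \code{\linkS4class{ConfoundRegressor}}.
#' @param x feature matrix to residualize.
#' @param cf confound frame aligned with \code{x}; categories must match
#'   the fit.
#' @return residual matrix of the same shape as \code{x}.
#' @export
applyConfoundRegressor <- function(reg, x, cf) {
  x <- as.matrix(x)
  stopIfNot(nrow(x) == length(cf), "features and confounds must align")
  if (!all(as.character(confoundSex(cf)) %in% reg@sexLevels) ||
      !all(as.character(confoundSite(cf)) %in% reg@siteLevels))
    stop("confound category unseen at fit time", call. = FALSE)
  cfAligned <- confoundFrame(
    factor(as.character(confoundSex(cf)), levels = reg@sexLevels),
    factor(as.character(confoundSite(cf)), levels = reg@siteLevels))
  D <- designMatrix(cfAligned, "regression")
  D <- D[, reg@columns, drop = FALSE]
  x - D %*% reg@coefficients
}

#' Counterbalance training rows across confound strata
#'
#' Within every confound stratum (by default the joint sex x site cell),
#' the two label classes are equalized: to the stratum minimum by dropping
#' rows (\code{mode = "under"}) or to the stratum maximum by
#' sampling-with-replacement of the minority class (\code{mode = "over"}).
#' Strata in which either class is absent are dropped entirely with a
#' warning. On the resampled multiset the empirical confound distribution
#' is identical across label classes (the chi-square statistic of cell x
#' label is exactly zero) and the label classes are globally equal in
#' size. Apply to training rows only, after the train/test split.
#'
#' @param labels binary (0/1) label vector of the training rows.
#' @param cf \code{\linkS4class{ConfoundFrame}} of the same rows.
#' @param mode "under" or "over".
#' @param seed integer resampling seed.
#' @param strata which confounds to balance jointly: "sex_site" (default),
#'   "sex", or "site"; sex-only is what leave-one-site-out folds use, where
#'   site cannot be balanced.
#' @return a \code{\linkS4class{ResamplePlan}}; indices are positions into
#'   the supplied training rows (test rows can never appear).
#' @examples
#' cf <- confoundFrame(rep("f", 8), rep(c("A", "B"), each = 4))
#' counterbalance(c(1, 1, 1, 0, 1, 0, 0, 0), cf, "over", seed = 1)
#' @export
counterbalance <- function(labels, cf, mode = c("under", "over"), seed = 1L,
                           strata = c("sex_site", "sex", "site")) {
  mode <- match.arg(mode)
  strata <- match.arg(strata)
  stopIfNot(length(labels) == length(cf), "labels and confounds must align")
  stopIfNot(all(labels %in% c(0L, 1L)), "labels must be binary 0/1")
  cell <- switch(strata,
                 sex_site = confoundStrata(cf),
                 sex = as.character(confoundSex(cf)),
                 site = as.character(confoundSite(cf)))
  idx <- integer(0)
  tabStratum <- character(0)
  tabBefore1 <- tabBefore0 <- tabAfter1 <- tabAfter0 <- integer(0)
  dropped <- 0L
  withSeed(seed, {
    for (cl in sort(unique(cell))) {
      i1 <- which(cell == cl & labels == 1L)
      i0 <- which(cell == cl & labels == 0L)
      n1 <- length(i1); n0 <- length(i0)
      tabStratum <- c(tabStratum, cl)
      tabBefore1 <- c(tabBefore1, n1); tabBefore0 <- c(tabBefore0, n0)
      if (n1 == 0L || n0 == 0L) {
        dropped <- dropped + n1 + n0
        tabAfter1 <- c(tabAfter1, 0L); tabAfter0 <- c(tabAfter0, 0L)
        next
      }
      pick <- function(v, size, replace = FALSE)
        v[sample.int(length(v), size, replace = replace)]
      if (mode == "under") {
        m <- min(n1, n0)
        s1 <- if (n1 == m) i1 else pick(i1, m)
        s0 <- if (n0 == m) i0 else pick(i0, m)
      } else {
        m <- max(n1, n0)
        s1 <- if (n1 == m) i1 else c(i1, pick(i1, m - n1, replace = TRUE))
        s0 <- if (n0 == m) i0 else c(i0, pick(i0, m - n0, replace = TRUE))
      }
      idx <- c(idx, s1, s0)
      tabAfter1 <- c(tabAfter1, length(s1)); tabAfter0 <- c(tabAfter0, length(s0))
    }
  })
  if (!length(idx))
    stop("no confound stratum contains both label classes", call. = FALSE)
  if (dropped > 0L)
    warning(sprintf("%d subject(s) dropped from strata missing a label class",
                    dropped), call. = FALSE)
  cellTable <- data.frame(stratum = tabStratum, n1Before = tabBefore1,
                          n0Before = tabBefore0, n1After = tabAfter1,
                          n0After = tabAfter0)
    S4Vectors::new2("ResamplePlan", mode = mode, strata = cell,
                  indices = sort(idx), cellTable = cellTable,
                  droppedRows = dropped, seed = as.integer(seed),
                  check = FALSE)
}

#' @describeIn counterbalance selected training-row index multiset.
#' @param plan a \code{\linkS4class{ResamplePlan}}.
#' @export
planIndices <- function(plan) plan@indices

setMethod("show", "ResamplePlan", function(object) {
  cat(sprintf("ResamplePlan (%s-sampling): %d rows -> %d rows, %d dropped\n",
              object@mode, length(object@strata), length(object@indices),
              object@droppedRows))
})

#' Serialize a resample plan to JSON
#'
#' @param plan a \code{\linkS4class{ResamplePlan}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeResamplePlan <- function(plan, path) {
  jsonlite::write_json(list(
    mode = plan@mode, seed = plan@seed, droppedRows = plan@droppedRows,
    cellTable = plan@cellTable, indices = plan@indices
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
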