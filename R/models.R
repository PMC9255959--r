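#' Construct a model specification
#'
#' Four families mirror common practice in tabular neuroimaging ML:
#' L2-penalized logistic regression, linear SVM, RBF-kernel SVM and
#' gradient boosting. Each carries an ordered hyperparameter grid; nested
#' cross-validation selects a combination by inner-fold balanced accuracy
#' with ties broken by grid order.
#'
#' Default grids: logistic and linear SVM search the inverse regularization
#' strength C over four log-spaced values; the RBF SVM searches a 3 x 3
#' (C, kernel-width scale) grid where the kernel width is
#' \code{gammaScale / nFeatures}; boosting searches a 2 x 2 x 2 grid over
#' rounds, depth and learning rate.
#'
#' @param family one of "logistic", "linear-svm", "rbf-svm",
#'   "gradient-boosting".
#' @param grid optional list of named hyperparameter lists replacing the
#'   default grid.
#' @param seed integer model seed (used by stochastic families and
#'   resampling inside pipelines).
#' @return a \code{\linkS4class{ModelSpec}}.
#' @examples
#' modelSpec("rbf-svm")
#' modelSpec("logistic", grid = list(list(C = 1)))
#' @export
modelSpec <- function(family = c("logistic", "linear-svm", "rbf-svm",
                                 "gradient-boosting"),
                      grid = NULL, seed = 0L) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- defaultGrid(family)
  new("ModelSpec", family = family, grid = grid, seed = as.integer(seed))
}

defaultGrid <- function(family) {
  switch(family,
    "logistic" = lapply(10^seq(-2, 1), function(C) list(C = C)),
    "linear-svm" = lapply(10^seq(-2, 1), function(C) list(C = C)),
    "rbf-svm" = {
      g <- expand.grid(C = c(0.1, 1, 10), gammaScale = c(1, 0.1, 10))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    "gradient-boosting" = {
      g <- expand.grid(nrounds = c(50, 100), maxDepth = c(2, 4),
                       eta = c(0.1, 0.3))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    })
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s, %d hyperparameter combination(s), seed %d\n",
              object@family, length(object@grid), object@seed))
})

# ---- ridge-penalized logistic regression (IRLS) -------------------------
# L2-penalized logistic regression with inverse regularization C
# (penalty 1/C on all non-intercept coefficients), fitted by iteratively
# reweighted least squares on the normal equations. Written in-package
# because the diagnostic battery refits this model hundreds of thousands
# of times inside permutation tests; verified against glm() in the tests.
fitRidgeLogit <- function(X, y01, lambda, maxit = 12L, tol = 1e-6) {
  drop(ridgeLogitFit(as.matrix(X), as.numeric(y01), lambda,
                     as.integer(maxit), tol))
}

# ---- unified fit/predict interface --------------------------------------

#' Fit a classifier of a given family
#'
#' Uniform interface over the four model families. \code{y} may be any
#' factor; multiclass targets are handled by one-vs-rest for the logistic
#' family and natively by the SVM (one-vs-one) and boosting (softmax)
#' implementations.
#'
#' @param spec a \code{\linkS4class{ModelSpec}}.
#' @param params one hyperparameter combination (an element of the grid).
#' @param X numeric training matrix.
#' @param y training target (factor or coercible).
#' @param seed integer seed for stochastic families.
#' @return a fitted model object for \code{\link{predictModel}}.
#' @export
fitModel <- function(spec, params, X, y, seed = spec@seed) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  lv <- levels(y)
  stopIfNot(length(lv) >= 2, "training target has a single class")
  family <- spec@family
  fit <- switch(family,
    "logistic" = {
      lambda <- 1 / params[["C"]]
      if (length(lv) == 2L) {
        list(beta = fitRidgeLogit(X, as.numeric(y == lv[2]), lambda))
      } else {
        list(betas = lapply(lv, function(l)
          fitRidgeLogit(X, as.numeric(y == l), lambda)))
      }
    },
    "linear-svm" = withSeed(seed,
      e1071::svm(X, y, kernel = "linear", cost = params[["C"]],
                 cachesize = 200, scale = FALSE)),
    "rbf-svm" = {
      gamma <- if (!is.null(params[["gamma"]])) params[["gamma"]]
               else (if (is.null(params[["gammaScale"]])) 1
                     else params[["gammaScale"]]) / ncol(X)
      withSeed(seed,
        e1071::svm(X, y, kernel = "radial", cost = params[["C"]], gamma = gamma,
                   cachesize = 200, scale = FALSE))
    },
    "gradient-boosting" = {
      if (length(lv) == 2L) {
        pars <- list(objective = "binary:logistic",
                     max_depth = params[["maxDepth"]], eta = params[["eta"]],
                     nthread = 1L, seed = as.integer(seed))
        dm <- xgboost::xgb.DMatrix(X, label = as.numeric(y == lv[2]),
                                   nthread = 1L)
      } else {
        pars <- list(objective = "multi:softprob", num_class = length(lv),
                     max_depth = params[["maxDepth"]], eta = params[["eta"]],
                     nthread = 1L, seed = as.integer(seed))
        dm <- xgboost::xgb.DMatrix(X, label = as.numeric(y) - 1, nthread = 1L)
      }
      xgboost::xgb.train(params = pars, data = dm,
                         nrounds = params[["nrounds"]], verbose = 0)
    })
  structure(list(family = family, fit = fit, levels = lv, params = params),
            class = "ccvModel")
}

#' Predict classes or decision scores
#'
#' @param model object from \code{\link{fitModel}}.
#' @param X matrix of new data (same feature space).
#' @param type "class" for hard labels, "decision" for a continuous score
#'   on the model's decision scale (binary targets only): the linear
#'   predictor for logistic, the margin for SVMs and the log-odds margin
#'   for boosting, oriented so larger values indicate the second factor
#'   level.
#' @return factor of predictions, or numeric decision vector.
#' @export
predictModel <- function(model, X, type = c("class", "decision")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  lv <- model$levels
  binary <- length(lv) == 2L
  if (type == "decision") stopIfNot(binary, "decision scores are binary-only")
  switch(model$family,
    "logistic" = {
      if (binary) {
        eta <- drop(cbind(1, X) %*% model$fit$beta)
        if (type == "decision") eta
        else factor(lv[(eta > 0) + 1L], levels = lv)
      } else {
        etas <- vapply(model$fit$betas, function(b) drop(cbind(1, X) %*% b),
                       numeric(nrow(X)))
        factor(lv[max.col(matrix(etas, nrow(X)))], levels = lv)
      }
    },
    "linear-svm" = ,
    "rbf-svm" = {
      pr <- stats::predict(model$fit, X, decision.values = (type == "decision"))
      if (type == "class") return(factor(as.character(pr), levels = lv))
      dv <- attr(pr, "decision.values")
      # e1071 orients the margin toward the first label of the pair name
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      if (first == lv[2]) dv[, 1] else -dv[, 1]
    },
    "gradient-boosting" = {
      if (binary) {
        marg <- stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1L),
                               outputmargin = TRUE)
        if (type == "decision") marg
        else factor(lv[(marg > 0) + 1L], levels = lv)
      } else {
        pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1L))
        if (!is.matrix(pr)) pr <- matrix(pr, nrow(X), length(lv), byrow = TRUE)
        factor(lv[max.col(pr)], levels = lv)
      }
    })
}
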