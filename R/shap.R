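#' Permutation-based Shapley attributions
#'
#' Model-agnostic Shapley-value estimate on the model's decision scale.
#' For each sampled feature ordering (and its reverse, an antithetic pair
#' that makes the estimator exact for additive models), features of a
#' background row are switched to the explained subject's values one at a
#' time; the change in model output at each step is that feature's
#' contribution for that ordering. Averaging over orderings and background
#' rows yields the interventional Shapley value. By telescoping, each
#' subject's attributions sum exactly to its model output minus the mean
#' output over the background rows used (additivity).
#'
#' @param model either a fitted model from \code{\link{fitModel}} (for
#'   which exact fast chain evaluators are used where the model algebra
#'   permits) or a plain function mapping a numeric matrix to decision
#'   scores.
#' @param background matrix of background (training) rows the masked
#'   features are drawn from.
#' @param targets matrix of subjects to explain (same feature space).
#' @param nRepeats number of ordering/background draws; each draw uses one
#'   ordering plus its reverse.
#' @param seed integer estimator seed; results are deterministic given it.
#' @return an \code{\linkS4class{AttributionMatrix}}.
#' @examples
#' f <- function(Z) 2 * Z[, 1]
#' bg <- matrix(rnorm(200), 100, 2)
#' shap <- permutationShap(f, bg, matrix(c(1, 0), 1, 2), nRepeats = 5)
#' attributionValues(shap)  # ~ (2 * (1 - mean(bg[,1])), 0)
#' @export
permutationShap <- function(model, background, targets, nRepeats = 10L,
                            seed = 1L) {
  background <- as.matrix(background)
  targets <- as.matrix(targets)
  stopIfNot(nrow(background) > 0, "background must be non-empty")
  stopIfNot(ncol(background) == ncol(targets),
            "background and targets must share the feature space")
  predictFun <- if (is.function(model)) model
                else function(Z) predictModel(model, Z, "decision")
  d <- ncol(targets)
  nT <- nrow(targets)
  contrib <- matrix(0, nT, d)
  fTarget <- as.numeric(predictFun(targets))
  chain <- makeChainEvaluator(model, predictFun, targets, fTarget)
  baseSum <- 0
  withSeed(seed, {
    for (r in seq_len(nRepeats)) {
      b <- background[sample.int(nrow(background), 1L), ]
      fB <- as.numeric(predictFun(matrix(b, 1L, d)))
      baseSum <- baseSum + fB
      ord <- sample.int(d)
      contrib <- contrib + chain(b, fB, ord) + chain(b, fB, rev(ord))
    }
  })
  values <- contrib / (2 * nRepeats)
  base <- baseSum / nRepeats
  colnames(values) <- colnames(targets)
  new("AttributionMatrix", values = values, baseValue = base,
      prediction = fTarget, seed = as.integer(seed))
}

# One forward pass along a feature ordering: start from the background row
# and switch features to the target's values one at a time; the output
# change at each step is that feature's contribution. Returns an
# nTargets x d matrix. Fast exact evaluators exist for the model families
# whose algebra permits incremental updates (linear predictors; RBF kernel
# sums via rank-one squared-distance updates); everything else goes
# through the model's predict function, one call per step.
makeChainEvaluator <- function(model, predictFun, targets, fTarget) {
  d <- ncol(targets)
  nT <- nrow(targets)
  generic <- function(b, fB, ord) {
    contrib <- matrix(0, nT, d)
    Z <- matrix(b, nT, d, byrow = TRUE)
    prev <- rep(fB, nT)
    for (s in seq_len(d)) {
      j <- ord[s]
      Z[, j] <- targets[, j]
      cur <- if (s == d) fTarget else as.numeric(predictFun(Z))
      contrib[, j] <- cur - prev
      prev <- cur
    }
    contrib
  }
  if (is.function(model)) return(generic)
  linearChain <- function(w) {
    # linear decision: contributions are order-independent and exact
    function(b, fB, ord) {
      sweep(targets, 2L, b, "-") * matrix(w, nT, d, byrow = TRUE)
    }
  }
  if (model$family == "logistic" && length(model$levels) == 2L)
    return(linearChain(model$fit$beta[-1]))
  if (model$family %in% c("linear-svm", "rbf-svm")) {
    fit <- model$fit
    first <- fit$levels[fit$labels[1]]
    flip <- if (first == model$levels[2]) 1 else -1
    SV <- as.matrix(fit$SV)
    alpha <- as.numeric(fit$coefs)
    if (model$family == "linear-svm")
      return(linearChain(flip * drop(crossprod(SV, alpha))))
    gamma <- fit$gamma
    rho <- fit$rho
    return(function(b, fB, ord) {
      contrib <- matrix(0, nT, d)
      # squared distances of the current chain state to every SV;
      # switching feature j is a rank-one update
      D <- matrix(colSums((t(SV) - b)^2), nT, nrow(SV), byrow = TRUE)
      prev <- rep(fB, nT)
      for (s in seq_len(d)) {
        j <- ord[s]
        u <- targets[, j] - b[j]
        D <- D + (targets[, j]^2 - b[j]^2) - 2 * outer(u, SV[, j])
        cur <- if (s == d) fTarget
               else flip * (drop(exp(-gamma * D) %*% alpha) - rho)
        contrib[, j] <- cur - prev
        prev <- cur
      }
      contrib
    })
  }
  generic
}

#' @describeIn permutationShap subjects x features attribution values.
#' @param x an \code{\linkS4class{AttributionMatrix}}.
#' @export
attributionValues <- function(x) x@values

#' @describeIn permutationShap base value (mean background output).
#' @export
attributionBase <- function(x) x@baseValue

setMethod("show", "AttributionMatrix", function(object) {
  cat(sprintf("AttributionMatrix: %d subjects x %d features, base %.4f\n",
              nrow(object@values), ncol(object@values), object@baseValue))
})

#' Exact Shapley values by coalition enumeration
#'
#' Brute-force reference estimator: averages the model output over all
#' 2^d feature coalitions (masked features drawn from every background
#' row) and applies the Shapley weighting. Exponential in the feature
#' count - intended as an independent oracle for small d, not for use on
#' real feature tables.
#'
#' @inheritParams permutationShap
#' @return subjects x features matrix of exact Shapley values.
#' @export
exactShap <- function(model, background, targets) {
  background <- as.matrix(background)
  targets <- as.matrix(targets)
  predictFun <- if (is.function(model)) model
                else function(Z) predictModel(model, Z, "decision")
  d <- ncol(targets)
  stopIfNot(d <= 15, "exact enumeration is limited to d <= 15")
  nT <- nrow(targets)
  nB <- nrow(background)
  # value of coalition S for each target: mean over background rows of
  # f(x with S from target, rest from background)
  vals <- matrix(0, 2^d, nT)
  for (s in 0:(2^d - 1)) {
    inS <- as.logical(bitwAnd(s, 2^(0:(d - 1))))
    tot <- numeric(nT)
    for (bIdx in seq_len(nB)) {
      Z <- matrix(background[bIdx, ], nT, d, byrow = TRUE)
      Z[, inS] <- targets[, inS, drop = FALSE]
      tot <- tot + as.numeric(predictFun(Z))
    }
    vals[s + 1L, ] <- tot / nB
  }
  fact <- factorial(0:d)
  phi <- matrix(0, nT, d)
  for (j in seq_len(d)) {
    bitJ <- 2^(j - 1L)
    for (s in 0:(2^d - 1)) {
      if (bitwAnd(s, bitJ) > 0) next
      k <- sum(as.logical(bitwAnd(s, 2^(0:(d - 1)))))
      w <- fact[k + 1L] * fact[d - k] / fact[d + 1L]
      phi[, j] <- phi[, j] + w * (vals[s + bitJ + 1L, ] - vals[s + 1L, ])
    }
  }
  colnames(phi) <- colnames(targets)
  phi
}

#' Cross-run feature-importance summary with stability rule
#'
#' Per run, computes each feature's mean absolute attribution
#' \eqn{\bar S_f = \frac{1}{N}\sum_s |S_{s,f}|} and the grand mean
#' \eqn{\bar S} over features. A feature enters the stable set iff
#' \eqn{\bar S_f \ge 2 \bar S} (inclusive) in at least 6 of 7 runs; for k
#' runs the threshold scales as \eqn{\lceil 6k/7 \rceil}.
#'
#' @param runs list of \code{\linkS4class{AttributionMatrix}} objects with
#'   identical feature spaces.
#' @return an \code{\linkS4class{ImportanceSummary}}.
#' @export
summarizeImportance <- function(runs) {
  stopIfNot(length(runs) >= 1, "need at least one attribution run")
  d <- ncol(attributionValues(runs[[1]]))
  stopIfNot(all(vapply(runs, function(r) ncol(attributionValues(r)), 0L) == d),
            "runs must share the feature space")
  perFeature <- t(vapply(runs, function(r)
    colMeans(abs(attributionValues(r))), numeric(d)))
  grand <- rowMeans(perFeature)
  qualifies <- perFeature >= 2 * grand
  nQual <- colSums(qualifies)
  required <- as.integer(ceiling(6 * length(runs) / 7))
  stable <- which(nQual >= required)
  colnames(perFeature) <- colnames(attributionValues(runs[[1]]))
  new("ImportanceSummary", perFeatureMeanAbs = perFeature,
      grandMean = grand, qualifyingRuns = as.integer(nQual),
      stableSet = as.integer(stable), requiredRuns = required)
}

#' @describeIn summarizeImportance stable feature indices.
#' @param x an \code{\linkS4class{ImportanceSummary}}.
#' @export
stableFeatures <- function(x) x@stableSet

#' @describeIn summarizeImportance runs x features mean-|attribution|
#'   matrix.
#' @export
importanceMatrix <- function(x) x@perFeatureMeanAbs

setMethod("show", "ImportanceSummary", function(object) {
  cat(sprintf(
    "ImportanceSummary: %d run(s) x %d features; %d stable (>= 2x grand mean in >= %d runs)\n",
    nrow(object@perFeatureMeanAbs), ncol(object@perFeatureMeanAbs),
    length(object@stableSet), object@requiredRuns))
})

#' Direction of effect for stable features
#'
#' For each stable feature, "higher" if its mean among predicted-positive
#' subjects exceeds its overall holdout mean, else "lower" - i.e. whether
#' subjects the model flags carry higher- or lower-than-average feature
#' values. Degenerate when every subject is predicted positive, in which
#' case directions are "undefined" with a warning.
#'
#' @param xHoldout holdout subjects x features matrix.
#' @param predictions binary 0/1 predicted labels on the holdout.
#' @param stableSet feature indices to annotate.
#' @return character vector ("higher"/"lower"/"undefined") named by
#'   feature index.
#' @export
effectDirection <- function(xHoldout, predictions, stableSet) {
  stopIfNot(length(stableSet) >= 1, "stable set must be non-empty")
  xHoldout <- as.matrix(xHoldout)
  predictions <- as.integer(predictions)
  stopIfNot(sum(predictions == 1L) > 0, "no predicted-positive subjects")
  out <- setNames(character(length(stableSet)), stableSet)
  if (all(predictions == 1L)) {
    warning("all subjects predicted positive; direction undefined",
            call. = FALSE)
    out[] <- "undefined"
    return(out)
  }
  posMean <- colMeans(xHoldout[predictions == 1L, stableSet, drop = FALSE])
  allMean <- colMeans(xHoldout[, stableSet, drop = FALSE])
  out[] <- ifelse(posMean > allMean, "higher", "lower")
  out
}

#' Write an importance summary to TSV
#'
#' One row per feature: per-run mean |attribution|, qualifying-run count,
#' stability flag and (where annotated) effect direction.
#'
#' @param x an \code{\linkS4class{ImportanceSummary}}.
#' @param path output file.
#' @param direction optional named direction vector from
#'   \code{\link{effectDirection}}.
#' @return \code{path}, invisibly.
#' @export
writeImportance <- function(x, path, direction = NULL) {
  pf <- t(x@perFeatureMeanAbs)
  colnames(pf) <- paste0("run", seq_len(ncol(pf)))
  df <- data.frame(feature = if (is.null(rownames(pf)))
    seq_len(nrow(pf)) else rownames(pf), pf,
    qualifyingRuns = x@qualifyingRuns,
    stable = seq_len(nrow(pf)) %in% x@stableSet)
  df$direction <- NA_character_
  if (!is.null(direction))
    df$direction[as.integer(names(direction))] <- unname(direction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
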