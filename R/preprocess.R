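#' Fit a feature standardizer on training data
#'
#' Column means and population (divide-by-n) standard deviations are
#' estimated on the training rows only; zero-variance training columns are
#' dropped. The fitted transform is a pure function of the training rows,
#' so no information from test rows can leak in.
#'
#' @param xTrain numeric training matrix (rows = subjects).
#' @return a \code{\linkS4class{Standardizer}}.
#' @examples
#' s <- fitStandardizer(matrix(c(1, 3), 2, 1))
#' applyStandardizer(s, matrix(5, 1, 1))  # (5 - 2) / 1 = 3
#' @export
fitStandardizer <- function(xTrain) {
  xTrain <- as.matrix(xTrain)
  stopIfNot(nrow(xTrain) > 0 && ncol(xTrain) > 0, "training matrix is empty")
  stopIfNot(all(is.finite(xTrain)), "training matrix must be finite")
  mu <- colMeans(xTrain)
  sds <- sqrt(colMeans(xTrain^2) - mu^2)
  sds <- pmax(sds, 0)
  kept <- which(sds > 0)
  if (!length(kept)) stop("all columns have zero variance", call. = FALSE)
  new("Standardizer", keptColumns = as.integer(kept),
      means = mu[kept], sds = sds[kept], nColumns = ncol(xTrain))
}

#' Apply a fitted standardizer
#'
#' @param s a \code{\linkS4class{Standardizer}}.
#' @param x matrix with the original column count.
#' @return matrix restricted to the kept columns, centered and scaled with
#'   the training parameters.
#' @export
applyStandardizer <- function(s, x) {
  x <- as.matrix(x)
  stopIfNot(ncol(x) == s@nColumns,
            sprintf("expected %d columns, got %d", s@nColumns, ncol(x)))
  out <- x[, s@keptColumns, drop = FALSE]
  sweep(sweep(out, 2L, s@means, "-"), 2L, s@sds, "/")
}

#' Flag subjects whose block-mean intensity is an outlier
#'
#' A subject is flagged when the mean of its features in one block (e.g.
#' the DTI-FA columns) deviates from the cohort mean of those block means
#' by more than \code{kSd} cohort standard deviations. Applied per block at
#' data preparation, before any train/test split.
#'
#' @param xBlock subjects x features matrix of one feature block.
#' @param kSd deviation threshold in standard deviations (default 3).
#' @return logical vector, \code{TRUE} for subjects to exclude.
#' @export
excludeOutlierSubjects <- function(xBlock, kSd = 3) {
  xBlock <- as.matrix(xBlock)
  stopIfNot(nrow(xBlock) >= 3, "need at least 3 subjects to define outliers")
  m <- rowMeans(xBlock)
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(m)))
  abs(m - mean(m)) > kSd * s
}
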