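#' Bin misuse scores into three severity stages
#'
#' Half-open bins: \code{score < tLow} is safe, \code{tLow <= score < tHigh}
#' is moderate, and \code{score >= tHigh} is heavy (the upper boundary is
#' inclusive for heavy). Thresholds are study choices; see
#' \code{\link{matchedThresholds}} for simulator-matched defaults.
#'
#' @param scores numeric vector of finite misuse scores.
#' @param tLow,tHigh thresholds with \code{tLow < tHigh}.
#' @return factor with levels safe, moderate, heavy.
#' @examples
#' binSeverity(c(0, 2, 5), tLow = 1, tHigh = 4)
#' @export
binSeverity <- function(scores, tLow, tHigh) {
  stopIfNot(tLow < tHigh, "tLow must be strictly below tHigh")
  stopIfNot(all(is.finite(scores)), "scores must be finite")
  out <- ifelse(scores >= tHigh, "heavy",
                ifelse(scores >= tLow, "moderate", "safe"))
  factor(out, levels = c("safe", "moderate", "heavy"))
}

#' Binary labels with moderate-user exclusion
#'
#' Moderate misusers are excluded from the analysis; heavy subjects become
#' the positive class (1) and safe subjects the controls (0).
#'
#' @param severity factor/character vector over safe, moderate, heavy.
#' @return a \code{\linkS4class{PhenotypeLabels}}.
#' @examples
#' lab <- makeBinaryLabels(c("safe", "moderate", "heavy"))
#' phenotypeLabel(lab); includedSubjects(lab)
#' @export
makeBinaryLabels <- function(severity) {
  stopIfNot(length(severity) > 0, "severity must be non-empty")
  severity <- factor(as.character(severity),
                     levels = c("safe", "moderate", "heavy"))
  stopIfNot(!anyNA(severity), "severity contains values outside safe/moderate/heavy")
  included <- severity != "moderate"
  label <- ifelse(severity == "heavy", 1L,
                  ifelse(severity == "safe", 0L, NA_integer_))
  if (sum(label == 1L, na.rm = TRUE) == 0 || sum(label == 0L, na.rm = TRUE) == 0)
    stop("degenerate labels: need both heavy and safe subjects after exclusion",
         call. = FALSE)
  new("PhenotypeLabels", severity = severity, label = as.integer(label),
      included = included, excluded = sum(!included))
}

#' @describeIn PhenotypeLabels-accessors binary label vector (NA = excluded).
#' @export
phenotypeLabel <- function(x) x@label

#' Accessors for PhenotypeLabels
#' @param x a \code{\linkS4class{PhenotypeLabels}}.
#' @name PhenotypeLabels-accessors
NULL

#' @describeIn PhenotypeLabels-accessors logical inclusion mask.
#' @export
includedSubjects <- function(x) x@included

#' @describeIn PhenotypeLabels-accessors number of excluded (moderate)
#'   subjects.
#' @export
excludedCount <- function(x) x@excluded

#' @describeIn PhenotypeLabels-accessors severity factor.
#' @export
severityOf <- function(x) x@severity

setMethod("show", "PhenotypeLabels", function(object) {
  tb <- table(object@severity)
  cat(sprintf("PhenotypeLabels: %d subjects (%s); %d excluded as moderate\n",
              length(object@severity),
              paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = " "),
              object@excluded))
})

#' Per-subject linear misuse trajectories
#'
#' Ordinary-least-squares line of score on centered age for every subject,
#' a light-weight per-subject summary of the longitudinal trajectory
#' (intercept at the mean age, slope in score units per year). Subjects
#' with fewer than two non-missing observations are flagged with NA rather
#' than raising an error.
#'
#' @param scores subjects x timepoints matrix.
#' @param ages strictly increasing acquisition ages, one per column.
#' @return data.frame with columns intercept and slope.
#' @examples
#' fitTrajectory(rbind(c(0, 1, 2, 3)), ages = c(0, 1, 2, 3))
#' @export
fitTrajectory <- function(scores, ages) {
  scores <- as.matrix(scores)
  stopIfNot(length(ages) == ncol(scores), "one age per score column required")
  stopIfNot(length(ages) >= 2 && !is.unsorted(ages, strictly = TRUE),
            "ages must be >= 2 strictly increasing values")
  tc <- ages - mean(ages)
  n <- nrow(scores)
  intercept <- slope <- rep(NA_real_, n)
  complete <- rowSums(!is.na(scores))
  for (i in seq_len(n)) {
    ok <- !is.na(scores[i, ])
    if (sum(ok) < 2L) next
    x <- tc[ok]; y <- scores[i, ok]
    xc <- x - mean(x)
    slope[i] <- sum(xc * y) / sum(xc^2)
    intercept[i] <- mean(y) - slope[i] * mean(x)
  }
  data.frame(intercept = intercept, slope = slope,
             nObs = as.integer(complete))
}

#' Combined phenotype by clustering misuse measures
#'
#' Standardizes the given misuse measures and partitions subjects with
#' k-means under a fixed seed; the cluster with the highest mean of
#' \code{heavyMeasure} (default: last column) is designated "heavy".
#'
#' @param misuse subjects x measures numeric matrix.
#' @param k number of clusters (>= 2).
#' @param seed integer seed; the partition is deterministic given it.
#' @param heavyMeasure column index used to designate the heavy cluster.
#' @return list with \code{cluster} (integer vector), \code{heavyCluster}
#'   (id), and \code{label} (1 = member of the heavy cluster).
#' @export
combinedPhenotype <- function(misuse, k = 2L, seed = 1L,
                              heavyMeasure = ncol(misuse)) {
  misuse <- as.matrix(misuse)
  stopIfNot(k >= 2, "k must be at least 2")
  stopIfNot(k <= nrow(misuse), "k must not exceed the number of subjects")
  Z <- scale(misuse)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  nDistinct <- nrow(unique(Z))
  degenerate <- nDistinct < k
  if (degenerate) {
    km <- list(cluster = rep(1L, nrow(Z)),
               centers = matrix(colMeans(Z), 1L))
  } else {
    km <- withSeed(seed, stats::kmeans(Z, centers = k, nstart = 10L))
  }
  sizes <- tabulate(km$cluster, nbins = k)
  if (degenerate || any(sizes == 0L))
    warning("degenerate clustering: at least one cluster is empty", call. = FALSE)
  means <- vapply(seq_len(max(km$cluster)), function(cl) {
    m <- misuse[km$cluster == cl, heavyMeasure]
    if (length(m)) mean(m) else -Inf
  }, numeric(1))
  heavyCluster <- which.max(means)
  list(cluster = as.integer(km$cluster), heavyCluster = heavyCluster,
       label = as.integer(km$cluster == heavyCluster))
}
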