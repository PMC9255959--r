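#' Write a cohort to plain-text files
#'
#' Writes \code{features.csv} (subject_id + one column per feature),
#' \code{confounds.csv} (subject_id, sex, site), \code{phenotype.csv}
#' (subject_id + one score column per timepoint) and a \code{truth.json}
#' sidecar with the generative ground truth.
#'
#' @param cohort a \code{\linkS4class{SimCohort}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- featureMatrix(cohort)
  cd <- SummarizedExperiment::colData(cohort)
  subj <- colnames(cohort)
  utils::write.csv(data.frame(subject_id = subj, X, check.names = FALSE),
                   file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = subj,
                              sex = as.character(cd$sex),
                              site = as.character(cd$site)),
                   file.path(dir, "confounds.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subject_id = subj, misuseScores(cohort),
                              check.names = FALSE),
                   file.path(dir, "phenotype.csv"), row.names = FALSE)
  tr <- cohortTruth(cohort)
  truth <- list(informative = tr$informative, effect = tr$effect,
                severity = as.character(cd$severity),
                siteSd = tr$siteSd, siteScore = tr$siteScore)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' Also accepts externally prepared directories holding the same three
#' CSV files; \code{truth.json} (and with it the severity column) is
#' optional for real data.
#'
#' @param dir directory with features.csv, confounds.csv, phenotype.csv.
#' @return list with \code{features} (matrix), \code{cf}
#'   (\code{\linkS4class{ConfoundFrame}}), \code{scores} (matrix),
#'   \code{severity} (factor or NULL), \code{truth} (list or NULL).
#' @export
readCohort <- function(dir) {
  feat <- utils::read.csv(file.path(dir, "features.csv"), check.names = FALSE)
  conf <- utils::read.csv(file.path(dir, "confounds.csv"))
  phen <- utils::read.csv(file.path(dir, "phenotype.csv"), check.names = FALSE)
  stopIfNot(identical(feat$subject_id, conf$subject_id) &&
              identical(feat$subject_id, phen$subject_id),
            "subject_id columns disagree across files")
  X <- as.matrix(feat[, -1, drop = FALSE])
  rownames(X) <- feat$subject_id
  truth <- NULL
  severity <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    if (!is.null(truth$severity))
      severity <- factor(truth$severity,
                         levels = c("safe", "moderate", "heavy"))
  }
  list(features = X, cf = confoundFrame(conf$sex, conf$site),
       scores = as.matrix(phen[, -1, drop = FALSE]),
       severity = severity, truth = truth)
}

#' Write phenotype labels to CSV
#'
#' @param labels a \code{\linkS4class{PhenotypeLabels}}.
#' @param path output file.
#' @param subjectIds optional subject identifiers.
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(labels, path, subjectIds = NULL) {
  n <- length(severityOf(labels))
  if (is.null(subjectIds)) subjectIds <- sprintf("sub_%04d", seq_len(n))
  utils::write.csv(data.frame(
    subject_id = subjectIds,
    severity = as.character(severityOf(labels)),
    label = phenotypeLabel(labels),
    included = includedSubjects(labels)
  ), path, row.names = FALSE)
  invisible(path)
}
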