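test_that("identical config and seed give a bit-identical cohort", {
  cfg <- cohortConfig(nSubjects = 120, nFeatures = 15, seed = 7)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(featureMatrix(a), featureMatrix(b))
  expect_identical(misuseScores(a), misuseScores(b))
  expect_identical(as.character(cohortSeverity(a)),
                   as.character(cohortSeverity(b)))
  d <- generateCohort(cohortConfig(nSubjects = 120, nFeatures = 15, seed = 8))
  expect_false(identical(featureMatrix(a), featureMatrix(d)))
})

test_that("the full-size cohort has the documented shape", {
  co <- fixture("fullCohort", generateCohort(cohortConfig(seed = 11)))
  expect_equal(dim(featureMatrix(co)), c(1400L, 719L))
  expect_equal(dim(misuseScores(co)), c(1400L, 4L))
  expect_equal(nlevels(confoundSite(cohortConfounds(co))), 8L)
  expect_equal(sum(table(SummarizedExperiment::rowData(co)$block)), 719L)
  expect_equal(as.vector(table(SummarizedExperiment::rowData(co)$block)[c("t1w", "dti")]),
               c(656L, 63L))
  tr <- cohortTruth(co)
  expect_length(tr$informative, 20L)
  expect_false(anyDuplicated(tr$informative) > 0)
})

test_that("a null configuration carries no site-prevalence structure", {
  co <- generateCohort(cohortPreset("null", seed = 21, nSubjects = 1400,
                                    nFeatures = 5))
  sm <- cohortSummary(co)
  bySite <- tapply(sm$nHeavy, sm$site, sum) / tapply(sm$n, sm$site, sum)
  n <- tapply(sm$n, sm$site, sum)
  p <- sum(sm$nHeavy) / sum(sm$n)
  # any two sites within 3 binomial SEs of no difference
  for (i in seq_along(bySite)) for (j in seq_len(i - 1)) {
    se <- sqrt(p * (1 - p) * (1 / n[i] + 1 / n[j]))
    expect_lt(abs(bySite[i] - bySite[j]), 3 * se)
  }
})

test_that("cohort summary cells cover the cohort and bound proportions", {
  co <- smallCohort()
  sm <- cohortSummary(co)
  expect_equal(sum(sm$n), 300L)
  ok <- !is.na(sm$propHeavy)
  expect_true(all(sm$propHeavy[ok] >= 0 & sm$propHeavy[ok] <= 1))

  probs <- defaultSeverityProbs(heavyFemale = 0.5, heavyMale = 0.5,
                                highBonus = 0, pModerate = 0.25)
  co2 <- generateCohort(cohortConfig(nSubjects = 2000, nFeatures = 3,
                                     severityProbs = probs, seed = 4))
  sm2 <- cohortSummary(co2)
  for (i in which(sm2$n >= 20)) {
    se <- sqrt(0.5 * 0.5 / sm2$n[i])
    expect_lt(abs(sm2$propHeavy[i] - 0.5), 3 * se)
  }
})

test_that("cohorts round-trip through the CSV/JSON writer", {
  dir <- withr::local_tempdir()
  co <- generateCohort(cohortConfig(nSubjects = 40, nFeatures = 8, seed = 2))
  writeCohort(co, dir)
  expect_setequal(list.files(dir),
                  c("features.csv", "confounds.csv", "phenotype.csv",
                    "truth.json"))
  back <- readCohort(dir)
  expect_equal(unname(back$features), unname(featureMatrix(co)),
               tolerance = 1e-12)
  expect_equal(as.character(confoundSite(back$cf)),
               as.character(confoundSite(cohortConfounds(co))))
  expect_equal(back$truth$informative, cohortTruth(co)$informative)
  expect_equal(as.character(back$severity), as.character(cohortSeverity(co)))
})

test_that("configured confound pathways are actually detectable", {
  co <- fixture("pathwayCohort", generateCohort(
    cohortConfig(nSubjects = 1000, nFeatures = 30, seed = 31,
                 severityProbs = defaultSeverityProbs(heavyFemale = 0.28,
                                                      heavyMale = 0.52,
                                                      highBonus = 0))))
  X <- featureMatrix(co)
  cf <- cohortConfounds(co)
  sex <- as.integer(confoundSex(cf) == "male")
  spec <- modelSpec("logistic", grid = list(list(C = 1)), seed = 1)
  half <- 1:500
  # sex is decodable from the features (X -> c pathway)
  r <- ConfoundCV:::pipelineScore(X, sex, cf, half, 501:1000, spec,
                                  list(C = 1), "none", seed = 1)
  expect_gt(r$ba, 0.6)
  # and sex predicts the label (c -> y pathway) via unequal prevalence
  lb <- labelCohort(co)
  sexInc <- as.integer(confoundSex(lb$cf) == "male")
  D <- matrix(sexInc, ncol = 1)
  half2 <- seq_len(floor(length(lb$y) / 2))
  r2 <- ConfoundCV:::pipelineScore(D, lb$y, lb$cf, half2,
                                   setdiff(seq_along(lb$y), half2), spec,
                                   list(C = 1), "none", seed = 1,
                                   standardize = FALSE)
  expect_gt(r2$ba, 0.55)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(siteProbs = rep(0.2, 8)), "sum to 1")
  expect_error(cohortConfig(nInformative = 1000, nFeatures = 10), "exceed")
  expect_error(cohortConfig(siteVarRange = c(-1, 1)), "positive")
})

test_that("null cohorts show no association on any pathway", {
  spec <- modelSpec("logistic", grid = list(list(C = 1)), seed = 5)
  baSex <- baSexY <- numeric(20)
  for (r in 1:20) {
    co <- generateCohort(cohortPreset("null", seed = 40 + r,
                                      nSubjects = 250, nFeatures = 12))
    X <- featureMatrix(co)
    cf <- cohortConfounds(co)
    sex <- as.integer(confoundSex(cf) == "male")
    half <- 1:125
    baSex[r] <- ConfoundCV:::pipelineScore(X, sex, cf, half, 126:250, spec,
                                           list(C = 1), "none", seed = r)$ba
    lb <- suppressWarnings(labelCohort(co))
    D <- matrix(as.integer(confoundSex(lb$cf) == "male"), ncol = 1)
    h2 <- seq_len(floor(length(lb$y) / 2))
    baSexY[r] <- ConfoundCV:::pipelineScore(D, lb$y, lb$cf, h2,
                                            setdiff(seq_along(lb$y), h2),
                                            spec, list(C = 1), "none",
                                            seed = r, standardize = FALSE)$ba
  }
  # mean over 20 replicates within 2 SEs of chance
  expect_lt(abs(mean(baSex) - 0.5), 2 * sd(baSex) / sqrt(20))
  expect_lt(abs(mean(baSexY) - 0.5), 2 * sd(baSexY) / sqrt(20))
})
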