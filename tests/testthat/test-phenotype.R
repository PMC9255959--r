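test_that("severity bins are half-open with heavy inclusive at the top", {
  expect_equal(as.character(binSeverity(c(0, 2, 5), 1, 4)),
               c("safe", "moderate", "heavy"))
  expect_equal(as.character(binSeverity(4, 1, 4)), "heavy")
  expect_equal(as.character(binSeverity(1, 1, 4)), "moderate")
  expect_equal(as.character(binSeverity(c(-3, 0, 0.9), 1, 4)),
               rep("safe", 3))
  expect_error(binSeverity(1, 2, 2), "strictly below")
  expect_error(binSeverity(c(1, NA), 0, 1), "finite")
})

test_that("binary labels exclude moderates and keep the bookkeeping", {
  lab <- makeBinaryLabels(c("safe", "moderate", "heavy"))
  expect_equal(includedSubjects(lab), c(TRUE, FALSE, TRUE))
  expect_equal(phenotypeLabel(lab), c(0L, NA, 1L))
  expect_equal(excludedCount(lab), 1L)
  expect_error(makeBinaryLabels(rep("moderate", 5)), "degenerate")
  expect_error(makeBinaryLabels(c("safe", "safe")), "degenerate")
  # exclusion bookkeeping holds for arbitrary severity draws
  set.seed(1)
  for (r in 1:10) {
    sev <- sample(c("safe", "moderate", "heavy"), 60, TRUE)
    if (!any(sev == "safe") || !any(sev == "heavy")) next
    lab <- makeBinaryLabels(sev)
    expect_equal(sum(includedSubjects(lab)) + excludedCount(lab), 60L)
  }
})

test_that("the default cohort excludes a plausible number of moderates", {
  # moderate share 0.25 at n = 1400: expect roughly 350 excluded; the
  # binSeverity thresholds add only threshold-leakage noise
  for (s in c(101, 202, 303)) {
    co <- generateCohort(cohortConfig(nSubjects = 1400, nFeatures = 4,
                                      nInformative = 2, seed = s))
    lb <- labelCohort(co)
    expect_gte(excludedCount(lb$labels), 250)
    expect_lte(excludedCount(lb$labels), 400)
  }
})

test_that("per-subject trajectories are exact least-squares lines", {
  tr <- fitTrajectory(rbind(c(0, 1, 2, 3)), ages = c(0, 1, 2, 3))
  expect_equal(tr$slope, 1)
  expect_equal(tr$intercept, 1.5)  # value at the centered age
  expect_equal(fitTrajectory(rbind(c(2, 2, 2, 2)), c(14, 16, 19, 22))$slope, 0)
  # unequally spaced ages against lm()
  ages <- c(14, 16, 19, 22)
  set.seed(9)
  sc <- matrix(rnorm(20), 5, 4)
  tr2 <- fitTrajectory(sc, ages)
  for (i in 1:5) {
    ref <- lm(sc[i, ] ~ I(ages - mean(ages)))
    expect_equal(tr2$slope[i], unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(tr2$intercept[i], unname(coef(ref)[1]), tolerance = 1e-10)
  }
  # pure-noise slopes center on zero
  set.seed(10)
  sc3 <- matrix(rnorm(500 * 4), 500, 4)
  tr3 <- fitTrajectory(sc3, ages)
  expect_lt(abs(mean(tr3$slope)), 3 * sd(tr3$slope) / sqrt(500))
  # too few observations flagged, not fatal
  sc4 <- rbind(c(1, NA, NA, NA), c(1, 2, NA, NA))
  tr4 <- fitTrajectory(sc4, ages)
  expect_true(is.na(tr4$slope[1]))
  expect_false(is.na(tr4$slope[2]))
})

test_that("combined phenotype clustering recovers separated groups", {
  set.seed(5)
  blob <- rbind(matrix(rnorm(150 * 2), 150, 2),
                matrix(rnorm(150 * 2, mean = 10), 150, 2))
  cp <- combinedPhenotype(blob, k = 2, seed = 3)
  truth <- rep(c(0L, 1L), each = 150)
  expect_gte(mean(cp$label == truth), 0.95)
  # heavy cluster is the one with the larger mean of the last measure
  expect_equal(cp$heavyCluster,
               unname(which.max(tapply(blob[, 2], cp$cluster, mean))))
  # determinism
  cp2 <- combinedPhenotype(blob, k = 2, seed = 3)
  expect_identical(cp$cluster, cp2$cluster)
  expect_error(combinedPhenotype(blob, k = 1), "at least 2")
  expect_error(combinedPhenotype(blob[1:3, ], k = 5), "exceed")
  expect_warning(combinedPhenotype(matrix(1, 10, 2), k = 2, seed = 1),
                 "degenerate")
})

test_that("generator severity is recovered from final scores", {
  co <- smallCohort()
  lb <- labelCohort(co)
  agree <- mean(as.character(severityOf(lb$labels)) ==
                  as.character(cohortSeverity(co)))
  expect_gte(agree, 0.9)
})
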