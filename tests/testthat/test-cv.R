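test_that("balanced accuracy follows the per-class recall definition", {
  expect_equal(balancedAccuracy(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.75)
  expect_equal(balancedAccuracy(c("a", "a", "a", "b"), c("a", "a", "a", "b")), 1)
  # constant prediction on binary input is chance
  expect_equal(balancedAccuracy(c(1, 1, 1, 0), c(1, 1, 1, 1)), 0.5)
  expect_error(balancedAccuracy(1:3, 1:2), "equal length")
})

test_that("stratified folds have near-equal class composition", {
  y <- rep(0:1, each = 35)
  fold <- ConfoundCV:::makeFolds(y, 7, seed = 3)
  expect_equal(as.vector(table(fold)), rep(10L, 7))
  expect_true(all(table(fold, y) == 5L))
})

test_that("explore/holdout split is a stratified partition", {
  co <- fixture("pathwayCohort", generateCohort(
    cohortConfig(nSubjects = 1000, nFeatures = 30, seed = 31,
                 severityProbs = defaultSeverityProbs(heavyFemale = 0.28,
                                                      heavyMale = 0.52,
                                                      highBonus = 0))))
  lb <- labelCohort(co)
  plan <- cvPlan(holdoutFraction = 0.2, seed = 5)
  sp <- splitExploreHoldout(lb$y, lb$cf, plan)
  n <- length(lb$y)
  expect_length(intersect(sp$explore, sp$holdout), 0)
  expect_setequal(c(sp$explore, sp$holdout), seq_len(n))
  expect_lt(abs(length(sp$holdout) / n - 0.2), 0.03)
  expect_lt(abs(mean(lb$y[sp$holdout]) - mean(lb$y[sp$explore])), 0.02)
  expect_error(splitExploreHoldout(rep(1, 10),
                                   confoundFrame(rep("f", 10), rep("A", 10)),
                                   plan), "both label classes")
})

test_that("nested CV respects fold geometry, grid order and sanity ceiling", {
  pr <- separableProblem(n = 70, gap = 6, seed = 12)
  spec <- modelSpec("logistic", grid = list(list(C = 1)), seed = 2)
  plan <- cvPlan(outerFolds = 7, innerFolds = 2, seed = 3)
  ev <- nestedCV(spec, pr$X, pr$y, pr$cf, plan, "none")
  expect_length(evalScores(ev), 7)
  # grid of size one: that combination is chosen in every fold
  expect_true(all(vapply(evalChosen(ev), function(p) p$C == 1, logical(1))))
  # a separable feature gives a near-perfect outer score
  expect_gte(mean(evalScores(ev)), 0.95)
  expect_true(all(evalAUC(ev) > 0.95))
})

test_that("tie-breaks select the earliest best grid entry", {
  pr <- separableProblem(n = 60, gap = 8, seed = 13)
  # two identical combinations: the first must win everywhere
  spec <- modelSpec("logistic", grid = list(list(C = 1), list(C = 1)),
                    seed = 2)
  ev <- nestedCV(spec, pr$X, pr$y, pr$cf, cvPlan(3, 2, seed = 4), "none")
  expect_true(all(vapply(evalChosen(ev), identical, logical(1),
                         y = list(C = 1))))
})

test_that("holdout retraining is deterministic for deterministic pipelines", {
  pr <- separableProblem(n = 100, seed = 14)
  spec <- modelSpec("logistic", grid = list(list(C = 1)), seed = 2)
  hv <- holdoutEvaluate(spec, list(C = 1), pr$X, pr$y, pr$cf, 1:80, 81:100,
                        nSeeds = 5, correction = "none")
  expect_equal(sd(evalScores(hv)), 0)   # no seed sensitivity, no resampling
  expect_error(holdoutEvaluate(spec, list(C = 1), pr$X, pr$y, pr$cf,
                               1:80, 80:100, correction = "none"),
               "overlap")
})

test_that("pure-noise cohorts stay at chance on the holdout", {
  spec <- modelSpec("logistic", grid = list(list(C = 1)), seed = 2)
  bas <- vapply(1:20, function(r) {
    set.seed(300 + r)
    X <- matrix(rnorm(120 * 10), 120, 10)
    y <- rep(0:1, 60)
    cf <- confoundFrame(sample(c("f", "m"), 120, TRUE),
                        sample(c("A", "B"), 120, TRUE))
    mean(evalScores(holdoutEvaluate(spec, list(C = 1), X, y, cf, 1:90,
                                    91:120, nSeeds = 2,
                                    correction = "none")))
  }, numeric(1))
  expect_lt(abs(mean(bas) - 0.5), 2 * sd(bas))
})

test_that("the add-one permutation p-value is computed as documented", {
  y <- rep(0:1, 20)
  # a runner that scores 1 on the true labels and below on any shuffle
  runner <- function(lab) mean(lab == y)
  pt <- permutationTest(runner, y, nPerm = 99, seed = 5)
  expect_equal(pt$observed, 1)
  expect_true(all(pt$nullScores < 1))
  expect_equal(pt$p, 1 / 100)
  expect_length(pt$nullScores, 99)
  expect_error(permutationTest(runner, y, nPerm = 0), "at least 1")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(c(0.01, 0.04, 0.2)), c(0.03, 0.12, 0.6))
  expect_equal(bonferroniAdjust(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_equal(bonferroniAdjust(0.2, m = 1), 0.2)
  expect_equal(bonferroniAdjust(0.02, m = 3), 0.06)
  expect_error(bonferroniAdjust(c(0.1, 1.2)), "0, 1")
})

test_that("leave-one-site-out folds are sites and detect site heterogeneity", {
  cfg <- cohortConfig(nSubjects = 900, nFeatures = 30, nInformative = 10,
                      effectSizeD = 1.2, sexShift = 0.1, siteShift = 0.2,
                      interactionScale = 0, seed = 17)
  co <- generateCohort(cfg)
  lb <- labelCohort(co)
  spec <- modelSpec("logistic", grid = list(list(C = 1)), seed = 3)
  lo <- suppressWarnings(
    leaveOneSiteOut(spec, lb$X, lb$y, lb$cf, holdoutSite = "site8",
                    correction = "over"))
  info <- evalInfo(lo)
  expect_length(evalScores(lo), 7)
  expect_setequal(info$foldSites, paste0("site", 1:7))
  expect_match(info$counterbalanced, "sex only")
  # site-independent signal: every fold scores above chance
  expect_true(all(evalScores(lo) > 0.5))
  expect_gt(info$holdout$ba, 0.55)
  expect_error(leaveOneSiteOut(spec, lb$X, lb$y, lb$cf, "siteX"), "absent")

  # flip the signal direction at one site: that fold drops below the rest
  Xflip <- lb$X
  flipSite <- confoundSite(lb$cf) == "site1"
  inf <- cohortTruth(co)$informative
  mu <- colMeans(lb$X[, inf, drop = FALSE])
  Xflip[flipSite, inf] <- 2 * rep(mu, each = sum(flipSite)) -
    Xflip[flipSite, inf]
  lo2 <- suppressWarnings(
    leaveOneSiteOut(spec, Xflip, lb$y, lb$cf, holdoutSite = "site8",
                    correction = "over"))
  sc <- setNames(evalScores(lo2), evalInfo(lo2)$foldSites)
  expect_lt(sc["site1"], min(sc[names(sc) != "site1"]))
})
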