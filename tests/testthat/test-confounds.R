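test_that("one-hot designs use the documented encodings", {
  cf <- confoundFrame(c("f", "m", "m"), c("A", "A", "B"))
  Dreg <- designMatrix(cf, "regression")
  expect_equal(colnames(Dreg), c("(Intercept)", "sexm", "siteB"))
  Dfull <- designMatrix(cf, "full")
  expect_equal(colnames(Dfull), c("sexf", "sexm", "siteA", "siteB"))
  expect_equal(rowSums(Dfull), rep(2, 3))  # one sex + one site each
})

test_that("confound regression matches OLS and is train-pure", {
  set.seed(4)
  n <- 60
  cf <- confoundFrame(sample(c("f", "m"), n, TRUE),
                      sample(c("A", "B", "C"), n, TRUE))
  sexNum <- as.numeric(confoundSex(cf) == "m")
  X <- cbind(2 * sexNum, rnorm(n))
  reg <- fitConfoundRegressor(X, cf)
  res <- applyConfoundRegressor(reg, X, cf)
  expect_lt(max(abs(res[, 1])), 1e-10)    # perfectly explained feature
  # coefficients agree with lm()
  ref <- lm(X[, 2] ~ confoundSex(cf) + confoundSite(cf))
  expect_equal(unname(reg@coefficients[, 2]), unname(coef(ref)),
               tolerance = 1e-8)
  # pure-noise feature: every non-intercept coefficient within 3 SEs of 0
  se <- summary(ref)$coefficients[-1, "Std. Error"]
  expect_true(all(abs(reg@coefficients[-1, 2]) < 3 * se))
  # single confound cell is rejected
  cf1 <- confoundFrame(rep("f", 10), rep("A", 10))
  expect_error(fitConfoundRegressor(matrix(rnorm(10), 10, 1), cf1),
               "at least 2")
  # unseen categories are rejected at apply time
  cfNew <- confoundFrame(rep("f", 2), c("A", "D"))
  expect_error(applyConfoundRegressor(reg, matrix(0, 2, 2), cfNew), "unseen")
  # all-reference rows: only the intercept is subtracted
  cfRef <- confoundFrame(rep("f", 3), rep("A", 3))
  Z <- matrix(5, 3, 2)
  resRef <- applyConfoundRegressor(reg, Z, cfRef)
  expect_equal(unname(resRef),
               unname(Z - rep(1, 3) %o% reg@coefficients[1, ]))
})

test_that("regression removes cell means but not cell variances", {
  set.seed(6)
  n <- 400
  cf <- confoundFrame(sample(c("f", "m"), n, TRUE),
                      sample(paste0("s", 1:4), n, TRUE))
  sdBySite <- c(s1 = 0.5, s2 = 1, s3 = 1.5, s4 = 2)
  X <- matrix(rnorm(n * 6), n, 6) *
    sdBySite[as.character(confoundSite(cf))]
  # add genuine per-category mean shifts on top of the variance structure
  X <- X + 0.8 * as.numeric(confoundSex(cf) == "m") +
    0.5 * as.numeric(confoundSite(cf) == "s3")
  reg <- fitConfoundRegressor(X, cf)
  res <- applyConfoundRegressor(reg, X, cf)
  # training residuals are orthogonal to every design column: category
  # (margin) means vanish to numerical precision
  for (st in levels(confoundSite(cf)))
    expect_lt(max(abs(colMeans(res[confoundSite(cf) == st, , drop = FALSE]))),
              1e-8)
  for (sx in levels(confoundSex(cf)))
    expect_lt(max(abs(colMeans(res[confoundSex(cf) == sx, , drop = FALSE]))),
              1e-8)
  # within a joint cell the fit only subtracts a constant, so per-cell
  # variances are essentially untouched
  cell <- confoundStrata(cf)
  for (cl in unique(cell)) {
    i <- cell == cl
    ratio <- apply(res[i, , drop = FALSE], 2, sd) /
      apply(X[i, , drop = FALSE], 2, sd)
    expect_true(all(abs(ratio - 1) < 0.05))
  }
  # site is still decodable from the residuals by a kernel model
  spec <- modelSpec("rbf-svm", grid = list(list(C = 1, gammaScale = 1)),
                    seed = 2)
  half <- 1:200
  fit <- fitModel(spec, spec@grid[[1]], res[half, ],
                  confoundSite(cf)[half])
  ba <- balancedAccuracy(as.character(confoundSite(cf)[-half]),
                         as.character(predictModel(fit, res[-half, ])))
  expect_gt(ba, 0.25 + 0.1)  # chance for 4 sites is 0.25
})

test_that("counterbalancing equalizes classes within every stratum", {
  cf <- confoundFrame(rep("f", 8), rep(c("A", "B"), each = 4))
  y <- c(1, 1, 1, 0, 1, 0, 0, 0)
  over <- counterbalance(y, cf, "over", seed = 1)
  idx <- planIndices(over)
  expect_length(idx, 12)                       # 3/3 per stratum
  expect_equal(sum(y[idx] == 1), 6)
  expect_equal(sum(y[idx] == 0), 6)
  siteOfIdx <- as.character(confoundSite(cf))[idx]
  expect_equal(mean(siteOfIdx[y[idx] == 1] == "A"), 0.5)
  expect_equal(mean(siteOfIdx[y[idx] == 0] == "A"), 0.5)
  under <- counterbalance(y, cf, "under", seed = 1)
  expect_length(planIndices(under), 4)         # 1/1 per stratum
  expect_false(anyDuplicated(planIndices(under)) > 0)
  # already balanced input is a fixed point: each row exactly once
  yb <- rep(c(1, 0), 4)
  for (mode in c("under", "over"))
    expect_equal(planIndices(counterbalance(yb, cf, mode, seed = 2)), 1:8)
  # strata missing a class are dropped with a warning
  cf2 <- confoundFrame(rep("f", 6), rep(c("A", "B"), each = 3))
  y2 <- c(1, 1, 0, 1, 1, 1)
  expect_warning(p2 <- counterbalance(y2, cf2, "under", seed = 3), "dropped")
  expect_true(all(planIndices(p2) <= 3))
  expect_error(suppressWarnings(
    counterbalance(c(1, 1, 0, 0), confoundFrame(c("f", "f", "m", "m"),
                                                rep("A", 4)), "under")),
    "both label classes")
})

test_that("resampled multisets carry exactly zero confound-label association", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(40:120, 1)
    cf <- confoundFrame(sample(c("f", "m"), n, TRUE),
                        sample(paste0("s", 1:3), n, TRUE))
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    for (mode in c("under", "over")) {
      pl <- tryCatch(suppressWarnings(counterbalance(y, cf, mode, seed = r)),
                     error = function(e) NULL)
      if (is.null(pl)) next
      idx <- planIndices(pl)
      tab <- table(confoundStrata(cf)[idx], y[idx])
      exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      chisq <- sum((tab - exp_counts)^2 / exp_counts)
      expect_equal(chisq, 0)
      expect_true(all(idx >= 1 & idx <= n))    # test rows can never appear
    }
    over <- suppressWarnings(counterbalance(y, cf, "over", seed = r))
    under <- suppressWarnings(counterbalance(y, cf, "under", seed = r))
    kept <- n - over@droppedRows
    expect_gte(length(planIndices(over)), kept)
    expect_lte(length(planIndices(under)), kept)
  }
})
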