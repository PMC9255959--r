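test_that("attributions of a linear score are exact", {
  f <- function(Z) 2 * Z[, 1]
  set.seed(3)
  bg <- matrix(rnorm(60), 20, 3)
  tg <- matrix(c(1, 0.5, -1), 1, 3)
  shap <- permutationShap(f, bg, tg, nRepeats = 6, seed = 2)
  v <- attributionValues(shap)
  # for a linear model every pass is exact: 2 * (x1 - b1), 0, 0
  expect_equal(v[1, 2], 0)
  expect_equal(v[1, 3], 0)
  expect_equal(v[1, 1] + attributionBase(shap), 2 * tg[1, 1],
               tolerance = 1e-12)
})

test_that("constant models attribute nothing and additivity always holds", {
  f <- function(Z) rep(7, nrow(Z))
  bg <- matrix(rnorm(40), 10, 4)
  tg <- matrix(rnorm(20), 5, 4)
  shap <- permutationShap(f, bg, tg, nRepeats = 4, seed = 1)
  expect_equal(max(abs(attributionValues(shap))), 0)
  expect_equal(attributionBase(shap), 7)

  g <- function(Z) Z[, 1] * Z[, 2] + sin(Z[, 3])
  shap2 <- permutationShap(g, bg, tg, nRepeats = 5, seed = 4)
  expect_lt(max(abs(attributionBase(shap2) +
                      rowSums(attributionValues(shap2)) - g(tg))), 1e-10)
})

test_that("duplicated features used symmetrically share credit", {
  f <- function(Z) Z[, 1] + Z[, 2]
  bg <- matrix(0, 5, 3)
  tg <- matrix(c(2, 2, 9), 1, 3)       # features 1 and 2 identical in use
  shap <- permutationShap(f, bg, tg, nRepeats = 20, seed = 6)
  v <- attributionValues(shap)
  expect_equal(v[1, 1], v[1, 2], tolerance = 1e-10)
  expect_equal(v[1, 3], 0)
})

test_that("fast model chains reproduce the generic estimator exactly", {
  set.seed(7)
  n <- 60; p <- 7
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(rbinom(n, 1, plogis(X[, 1] * X[, 2] + X[, 3])))
  bg <- X[1:20, ]; tg <- X[21:30, ]
  grids <- list("logistic" = list(C = 1), "linear-svm" = list(C = 1),
                "rbf-svm" = list(C = 1, gammaScale = 1))
  for (fam in names(grids)) {
    spec <- modelSpec(fam, grid = list(grids[[fam]]), seed = 1)
    fit <- fitModel(spec, grids[[fam]], X, y, seed = 1)
    fast <- permutationShap(fit, bg, tg, nRepeats = 4, seed = 9)
    slow <- permutationShap(function(Z) predictModel(fit, Z, "decision"),
                            bg, tg, nRepeats = 4, seed = 9)
    expect_equal(attributionValues(fast), attributionValues(slow),
                 tolerance = 1e-10)
  }
})

test_that("exact enumeration matches the closed form for linear models", {
  w <- c(1.5, -2, 0.5)
  f <- function(Z) drop(Z %*% w)
  set.seed(8)
  bg <- matrix(rnorm(30), 10, 3)
  tg <- matrix(rnorm(6), 2, 3)
  phi <- exactShap(f, bg, tg)
  ref <- sweep(tg, 2, colMeans(bg)) * rep(w, each = 2)
  expect_equal(phi, ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a larger sampling budget never drops the top-ranked feature", {
  set.seed(11)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(rbinom(n, 1, plogis(2 * X[, 1])))
  spec <- modelSpec("rbf-svm", grid = list(list(C = 1, gammaScale = 1)),
                    seed = 1)
  fit <- fitModel(spec, spec@grid[[1]], X, y, seed = 1)
  bg <- X[1:30, ]; tg <- X[31:60, ]
  s1 <- permutationShap(fit, bg, tg, nRepeats = 4, seed = 3)
  s2 <- permutationShap(fit, bg, tg, nRepeats = 16, seed = 3)
  top <- which.max(colMeans(abs(attributionValues(s2))))
  imp1 <- summarizeImportance(list(s1))
  imp2 <- summarizeImportance(list(s2))
  expect_true(top %in% stableFeatures(imp1))
  expect_true(top %in% stableFeatures(imp2))
})

test_that("the stability rule applies the 2x grand-mean / 6-of-7 criterion", {
  mk <- function(v) new("AttributionMatrix", values = matrix(v, 1),
                        baseValue = 0, prediction = sum(v), seed = 1L)
  runs <- replicate(7, mk(c(0.6, 0.2, 0.1)), simplify = FALSE)
  imp <- summarizeImportance(runs)
  expect_equal(unname(imp@grandMean), rep(0.3, 7))
  expect_equal(stableFeatures(imp), 1L)     # 0.6 >= 2 * 0.3, inclusive
  # qualifying in only 5 of 7 runs is not enough
  runs2 <- c(replicate(5, mk(c(0.6, 0.2, 0.1)), simplify = FALSE),
             replicate(2, mk(c(0.2, 0.2, 0.2)), simplify = FALSE))
  expect_length(stableFeatures(summarizeImportance(runs2)), 0)
  # identical importances can never reach twice their own mean
  runs3 <- replicate(7, mk(c(0.3, 0.3, 0.3)), simplify = FALSE)
  expect_length(stableFeatures(summarizeImportance(runs3)), 0)
  # threshold scales as ceiling(6k/7)
  expect_equal(summarizeImportance(runs[1:3])@requiredRuns, 3L)
  expect_error(summarizeImportance(list(mk(1:2), mk(1:3))), "feature space")
})

test_that("effect directions compare predicted-positive and overall means", {
  X <- cbind(c(2, 2, 0, 0), c(1, 1, 1, 1))
  pred <- c(1L, 1L, 0L, 0L)
  dir <- effectDirection(X, pred, stableSet = 1L)
  expect_equal(unname(dir), "higher")
  dir2 <- effectDirection(-X, pred, stableSet = 1L)
  expect_equal(unname(dir2), "lower")
  expect_warning(d3 <- effectDirection(X, rep(1L, 4), 1L), "undefined")
  expect_equal(unname(d3), "undefined")
  expect_error(effectDirection(X, rep(0L, 4), 1L), "positive")
  expect_error(effectDirection(X, pred, integer(0)), "non-empty")
})
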