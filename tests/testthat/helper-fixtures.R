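# Shared, lazily built fixtures (memoized for the duration of the run).
.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureEnv, inherits = FALSE))
    assign(name, expr, envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

smallCohort <- function()
  fixture("smallCohort",
          generateCohort(cohortConfig(nSubjects = 300, nFeatures = 40,
                                      seed = 7)))

smallLabeled <- function() fixture("smallLabeled", labelCohort(smallCohort()))

# a tiny separable two-class problem with neutral confounds
separableProblem <- function(n = 120, p = 6, gap = 4, seed = 3) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + gap * y
  cf <- confoundFrame(sample(c("f", "m"), n, TRUE),
                      sample(c("A", "B"), n, TRUE))
  list(X = X, y = y, cf = cf)
}
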