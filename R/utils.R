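# Internal helpers shared across the package.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All user-facing randomness goes through this,
# which is what makes identical seeds give bit-identical results.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 7919L * as.numeric(k)) %% 2147483647)
}

# Stratified k-fold assignment: shuffle within each class, deal round-robin.
# Returns an integer fold id per element.
makeFolds <- function(y, k, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Rank-free AUC via pROC, oriented so that larger scores indicate the
# positive (second) level. Returns NA when a class is absent.
aucScore <- function(yTrue, scores) {
  yTrue <- as.factor(yTrue)
  if (nlevels(droplevels(yTrue)) != 2L) return(NA_real_)
  lv <- levels(droplevels(yTrue))
  as.numeric(pROC::auc(pROC::roc(
    response = factor(as.character(yTrue), levels = lv),
    predictor = as.numeric(scores),
    levels = lv, direction = "<", quiet = TRUE
  )))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
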