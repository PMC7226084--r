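#' Derive child seeds from a master seed
#'
#' Reproducibly expands one master seed into `n` independent seeds so that
#' every pipeline stage can be re-run in isolation. Does not disturb the
#' caller's RNG state.
#'
#' @param master integer master seed (non-negative, < 2^31)
#' @param n number of child seeds
#' @return integer vector of length `n`
#' @export
derive_seeds <- function(master, n) {
  stopifnot(length(master) == 1, is.finite(master), master >= 0)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Stratified fold assignment
#'
#' @param labels factor-like vector of class labels
#' @param k number of folds
#' @param seed integer seed
#' @return integer vector of fold ids in 1..k, one per observation
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  if (any(table(labels) < k))
    stop("stratification error: class with fewer than ", k, " members: ",
         paste(names(which(table(labels) < k)), collapse = ", "))
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# z-scoring helpers; zero-variance columns get scale 1 so they map to 0
fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, X) {
  scale(X, center = scaler$center, scale = scaler$scale)[, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
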