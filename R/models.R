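#' Algorithm specification with its hyperparameter grid
#'
#' The five classifier families compared by the pipeline, with the study's
#' hyperparameter grids: LDA has no grid; L2 logistic regression and linear
#' SVM search a 13-point log grid of exponents -3..3 in half-decade steps
#' (penalty strength lambda and cost C respectively); KNN searches
#' k in 1..20; random forest searches trees {100, 200} x max depth
#' {5, 10, 20} x min samples to split {2, 5, 10} x min samples per leaf
#' {1, 2, 4}. Grids are ordered simplest-first (heavier regularization,
#' larger k, smaller forests) so that score ties resolve to the simpler
#' model.
#'
#' @param family one of `"lda"`, `"lr"`, `"svm"`, `"knn"`, `"rf"`
#' @return an `algorithm_spec` list with `family` and `grid` (a data.frame,
#'   zero rows for LDA)
#' @export
algorithm_spec <- function(family = ALGORITHM_FAMILIES) {
  family <- match.arg(family)
  log_grid <- 10^seq(3, -3, by = -0.5)   # heavier regularization first
  grid <- switch(family,
    lda = data.frame(),
    lr = data.frame(lambda = log_grid),
    svm = data.frame(cost = rev(log_grid)),  # low cost = simpler, first
    knn = data.frame(k = 20:1),              # large k = smoother, first
    rf = expand.grid(min_leaf = c(4, 2, 1), min_split = c(10, 5, 2),
                     max_depth = c(5, 10, 20), num_trees = c(100, 200))[
                       , c("num_trees", "max_depth", "min_split", "min_leaf")])
  if (family == "rf") {
    # simplest-first: fewer trees, shallower, larger split/leaf minima
    grid <- grid[order(grid$num_trees, grid$max_depth, -grid$min_split,
                       -grid$min_leaf), , drop = FALSE]
    rownames(grid) <- NULL
  }
  structure(list(family = family, grid = grid), class = "algorithm_spec")
}

# Fit one classifier on standardized features. X: numeric matrix, y: factor.
fit_model <- function(family, params, X, y, seed = 1L) {
  y <- droplevels(as.factor(y))
  model <- switch(family,
    lda = MASS::lda(x = X, grouping = y),
    lr = {
      fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
      lam_path <- sort(unique(c(10^seq(-3, 3, by = 0.5), params$lambda)),
                       decreasing = TRUE)
      glmnet::glmnet(X, y, family = fam, alpha = 0, lambda = lam_path,
                     standardize = FALSE)
    },
    svm = with_seed(seed,
      e1071::svm(X, y, kernel = "linear", cost = params$cost,
                 probability = TRUE, scale = FALSE)),
    knn = list(X = X, y = y, k = params$k),
    rf = ranger::ranger(
      x = X, y = y, probability = TRUE, num.trees = params$num_trees,
      max.depth = params$max_depth, min.node.size = params$min_split,
      min.bucket = params$min_leaf, seed = seed, num.threads = 1),
    stop("unknown algorithm family: ", family))
  structure(list(family = family, params = params, fit = model,
                 levels = levels(y), seed = seed),
            class = "hfo_model")
}

# class-probability matrix (n x levels) on standardized features
predict_proba <- function(model, X) {
  lv <- model$levels
  P <- switch(model$family,
    lda = predict(model$fit, X)$posterior,
    lr = {
      pr <- predict(model$fit, X, s = model$params$lambda,
                    type = "response")
      if (length(lv) == 2) {
        p2 <- as.vector(pr)
        out <- cbind(1 - p2, p2)
        colnames(out) <- model$fit$classnames
        out
      } else pr[, , 1]
    },
    svm = attr(predict(model$fit, X, probability = TRUE), "probabilities"),
    knn = knn_vote_proba(model$fit$X, model$fit$y, X, model$fit$k),
    rf = predict(model$fit, data = X, num.threads = 1)$predictions)
  P <- P[, lv, drop = FALSE]
  rownames(P) <- NULL
  P
}

# Exact brute-force KNN vote fractions for all classes (Euclidean).
# class::knn reports only the winning class's vote share, which is not
# enough for one-vs-rest AUCs or a 0.5 posterior rule, hence this helper.
knn_vote_proba <- function(Xtr, ytr, Xte, k) {
  ytr <- as.factor(ytr)
  lv <- levels(ytr)
  ntr <- nrow(Xtr); nte <- nrow(Xte)
  k <- min(k, ntr)
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- matrix(rowSums(Xte^2), nte, ntr) +
    matrix(rowSums(Xtr^2), nte, ntr, byrow = TRUE) -
    2 * Xte %*% t(Xtr)
  P <- matrix(0, nte, length(lv), dimnames = list(NULL, lv))
  yi <- as.integer(ytr)
  for (i in seq_len(nte)) {
    nn <- yi[order(d2[i, ])[seq_len(k)]]
    tab <- tabulate(nn, nbins = length(lv))
    P[i, ] <- tab / k
  }
  P
}

#' Area under the ROC curve for a binary score
#'
#' @param y true labels (factor or vector)
#' @param score numeric score, higher = more likely positive
#' @param positive level treated as positive
#' @return AUC in `[0, 1]`; fixed score direction, so chance-level scores
#'   give ~0.5 rather than being flipped
#' @export
auc_binary <- function(y, score, positive) {
  y <- as.factor(y)
  neg <- setdiff(levels(y), positive)
  if (length(neg) != 1) {
    y <- factor(ifelse(y == positive, positive, "rest"),
                levels = c("rest", positive))
    neg <- "rest"
  }
  r <- pROC::roc(response = y, predictor = score,
                 levels = c(neg, positive), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# macro-averaged one-vs-rest AUC from a probability matrix; levels without
# both positives and negatives in `y` contribute no term (AUC undefined)
macro_ovr_auc <- function(y, P) {
  y <- as.factor(y)
  aucs <- vapply(levels(y), function(lv) {
    n_pos <- sum(y == lv)
    if (n_pos == 0 || n_pos == length(y)) return(NA_real_)
    auc_binary(y, P[, lv], lv)
  }, 0)
  mean(aucs, na.rm = TRUE)
}
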