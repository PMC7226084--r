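#' ADASYN configuration
#'
#' @param K neighbor count used both for the density ratio and for
#'   interpolation partners (default 5, the algorithm's canonical setting)
#' @param beta balance level in `[0, 1]`; 1 = generate enough synthetics to
#'   fully balance the minority class with the majority
#' @param seed integer seed
#' @return an `adasyn_config` list
#' @export
adasyn_config <- function(K = 5, beta = 1.0, seed = 1L) {
  stopifnot(K >= 1, beta >= 0, beta <= 1)
  structure(list(K = as.integer(K), beta = beta, seed = as.integer(seed)),
            class = "adasyn_config")
}

#' ADASYN adaptive synthetic oversampling of one minority class
#'
#' Generates `G = round((m_l - m_s) * beta)` synthetic minority points,
#' where `m_s`/`m_l` are the minority/majority counts. Each minority point
#' `x_i` receives `g_i = round(rhat_i * G)` synthetics, with
#' `rhat_i` proportional to `Delta_i / K`, the fraction of non-minority
#' points among `x_i`'s K nearest neighbors in the pooled set (Euclidean
#' distance; pass standardized features). Generation thus concentrates near
#' the class boundary. Each synthetic point is
#' `x_i + lambda * (x_z - x_i)` with `lambda ~ U(0, 1)` and `x_z` drawn
#' among `x_i`'s K nearest minority neighbors. If no minority point has
#' non-minority neighbors, the `G` synthetics are spread uniformly.
#'
#' @param X_min minority-class feature matrix (m_s x p, m_s >= 2)
#' @param X_other feature matrix of all other classes
#' @param config an `adasyn_config`; `K < m_s` required
#' @param m_l majority count used in the G formula (default `nrow(X_other)`;
#'   pass the single largest class count when `X_other` pools several
#'   classes)
#' @return matrix of synthetic minority points (possibly 0 rows)
#' @export
adasyn_oversample <- function(X_min, X_other, config = adasyn_config(),
                              m_l = nrow(X_other)) {
  X_min <- as.matrix(X_min); X_other <- as.matrix(X_other)
  m_s <- nrow(X_min); K <- config$K
  if (m_s < 2)
    stop("configuration error: minority class needs at least 2 points")
  if (K >= m_s)
    stop("configuration error: K (", K, ") must be < minority count (",
         m_s, ")")
  G <- round((m_l - m_s) * config$beta)
  if (G <= 0) return(X_min[0, , drop = FALSE])
  X_all <- rbind(X_min, X_other)
  is_other <- c(rep(FALSE, m_s), rep(TRUE, nrow(X_other)))
  # K nearest neighbors of each minority point in the pooled set / in the
  # minority set (self excluded)
  d2_all <- as.matrix(stats::dist(X_all))[seq_len(m_s), , drop = FALSE]
  d2_min <- d2_all[, seq_len(m_s), drop = FALSE]
  delta <- integer(m_s)
  nn_min <- matrix(0L, m_s, K)
  for (i in seq_len(m_s)) {
    ord <- order(d2_all[i, ])
    ord <- ord[ord != i][seq_len(K)]
    delta[i] <- sum(is_other[ord])
    ord_m <- order(d2_min[i, ])
    nn_min[i, ] <- ord_m[ord_m != i][seq_len(K)]
  }
  r <- delta / K
  g <- if (sum(r) == 0) {
    base <- rep(G %/% m_s, m_s)
    base[seq_len(G %% m_s)] <- base[seq_len(G %% m_s)] + 1L
    base
  } else round(r / sum(r) * G)
  g <- as.integer(g)
  synth <- matrix(NA_real_, sum(g), ncol(X_min),
                  dimnames = list(NULL, colnames(X_min)))
  if (sum(g) == 0) return(synth)
  with_seed(config$seed, {
    row <- 1L
    for (i in seq_len(m_s)) {
      if (g[i] == 0) next
      partners <- nn_min[i, sample.int(K, g[i], replace = TRUE)]
      lam <- runif(g[i])
      for (j in seq_len(g[i])) {
        synth[row, ] <- X_min[i, ] +
          lam[j] * (X_min[partners[j], ] - X_min[i, ])
        row <- row + 1L
      }
    }
  })
  attr(synth, "g") <- g
  attr(synth, "delta") <- delta
  synth
}

#' Balance a three-class HFO table with ADASYN
#'
#' Applies ADASYN to each non-majority class in turn (against all other
#' classes) until every class count matches the majority within rounding.
#' Distances are computed on z-scored features; synthetic rows are
#' back-transformed to the original scale and flagged `synthetic = TRUE` so
#' they can never leak into an evaluation fold.
#'
#' @param table feature table restricted to HFO rows (labels R/FR/FRonR,
#'   all three present)
#' @param config an `adasyn_config`
#' @return augmented table with the `synthetic` flag set on generated rows
#' @export
balance_multiclass <- function(table, config = adasyn_config()) {
  counts <- table(factor(table$label, levels = HFO_LABELS))
  if (any(counts == 0))
    stop("class-coverage error: missing class(es): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  fc <- feature_columns()
  X <- as.matrix(table[, fc, drop = FALSE])
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  majority <- names(which.max(counts))
  out <- table
  seeds <- derive_seeds(config$seed, length(HFO_LABELS))
  for (ci in seq_along(HFO_LABELS)) {
    cls <- HFO_LABELS[ci]
    if (cls == majority || counts[[cls]] == max(counts)) next
    cfg <- adasyn_config(config$K, config$beta, seeds[ci])
    synth <- adasyn_oversample(Xs[table$label == cls, , drop = FALSE],
                               Xs[table$label != cls, , drop = FALSE],
                               cfg, m_l = max(counts))
    if (nrow(synth) == 0) next
    orig <- sweep(sweep(synth, 2, scaler$scale, `*`), 2, scaler$center, `+`)
    new_rows <- table[rep(1L, nrow(synth)), , drop = FALSE]
    new_rows[, fc] <- orig
    new_rows$label <- cls
    new_rows$synthetic <- TRUE
    new_rows$channel_id <- "synthetic"
    new_rows$segment_start <- NA_real_
    out <- rbind(out, new_rows)
  }
  rownames(out) <- NULL
  out
}

confusion_multiclass <- function(truth, pred, levels) {
  table(factor(truth, levels = levels), factor(pred, levels = levels))
}

per_class_metrics <- function(cm) {
  lv <- rownames(cm)
  do.call(rbind, lapply(lv, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- sum(cm) - tp - fn - fp
    data.frame(class = cl, sensitivity = tp / (tp + fn),
               specificity = tn / (tn + fp), stringsAsFactors = FALSE)
  }))
}

#' Three-class cross-validated HFO classification (step 2)
#'
#' On HFO segments only: 30% stratified holdout for hyperparameter tuning
#' (macro one-vs-rest AUC), then stratified k-fold CV on the remaining 70%.
#' ADASYN is fitted and applied inside each training fold only — evaluation
#' folds contain no synthetic rows — unless `adasyn_before_split = TRUE`
#' deliberately reproduces the leaky ordering for comparison. Reports
#' one-vs-rest sensitivity and specificity per class and fold.
#'
#' @param table feature table restricted to HFO rows (10 ms window in the
#'   study design)
#' @param family algorithm family
#' @param folds CV folds (default 3)
#' @param seed integer seed
#' @param adasyn adasyn settings (an `adasyn_config`)
#' @param tuning_fraction holdout fraction (default 0.30)
#' @param adasyn_before_split if TRUE, oversample before splitting
#'   (leaky; off by default)
#' @return a `multiclass_metrics` list: `per_fold` (fold x class metrics),
#'   `mean` (per class), `confusion` (summed 3x3 matrix), chosen params
#' @export
crossval_classify <- function(table, family, folds = 3, seed = 1L,
                              adasyn = adasyn_config(),
                              tuning_fraction = 0.30,
                              adasyn_before_split = FALSE) {
  stopifnot(all(table$label %in% HFO_LABELS))
  counts <- table(factor(table$label, levels = HFO_LABELS))
  if (any(counts < max(10, 2 * folds)))
    stop("class-coverage error: need at least ", max(10, 2 * folds),
         " segments per class; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  spec <- algorithm_spec(family)
  seeds <- derive_seeds(seed, 5)
  if (adasyn_before_split)
    table <- balance_multiclass(table,
                                adasyn_config(adasyn$K, adasyn$beta,
                                              seeds[5]))
  sp <- split_tuning_holdout(table, tuning_fraction, seeds[1],
                             labels = table$label)
  fc <- feature_columns()
  Xt <- as.matrix(sp$tuning[, fc, drop = FALSE])
  yt <- factor(sp$tuning$label, levels = HFO_LABELS)
  tuned <- tune(spec, Xt, yt, seed = seeds[2])
  dev <- sp$development
  y <- factor(dev$label, levels = HFO_LABELS)
  fold_id <- stratified_folds(y, folds, seeds[3])
  fold_seeds <- derive_seeds(seeds[4], folds)
  # real (non-synthetic) rows only are ever evaluated
  per_fold <- list()
  cm_total <- matrix(0, 3, 3, dimnames = list(HFO_LABELS, HFO_LABELS))
  for (f in seq_len(folds)) {
    tr_tbl <- dev[fold_id != f, , drop = FALSE]
    te_tbl <- dev[fold_id == f & !dev$synthetic, , drop = FALSE]
    if (!adasyn_before_split)
      tr_tbl <- balance_multiclass(
        tr_tbl, adasyn_config(adasyn$K, adasyn$beta, fold_seeds[f]))
    Xtr <- as.matrix(tr_tbl[, fc, drop = FALSE])
    scaler <- fit_scaler(Xtr)
    m <- fit_model(family, tuned$params, apply_scaler(scaler, Xtr),
                   factor(tr_tbl$label, levels = HFO_LABELS),
                   seed = seeds[4])
    Xte <- apply_scaler(scaler, as.matrix(te_tbl[, fc, drop = FALSE]))
    P <- predict_proba(m, Xte)
    pred <- colnames(P)[max.col(P, ties.method = "first")]
    cm <- confusion_multiclass(te_tbl$label, pred, HFO_LABELS)
    cm_total <- cm_total + cm
    pf <- per_class_metrics(cm)
    pf$fold <- f
    per_fold[[f]] <- pf
  }
  per_fold <- do.call(rbind, per_fold)
  means <- do.call(rbind, lapply(HFO_LABELS, function(cl) {
    sub <- per_fold[per_fold$class == cl, ]
    data.frame(class = cl, sensitivity = mean(sub$sensitivity),
               specificity = mean(sub$specificity))
  }))
  structure(list(per_fold = per_fold, mean = means, confusion = cm_total,
                 params = tuned$params, family = family),
            class = "multiclass_metrics")
}

#' @export
print.multiclass_metrics <- function(x, ...) {
  cat(sprintf("three-class metrics (%s), mean over folds:\n", x$family))
  for (i in seq_len(nrow(x$mean)))
    cat(sprintf("  %-6s sensitivity %.3f  specificity %.3f\n",
                x$mean$class[i], x$mean$sensitivity[i],
                x$mean$specificity[i]))
  invisible(x)
}
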