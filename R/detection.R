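#' Balance a feature table for binary HFO detection
#'
#' Step 1 treats the union of R/FR/FRonR segments as the positive class.
#' Segments with HFOs are rare (< 10% of observations), so the negative
#' class is randomly undersampled to the positive count: all positives are
#' kept, exactly as many negatives are drawn uniformly without replacement,
#' and the result is shuffled.
#'
#' @param table a `segment_feature_table`
#' @param seed integer seed
#' @return balanced table with an added logical `positive` column
#' @export
balance_binary <- function(table, seed) {
  pos <- which(table$label %in% HFO_LABELS)
  neg <- which(table$label == "noHFO")
  if (length(pos) == 0)
    stop("imbalance error: no HFO-labeled rows (0 positives, ",
         length(neg), " negatives)")
  if (length(neg) < length(pos))
    stop("imbalance error: fewer noHFO rows (", length(neg),
         ") than HFO rows (", length(pos), ")")
  with_seed(seed, {
    keep_neg <- sample(neg, length(pos))
    idx <- sample(c(pos, keep_neg))
  })
  out <- table[idx, , drop = FALSE]
  out$positive <- out$label %in% HFO_LABELS
  rownames(out) <- NULL
  out
}

#' Stratified tuning/development split
#'
#' Puts `fraction` of the rows (stratified on `labels`, so class ratios are
#' preserved) into a tuning set for hyperparameter optimization and the
#' rest into a development set; the two are disjoint and exhaustive.
#'
#' @param table a feature table
#' @param fraction tuning fraction (default 0.30)
#' @param seed integer seed
#' @param labels stratification labels (default: binary HFO indicator)
#' @return list with elements `tuning` and `development`
#' @export
split_tuning_holdout <- function(table, fraction = 0.30, seed = 1L,
                                 labels = table$label %in% HFO_LABELS) {
  stopifnot(fraction >= 0, fraction < 1)
  labels <- as.factor(labels)
  if (fraction > 0 && any(table(labels) < 2))
    stop("stratification error: class with fewer than 2 rows")
  tune_idx <- integer()
  if (fraction > 0) with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      tune_idx <- c(tune_idx, sample(idx, round(fraction * length(idx))))
    }
  })
  list(tuning = table[sort(tune_idx), , drop = FALSE],
       development = table[setdiff(seq_len(nrow(table)), tune_idx), ,
                           drop = FALSE])
}

#' Hyperparameter tuning by internal cross-validated AUC
#'
#' Exhaustive grid search on the tuning set: features are standardized with
#' tuning-set statistics, each candidate is scored by mean AUC under an
#' internal stratified 3-fold CV (binary AUC, or macro one-vs-rest AUC for
#' multiclass labels), and the highest score wins. Grids are ordered
#' simplest-first, so exact ties resolve to the simpler model. LDA has no
#' hyperparameters and returns an empty set without searching.
#'
#' @param spec an `algorithm_spec`
#' @param X numeric feature matrix of the tuning set
#' @param y labels (factor)
#' @param seed integer seed
#' @param inner_folds internal CV folds (default 3)
#' @return list: `params` (one-row data.frame, empty for LDA), `score`
#'   (mean CV AUC, NA for LDA), `scores` (per-candidate)
#' @export
tune <- function(spec, X, y, seed = 1L, inner_folds = 3) {
  stopifnot(inherits(spec, "algorithm_spec"))
  if (spec$family == "lda")
    return(list(params = data.frame(), score = NA_real_,
                scores = numeric()))
  if (nrow(spec$grid) == 0)
    stop("configuration error: empty hyperparameter grid for family ",
         spec$family)
  if (nrow(X) == 0) stop("tuning set is empty")
  y <- droplevels(as.factor(y))
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  seeds <- derive_seeds(seed, 2)
  folds <- stratified_folds(y, inner_folds, seeds[1])
  binary <- nlevels(y) == 2
  pos <- if (binary) levels(y)[2] else NA
  scores <- vapply(seq_len(nrow(spec$grid)), function(g) {
    params <- spec$grid[g, , drop = FALSE]
    mean(vapply(seq_len(inner_folds), function(f) {
      tr <- folds != f
      m <- fit_model(spec$family, params, Xs[tr, , drop = FALSE], y[tr],
                     seed = seeds[2])
      P <- predict_proba(m, Xs[!tr, , drop = FALSE])
      if (binary) auc_binary(y[!tr], P[, pos], pos)
      else macro_ovr_auc(y[!tr], P)
    }, 0))
  }, 0)
  best <- which.max(scores)
  list(params = spec$grid[best, , drop = FALSE], score = scores[best],
       scores = scores)
}

confusion_binary <- function(truth, pred) {
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  c(tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Stratified k-fold cross-validation of binary HFO detection
#'
#' On the development set: per fold, features are standardized with
#' training-fold statistics, the model is fitted and the held-out fold
#' scored. AUC comes from the continuous positive-class probability;
#' sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` use a 0.5
#' threshold on that probability.
#'
#' @param table balanced development table (from [balance_binary()] /
#'   [split_tuning_holdout()])
#' @param spec an `algorithm_spec`
#' @param params chosen hyperparameters (one-row data.frame; empty for LDA)
#' @param folds number of CV folds (default 5)
#' @param seed integer seed
#' @return a `binary_metrics` list: `per_fold` data.frame (fold, auc,
#'   sensitivity, specificity, tp/fn/tn/fp), `mean`, `sd`
#' @export
crossval_detect <- function(table, spec, params = NULL, folds = 5,
                            seed = 1L) {
  X <- as.matrix(table[, feature_columns(), drop = FALSE])
  y <- factor(ifelse(table$label %in% HFO_LABELS, "HFO", "noHFO"),
              levels = c("noHFO", "HFO"))
  seeds <- derive_seeds(seed, 2)
  fold_id <- stratified_folds(y, folds, seeds[1])
  per_fold <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    scaler <- fit_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(scaler, X[tr, , drop = FALSE])
    Xte <- apply_scaler(scaler, X[!tr, , drop = FALSE])
    m <- fit_model(spec$family, params, Xtr, y[tr], seed = seeds[2])
    p_pos <- predict_proba(m, Xte)[, "HFO"]
    truth <- y[!tr] == "HFO"
    cm <- confusion_binary(truth, p_pos >= 0.5)
    data.frame(fold = f, auc = auc_binary(y[!tr], p_pos, "HFO"),
               sensitivity = cm["tp"] / (cm["tp"] + cm["fn"]),
               specificity = cm["tn"] / (cm["tn"] + cm["fp"]),
               tp = cm["tp"], fn = cm["fn"], tn = cm["tn"], fp = cm["fp"],
               row.names = NULL)
  })
  per_fold <- do.call(rbind, per_fold)
  metrics <- c("auc", "sensitivity", "specificity")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[, metrics]),
                 sd = apply(per_fold[, metrics], 2, sd)),
            class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf("binary detection metrics over %d folds:\n",
              nrow(x$per_fold)))
  for (m in names(x$mean))
    cat(sprintf("  %-11s %.3f +/- %.3f\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Learning curve: AUC and fit time versus training-set size
#'
#' For each requested size, a stratified subsample of the development set is
#' evaluated by 10-fold cross-validation, recording AUC on the training
#' folds, AUC on the held-out folds, and the wall-clock time to fit one
#' model (reported for inspection, never asserted).
#'
#' @param table balanced development table
#' @param spec an `algorithm_spec`
#' @param params chosen hyperparameters
#' @param sizes training-set sizes to probe
#' @param folds CV folds per size (default 10)
#' @param seed integer seed
#' @return data.frame: size, train_auc_mean/sd, val_auc_mean/sd,
#'   fit_time_s
#' @export
learning_curve <- function(table, spec, params = NULL,
                           sizes = c(720, 1440, 2520, 3240), folds = 10,
                           seed = 1L) {
  if (max(sizes) > nrow(table))
    stop("size error: requested size ", max(sizes), " exceeds available ",
         nrow(table), " rows")
  X <- as.matrix(table[, feature_columns(), drop = FALSE])
  y <- factor(ifelse(table$label %in% HFO_LABELS, "HFO", "noHFO"),
              levels = c("noHFO", "HFO"))
  seeds <- derive_seeds(seed, length(sizes))
  out <- lapply(seq_along(sizes), function(si) {
    sz <- sizes[si]
    sseeds <- derive_seeds(seeds[si], 3)
    sub <- integer()
    with_seed(sseeds[1], {
      for (lv in levels(y)) {
        idx <- which(y == lv)
        sub <- c(sub, sample(idx, round(sz * length(idx) / length(y))))
      }
    })
    Xs <- X[sub, , drop = FALSE]; ys <- y[sub]
    fold_id <- stratified_folds(ys, folds, sseeds[2])
    tr_auc <- val_auc <- ft <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      scaler <- fit_scaler(Xs[tr, , drop = FALSE])
      Xtr <- apply_scaler(scaler, Xs[tr, , drop = FALSE])
      Xte <- apply_scaler(scaler, Xs[!tr, , drop = FALSE])
      t0 <- proc.time()[["elapsed"]]
      m <- fit_model(spec$family, params, Xtr, ys[tr], seed = sseeds[3])
      ft[f] <- proc.time()[["elapsed"]] - t0
      tr_auc[f] <- auc_binary(ys[tr], predict_proba(m, Xtr)[, "HFO"], "HFO")
      val_auc[f] <- auc_binary(ys[!tr], predict_proba(m, Xte)[, "HFO"],
                               "HFO")
    }
    data.frame(size = sz, train_auc_mean = mean(tr_auc),
               train_auc_sd = sd(tr_auc), val_auc_mean = mean(val_auc),
               val_auc_sd = sd(val_auc), fit_time_s = mean(ft))
  })
  do.call(rbind, out)
}

#' Train a step-1 HFO detector end-to-end
#'
#' Balances the table, holds out 30% (stratified) for hyperparameter
#' tuning, cross-validates the chosen setting on the remaining 70%, and
#' refits on the full balanced table for deployment.
#'
#' @param table a `segment_feature_table` (one window length)
#' @param family algorithm family
#' @param seed integer seed driving balancing, splitting, tuning and CV
#' @param tuning_fraction holdout fraction (default 0.30)
#' @param folds CV folds (default 5)
#' @return an `hfo_detector` list: family, params, metrics
#'   (`binary_metrics`), fitted model + scaler, window_ms
#' @export
detect_train <- function(table, family, seed = 1L, tuning_fraction = 0.30,
                         folds = 5) {
  spec <- algorithm_spec(family)
  seeds <- derive_seeds(seed, 4)
  bal <- balance_binary(table, seeds[1])
  sp <- split_tuning_holdout(bal, tuning_fraction, seeds[2])
  Xt <- as.matrix(sp$tuning[, feature_columns(), drop = FALSE])
  yt <- factor(ifelse(sp$tuning$label %in% HFO_LABELS, "HFO", "noHFO"),
               levels = c("noHFO", "HFO"))
  tuned <- tune(spec, Xt, yt, seed = seeds[3])
  metrics <- crossval_detect(sp$development, spec, tuned$params,
                             folds = folds, seed = seeds[4])
  X <- as.matrix(bal[, feature_columns(), drop = FALSE])
  y <- factor(ifelse(bal$label %in% HFO_LABELS, "HFO", "noHFO"),
              levels = c("noHFO", "HFO"))
  scaler <- fit_scaler(X)
  final <- fit_model(family, tuned$params, apply_scaler(scaler, X), y,
                     seed = seeds[4])
  structure(list(family = family, params = tuned$params,
                 tuning_score = tuned$score, metrics = metrics,
                 model = final, scaler = scaler,
                 window_ms = table$window_ms[1],
                 feature_cols = feature_columns(), seed = seed),
            class = "hfo_detector")
}

#' Detect HFO intervals in a recording
#'
#' Extracts features with the detector's window length, scores every
#' segment, and returns merged intervals of consecutive positive segments
#' with the mean positive-class probability of each merged run.
#'
#' @param rec an `hfo_recording`
#' @param detector an `hfo_detector` from [detect_train()]
#' @param threshold positive-class probability threshold (default 0.5)
#' @return data.frame: channel_id, start, end (seconds), score
#' @export
detect <- function(rec, detector, threshold = 0.5) {
  if (!inherits(detector, "hfo_detector"))
    stop("model-compatibility error: detector must be an hfo_detector")
  tbl <- extract_features(rec, NULL, detector$window_ms)
  if (!all(detector$feature_cols %in% names(tbl)))
    stop("model-compatibility error: feature schema mismatch")
  X <- apply_scaler(detector$scaler,
                    as.matrix(tbl[, detector$feature_cols, drop = FALSE]))
  p <- predict_proba(detector$model, X)[, "HFO"]
  w_s <- detector$window_ms / 1000
  out <- list()
  for (ch in unique(tbl$channel_id)) {
    rows <- which(tbl$channel_id == ch & p >= threshold)
    if (!length(rows)) next
    starts <- tbl$segment_start[rows]
    runs <- cumsum(c(1, diff(round(starts / w_s)) != 1))
    for (r in unique(runs)) {
      seg <- rows[runs == r]
      out[[length(out) + 1]] <- data.frame(
        channel_id = ch, start = tbl$segment_start[seg[1]],
        end = tbl$segment_start[seg[length(seg)]] + w_s,
        score = mean(p[seg]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(channel_id = character(), start = numeric(),
                      end = numeric(), score = numeric()))
  res <- do.call(rbind, out)
  res[order(res$channel_id, res$start), , drop = FALSE]
}
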