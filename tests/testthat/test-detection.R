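test_that("binary balancing keeps all positives and matches counts", {
  tbl <- cloud_table(c(noHFO = 900, R = 100), seed = 1)
  bal <- balance_binary(tbl, seed = 5)
  expect_identical(nrow(bal), 200L)
  expect_identical(sum(bal$label == "R"), 100L)
  expect_identical(sum(bal$label == "noHFO"), 100L)
  expect_identical(balance_binary(tbl, seed = 5), balance_binary(tbl, 5))
  expect_error(balance_binary(cloud_table(c(noHFO = 50, R = 100)),
                              1), "imbalance")
  expect_error(balance_binary(cloud_table(c(noHFO = 100)), 1),
               "imbalance")
})

test_that("tuning holdout split is stratified, disjoint and exhaustive", {
  tbl <- cloud_table(c(noHFO = 100, R = 100), seed = 2)
  sp <- split_tuning_holdout(tbl, 0.30, seed = 3)
  expect_identical(nrow(sp$tuning), 60L)
  expect_identical(nrow(sp$development), 140L)
  expect_identical(sum(sp$tuning$label == "R"), 30L)
  expect_identical(sum(sp$development$label == "R"), 70L)
  key <- function(d) paste(d$segment_start, d$label)
  expect_length(intersect(key(sp$tuning), key(sp$development)), 0)
  expect_setequal(c(key(sp$tuning), key(sp$development)), key(tbl))
  sp0 <- split_tuning_holdout(tbl, 0, seed = 3)
  expect_identical(nrow(sp0$tuning), 0L)
  expect_identical(nrow(sp0$development), nrow(tbl))
})

test_that("grid search honors LDA's empty grid and the simplicity tie-break", {
  expect_identical(nrow(tune(algorithm_spec("lda"), matrix(0, 5, 2),
                             rep(c("a", "b"), c(3, 2)))$params), 0L)
  # widely separated clouds: every candidate scores AUC 1, simplest wins
  tbl <- cloud_table(c(noHFO = 30, R = 30), sep = 40, seed = 4)
  X <- as.matrix(tbl[, hfopipe:::feature_columns()])
  y <- factor(tbl$label, levels = c("noHFO", "R"))
  tuned_svm <- tune(algorithm_spec("svm"), X, y, seed = 1)
  expect_equal(tuned_svm$score, 1.0)
  expect_equal(tuned_svm$params$cost, 1e-3)     # lowest cost = simplest
  tuned_knn <- tune(algorithm_spec("knn"), X, y, seed = 1)
  expect_equal(tuned_knn$params$k, 20)          # largest k = smoothest
})

test_that("cross-validated detection is near-perfect on separable clouds", {
  tbl <- cloud_table(c(noHFO = 120, R = 120), sep = 8, seed = 6)
  for (fam in c("lda", "lr", "svm", "knn", "rf")) {
    params <- switch(fam, lda = NULL, lr = data.frame(lambda = 0.01),
                     svm = data.frame(cost = 1),
                     knn = data.frame(k = 5),
                     rf = data.frame(num_trees = 100, max_depth = 10,
                                     min_split = 2, min_leaf = 1))
    m <- crossval_detect(tbl, algorithm_spec(fam), params, folds = 5,
                         seed = 7)
    expect_gte(m$mean["auc"], 0.99)
    expect_gte(m$mean["sensitivity"], 0.95)
    expect_gte(m$mean["specificity"], 0.95)
    # balanced accuracy consistent with fold confusion matrices
    pf <- m$per_fold
    expect_equal((pf$tp / (pf$tp + pf$fn) + pf$tn / (pf$tn + pf$fp)) / 2,
                 (pf$sensitivity + pf$specificity) / 2)
    expect_true(all(pf$tp + pf$fn + pf$tn + pf$fp == 48))
  }
})

test_that("label permutation drives AUC to chance", {
  tbl <- cloud_table(c(noHFO = 150, R = 150), sep = 8, seed = 8)
  withr::with_seed(9, tbl$label <- sample(tbl$label))
  m <- crossval_detect(tbl, algorithm_spec("lda"), NULL, folds = 5,
                       seed = 10)
  expect_gte(m$mean["auc"], 0.4)
  expect_lte(m$mean["auc"], 0.6)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(3, {
    y <- factor(rep(c("noHFO", "HFO"), each = 50),
                levels = c("noHFO", "HFO"))
    s <- rnorm(100) + (y == "HFO")
  })
  a0 <- auc_binary(y, s, "HFO")
  expect_equal(auc_binary(y, exp(s), "HFO"), a0)
  expect_equal(auc_binary(y, 3 * s - 100, "HFO"), a0)
})

test_that("learning curves are reproducible and guard their sizes", {
  tbl <- cloud_table(c(noHFO = 150, R = 150), sep = 2, seed = 12)
  lc1 <- learning_curve(tbl, algorithm_spec("lda"), NULL,
                        sizes = c(60, 120), folds = 10, seed = 5)
  lc2 <- learning_curve(tbl, algorithm_spec("lda"), NULL,
                        sizes = c(60, 120), folds = 10, seed = 5)
  expect_identical(lc1$val_auc_mean, lc2$val_auc_mean)
  expect_identical(lc1$train_auc_mean, lc2$train_auc_mean)
  expect_error(learning_curve(tbl, algorithm_spec("lda"), NULL,
                              sizes = 5000), "size error")
  # flexible family overfits noisy data: train AUC above validation AUC
  noisy <- cloud_table(c(noHFO = 150, R = 150), sep = 0.5, seed = 13)
  lcr <- learning_curve(noisy, algorithm_spec("rf"),
                        data.frame(num_trees = 100, max_depth = 20,
                                   min_split = 2, min_leaf = 1),
                        sizes = 120, folds = 10, seed = 6)
  expect_gt(lcr$train_auc_mean, lcr$val_auc_mean)
})

test_that("detector training plus interval detection recovers loud events", {
  gr <- small_subject(seed = 14, duration = 60, snr = 10)
  tbl <- extract_features(gr$recording, gr$annotations, 10)
  det <- detect_train(tbl, "lda", seed = 15)
  expect_s3_class(det$metrics, "binary_metrics")

  hits <- detect(gr$recording, det)
  expect_true(all(hits$end > hits$start))
  # merged intervals never abut within a channel
  for (ch in unique(hits$channel_id)) {
    h <- hits[hits$channel_id == ch, ]
    if (nrow(h) > 1)
      expect_true(all(h$start[-1] > h$end[-nrow(h)] + 1e-9))
  }
  ann <- gr$annotations
  covered <- vapply(seq_len(nrow(ann)), function(i) {
    h <- hits[hits$channel_id == ann$channel_id[i], ]
    any(h$start < ann$end[i] & h$end > ann$start[i])
  }, TRUE)
  expect_gte(mean(covered), 0.9)

  zero <- recording(matrix(0, 2, 20000), 2000)
  expect_identical(nrow(detect(zero, det)), 0L)
})
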