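test_that("ADASYN count arithmetic and guards", {
  withr::with_seed(1, {
    X_min <- matrix(rnorm(40 * 2), 40, 2)
    X_maj <- matrix(rnorm(100 * 2, mean = 3), 100, 2)
  })
  expect_identical(nrow(adasyn_oversample(X_min, X_min[1:40, ],
                                          adasyn_config(seed = 2))), 0L)
  synth <- adasyn_oversample(X_min, X_maj, adasyn_config(seed = 2))
  g <- attr(synth, "g")
  expect_lte(abs(sum(g) - 60), 20)              # G = 60 within rounding
  expect_identical(nrow(synth), sum(g))
  expect_error(adasyn_oversample(X_min[1, , drop = FALSE], X_maj,
                                 adasyn_config()), "at least 2")
  expect_error(adasyn_oversample(X_min[1:4, ], X_maj,
                                 adasyn_config(K = 5)), "K")
})

test_that("every ADASYN synthetic lies between two minority points", {
  withr::with_seed(3, {
    X_min <- matrix(rnorm(15 * 3), 15, 3)
    X_maj <- matrix(rnorm(60 * 3, mean = 1.5), 60, 3)
  })
  synth <- adasyn_oversample(X_min, X_maj, adasyn_config(K = 4, seed = 4))
  g <- attr(synth, "g")
  owner <- rep(seq_along(g), g)
  for (r in seq_len(nrow(synth))) {
    xi <- X_min[owner[r], ]
    on_segment <- FALSE
    for (j in seq_len(nrow(X_min))) {
      if (j == owner[r]) next
      d <- X_min[j, ] - xi
      if (all(abs(d) < 1e-12)) next
      lam <- (synth[r, ] - xi) / d
      if (max(lam) - min(lam) < 1e-8 && min(lam) >= -1e-8 &&
            max(lam) <= 1 + 1e-8) { on_segment <- TRUE; break }
    }
    expect_true(on_segment)
  }
})

test_that("ADASYN density adaptation: more foreign neighbors, more synthetics", {
  # minority points arranged so some sit inside the majority cloud
  withr::with_seed(5, {
    X_min <- rbind(matrix(rnorm(10 * 2, mean = 0, sd = 0.3), 10, 2),
                   matrix(rnorm(10 * 2, mean = 4, sd = 0.3), 10, 2))
    X_maj <- matrix(rnorm(200 * 2, mean = 4, sd = 0.8), 200, 2)
  })
  synth <- adasyn_oversample(X_min, X_maj, adasyn_config(K = 5, seed = 6))
  g <- attr(synth, "g"); delta <- attr(synth, "delta")
  for (i in seq_along(g)) for (j in seq_along(g))
    if (delta[i] > delta[j]) expect_gte(g[i], g[j] - 1)
})

test_that("multiclass balancing equalizes counts and flags synthetics", {
  tbl <- cloud_table(c(R = 300, FR = 40, FRonR = 50), sep = 6, seed = 7)
  out <- balance_multiclass(tbl, adasyn_config(seed = 8))
  counts <- table(out$label)
  expect_lte(max(counts) - min(counts), 30)
  expect_true(all(out$synthetic[-seq_len(nrow(tbl))]))
  expect_false(any(out$synthetic[seq_len(nrow(tbl))]))

  even <- cloud_table(c(R = 50, FR = 50, FRonR = 50), seed = 9)
  expect_identical(nrow(balance_multiclass(even, adasyn_config())),
                   nrow(even))
  expect_error(balance_multiclass(tbl[tbl$label != "FR", ],
                                  adasyn_config()), "class-coverage")
})

test_that("three-class CV is near-perfect on separated clouds", {
  tbl <- cloud_table(c(R = 300, FR = 60, FRonR = 60), sep = 8, seed = 10)
  for (fam in c("knn", "rf")) {
    m <- crossval_classify(tbl, fam, folds = 3, seed = 11)
    expect_true(all(m$mean$sensitivity >= 0.95))
    expect_true(all(m$mean$specificity >= 0.95))
    # every evaluated row is real: totals match the development set
    expect_identical(sum(m$confusion), round(0.7 * nrow(tbl)))
  }
})

test_that("permuted labels drop per-class sensitivity to the class prior", {
  tbl <- cloud_table(c(R = 200, FR = 100, FRonR = 100), sep = 6, seed = 12)
  withr::with_seed(13, tbl$label <- sample(tbl$label))
  m <- crossval_classify(tbl, "knn", folds = 3, seed = 14)
  # chance level: each class recovered at roughly its post-ADASYN share
  expect_true(all(m$mean$sensitivity < 0.65))
  expect_true(all(m$mean$specificity > 0.4))
})

test_that("oversampling before the split is available but explicit", {
  tbl <- cloud_table(c(R = 150, FR = 40, FRonR = 40), sep = 8, seed = 15)
  m <- crossval_classify(tbl, "knn", folds = 3, seed = 16,
                         adasyn_before_split = TRUE)
  # evaluation folds still contain only real rows, so the evaluated total
  # can never exceed the real-row count even though the split saw synthetics
  expect_gt(sum(m$confusion), 0)
  expect_lt(sum(m$confusion), sum(!tbl$synthetic))
})

test_that("band-feature separability holds on simulated HFO segments", {
  gr <- small_subject(seed = 20, duration = 120, n_channels = 4)
  tbl <- extract_features(gr$recording, gr$annotations, 10)
  hfo <- tbl[tbl$label != "noHFO", ]
  med <- function(cls, col) median(hfo[hfo$label == cls, col])
  fr_col <- "band250_500_short_time_energy"
  r_col <- "band80_250_short_time_energy"
  expect_gt(med("FR", fr_col), med("R", fr_col))
  expect_gt(med("FRonR", fr_col), med("R", fr_col))
  expect_gt(med("FRonR", r_col), med("FR", r_col))
})
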