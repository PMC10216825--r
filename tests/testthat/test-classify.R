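test_that("metrics follow the confusion-count formulas", {
  m <- classification_metrics(8, 2, 1, 1)
  expect_equal(m[["AC"]], 83.33333, tolerance = 1e-5)
  expect_equal(m[["SE"]], 88.88889, tolerance = 1e-5)
  expect_equal(m[["F1"]], 88.88889, tolerance = 1e-5)
  expect_equal(unname(classification_metrics(5, 10, 0, 0)),
               c(100, 100, 100))
  m2 <- classification_metrics(0, 10, 0, 5)
  expect_equal(m2[["AC"]], 66.66667, tolerance = 1e-5)
  expect_equal(m2[["SE"]], 0)
  expect_equal(m2[["F1"]], 0)
})

test_that("metric identities hold over enumerated confusion tables", {
  grid <- expand.grid(tp = 0:6, tn = 0:6, fp = 0:6, fn = 0:6)
  grid <- grid[rowSums(grid) > 0, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- suppressWarnings(classification_metrics(g$tp, g$tn, g$fp, g$fn))
    # direct re-derivation
    expect_equal(m[["AC"]], 100 * (g$tp + g$tn) / sum(g))
    if (g$tp + g$fn > 0) expect_equal(m[["SE"]], 100 * g$tp / (g$tp + g$fn))
    # F1 = harmonic mean of precision and sensitivity when both defined
    if (g$tp + g$fp > 0 && g$tp + g$fn > 0 && g$tp > 0) {
      prec <- g$tp / (g$tp + g$fp)
      sens <- g$tp / (g$tp + g$fn)
      expect_equal(m[["F1"]], 100 * 2 * prec * sens / (prec + sens),
                   tolerance = 1e-10)
    }
    # AC invariant under swapping positives and negatives
    m_swap <- suppressWarnings(classification_metrics(g$tn, g$tp, g$fn, g$fp))
    expect_equal(m_swap[["AC"]], m[["AC"]])
  }
})

test_that("undefined metrics warn and return NaN", {
  expect_warning(m <- classification_metrics(0, 5, 1, 0), "SE undefined")
  expect_true(is.nan(m[["SE"]]))
  expect_identical(m[["F1"]], 0)
  w <- capture_warnings(m2 <- classification_metrics(0, 5, 0, 0))
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.nan(m2[["SE"]]) && is.nan(m2[["F1"]]))
  expect_error(classification_metrics(-1, 0, 0, 2), "non-negative")
})

test_that("stratified folds conserve samples and class balance", {
  cls <- rep(1:4, times = c(40, 30, 30, 28))
  for (k in c(2, 5, 19)) {
    f <- make_folds(cls, k, seed = 3)
    expect_identical(length(f), length(cls))
    expect_setequal(unique(f), 1:k)
    # per-class fold counts differ by at most one
    for (c in 1:4) {
      tab <- tabulate(f[cls == c], k)
      expect_lte(diff(range(tab)), 1)
    }
  }
  expect_identical(make_folds(cls, 7, seed = 9), make_folds(cls, 7, seed = 9))
  expect_false(identical(make_folds(cls, 7, seed = 9),
                         make_folds(cls, 7, seed = 10)))
})

test_that("a perfectly separated feature scores 100% for every class", {
  fv <- separable_features(16)
  for (clf in c("knn", "svm")) {
    res <- evaluate_ova(fv, clf, K = 3, k_fold = 5, seed = 2)
    expect_identical(nrow(res), 4L)
    expect_true(all(res$AC == 100))
    expect_true(all(res$SE == 100))
    expect_true(all(res$F1 == 100))
    # fold pooling conserves the sample count
    expect_true(all(res$TP + res$TN + res$FP + res$FN == nrow(fv)))
  }
})

test_that("evaluation is deterministic given the seed", {
  fv <- separable_features(8, seed = 4)
  fv$quantifier_norm <- fv$quantifier_norm + rnorm(nrow(fv), sd = 0.3)
  r1 <- evaluate_ova(fv, "knn", K = 4, k_fold = 6, seed = 11)
  r2 <- evaluate_ova(fv, "knn", K = 4, k_fold = 6, seed = 11)
  expect_identical(r1, r2)
  p1 <- sweep_performance(fv, "knn", K_range = 1:5, kfold_range = 2:4,
                          seed = 11)
  p2 <- sweep_performance(fv, "knn", K_range = 1:5, kfold_range = 2:4,
                          seed = 11)
  expect_identical(p1$records, p2$records)
})

test_that("hand-rolled KNN agrees with class::knn at odd K", {
  skip_if_not_installed("class")
  set.seed(21)
  train_x <- runif(60)
  train_pos <- train_x > 0.5
  test_x <- runif(25)
  for (K in c(1, 3, 7)) {
    mine <- gcq:::.knn_predict(train_x, train_pos, test_x, K)
    ref <- class::knn(matrix(train_x), matrix(test_x),
                      factor(train_pos), k = K)
    expect_identical(mine, as.logical(ref))
  }
})

test_that("voting ties at even K go to the positive class", {
  # two neighbours, one of each label, equidistant: positive wins
  pred <- gcq:::.knn_predict(train_x = c(0, 1), train_pos = c(TRUE, FALSE),
                             test_x = 0.5, K = 2)
  expect_true(pred)
})

test_that("shuffled labels score near the majority-class rate", {
  set.seed(77)
  accs <- replicate(10, {
    n <- 200
    x <- runif(n, -1, 1)
    cls <- sample(rep(1:4, each = n / 4))
    fv <- data.frame(quantifier_norm = x, class_id = cls)
    res <- evaluate_ova(fv, "knn", K = 15, k_fold = 5,
                        seed = sample.int(1000, 1))
    mean(res$AC)
  })
  # chance level for a 1-vs-3 task is 75% (the negative prior)
  expect_lt(abs(mean(accs) - 75), 3)
})

test_that("the sweep enumerates the full grid and summarizes its argmax", {
  fv <- separable_features(8, seed = 5)
  fv$quantifier_norm <- fv$quantifier_norm + rnorm(nrow(fv), sd = 0.4)
  K_range <- 1:6
  kfold_range <- 2:5
  perf <- sweep_performance(fv, c("knn", "svm"), K_range, kfold_range,
                            seed = 3)
  rec <- perf$records
  expect_identical(nrow(rec),
                   4L * (length(K_range) * length(kfold_range) +
                           length(kfold_range)))
  # summary re-derived independently: per classifier/class max accuracy
  for (clf in c("knn", "svm")) {
    for (c in 1:4) {
      sub <- rec[rec$classifier == clf & rec$class_id == c, ]
      best <- perf$summary[perf$summary$classifier == clf &
                             perf$summary$class_id == c, ]
      expect_identical(nrow(best), 1L)
      expect_equal(best$AC, max(sub$AC))
      # the reported SE/F1 belong to the reported configuration
      match_row <- sub[sub$k_fold == best$k_fold &
                         (clf == "svm" | sub$K == best$K), ]
      expect_equal(best$SE, match_row$SE[1])
      expect_equal(best$F1, match_row$F1[1])
    }
  }
})

test_that("the fast KNN sweep equals per-configuration evaluation", {
  fv <- separable_features(8, seed = 6)
  fv$quantifier_norm <- fv$quantifier_norm + rnorm(nrow(fv), sd = 0.5)
  perf <- sweep_performance(fv, "knn", K_range = c(1, 2, 4), kfold_range = 3:4,
                            seed = 13)
  for (K in c(1, 2, 4)) {
    for (kf in 3:4) {
      slow <- evaluate_ova(fv, "knn", K = K, k_fold = kf, seed = 13)
      fast <- perf$records[perf$records$K == K & perf$records$k_fold == kf, ]
      rownames(fast) <- NULL
      expect_equal(fast[, names(slow)], slow)
    }
  }
})

test_that("degenerate stratification is reported with fold and class", {
  fv <- data.frame(quantifier_norm = runif(6),
                   class_id = c(1, 1, 1, 1, 1, 2))
  expect_error(evaluate_ova(fv, "knn", K = 1, k_fold = 3, seed = 1),
               "stratification error: training split of fold \\d+")
  expect_error(evaluate_ova(fv[fv$class_id == 1, ], "knn", k_fold = 2),
               "at least 2 classes")
})
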