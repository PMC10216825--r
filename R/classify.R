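# One-vs-all classification of the scalar connectivity feature with k-fold
# cross-validation, and accuracy / sensitivity / F1 reporting.

#' Classification metrics from confusion counts
#'
#' `AC = (TP + TN) / (TP + TN + FP + FN) * 100`,
#' `SE = TP / (TP + FN) * 100`,
#' `F1 = 2 TP / (2 TP + FP + FN) * 100`.
#' An undefined metric (empty denominator) is returned as `NaN` with a
#' warning.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return Named numeric vector `c(AC, SE, F1)` in percent.
#' @export
#' @examples
#' classification_metrics(8, 2, 1, 1)
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("confusion counts must be non-negative integers")
  }
  total <- tp + tn + fp + fn
  if (total == 0) stopf("no evaluated samples (all counts zero)")
  ac <- (tp + tn) / total * 100
  if (tp + fn == 0) {
    warnf("SE undefined: no positive samples (TP + FN = 0)")
    se <- NaN
  } else {
    se <- tp / (tp + fn) * 100
  }
  if (2 * tp + fp + fn == 0) {
    warnf("F1 undefined: 2TP + FP + FN = 0")
    f1 <- NaN
  } else {
    f1 <- 2 * tp / (2 * tp + fp + fn) * 100
  }
  c(AC = ac, SE = se, F1 = f1)
}

#' Stratified cross-validation fold assignment
#'
#' Deals the samples of each class round-robin into `k` folds after a seeded
#' shuffle, so per-class counts differ by at most one across folds.
#'
#' @param class_id Integer vector of class labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the assignment is deterministic given
#'   `(class_id, k, seed)`.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(class_id, k, seed = 1) {
  k <- as.integer(k)
  if (k < 2L) stopf("k-fold requires k >= 2")
  n <- length(class_id)
  if (k > n) stopf("more folds (%d) than samples (%d)", k, n)
  folds <- integer(n)
  with_seed(derive_seed(seed, k), {
    for (c in sort(unique(class_id))) {
      idx <- which(class_id == c)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Check every fold's training split contains both positives and negatives
# for every one-vs-all task.
.check_stratification <- function(class_id, folds) {
  for (f in sort(unique(folds))) {
    train_cls <- class_id[folds != f]
    for (c in sort(unique(class_id))) {
      n_pos <- sum(train_cls == c)
      if (n_pos == 0L || n_pos == length(train_cls)) {
        stopf("stratification error: training split of fold %d has %s of class %d",
              f, if (n_pos == 0L) "no samples" else "only samples", c)
      }
    }
  }
  invisible(TRUE)
}

# Ordered train-neighbour class labels for each test point (1-D Euclidean
# distance, distance ties broken by train index). Returns a
# n_test x k_max matrix of train class labels.
.knn_neighbours <- function(train_x, test_x, k_max) {
  k_max <- min(k_max, length(train_x))
  out <- matrix(0L, length(test_x), k_max)
  for (t in seq_along(test_x)) {
    ord <- order(abs(train_x - test_x[t]), seq_along(train_x))[seq_len(k_max)]
    out[t, ] <- ord
  }
  out
}

# Predict positive/negative for one OVA task with the K nearest neighbours.
# Voting ties (possible at even K) go to the positive class.
.knn_predict <- function(train_x, train_pos, test_x, K) {
  K <- min(K, length(train_x))
  nb <- .knn_neighbours(train_x, test_x, K)
  votes <- rowSums(matrix(train_pos[nb], nrow(nb), K))
  2 * votes >= K
}

.svm_predict <- function(train_x, train_pos, test_x) {
  fit <- e1071::svm(x = matrix(train_x, ncol = 1),
                    y = factor(train_pos, levels = c(FALSE, TRUE)),
                    kernel = "radial", scale = FALSE)
  as.logical(stats::predict(fit, matrix(test_x, ncol = 1)))
}

#' One-vs-all cross-validated evaluation at a single configuration
#'
#' For each class, the binary task "this class vs the rest" is evaluated by
#' stratified k-fold cross-validation on the normalized scalar feature.
#' Confusion counts are pooled over folds (micro-averaging) and converted to
#' metrics; `pooling = "macro"` instead averages per-fold metrics.
#'
#' @param features A `gc_features` data frame (or any data frame with
#'   `quantifier_norm` and `class_id` columns).
#' @param classifier `"knn"` (K nearest neighbours on the 1-D feature,
#'   Euclidean distance, voting ties to the positive class) or `"svm"`
#'   (radial-kernel support vector machine).
#' @param K Neighbourhood size for KNN (ignored for SVM).
#' @param k_fold Number of cross-validation folds.
#' @param seed Seed for the fold assignment; results are deterministic given
#'   `(features, classifier, K, k_fold, seed)`.
#' @param pooling `"micro"` (default) or `"macro"`.
#' @return Data frame with one row per class: `class_id`, `classifier`, `K`,
#'   `k_fold`, `TP`, `TN`, `FP`, `FN`, `AC`, `SE`, `F1`.
#' @export
evaluate_ova <- function(features, classifier = c("knn", "svm"), K = 5,
                         k_fold = 10, seed = 1,
                         pooling = c("micro", "macro")) {
  classifier <- match.arg(classifier)
  pooling <- match.arg(pooling)
  x <- features$quantifier_norm
  cls <- as.integer(features$class_id)
  classes <- sort(unique(cls))
  if (length(classes) < 2L) stopf("need at least 2 classes present")
  folds <- make_folds(cls, k_fold, seed)
  .check_stratification(cls, folds)
  rows <- list()
  for (c in classes) {
    pos <- cls == c
    tp <- tn <- fp <- fn <- 0L
    fold_metrics <- NULL
    for (f in seq_len(k_fold)) {
      te <- folds == f
      pred <- if (classifier == "knn") {
        .knn_predict(x[!te], pos[!te], x[te], K)
      } else {
        .svm_predict(x[!te], pos[!te], x[te])
      }
      truth <- pos[te]
      ftp <- sum(pred & truth); ftn <- sum(!pred & !truth)
      ffp <- sum(pred & !truth); ffn <- sum(!pred & truth)
      tp <- tp + ftp; tn <- tn + ftn; fp <- fp + ffp; fn <- fn + ffn
      if (pooling == "macro" && length(truth)) {
        fold_metrics <- rbind(fold_metrics,
                              suppressWarnings(
                                classification_metrics(ftp, ftn, ffp, ffn)))
      }
    }
    m <- if (pooling == "micro") {
      classification_metrics(tp, tn, fp, fn)
    } else {
      colMeans(fold_metrics, na.rm = TRUE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      class_id = c, classifier = classifier,
      K = if (classifier == "knn") as.integer(K) else NA_integer_,
      k_fold = as.integer(k_fold), TP = tp, TN = tn, FP = fp, FN = fn,
      AC = m[["AC"]], SE = m[["SE"]], F1 = m[["F1"]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Fast KNN sweep sharing the neighbour ordering across all K and classes.
# Produces rows identical to looping evaluate_ova over K_range.
.knn_sweep <- function(x, cls, K_range, k_fold, seed) {
  classes <- sort(unique(cls))
  folds <- make_folds(cls, k_fold, seed)
  .check_stratification(cls, folds)
  k_max <- max(K_range)
  counts <- array(0L, dim = c(length(classes), length(K_range), 4L))
  for (f in seq_len(k_fold)) {
    te <- folds == f
    if (!any(te)) next
    train_cls <- cls[!te]
    nb <- .knn_neighbours(x[!te], x[te], k_max)
    eff_kmax <- ncol(nb)
    for (ci in seq_along(classes)) {
      pos_mat <- matrix(train_cls[nb] == classes[ci], nrow(nb), eff_kmax)
      cum <- if (eff_kmax > 1L) t(apply(pos_mat, 1L, cumsum)) else pos_mat * 1L
      truth <- cls[te] == classes[ci]
      for (ki in seq_along(K_range)) {
        K <- min(K_range[ki], eff_kmax)
        votes <- cum[, K]
        pred <- 2 * votes >= K
        counts[ci, ki, ] <- counts[ci, ki, ] +
          c(sum(pred & truth), sum(!pred & !truth),
            sum(pred & !truth), sum(!pred & truth))
      }
    }
  }
  rows <- list()
  for (ci in seq_along(classes)) {
    for (ki in seq_along(K_range)) {
      cnt <- counts[ci, ki, ]
      m <- suppressWarnings(
        classification_metrics(cnt[1], cnt[2], cnt[3], cnt[4]))
      rows[[length(rows) + 1L]] <- data.frame(
        class_id = classes[ci], classifier = "knn",
        K = as.integer(K_range[ki]), k_fold = as.integer(k_fold),
        TP = cnt[1], TN = cnt[2], FP = cnt[3], FN = cnt[4],
        AC = m[["AC"]], SE = m[["SE"]], F1 = m[["F1"]],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Sweep classifiers over neighbourhood sizes and fold counts
#'
#' Full Cartesian evaluation — for KNN every combination of `K_range` and
#' `kfold_range`, for SVM every value of `kfold_range` — with a per-class
#' best-accuracy summary (the reporting rule: per classifier and class, the
#' row achieving maximum accuracy, ties resolved toward the smallest
#' `k_fold` then smallest `K`).
#'
#' @param features A `gc_features` data frame.
#' @param classifiers Subset of `c("knn", "svm")`.
#' @param K_range KNN neighbourhood sizes; default `1:20`.
#' @param kfold_range Cross-validation fold counts; default `2:20`.
#' @param seed Fold-assignment seed.
#' @return A `gc_performance` object: list with `records` (all rows) and
#'   `summary` (best row per classifier and class).
#' @export
sweep_performance <- function(features, classifiers = c("knn", "svm"),
                              K_range = 1:20, kfold_range = 2:20, seed = 1) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (!length(K_range) || !length(kfold_range)) {
    stopf("K_range and kfold_range must be non-empty")
  }
  x <- features$quantifier_norm
  cls <- as.integer(features$class_id)
  records <- list()
  for (kf in kfold_range) {
    if ("knn" %in% classifiers) {
      records[[length(records) + 1L]] <- .knn_sweep(x, cls, K_range, kf, seed)
    }
    if ("svm" %in% classifiers) {
      records[[length(records) + 1L]] <-
        evaluate_ova(features, "svm", k_fold = kf, seed = seed)
    }
  }
  records <- do.call(rbind, records)
  ord <- order(records$classifier, records$class_id, records$k_fold,
               records$K, method = "radix")
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  summary <- do.call(rbind, lapply(
    split(records, list(records$classifier, records$class_id), drop = TRUE),
    function(df) {
      df <- df[order(-df$AC, df$k_fold, df$K, method = "radix"), ,
               drop = FALSE]
      df[1L, , drop = FALSE]
    }))
  summary <- summary[order(summary$classifier, summary$class_id), ,
                     drop = FALSE]
  rownames(summary) <- NULL
  structure(list(records = records, summary = summary, seed = seed),
            class = "gc_performance")
}

#' @export
print.gc_performance <- function(x, ...) {
  cat(sprintf("<gc_performance> %d records (seed %s)\n",
              nrow(x$records), format(x$seed)))
  cat("Best accuracy per classifier and class:\n")
  print(x$summary[, c("classifier", "class_id", "k_fold", "K",
                      "AC", "SE", "F1")], digits = 4)
  invisible(x)
}

#' @export
summary.gc_performance <- function(object, ...) object$summary

#' Write performance records and summary as CSV
#'
#' @param perf A `gc_performance` object.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths of the two files, invisibly.
#' @export
write_performance <- function(perf, dir, prefix = "performance") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_records.csv"))
  p2 <- file.path(dir, paste0(prefix, "_summary.csv"))
  utils::write.csv(perf$records, p1, row.names = FALSE)
  utils::write.csv(perf$summary, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
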