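# metrics_eval: brute-force oracles, metric identities, report plumbing

brute_force_metrics <- function(y_true, y_pred, k = 4L) {
  per <- lapply(0:(k - 1), function(c) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    tn <- sum(y_true != c & y_pred != c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    c(prec = prec, rec = rec, f1 = f1, mcc = mcc, tp = tp, fp = fp, fn = fn)
  })
  m <- do.call(rbind, per)
  list(accuracy = mean(y_true == y_pred),
       precision = mean(m[, "prec"], na.rm = TRUE),
       recall = mean(m[, "rec"], na.rm = TRUE),
       f1 = mean(m[, "f1"], na.rm = TRUE),
       mcc = mean(m[, "mcc"]),
       pooled_precision = sum(m[, "tp"]) / sum(m[, "tp"] + m[, "fp"]),
       pooled_recall = sum(m[, "tp"]) / sum(m[, "tp"] + m[, "fn"]))
}

test_that("classification metrics match brute force on 200 random cases", {
  set.seed(30)
  for (case in 1:200) {
    n <- sample(3:60, 1)
    y_true <- sample(0:3, n, replace = TRUE)
    # mix of good and bad predictors so degenerate classes occur
    y_pred <- ifelse(runif(n) < 0.6, y_true, sample(0:3, n, replace = TRUE))
    cm <- confusion_matrix(y_true, y_pred)
    got <- classification_metrics(cm)
    mcc <- mcc_score(cm)
    want <- brute_force_metrics(y_true, y_pred)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(mcc$mcc, want$mcc, tolerance = 1e-12)
    expect_equal(got$pooled$precision, want$pooled_precision,
                 tolerance = 1e-12)
    expect_equal(got$pooled$recall, want$pooled_recall, tolerance = 1e-12)
    # pooled precision = pooled recall = accuracy in single-label multiclass
    expect_equal(got$pooled$precision, got$accuracy, tolerance = 1e-12)
    expect_equal(got$pooled$recall, got$accuracy, tolerance = 1e-12)
  }
})

test_that("segmentation metrics match brute force and the dice-iou identity", {
  set.seed(31)
  for (case in 1:200) {
    d <- c(sample(2:12, 1), sample(2:12, 1))
    pred <- matrix(rbinom(prod(d), 1, runif(1)), d[1], d[2])
    true <- matrix(rbinom(prod(d), 1, runif(1)), d[1], d[2])
    sm <- segmentation_metrics(pred, true)
    inter <- sum(pred == 1 & true == 1)
    uni <- sum(pred == 1 | true == 1)
    if (uni == 0) {
      expect_identical(sm$dice, 1)
      expect_identical(sm$iou, 1)
    } else {
      expect_equal(sm$iou, inter / uni, tolerance = 1e-12)
      expect_equal(sm$dice, 2 * inter / (sum(pred) + sum(true)),
                   tolerance = 1e-12)
      # dice = 2 iou / (1 + iou)
      expect_equal(sm$dice, 2 * sm$iou / (1 + sm$iou), tolerance = 1e-12)
    }
  }
  # both-empty convention
  z <- matrix(0, 3, 3)
  expect_identical(segmentation_metrics(z, z), list(dice = 1, iou = 1))
  expect_error(segmentation_metrics(matrix(0, 2, 2), z), "mismatch")
})

test_that("confusion_matrix validates input and orients rows as true class", {
  cm <- confusion_matrix(c(0L, 0L, 1L), c(0L, 1L, 1L), k = 2L)
  expect_identical(cm[1, 2], 1L)   # true 0 predicted 1
  expect_identical(cm[2, 1], 0L)
  expect_identical(sum(cm), 3L)
  expect_error(confusion_matrix(0L, c(0L, 1L)), "mismatch")
  expect_error(confusion_matrix(4L, 0L), "labels")
  expect_error(classification_metrics(matrix(0, 4, 4)), "empty")
})

test_that("mcc zero-denominator convention and perfect prediction", {
  # all predictions in one class: every per-class denominator degenerates
  cm <- confusion_matrix(rep(0:3, 5), rep(0L, 20))
  expect_identical(mcc_score(cm)$per_class[2:4], rep(0, 3))
  perfect <- confusion_matrix(rep(0:3, 5), rep(0:3, 5))
  expect_equal(mcc_score(perfect)$mcc, 1)
  expect_equal(mcc_score(perfect)$pooled, 1)
})

test_that("evaluate refuses training manifests and writes JSON reports", {
  fit <- tiny_fit()
  rep_test <- evaluate(fit$model, fit$splits$source$test)
  expect_s3_class(rep_test, "metrics_report")
  expect_true(rep_test$accuracy >= 0 && rep_test$accuracy <= 1)
  expect_true(!is.null(rep_test$dice))
  expect_error(evaluate(fit$model, fit$splits$source$train), "train")
  rep_train <- evaluate(fit$model, fit$splits$source$train,
                        allow_train_eval = TRUE)
  expect_s3_class(rep_train, "metrics_report")
  path <- tempfile(fileext = ".json")
  write_report(rep_test, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$accuracy, rep_test$accuracy, tolerance = 1e-12)
  expect_identical(dim(as.matrix(js$confusion)), c(4L, 4L))
})
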