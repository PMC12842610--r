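# Confusion-matrix classification metrics, segmentation overlap metrics and
# the evaluation runner.
#
# Precision/recall written as pooled sums over per-class TP/FP/FN provably
# collapse to accuracy in the single-label multiclass setting
# (sum(TP+FP) = sum(TP+FN) = N), so the headline values reported here are
# macro-averaged; the literal pooled forms are computed alongside and
# labelled as such.

#' Confusion matrix
#'
#' @param y_true,y_pred integer labels in `0..K-1`.
#' @param k number of classes.
#' @return `k x k` integer matrix; rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, k = 4L) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (any(c(y_true, y_pred) < 0 | c(y_true, y_pred) >= k)) {
    stop("labels must lie in 0..", k - 1, call. = FALSE)
  }
  cm <- table(factor(y_true, levels = 0:(k - 1)),
              factor(y_pred, levels = 0:(k - 1)))
  matrix(as.integer(cm), k, k,
         dimnames = list(true = 0:(k - 1), pred = 0:(k - 1)))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1 in two conventions: `macro` averages
#' the per-class values (classes with an empty denominator are excluded),
#' `pooled` follows the literal pooled-sum definitions, under which
#' precision and recall both equal accuracy.
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @return list with `accuracy`, `macro` and `pooled` precision/recall/f1,
#'   `per_class` breakdowns and `n`.
#' @export
classification_metrics <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  accuracy <- sum(tp) / n
  prec_c <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec_c <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1_c <- ifelse(!is.na(prec_c) & !is.na(rec_c) & (prec_c + rec_c) > 0,
                 2 * prec_c * rec_c / (prec_c + rec_c), NA_real_)
  pooled_prec <- sum(tp) / sum(tp + fp)
  pooled_rec <- sum(tp) / sum(tp + fn)
  pooled_f1 <- if (pooled_prec + pooled_rec > 0) {
    2 * pooled_prec * pooled_rec / (pooled_prec + pooled_rec)
  } else 0
  list(
    accuracy = accuracy,
    precision = mean(prec_c, na.rm = TRUE),
    recall = mean(rec_c, na.rm = TRUE),
    f1 = mean(f1_c, na.rm = TRUE),
    pooled = list(precision = pooled_prec, recall = pooled_rec,
                  f1 = pooled_f1),
    per_class = list(precision = prec_c, recall = rec_c, f1 = f1_c,
                     tp = tp, fp = fp, fn = fn),
    n = n
  )
}

binary_mcc <- function(tp, fp, fn, tn) {
  # doubles: the four-way product overflows integer range for a few
  # thousand samples
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Matthews correlation coefficient
#'
#' Headline value: macro average of per-class one-vs-rest binary MCC (a
#' class with a zero denominator factor contributes 0).  The literal pooled
#' multiclass form summing TP/TN/FP/FN over classes is reported alongside.
#'
#' @param cm confusion matrix.
#' @return list with `mcc` (macro) and `pooled`.
#' @export
mcc_score <- function(cm) {
  n <- sum(cm)
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  per_class <- vapply(seq_len(k), function(i) {
    binary_mcc(tp[i], fp[i], fn[i], tn[i])
  }, 0)
  list(mcc = mean(per_class),
       per_class = per_class,
       # micro average: the one-vs-rest counts are pooled over classes first
       pooled = binary_mcc(sum(tp), sum(fp), sum(fn), sum(tn)))
}

#' Segmentation overlap metrics
#'
#' Dice `= 2|A∩B| / (|A| + |B|)` and IoU `= |A∩B| / |A∪B|` between binary
#' masks; when both masks are empty both metrics are 1 (perfect agreement).
#'
#' @param pred_mask,true_mask binary arrays of identical shape.
#' @return list with `dice` and `iou`.
#' @export
segmentation_metrics <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop("mask shape mismatch", call. = FALSE)
  }
  a <- as.logical(pred_mask)
  b <- as.logical(true_mask)
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0) return(list(dice = 1, iou = 1))
  list(dice = 2 * inter / (sum(a) + sum(b)), iou = inter / union)
}

# run the model in evaluation mode over a manifest; returns predictions,
# features (for t-SNE) and per-record segmentation scores
predict_manifest <- function(model, manifest, batch_size = 16L,
                             collect_features = FALSE) {
  n <- nrow(manifest)
  size <- model$config$input_size
  preds <- integer(n)
  feats <- if (collect_features) matrix(0, n, model$feat_dim)
  dice <- iou <- rep(NA_real_, n)
  has_mask <- nzchar(manifest$mask_path)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    imgs <- lapply(idx, function(i) {
      p <- resolve_path(manifest, manifest$path[i])
      if (!file.exists(p)) stop("missing image file for record ", i, ": ", p,
                                call. = FALSE)
      img <- load_image(p)
      aug <- augment(img, directive = manifest$augment[i],
                     rng_seed = unit_hash(paste0(manifest$path[i], "#",
                                                 manifest$augment[i])))
      preprocess(aug$image, size)
    })
    x <- stack_batch(imgs)
    out <- model_forward(model, x, training = FALSE, lambda = 0)
    preds[idx] <- max.col(t(out$cls_logits$value)) - 1L
    if (collect_features) feats[idx, ] <- t(av_flatten_value(out$fprime$value))
    if (!is.null(out$seg_logits)) {
      S <- out$seg_logits$value
      for (j in seq_along(idx)) {
        i <- idx[j]
        if (!has_mask[i]) next
        pm <- (S[, , j, 2] > S[, , j, 1]) * 1L
        tm <- load_mask(resolve_path(manifest, manifest$mask_path[i]))
        tm <- resize_matrix(tm, size, size, "nearest")
        sm <- segmentation_metrics(pm, tm)
        dice[i] <- sm$dice
        iou[i] <- sm$iou
      }
    }
  }
  list(pred = preds, features = feats, dice = dice, iou = iou)
}

av_flatten_value <- function(v) {
  d <- dim(v)
  matrix(aperm(v, c(1L, 2L, 4L, 3L)), prod(d[c(1, 2, 4)]), d[3])
}

#' Evaluate a model on a manifest
#'
#' Runs the model in evaluation mode, computes the confusion matrix and all
#' classification metrics, and -- for records that carry a mask --
#' segmentation Dice/IoU.  Evaluating a manifest whose `role` is `"train"`
#' is refused unless `allow_train_eval = TRUE` (leakage guard).
#'
#' @param model an `adamnet_model` or a checkpoint path.
#' @param manifest an `adamnet_manifest` (or CSV path).
#' @param allow_train_eval permit evaluation on a training manifest.
#' @param batch_size evaluation batch size.
#' @return a `metrics_report` list: `confusion`, `accuracy`, `precision`,
#'   `recall`, `f1`, `mcc` (macro headline values), `pooled` variants,
#'   `per_class`, `dice`, `iou` (NULL when no record has a mask), `n`.
#' @export
evaluate <- function(model, manifest, allow_train_eval = FALSE,
                     batch_size = 16L) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  role <- attr(manifest, "role")
  if (identical(role, "train") && !allow_train_eval) {
    stop("refusing to evaluate on a training manifest; ",
         "set allow_train_eval = TRUE to override", call. = FALSE)
  }
  pr <- predict_manifest(model, manifest, batch_size)
  cm <- confusion_matrix(manifest$grade, pr$pred, model$config$k_cls)
  cls <- classification_metrics(cm)
  mcc <- mcc_score(cm)
  has_seg <- any(!is.na(pr$dice))
  structure(list(
    confusion = cm,
    accuracy = cls$accuracy, precision = cls$precision, recall = cls$recall,
    f1 = cls$f1, mcc = mcc$mcc,
    pooled = c(cls$pooled, list(mcc = mcc$pooled)),
    per_class = cls$per_class,
    dice = if (has_seg) mean(pr$dice, na.rm = TRUE),
    iou = if (has_seg) mean(pr$iou, na.rm = TRUE),
    n = cls$n
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d\n", x$n))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  mcc %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$mcc))
  if (!is.null(x$dice)) {
    cat(sprintf("  dice %.4f  iou %.4f\n", x$dice, x$iou))
  }
  cat("  confusion (rows true, cols pred):\n")
  print(x$confusion)
  invisible(x)
}

#' Write a metrics report to a JSON file
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  obj <- unclass(report)
  obj$confusion <- unname(as.matrix(obj$confusion))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
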