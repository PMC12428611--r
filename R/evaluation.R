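#' Mean Intersection over Union of binary masks
#'
#' Per image, the IoU of the positive (content) class is
#' `|pred AND truth| / |pred OR truth|`; when both masks are empty the IoU
#' is defined as 1, so a correct all-clean prediction scores perfectly.
#' Returns the unweighted mean over images.
#'
#' @param preds,truths Equal-length lists of shape-matched binary matrices.
#' @return Scalar in `[0, 1]`.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(0, 1, 1, 0), 2)
#' evaluate_miou(list(a), list(b))  # 1/3
#' @export
evaluate_miou <- function(preds, truths) {
  stopifnot(is.list(preds), is.list(truths), length(preds) == length(truths),
            length(preds) >= 1)
  ious <- vapply(seq_along(preds), function(i) {
    p <- preds[[i]]; t_ <- truths[[i]]
    check_binary_mask(p); check_binary_mask(t_)
    if (!all(dim(p) == dim(t_)))
      stop("mask ", i, ": shape mismatch", call. = FALSE)
    u <- sum(p == 1 | t_ == 1)
    if (u == 0) 1 else sum(p == 1 & t_ == 1) / u
  }, numeric(1))
  mean(ious)
}

#' Patch-classification metrics derived from a segmenter
#'
#' Evaluates a segmenter as a patch classifier: each labelled patch receives
#' a hard prediction via [patch_label_from_mask()] applied to the model's
#' post-processed binary mask, and a continuous score equal to the mean
#' content probability inside the patch (used for the AUC). Dirty is the
#' positive class.
#'
#' @param model A fitted [patch_segmenter()] (or any object whose `predict`
#'   honours `type = "prob"` / `type = "mask"`).
#' @param frames List of RGB frames.
#' @param patches Data frame of labelled patches (`frame`, `x0`, `y0`, `h`,
#'   `w`).
#' @param labels Binary ground-truth labels.
#' @param coverage_threshold Coverage rule for the hard prediction,
#'   default 0.5 (inclusive).
#' @return A list of class `patch_metrics` with `accuracy`, `auc`,
#'   `precision`, `recall`, `f1`, plus `pred` and `score`. `auc` is `NA`
#'   when the ground truth has a single class; `precision`/`f1` are `NA`
#'   when no patch is predicted dirty.
#' @export
evaluate_patch_classification <- function(model, frames, patches, labels,
                                          coverage_threshold = 0.5) {
  stopifnot(nrow(patches) == length(labels))
  if (!"frame" %in% names(patches))
    stop("patches must carry a 'frame' column", call. = FALSE)
  probs <- list(); masks <- list()
  for (f in sort(unique(patches$frame))) {
    probs[[f]] <- predict(model, frames[[f]], type = "prob")
    masks[[f]] <- predict(model, frames[[f]], type = "mask")
  }
  n <- nrow(patches)
  pred <- integer(n); score <- numeric(n)
  for (k in seq_len(n)) {
    p <- patches[k, ]
    pred[k] <- patch_label_from_mask(masks[[p$frame]], p, coverage_threshold)
    score[k] <- mean(probs[[p$frame]][patch_rows(p), patch_cols(p)])
  }
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  auc <- if (length(unique(labels)) < 2) NA_real_
  else as.numeric(pROC::auc(labels, score, quiet = TRUE,
                            direction = "<", levels = c(0, 1)))
  structure(list(accuracy = mean(pred == labels), auc = auc,
                 precision = precision, recall = recall, f1 = f1,
                 pred = pred, score = score),
            class = "patch_metrics")
}

#' @export
print.patch_metrics <- function(x, ...) {
  cat(sprintf(
    "Patch classification (dirty = positive):\n  accuracy %.3f | AUC %s | precision %s | recall %s | F1 %s\n",
    x$accuracy, fmt_na(x$auc), fmt_na(x$precision), fmt_na(x$recall),
    fmt_na(x$f1)))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
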