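#' Consensus CC-Clear score of one clip
#'
#' The mean of the raters' scores rounded to the nearest integer, with
#' halves rounded away from zero. With three raters the mean is a multiple
#' of 1/3, so halves can only arise for even rater counts.
#'
#' @param scores Numeric vector of one clip's rater scores, each in
#'   `{0,1,2,3}`.
#' @return Integer 0–3.
#' @examples
#' consensus_score(c(2, 2, 3))  # 2
#' consensus_score(c(0, 3))     # 2 (half rounds away from zero)
#' @export
consensus_score <- function(scores) {
  if (length(scores) == 0) stop("no scores supplied", call. = FALSE)
  if (!all(scores %in% 0:3)) stop("scores must be in 0..3", call. = FALSE)
  m <- mean(scores)
  as.integer(sign(m) * floor(abs(m) + 0.5))
}

ccclear_levels <- function() factor(0:3, levels = 0:3)

# fit a depth-limited random forest on (X, y) and predict newdata;
# degenerate single-class folds predict that class with a warning
rf_fold_predict <- function(X, y, newX, n_trees, max_depth, seed) {
  if (length(unique(y)) < 2) {
    warning("training fold has a single class; predicting it", call. = FALSE)
    return(rep(unique(y), nrow(newX)))
  }
  df <- data.frame(X, .y = factor(y, levels = 0:3))
  # ranger warns when a fold lacks some of the four levels; that is expected
  fit <- withCallingHandlers(
    ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = n_trees, max.depth = max_depth,
      seed = seed, num.threads = 1, verbose = FALSE),
    warning = function(w) {
      if (grepl("Dropped unused factor level", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  as.integer(as.character(
    predict(fit, data.frame(newX), num.threads = 1)$predictions))
}

#' Leave-one-out CC-Clear classification
#'
#' Evaluates a depth-limited random forest (default 100 trees, maximum
#' depth 2 — deliberately shallow to avoid overfitting the small number of
#' clips) on the four CC-Clear frame-count features under leave-one-out
#' cross-validation: each clip is predicted by a forest trained on all the
#' others, so every clip is tested exactly once and no fold ever sees its
#' own test clip.
#'
#' @param features Matrix or data frame of per-clip features; a `clip_id`
#'   column, if present, is used for labelling and dropped from the design
#'   matrix. Default features are the raw frame counts
#'   `(n_lt50, n_50_75, n_75_90, n_ge90)`.
#' @param targets Integer vector of per-clip scores in `{0,1,2,3}`.
#' @param n_trees,max_depth Forest size and depth limit.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param normalize Divide each feature row by its sum (for variable-length
#'   clips); default `FALSE`, matching raw frame counts.
#' @return Object of class `loo_result`: `clip_ids`, `y_true`, `y_pred`,
#'   `kappa` (Cohen's, unweighted), `accuracy`, `confusion` (4x4, rows =
#'   truth).
#' @examples
#' feats <- t(vapply(rep(0:3, each = 4), function(cl)
#'   bin_counts(generate_clip(60, cl, seed = cl * 7 + 1)$truth_visibility),
#'   integer(4)))
#' loo_evaluate(feats, rep(0:3, each = 4), seed = 1)
#' @export
loo_evaluate <- function(features, targets, n_trees = 100, max_depth = 2,
                         seed = 1, normalize = FALSE) {
  clip_ids <- NULL
  if (is.data.frame(features) && "clip_id" %in% names(features)) {
    clip_ids <- features$clip_id
    features <- features[setdiff(names(features), "clip_id")]
  }
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  n <- nrow(X)
  stopifnot(n >= 2, length(targets) == n, all(targets %in% 0:3),
            n_trees >= 1, max_depth >= 1)
  if (length(unique(targets)) < 2)
    stop("need at least two distinct target values", call. = FALSE)
  if (normalize) X <- X / pmax(rowSums(X), 1)
  clip_ids <- clip_ids %||% sprintf("clip_%03d", seq_len(n))
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))

  y_pred <- integer(n)
  for (i in seq_len(n)) {
    y_pred[i] <- rf_fold_predict(X[-i, , drop = FALSE], targets[-i],
                                 X[i, , drop = FALSE],
                                 n_trees, max_depth, seed + i)
  }
  structure(
    list(clip_ids = clip_ids, y_true = as.integer(targets), y_pred = y_pred,
         kappa = cohens_kappa(targets, y_pred, categories = 0:3),
         accuracy = mean(y_pred == targets),
         confusion = confusion_matrix(targets, y_pred, n_classes = 4),
         config = list(n_trees = n_trees, max_depth = max_depth,
                       seed = seed, normalize = normalize)),
    class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out CC-Clear classification (%d clips, %d trees, depth %d)\n",
    length(x$y_true), x$config$n_trees, x$config$max_depth))
  cat(sprintf("  Cohen's kappa %.3f | accuracy %.1f%%\n",
              x$kappa, 100 * x$accuracy))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

check_complete_table <- function(rater_table) {
  stopifnot(all(c("clip_id", "rater_id", "score") %in% names(rater_table)))
  if (!all(rater_table$score %in% 0:3))
    stop("scores must be in 0..3", call. = FALSE)
  tab <- table(rater_table$clip_id, rater_table$rater_id)
  if (any(tab != 1)) {
    miss <- which(tab != 1, arr.ind = TRUE)
    stop("rater table is not complete (one score per clip and rater); ",
         "offending pairs: ",
         paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
               sep = "/", collapse = ", "), call. = FALSE)
  }
  invisible(rater_table)
}

#' Individual and consensus scoring models
#'
#' Runs one leave-one-out evaluation per rater — each forest trained to
#' replicate that rater's scores — plus one trained on the consensus score
#' (per-clip mean rating rounded to the nearest integer). The mean of the
#' per-rater kappas summarises how well the individual models replicate
#' their raters; the consensus kappa measures agreement with the pooled
#' ground truth.
#'
#' @param features Per-clip feature table with a `clip_id` column plus the
#'   four CC-Clear bin counts.
#' @param rater_table Complete long-format table (`clip_id`, `rater_id`,
#'   `score`), every clip scored by every rater.
#' @param ... Passed to [loo_evaluate()] (`n_trees`, `max_depth`, `seed`,
#'   `normalize`).
#' @return Object of class `ccclear_fit`: `individual` (named list of
#'   `loo_result`, one per rater), `consensus` (`loo_result`),
#'   `consensus_targets`, `mean_individual_kappa`.
#' @export
fit_modes <- function(features, rater_table, ...) {
  stopifnot(is.data.frame(features), "clip_id" %in% names(features))
  check_complete_table(rater_table)
  clips <- features$clip_id
  if (!setequal(clips, unique(rater_table$clip_id)))
    stop("features and rater table cover different clips", call. = FALSE)

  raters <- sort(unique(rater_table$rater_id))
  per_rater_scores <- lapply(raters, function(r) {
    sub <- rater_table[rater_table$rater_id == r, ]
    sub$score[match(clips, sub$clip_id)]
  })
  names(per_rater_scores) <- raters

  individual <- lapply(per_rater_scores, function(y)
    loo_evaluate(features, y, ...))
  cons <- vapply(clips, function(cl)
    consensus_score(rater_table$score[rater_table$clip_id == cl]),
    integer(1))
  consensus <- loo_evaluate(features, cons, ...)

  structure(
    list(individual = individual, consensus = consensus,
         consensus_targets = setNames(cons, clips),
         mean_individual_kappa =
           mean(vapply(individual, `[[`, numeric(1), "kappa"))),
    class = "ccclear_fit")
}

#' @export
print.ccclear_fit <- function(x, ...) {
  cat("CC-Clear scoring models (leave-one-out)\n")
  for (r in names(x$individual))
    cat(sprintf("  individual %-4s kappa %.3f  accuracy %.1f%%\n", r,
                x$individual[[r]]$kappa, 100 * x$individual[[r]]$accuracy))
  cat(sprintf("  mean individual kappa %.3f\n", x$mean_individual_kappa))
  cat(sprintf("  consensus       kappa %.3f  accuracy %.1f%%\n",
              x$consensus$kappa, 100 * x$consensus$accuracy))
  invisible(x)
}
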