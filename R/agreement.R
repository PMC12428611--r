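#' Cohen's kappa for two categorical raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, where
#' `p_o` is the observed fraction of identical labels and `p_e` the
#' agreement expected from the two raters' marginal label frequencies.
#' Unweighted by default; linear or quadratic disagreement weights are
#' available for sensitivity analysis on ordinal scales.
#'
#' @param a,b Equal-length label vectors over a shared finite category set.
#' @param categories Optional category set; default the union of observed
#'   labels.
#' @param weights `"none"` (default), `"linear"` or `"quadratic"`.
#' @return Scalar kappa; 1 for perfect agreement (returned exactly when
#'   both sequences are identical, including the degenerate constant case
#'   where `p_e = 1`).
#' @examples
#' cohens_kappa(c(0, 1, 2, 2), c(0, 1, 2, 1))  # 7/11 = 0.6364
#' @export
cohens_kappa <- function(a, b, categories = NULL,
                         weights = c("none", "linear", "quadratic")) {
  weights <- match.arg(weights)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 1) stop("empty input", call. = FALSE)
  categories <- categories %||% sort(unique(c(a, b)))
  if (!all(c(a, b) %in% categories))
    stop("labels outside the category set", call. = FALSE)
  K <- length(categories)
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  n <- length(a)
  obs <- table(fa, fb) / n
  pa <- rowSums(obs); pb <- colSums(obs)
  W <- switch(weights,
    none = diag(K),
    linear = 1 - abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1),
    quadratic = 1 - (outer(seq_len(K), seq_len(K), "-") / (K - 1))^2)
  po <- sum(W * obs)
  pe <- sum(W * outer(pa, pb))
  if (abs(1 - pe) < 1e-15) {
    if (abs(1 - po) < 1e-15) return(1)
    stop("degenerate marginals with imperfect agreement", call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Arithmetic mean of agreement coefficients
#'
#' @param values Nonempty numeric vector of kappas.
#' @return Scalar mean.
#' @examples
#' mean_kappa(c(0.537, 0.459, 0.643))  # 0.546
#' @export
mean_kappa <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  mean(values)
}

#' Confusion matrix over the CC-Clear classes
#'
#' @param y_true,y_pred Equal-length label vectors in `[0, n_classes)`.
#' @param n_classes Number of classes, default 4.
#' @return `n_classes x n_classes` integer matrix; entry `(i, j)` counts
#'   true class `i-1` predicted as `j-1`, so row sums are the per-class
#'   true counts and the grand total is the number of items.
#' @examples
#' confusion_matrix(c(0, 0, 1), c(0, 1, 1))
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 4) {
  stopifnot(length(y_true) == length(y_pred))
  if (!all(c(y_true, y_pred) %in% 0:(n_classes - 1)))
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1),
                              pred = 0:(n_classes - 1)))
  for (i in seq_along(y_true))
    m[y_true[i] + 1L, y_pred[i] + 1L] <- m[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  m
}

#' Score-distribution summary from per-score counts
#'
#' @param counts Length-4 vector: number of clips scored 0, 1, 2, 3.
#' @return List with `counts`, `n`, `mean`, `sd_population`, `sd_sample`.
#' @examples
#' score_summary_from_counts(c(4, 12, 27, 9))  # mean 1.79
#' @export
score_summary_from_counts <- function(counts) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("no scores", call. = FALSE)
  s <- 0:3
  m <- sum(s * counts) / n
  v_pop <- sum(counts * (s - m)^2) / n
  list(counts = as.integer(counts), n = as.integer(n), mean = m,
       sd_population = sqrt(v_pop),
       sd_sample = if (n > 1) sqrt(v_pop * n / (n - 1)) else NA_real_)
}

#' Per-rater score-distribution summaries
#'
#' Tabulates each rater's CC-Clear scores and reports the mean and both
#' standard-deviation conventions (population and sample).
#'
#' @param rater_table Long-format table (`clip_id`, `rater_id`, `score`).
#' @return Data frame with one row per rater: columns `rater_id`,
#'   `n0`–`n3`, `n`, `mean`, `sd_population`, `sd_sample`.
#' @export
summarize_scores <- function(rater_table) {
  stopifnot(all(c("rater_id", "score") %in% names(rater_table)))
  if (!all(rater_table$score %in% 0:3))
    stop("scores must be in 0..3", call. = FALSE)
  do.call(rbind, lapply(split(rater_table, rater_table$rater_id), function(d) {
    s <- score_summary_from_counts(tabulate(d$score + 1L, 4L))
    data.frame(rater_id = d$rater_id[1],
               n0 = s$counts[1], n1 = s$counts[2], n2 = s$counts[3],
               n3 = s$counts[4], n = s$n, mean = s$mean,
               sd_population = s$sd_population, sd_sample = s$sd_sample,
               row.names = NULL)
  }))
}

#' Full agreement report: raters vs raters, models vs raters
#'
#' Collects the pairwise Cohen's kappas between raters (and their mean),
#' and — when a fitted [fit_modes()] object is supplied — each individual
#' model's kappa with its rater, their mean, and the consensus model's
#' kappa with the consensus score.
#'
#' @param rater_table Complete long-format rater table.
#' @param modes Optional `ccclear_fit` from [fit_modes()].
#' @return Object of class `agreement_report`: `pairwise` (named kappas
#'   `"Ri:Rj"`), `mean_pairwise`, and when models are present
#'   `model_kappas`, `mean_model`, `consensus_kappa`.
#' @export
agreement_report <- function(rater_table, modes = NULL) {
  check_complete_table(rater_table)
  raters <- sort(unique(rater_table$rater_id))
  clips <- sort(unique(rater_table$clip_id))
  scores <- sapply(raters, function(r) {
    sub <- rater_table[rater_table$rater_id == r, ]
    sub$score[match(clips, sub$clip_id)]
  })
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  pairwise <- vapply(pairs, function(p)
    cohens_kappa(scores[, p[1]], scores[, p[2]], categories = 0:3),
    numeric(1))
  names(pairwise) <- vapply(pairs, paste, character(1), collapse = ":")

  rep <- list(pairwise = pairwise, mean_pairwise = mean_kappa(pairwise))
  if (!is.null(modes)) {
    stopifnot(inherits(modes, "ccclear_fit"))
    rep$model_kappas <- vapply(modes$individual, `[[`, numeric(1), "kappa")
    rep$mean_model <- mean_kappa(rep$model_kappas)
    rep$consensus_kappa <- modes$consensus$kappa
  }
  structure(rep, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (Cohen's kappa)\n  pairwise raters:\n")
  for (nm in names(x$pairwise))
    cat(sprintf("    %-10s %.3f\n", nm, x$pairwise[[nm]]))
  cat(sprintf("    mean       %.3f\n", x$mean_pairwise))
  if (!is.null(x$model_kappas)) {
    cat("  individual models vs their raters:\n")
    for (nm in names(x$model_kappas))
      cat(sprintf("    %-10s %.3f\n", nm, x$model_kappas[[nm]]))
    cat(sprintf("    mean       %.3f\n", x$mean_model))
    cat(sprintf("  consensus model    %.3f\n", x$consensus_kappa))
  }
  invisible(x)
}

#' Write an agreement report as JSON or Markdown
#'
#' @param report An `agreement_report`.
#' @param path Output file; extension `.json` writes JSON, `.md` a
#'   Markdown summary table.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    lines <- c("| quantity | kappa |", "|---|---|",
               sprintf("| raters %s | %.3f |", names(report$pairwise),
                       report$pairwise),
               sprintf("| mean pairwise | %.3f |", report$mean_pairwise))
    if (!is.null(report$model_kappas))
      lines <- c(lines,
                 sprintf("| model %s | %.3f |", names(report$model_kappas),
                         report$model_kappas),
                 sprintf("| mean individual model | %.3f |",
                         report$mean_model),
                 sprintf("| consensus model | %.3f |",
                         report$consensus_kappa))
    writeLines(lines, path)
  }
  invisible(path)
}
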