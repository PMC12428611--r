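test_that("consensus score averages and rounds halves away from zero", {
  expect_identical(consensus_score(c(2, 2, 3)), 2L)
  expect_identical(consensus_score(c(1, 2, 3)), 2L)
  expect_identical(consensus_score(c(0, 3)), 2L)     # half away from zero
  expect_identical(consensus_score(c(1, 2)), 2L)
  expect_identical(consensus_score(3), 3L)
  expect_error(consensus_score(numeric(0)), "no scores")
  expect_error(consensus_score(c(1, 5)), "0..3")
})

make_feats <- function(n_per_class = 13, n_frames = 200, seed = 100) {
  classes <- rep(0:3, each = n_per_class)
  clips <- lapply(seq_along(classes), function(i)
    generate_clip(n_frames, classes[i], seed = seed + i,
                  clip_id = sprintf("clip_%03d", i)))
  list(classes = classes, feats = visibility_features(clips))
}

test_that("leave-one-out evaluation is deterministic with honest folds", {
  d <- make_feats(n_per_class = 4, n_frames = 80)
  res <- loo_evaluate(d$feats, d$classes, seed = 3)
  expect_s3_class(res, "loo_result")
  expect_length(res$y_pred, 16)
  expect_identical(sum(res$confusion), 16L)
  expect_identical(as.integer(rowSums(res$confusion)),
                   as.integer(table(factor(d$classes, 0:3))))
  # determinism under a fixed seed
  res2 <- loo_evaluate(d$feats, d$classes, seed = 3)
  expect_identical(res$y_pred, res2$y_pred)
  expect_identical(res$kappa, res2$kappa)

  # two clips -> exactly two predictions
  tiny <- suppressWarnings(
    loo_evaluate(data.frame(a = c(0, 200), b = c(200, 0)),
                 c(0L, 3L), seed = 1))
  expect_length(tiny$y_pred, 2)

  expect_error(loo_evaluate(d$feats, rep(1L, 16)), "distinct")
})

test_that("fold exclusion is real: a poisoned clip cannot leak its label", {
  # one clip carries a unique feature signature; if its own row leaked into
  # training, the forest would memorise it. Train labels are arranged so
  # that signature maps elsewhere.
  feats <- data.frame(f1 = c(rep(0, 6), 999), f2 = c(rep(200, 6), -999))
  targets <- c(0L, 0L, 0L, 1L, 1L, 1L, 3L)
  res <- suppressWarnings(loo_evaluate(feats, targets, seed = 2))
  # fold 7 never saw label 3, so it cannot predict it
  expect_true(res$y_pred[7] != 3L)
})

test_that("class-consistent features are recovered under LOO", {
  d <- make_feats(n_per_class = 6, n_frames = 150)
  res <- loo_evaluate(d$feats, d$classes, seed = 1)
  expect_gte(res$kappa, 0.7)
})

test_that("identical features for all clips carry no signal", {
  feats <- as.data.frame(matrix(50, 52, 4))
  targets <- with_seed(8, sample(0:3, 52, replace = TRUE))
  ks <- vapply(1:5, function(s)
    loo_evaluate(feats, targets, seed = s)$kappa, numeric(1))
  expect_lt(max(abs(ks)), 0.15)
})

test_that("individual and consensus modes fit one model per target set", {
  d <- make_feats(n_per_class = 4, n_frames = 100)
  rt <- simulate_raters(d$classes, kernel = rater_kernel(0.1), n_raters = 3,
                        seed = 7, clip_ids = d$feats$clip_id)
  modes <- fit_modes(d$feats, rt, seed = 2)
  expect_length(modes$individual, 3)
  expect_s3_class(modes$consensus, "loo_result")
  expect_equal(modes$mean_individual_kappa,
               mean(vapply(modes$individual, `[[`, numeric(1), "kappa")))
  # consensus targets recompute from the table
  cons <- vapply(d$feats$clip_id, function(cl)
    consensus_score(rt$score[rt$clip_id == cl]), integer(1))
  expect_identical(unname(modes$consensus_targets), unname(cons))

  # identity raters: all individual targets coincide, so all kappas agree
  rt_id <- simulate_raters(d$classes, kernel = diag(4), n_raters = 3,
                           clip_ids = d$feats$clip_id)
  m_id <- fit_modes(d$feats, rt_id, seed = 2)
  ks <- vapply(m_id$individual, `[[`, numeric(1), "kappa")
  expect_true(all(ks == ks[1]))

  # incomplete tables are rejected with the offending pair named
  expect_error(fit_modes(d$feats, rt[-1, ], seed = 2), "clip_001")
})

test_that("noisier raters favour the consensus model over individuals", {
  d <- make_feats(n_per_class = 6, n_frames = 150)
  hits <- vapply(1:4, function(s) {
    rt <- simulate_raters(d$classes, kernel = rater_kernel(0.15),
                          n_raters = 3, seed = 20 + s,
                          clip_ids = d$feats$clip_id)
    m <- fit_modes(d$feats, rt, seed = s)
    m$consensus$kappa >=
      max(vapply(m$individual, `[[`, numeric(1), "kappa")) - 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.5)
})
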