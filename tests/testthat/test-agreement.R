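test_that("kappa reproduces hand-counted and degenerate cases", {
  expect_equal(cohens_kappa(c(0, 1, 2, 2), c(0, 1, 2, 1)), 7 / 11)
  expect_equal(cohens_kappa(c(0, 1, 2, 2), c(0, 1, 2, 1)), 0.6364,
               tolerance = 1e-4)
  set.seed(1)
  a <- sample(0:3, 40, replace = TRUE)
  expect_equal(cohens_kappa(a, a), 1)
  # constant identical sequences: p_e = 1 handled explicitly
  expect_equal(cohens_kappa(rep(2, 5), rep(2, 5)), 1)
  expect_error(cohens_kappa(0:2, 0:3), "length")
})

test_that("kappa is symmetric, bounded and matches first principles", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(2:30, 1)
    a <- sample(0:3, n, replace = TRUE)
    b <- sample(0:3, n, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    k <- cohens_kappa(a, b)
    expect_identical(k, cohens_kappa(b, a))
    expect_lte(k, 1)
    expect_equal(k, oracle_kappa(a, b), tolerance = 1e-12)
  }
  # cross-check against an established implementation
  a <- c(0, 1, 2, 2, 3, 0, 1); b <- c(0, 1, 2, 1, 3, 1, 1)
  expect_equal(cohens_kappa(a, b),
               e1071::classAgreement(table(a, b))$kappa)
})

test_that("independent raters give near-zero kappa at large n", {
  set.seed(23)
  a <- sample(0:3, 10000, replace = TRUE)
  b <- sample(0:3, 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.05)
})

test_that("mean kappa reproduces the reference study arithmetic", {
  expect_equal(round(mean_kappa(c(0.537, 0.459, 0.643)), 3), 0.546)
  expect_equal(round(mean_kappa(c(0.649, 0.645, 0.528)), 3), 0.607)
  expect_identical(mean_kappa(0.3), 0.3)
  expect_error(mean_kappa(numeric(0)), "empty")
})

test_that("confusion matrices count and conserve", {
  set.seed(3)
  yt <- sample(0:3, 60, replace = TRUE)
  m <- confusion_matrix(yt, yt)
  expect_true(all(m[upper.tri(m) | lower.tri(m)] == 0))
  expect_identical(as.integer(diag(m)),
                   as.integer(table(factor(yt, 0:3))))

  m2 <- confusion_matrix(c(0, 0, 1), c(0, 1, 1))
  expect_identical(m2[1, 1], 1L); expect_identical(m2[1, 2], 1L)
  expect_identical(m2[2, 2], 1L); expect_identical(sum(m2), 3L)

  yp <- sample(0:3, 60, replace = TRUE)
  expect_identical(sum(confusion_matrix(yt, yp)), 60L)
  expect_error(confusion_matrix(c(0, 4), c(0, 1)), "n_classes")
})

test_that("score summaries reproduce the reference count arithmetic", {
  s1 <- score_summary_from_counts(c(4, 12, 27, 9))
  expect_equal(round(s1$mean, 2), 1.79)
  expect_equal(round(s1$sd_population, 2), 0.82)
  expect_equal(round(s1$sd_sample, 2), 0.82)
  s2 <- score_summary_from_counts(c(1, 10, 23, 18))
  expect_equal(round(s2$mean, 2), 2.12)
  s3 <- score_summary_from_counts(c(2, 10, 27, 13))
  expect_equal(round(s3$mean, 2), 1.98)
  s0 <- score_summary_from_counts(c(0, 0, 0, 7))
  expect_equal(s0$mean, 3)
  expect_equal(s0$sd_population, 0)

  rt <- data.frame(clip_id = rep(sprintf("c%02d", 1:5), 2),
                   rater_id = rep(c("R1", "R2"), each = 5),
                   score = c(0, 1, 2, 2, 3, 1, 1, 2, 3, 3))
  sm <- summarize_scores(rt)
  expect_identical(nrow(sm), 2L)
  expect_identical(sm$n, c(5L, 5L))
  expect_equal(sm$mean[1], 1.6)
})

test_that("agreement reports assemble pairwise and model kappas", {
  classes <- rep(0:3, each = 4)
  clips <- lapply(seq_along(classes), function(i)
    generate_clip(80, classes[i], seed = 50 + i,
                  clip_id = sprintf("clip_%03d", i)))
  feats <- visibility_features(clips)
  rt <- simulate_raters(classes, kernel = rater_kernel(0.1), n_raters = 3,
                        seed = 4, clip_ids = feats$clip_id)
  modes <- fit_modes(feats, rt, seed = 1)
  rep <- agreement_report(rt, modes)
  expect_length(rep$pairwise, 3)
  expect_equal(rep$mean_pairwise, mean(rep$pairwise), tolerance = 1e-12)
  expect_equal(rep$mean_model, mean(rep$model_kappas), tolerance = 1e-12)
  expect_identical(rep$consensus_kappa, modes$consensus$kappa)

  jf <- withr::local_tempfile(fileext = ".json")
  write_agreement_report(rep, jf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$mean_pairwise, rep$mean_pairwise)
  md <- withr::local_tempfile(fileext = ".md")
  write_agreement_report(rep, md)
  expect_true(any(grepl("consensus model", readLines(md))))
})
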