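corpus <- make_training_corpus()

test_that("segmenter honours shape, determinism and untrained contracts", {
  # untrained model: probability 0.5 everywhere, shapes preserved
  unt <- patch_segmenter(corpus$frames, corpus$patches, corpus$labels,
                         epochs = 0, seed = 1)
  pr <- predict(unt, corpus$frames[[1]], type = "prob")
  expect_identical(dim(pr), c(64L, 64L))
  expect_true(all(pr == 0.5))
  # strict > 0.5 threshold: untrained mask is empty
  expect_true(all(predict(unt, corpus$frames[[1]], type = "mask") == 0))

  fit <- patch_segmenter(corpus$frames, corpus$patches, corpus$labels,
                         epochs = 40, seed = 1)
  fit2 <- patch_segmenter(corpus$frames, corpus$patches, corpus$labels,
                          epochs = 40, seed = 1)
  expect_identical(fit$history, fit2$history)
  expect_lt(fit$history[length(fit$history)], fit$history[1])

  img <- corpus$frames[[2]]$image
  p1 <- predict(fit, img); p2 <- predict(fit, img)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))

  # degenerate input: all-black image still yields finite output
  expect_false(anyNA(predict(fit, array(0, dim = c(64, 64, 3)))))
  expect_error(predict(fit, array(0, dim = c(64, 64, 2))), "RGB")

  expect_warning(patch_segmenter(corpus$frames, corpus$patches[1:3, ],
                                 c(1L, 1L, 1L), epochs = 1, seed = 1),
                 "same class")
})

test_that("post-processing smooths then thresholds strictly", {
  expect_true(all(postprocess(matrix(0.6, 16, 16), 0.4, 0.5) == 1))
  # exactly at the threshold: strict comparison gives zeros
  expect_true(all(postprocess(matrix(0.5, 16, 16), 0.4, 0.5) == 0))
  # an isolated peak is diluted below threshold by a wide kernel
  spot <- matrix(0, 31, 31); spot[16, 16] <- 1
  expect_true(all(postprocess(spot, 2, 0.5) == 0))
  # sigma 0 is the identity on binary fields (idempotence)
  b <- matrix(as.numeric(matrix(runif(64), 8) > 0.5), 8)
  expect_identical(postprocess(b, 0, 0.5), matrix(as.integer(b), 8))
  expect_error(postprocess(matrix(2, 4, 4)), "\\[0, 1\\]")
})

test_that("mIoU follows the set-overlap definition with empty-empty = 1", {
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L; a[2, 2] <- 1L   # pixels A, B
  b <- matrix(0L, 4, 4); b[2, 2] <- 1L; b[3, 3] <- 1L   # pixels B, C
  expect_equal(evaluate_miou(list(a), list(b)), 1 / 3)
  expect_equal(evaluate_miou(list(a), list(a)), 1)
  d <- matrix(0L, 4, 4); d[4, 4] <- 1L
  expect_equal(evaluate_miou(list(a), list(d)), 0)
  e <- matrix(0L, 4, 4)
  expect_equal(evaluate_miou(list(e), list(e)), 1)
  expect_equal(evaluate_miou(list(a, e), list(a, e)), 1)
  expect_error(evaluate_miou(list(a), list(matrix(0L, 3, 3))), "mismatch")
})

test_that("weak-label training recovers the occlusion masks at small scale", {
  fit <- patch_segmenter(corpus$frames, corpus$patches, corpus$labels,
                         epochs = 100, seed = 1)
  test_frames <- lapply(1:8, function(i)
    generate_frame(64, with_seed(400 + i, runif(1, 0.1, 0.6)),
                   blob_scale = 4, seed = 900 + i))
  preds <- lapply(test_frames, function(f) predict(fit, f, type = "mask"))
  truths <- lapply(test_frames, function(f) f$truth_mask)
  miou <- evaluate_miou(preds, truths)
  expect_gte(miou, 0.6)

  unt <- patch_segmenter(corpus$frames, corpus$patches, corpus$labels,
                         epochs = 0, seed = 1)
  miou_unt <- evaluate_miou(lapply(test_frames, function(f)
    predict(unt, f, type = "mask")), truths)
  expect_lte(miou_unt, 0.15)
  expect_gt(miou, miou_unt)
})

test_that("patch-classification metrics behave at the extremes", {
  fit <- patch_segmenter(corpus$frames, corpus$patches, corpus$labels,
                         epochs = 100, seed = 1)
  m <- evaluate_patch_classification(fit, corpus$frames, corpus$patches,
                                     corpus$labels)
  expect_gte(m$accuracy, 0.85)
  expect_gte(m$auc, 0.9)

  # constant-0.5 model predicts everything clean: recall 0
  unt <- patch_segmenter(corpus$frames, corpus$patches, corpus$labels,
                         epochs = 0, seed = 1)
  m0 <- evaluate_patch_classification(unt, corpus$frames, corpus$patches,
                                      corpus$labels)
  expect_identical(m0$recall, 0)
  expect_true(is.na(m0$precision))

  # single-class ground truth: AUC reported as absent
  keep <- corpus$labels == 0
  m1 <- evaluate_patch_classification(fit, corpus$frames,
                                      corpus$patches[keep, ],
                                      corpus$labels[keep])
  expect_true(is.na(m1$auc))
})
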