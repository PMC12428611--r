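test_that("patch sampling is uniform over valid positions and seeded", {
  ps <- sample_patches(c(256, 256), c(64, 64), 10, seed = 1)
  expect_identical(nrow(ps), 10L)
  expect_true(all(ps$x0 >= 0 & ps$x0 <= 192))
  expect_true(all(ps$y0 >= 0 & ps$y0 <= 192))
  expect_identical(ps, sample_patches(c(256, 256), c(64, 64), 10, seed = 1))

  # unique valid position
  ps1 <- sample_patches(c(64, 64), c(64, 64), 3)
  expect_true(all(ps1$x0 == 0 & ps1$y0 == 0))

  # uniformity: empirical mean of x0 near the centre of [0, 192]
  big <- sample_patches(c(256, 256), c(64, 64), 5000, seed = 2)
  expect_lt(abs(mean(big$x0) - 96), 5)

  expect_error(sample_patches(c(32, 32), c(64, 64), 1), "fit")
})

test_that("coverage labelling rule is inclusive at the threshold", {
  m <- matrix(0L, 64, 64)
  p <- list(x0 = 0, y0 = 0, h = 64, w = 64)
  m[seq_len(2048)] <- 1L                     # exactly 50% of 4096
  expect_identical(patch_label_from_mask(m, p), 1L)
  m[2048] <- 0L                              # 2047 pixels: just below
  expect_identical(patch_label_from_mask(m, p), 0L)
  expect_identical(patch_label_from_mask(matrix(0L, 64, 64), p), 0L)
  expect_error(patch_label_from_mask(matrix(0L, 32, 32), p), "outside")
})

test_that("patch loss matches analytic and hand-computed values", {
  p64 <- data.frame(x0 = 0, y0 = 0, h = 64, w = 64)
  # uniform 0.5 probabilities: 4096 * ln 2, independent of the label
  expect_equal(patch_loss(matrix(0.5, 64, 64), p64, 1), 4096 * log(2))
  expect_equal(patch_loss(matrix(0.5, 64, 64), p64, 0), 4096 * log(2))
  # 2x2 patch, hand-summed elementwise cross-entropy
  pm <- matrix(c(0.9, 0.7, 0.8, 0.6), 2, 2)   # [[0.9,0.8],[0.7,0.6]]
  p22 <- data.frame(x0 = 0, y0 = 0, h = 2, w = 2)
  expect_equal(patch_loss(pm, p22, 1),
               -(log(0.9) + log(0.8) + log(0.7) + log(0.6)))
  expect_equal(patch_loss(pm, p22, 1), 1.1960, tolerance = 1e-4)
  # perfect prediction limit: loss ~ 0 after clamping
  expect_lt(patch_loss(matrix(1, 64, 64), p64, 1), 5e-4)
  expect_gte(patch_loss(matrix(1, 64, 64), p64, 1), 0)
  # mean reduction divides by patch area
  expect_equal(patch_loss(matrix(0.5, 64, 64), p64, 1, reduce = "mean"),
               log(2))
  expect_error(patch_loss(matrix(1.5, 2, 2), p22, 1), "\\[0, 1\\]")
})

test_that("patch loss equals the broadcast-label cross-entropy oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n_maps <- sample(1:3, 1)
    maps <- replicate(n_maps, matrix(runif(48 * 48), 48, 48),
                      simplify = FALSE)
    B <- sample(1:4, 1)
    patches <- do.call(rbind, lapply(seq_len(B), function(k) {
      h <- sample(2:16, 1); w <- sample(2:16, 1)
      data.frame(x0 = sample(0:(48 - w), 1), y0 = sample(0:(48 - h), 1),
                 h = h, w = w)
    }))
    labels <- sample(0:1, B, replace = TRUE)
    batch_maps <- maps[sample(n_maps, B, replace = TRUE)]
    got <- patch_loss(batch_maps, patches, labels)
    want <- oracle_patch_loss(batch_maps, patches, labels)
    expect_equal(got, want, tolerance = 1e-9)
    expect_gte(got, 0)
  }
})

test_that("patch loss is local, monotone and linear over batches", {
  set.seed(5)
  pm <- matrix(runif(32 * 32), 32, 32)
  patches <- data.frame(x0 = c(2, 18), y0 = c(4, 10), h = c(8, 8), w = c(8, 8))
  labels <- c(1, 0)
  base <- patch_loss(pm, patches, labels)

  # locality: perturbing pixels outside all patches leaves the loss unchanged
  pm2 <- pm
  pm2[32, 32] <- runif(1); pm2[1, 20] <- runif(1)
  expect_identical(patch_loss(pm2, patches, labels), base)
  # ... and the gradient there is exactly zero
  g <- patch_loss_gradient(pm, patches, labels)
  outside <- matrix(TRUE, 32, 32)
  for (k in 1:2) outside[(patches$y0[k] + 1):(patches$y0[k] + 8),
                         (patches$x0[k] + 1):(patches$x0[k] + 8)] <- FALSE
  expect_true(all(g[outside] == 0))
  expect_true(all(g[!outside] != 0))

  # monotonicity: raising an in-patch probability of a y=1 patch lowers loss
  pm3 <- pm
  pm3[5, 3] <- min(pm[5, 3] + 0.2, 0.999)   # inside patch 1 (y=1)
  expect_lt(patch_loss(pm3, patches, labels), base)

  # batch linearity: concatenated batch = B-weighted mean of item losses
  l1 <- patch_loss(pm, patches[1, ], labels[1])
  l2 <- patch_loss(pm, patches[2, ], labels[2])
  expect_equal(base, (l1 + l2) / 2)
})
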