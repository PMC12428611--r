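# Occlusion segmenter trained with the patch loss.
#
# The backbone is deliberately small so the whole pipeline runs on a single
# CPU core in seconds: each pixel is described by its RGB colour plus the
# same colours Gaussian-smoothed at a short scale (local denoising), and a
# logistic model (optionally with one small tanh hidden layer) maps that
# feature vector to a content probability. What is being exercised is the
# weak supervision scheme — the model sees only binary 64x64 patch labels
# and is fit by gradient descent on the patch loss — not backbone capacity.
#
# The features are kept deliberately local. Under a pointwise broadcast-
# label loss the optimum is the posterior of the *patch* label given the
# pixel's features; long-range context features let the model fit the
# coverage idiosyncrasies of the patch-labelling rule (how much of the
# patch is occluded) instead of the pixel's own identity, which degrades
# the thresholded mask. See the methods vignette.

as_image_array <- function(x) {
  if (inherits(x, "frame_phantom")) x <- x$image
  check_rgb_image(x)
  x
}

# per-pixel feature matrix: raw RGB plus Gaussian-smoothed RGB per sigma,
# all scaled to [0, 1]
pixel_features <- function(image, sigmas = 1.5) {
  image <- as_image_array(image) / 255
  planes <- list(image[, , 1], image[, , 2], image[, , 3])
  for (s in sigmas)
    for (ch in 1:3)
      planes[[length(planes) + 1L]] <- gaussian_blur(image[, , ch], s)
  do.call(cbind, lapply(planes, as.vector))
}

seg_forward <- function(weights, X) {
  X1 <- cbind(1, X)
  if (is.null(weights$W1)) return(plogis(drop(X1 %*% weights$w)))
  H <- tanh(X1 %*% weights$W1)
  plogis(drop(cbind(1, H) %*% weights$w))
}

#' Fit an occlusion segmenter from binary patch labels
#'
#' Trains an image-to-probability-mask model by full-batch gradient descent
#' on the patch loss ([patch_loss()]): the only supervision is a set of
#' 64x64 (by default) patches, each carrying a single binary dirty/clean
#' label that is broadcast to every pixel of the patch. The backbone is a
#' multiscale pixel-colour logistic model (see Details), small enough to
#' train on a CPU in seconds while leaving the supervision scheme untouched.
#'
#' @param frames List of RGB frames (`H x W x 3` arrays in `[0,255]`, or
#'   `frame_phantom` objects).
#' @param patches Data frame with one labelled patch per row: columns
#'   `frame` (index into `frames`), `x0`, `y0`, `h`, `w` (0-based,
#'   half-open).
#' @param labels Binary vector, one dirty/clean label per patch.
#' @param hidden Number of tanh hidden units; 0 (default) for a plain
#'   logistic pixel model.
#' @param epochs Full-batch Adam epochs; 0 returns the untrained model,
#'   which predicts probability 0.5 everywhere.
#' @param learning_rate Adam step size, default 0.1.
#' @param sigmas Gaussian scales (pixels) of the smoothed-colour features;
#'   kept short so features stay pixel-local (see Details).
#' @param smoothing_sigma,threshold Post-processing defaults stored in the
#'   model and used by `predict(..., type = "mask")`; see [postprocess()].
#' @param seed Integer seed (weight initialisation when `hidden > 0`).
#' @return An object of class `patch_segmenter` with components `weights`,
#'   `history` (per-epoch mean-reduced patch loss, element 1 = before any
#'   update), `hidden`, `sigmas`, `smoothing_sigma`, `threshold`, `seed`.
#' @details Each pixel's features are its RGB colour and the frame's RGB
#'   smoothed at each `sigmas` scale. Training minimises the mean-reduced
#'   patch loss, which for same-size patches has the same minimiser as the
#'   summed form printed in [patch_loss()]. With a single label class the
#'   model can collapse; a warning is raised rather than an error.
#'
#'   The feature scales are deliberately short. A pointwise loss with
#'   broadcast labels is minimised by the posterior of the patch label
#'   given the pixel's features; features that see far beyond the pixel
#'   let the model predict how much of the surrounding patch is occluded
#'   rather than whether the pixel itself is, which systematically drags
#'   content pixels in sparsely occluded regions below the 0.5 decision
#'   threshold. Balanced patch annotation (see
#'   [sample_labeled_patches()]) keeps the posterior margins stable.
#' @examples
#' fr <- generate_frame(64, 0.4, blob_scale = 4, seed = 1)
#' ps <- sample_patches(c(64, 64), c(16, 16), n = 8, seed = 2)
#' ps$frame <- 1L
#' y <- vapply(seq_len(8), function(i)
#'   patch_label_from_mask(fr$truth_mask, ps[i, ]), integer(1))
#' fit <- patch_segmenter(list(fr), ps, y, epochs = 50, seed = 1)
#' fit
#' @export
patch_segmenter <- function(frames, patches, labels, hidden = 0,
                            epochs = 150, learning_rate = 0.1,
                            sigmas = 1.5, smoothing_sigma = 0.4,
                            threshold = 0.5, seed = 1) {
  stopifnot(is.list(frames), length(frames) >= 1, nrow(patches) >= 1,
            length(labels) == nrow(patches), all(labels %in% c(0, 1)),
            epochs >= 0, hidden >= 0)
  if (!"frame" %in% names(patches))
    stop("patches must carry a 'frame' column indexing into frames",
         call. = FALSE)
  if (any(patches$frame < 1 | patches$frame > length(frames)))
    stop("patch references a frame that was not provided", call. = FALSE)
  if (length(unique(labels)) < 2)
    warning("all patch labels are the same class; the model may collapse")

  # assemble the design matrix of in-patch pixels with broadcast labels
  feats <- lapply(frames, pixel_features, sigmas = sigmas)
  nr <- vapply(frames, function(f) nrow(as_image_array(f)), integer(1))
  rows <- vector("list", nrow(patches))
  for (k in seq_len(nrow(patches))) {
    p <- patches[k, ]
    f <- p$frame
    img <- as_image_array(frames[[f]])
    if (p$x0 < 0 || p$y0 < 0 || p$y0 + p$h > nrow(img) ||
        p$x0 + p$w > ncol(img))
      stop("patch ", k, " extends outside its frame", call. = FALSE)
    idx <- as.vector(outer(patch_rows(p), (patch_cols(p) - 1L) * nr[f], `+`))
    rows[[k]] <- cbind(feats[[f]][idx, , drop = FALSE],
                       y = labels[k], wt = 1 / (nrow(patches) * p$h * p$w))
  }
  M <- do.call(rbind, rows)
  d <- ncol(M) - 2L
  X1 <- cbind(1, M[, seq_len(d), drop = FALSE])
  y <- M[, d + 1L]
  wt <- M[, d + 2L]

  bce <- function(p) -sum(wt * (y * log(pmax(p, 1e-12)) +
                                (1 - y) * log(pmax(1 - p, 1e-12))))

  weights <- with_seed(seed, {
    if (hidden == 0) list(w = numeric(d + 1L))
    else list(W1 = matrix(rnorm((d + 1L) * hidden, 0, 0.5), d + 1L, hidden),
              w = rnorm(hidden + 1L, 0, 0.1))
  })

  # full-batch Adam on the (weighted) broadcast-label cross-entropy
  adam_state <- function(par) list(m = par * 0, v = par * 0)
  adam_step <- function(st, par, g, e) {
    st$m <- 0.9 * st$m + 0.1 * g
    st$v <- 0.999 * st$v + 0.001 * g^2
    mh <- st$m / (1 - 0.9^e)
    vh <- st$v / (1 - 0.999^e)
    list(st = st, par = par - learning_rate * mh / (sqrt(vh) + 1e-8))
  }

  history <- numeric(0)
  if (hidden == 0) {
    st <- adam_state(weights$w)
    for (e in seq_len(epochs + 1L)) {
      p <- plogis(drop(X1 %*% weights$w))
      history[e] <- bce(p)
      if (e > epochs) break
      g <- drop(crossprod(X1, wt * (p - y)))
      up <- adam_step(st, weights$w, g, e)
      st <- up$st; weights$w <- up$par
    }
  } else {
    stW1 <- adam_state(weights$W1); stw <- adam_state(weights$w)
    for (e in seq_len(epochs + 1L)) {
      H <- tanh(X1 %*% weights$W1)
      H1 <- cbind(1, H)
      p <- plogis(drop(H1 %*% weights$w))
      history[e] <- bce(p)
      if (e > epochs) break
      dz <- wt * (p - y)
      gw <- drop(crossprod(H1, dz))
      dH <- (dz %*% t(weights$w[-1])) * (1 - H^2)
      gW1 <- crossprod(X1, dH)
      up <- adam_step(stw, weights$w, gw, e)
      stw <- up$st; weights$w <- up$par
      up <- adam_step(stW1, weights$W1, gW1, e)
      stW1 <- up$st; weights$W1 <- up$par
    }
  }

  structure(
    list(weights = weights, hidden = hidden, sigmas = sigmas,
         smoothing_sigma = smoothing_sigma, threshold = threshold,
         history = history, epochs = epochs, learning_rate = learning_rate,
         seed = seed, n_patches = nrow(patches), call = match.call()),
    class = "patch_segmenter")
}

#' Predict a content-probability or binary occlusion mask
#'
#' @param object A fitted [patch_segmenter()].
#' @param image RGB frame (`H x W x 3` in `[0,255]` or `frame_phantom`).
#' @param type `"prob"` for the raw probability map, `"mask"` for the
#'   post-processed binary mask (Gaussian smoothing then strict
#'   thresholding, using the settings stored in the model).
#' @param ... Unused.
#' @return A matrix with the spatial dimensions of `image`: probabilities in
#'   `[0,1]`, or 0/1 integers for `type = "mask"`.
#' @export
predict.patch_segmenter <- function(object, image, type = c("prob", "mask"),
                                    ...) {
  type <- match.arg(type)
  image <- as_image_array(image)
  X <- pixel_features(image, object$sigmas)
  p <- matrix(seg_forward(object$weights, X), nrow(image[, , 1]))
  if (type == "prob") p
  else postprocess(p, object$smoothing_sigma, object$threshold)
}

#' @export
print.patch_segmenter <- function(x, ...) {
  cat(sprintf("Patch-loss segmenter (%s backbone)\n",
              if (x$hidden == 0) "multiscale pixel logistic"
              else sprintf("pixel MLP, %d hidden units", x$hidden)))
  cat(sprintf("  trained on %d labelled patches, %d epochs\n",
              x$n_patches, x$epochs))
  cat(sprintf("  patch loss (mean-reduced): %.5f -> %.5f\n",
              x$history[1], x$history[length(x$history)]))
  invisible(x)
}

#' @export
summary.patch_segmenter <- function(object, ...) {
  cat(sprintf("Patch-loss segmenter: hidden = %d, sigmas = %s, seed = %d\n",
              object$hidden, paste(object$sigmas, collapse = "/"),
              object$seed))
  cat(sprintf("  post-processing: Gaussian sigma %.2f px, threshold > %.2f\n",
              object$smoothing_sigma, object$threshold))
  cat(sprintf("  training: %d epochs, lr %.3g, loss %.5f -> %.5f\n",
              object$epochs, object$learning_rate,
              object$history[1], object$history[length(object$history)]))
  invisible(object)
}

#' @export
coef.patch_segmenter <- function(object, ...) object$weights

#' @export
plot.patch_segmenter <- function(x, ...) {
  plot(seq_along(x$history) - 1L, x$history, type = "l",
       xlab = "epoch", ylab = "patch loss (mean-reduced)",
       main = "Patch-loss training history", ...)
  invisible(x)
}

#' Post-process a probability map into a binary occlusion mask
#'
#' Gaussian-smooths the probability map (standard deviation `sigma` pixels;
#' `sigma = 0` is the identity), then keeps pixels whose smoothed activation
#' is strictly greater than `threshold`. A constant field at exactly the
#' threshold therefore yields an empty mask.
#'
#' @param prob Probability matrix, values in `[0, 1]`.
#' @param sigma Smoothing standard deviation in pixels, default 0.4.
#' @param threshold Strict activation threshold, default 0.5.
#' @return Binary 0/1 integer matrix of the same shape.
#' @examples
#' postprocess(matrix(0.6, 8, 8))        # all ones
#' postprocess(matrix(0.5, 8, 8))        # all zeros: strict threshold
#' @export
postprocess <- function(prob, sigma = 0.4, threshold = 0.5) {
  stopifnot(is.matrix(prob), sigma >= 0)
  if (min(prob) < 0 || max(prob) > 1)
    stop("prob values must lie in [0, 1]", call. = FALSE)
  sm <- gaussian_blur(prob, sigma)
  matrix(as.integer(sm > threshold), nrow(prob))
}

#' Patch-tiling baseline segmenter
#'
#' The comparison baseline: a patch-level classifier (logistic regression on
#' patch mean colour) applied to a non-overlapping tiling of the frame, each
#' tile painted uniformly with its predicted label. This is the
#' classify-patches-then-tile strategy that patch-loss training is designed
#' to improve on: it cannot follow irregular content boundaries within a
#' tile.
#'
#' @inheritParams patch_segmenter
#' @param tile Tile side length used at prediction time, default 64.
#' @return Object of class `tile_baseline` with a `predict` method
#'   returning a binary mask.
#' @export
tile_baseline <- function(frames, patches, labels, tile = 64) {
  stopifnot(nrow(patches) == length(labels))
  mcol <- t(vapply(seq_len(nrow(patches)), function(k) {
    p <- patches[k, ]
    img <- as_image_array(frames[[p$frame]]) / 255
    vapply(1:3, function(ch)
      mean(img[patch_rows(p), patch_cols(p), ch]), numeric(1))
  }, numeric(3)))
  df <- data.frame(y = labels, r = mcol[, 1], g = mcol[, 2], b = mcol[, 3])
  fit <- suppressWarnings(glm(y ~ r + g + b, family = binomial(), data = df))
  structure(list(fit = fit, tile = as.integer(tile)),
            class = "tile_baseline")
}

#' @export
predict.tile_baseline <- function(object, image, ...) {
  image <- as_image_array(image) / 255
  n <- nrow(image[, , 1]); m <- ncol(image[, , 1])
  t_ <- object$tile
  out <- matrix(0L, n, m)
  for (y0 in seq(0, n - 1, by = t_)) {
    for (x0 in seq(0, m - 1, by = t_)) {
      ridx <- (y0 + 1):min(y0 + t_, n)
      cidx <- (x0 + 1):min(x0 + t_, m)
      nd <- data.frame(r = mean(image[ridx, cidx, 1]),
                       g = mean(image[ridx, cidx, 2]),
                       b = mean(image[ridx, cidx, 3]))
      pr <- predict(object$fit, newdata = nd, type = "response")
      if (pr > 0.5) out[ridx, cidx] <- 1L
    }
  }
  out
}
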