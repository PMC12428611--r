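#' Sample random patch positions within a frame
#'
#' Draws `n` patch top-left positions uniformly over all placements that fit
#' inside the frame, with replacement. Coordinates are 0-based; a patch
#' occupies the half-open window `[x0, x0 + w) x [y0, y0 + h)` with `x`
#' horizontal (columns) and `y` vertical (rows).
#'
#' @param frame_size Integer pair `(height, width)` (a scalar is recycled).
#' @param patch_size Integer pair `(h, w)`; default 64x64.
#' @param n Number of patches to draw.
#' @param seed Integer seed.
#' @return Data frame with columns `x0`, `y0`, `h`, `w`.
#' @examples
#' sample_patches(c(256, 256), n = 4, seed = 1)
#' @export
sample_patches <- function(frame_size, patch_size = c(64, 64), n, seed = 1) {
  frame_size <- rep(as.integer(frame_size), length.out = 2)
  patch_size <- rep(as.integer(patch_size), length.out = 2)
  stopifnot(n >= 1)
  if (any(patch_size > frame_size))
    stop("patch does not fit inside the frame", call. = FALSE)
  h <- patch_size[1]; w <- patch_size[2]
  with_seed(seed, {
    y0 <- sample.int(frame_size[1] - h + 1L, n, replace = TRUE) - 1L
    x0 <- sample.int(frame_size[2] - w + 1L, n, replace = TRUE) - 1L
    data.frame(x0 = x0, y0 = y0, h = h, w = w)
  })
}

# rows/cols of a 0-based half-open patch in matrix indexing
patch_rows <- function(p) (p$y0 + 1L):(p$y0 + p$h)
patch_cols <- function(p) (p$x0 + 1L):(p$x0 + p$w)

#' Label a patch from a binary occlusion mask
#'
#' A patch is labelled dirty (1) when the occluded area covers at least
#' `coverage_threshold` of its pixels — the comparison is inclusive, so
#' exactly 50\% coverage is dirty under the default.
#'
#' @param mask Binary matrix (1 = intraluminal content).
#' @param patch One-row data frame or list with `x0`, `y0`, `h`, `w`
#'   (0-based top-left, half-open extent).
#' @param coverage_threshold Fraction of patch pixels required, default 0.5.
#' @return Integer 0 or 1.
#' @examples
#' m <- matrix(0L, 64, 64); m[1:32, ] <- 1L
#' patch_label_from_mask(m, list(x0 = 0, y0 = 0, h = 64, w = 64))
#' @export
patch_label_from_mask <- function(mask, patch, coverage_threshold = 0.5) {
  check_binary_mask(mask)
  if (patch$x0 < 0 || patch$y0 < 0 ||
      patch$y0 + patch$h > nrow(mask) || patch$x0 + patch$w > ncol(mask))
    stop("patch extends outside the mask", call. = FALSE)
  cov <- mean(mask[patch_rows(patch), patch_cols(patch)])
  as.integer(cov >= coverage_threshold)
}

# normalize prob_maps argument: a single matrix is recycled across the batch
as_prob_map_list <- function(prob_maps, B) {
  if (is.matrix(prob_maps)) prob_maps <- list(prob_maps)
  stopifnot(is.list(prob_maps))
  if (length(prob_maps) == 1L) prob_maps <- rep(prob_maps, B)
  if (length(prob_maps) != B)
    stop("need one probability map per patch (or a single shared map)",
         call. = FALSE)
  for (m in prob_maps)
    if (min(m) < 0 || max(m) > 1)
      stop("probabilities must lie in [0, 1]", call. = FALSE)
  prob_maps
}

#' Patch loss: cross-entropy restricted to labelled patches
#'
#' The weak-supervision loss used to train the segmenter. For a batch of B
#' labelled patches, each patch's binary label is broadcast to every pixel
#' it covers and the binary cross-entropy between the model's per-pixel
#' content probability and that broadcast label is accumulated over the
#' patch:
#' \deqn{\mathrm{PatchLoss} = -\frac{1}{B}\sum_{k=1}^{B}
#'   \sum_{(i,j)\in P_k} \big[y_k \log p_{ij} + (1-y_k)\log(1-p_{ij})\big]}
#' Pixels outside every labelled patch contribute nothing, which is what
#' lets dense segmentation be learned from sparse binary patch labels.
#'
#' @param prob_maps A probability matrix, or a list of them, one per patch
#'   (a single matrix is shared by the whole batch). Values in `[0, 1]`;
#'   clamped to `[eps, 1 - eps]` before the logs.
#' @param patches Data frame with one row per patch: `x0`, `y0`, `h`, `w`
#'   (0-based, half-open).
#' @param labels Binary vector, one label per patch.
#' @param reduce Pixel reduction: `"sum"` (default; the loss as written
#'   above) or `"mean"` (each patch term additionally divided by `h*w`,
#'   which keeps the scale comparable across patch sizes).
#' @param eps Clamping bound, default 1e-7.
#' @return Nonnegative scalar.
#' @seealso [patch_loss_gradient()] for the exact gradient with respect to
#'   the probability maps.
#' @examples
#' p <- matrix(0.5, 64, 64)
#' patch_loss(p, data.frame(x0 = 0, y0 = 0, h = 64, w = 64), 1)  # 4096*log(2)
#' @export
patch_loss <- function(prob_maps, patches, labels,
                       reduce = c("sum", "mean"), eps = 1e-7) {
  reduce <- match.arg(reduce)
  B <- nrow(patches)
  stopifnot(B >= 1, length(labels) == B, all(labels %in% c(0, 1)))
  maps <- as_prob_map_list(prob_maps, B)
  total <- 0
  for (k in seq_len(B)) {
    p <- patches[k, ]
    pr <- clamp(maps[[k]][patch_rows(p), patch_cols(p)], eps, 1 - eps)
    lk <- -sum(labels[k] * log(pr) + (1 - labels[k]) * log1p(-pr))
    if (reduce == "mean") lk <- lk / (p$h * p$w)
    total <- total + lk
  }
  total / B
}

#' Gradient of the patch loss with respect to the probability maps
#'
#' Returns, for each probability map, the exact partial derivative of
#' [patch_loss()] at every pixel. The gradient is identically zero outside
#' labelled patches.
#'
#' @inheritParams patch_loss
#' @return A list of matrices shaped like the input maps (a single matrix
#'   if `prob_maps` was one).
#' @export
patch_loss_gradient <- function(prob_maps, patches, labels,
                                reduce = c("sum", "mean"), eps = 1e-7) {
  reduce <- match.arg(reduce)
  B <- nrow(patches)
  stopifnot(B >= 1, length(labels) == B)
  single <- is.matrix(prob_maps)
  maps <- as_prob_map_list(prob_maps, B)
  # shared map: accumulate into one gradient; else one per patch
  grads <- if (single) list(matrix(0, nrow(maps[[1]]), ncol(maps[[1]])))
           else lapply(maps, function(m) matrix(0, nrow(m), ncol(m)))
  for (k in seq_len(B)) {
    p <- patches[k, ]
    ridx <- patch_rows(p); cidx <- patch_cols(p)
    pr <- clamp(maps[[k]][ridx, cidx], eps, 1 - eps)
    g <- -(labels[k] / pr - (1 - labels[k]) / (1 - pr)) / B
    if (reduce == "mean") g <- g / (p$h * p$w)
    tgt <- if (single) 1L else k
    grads[[tgt]][ridx, cidx] <- grads[[tgt]][ridx, cidx] + g
  }
  if (single) grads[[1]] else grads
}
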