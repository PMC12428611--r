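#' Generate a synthetic capsule-endoscopy frame phantom
#'
#' Builds one square RGB frame that mimics the geometry of a capsule
#' endoscopy image: a bright circular field of view (FOV) over near-black
#' corners, pink mucosa-like background texture, and irregular yellow-brown
#' blobs of intraluminal content with a known ground-truth mask. The content
#' region is constructed by Gaussian-smoothing white noise and keeping the
#' top-k pixels inside the FOV, where k is chosen so the occluded fraction of
#' the FOV matches `target_dirty_fraction` (achieved coverage is exact up to
#' one pixel in k). Borders of the blobs are therefore irregular and
#' ill-defined, as residual stool and debris are in real frames.
#'
#' @param size Side length in pixels (square frame); at least 32.
#' @param target_dirty_fraction Desired occluded fraction of the FOV, in
#'   `[0, 0.95]`.
#' @param blob_scale Standard deviation (pixels) of the noise-smoothing
#'   kernel; larger values give fewer, larger blobs.
#' @param seed Integer seed; output is bit-identical for equal seeds.
#' @return An object of class `frame_phantom`: a list with
#'   \item{image}{`size x size x 3` array, values in `[0, 255]`}
#'   \item{truth_mask}{binary matrix, 1 = intraluminal content}
#'   \item{fov_mask}{binary matrix, 1 = inside the field of view}
#'   \item{dirty_fraction}{content pixels / FOV pixels, exact}
#' @details The FOV is the inscribed circle of radius `0.48 * size` centred
#'   in the frame; corner pixels outside it take channel values 0–5.
#'   Content only ever occurs inside the FOV.
#' @examples
#' fr <- generate_frame(64, 0.3, blob_scale = 4, seed = 1)
#' fr$dirty_fraction
#' @export
generate_frame <- function(size, target_dirty_fraction, blob_scale = 8, seed = 1) {
  stopifnot(size >= 32, blob_scale > 0)
  if (target_dirty_fraction < 0 || target_dirty_fraction > 0.95)
    stop("target_dirty_fraction must lie in [0, 0.95]", call. = FALSE)

  with_seed(seed, {
    cx <- (size + 1) / 2
    r <- 0.48 * size
    ix <- matrix(seq_len(size), size, size)          # row index
    jx <- matrix(seq_len(size), size, size, byrow = TRUE)
    fov <- ((ix - cx)^2 + (jx - cx)^2 <= r^2) * 1L
    n_fov <- sum(fov)

    # content blobs: top-k pixels of smoothed white noise inside the FOV
    k <- min(round(target_dirty_fraction * n_fov), floor(0.95 * n_fov))
    truth <- matrix(0L, size, size)
    if (k > 0) {
      field <- gaussian_blur(matrix(runif(size * size), size, size), blob_scale)
      field[fov == 0] <- -Inf
      truth[order(field, decreasing = TRUE)[seq_len(k)]] <- 1L
    }

    # mucosa: pink with low-frequency texture; content: yellow-brown
    tex <- gaussian_blur(matrix(rnorm(size * size, 0, 30), size, size), 3)
    img <- array(0, dim = c(size, size, 3))
    base_mucosa <- c(190, 110, 110)
    base_content <- c(180, 140, 60)
    for (ch in 1:3) {
      plane <- base_mucosa[ch] + tex + rnorm(size * size, 0, 4)
      plane[truth == 1] <- base_content[ch] + tex[truth == 1] / 2 +
        rnorm(sum(truth), 0, 6)
      plane[fov == 0] <- runif(sum(fov == 0), 0, 5)
      img[, , ch] <- clamp(plane, 0, 255)
    }

    structure(
      list(image = img, truth_mask = truth, fov_mask = fov,
           dirty_fraction = sum(truth) / n_fov),
      class = "frame_phantom")
  })
}

#' @export
print.frame_phantom <- function(x, ...) {
  cat(sprintf("<frame_phantom %dx%d, dirty fraction %.3f>\n",
              nrow(x$truth_mask), ncol(x$truth_mask), x$dirty_fraction))
  invisible(x)
}

# visibility band of each CC-Clear class: 0 worst .. 3 cleanest
ccclear_bands <- function() {
  list(c(0, 0.50), c(0.50, 0.75), c(0.75, 0.90), c(0.90, 1.0))
}

#' Generate a synthetic 10-minute-style clip phantom
#'
#' Simulates a video clip whose per-frame mucosa visibility follows a
#' bounded random walk confined (up to small observation noise) to the
#' visibility band of one CC-Clear class: class 0 below 50\%, class 1
#' 50–75\%, class 2 75–90\%, class 3 at or above 90\%. Optionally renders
#' each frame as a [generate_frame()] phantom whose occluded fraction equals
#' one minus the frame's visibility.
#'
#' @param n_frames Number of frames, at least 1.
#' @param true_class Target CC-Clear class, integer 0–3.
#' @param render If `TRUE`, render a `frame_phantom` per frame; otherwise
#'   the clip is timeline-only.
#' @param obs_noise Per-frame visibility noise standard deviation
#'   (absolute). A scalar, or one value per class; the default
#'   `c(0.025, 0.05, 0.05, 0.025)` makes the central classes noisier than
#'   the extremes, reproducing the pattern seen in real clips where fully
#'   clean / fully obscured segments are scored homogeneously while
#'   intermediate cleanliness is ambiguous between adjacent classes. The
#'   noise lets frames near a band edge spill into the neighbouring band;
#'   the per-frame majority stays in the class band.
#' @param seed Integer seed.
#' @param size Side length of rendered frames (ignored unless `render`).
#' @param blob_scale Blob scale of rendered frames.
#' @param clip_id Identifier; default derived from class and seed.
#' @return An object of class `clip_phantom`: list with `clip_id`, `frames`
#'   (list of `frame_phantom` or `NULL`), `truth_visibility` (numeric in
#'   `[0,1]`), `true_class`, `n_frames`.
#' @examples
#' cl <- generate_clip(50, true_class = 2, seed = 3)
#' range(cl$truth_visibility)
#' @export
generate_clip <- function(n_frames, true_class, render = FALSE,
                          obs_noise = c(0.025, 0.05, 0.05, 0.025), seed = 1,
                          size = 128, blob_scale = 8, clip_id = NULL) {
  stopifnot(n_frames >= 1)
  if (!true_class %in% 0:3) stop("true_class must be in 0..3", call. = FALSE)
  clip_id <- clip_id %||% sprintf("clip_c%d_s%d", true_class, seed)

  band <- ccclear_bands()[[true_class + 1]]
  lo <- band[1]; hi <- band[2]; w <- hi - lo

  wlo <- lo + 0.15 * w
  whi <- hi - 0.15 * w

  vis <- with_seed(seed, {
    x <- numeric(n_frames)
    x[1] <- runif(1, wlo, whi)
    if (n_frames > 1) {
      step <- rnorm(n_frames - 1, 0, 0.08 * w)
      for (t in 2:n_frames) {
        v <- x[t - 1] + step[t - 1]
        # reflect at the walk bounds
        if (v > whi) v <- whi - (v - whi)
        if (v < wlo) v <- wlo + (wlo - v)
        x[t] <- clamp(v, wlo, whi)
      }
    }
    sdn <- rep(obs_noise, length.out = 4)[true_class + 1]
    clamp(x + rnorm(n_frames, 0, sdn), 0, 1)
  })

  frames <- NULL
  if (render) {
    frames <- lapply(seq_len(n_frames), function(t) {
      generate_frame(size, min(1 - vis[t], 0.95), blob_scale = blob_scale,
                     seed = seed * 1000L + t)
    })
  }

  structure(
    list(clip_id = clip_id, frames = frames, truth_visibility = vis,
         true_class = as.integer(true_class), n_frames = as.integer(n_frames)),
    class = "clip_phantom")
}

#' @export
print.clip_phantom <- function(x, ...) {
  cat(sprintf("<clip_phantom '%s': %d frames%s, true class %d, mean visibility %.3f>\n",
              x$clip_id, x$n_frames, if (is.null(x$frames)) " (timeline-only)" else "",
              x$true_class, mean(x$truth_visibility)))
  invisible(x)
}

#' Sample a balanced labelled-patch annotation from ground-truth masks
#'
#' Emulates the patch-annotation step of the weak-supervision protocol:
#' candidate 64x64 windows are drawn uniformly from every frame, labelled
#' dirty/clean by the coverage rule ([patch_label_from_mask()]), and a
#' corpus-level class-balanced subset is kept — half the labelled patches
#' dirty, half clean, as an annotator assembling a training set would
#' balance it. If one class is scarce across the whole corpus the other
#' fills the shortfall.
#'
#' @param masks List of binary ground-truth masks (or `frame_phantom`
#'   objects, whose `truth_mask` is used).
#' @param n_total Total number of labelled patches to keep.
#' @param patch_size Integer pair, default 64x64.
#' @param balance Balance dirty/clean at the corpus level (default `TRUE`);
#'   `FALSE` keeps the first `n_total` uniform draws.
#' @param candidates_per_frame Uniform candidate windows drawn per frame.
#' @param coverage_threshold Labelling rule threshold, default 0.5.
#' @param seed Integer seed.
#' @return List with `patches` (data frame `frame`, `x0`, `y0`, `h`, `w`)
#'   and `labels` (binary vector).
#' @export
sample_labeled_patches <- function(masks, n_total, patch_size = c(64, 64),
                                   balance = TRUE, candidates_per_frame = 40,
                                   coverage_threshold = 0.5, seed = 1) {
  stopifnot(length(masks) >= 1, n_total >= 1)
  masks <- lapply(masks, function(m)
    if (inherits(m, "frame_phantom")) m$truth_mask else m)
  cand <- do.call(rbind, lapply(seq_along(masks), function(i) {
    ps <- sample_patches(dim(masks[[i]]), patch_size, candidates_per_frame,
                         seed = seed * 1009L + i)
    ps$frame <- i
    ps
  }))
  lab <- vapply(seq_len(nrow(cand)), function(k)
    patch_label_from_mask(masks[[cand$frame[k]]], cand[k, ],
                          coverage_threshold), integer(1))
  if (nrow(cand) < n_total)
    stop("not enough candidate patches; raise candidates_per_frame",
         call. = FALSE)
  idx <- if (!balance) seq_len(n_total) else {
    want <- n_total %/% 2
    i1 <- which(lab == 1); i0 <- which(lab == 0)
    n1 <- min(max(want, n_total - length(i0)), length(i1))
    c(head(i1, n1), head(i0, n_total - n1))
  }
  # interleave frames back into original candidate order
  idx <- sort(idx)
  list(patches = cand[idx, c("frame", "x0", "y0", "h", "w")],
       labels = lab[idx])
}

#' Build a rater confusion kernel
#'
#' Row-stochastic 4x4 matrix giving the probability that a simulated rater
#' reports each CC-Clear score (columns) given the true class (rows). A
#' probability `spill` goes to each adjacent score that exists; the rest
#' stays on the diagonal, so edge classes are reported more reliably, as an
#' ordinal scale behaves in practice.
#'
#' @param spill Probability mass moved to each adjacent score, in `[0, 0.5)`.
#' @return 4x4 row-stochastic matrix.
#' @examples
#' rater_kernel(0.15)
#' @export
rater_kernel <- function(spill = 0.15) {
  stopifnot(spill >= 0, spill < 0.5)
  k <- diag(4)
  for (i in 1:4) {
    nb <- intersect(c(i - 1, i + 1), 1:4)
    k[i, nb] <- spill
    k[i, i] <- 1 - spill * length(nb)
  }
  k
}

#' Simulate ordinal cleanliness raters
#'
#' Draws CC-Clear scores from independent simulated raters. Each rater
#' reports, for a clip of true class `t`, a score drawn from row `t` of the
#' confusion kernel. The identity kernel reproduces the truth exactly.
#'
#' @param true_classes Integer vector of true classes in `{0,1,2,3}`.
#' @param kernel 4x4 row-stochastic confusion matrix; see [rater_kernel()].
#' @param n_raters Number of raters, at least 1.
#' @param seed Integer seed.
#' @param clip_ids Optional clip identifiers (default `clip_001`, ...).
#' @return Long-format data frame with columns `clip_id`, `rater_id`,
#'   `score`; one row per (clip, rater).
#' @examples
#' simulate_raters(c(0, 1, 2, 3), kernel = diag(4), n_raters = 2)
#' @export
simulate_raters <- function(true_classes, kernel = diag(4), n_raters = 3,
                            seed = 1, clip_ids = NULL) {
  if (!all(true_classes %in% 0:3))
    stop("true_classes must be in 0..3", call. = FALSE)
  stopifnot(n_raters >= 1)
  if (!is.matrix(kernel) || !all(dim(kernel) == c(4, 4)) || any(kernel < 0) ||
      any(abs(rowSums(kernel) - 1) > 1e-12))
    stop("kernel must be a 4x4 row-stochastic matrix", call. = FALSE)

  n <- length(true_classes)
  clip_ids <- clip_ids %||% sprintf("clip_%03d", seq_len(n))
  stopifnot(length(clip_ids) == n)

  with_seed(seed, {
    rows <- lapply(seq_len(n_raters), function(r) {
      score <- vapply(true_classes, function(tc)
        sample(0:3, 1L, prob = kernel[tc + 1L, ]), integer(1))
      data.frame(clip_id = clip_ids, rater_id = sprintf("R%d", r),
                 score = score, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
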