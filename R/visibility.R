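#' Estimate the field-of-view mask of a capsule frame
#'
#' Capsule frames show a bright circular imaging region over near-black
#' corners; area statistics must exclude those corners. The mask is 1 where
#' the per-pixel maximum channel value, after 3x3 median denoising, exceeds
#' the darkness threshold.
#'
#' @param image RGB array (`H x W x 3`, values in `[0, 255]`) or
#'   `frame_phantom`.
#' @param darkness Channel-value threshold separating the black corners from
#'   the imaged region, default 10 (of 255).
#' @param denoise Apply the 3x3 median filter first (default `TRUE`).
#' @return Binary matrix, 1 = inside the field of view.
#' @examples
#' fr <- generate_frame(64, 0.2, blob_scale = 4, seed = 1)
#' mean(compute_fov_mask(fr) == fr$fov_mask)
#' @export
compute_fov_mask <- function(image, darkness = 10, denoise = TRUE) {
  image <- as_image_array(image)
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  if (denoise) mx <- EBImage::medianFilter(mx / 255, size = 1) * 255
  fov <- matrix(as.integer(mx > darkness), nrow(mx))
  if (sum(fov) == 0) stop("empty field of view", call. = FALSE)
  fov
}

#' Per-frame visibility score
#'
#' The fraction of clean (unobscured) mucosa within the field of view:
#' one minus the proportion of FOV pixels covered by the occlusion mask.
#' Black corners outside the FOV are excluded from both numerator and
#' denominator.
#'
#' @param mask Binary occlusion mask (1 = intraluminal content).
#' @param fov Binary field-of-view mask; must be nonempty.
#' @return Scalar in `[0, 1]`; 1 means fully clean.
#' @examples
#' visibility_score(matrix(0L, 4, 4), matrix(1L, 4, 4))  # 1
#' @export
visibility_score <- function(mask, fov) {
  check_binary_mask(mask); check_binary_mask(fov)
  if (!all(dim(mask) == dim(fov))) stop("shape mismatch", call. = FALSE)
  nf <- sum(fov == 1)
  if (nf == 0) stop("empty field of view", call. = FALSE)
  1 - sum(mask == 1 & fov == 1) / nf
}

#' Centered moving-average smoothing of a visibility timeline
#'
#' At the sequence edges the window truncates to the available frames, so
#' no frame is lost and the smoothed sequence has the original length.
#' Window 1 is the identity.
#'
#' @param values Numeric sequence.
#' @param window Odd window length, at least 1.
#' @return Numeric sequence of the same length.
#' @examples
#' smooth_timeline(c(0, 1, 0), 3)  # 0.5, 1/3, 0.5
#' @export
smooth_timeline <- function(values, window = 25) {
  stopifnot(length(values) >= 1)
  if (window < 1 || window %% 2 == 0)
    stop("window must be an odd integer >= 1", call. = FALSE)
  if (window == 1) return(values)
  n <- length(values)
  half <- (window - 1) / 2
  cs <- c(0, cumsum(values))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' CC-Clear frame-count features of a visibility timeline
#'
#' Counts the frames falling in each of the four CC-Clear visibility bands:
#' below 50\%, 50–75\%, 75–90\%, and 90\% or above. The bands partition
#' `[0, 1]` with each boundary belonging to the upper band, so every frame
#' lands in exactly one bin and the counts always sum to the number of
#' frames.
#'
#' @param values Visibility values in `[0, 1]`.
#' @return Named integer vector `(n_lt50, n_50_75, n_75_90, n_ge90)`.
#' @examples
#' bin_counts(c(0.2, 0.5, 0.6, 0.75, 0.9, 0.95, 1.0))  # 1 2 1 3
#' @export
bin_counts <- function(values) {
  stopifnot(length(values) >= 1)
  if (min(values) < 0 || max(values) > 1)
    stop("visibility values must lie in [0, 1]", call. = FALSE)
  b <- findInterval(values, c(0.50, 0.75, 0.90))
  setNames(tabulate(b + 1L, nbins = 4L),
           c("n_lt50", "n_50_75", "n_75_90", "n_ge90"))
}

#' Visibility timeline of a clip
#'
#' Computes the per-frame visibility of a rendered clip, either from a
#' fitted segmenter or — when `model` is `NULL` — from the clip's own
#' ground-truth masks (the oracle path used to validate the downstream
#' stages in isolation).
#'
#' @param clip A rendered `clip_phantom`, or a list of RGB frames.
#' @param model Optional [patch_segmenter()]; `NULL` uses ground-truth
#'   masks (requires a `clip_phantom`).
#' @param window Odd smoothing window for the `smoothed` column.
#' @return Data frame with columns `clip_id`, `frame_idx` (1-based),
#'   `visibility`, `smoothed`.
#' @export
clip_visibility <- function(clip, model = NULL, window = 25) {
  if (inherits(clip, "clip_phantom")) {
    if (is.null(clip$frames))
      stop("clip is timeline-only; render it first", call. = FALSE)
    frames <- clip$frames
    clip_id <- clip$clip_id
  } else {
    frames <- clip
    clip_id <- "clip"
  }
  window <- min(window, length(frames) - (1 - length(frames) %% 2))
  vis <- vapply(frames, function(fr) {
    img <- as_image_array(fr)
    fov <- compute_fov_mask(img)
    m <- if (is.null(model)) {
      if (!inherits(fr, "frame_phantom"))
        stop("oracle visibility needs frame_phantom truth masks", call. = FALSE)
      fr$truth_mask
    } else predict(model, img, type = "mask")
    visibility_score(m, fov)
  }, numeric(1))
  data.frame(clip_id = clip_id, frame_idx = seq_along(vis),
             visibility = vis, smoothed = smooth_timeline(vis, window))
}

ccclear_colors <- function() c("firebrick2", "darkorange", "gold", "forestgreen")

#' Plot a visibility timeline with CC-Clear banding
#'
#' Writes a PNG showing the raw per-frame visibility, its centered moving
#' average, dashed horizontal lines at the 50/75/90\% CC-Clear thresholds,
#' and a top colour bar classifying each frame by the band of its smoothed
#' visibility: red below 50\%, orange 50–75\%, yellow 75–90\%, green at or
#' above 90\%.
#'
#' @param values Visibility sequence in `[0, 1]` (or a data frame from
#'   [clip_visibility()], whose `visibility` column is used).
#' @param file Output PNG path.
#' @param window Odd smoothing window, default 25 (truncated for short
#'   clips).
#' @param clip_id Title label.
#' @return Invisibly, a list with `bands` (per-frame bin index 0–3) and
#'   `colors` (per-frame colour), each of length `n_frames`.
#' @export
timeline_report <- function(values, file, window = 25, clip_id = "clip") {
  if (is.data.frame(values)) {
    clip_id <- values$clip_id[1]
    values <- values$visibility
  }
  stopifnot(length(values) >= 1)
  window <- min(window, length(values) - (1 - length(values) %% 2))
  sm <- smooth_timeline(values, window)
  bands <- findInterval(sm, c(0.50, 0.75, 0.90))
  cols <- ccclear_colors()[bands + 1L]
  n <- length(values)

  grDevices::png(file, width = 900, height = 420)
  on.exit(grDevices::dev.off())
  op <- par(mar = c(4, 4, 3, 1))
  on.exit(par(op), add = TRUE, after = FALSE)
  plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0, 1.12), xaxs = "i",
       xlab = "frame", ylab = "clean mucosa fraction",
       main = paste("Visibility —", clip_id), yaxt = "n")
  axis(2, at = c(0, 0.25, 0.5, 0.75, 0.9, 1))
  abline(h = c(0.50, 0.75, 0.90), lty = 2, col = "grey40")
  rect(seq_len(n) - 0.5, 1.04, seq_len(n) + 0.5, 1.12, col = cols,
       border = NA)
  points_col <- grDevices::adjustcolor("grey30", 0.5)
  lines(seq_len(n), values, col = points_col)
  lines(seq_len(n), sm, col = "blue", lwd = 2)
  invisible(list(bands = bands, colors = cols))
}
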