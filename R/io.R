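# Plain-text / PNG plumbing between pipeline stages. All tabular exchange
# is CSV with headers; images and masks are PNG; reports are JSON.

#' Read and write binary masks as single-channel PNG
#'
#' Masks are stored as {0, 255} grayscale PNG.
#'
#' @param mask Binary 0/1 matrix.
#' @param path PNG path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a binary integer matrix.
#' @export
write_mask_png <- function(mask, path) {
  check_binary_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m))
}

#' Read and write RGB frames as PNG
#'
#' @param image `H x W x 3` array in `[0, 255]` (or `frame_phantom`).
#' @param path PNG path.
#' @return `write_image_png` returns `path` invisibly; `read_image_png`
#'   an `H x W x 3` array in `[0, 255]`.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(as_image_array(image) / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' Patch-label tables on disk
#'
#' CSV with header and columns `frame_id`, `x0`, `y0`, `h`, `w`, `label`
#' (coordinates 0-based, half-open extent).
#'
#' @param df Data frame with those columns.
#' @param path CSV path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_patch_labels <- function(df, path) {
  stopifnot(all(c("frame_id", "x0", "y0", "h", "w", "label") %in% names(df)))
  write.csv(df[c("frame_id", "x0", "y0", "h", "w", "label")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_patch_labels
#' @export
read_patch_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame_id", "x0", "y0", "h", "w", "label") %in% names(df)))
  df
}

#' Rater-score tables on disk
#'
#' CSV with header and columns `clip_id`, `rater_id`, `score`.
#'
#' @param df Long-format rater table.
#' @param path CSV path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_rater_table <- function(df, path) {
  stopifnot(all(c("clip_id", "rater_id", "score") %in% names(df)))
  write.csv(df[c("clip_id", "rater_id", "score")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rater_table
#' @export
read_rater_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("clip_id", "rater_id", "score") %in% names(df)))
  df
}

#' Feature and timeline tables on disk
#'
#' Features: one row per clip, columns `clip_id`, `n_lt50`, `n_50_75`,
#' `n_75_90`, `n_ge90`. Timelines: one row per frame, columns `clip_id`,
#' `frame_idx`, `visibility`, `smoothed`.
#'
#' @param df The table.
#' @param path CSV path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_features_csv <- function(df, path) {
  cols <- c("clip_id", "n_lt50", "n_50_75", "n_75_90", "n_ge90")
  stopifnot(all(cols %in% names(df)))
  write.csv(df[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_features_csv
#' @export
write_timeline_csv <- function(df, path) {
  cols <- c("clip_id", "frame_idx", "visibility", "smoothed")
  stopifnot(all(cols %in% names(df)))
  write.csv(df[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_timeline_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' CC-Clear feature table of a set of clips
#'
#' Bins each clip's visibility values into the four CC-Clear bands.
#'
#' @param clips List of `clip_phantom` objects, or a named list of numeric
#'   visibility vectors.
#' @return Data frame: `clip_id`, the four bin counts, `n_frames`.
#' @export
visibility_features <- function(clips) {
  rows <- lapply(seq_along(clips), function(i) {
    cl <- clips[[i]]
    if (inherits(cl, "clip_phantom")) {
      id <- cl$clip_id; v <- cl$truth_visibility
    } else {
      id <- names(clips)[i] %||% sprintf("clip_%03d", i); v <- cl
    }
    cbind(data.frame(clip_id = id), as.data.frame(t(bin_counts(v))),
          n_frames = length(v))
  })
  do.call(rbind, rows)
}

#' Write a synthetic dataset to disk
#'
#' Generates a balanced set of clips (classes cycled 0..3), simulated rater
#' scores, per-clip ground-truth visibility timelines, and — when
#' rendering — frames, truth masks, and a patch-label table, laid out as
#' the CLI and pipeline stages expect: `manifest.csv`, `raters.csv`,
#' `timelines.csv`, and per-clip `frames/<clip>/frame_NNNN.png` +
#' `masks/<clip>/frame_NNNN.png`, plus `patch_labels.csv`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_clips Number of clips; classes are assigned round-robin.
#' @param n_frames Frames per clip.
#' @param size Frame side length when rendering.
#' @param render Render frames and masks to PNG.
#' @param patches_per_frame Labelled patches sampled per rendered frame.
#' @param patch_size Patch side length.
#' @param n_raters,kernel Simulated-rater settings; see [simulate_raters()].
#' @param seed Integer seed; the whole dataset is deterministic in it.
#' @return Invisibly, a list with the generated `clips`, `rater_table`,
#'   `features`, and file paths.
#' @export
synth_dataset <- function(out_dir, n_clips = 8, n_frames = 30, size = 128,
                          render = TRUE, patches_per_frame = 4,
                          patch_size = 64, n_raters = 3,
                          kernel = rater_kernel(0.15), seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  classes <- rep(0:3, length.out = n_clips)
  clips <- lapply(seq_len(n_clips), function(i)
    generate_clip(n_frames, classes[i], render = render, seed = seed * 100 + i,
                  size = size, clip_id = sprintf("clip_%03d", i)))

  manifest <- data.frame(
    clip_id = vapply(clips, `[[`, character(1), "clip_id"),
    true_class = classes, n_frames = n_frames)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

  rater_table <- simulate_raters(classes, kernel = kernel,
                                 n_raters = n_raters, seed = seed + 1,
                                 clip_ids = manifest$clip_id)
  write_rater_table(rater_table, file.path(out_dir, "raters.csv"))

  timelines <- do.call(rbind, lapply(clips, function(cl)
    data.frame(clip_id = cl$clip_id,
               frame_idx = seq_len(cl$n_frames),
               visibility = cl$truth_visibility,
               smoothed = smooth_timeline(
                 cl$truth_visibility,
                 min(25, cl$n_frames - (1 - cl$n_frames %% 2))))))
  write_timeline_csv(timelines, file.path(out_dir, "timelines.csv"))

  features <- visibility_features(clips)
  write_features_csv(features, file.path(out_dir, "features.csv"))

  if (render) {
    plabs <- list()
    for (cl in clips) {
      fdir <- file.path(out_dir, "frames", cl$clip_id)
      mdir <- file.path(out_dir, "masks", cl$clip_id)
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      for (t in seq_len(cl$n_frames)) {
        fid <- sprintf("%s/frame_%04d", cl$clip_id, t)
        write_image_png(cl$frames[[t]],
                        file.path(out_dir, "frames", paste0(fid, ".png")))
        write_mask_png(cl$frames[[t]]$truth_mask,
                       file.path(out_dir, "masks", paste0(fid, ".png")))
        if (patches_per_frame > 0 && size >= patch_size) {
          ps <- sample_patches(c(size, size), c(patch_size, patch_size),
                               patches_per_frame,
                               seed = seed * 10000 + length(plabs) + t)
          ps$label <- vapply(seq_len(nrow(ps)), function(k)
            patch_label_from_mask(cl$frames[[t]]$truth_mask, ps[k, ]),
            integer(1))
          ps$frame_id <- fid
          plabs[[length(plabs) + 1L]] <- ps
        }
      }
    }
    if (length(plabs))
      write_patch_labels(do.call(rbind, plabs),
                         file.path(out_dir, "patch_labels.csv"))
  }

  invisible(list(clips = clips, rater_table = rater_table,
                 features = features, manifest = manifest,
                 dir = out_dir))
}

#' Run the full pipeline end-to-end on synthetic data
#'
#' Exercises every stage in sequence: generates a labelled training set of
#' frames, trains the patch-loss segmenter, generates rendered evaluation
#' clips, predicts per-frame masks and visibility, bins the CC-Clear
#' features, simulates raters, fits the individual and consensus scoring
#' models under leave-one-out, and writes the agreement report.
#'
#' @param out_dir Output directory for artifacts (timelines, features,
#'   raters, report JSON, a timeline plot).
#' @param seed Master seed; every random stage derives from it.
#' @param n_train_frames,train_size Training frames for the segmenter.
#' @param patches_per_frame,patch_size Patch supervision density and size.
#' @param n_clips,n_frames,clip_size Evaluation clips.
#' @param epochs Segmenter training epochs.
#' @param n_raters,kernel Simulated raters.
#' @param ... Passed to [loo_evaluate()] via [fit_modes()].
#' @return Invisibly, a list with `segmenter`, `features`, `modes`
#'   (`ccclear_fit`), `report` (`agreement_report`) and artifact paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_train_frames = 30,
                         train_size = 96, patches_per_frame = 6,
                         patch_size = 32, n_clips = 8, n_frames = 30,
                         clip_size = 96, epochs = 120, n_raters = 3,
                         kernel = rater_kernel(0.15), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: weakly supervised segmenter
  train <- with_seed(seed, runif(n_train_frames, 0.05, 0.7))
  frames <- lapply(seq_len(n_train_frames), function(i)
    generate_frame(train_size, train[i], blob_scale = 6,
                   seed = seed * 300 + i))
  ann <- sample_labeled_patches(frames,
                                n_total = n_train_frames * patches_per_frame,
                                patch_size = c(patch_size, patch_size),
                                seed = seed * 500)
  seg <- patch_segmenter(frames, ann$patches, ann$labels, epochs = epochs,
                         seed = seed)

  # stage 2: clips -> visibility -> features
  classes <- rep(0:3, length.out = n_clips)
  clips <- lapply(seq_len(n_clips), function(i)
    generate_clip(n_frames, classes[i], render = TRUE,
                  seed = seed * 700 + i, size = clip_size,
                  clip_id = sprintf("clip_%03d", i)))
  timelines <- do.call(rbind, lapply(clips, clip_visibility, model = seg))
  write_timeline_csv(timelines, file.path(out_dir, "timelines.csv"))
  vis_by_clip <- split(timelines$visibility, timelines$clip_id)
  features <- visibility_features(vis_by_clip[unique(timelines$clip_id)])
  write_features_csv(features, file.path(out_dir, "features.csv"))
  timeline_report(timelines[timelines$clip_id == features$clip_id[1], ],
                  file.path(out_dir, "timeline_clip_001.png"))

  # stage 3: raters, LOO scoring, agreement
  rater_table <- simulate_raters(classes, kernel = kernel,
                                 n_raters = n_raters, seed = seed + 1,
                                 clip_ids = features$clip_id)
  write_rater_table(rater_table, file.path(out_dir, "raters.csv"))
  modes <- fit_modes(features, rater_table, seed = seed, ...)
  report <- agreement_report(rater_table, modes)
  write_agreement_report(report, file.path(out_dir, "agreement.json"))

  invisible(list(segmenter = seg, features = features, modes = modes,
                 report = report, dir = out_dir))
}

#' Reference score counts and agreement statistics
#'
#' Loads the published per-physician CC-Clear score counts and the
#' pairwise / model agreement kappas from the motivating clinical study of
#' 52 capsule-endoscopy clips, shipped with the package as plain CSV. These
#' are inputs for reproducing that study's summary arithmetic (score means
#' and standard deviations, mean pairwise and mean model kappas); they are
#' not outputs of this package's models.
#'
#' @return `reference_score_counts()`: data frame `rater_id`, `n0`–`n3`.
#'   `reference_kappas()`: data frame `kind` (`pairwise`, `model`,
#'   `consensus`), `name`, `value`.
#' @export
reference_score_counts <- function() {
  read.csv(system.file("extdata", "physician_score_counts.csv",
                       package = "capclear"), stringsAsFactors = FALSE)
}

#' @rdname reference_score_counts
#' @export
reference_kappas <- function() {
  read.csv(system.file("extdata", "reference_kappas.csv",
                       package = "capclear"), stringsAsFactors = FALSE)
}

#' Summary table of the reference study statistics
#'
#' Recomputes, from the shipped reference inputs, the per-physician score
#' means and standard deviations and the mean pairwise / mean individual
#' model kappas, i.e. the derivable summary arithmetic of the motivating
#' study.
#'
#' @return List with `score_summaries` (data frame) and `kappas` (named
#'   list: `pairwise`, `mean_pairwise`, `model`, `mean_model`,
#'   `consensus`).
#' @export
reference_summary <- function() {
  counts <- reference_score_counts()
  sums <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    s <- score_summary_from_counts(as.numeric(counts[i, c("n0", "n1", "n2", "n3")]))
    data.frame(rater_id = counts$rater_id[i], n = s$n, mean = s$mean,
               sd_population = s$sd_population, sd_sample = s$sd_sample)
  }))
  k <- reference_kappas()
  pw <- setNames(k$value[k$kind == "pairwise"], k$name[k$kind == "pairwise"])
  md <- setNames(k$value[k$kind == "model"], k$name[k$kind == "model"])
  list(score_summaries = sums,
       kappas = list(pairwise = pw, mean_pairwise = mean_kappa(pw),
                     model = md, mean_model = mean_kappa(md),
                     consensus = k$value[k$kind == "consensus"]))
}
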