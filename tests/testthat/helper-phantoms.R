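# Shared fixtures, built in code once per test run.

# small labelled training corpus for segmenter tests
make_training_corpus <- function(n_frames = 20, size = 64, patch = 16,
                                 n_patches = 120, seed = 11) {
  fracs <- with_seed(seed, runif(n_frames, 0.05, 0.7))
  frames <- lapply(seq_len(n_frames), function(i)
    generate_frame(size, fracs[i], blob_scale = 4, seed = seed * 1000 + i))
  ann <- sample_labeled_patches(frames, n_patches,
                                patch_size = c(patch, patch),
                                seed = seed * 13)
  list(frames = frames, patches = ann$patches, labels = ann$labels)
}

with_seed <- capclear:::with_seed

# independent elementwise cross-entropy oracle: broadcast the patch label
# to every patch pixel and sum naive scalar BCE terms
oracle_patch_loss <- function(prob_maps, patches, labels, eps = 1e-7) {
  if (is.matrix(prob_maps)) prob_maps <- rep(list(prob_maps), nrow(patches))
  total <- 0
  for (k in seq_len(nrow(patches))) {
    p <- patches[k, ]
    acc <- 0
    for (i in seq_len(p$h)) {
      for (j in seq_len(p$w)) {
        pr <- prob_maps[[k]][p$y0 + i, p$x0 + j]
        pr <- min(max(pr, eps), 1 - eps)
        acc <- acc - (labels[k] * log(pr) + (1 - labels[k]) * log(1 - pr))
      }
    }
    total <- total + acc
  }
  total / nrow(patches)
}

# first-principles kappa: explicit contingency counting
oracle_kappa <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (k in cats) pe <- pe + (sum(a == k) / n) * (sum(b == k) / n)
  (po - pe) / (1 - pe)
}
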