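---
title: "Weakly supervised cleanliness scoring for colon capsule endoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised cleanliness scoring for colon capsule endoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capclear)
```

## The problem

Colon capsule endoscopy (CCE) produces tens of thousands of frames per
procedure. Before any diagnostic reading, the video must be judged
*admissible*: residual stool, debris, bile and bubbles — intraluminal
content — can obscure the mucosa and hide pathology. The CC-Clear scale
grades cleanliness 0–3 from the percentage of visible colonic mucosa
(0 = almost no visible mucosa, 3 = clean beyond doubt). Scoring is
subjective; chance-corrected agreement between experienced readers is only
moderate, which is precisely what makes an automated, transparent score
useful.

capclear implements a three-stage pipeline that scores 10-minute video
segments while requiring only *weak* annotation — binary dirty/clean labels
on 64×64 patches, never full segmentation masks:

1. an image→mask occlusion segmenter trained with a patch-restricted
   cross-entropy (the *patch loss*);
2. per-frame mucosa *visibility* inside the circular field of view,
   aggregated into four CC-Clear frame-count features per clip;
3. a depth-limited random forest scoring clips 0–3 under leave-one-out
   cross-validation, evaluated against raters with Cohen's kappa.

Because clinical capsule data cannot be redistributed, the package ships a
synthetic phantom generator with exact ground truth; every stage is
developed and tested against it.

## Stage 1: segmentation from patch labels

### The patch loss

An annotator looks at a 64×64 patch $P_k$ of frame $X_k$ and answers one
question: could the content in this patch hide pathology? That yields a
binary label $y_k$. The segmenter $f$ outputs a per-pixel content
probability map; training broadcasts each patch's label to every pixel it
covers:

$$\mathrm{PatchLoss} \;=\; -\frac{1}{B}\sum_{k=1}^{B}
  \sum_{(i,j) \in P_k}\Big[\,y_k \log p_k(i,j) + (1-y_k)\log\big(1-p_k(i,j)\big)\Big]$$

with $B$ the batch size and $p_k(i,j)$ the predicted probability at pixel
$(i,j)$. Pixels outside every labelled patch contribute nothing — the loss
(and its gradient, see `patch_loss_gradient()`) is exactly local to the
labelled windows. `patch_loss()` implements the summed form above
(`reduce = "sum"`); `reduce = "mean"` divides each patch term by its area,
which keeps magnitudes comparable across patch sizes and is what the
training loop optimises (for same-size patches the two have the same
minimiser). Probabilities are clamped to $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-7}$ before the logarithms.

### What a pointwise weak loss can and cannot learn

The broadcast-label loss is pointwise, so its population minimiser at a
pixel with feature vector $x$ is $\Pr(\text{patch label} = 1 \mid x)$ —
the posterior of the *patch's* label, not of the pixel's own class. Two
design consequences follow, both visible empirically in this package's
development experiments:

* **Features must stay pixel-local.** If the features see far beyond the
  pixel (wide smoothing kernels), the model can estimate how much of the
  surrounding patch is occluded and fit the labelling rule itself: content
  pixels in sparsely occluded regions are pushed below the 0.5 decision
  threshold and the thresholded mask collapses. With colour-only features
  the same training data yields near-perfect masks. The default backbone
  therefore uses each pixel's RGB plus RGB smoothed at σ = 1.5 px only.
* **Label prevalence must not be skewed.** The posterior level (and hence
  where it sits relative to the fixed 0.5 threshold) tracks the dirty/clean
  mix of the annotation. `sample_labeled_patches()` therefore emulates an
  annotator who labels a corpus-level class-balanced patch set — half
  dirty, half clean — a standard dataset-construction practice. The loss
  itself is untouched.

### Backbone

The backbone is a multiscale pixel-colour logistic model (optionally one
small tanh hidden layer, `hidden > 0`), fitted by full-batch Adam
(learning rate 0.1, 150 epochs by default) on the exact loss above. It is
deliberately tiny: the scientific content exercised here is the
supervision scheme, not backbone capacity, and a pixel-level model runs on
one CPU core in seconds. The training history (mean-reduced patch loss per
epoch, element 1 = before any update) is stored in the fit and plotted by
`plot()`. An untrained model (`epochs = 0`) predicts probability 0.5
everywhere, which under the strict threshold yields an empty mask — the
natural ignorant baseline.

### Post-processing

`postprocess()` smooths the probability map with a Gaussian kernel of
standard deviation 0.4 px and keeps pixels whose activation is *strictly*
greater than 0.5. Both values are configurable; σ is interpreted as a
standard deviation in pixels (the only self-consistent reading of a
"kernel of size 0.4"), and a constant field exactly at the threshold maps
to an empty mask.

### Evaluation protocols

`evaluate_miou()` scores predicted against true binary masks with the
positive-class intersection-over-union, averaged per image, with the
convention IoU = 1 when prediction and truth are both empty (a correct
all-clean frame should score perfectly; without this convention all-clean
frames are undefined). `evaluate_patch_classification()` treats the
segmenter as a patch classifier: a patch is predicted dirty when the
thresholded mask covers at least 50% of it (inclusive), and the continuous
score for the AUC is the mean in-patch probability (the natural choice;
any monotone summary of the in-patch probabilities would do). The
comparison baseline `tile_baseline()` is the classify-patches-then-tile
strategy: a logistic patch classifier on mean patch colour painted over a
non-overlapping 64-px tiling, which by construction cannot follow content
boundaries within a tile.

## Stage 2: visibility and CC-Clear features

Capsule frames have a bright circular field of view (FOV) over black
corners; all area statistics exclude the corners. `compute_fov_mask()`
thresholds the per-pixel maximum channel (default > 10 of 255) after 3×3
median denoising; for synthetic phantoms the estimated mask agrees with
the generator's geometric FOV on ≥ 99% of pixels. The per-frame
visibility is

$$v = 1 - \frac{|\,\mathrm{mask} \cap \mathrm{FOV}\,|}{|\mathrm{FOV}|},$$

the clean fraction of the imaged area. A clip's visibility timeline is
smoothed for display with a centered moving average (default window 25
frames, truncated at the edges; the window length is a display choice).
`bin_counts()` counts frames in the four CC-Clear bands — below 50%,
50–75%, 75–90%, and 90% or above. The verbal band definitions overlap at
their edges; capclear resolves them as a partition of $[0,1]$ with every
boundary belonging to the upper band (so 90% counts as the cleanest band).
Features are raw frame counts, not fractions, matching fixed-length clips;
`normalize = TRUE` in the classifier divides by clip length for
variable-length use. Frame counting uses the raw (unsmoothed) visibility
by default; the smoothed curve drives only the colour banding of
`timeline_report()`.

## Stage 3: clip scoring and agreement

`loo_evaluate()` fits a random forest — 100 trees, maximum depth 2, a
deliberately shallow setting for 52-clip samples — on the four features
under leave-one-out cross-validation: each clip is predicted by a forest
that never saw it. Two training modes mirror clinical practice
(`fit_modes()`): one model per rater, and one model on the consensus
score, the per-clip mean rating rounded to the nearest integer (halves,
which can only arise for even rater counts, round away from zero; with
three raters the mean is a multiple of 1/3 and the case never occurs).
The forest is unweighted; real score distributions are skewed toward
class 2, but the motivating protocol does not state any class weighting,
so none is applied.

`cohens_kappa()` is the unweighted chance-corrected agreement
$\kappa = (p_o - p_e)/(1 - p_e)$; linear and quadratic weights are
available behind a flag for ordinal sensitivity analysis but are used
nowhere by default. `summarize_scores()` reports both population and
sample standard deviations, since published "±" values do not always say
which convention they use.

## The synthetic phantom generator

`generate_frame()` emulates the geometry and photometry that the pipeline
actually relies on, nothing more:

* an inscribed circular FOV of radius 0.48 × side, corners near-black
  (channel values 0–5 with tiny noise);
* pink mucosa (RGB ≈ 190/110/110) with low-frequency texture;
* yellow-brown content (RGB ≈ 180/140/60) in irregular blobs built by
  thresholding Gaussian-smoothed white noise at the coverage quantile —
  the resulting ragged, ill-defined borders are the qualitative feature
  that makes real content hard to segment;
* exact bookkeeping: the occluded fraction of the FOV equals the target to
  within one pixel, and `dirty_fraction` is computed from the stored
  masks, not the target.

`generate_clip()` draws a per-frame visibility trajectory as a bounded
random walk confined to the class band (class 0 → below 0.5, 1 →
0.5–0.75, 2 → 0.75–0.90, 3 → 0.90 and above), plus absolute per-frame
observation noise of 0.025 for the extreme classes and 0.05 for the
central ones — the central classes are noisier because that is the
pattern real readers produce: fully clean or fully obscured segments are
scored homogeneously, intermediate cleanliness is ambiguous between
adjacent classes. Rendered clips generate one frame phantom per time step
with occluded fraction 1 − visibility. `simulate_raters()` draws ordinal
scores from a row-stochastic 4×4 confusion kernel (default: 0.15 spilled
to each adjacent score); the identity kernel reproduces the truth exactly.

What the generator does *not* emulate — and hence what passing tests do
not establish about clinical data: photorealistic appearance, bubbles and
bile as distinct content types, capsule motion and adaptive frame rate,
dual-camera geometry, illumination drift, and content whose colour
overlaps the mucosa. On phantoms the colour separation is strong, so
segmentation accuracy saturates; the synthetic benchmark validates the
*mechanics* of weak-label recovery (that patch-level supervision alone
drives dense masks from near-zero to near-truth), not clinical-grade
accuracy.

## Numerical choices and edge cases

* Patch coordinates are 0-based with half-open extents
  $[x_0, x_0+w) \times [y_0, y_0+h)$; stated once, used everywhere.
* Probability clamping $\varepsilon = 10^{-7}$; coverage comparisons are
  inclusive (≥ 0.5 is dirty), activation thresholding is strict (> 0.5).
* The untrained logistic backbone starts at exactly zero weights
  (probability 0.5); hidden layers use small seeded Gaussian
  initialisation.
* Empty-vs-empty IoU = 1; an empty FOV is an error, never a silent 0/0.
* All generators and fits take an explicit integer seed and are
  bit-reproducible; generator functions restore the caller's RNG state.
* A leave-one-out fold whose training set is single-class predicts that
  class and warns rather than failing.

## Problem sizes used by the tests and acceptance script

The package validates itself at desk scale, chosen so the whole suite runs
on one CPU core in minutes: segmenter benchmarks use 60 training frames of
128×128 px with 8 labelled 64×64 patches each (480 patches,
corpus-balanced) and 20 held-out frames; clip benchmarks use 52 clips of
200 frames, 13 per class, mirroring the 52-video LOO design of the
motivating protocol; permutation nulls use 100 permutations.

## A note on the leave-one-out permutation null

The chance-floor check — re-running LOO after permuting the 52 targets —
does not centre on zero. With a balanced label vector, every held-out
clip's class has 12 training examples against 13 for each other class, so
any classifier sensitive to training marginals is biased *against* the
held-out label. Empirically the null kappa distribution has mean ≈ −0.08
and standard deviation ≈ 0.11, and the effect is identical with pure
noise features, i.e. it is a property of leave-one-out under permutation,
not of the features or the forest. Consequently about 15–20% of permuted
runs fall below κ = −0.2. Users building permutation tests on LOO
pipelines should centre the null empirically rather than assuming
symmetry around zero.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
# train a segmenter from weak labels on synthetic frames
fracs <- runif(20, 0.05, 0.7)
frames <- lapply(seq_along(fracs), function(i)
  generate_frame(64, fracs[i], blob_scale = 4, seed = 100 + i))
ann <- sample_labeled_patches(frames, 120, patch_size = c(16, 16), seed = 2)
fit <- patch_segmenter(frames, ann$patches, ann$labels, epochs = 100, seed = 1)
fit

# score 52 synthetic clips under leave-one-out
classes <- rep(0:3, each = 13)
clips <- lapply(seq_along(classes), function(i)
  generate_clip(200, classes[i], seed = 200 + i,
                clip_id = sprintf("clip_%03d", i)))
feats <- visibility_features(clips)
rt <- simulate_raters(classes, kernel = rater_kernel(0.15), n_raters = 3,
                      seed = 3, clip_ids = feats$clip_id)
modes <- fit_modes(feats, rt, seed = 1)
agreement_report(rt, modes)
```

The end-to-end path (`run_pipeline()`) chains every stage — synthetic
training set, patch-loss training, rendered clips, mask prediction,
visibility, features, simulated raters, LOO scoring, agreement report —
and writes all intermediate artifacts as CSV/PNG/JSON.

## Known limitations

* The backbone is a pixel-colour model; it cannot exploit shape or
  texture context, which clinical content segmentation would need.
* The generator's colour separation makes segmentation easier than
  clinical reality; synthetic accuracy figures are mechanics checks, not
  clinical estimates.
* Kappa is unweighted by default; for an ordinal scale a weighted kappa
  arguably reflects near-miss disagreements better, and is available but
  not used in the headline numbers.
* Only complete rater tables are supported; missing scores are an error,
  not an imputation problem this package tries to solve.
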