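# capclear

Weakly supervised cleanliness scoring for colon capsule endoscopy (CCE)
video segments.

Before a capsule video can be read diagnostically it must be judged
admissible: residual stool, debris, bile and bubbles can obscure the
mucosa and hide pathology. The CC-Clear scale grades cleanliness 0–3 from
the percentage of visible colonic mucosa, but human scoring is subjective
and inter-reader agreement is only moderate. capclear implements a
pipeline that scores 10-minute clips automatically while requiring only
*weak* annotation — binary dirty/clean labels on 64×64 patches, never full
segmentation masks — and that justifies each score with a per-frame
visibility timeline.

## The method

**1. Segmentation from patch labels.** An image→mask model is trained with
the *patch loss*, a cross-entropy restricted to labelled patches with each
patch's binary label y_k broadcast to every pixel it covers:

    PatchLoss = -(1/B) Σ_k Σ_{(i,j)∈P_k} [ y_k log p_k(i,j) + (1−y_k) log(1 − p_k(i,j)) ]

Pixels outside every labelled patch contribute nothing, so dense masks are
learned from sparse binary supervision. Masks are post-processed with a
Gaussian blur (σ = 0.4 px) and a strict 0.5 threshold.

**2. Visibility features.** Each frame's visibility is the clean fraction
of the circular field of view, v = 1 − |mask ∩ FOV| / |FOV| (black corners
excluded). A clip's timeline is binned into the four CC-Clear bands —
<50%, 50–75%, 75–90%, ≥90% — giving a 4-dimensional frame-count feature
vector.

**3. Clip scoring and agreement.** A random forest (100 trees, maximum
depth 2) maps features to CC-Clear scores 0–3 under leave-one-out
cross-validation, trained either per rater or on the consensus score
(mean rating rounded to the nearest integer). Agreement is measured with
unweighted Cohen's kappa, κ = (p_o − p_e)/(1 − p_e).

A synthetic phantom generator (frames with exact ground-truth masks,
clips with known visibility trajectories, simulated raters with a
confusion kernel) makes every stage testable without clinical data.

## Worked example

```r
library(capclear)
set.seed(1)

# ---- stage 1: train a segmenter from weak patch labels ----
fracs  <- runif(20, 0.05, 0.7)
frames <- lapply(seq_along(fracs), function(i)
  generate_frame(64, fracs[i], blob_scale = 4, seed = 100 + i))
ann <- sample_labeled_patches(frames, 120, patch_size = c(16, 16), seed = 2)
fit <- patch_segmenter(frames, ann$patches, ann$labels, epochs = 100, seed = 1)
fit
#> Patch-loss segmenter (multiscale pixel logistic backbone)
#>   trained on 120 labelled patches, 100 epochs
#>   patch loss (mean-reduced): 0.69315 -> 0.53849

# ---- stages 2–3: score 52 synthetic clips under leave-one-out ----
classes <- rep(0:3, each = 13)
clips <- lapply(seq_along(classes), function(i)
  generate_clip(200, classes[i], seed = 200 + i,
                clip_id = sprintf("clip_%03d", i)))
feats <- visibility_features(clips)
rt <- simulate_raters(classes, kernel = rater_kernel(0.15), n_raters = 3,
                      seed = 3, clip_ids = feats$clip_id)
modes <- fit_modes(feats, rt, seed = 1)
agreement_report(rt, modes)
#> Agreement report (Cohen's kappa)
#>   pairwise raters:
#>     R1:R2      0.489
#>     R1:R3      0.666
#>     R2:R3      0.465
#>     mean       0.540
#>   individual models vs their raters:
#>     R1         0.742
#>     R2         0.488
#>     R3         0.768
#>     mean       0.666
#>   consensus model    0.949
```

Reading the output: the training loss falls from ln 2 (the ignorant
0.5-probability model) as the segmenter learns content appearance from
patch labels alone. The three simulated raters agree with each other only
moderately (mean pairwise κ 0.540, by construction of the noise kernel),
while the models trained to replicate them agree with their raters more
strongly (mean κ 0.666), and the consensus-trained model agrees with the
consensus score best of all (κ 0.949) — the qualitative pattern the
pipeline is designed to exhibit. `timeline_report()` renders any clip's
visibility timeline with the CC-Clear colour banding, and
`run_pipeline()` chains all stages end-to-end, writing CSV/PNG/JSON
artifacts.

A command-line front end is included at `inst/cli/capclear.R` with
subcommands `synth`, `train`, `segment`, `visibility`, `score`, `report`
and `pipeline`.

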