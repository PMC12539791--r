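# atlaswarp

Self-supervised atlas-based segmentation of single anatomical structures
in 3D CT volumes, for image-analysis researchers who have exactly one
annotated reference scan (an *atlas*) and a cohort of unlabelled,
affinely pre-aligned target scans. The motivating use case is
segmenting small, high-contrast structures such as the internal auditory
canal, where per-case manual labels are impractical but one carefully
annotated atlas exists.

## Method

A 3D U-Net-style network maps a single-channel target volume $T$
(cropped to an isotropic cube) to a dense displacement field $u$,
defining the deformation $\varphi(x) = x + u(x)$ from atlas to target
coordinates. The atlas mask transferred through $\varphi$ segments the
target. Training is fully self-supervised with the composite loss

$$\mathcal{L} = \omega_{cc}\,\mathcal{L}_{cc}
  + \omega_{grad}\,\mathcal{L}_{grad}
  + \omega_{wgrad}\,\mathcal{L}_{wgrad}
  + \omega_{MS}\,\mathcal{L}_{MS}$$

* $\mathcal{L}_{cc} = \tfrac12 - \tfrac{r}{2}$ — $r$ the global Pearson
  correlation between the pulled-back target $\varphi^{-1}(T)$ and the
  atlas image;
* $\mathcal{L}_{grad} = \tfrac{1}{3N}\sum_i \lVert\nabla u_i\rVert^2$ —
  displacement smoothness;
* $\mathcal{L}_{wgrad} = \tfrac{1}{3N}\sum_i \lVert W_i \nabla u_i\rVert^2$
  — smoothness concentrated near the structure boundary via a weight map
  $W \in [0.5, 1]$ built from the signed Euclidean distance map of the
  atlas mask (thresholds 1 and 4 mm);
* $\mathcal{L}_{MS} = \sigma^2_{int} + \sigma^2_{ext}$ — a
  Mumford–Shah/Chan–Vese-style region-variance term: the transferred
  mask should cover an intensity-homogeneous region.

Everything is implemented from first principles in R + Rcpp (including
the network's forward/backward passes, verified against finite
differences); evaluation provides Dice and symmetric 95th-percentile
Hausdorff distance with optional exclusion regions, paired t-tests, a
greedy two-stage loss-weight sweep, a seeded multi-trial median
protocol, and a phantom generator so the whole pipeline runs offline.
See `vignettes/atlaswarp-methods.Rmd` for the full methods account.

## Worked example

A fully synthetic end-to-end run on the built-in phantom world — an
ellipsoid "structure" (interior intensity 0.25, background 0.75, noise
0.05) on a 32^3 cube, 16 targets deformed by random smooth fields with
3-voxel maximum displacement:

```r
library(atlaswarp)

atlas  <- make_atlas(phantom_spec(seed = 7))          # atlas + masks + maps
cohort <- make_cohort(atlas, cohort_spec(seed = 7))   # 16 deformed targets

base <- baseline_metrics(cohort, atlas)               # identity transform
cfg  <- train_config(seed = 42, epochs = 25, learning_rate = 8e-4,
                     lr_final = 8e-5,
                     weights = loss_weights(1, 0, 0.5, 0.5),
                     spec = unet_spec(levels = 4, base_channels = 16))
res  <- train(NULL, lapply(cohort, `[[`, "target"), atlas, cfg)
ev   <- evaluate_cohort(res$model, cohort, atlas)

base$summary
#>   metric    median         sd
#> 1   dice 0.8625576 0.03520633
#> 2   hd95 1.4142136 0.35097449
ev$summary
#>   metric    median         sd
#> 1   dice 0.9184368 0.01181536
#> 2   hd95 0.9668608 0.04029022
```

Reading: before deformable registration (affine/identity baseline) the
atlas mask overlaps the deformed ground-truth masks at median Dice 0.86
with a 1.41 mm median 95th-percentile Hausdorff distance; after 400
self-supervised training steps (weights 1.0 similarity, 0.5
boundary-weighted smoothness, 0.5 region variance; Adam with a cosine
step-size decay) the network's segmentations reach median Dice 0.92 and
cut the surface error to 0.97 mm. (25 epochs × 16 targets = 400
parameter updates; ~6 minutes on one CPU. Runs are bitwise reproducible
for a fixed seed on a given machine.)

A command-line front end with `synth`, `preprocess`, `train`, `segment`
and `evaluate` subcommands is installed at `inst/cli/atlaswarp.R`
(`system.file("cli", "atlaswarp.R", package = "atlaswarp")`).

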