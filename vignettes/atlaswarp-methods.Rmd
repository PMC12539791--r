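---
title: "Methods: self-supervised atlas-based segmentation with a region-variance loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised atlas-based segmentation with a region-variance loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`atlaswarp` segments a single anatomical structure in 3D CT volumes by
deformable registration against one annotated reference volume (the
*atlas*). A convolutional network takes a single-channel target volume
$T$ on an isotropic cube grid and regresses a dense displacement field
$u$, defining the deformation $\varphi(x) = x + u(x)$ from atlas
coordinates to target coordinates. The pull-back
$\varphi^{-1}(T)(x) = T(x + u(x))$ resamples the target onto the atlas
grid; the atlas mask, pushed the other way through $\varphi$, becomes the
segmentation of the target. Training needs no per-case labels: the loss
is computed from the images and the (fixed) atlas annotations alone.

The composite training loss is

$$
\mathcal{L} \;=\; \omega_{cc}\,\mathcal{L}_{cc}
 \;+\; \omega_{grad}\,\mathcal{L}_{grad}
 \;+\; \omega_{wgrad}\,\mathcal{L}_{wgrad}
 \;+\; \omega_{MS}\,\mathcal{L}_{MS},
$$

with the following terms, each exposed as its own function and each
differentiable with respect to the field:

* **Image similarity** `loss_cc`: $0.5 - r/2$, where $r$ is the global
  Pearson correlation between $\varphi^{-1}(T)$ and the atlas image over
  all voxels. It is 0 for a perfect positive linear intensity relation
  and 1 for a perfect negative one. We read the similarity as a *global*
  correlation: the defining expression is a single inner product of
  mean-centred volumes over the product of their norms, with no window.
  A local/windowed NCC variant is a known alternative in this framework
  family; a window option is deliberately not implemented until needed
  (see Limitations).
* **Smoothness** `loss_grad`: the mean squared gradient magnitude of the
  displacement, $\frac{1}{3N}\sum_i \lVert \nabla u_i \rVert^2$, with
  central finite differences in voxel units and replicate borders. The
  gradient is taken of the *displacement* $u$, not of $\varphi = \mathrm{id} + u$,
  so the identity transform incurs zero penalty; the two readings differ
  only by a constant under the summed Frobenius norm.
* **Boundary-weighted smoothness** `loss_wgrad`:
  $\frac{1}{3N}\sum_i \lVert W_i \nabla u_i \rVert^2$. The weight map
  $W = 0.5 + \frac{t_U - \max(t_L, \min(t_U, |D|))}{2\,(t_U - t_L)}$
  derives from the signed Euclidean distance map $D$ of the atlas mask:
  $W = 1$ on the boundary, decaying linearly to $0.5$ at $|D| \ge t_U$.
  Since $W$ is a scalar per voxel, it enters the squared norm as $W^2$.
  Defaults $t_L = 1$ mm and $t_U = 4$ mm. $D$ and $W$ depend only on the
  atlas segmentation, so they are computed once and cached in the
  `atlas_bundle`.
* **Region variance** `loss_ms`: the Mumford–Shah/Chan–Vese-style term
  $\sigma^2_{int} + \sigma^2_{ext}$, the population variances (divide by
  count, not $n-1$) of the warped target's intensities inside and
  outside the atlas mask. It rewards deformations that place the
  transferred mask on an intensity-homogeneous region — the actual
  segmentation objective — rather than rewarding whole-volume alignment.
  When arbitrary (non-anatomical) boundaries exist in the annotation, a
  distinct, e.g. tissue-based, `ms_mask` can be supplied so the variance
  term does not try to align arbitrary boundaries with visible ones.

Named weight presets: `vxm` $(1, 1, 0, 0)$ — the plain registration
loss; `iac` $(1, 0.5, 0, 0.5)$; `segthor` $(1, 1, 0, 0.5)$; `hkits21`
$(1, 0, 2, 0.5)$, the last using the boundary-weighted smoothness.

## Preprocessing

Targets are assumed affinely pre-aligned to the atlas (the affine is
consumed, not computed; `crop_to_cube()` accepts an optional 4×4 world
affine). The pipeline is: window-normalize intensities
($T \mapsto (T - i_{min})/(i_{max} - i_{min})$, out-of-window values
retained), then crop/resample to an isotropic cube (default $64^3$)
centred on the atlas-mask centroid, with trilinear interpolation for
images, nearest-neighbour for masks, and out-of-volume samples filled
with the mean of the in-bounds samples of that crop. Because a fixed
mm-per-voxel cube is specified while native spacings vary, the crop
*resamples* rather than merely extracts. When no hand-picked window is
available, `estimate_window()` substitutes the pooled 1st/99th
percentiles of the training cohort — robust, documented, and always
overridable.

## Network and training

The network is a 3D U-Net-style regressor: an initial 3³ convolution at
full resolution, three encoder levels (2× max-pool + convolution), three
decoder levels (2× up-sample + skip concatenation + convolution), and a
final convolution producing the 3-channel displacement directly — no
affine head, no velocity-field integration. Channels default to
16→32→64→128 with LeakyReLU (slope 0.2) activations. The final layer's
weights are scaled by $10^{-5}$ at initialization so training starts at
(approximately) the identity transform, which stabilizes the first
self-supervised steps.

Implementation notes, all deliberate:

* Forward and backward passes are hand-written (im2col + BLAS `gemm` in
  compiled code); every analytic gradient — trilinear-sampling position
  derivatives, the central-difference adjoints of the smoothness terms,
  the correlation and variance derivatives, and all layer backwards — is
  verified against central finite differences in the test suite.
* Decoder up-sampling defaults to nearest-neighbour 2× repetition, whose
  adjoint is exact summation; a half-voxel-aligned trilinear variant with
  its exact adjoint is available (`unet_spec(upsample = "trilinear")`).
  On the phantom world, nearest converges measurably faster within short
  (≤ 400 step) budgets, which is why it is the default.
* The convolution forward/backward gemms run in single precision (as is
  standard for networks of this kind); parameters, optimizer state, losses
  and their gradients stay double. Runs remain bitwise reproducible for a
  fixed seed on a given machine.
* Optimizer: Adam, default learning rate $10^{-4}$, batch size 1, with
  an optional cosine step-size decay (`lr_final`) and linear warmup
  (`lr_warmup`). None of these are pinned by the method; they are
  standard for the family. The phantom experiments in the tests use
  $8\times10^{-4}$ decaying to $8\times10^{-5}$, chosen by a small
  learning-rate sweep as appropriate for the short (≤ 400 step)
  desk-scale budgets there; constant rates above $\sim10^{-3}$
  destabilize the first self-supervised epochs.
* Out-of-grid samples replicate the border during warping: the cube
  crop's mean-fill already handled field-of-view issues, and replication
  introduces no new intensity levels.
* Mask transfer to target space inverts the field by the fixed-point
  iteration $v_{k+1}(y) = -\tilde u(y + v_k(y))$ (20 iterations,
  0.05-voxel mean-update tolerance; non-convergence is flagged, not
  fatal), then samples the atlas mask nearest-neighbour. Surfaces go the
  forward way: mesh vertices are mapped by $p \mapsto p + \tilde u(p)$.

### Hyperparameter sweep and trial protocol

`greedy_sweep()` reproduces the two-stage greedy search: with the
similarity weight fixed at 1.0, stage 1 sweeps the smoothness weight
over $\{0.1, 0.5, 1, 2, 10\}$ with the region-variance weight at 0;
stage 2 fixes the stage-1 winner and sweeps the region-variance weight
over the same grid — exactly $2 \times |grid|$ trainings. Ties resolve
to the smaller candidate (deterministic). The validation score is the
cohort-median Dice, matching how results are reported.

`repeat_and_summarize()` implements the five-trial protocol: trials use
seeds $s, s+1, \dots$ (the protocol seeds "a constant" per trial yet
runs distinct trials; distinct derived seeds reconcile both), and
metrics are median-aggregated per case across trials, then across the
cohort. R's `median()` (mid-mean for even counts) is the documented
convention. `seed_everything()` reseeds the single global RNG stream;
since the compiled code draws no random numbers and runs single-threaded,
identical configurations are bitwise reproducible on one CPU.

## Evaluation

* **Dice**: $2|P \cap G| / (|P| + |G|)$ over voxels, computed after
  removing any exclusion-region voxels *from both masks* — the only
  symmetric reading of "excluded from the metrics". An exclusion region
  covers annotation stretches with no true anatomical boundary.
* **95HD**: the method names the metric but not the estimator; ours is
  vertex-based and symmetric: pool the two directed vertex-to-nearest-
  vertex distance sets and take the 95th percentile with linear
  interpolation, in mm. A quadratic all-pairs oracle pins the estimator
  down in the tests. Excluded vertices are dropped from both meshes.
* **Surfaces**: `extract_surface()` builds the exact voxel-boundary
  isosurface (each foreground voxel face adjacent to background becomes
  two triangles; watertight, Euler characteristic 2 for genus-0 masks).
  A marching-cubes surface would be smoother but needs a 256-case table
  that buys nothing for these metrics; the blocky surface is exact for
  the 0/1 masks it represents, at half-voxel resolution.
* `paired_ttest()` wraps the two-sided dependent t-test for paired
  samples.

## The phantom world

`make_atlas()` / `make_cohort()` generate a fully synthetic world so
every module is testable offline: an ellipsoid (or bent-tube, canal-like)
interior of mean intensity 0.25 on a 0.75 background — normalized-CT-like
units, separability $|\mu_{int} - \mu_{ext}| > 3\sigma_{noise}$ as the
region-variance term assumes — plus a few distractor blobs placed at
least $t_U$ from the shape boundary (so the weight map's high-weight band
covers only true boundary), and Gaussian noise ($\sigma = 0.05$).
Deformed targets are built by forward simulation: draw a random smooth
field (white noise, Gaussian-smoothed at scale 6 voxels, rescaled to a
3-voxel maximum displacement), push the atlas image through its
approximate inverse, add fresh noise; the ground-truth mask is the atlas
mask transferred through the field. By construction, pulling a target
back through its ground-truth field recovers the atlas, mirroring the
training objective's fixed-atlas geometry and giving a known-good field
for recovery tests.

The random-field smoothing uses *circular* (wrap-around) padding so the
smoothed noise is statistically stationary across the cube. With
replicate padding the border variance dominates, the max-normalization
is then set by border voxels, and the interior — where the structure
lives — barely deforms, producing degenerate cohorts whose identity
baseline is unbeatable. Stationary fields with a 3-voxel maximum
displacement yield identity-baseline median Dice around 0.86 on the
default $32^3$ phantom: clearly beatable, clearly non-trivial.

What a green phantom test does establish: the losses, their gradients,
the optimization loop, the mask/surface transfer, and the metrics all
interlock correctly, and the composite loss actually drives Dice above
the affine baseline at desk scale. What it does not establish: real-CT
performance — the phantom has no beam hardening, no metal artifacts, no
anatomical shape variability, and its deformations come from the same
family the method's smoothness prior favours.

## Numerical choices and degenerate inputs

* Correlation is undefined for constant volumes; `loss_cc` errors rather
  than returning an arbitrary value. Likewise `ms_stats` with an empty
  foreground or background, `signed_distance` on empty/full masks, and
  the paired t-test on zero-variance differences.
* The signed distance is measured voxel-centre to voxel-centre of the
  opposite class (negative inside). The sign convention is cosmetic for
  the weight map (it uses $|D|$) but fixed and tested.
* Percentiles (intensity windows, 95HD) use linear interpolation
  (R's type-7 quantile).
* Sweep ties resolve to the first (smallest) candidate.
* All voxel coordinates are 0-based, a voxel's coordinate is its centre,
  and world = origin + index × spacing. Displacements are stored in
  voxel units on the isotropic cube; metrics convert to mm at the end.

## Known limitations

* Global (not windowed) correlation: on real CT with spatially varying
  contrast, local NCC may register better; the global form is the
  direct reading of the defining equation and suffices for the phantom
  world.
* Single binary structure per atlas; no multi-label transfer.
* No diffeomorphic guarantee: large or adversarial fields can fold, and
  the fixed-point inverse is approximate (flagged when not converged).
* The desk-scale network (levels 4, base 16) and step budgets here are
  far below the scale used for the real clinical cohorts; numbers from
  the phantom world are not comparable to published clinical metrics.
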