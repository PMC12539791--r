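#' Phantom atlas specification
#'
#' Describes a synthetic atlas volume whose statistics match what the
#' region-variance loss assumes: a near-piecewise-constant interior on a
#' contrasting background, optional distractor structures away from the
#' shape, and additive Gaussian noise. Separability requires
#' `|interior_mean - exterior_mean| > 3 * noise_sd`, and the shape must
#' fit in the cube with at least a 4-voxel margin.
#'
#' @param grid a [cube_grid()] (default 32^3 at 1 mm).
#' @param shape `"ellipsoid"` or `"bent_tube"` (a curved canal-like tube).
#' @param interior_mean,exterior_mean intensities in normalized units.
#' @param n_distractors background blobs (default 3).
#' @param distractor_contrast their intensity offset from the background.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer controlling all randomness of the atlas.
#' @export
phantom_spec <- function(grid = cube_grid(32L, 1), shape = c("ellipsoid", "bent_tube"),
                         interior_mean = 0.25, exterior_mean = 0.75,
                         n_distractors = 3L, distractor_contrast = 0.25,
                         noise_sd = 0.05, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(inherits(grid, "cube_grid"))
  if (abs(interior_mean - exterior_mean) <= 3 * noise_sd)
    stop("separability violated: need |interior_mean - exterior_mean| > 3 * noise_sd")
  structure(list(grid = grid, shape = shape, interior_mean = interior_mean,
                 exterior_mean = exterior_mean,
                 n_distractors = as.integer(n_distractors),
                 distractor_contrast = distractor_contrast,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Cohort specification for simulated deformed targets
#'
#' @param n_targets number of deformed targets (default 16).
#' @param amplitude maximum displacement magnitude in voxels (default 3).
#' @param smoothness Gaussian smoothing sigma of the random fields, voxels
#'   (default 6).
#' @param noise_sd fresh per-target additive noise sd (default 0.05).
#' @param seed integer; target `t` uses seed `seed + t`.
#' @export
cohort_spec <- function(n_targets = 16L, amplitude = 3, smoothness = 6,
                        noise_sd = 0.05, seed = 1L) {
  structure(list(n_targets = as.integer(n_targets), amplitude = amplitude,
                 smoothness = smoothness, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

shape_mask <- function(spec) {
  s <- spec$grid$side
  c0 <- (s - 1) / 2
  ax <- seq_len(s) - 1
  X <- array(rep(ax, times = s * s), c(s, s, s))
  Y <- array(rep(rep(ax, each = s), times = s), c(s, s, s))
  Z <- array(rep(ax, each = s * s), c(s, s, s))
  if (spec$shape == "ellipsoid") {
    # semi-axes as cube fractions, capped so the 4-voxel margin holds on
    # small grids
    cap <- (s - 1) / 2 - 4
    a <- min(0.30 * s, cap); b <- min(0.24 * s, cap); cc <- min(0.20 * s, cap)
    m <- ((X - c0) / a)^2 + ((Y - c0) / b)^2 + ((Z - c0) / cc)^2 <= 1
  } else {
    # bent tube: quarter arc of radius R in the xy mid-plane, tube radius r
    R <- 0.28 * s
    r <- 0.10 * s
    cx <- c0 - 0.12 * s
    cy <- c0 - 0.12 * s
    tt <- seq(0, pi / 2, length.out = 64L)
    px <- cx + R * cos(tt)
    py <- cy + R * sin(tt)
    d2min <- array(Inf, c(s, s, s))
    for (k in seq_along(tt)) {
      d2 <- (X - px[k])^2 + (Y - py[k])^2 + (Z - c0)^2
      d2min <- pmin(d2min, d2)
    }
    m <- d2min <= r^2
  }
  array(as.numeric(m), c(s, s, s))
}

#' Generate a phantom atlas bundle
#'
#' Rasterizes the analytic shape to the transfer mask, paints interior and
#' exterior intensities, adds distractor blobs placed at least `tU` mm
#' away from the shape boundary (so the boundary-weight band covers only
#' the true boundary), adds Gaussian noise, and precomputes the distance
#' and weight maps. Deterministic in `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param tL,tU weight-map thresholds passed to [atlas_bundle()].
#' @return an [atlas_bundle()] (no exclusion mask).
#' @export
make_atlas <- function(spec, tL = 1, tU = 4) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$grid$side
  vs <- spec$grid$voxel_size
  m <- shape_mask(spec)
  idx <- which(m == 1, arr.ind = TRUE)
  margins <- c(idx - 1, s - idx)
  if (min(margins) < 4)
    stop("shape does not fit inside the cube with a 4-voxel margin")
  mask <- mask_volume(m, spacing = rep(vs, 3))
  D <- signed_distance(mask)
  img <- withr::with_seed(spec$seed, {
    v <- ifelse(m == 1, spec$interior_mean, spec$exterior_mean)
    if (spec$n_distractors > 0) {
      ax <- seq_len(s) - 1
      X <- array(rep(ax, times = s * s), c(s, s, s))
      Y <- array(rep(rep(ax, each = s), times = s), c(s, s, s))
      Z <- array(rep(ax, each = s * s), c(s, s, s))
      placed <- 0L
      tries <- 0L
      rd <- 2  # distractor radius, voxels
      while (placed < spec$n_distractors && tries < 200L) {
        tries <- tries + 1L
        p <- stats::runif(3, min = 4, max = s - 5)
        pv <- round(p) + 1
        # keep the whole blob at least tU mm away from the shape boundary
        if (D$values[pv[1], pv[2], pv[3]] < tU + (rd + 1) * vs) next
        blob <- (X - p[1])^2 + (Y - p[2])^2 + (Z - p[3])^2 <= rd^2
        sgn <- if (placed %% 2 == 0) 1 else -1
        v[blob] <- spec$exterior_mean + sgn * spec$distractor_contrast
        placed <- placed + 1L
      }
    }
    if (spec$noise_sd > 0)
      v <- v + stats::rnorm(length(v), sd = spec$noise_sd)
    array(v, c(s, s, s))
  })
  atlas_bundle(image_volume(img, spacing = rep(vs, 3)), mask,
               tL = tL, tU = tU)
}

#' Simulate a cohort of deformed targets with known ground truth
#'
#' For each target a random smooth displacement field is drawn; the target
#' image is the atlas pushed through the field's approximate inverse (so
#' pulling the target back through the ground-truth field recovers the
#' atlas up to interpolation and fresh noise), and the ground-truth mask
#' is the atlas transfer mask transferred through the field. Deterministic
#' in `spec$seed` (target `t` uses `spec$seed + t`).
#'
#' @param atlas an [atlas_bundle()] (typically from [make_atlas()]).
#' @param spec a [cohort_spec()].
#' @return list of cases: each a list with `target`, `gt_mask` and
#'   `gt_field`.
#' @export
make_cohort <- function(atlas, spec) {
  stopifnot(inherits(atlas, "atlas_bundle"), inherits(spec, "cohort_spec"))
  s <- dim(atlas$image$voxels)[1]
  grid <- cube_grid(s, atlas$image$spacing[1])
  lapply(seq_len(spec$n_targets), function(t) {
    withr::with_seed(spec$seed + t, {
      u <- random_smooth_field(grid, amplitude = spec$amplitude,
                               smoothness = spec$smoothness)
      inv <- invert_field(u)
      tgt <- pull_back(atlas$image, inv)
      if (spec$noise_sd > 0)
        tgt$voxels <- tgt$voxels +
          array(stats::rnorm(s^3, sd = spec$noise_sd), dim(tgt$voxels))
      gt_mask <- suppressWarnings(transfer_mask(atlas$transfer_mask, u))
      border <- sum(gt_mask$voxels[c(1, s), , ]) +
        sum(gt_mask$voxels[, c(1, s), ]) + sum(gt_mask$voxels[, , c(1, s)])
      if (border > 0)
        stop("deformed mask left the cube; reduce the field amplitude")
      list(target = tgt, gt_mask = gt_mask, gt_field = u)
    })
  })
}

#' Identity-baseline metrics for a simulated cohort
#'
#' Dice and 95th-percentile Hausdorff of the undeformed atlas mask
#' against each ground-truth mask — the score an identity (affine-only)
#' transform would achieve. Equals [evaluate_cohort()] with a zero-field
#' model.
#'
#' @param cohort from [make_cohort()].
#' @param atlas the generating [atlas_bundle()].
#' @return as [evaluate_cohort()].
#' @export
baseline_metrics <- function(cohort, atlas) {
  s <- dim(atlas$image$voxels)[1]
  grid <- cube_grid(s, atlas$image$spacing[1])
  evaluate_cohort(function(target) zero_field(grid), cohort, atlas)
}
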