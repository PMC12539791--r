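#' Dice similarity coefficient
#'
#' `2 |P intersect G| / (|P| + |G|)` over voxels, optionally restricted to
#' voxels outside an exclusion mask (excluded voxels are removed from both
#' masks before counting).
#'
#' @param pred,gt [mask_volume()]s on the same grid.
#' @param exclusion optional [mask_volume()]; foreground voxels are
#'   excluded from the computation.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(pred, gt, exclusion = NULL) {
  stopifnot(inherits(pred, "mask_volume"), inherits(gt, "mask_volume"))
  stopifnot_same_grid(pred, gt)
  p <- as.vector(pred$voxels)
  g <- as.vector(gt$voxels)
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "mask_volume"))
    stopifnot_same_grid(pred, exclusion)
    keep <- as.vector(exclusion$voxels) == 0
    p <- p[keep]
    g <- g[keep]
  }
  if (sum(g) == 0) stop("ground truth is empty after exclusion")
  denom <- sum(p) + sum(g)
  2 * sum(p * g) / denom
}

#' 95th-percentile Hausdorff distance between two surfaces
#'
#' Symmetric, vertex-based estimator: the two directed vertex-to-nearest-
#' vertex distance sets (pred to gt and gt to pred) are pooled and the
#' 95th percentile (linear interpolation) of the pooled set is returned,
#' in mm. Vertices lying inside the exclusion mask are dropped from both
#' meshes first.
#'
#' @param pred_surface,gt_surface [surface_mesh()]es with vertices in
#'   0-based voxel coordinates of a common isotropic grid.
#' @param exclusion optional [mask_volume()] on that grid.
#' @param spacing isotropic mm per voxel used to convert distances
#'   (default 1).
#' @param percentile percentile of the pooled distances (default 95).
#' @return distance in mm.
#' @export
hd95 <- function(pred_surface, gt_surface, exclusion = NULL, spacing = 1,
                 percentile = 95) {
  stopifnot(inherits(pred_surface, "surface_mesh"),
            inherits(gt_surface, "surface_mesh"))
  vp <- pred_surface$vertices
  vg <- gt_surface$vertices
  if (!is.null(exclusion)) {
    stopifnot(inherits(exclusion, "mask_volume"))
    keep <- function(v) {
      inside <- cpp_sample_nearest(exclusion$voxels, dim(exclusion$voxels),
                                   v, 0L) > 0.5
      v[!inside, , drop = FALSE]
    }
    vp <- keep(vp)
    vg <- keep(vg)
  }
  if (nrow(vp) == 0 || nrow(vg) == 0)
    stop("empty surface after exclusion filtering")
  d1 <- cpp_nn_min_dists(vp, vg)
  d2 <- cpp_nn_min_dists(vg, vp)
  as.numeric(stats::quantile(c(d1, d2), percentile / 100,
                             names = FALSE, type = 7)) * spacing
}

#' Two-sided paired t-test
#'
#' Dependent t-test for paired samples on `a - b`.
#'
#' @param a,b equal-length numeric vectors (n >= 2) with non-constant
#'   differences.
#' @return list with `t` and `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0)
    stop("t statistic undefined: all paired differences are identical")
  r <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(r$statistic), p = unname(r$p.value))
}

#' Evaluate a model (or field-predicting function) on a cohort
#'
#' Per case: predict the displacement field, transfer the atlas mask into
#' target space for Dice, project the atlas surface through the field and
#' compare against the ground-truth surface for the 95th-percentile
#' Hausdorff distance. Exclusion masks (per-case `exclusion` entries or
#' the atlas bundle's) are applied when present.
#'
#' @param model a `deformation_model`, or a `function(target)` returning a
#'   [displacement_field()] (useful for identity/oracle baselines).
#' @param cohort list of cases; each case is a list with `target`
#'   ([image_volume()]), `gt_mask` ([mask_volume()]) and optionally
#'   `exclusion`.
#' @param atlas an [atlas_bundle()].
#' @return list with `cases` (data.frame: case, dice, hd95,
#'   inverse_converged, exclusion_applied) and `summary` (median and sd
#'   per metric).
#' @export
evaluate_cohort <- function(model, cohort, atlas) {
  stopifnot(inherits(atlas, "atlas_bundle"))
  predict_fn <- if (is.function(model)) model else {
    stopifnot(inherits(model, "deformation_model"))
    function(target) predict_field(model, target)
  }
  atlas_surf <- extract_surface(atlas$transfer_mask)
  vs <- atlas$transfer_mask$spacing[1]
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    case <- cohort[[i]]
    field <- predict_fn(case$target)
    excl <- case$exclusion
    if (is.null(excl)) excl <- atlas$exclusion_mask
    pred_mask <- suppressWarnings(
      transfer_mask(atlas$transfer_mask, field))
    dc <- dice(pred_mask, case$gt_mask, exclusion = excl)
    pred_surf <- surface_mesh(transform_points(atlas_surf$vertices, field),
                              atlas_surf$faces)
    gt_surf <- extract_surface(case$gt_mask)
    hd <- hd95(pred_surf, gt_surf, exclusion = excl, spacing = vs)
    rows[[i]] <- data.frame(case = i, dice = dc, hd95 = hd,
                            inverse_converged =
                              isTRUE(attr(pred_mask, "converged")),
                            exclusion_applied = !is.null(excl))
  }
  cases <- do.call(rbind, rows)
  list(cases = cases,
       summary = data.frame(
         metric = c("dice", "hd95"),
         median = c(stats::median(cases$dice), stats::median(cases$hd95)),
         sd = c(stats::sd(cases$dice), stats::sd(cases$hd95))))
}
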