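#' Construct a 3D scalar image volume
#'
#' The basic container for a 3D scalar grid (e.g. a CT volume in HU or in
#' normalized units). Voxel coordinates are 0-based and refer to voxel
#' centers; the world position of voxel index `i` along axis `k` is
#' `origin[k] + i * spacing[k]` (mm).
#'
#' @param voxels numeric 3D array; all values must be finite.
#' @param spacing positive mm-per-voxel, length 3 (a scalar is recycled).
#' @param origin world-space mm offset of voxel (0,0,0), length 3.
#' @return an object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(dim(voxels) < 2L)) stop("grid dimensions must be >= 2 per axis")
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels))) stop("all voxel values must be finite")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be > 0")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a binary mask volume
#'
#' Same geometry conventions as [image_volume()]; values must be 0/1
#' (logical input is coerced).
#'
#' @inheritParams image_volume
#' @return an object of class `mask_volume` (inherits `image_volume`).
#' @export
mask_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.logical(voxels)) {
    d <- dim(voxels)
    voxels <- array(as.numeric(voxels), d)
  }
  vol <- image_volume(voxels, spacing, origin)
  if (!all(vol$voxels %in% c(0, 1))) stop("mask values must be 0 or 1")
  class(vol) <- c("mask_volume", "image_volume")
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(what, " must share one grid")
  invisible(TRUE)
}

#' Intensity window
#'
#' The `[imin, imax]` HU window used to normalize CT intensities; values
#' outside the window are retained (mapped below 0 / above 1).
#'
#' @param imin,imax window bounds, `imax > imin`.
#' @export
intensity_window <- function(imin, imax) {
  imin <- as.numeric(imin); imax <- as.numeric(imax)
  if (!is.finite(imin) || !is.finite(imax) || imax <= imin)
    stop("degenerate window: imax must be > imin")
  structure(list(imin = imin, imax = imax), class = "intensity_window")
}

#' Isotropic cube grid
#'
#' The common working grid all targets are cropped/resampled to (default
#' 64^3 voxels).
#'
#' @param side voxels per axis (>= 8).
#' @param voxel_size isotropic mm per voxel (> 0).
#' @export
cube_grid <- function(side = 64L, voxel_size = 1) {
  side <- as.integer(side)
  if (is.na(side) || side < 8L) stop("side must be >= 8")
  voxel_size <- as.numeric(voxel_size)
  if (!is.finite(voxel_size) || voxel_size <= 0) stop("voxel_size must be > 0")
  structure(list(side = side, voxel_size = voxel_size), class = "cube_grid")
}

#' Window-normalize intensities
#'
#' Affine map `(v - imin) / (imax - imin)`: `imin` maps to 0 and `imax` to
#' 1; out-of-window values are retained outside `[0, 1]`.
#'
#' @param vol an [image_volume()].
#' @param window an [intensity_window()].
#' @return normalized `image_volume`.
#' @seealso [denormalize_intensity()]
#' @export
normalize_intensity <- function(vol, window) {
  stopifnot(inherits(vol, "image_volume"), inherits(window, "intensity_window"))
  out <- vol
  out$voxels <- (vol$voxels - window$imin) / (window$imax - window$imin)
  out
}

#' Invert [normalize_intensity()]
#' @inheritParams normalize_intensity
#' @export
denormalize_intensity <- function(vol, window) {
  stopifnot(inherits(vol, "image_volume"), inherits(window, "intensity_window"))
  out <- vol
  out$voxels <- vol$voxels * (window$imax - window$imin) + window$imin
  out
}

#' Estimate an intensity window from a cohort
#'
#' Pools the intensities of all supplied volumes and returns the
#' `(lo_pct, hi_pct)` percentiles as the window. This is a documented
#' substitute for per-dataset hand-picked bounds, and is always overridable
#' by an explicit [intensity_window()].
#'
#' @param volumes list of [image_volume()] (a single volume is accepted).
#' @param lo_pct,hi_pct percentiles in `[0, 100]`, `lo_pct < hi_pct`.
#' @return an [intensity_window()].
#' @export
estimate_window <- function(volumes, lo_pct = 1, hi_pct = 99) {
  if (inherits(volumes, "image_volume")) volumes <- list(volumes)
  if (length(volumes) == 0) stop("need at least one volume")
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100))
    stop("need 0 <= lo_pct < hi_pct <= 100")
  pooled <- unlist(lapply(volumes, function(v) as.vector(v$voxels)),
                   use.names = FALSE)
  q <- stats::quantile(pooled, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  if (q[1] >= q[2])
    stop("degenerate window: pooled intensities have no spread at these percentiles")
  intensity_window(q[1], q[2])
}

#' Centroid of a binary mask
#'
#' Arithmetic mean of the 0-based index coordinates of foreground voxels.
#'
#' @param mask a [mask_volume()] with at least one foreground voxel.
#' @return numeric length-3 point in 0-based voxel coordinates.
#' @export
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  idx <- which(mask$voxels == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  colMeans(idx) - 1
}

#' Crop and resample to an isotropic cube
#'
#' Extracts a `side^3` cube of `voxel_size` mm voxels centered on `center`
#' (given in the source volume's 0-based voxel coordinates). Images are
#' resampled trilinearly, masks by nearest neighbor. Samples falling
#' outside the source extent receive the mean of the in-bounds samples of
#' the crop (masks receive background, 0). An optional 4x4 `affine` maps
#' cube world coordinates into source world coordinates before sampling
#' (for consuming an externally computed affine alignment).
#'
#' @param vol an [image_volume()] or [mask_volume()].
#' @param center length-3 point in the source grid's 0-based voxel frame.
#' @param grid a [cube_grid()].
#' @param affine optional 4x4 matrix acting on homogeneous world mm
#'   coordinates.
#' @return a volume of the same class on the cube grid.
#' @export
crop_to_cube <- function(vol, center, grid, affine = NULL) {
  stopifnot(inherits(vol, "image_volume"), inherits(grid, "cube_grid"))
  center <- rep_len(as.numeric(center), 3L)
  s <- grid$side
  half <- (s - 1) / 2
  ax <- (seq_len(s) - 1 - half) * grid$voxel_size
  # world offsets of cube voxels relative to the cube center
  off <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  center_world <- vol$origin + center * vol$spacing
  world <- sweep(off, 2, center_world, "+")
  if (!is.null(affine)) {
    if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
      stop("affine must be a 4x4 matrix")
    world <- t(affine %*% rbind(t(world), 1))[, 1:3, drop = FALSE]
  }
  src <- sweep(sweep(world, 2, vol$origin, "-"), 2, vol$spacing, "/")
  is_mask <- inherits(vol, "mask_volume")
  dimv <- dim(vol$voxels)
  vals <- if (is_mask) {
    cpp_sample_nearest(vol$voxels, dimv, src, 1L)
  } else {
    cpp_sample_trilinear(vol$voxels, dimv, src, 1L)
  }
  oob <- is.na(vals)
  if (all(oob)) stop("crop lies entirely outside the source volume")
  if (any(oob)) vals[oob] <- if (is_mask) 0 else mean(vals[!oob])
  out_origin <- center_world - half * grid$voxel_size
  arr <- array(vals, c(s, s, s))
  if (is_mask) {
    mask_volume(arr, spacing = rep(grid$voxel_size, 3), origin = out_origin)
  } else {
    image_volume(arr, spacing = rep(grid$voxel_size, 3), origin = out_origin)
  }
}

#' Bundle an atlas image with its masks and derived maps
#'
#' Holds the atlas image, the segmentation mask that is transferred to
#' targets, the (possibly distinct, e.g. tissue-based) mask driving the
#' region-variance loss, an optional evaluation-exclusion mask, and the
#' signed distance and smoothness weight maps derived from the transfer
#' mask (precomputed once; they are constant during training).
#'
#' @param image atlas [image_volume()].
#' @param transfer_mask [mask_volume()] transferred to targets.
#' @param ms_mask optional [mask_volume()] for the region-variance loss;
#'   defaults to `transfer_mask`.
#' @param exclusion_mask optional [mask_volume()] removed from evaluation.
#' @param tL,tU smoothness-weight thresholds in mm (defaults 1 and 4).
#' @param precompute compute the distance and weight maps now (default).
#' @return an object of class `atlas_bundle`.
#' @export
atlas_bundle <- function(image, transfer_mask, ms_mask = NULL,
                         exclusion_mask = NULL, tL = 1, tU = 4,
                         precompute = TRUE) {
  stopifnot(inherits(image, "image_volume"), inherits(transfer_mask, "mask_volume"))
  stopifnot_same_grid(image, transfer_mask, "atlas members")
  if (is.null(ms_mask)) ms_mask <- transfer_mask
  stopifnot(inherits(ms_mask, "mask_volume"))
  stopifnot_same_grid(image, ms_mask, "atlas members")
  if (!is.null(exclusion_mask)) {
    stopifnot(inherits(exclusion_mask, "mask_volume"))
    stopifnot_same_grid(image, exclusion_mask, "atlas members")
  }
  b <- structure(list(image = image, transfer_mask = transfer_mask,
                      ms_mask = ms_mask, exclusion_mask = exclusion_mask,
                      tL = tL, tU = tU,
                      distance_map = NULL, weight_map = NULL),
                 class = "atlas_bundle")
  if (precompute) {
    b$distance_map <- signed_distance(transfer_mask)
    b$weight_map <- weight_map(b$distance_map, tL = tL, tU = tU)
  }
  b
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("<atlas_bundle> %s voxels, %d fg, ms_mask %s, exclusion %s\n",
              paste(dim(x$image$voxels), collapse = "x"),
              sum(x$transfer_mask$voxels),
              if (identical(x$ms_mask$voxels, x$transfer_mask$voxels))
                "= transfer" else "distinct",
              if (is.null(x$exclusion_mask)) "none" else "present"))
  invisible(x)
}
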