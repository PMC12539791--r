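#' Dense displacement field on the atlas cube
#'
#' Represents the nonrigid deformation `phi(x) = x + u(x)` mapping atlas
#' coordinates to target coordinates. `u` holds per-voxel displacements in
#' voxel units, one channel per axis.
#'
#' @param u numeric 4D array `(side, side, side, 3)`; all values finite.
#' @param grid a [cube_grid()]; inferred (unit voxel size) when `NULL`.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(u, grid = NULL) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("`u` must be a (s, s, s, 3) array")
  d <- dim(u)
  if (d[1] != d[2] || d[2] != d[3]) stop("field grid must be cubic")
  storage.mode(u) <- "double"
  if (!all(is.finite(u))) stop("all displacements must be finite")
  if (is.null(grid)) grid <- cube_grid(d[1], 1)
  stopifnot(inherits(grid, "cube_grid"))
  if (grid$side != d[1]) stop("grid side does not match field array")
  structure(list(u = u, grid = grid), class = "displacement_field")
}

#' Zero displacement field on a grid
#' @param grid a [cube_grid()].
#' @export
zero_field <- function(grid) {
  displacement_field(array(0, c(grid$side, grid$side, grid$side, 3L)), grid)
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$u, ncol = 3L)^2))
  cat(sprintf("<displacement_field> %d^3, |u| max %.3f / mean %.3f voxels\n",
              x$grid$side, max(mag), mean(mag)))
  invisible(x)
}

field_matrix <- function(field) matrix(field$u, ncol = 3L)

check_on_field_grid <- function(vol, field) {
  d <- dim(vol$voxels)
  if (!all(d == field$grid$side)) stop("volume and field grids do not match")
  invisible(TRUE)
}

#' Warp a target volume into atlas space
#'
#' Computes the pull-back `out(x) = T(x + u(x))` by trilinear sampling of
#' the target at the deformed coordinates. Samples beyond the grid
#' replicate the border value.
#'
#' @param target an [image_volume()] on the field's cube grid.
#' @param field a [displacement_field()].
#' @return the warped `image_volume` on the atlas grid.
#' @export
pull_back <- function(target, field) {
  stopifnot(inherits(target, "image_volume"),
            inherits(field, "displacement_field"))
  check_on_field_grid(target, field)
  d <- dim(target$voxels)
  vals <- cpp_pull_back(target$voxels, d, field_matrix(field))
  out <- target
  out$voxels <- array(vals, d)
  class(out) <- "image_volume"
  out
}

#' Map points through a displacement field
#'
#' `p -> p + u~(p)` where `u~` is the trilinear interpolation of the field
#' at `p` (0-based voxel coordinates). Points outside the grid sample the
#' clamped border displacement.
#'
#' @param points numeric matrix `n x 3` (a length-3 vector is accepted).
#' @param field a [displacement_field()].
#' @return `n x 3` matrix of mapped points.
#' @export
transform_points <- function(points, field) {
  stopifnot(inherits(field, "displacement_field"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  d <- rep(field$grid$side, 3L)
  disp <- vapply(1:3, function(c)
    as.numeric(cpp_sample_trilinear(field$u[, , , c], d, points, 0L)),
    numeric(nrow(points)))
  points + disp
}

sample_field_at <- function(field, points) {
  d <- rep(field$grid$side, 3L)
  vapply(1:3, function(c)
    as.numeric(cpp_sample_trilinear(field$u[, , , c], d, points, 0L)),
    numeric(nrow(points)))
}

#' Approximate the inverse of a displacement field
#'
#' Fixed-point iteration `v_{k+1}(y) = -u~(y + v_k(y))` starting from
#' `v_0 = 0`, stopped after `iters` iterations or when the mean update
#' falls below `tol` voxels. The result satisfies
#' `phi(y + v(y)) ~= y`, i.e. `y + v(y) ~= phi^{-1}(y)`.
#'
#' @param field a [displacement_field()].
#' @param iters maximum fixed-point iterations (default 20).
#' @param tol mean-update tolerance in voxels (default 0.05).
#' @return a `displacement_field` with attribute `converged`.
#' @export
invert_field <- function(field, iters = 20L, tol = 0.05) {
  s <- field$grid$side
  grid_pts <- grid_points(s)
  v <- matrix(0, nrow(grid_pts), 3L)
  converged <- FALSE
  for (k in seq_len(iters)) {
    vn <- -sample_field_at(field, grid_pts + v)
    res <- mean(sqrt(rowSums((vn - v)^2)))
    v <- vn
    if (res < tol) { converged <- TRUE; break }
  }
  out <- displacement_field(array(v, c(s, s, s, 3L)), field$grid)
  attr(out, "converged") <- converged
  out
}

grid_points <- function(s) {
  ax <- seq_len(s) - 1
  as.matrix(expand.grid(x = ax, y = ax, z = ax))
}

#' Transfer the atlas mask into target space
#'
#' Points move with `phi`, so the mask seen in target space at `y` is the
#' atlas mask at `phi^{-1}(y)`. The inverse is approximated by
#' [invert_field()] and the atlas mask is then sampled nearest-neighbor at
#' `y + v(y)`.
#'
#' @param atlas_mask [mask_volume()] on the field's grid.
#' @param field a [displacement_field()].
#' @param target_grid optional [cube_grid()] of the output (defaults to the
#'   field's grid).
#' @param iters,tol passed to [invert_field()].
#' @return target-space `mask_volume` with attribute `converged` (`FALSE`
#'   flags a non-converged inverse).
#' @export
transfer_mask <- function(atlas_mask, field, target_grid = NULL,
                          iters = 20L, tol = 0.05) {
  stopifnot(inherits(atlas_mask, "mask_volume"),
            inherits(field, "displacement_field"))
  check_on_field_grid(atlas_mask, field)
  if (is.null(target_grid)) target_grid <- field$grid
  if (target_grid$side != field$grid$side)
    stop("target grid must match the field grid")
  inv <- invert_field(field, iters = iters, tol = tol)
  if (!isTRUE(attr(inv, "converged")))
    warning("inverse field iteration did not converge to tolerance")
  s <- target_grid$side
  pts <- grid_points(s) + matrix(inv$u, ncol = 3L)
  vals <- cpp_sample_nearest(atlas_mask$voxels, dim(atlas_mask$voxels), pts, 0L)
  out <- mask_volume(array(vals, c(s, s, s)),
                     spacing = rep(target_grid$voxel_size, 3),
                     origin = atlas_mask$origin)
  attr(out, "converged") <- attr(inv, "converged")
  out
}

#' Random smooth displacement field
#'
#' Per-channel Gaussian white noise, Gaussian-smoothed at scale
#' `smoothness` (voxels, replicate-padded), then rescaled so the maximum
#' displacement magnitude equals `amplitude` voxels. Used for data
#' augmentation and for simulating deformed cohort members.
#'
#' @param grid a [cube_grid()].
#' @param amplitude maximum displacement magnitude, voxels (>= 0).
#' @param smoothness Gaussian smoothing sigma, voxels (> 0).
#' @param seed optional integer; when given the field is a deterministic
#'   function of it (via a local RNG scope), otherwise the current RNG
#'   stream is consumed.
#' @return a [displacement_field()].
#' @export
random_smooth_field <- function(grid, amplitude = 3, smoothness = 6,
                                seed = NULL) {
  stopifnot(inherits(grid, "cube_grid"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (smoothness <= 0) stop("smoothness must be > 0")
  gen <- function() {
    s <- grid$side
    u <- array(stats::rnorm(s^3 * 3), c(s, s, s, 3L))
    if (amplitude == 0) return(displacement_field(array(0, dim(u)), grid))
    for (c in 1:3) u[, , , c] <- gauss_smooth3(u[, , , c], smoothness)
    mag <- sqrt(rowSums(matrix(u, ncol = 3L)^2))
    mmax <- max(mag)
    if (mmax > 0) u <- u * (amplitude / mmax)
    displacement_field(u, grid)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Separable Gaussian smoothing with circular (wrap-around) padding, so the
# smoothed noise field is statistically stationary across the cube (no
# variance pile-up at the borders that would dominate the max-rescaling).
gauss_smooth3 <- function(arr, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) arr <- conv_axis(arr, k, axis, r)
  arr
}

conv_axis <- function(arr, k, axis, r) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  pad_idx <- ((seq(1 - r, n + r) - 1L) %% n) + 1L
  p <- m[pad_idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * p[j:(j + n - 1), , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

# Replicate-border shift of a 3D array by `by` along `axis`:
# out[i] = arr[clamp(i + by)].
shift_rep <- function(arr, axis, by) {
  n <- dim(arr)[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

# Zero-fill shift: out[i] = arr[i + by] (0 beyond the ends).
shift_zero <- function(arr, axis, by) {
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  src <- seq_len(n) + by
  keep <- src >= 1L & src <= n
  if (!any(keep)) return(out)
  ik <- which(keep)
  sk <- src[keep]
  switch(axis,
         out[ik, , ] <- arr[sk, , , drop = FALSE],
         out[, ik, ] <- arr[, sk, , drop = FALSE],
         out[, , ik] <- arr[, , sk, drop = FALSE])
  out
}

central_diff <- function(arr, axis) {
  (shift_rep(arr, axis, 1L) - shift_rep(arr, axis, -1L)) / 2
}

# Adjoint of central_diff (replicate borders), needed for the smoothness
# loss gradients: sum_i g[i] * D(u)[i] = sum_j A(g)[j] * u[j].
central_diff_adjoint <- function(g, axis) {
  n <- dim(g)[axis]
  a <- (shift_zero(g, axis, -1L) - shift_zero(g, axis, 1L)) / 2
  edge_last <- slice_assign_add(a, axis, n, slice_get(g, axis, n) / 2)
  slice_assign_add(edge_last, axis, 1L, -slice_get(g, axis, 1L) / 2)
}

slice_get <- function(arr, axis, i) {
  switch(axis,
         arr[i, , , drop = FALSE],
         arr[, i, , drop = FALSE],
         arr[, , i, drop = FALSE])
}

slice_assign_add <- function(arr, axis, i, val) {
  switch(axis,
         arr[i, , ] <- arr[i, , , drop = FALSE] + val,
         arr[, i, ] <- arr[, i, , drop = FALSE] + val,
         arr[, , i] <- arr[, , i, drop = FALSE] + val)
  arr
}

#' Squared-gradient magnitude map of a displacement field
#'
#' Per-voxel `sum_c ||grad u_c||^2` with central finite differences in
#' voxel units and replicate borders. This is the integrand of the
#' smoothness losses.
#'
#' @param field a [displacement_field()].
#' @return 3D numeric array (>= 0 everywhere; 0 iff the field is constant).
#' @export
grad_map <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  s <- field$grid$side
  out <- array(0, c(s, s, s))
  for (c in 1:3)
    for (axis in 1:3)
      out <- out + central_diff(field$u[, , , c], axis)^2
  out
}
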