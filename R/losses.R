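#' Cross-correlation similarity loss
#'
#' `0.5 - r/2` where `r` is the global Pearson correlation between the
#' warped target and the atlas image over all voxels: 0 at a perfect
#' positive linear intensity relation, 1 at a perfect negative one.
#'
#' @param warped warped target [image_volume()] (the pull-back of the
#'   target into atlas space).
#' @param atlas_image atlas [image_volume()] on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
loss_cc <- function(warped, atlas_image) {
  stopifnot(inherits(warped, "image_volume"),
            inherits(atlas_image, "image_volume"))
  stopifnot_same_grid(warped, atlas_image)
  cc_value(as.vector(warped$voxels), as.vector(atlas_image$voxels))
}

cc_value <- function(w, a) {
  wc <- w - mean(w)
  ac <- a - mean(a)
  nw <- sqrt(sum(wc^2))
  na <- sqrt(sum(ac^2))
  if (nw == 0 || na == 0)
    stop("cross-correlation undefined for a constant (zero-variance) volume")
  0.5 - sum(wc * ac) / (2 * nw * na)
}

# value + gradient w.r.t. the warped vector
cc_with_grad <- function(w, a) {
  wc <- w - mean(w)
  ac <- a - mean(a)
  nw <- sqrt(sum(wc^2))
  na <- sqrt(sum(ac^2))
  if (nw == 0 || na == 0)
    stop("cross-correlation undefined for a constant (zero-variance) volume")
  r <- sum(wc * ac) / (nw * na)
  grad <- -0.5 * (ac / (nw * na) - r * wc / nw^2)
  list(value = 0.5 - r / 2, grad = grad)
}

#' Signed Euclidean distance map of a mask
#'
#' Distance (mm) from each voxel center to the nearest voxel center of the
#' opposite class: negative strictly inside the mask, positive strictly
#' outside.
#'
#' @param mask a [mask_volume()] that is neither empty nor all-foreground.
#' @return an object of class `distance_map` (fields `values`, `spacing`).
#' @export
signed_distance <- function(mask) {
  stopifnot(inherits(mask, "mask_volume"))
  m <- mask$voxels
  nfg <- sum(m)
  if (nfg == 0 || nfg == length(m))
    stop("signed distance needs both foreground and background voxels")
  d <- dim(m)
  d_to_fg <- cpp_edt(m == 1, d, mask$spacing)
  d_to_bg <- cpp_edt(m == 0, d, mask$spacing)
  vals <- array(ifelse(as.vector(m) == 1, -d_to_bg, d_to_fg), d)
  structure(list(values = vals, spacing = mask$spacing),
            class = "distance_map")
}

#' Boundary-weighting map from a signed distance map
#'
#' `W = 0.5 + (tU - max(tL, min(tU, |D|))) / (2 (tU - tL))`: 1 on the mask
#' boundary, decaying to 0.5 at distance `tU` and beyond. Concentrates the
#' smoothness penalty near the structure boundary.
#'
#' @param D a `distance_map` from [signed_distance()].
#' @param tL,tU lower/upper clamp thresholds in mm, `0 <= tL < tU`
#'   (defaults 1 and 4).
#' @return an object of class `weight_map` with values in `[0.5, 1]`.
#' @export
weight_map <- function(D, tL = 1, tU = 4) {
  stopifnot(inherits(D, "distance_map"))
  if (!(tL >= 0 && tL < tU)) stop("need 0 <= tL < tU")
  a <- pmin(pmax(abs(D$values), tL), tU)   # pmin/pmax keep dims of `a`
  W <- 0.5 + (tU - a) / (2 * (tU - tL))
  structure(list(values = W, spacing = D$spacing), class = "weight_map")
}

#' Displacement smoothness loss
#'
#' Mean squared gradient magnitude of the displacement field:
#' `(1 / (3N)) * sum_voxels sum_c ||grad u_c||^2` with central differences
#' in voxel units (see [grad_map()]).
#'
#' @param field a [displacement_field()].
#' @return scalar >= 0 (0 iff the field is constant).
#' @export
loss_grad <- function(field) {
  mean(grad_map(field)) / 3
}

#' Boundary-weighted smoothness loss
#'
#' As [loss_grad()] but each voxel's contribution is scaled by `W^2` (the
#' scalar weight enters inside the squared norm):
#' `(1 / (3N)) * sum W^2 * grad_map`.
#'
#' @param field a [displacement_field()].
#' @param W a `weight_map` on the field's grid (see [weight_map()]).
#' @export
loss_wgrad <- function(field, W) {
  stopifnot(inherits(W, "weight_map"))
  if (!all(dim(W$values) == field$grid$side))
    stop("weight map and field grids do not match")
  mean(W$values^2 * grad_map(field)) / 3
}

# gradient of loss_grad / loss_wgrad w.r.t. the field array (s,s,s,3).
# Wsq = NULL for the unweighted loss, else the W^2 array.
smoothness_grad <- function(field, Wsq = NULL) {
  s <- field$grid$side
  N <- s^3
  g <- array(0, c(s, s, s, 3L))
  for (c in 1:3) {
    uc <- field$u[, , , c]
    acc <- array(0, c(s, s, s))
    for (axis in 1:3) {
      d <- central_diff(uc, axis)
      if (!is.null(Wsq)) d <- d * Wsq
      acc <- acc + central_diff_adjoint(d, axis)
    }
    g[, , , c] <- (2 / (3 * N)) * acc
  }
  g
}

#' Foreground/background intensity statistics
#'
#' Masked means and population variances (divide by count) of the warped
#' image over mask foreground and background — the ingredients of the
#' region-variance (Mumford-Shah-style) loss.
#'
#' @param warped warped target [image_volume()].
#' @param ms_mask [mask_volume()] on the same grid, neither empty nor full.
#' @return object of class `ms_stats` with fields `mu_int`, `mu_ext`,
#'   `var_int`, `var_ext`.
#' @export
ms_stats <- function(warped, ms_mask) {
  stopifnot(inherits(warped, "image_volume"), inherits(ms_mask, "mask_volume"))
  stopifnot_same_grid(warped, ms_mask)
  A <- as.vector(ms_mask$voxels)
  w <- as.vector(warped$voxels)
  n_int <- sum(A)
  n_ext <- length(A) - n_int
  if (n_int == 0 || n_ext == 0)
    stop("ms_mask must have nonempty foreground and background")
  wi <- w[A == 1]
  we <- w[A == 0]
  mu_int <- mean(wi)
  mu_ext <- mean(we)
  structure(list(mu_int = mu_int, mu_ext = mu_ext,
                 var_int = mean((wi - mu_int)^2),
                 var_ext = mean((we - mu_ext)^2)),
            class = "ms_stats")
}

#' Region-variance (Mumford-Shah-style) loss
#'
#' Sum of the intra-class intensity variances of the warped image under
#' the atlas mask partition: `var_int + var_ext`. Minimal (0) when both
#' regions are piecewise constant.
#'
#' @param stats an `ms_stats` object from [ms_stats()].
#' @export
loss_ms <- function(stats) {
  stopifnot(inherits(stats, "ms_stats"))
  stats$var_int + stats$var_ext
}

# value + gradient of loss_ms w.r.t. the warped vector. The mean terms do
# not contribute: sum (w - mu) * A = 0 exactly.
ms_with_grad <- function(w, A) {
  n_int <- sum(A)
  n_ext <- length(A) - n_int
  if (n_int == 0 || n_ext == 0)
    stop("ms_mask must have nonempty foreground and background")
  mu_int <- sum(w * A) / n_int
  mu_ext <- sum(w * (1 - A)) / n_ext
  ri <- (w - mu_int) * A
  re <- (w - mu_ext) * (1 - A)
  list(value = sum(ri^2) / n_int + sum(re^2) / n_ext,
       grad = 2 * ri / n_int + 2 * re / n_ext)
}

#' Loss weights
#'
#' Nonnegative coefficients of the composite training loss
#' `w_cc * loss_cc + w_grad * loss_grad + w_wgrad * loss_wgrad +
#'  w_ms * loss_ms`; at least one must be positive.
#'
#' @param w_cc,w_grad,w_wgrad,w_ms nonnegative reals.
#' @export
loss_weights <- function(w_cc = 1, w_grad = 0, w_wgrad = 0, w_ms = 0) {
  w <- c(cc = w_cc, grad = w_grad, wgrad = w_wgrad, ms = w_ms)
  if (any(w < 0) || any(!is.finite(w))) stop("weights must be finite and >= 0")
  if (sum(w) == 0) stop("at least one weight must be > 0")
  structure(as.list(w), class = "loss_weights")
}

#' Named loss-weight presets
#'
#' `"vxm"` is the plain registration loss (similarity + smoothness);
#' `"iac"`, `"segthor"` and `"hkits21"` are the dataset-tuned composite
#' losses including the region-variance term (the `"hkits21"` preset uses
#' the boundary-weighted smoothness).
#'
#' @param name one of `"vxm"`, `"iac"`, `"segthor"`, `"hkits21"`.
#' @return a [loss_weights()] object.
#' @export
preset_weights <- function(name = c("vxm", "iac", "segthor", "hkits21")) {
  name <- match.arg(name)
  switch(name,
         vxm = loss_weights(1, 1, 0, 0),
         iac = loss_weights(1, 0.5, 0, 0.5),
         segthor = loss_weights(1, 1, 0, 0.5),
         hkits21 = loss_weights(1, 0, 2, 0.5))
}

#' Composite training loss with component breakdown
#'
#' Weighted sum of the active loss terms (those with weight > 0); inactive
#' terms are neither evaluated nor reported (NA in the breakdown). The
#' breakdown reports each active term unweighted.
#'
#' @param warped warped target [image_volume()] (pull-back of the target).
#' @param atlas_bundle an [atlas_bundle()].
#' @param field the predicted [displacement_field()].
#' @param weights a [loss_weights()] object or preset name.
#' @return list with `total` and `components` (named numeric:
#'   cc, grad, wgrad, ms).
#' @export
total_loss <- function(warped, atlas_bundle, field, weights) {
  if (is.character(weights)) weights <- preset_weights(weights)
  stopifnot(inherits(weights, "loss_weights"),
            inherits(atlas_bundle, "atlas_bundle"))
  comp <- c(cc = NA_real_, grad = NA_real_, wgrad = NA_real_, ms = NA_real_)
  total <- 0
  if (weights$cc > 0) {
    comp["cc"] <- loss_cc(warped, atlas_bundle$image)
    total <- total + weights$cc * comp["cc"]
  }
  if (weights$grad > 0) {
    comp["grad"] <- loss_grad(field)
    total <- total + weights$grad * comp["grad"]
  }
  if (weights$wgrad > 0) {
    W <- atlas_bundle$weight_map
    if (is.null(W)) {
      W <- weight_map(signed_distance(atlas_bundle$transfer_mask),
                      tL = atlas_bundle$tL, tU = atlas_bundle$tU)
    }
    comp["wgrad"] <- loss_wgrad(field, W)
    total <- total + weights$wgrad * comp["wgrad"]
  }
  if (weights$ms > 0) {
    comp["ms"] <- loss_ms(ms_stats(warped, atlas_bundle$ms_mask))
    total <- total + weights$ms * comp["ms"]
  }
  list(total = unname(total), components = comp)
}

# Fused loss + gradient w.r.t. the field, used by the training loop.
# Returns total, unweighted components, and g_field (s,s,s,3).
loss_and_field_grad <- function(target, bundle, field, weights) {
  s <- field$grid$side
  d <- rep(s, 3L)
  U <- field_matrix(field)
  wvec <- as.numeric(cpp_pull_back(target$voxels, d, U))
  comp <- c(cc = NA_real_, grad = NA_real_, wgrad = NA_real_, ms = NA_real_)
  total <- 0
  gw <- numeric(length(wvec))  # dL/d(warped)
  if (weights$cc > 0) {
    r <- cc_with_grad(wvec, as.vector(bundle$image$voxels))
    comp["cc"] <- r$value
    total <- total + weights$cc * r$value
    gw <- gw + weights$cc * r$grad
  }
  if (weights$ms > 0) {
    r <- ms_with_grad(wvec, as.vector(bundle$ms_mask$voxels))
    comp["ms"] <- r$value
    total <- total + weights$ms * r$value
    gw <- gw + weights$ms * r$grad
  }
  g_field <- array(0, c(s, s, s, 3L))
  if (weights$cc > 0 || weights$ms > 0) {
    gU <- cpp_pull_back_grad(target$voxels, d, U, gw)
    g_field <- g_field + array(gU, c(s, s, s, 3L))
  }
  if (weights$grad > 0) {
    comp["grad"] <- loss_grad(field)
    total <- total + weights$grad * comp["grad"]
    g_field <- g_field + weights$grad * smoothness_grad(field)
  }
  if (weights$wgrad > 0) {
    W <- bundle$weight_map
    if (is.null(W))
      W <- weight_map(signed_distance(bundle$transfer_mask),
                      tL = bundle$tL, tU = bundle$tU)
    comp["wgrad"] <- loss_wgrad(field, W)
    total <- total + weights$wgrad * comp["wgrad"]
    g_field <- g_field + weights$wgrad * smoothness_grad(field, W$values^2)
  }
  list(total = unname(total), components = comp, g_field = g_field,
       warped = wvec)
}
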