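#' U-Net specification for displacement regression
#'
#' A single-channel volume goes in; a three-channel displacement field
#' comes out at full resolution. The network has `levels` resolution
#' levels: an initial feature-extraction convolution at full resolution,
#' `levels - 1` encoder levels (2x max-pool + convolution), and
#' `levels - 1` decoder levels (2x up-sample + skip concatenation
#' + convolution), followed by a final 3-channel convolution. All kernels
#' are 3^3, activations LeakyReLU.
#'
#' @param levels resolution levels (default 4; encoder/decoder blocks are
#'   `levels - 1`).
#' @param base_channels channels at full resolution (default 16).
#' @param channel_growth per-level channel multiplier (default 2).
#' @param kernel isotropic kernel size (only 3 is supported).
#' @param activation `"leaky_relu"` (slope 0.2) or `"relu"`.
#' @param upsample decoder up-sampling: `"nearest"` (default; converges
#'   faster at short step budgets) or `"trilinear"` (exact-adjoint
#'   trilinear 2x).
#' @return an object of class `unet_spec`.
#' @export
unet_spec <- function(levels = 4L, base_channels = 16L, channel_growth = 2,
                      kernel = 3L, activation = c("leaky_relu", "relu"),
                      upsample = c("nearest", "trilinear")) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("need at least 2 resolution levels")
  if (kernel != 3L) stop("only 3^3 kernels are supported")
  activation <- match.arg(activation)
  upsample <- match.arg(upsample)
  structure(list(levels = levels,
                 encoder_blocks = levels - 1L,
                 decoder_blocks = levels - 1L,
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 kernel = 3L, activation = activation,
                 upsample = upsample,
                 final_channels = 3L),
            class = "unet_spec")
}

spec_channels <- function(spec, level) {
  as.integer(round(spec$base_channels * spec$channel_growth^level))
}

he_init <- function(n_rows, n_cols, fan_in) {
  matrix(stats::rnorm(n_rows * n_cols, sd = sqrt(2 / fan_in)), n_rows, n_cols)
}

#' Build a deformation-regression model
#'
#' Initializes the network weights deterministically from `seed` (He
#' initialization). The final convolution is scaled by 1e-5 so that a
#' freshly built model predicts an approximately zero field, i.e. training
#' starts from the identity transform.
#'
#' @param spec a [unet_spec()].
#' @param seed integer controlling the initialization.
#' @return an object of class `deformation_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  L <- spec$levels
  withr::with_seed(seed, {
    enc <- vector("list", L)
    for (l in seq_len(L) - 1L) {
      cin <- if (l == 0L) 1L else spec_channels(spec, l - 1L)
      cout <- spec_channels(spec, l)
      enc[[l + 1L]] <- list(W = he_init(27L * cin, cout, 27L * cin),
                            b = numeric(cout))
    }
    dec <- vector("list", L - 1L)
    for (l in (L - 2L):0L) {
      cin <- spec_channels(spec, l + 1L) + spec_channels(spec, l)
      cout <- spec_channels(spec, l)
      dec[[l + 1L]] <- list(W = he_init(27L * cin, cout, 27L * cin),
                            b = numeric(cout))
    }
    c0 <- spec_channels(spec, 0L)
    final <- list(W = he_init(27L * c0, 3L, 27L * c0) * 1e-5,
                  b = numeric(3L))
    structure(list(spec = spec,
                   params = list(enc = enc, dec = dec, final = final)),
              class = "deformation_model")
  })
}

#' @export
print.deformation_model <- function(x, ...) {
  cat(sprintf("<deformation_model> %d levels, base %d channels, %d parameters\n",
              x$spec$levels, x$spec$base_channels, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `deformation_model`.
#' @export
n_parameters <- function(model) {
  length(unlist(model$params, use.names = FALSE))
}

act_forward <- function(z, activation) {
  slope <- if (activation == "leaky_relu") 0.2 else 0
  pos <- z > 0
  z * pos + (slope * z) * (1 - pos)
}

act_grad <- function(z, activation) {
  slope <- if (activation == "leaky_relu") 0.2 else 0
  pos <- z > 0
  pos + slope * (1 - pos)
}

check_input_side <- function(spec, s) {
  f <- 2L^(spec$levels - 1L)
  if (s %% f != 0L)
    stop("input side ", s, " is not divisible by the down-sampling factor ", f)
  invisible(TRUE)
}

# Forward pass. x: (Nvox x 1) matrix of the input volume (column-major).
# Returns u (Nvox x 3) and, if want_cache, everything backward needs.
unet_forward <- function(model, x, side, want_cache = FALSE) {
  spec <- model$spec
  L <- spec$levels
  act <- spec$activation
  p <- model$params
  dims <- side / 2L^(0:(L - 1L))
  a <- vector("list", L)       # post-activation encoder features
  z <- vector("list", L)       # pre-activations
  xin <- vector("list", L)     # conv inputs
  pool_idx <- vector("list", L)
  cur <- x
  for (l in seq_len(L)) {
    if (l > 1L) {
      pl <- cpp_maxpool(cur, dims[l - 1L], dims[l - 1L], dims[l - 1L])
      cur <- pl$Y
      pool_idx[[l]] <- pl$idx
    }
    xin[[l]] <- cur
    z[[l]] <- cpp_conv3(cur, p$enc[[l]]$W, p$enc[[l]]$b,
                        dims[l], dims[l], dims[l])
    a[[l]] <- act_forward(z[[l]], act)
    cur <- a[[l]]
  }
  dz <- vector("list", L - 1L)
  din <- vector("list", L - 1L)
  d <- a[[L]]
  up_fwd <- if (identical(spec$upsample, "nearest")) cpp_upsample else
    cpp_upsample_tri
  for (l in (L - 1L):1L) {
    up <- up_fwd(d, dims[l + 1L], dims[l + 1L], dims[l + 1L])
    cat_in <- cbind(up, a[[l]])
    din[[l]] <- cat_in
    dz[[l]] <- cpp_conv3(cat_in, p$dec[[l]]$W, p$dec[[l]]$b,
                         dims[l], dims[l], dims[l])
    d <- act_forward(dz[[l]], act)
  }
  fin <- d
  u <- cpp_conv3(fin, p$final$W, p$final$b, side, side, side)
  if (!want_cache) return(list(u = u))
  list(u = u,
       cache = list(x = x, xin = xin, z = z, a = a, pool_idx = pool_idx,
                    din = din, dz = dz, fin = fin, dims = dims, side = side))
}

# Backward pass: du is (Nvox x 3) gradient of the loss w.r.t. u.
# Returns parameter gradients with the same structure as model$params.
unet_backward <- function(model, cache, du) {
  spec <- model$spec
  L <- spec$levels
  act <- spec$activation
  p <- model$params
  dims <- cache$dims
  side <- cache$side
  g <- list(enc = vector("list", L), dec = vector("list", L - 1L),
            final = NULL)
  bw <- cpp_conv3_backward(cache$fin, p$final$W, du, side, side, side)
  g$final <- list(W = bw$dW, b = as.numeric(bw$db))
  gd <- bw$dX
  genc <- vector("list", L)  # grad w.r.t. each encoder post-activation
  for (l in seq_len(L)) genc[[l]] <- NULL
  for (l in 1:(L - 1L)) {
    gz <- gd * act_grad(cache$dz[[l]], act)
    bw <- cpp_conv3_backward(cache$din[[l]], p$dec[[l]]$W, gz,
                             dims[l], dims[l], dims[l])
    g$dec[[l]] <- list(W = bw$dW, b = as.numeric(bw$db))
    cup <- spec_channels(spec, l)  # channels of the up-sampled part
    dcat <- bw$dX
    dup <- dcat[, seq_len(cup), drop = FALSE]
    dskip <- dcat[, -seq_len(cup), drop = FALSE]
    genc[[l]] <- dskip
    up_bwd <- if (identical(spec$upsample, "nearest")) cpp_upsample_backward
      else cpp_upsample_tri_backward
    gd <- up_bwd(dup, dims[l + 1L], dims[l + 1L], dims[l + 1L])
  }
  # gd now holds the gradient w.r.t. a[[L]]; walk the encoder back down
  gup <- gd
  for (l in L:1L) {
    ga <- gup
    if (l < L && !is.null(genc[[l]])) ga <- ga + genc[[l]]
    if (l == L) ga <- gup
    gz <- ga * act_grad(cache$z[[l]], act)
    bw <- cpp_conv3_backward(cache$xin[[l]], p$enc[[l]]$W, gz,
                             dims[l], dims[l], dims[l])
    g$enc[[l]] <- list(W = bw$dW, b = as.numeric(bw$db))
    if (l > 1L) {
      gup <- cpp_maxpool_backward(cache$pool_idx[[l]], bw$dX,
                                  as.numeric(dims[l - 1L])^3)
    }
  }
  g
}

#' Predict the displacement field for a target volume
#'
#' @param model a `deformation_model` from [build_model()] or [train()].
#' @param target an [image_volume()] whose (cubic) side is divisible by
#'   the model's down-sampling factor.
#' @return a [displacement_field()] in voxel units on the target's grid.
#' @export
predict_field <- function(model, target) {
  stopifnot(inherits(model, "deformation_model"),
            inherits(target, "image_volume"))
  d <- dim(target$voxels)
  if (d[1] != d[2] || d[2] != d[3]) stop("target must be a cube")
  check_input_side(model$spec, d[1])
  s <- d[1]
  out <- unet_forward(model, matrix(as.numeric(target$voxels), ncol = 1L), s)
  displacement_field(array(out$u, c(s, s, s, 3L)),
                     cube_grid(s, target$spacing[1]))
}
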