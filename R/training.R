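#' Training configuration
#'
#' @param seed integer; all randomness of a run (shuffling, initialization)
#'   derives from it.
#' @param epochs passes over the cohort (>= 1).
#' @param batch_size targets per parameter update (default 1).
#' @param learning_rate Adam step size (> 0).
#' @param lr_final optional final Adam step size; when given, the step
#'   size follows a cosine decay from `learning_rate` to `lr_final` over
#'   the run.
#' @param lr_warmup number of initial steps over which the step size ramps
#'   linearly from `learning_rate / 10` to `learning_rate` (default 0).
#' @param weights a [loss_weights()] object or preset name.
#' @param optimizer only `"adam"` is implemented.
#' @param spec a [unet_spec()] used when a model must be built.
#' @param label free-text variant label carried into logs.
#' @export
train_config <- function(seed = 1L, epochs = 10L, batch_size = 1L,
                         learning_rate = 1e-4, lr_final = NULL,
                         lr_warmup = 0L,
                         weights = preset_weights("iac"),
                         optimizer = "adam", spec = unet_spec(),
                         label = "") {
  if (is.character(weights)) weights <- preset_weights(weights)
  stopifnot(inherits(weights, "loss_weights"), inherits(spec, "unet_spec"))
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (!is.null(lr_final) && (lr_final <= 0 || lr_final > learning_rate))
    stop("lr_final must be in (0, learning_rate]")
  lr_warmup <- as.integer(lr_warmup)
  if (lr_warmup < 0L) stop("lr_warmup must be >= 0")
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  structure(list(seed = as.integer(seed), epochs = epochs,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_final = lr_final,
                 lr_warmup = lr_warmup, weights = weights,
                 optimizer = optimizer, spec = spec, label = label),
            class = "train_config")
}

#' Reseed every random stream used by the package
#'
#' All randomness in this package flows through R's global Mersenne-Twister
#' stream (the compiled code draws no random numbers), so a single
#' `set.seed()` makes full runs reproducible on one CPU.
#'
#' @param seed integer seed.
#' @export
seed_everything <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(NULL)
}

# ---- Adam over the nested parameter list ----------------------------------

map_params <- function(a, b, f) {
  if (is.list(a) && !is.null(a$W)) {
    list(W = f(a$W, b$W), b = f(a$b, b$b))
  } else if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- map_params(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

zeros_like_params <- function(p) map_params(p, p, function(x, y) x * 0)

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- map_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  mhat <- map_params(state$m, state$m, function(m, .) m / bc1)
  vhat <- map_params(state$v, state$v, function(v, .) v / bc2)
  step <- map_params(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  params <- map_params(params, step, function(p, s) p - s)
  list(params = params, state = state)
}

#' Train a deformation model on a cohort
#'
#' Self-supervised loop: for each target the model predicts a displacement
#' field, the target is pulled back into atlas space, the composite loss
#' against the atlas bundle is evaluated, and the parameters are updated
#' with Adam. Loss terms with weight 0 are never evaluated. The run is a
#' deterministic function of `config$seed` on one CPU.
#'
#' @param model a `deformation_model` (or `NULL` to build one from
#'   `config$spec` with `config$seed`).
#' @param cohort list of target [image_volume()]s preprocessed to the atlas
#'   cube.
#' @param atlas an [atlas_bundle()].
#' @param config a [train_config()].
#' @param shuffle randomize target order each epoch (default TRUE).
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained) and `history` (one row per epoch:
#'   epoch, loss_cc, loss_grad, loss_wgrad, loss_ms, total — unweighted
#'   components, weighted total).
#' @export
train <- function(model, cohort, atlas, config, shuffle = TRUE,
                  verbose = FALSE) {
  stopifnot(inherits(atlas, "atlas_bundle"), inherits(config, "train_config"))
  if (length(cohort) == 0) stop("empty cohort")
  seed_everything(config$seed)
  if (is.null(model)) model <- build_model(config$spec, seed = config$seed)
  stopifnot(inherits(model, "deformation_model"))
  side <- dim(cohort[[1]]$voxels)[1]
  check_input_side(model$spec, side)
  w <- config$weights
  state <- list(m = zeros_like_params(model$params),
                v = zeros_like_params(model$params))
  tstep <- 0L
  total_steps <- ceiling(length(cohort) / config$batch_size) * config$epochs
  hist <- vector("list", config$epochs)
  grid <- cube_grid(side, cohort[[1]]$spacing[1])
  for (ep in seq_len(config$epochs)) {
    ord <- if (shuffle) sample(length(cohort)) else seq_along(cohort)
    comp_sum <- c(cc = 0, grad = 0, wgrad = 0, ms = 0)
    comp_n <- c(cc = 0, grad = 0, wgrad = 0, ms = 0)
    tot_sum <- 0
    batch_grads <- NULL
    in_batch <- 0L
    for (i in ord) {
      tgt <- cohort[[i]]
      fwd <- unet_forward(model, matrix(as.numeric(tgt$voxels), ncol = 1L),
                          side, want_cache = TRUE)
      field <- displacement_field(array(fwd$u, c(side, side, side, 3L)), grid)
      lg <- loss_and_field_grad(tgt, atlas, field, w)
      if (!is.finite(lg$total))
        stop("training aborted: loss became non-finite at epoch ", ep)
      du <- matrix(lg$g_field, ncol = 3L)
      g <- unet_backward(model, fwd$cache, du)
      batch_grads <- if (is.null(batch_grads)) g else
        map_params(batch_grads, g, `+`)
      in_batch <- in_batch + 1L
      ok <- !is.na(lg$components)
      comp_sum[ok] <- comp_sum[ok] + lg$components[ok]
      comp_n[ok] <- comp_n[ok] + 1
      tot_sum <- tot_sum + lg$total
      if (in_batch == config$batch_size || i == ord[length(ord)]) {
        if (in_batch > 1L)
          batch_grads <- map_params(batch_grads, batch_grads,
                                    function(x, .) x / in_batch)
        tstep <- tstep + 1L
        lr <- if (is.null(config$lr_final)) config$learning_rate else {
          frac <- (tstep - 1) / max(1, total_steps - 1)
          config$lr_final + (config$learning_rate - config$lr_final) *
            (1 + cos(pi * frac)) / 2
        }
        if (config$lr_warmup > 0L && tstep <= config$lr_warmup)
          lr <- lr * (0.1 + 0.9 * (tstep - 1) / config$lr_warmup)
        upd <- adam_update(model$params, batch_grads, state, lr, tstep)
        model$params <- upd$params
        state <- upd$state
        batch_grads <- NULL
        in_batch <- 0L
      }
    }
    comp_mean <- ifelse(comp_n > 0, comp_sum / pmax(comp_n, 1), NA_real_)
    hist[[ep]] <- data.frame(epoch = ep,
                             loss_cc = unname(comp_mean["cc"]),
                             loss_grad = unname(comp_mean["grad"]),
                             loss_wgrad = unname(comp_mean["wgrad"]),
                             loss_ms = unname(comp_mean["ms"]),
                             total = tot_sum / length(cohort),
                             row.names = NULL)
    if (verbose)
      message(sprintf("epoch %d: total %.6f", ep, hist[[ep]]$total))
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Candidate grid for the greedy loss-weight sweep
#'
#' @param values ordered candidate weights (default
#'   `c(0.1, 0.5, 1, 2, 10)`).
#' @param w_cc similarity weight held fixed (default 1).
#' @export
sweep_grid <- function(values = c(0.1, 0.5, 1, 2, 10), w_cc = 1) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty sweep grid")
  if (any(values <= 0) || any(!is.finite(values)))
    stop("sweep values must be positive")
  structure(list(values = values, w_cc = w_cc), class = "sweep_grid")
}

#' Greedy two-stage loss-weight sweep
#'
#' Stage 1 sweeps the smoothness weight (plain or boundary-weighted
#' gradient) with the region-variance weight at 0; stage 2 fixes the
#' stage-1 winner and sweeps the region-variance weight over the same
#' grid. `eval_fn` maps a [train_config()] to a validation score (higher
#' is better, e.g. cohort-median Dice); ties pick the first (smallest)
#' candidate. Exactly `2 * length(grid$values)` evaluations are performed.
#'
#' @param base a [train_config()] whose weights are overwritten per trial.
#' @param grid a [sweep_grid()].
#' @param eval_fn function(config) -> scalar score.
#' @param smoothness `"grad"` or `"wgrad"`: which smoothness term to sweep.
#' @return list with `best` ([loss_weights()]), `stage1`/`stage2` score
#'   tables, and `n_trainings`.
#' @export
greedy_sweep <- function(base, grid, eval_fn,
                         smoothness = c("grad", "wgrad")) {
  stopifnot(inherits(base, "train_config"), inherits(grid, "sweep_grid"))
  smoothness <- match.arg(smoothness)
  mk_weights <- function(sm, ms) {
    loss_weights(w_cc = grid$w_cc,
                 w_grad = if (smoothness == "grad") sm else 0,
                 w_wgrad = if (smoothness == "wgrad") sm else 0,
                 w_ms = ms)
  }
  run <- function(sm, ms) {
    cfg <- base
    cfg$weights <- mk_weights(sm, ms)
    eval_fn(cfg)
  }
  s1 <- vapply(grid$values, function(v) run(v, 0), numeric(1))
  best_sm <- grid$values[which.max(s1)]
  s2 <- vapply(grid$values, function(v) run(best_sm, v), numeric(1))
  best_ms <- grid$values[which.max(s2)]
  list(best = mk_weights(best_sm, best_ms),
       stage1 = data.frame(weight = grid$values, score = s1),
       stage2 = data.frame(weight = grid$values, score = s2),
       n_trainings = 2L * length(grid$values))
}

#' Repeat a configuration over several trials and summarize
#'
#' Runs `eval_fn` on copies of `config` seeded `seed, seed + 1, ...` and
#' reports medians (R's `median`: mid-mean for even counts). `eval_fn` may
#' return a scalar, a per-case numeric vector, or a data frame of per-case
#' metrics; per-case values are first median-aggregated across trials,
#' then the cohort median is taken.
#'
#' @param config a [train_config()].
#' @param n_trials number of trials (default 5).
#' @param eval_fn function(config) -> metrics.
#' @return object of class `trial_set`: list with `per_trial`,
#'   `per_case_median`, and `summary` (named cohort medians).
#' @export
repeat_and_summarize <- function(config, n_trials = 5L, eval_fn) {
  stopifnot(inherits(config, "train_config"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be >= 1")
  res <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    cfg <- config
    cfg$seed <- config$seed + (t - 1L)
    r <- eval_fn(cfg)
    if (is.numeric(r) && is.null(dim(r))) r <- data.frame(metric = r)
    res[[t]] <- as.data.frame(r)
  }
  metrics <- names(res[[1]])
  per_case <- lapply(metrics, function(m) {
    mat <- vapply(res, function(r) as.numeric(r[[m]]),
                  numeric(nrow(res[[1]])))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
    apply(mat, 1, stats::median)
  })
  names(per_case) <- metrics
  summary <- vapply(per_case, stats::median, numeric(1))
  structure(list(per_trial = res, per_case_median = as.data.frame(per_case),
                 summary = summary, n_trials = n_trials,
                 seeds = config$seed + seq_len(n_trials) - 1L),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials (seeds %s)\n", x$n_trials,
              paste(x$seeds, collapse = ", ")))
  print(x$summary)
  invisible(x)
}
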