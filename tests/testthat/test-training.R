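# Small phantom world shared by the training tests: 16^3 cube, 3-level net.
tiny_world <- function(n_targets = 3L, seed = 5L) {
  spec <- phantom_spec(grid = cube_grid(16L, 1), n_distractors = 1L,
                       noise_sd = 0.02, seed = seed)
  atlas <- make_atlas(spec)
  cohort <- make_cohort(atlas, cohort_spec(n_targets = n_targets,
                                           amplitude = 1.5, smoothness = 4,
                                           noise_sd = 0.02, seed = seed))
  list(atlas = atlas, cohort = cohort,
       targets = lapply(cohort, `[[`, "target"),
       spec = unet_spec(levels = 3L, base_channels = 4L))
}

test_that("seed_everything makes runs deterministic; seeds change them", {
  w <- tiny_world()
  cfg <- train_config(seed = 11, epochs = 2, learning_rate = 1e-3,
                      weights = loss_weights(1, 0.5, 0, 0.5), spec = w$spec)
  r1 <- train(NULL, w$targets, w$atlas, cfg)
  r2 <- train(NULL, w$targets, w$atlas, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)

  cfg2 <- cfg; cfg2$seed <- 12L
  r3 <- train(NULL, w$targets, w$atlas, cfg2)
  expect_false(identical(r1$history$total, r3$history$total))
  f1 <- predict_field(r1$model, w$targets[[1]])
  f3 <- predict_field(r3$model, w$targets[[1]])
  expect_false(identical(f1$u, f3$u))
})

test_that("a short training run logs history and reduces the loss", {
  w <- tiny_world(n_targets = 2L)
  cfg1 <- train_config(seed = 3, epochs = 1, learning_rate = 1e-3,
                       weights = loss_weights(1, 0.5, 0, 0.5), spec = w$spec)
  r1 <- train(NULL, w$targets, w$atlas, cfg1)
  expect_identical(nrow(r1$history), 1L)
  expect_identical(names(r1$history),
                   c("epoch", "loss_cc", "loss_grad", "loss_wgrad",
                     "loss_ms", "total"))
  expect_true(all(is.na(r1$history$loss_wgrad)))

  cfg <- train_config(seed = 3, epochs = 15, learning_rate = 1e-3,
                      weights = loss_weights(1, 0.5, 0, 0.5), spec = w$spec)
  r <- train(NULL, w$targets, w$atlas, cfg)
  expect_lt(r$history$total[nrow(r$history)], r$history$total[1])
})

test_that("weight-0 terms are never evaluated during training", {
  w <- tiny_world(n_targets = 2L)
  # an all-foreground ms_mask would make ms_stats error if it were called
  bad <- atlas_bundle(w$atlas$image,
                      w$atlas$transfer_mask,
                      ms_mask = mask_volume(array(1, c(16, 16, 16))))
  cfg <- train_config(seed = 2, epochs = 1, learning_rate = 1e-3,
                      weights = preset_weights("vxm"), spec = w$spec)
  expect_silent(r <- train(NULL, w$targets, bad, cfg))
  expect_true(all(is.na(r$history$loss_ms)))
})

test_that("greedy_sweep recovers a planted optimum in 2x|grid| trainings", {
  base <- train_config(seed = 1, epochs = 1)
  grid <- sweep_grid(c(0.1, 0.5, 1, 2, 10))
  calls <- 0L
  # separable mock with unique optimum at (w_grad = 2, w_ms = 0.5)
  eval_fn <- function(cfg) {
    calls <<- calls + 1L
    -(log10(cfg$weights$grad / 2))^2 - (log10((cfg$weights$ms + 1e-12) / 0.5))^2
  }
  res <- greedy_sweep(base, grid, eval_fn, smoothness = "grad")
  expect_equal(res$best$grad, 2)
  expect_equal(res$best$ms, 0.5)
  expect_equal(res$best$cc, 1)
  expect_identical(calls, 10L)
  expect_identical(res$n_trainings, 10L)
  expect_identical(nrow(res$stage1), 5L)

  # single-value grid selects that value after both stages
  res1 <- greedy_sweep(base, sweep_grid(0.7), eval_fn, smoothness = "wgrad")
  expect_equal(res1$best$wgrad, 0.7)
  expect_equal(res1$best$ms, 0.7)
  expect_identical(res1$n_trainings, 2L)

  expect_error(sweep_grid(numeric(0)), "empty")
})

test_that("repeat_and_summarize medians across trials with derived seeds", {
  cfg <- train_config(seed = 10, epochs = 1)
  seeds_seen <- integer(0)
  r <- repeat_and_summarize(cfg, 5L, function(c) {
    seeds_seen <<- c(seeds_seen, c$seed)
    0.7
  })
  expect_identical(seeds_seen, 10:14)
  expect_equal(unname(r$summary), 0.7)

  vals <- c(5, 1, 3, 2, 4)
  i <- 0L
  r2 <- repeat_and_summarize(cfg, 5L, function(c) { i <<- i + 1L; vals[i] })
  expect_equal(unname(r2$summary), 3)

  # even count: mid-mean convention
  vals4 <- c(1, 2, 3, 4)
  i <- 0L
  r3 <- repeat_and_summarize(cfg, 4L, function(c) { i <<- i + 1L; vals4[i] })
  expect_equal(unname(r3$summary), 2.5)

  # per-case data frames: per-case median across trials, then cohort median
  i <- 0L
  r4 <- repeat_and_summarize(cfg, 3L, function(c) {
    i <<- i + 1L
    data.frame(dice = c(0.8, 0.9) + i / 100, hd95 = c(2, 1) - i / 10)
  })
  expect_equal(unname(r4$summary["dice"]), median(c(0.82, 0.92)))
  expect_equal(unname(r4$summary["hd95"]), median(c(1.8, 0.8)))
})

test_that("config plumbing round-trips through JSON", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(seed = 3, epochs = 7, learning_rate = 5e-4,
                            preset = "segthor", levels = 3,
                            base_channels = 8),
                       p, auto_unbox = TRUE)
  cfg <- read_train_config(p)
  expect_identical(cfg$epochs, 7L)
  expect_equal(cfg$weights$grad, 1)
  expect_equal(cfg$weights$ms, 0.5)
  expect_identical(cfg$spec$levels, 3L)

  mp <- file.path(dir, "manifest.json")
  write_manifest(cfg, mp)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  expect_identical(man$seed, 3L)
  expect_equal(man$weights$ms, 0.5)
})
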