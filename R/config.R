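# JSON configuration plumbing for the CLI and for run manifests.

#' Read a training configuration from JSON
#'
#' Recognized fields: `seed`, `epochs`, `batch_size`, `learning_rate`,
#' `preset` (name) or `weights` (object with `cc`, `grad`, `wgrad`, `ms`),
#' `levels`, `base_channels`, `label`. Missing fields fall back to
#' [train_config()] defaults.
#'
#' @param path JSON file.
#' @return a [train_config()].
#' @export
read_train_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- if (!is.null(j$weights)) {
    do.call(loss_weights, stats::setNames(as.list(j$weights),
      paste0("w_", names(j$weights))))
  } else if (!is.null(j$preset)) {
    preset_weights(j$preset)
  } else preset_weights("iac")
  spec <- unet_spec(levels = j$levels %||% 4L,
                    base_channels = j$base_channels %||% 16L)
  train_config(seed = j$seed %||% 1L,
               epochs = j$epochs %||% 10L,
               batch_size = j$batch_size %||% 1L,
               learning_rate = j$learning_rate %||% 1e-4,
               weights = weights, spec = spec,
               label = j$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records seed, loss weights, network spec and package version for a
#' training run, as JSON.
#'
#' @param config a [train_config()].
#' @param path output JSON path.
#' @export
write_manifest <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  jsonlite::write_json(list(
    seed = config$seed, epochs = config$epochs,
    batch_size = config$batch_size, learning_rate = config$learning_rate,
    weights = unclass(config$weights),
    spec = unclass(config$spec), label = config$label,
    package_version = as.character(utils::packageVersion("atlaswarp"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
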