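# YAML-backed run configuration: one nested list validated against simple
# range rules, a documented global-seed expansion, and provenance output
# (every artifact directory receives the resolved configuration).

#' Default run configuration
#'
#' All tunables in one nested list: sampling rates, windowing, audio
#' front-end constants, training hyperparameters, baseline settings, decision
#' thresholds and the global seed.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    sampling = list(imu_rate = 100, audio_rate = 44100),
    windowing = list(window_s = 2, overlap = 0.5, min_segment_s = 2),
    audio = list(stft_window = 1024, hop = 512, n_mels = 128,
                 silence_rms = 0.01),
    training = list(activity_min_epochs = 500, bark_min_epochs = 1000,
                    patience = 100, batch_size = 32, lr = 0.001,
                    beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8, decay = 0),
    baselines = list(knn_k = 5, rf_trees = 100),
    thresholds = list(stand = 0.5, bark = 0.5),
    evaluation = list(n_runs = 5),
    seed = 1L
  )
}

#' Validate a configuration list
#'
#' Checks types and ranges (positive rates, overlap in `[0, 1)`, thresholds in
#' `[0, 1]`, positive epoch counts); unknown keys are rejected to catch typos.
#'
#' @param config nested list as in [default_config()].
#' @return the config, invisibly, or an error describing the violation.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  extra <- setdiff(names(config), names(defaults))
  if (length(extra)) stop("unknown config section(s): ", paste(extra, collapse = ", "))
  for (sec in names(config)) {
    if (sec == "seed") next
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad)) {
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
    }
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid config: ", msg)
  chk(config$sampling$imu_rate > 0, "sampling$imu_rate must be positive")
  chk(config$sampling$audio_rate > 0, "sampling$audio_rate must be positive")
  chk(config$windowing$window_s > 0, "windowing$window_s must be positive")
  chk(config$windowing$overlap >= 0 && config$windowing$overlap < 1,
      "windowing$overlap must lie in [0, 1)")
  chk(config$audio$stft_window >= 2, "audio$stft_window must be >= 2")
  chk(config$audio$hop >= 1, "audio$hop must be >= 1")
  chk(config$audio$n_mels >= 1, "audio$n_mels must be >= 1")
  chk(config$audio$silence_rms >= 0, "audio$silence_rms must be >= 0")
  chk(config$training$patience >= 1, "training$patience must be >= 1")
  chk(config$training$activity_min_epochs >= config$training$patience,
      "training$activity_min_epochs must be >= patience")
  chk(config$training$bark_min_epochs >= config$training$patience,
      "training$bark_min_epochs must be >= patience")
  chk(config$training$lr > 0, "training$lr must be positive")
  chk(config$thresholds$stand >= 0 && config$thresholds$stand <= 1,
      "thresholds$stand must lie in [0, 1]")
  chk(config$thresholds$bark >= 0 && config$thresholds$bark <= 1,
      "thresholds$bark must lie in [0, 1]")
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer")
  invisible(config)
}

# deep-merge b into a (b wins on leaves)
merge_config <- function(a, b) {
  for (k in names(b)) {
    a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]])) {
      merge_config(a[[k]], b[[k]])
    } else {
      b[[k]]
    }
  }
  a
}

#' Load a YAML configuration, merged over the defaults and validated
#'
#' @param path YAML file; keys present override [default_config()] values.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Expand the global seed into per-component seeds
#'
#' One documented rule derives a distinct, reproducible seed per pipeline
#' component from the single global seed:
#' `seed_i = (global * 1009 + 97 * i) mod (2^31 - 1)`, with components
#' numbered in the fixed order given by `components`.
#'
#' @param global_seed single integer.
#' @param components character vector of component names.
#' @return named integer vector of seeds.
#' @export
expand_seeds <- function(global_seed,
                         components = c("data", "imu", "audio", "activity_cnn",
                                        "bark_cnn", "baselines", "evaluation")) {
  idx <- seq_along(components)
  seeds <- (as.numeric(global_seed) * 1009 + 97 * idx) %% (2^31 - 1)
  stats::setNames(as.integer(seeds), components)
}

#' Write the resolved configuration next to run artifacts
#'
#' @param config validated configuration list.
#' @param dir artifact directory (created if needed).
#' @return the YAML path, invisibly.
#' @export
write_resolved_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "config.resolved.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}
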