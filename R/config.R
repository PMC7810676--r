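# Run configuration: one YAML document carrying every tunable of the
# pipeline, round-tripping losslessly.  Defaults are the reference
# values used throughout: SNR threshold 10, erosion 0.25 ms, dilation
# 40 ms, 20 kHz sampling, 333/42/50 split counts, 100 folds.

#' Default run configuration
#'
#' @return A nested list of class \code{wb_run_config} with
#'   components \code{sensor}, \code{detection}, \code{band},
#'   \code{split}, \code{simulate}, \code{nn}, \code{methods},
#'   \code{n_folds}, \code{seed}.
#' @export
default_run_config <- function() {
  structure(list(
    sensor = list(sample_rate = 20000, bandwidth = 5000,
                  wavelengths = c(808, 980)),
    detection = list(snr_threshold = 10, erosion_ms = 0.25,
                     dilation_ms = 40, dilate_per_side = FALSE),
    band = c(30, 1000),
    split = list(n_target_train = 333L, n_other_train_each = 42L,
                 n_test_each = 50L, strict = TRUE),
    simulate = list(n_per_species = 500L, noise_sd = 1, peak_snr = 50,
                    event_rate = 0.5, total_duration = 30),
    nn = list(layer_sizes = c(2000L, 1500L, 1000L),
              learning_rate = 1e-3, epochs = 30L, batch_size = 32L,
              dropout = 0.5),
    methods = c("wbf", "features", "nn"),
    n_folds = 100L,
    seed = 1L), class = "wb_run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults; everything else
#' keeps its default, so a config file may be partial.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return A \code{wb_run_config}.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- unclass(default_run_config())
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (section in names(user)) {
      if (is.list(cfg[[section]]) && is.list(user[[section]])) {
        for (k in names(user[[section]]))
          cfg[[section]][[k]] <- user[[section]][[k]]
      } else {
        cfg[[section]] <- user[[section]]
      }
    }
  }
  structure(cfg, class = "wb_run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A \code{wb_run_config}.
#' @param path Output YAML path.
#' @return \code{path}, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "wb_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_sensor <- function(cfg) {
  sensor_config(sample_rate = cfg$sensor$sample_rate,
                bandwidth = cfg$sensor$bandwidth,
                wavelengths = cfg$sensor$wavelengths)
}

config_detection <- function(cfg) {
  detection_params(snr_threshold = cfg$detection$snr_threshold,
                   erosion_width = cfg$detection$erosion_ms / 1000,
                   dilation_width = cfg$detection$dilation_ms / 1000,
                   dilate_per_side = isTRUE(cfg$detection$dilate_per_side))
}

config_nn <- function(cfg) {
  nn_config(layer_sizes = cfg$nn$layer_sizes,
            learning_rate = cfg$nn$learning_rate,
            epochs = cfg$nn$epochs,
            batch_size = cfg$nn$batch_size,
            dropout = cfg$nn$dropout)
}
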