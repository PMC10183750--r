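#' Analysis configuration
#'
#' Bundles the frequency bands, time windows, regions of interest and test
#' parameters used throughout the pipeline. Defaults follow the study
#' design this package targets: theta 3-7 Hz, alpha 8-12 Hz, a 25-35 Hz
#' band for beta power and a 13-30 Hz band for PAC peak search; analysis
#' windows 160-260 ms (naming task) and 260-380 ms (size-judgment task)
#' with a -700 to -200 ms pre-stimulus baseline; 2000 permutations, cluster
#' alpha 0.05 with 3 minimum neighbour channels; 80% balanced subsampling
#' and 12 phase bins for PAC; Bonferroni alpha 0.0125 for the four
#' one-sample tests.
#'
#' @param ... named overrides of any default element.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    bands = list(theta = c(3, 7), alpha = c(8, 12),
                 beta_power = c(25, 35), beta_pac = c(13, 30)),
    windows = list(naming_roi = c(0.160, 0.260),
                   size_roi = c(0.260, 0.380),
                   baseline = c(-0.700, -0.200)),
    rois = list(
      naming = c("T3", "C3", "CP3", "CP4", "P3", "P4", "Pz", "POz", "PO2",
                 "Oz", "O2"),
      size = c("T5", "Cz", "C3", "C4", "CP3", "CP4", "P3", "P4"),
      common = c("C3", "CP3", "P3", "C4", "CP4", "P4", "Cz", "CPz", "Pz")),
    freqs = 1:40,
    n_cycles = 5,
    t_step = 0.020,
    n_permutations = 2000,
    min_neighbor_channels = 3,
    cluster_alpha = 0.05,
    subsample_fraction = 0.8,
    n_subsample_iterations = 100,
    n_phase_bins = 12,
    theta_filter_sd = 0.5,
    beta_filter_sd = 5,
    bonferroni_alpha = 0.0125,
    fractal_k = 2,
    fractal_max_iter = 10,
    reject_threshold = 150,
    rng_seed = 1L)
  cfg <- modifyList(cfg, list(...))
  validate_analysis_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_analysis_config <- function(cfg) {
  stopifnot(cfg$subsample_fraction > 0, cfg$subsample_fraction <= 1)
  if (360 %% cfg$n_phase_bins != 0)
    stop("n_phase_bins must divide 360 degrees evenly")
  invisible(cfg)
}

#' Check that all configured ROI channels exist in a montage
#' @param cfg an `analysis_config`.
#' @param montage an `eeg_montage`.
#' @return invisibly `TRUE`; errors listing offending names otherwise.
#' @export
check_config_montage <- function(cfg, montage) {
  all_roi <- unique(unlist(cfg$rois))
  missing <- setdiff(all_roi, montage$names)
  if (length(missing))
    stop("unknown channel: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read/write configuration files
#'
#' Configurations are stored as plain YAML.
#' @param path file path.
#' @param cfg a configuration list.
#' @rdname config_io
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}

#' @rdname config_io
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
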