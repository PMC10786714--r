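#' Run configuration
#'
#' Flat key-value configuration bundling the transition rates, caller
#' parameters, noise settings and run options; serialisable to YAML so a
#' run is reproducible and diffable. Unknown keys are rejected.
#'
#' @param ... Overrides of any default key.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- c(unclass(ibd_rates()), unclass(caller_params()),
                list(batch_size = 400L, qc_threshold = 0.70,
                     seed = 1L))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path Path to a flat YAML file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_rates <- function(config) {
  ibd_rates(config$ibd_in, config$ibd_out, config$ibd_switch,
            config$initial_nonibd)
}

config_caller <- function(config) {
  caller_params(config$post_threshold, config$min_length_cm,
                config$merge_max_gap_cm, config$merge_min_flank_cm,
                config$density_min_snps_per_cm,
                config$output_min_length_cm, config$mask_max_overlap)
}
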