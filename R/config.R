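#' Structured run configuration
#'
#' `default_config()` returns the full default configuration reproducing
#' the study setup; `read_config()` reads a YAML file and merges it over
#' the defaults (unknown keys are an error, so typos fail loudly). The
#' schema (`version: 1`) has three blocks:
#'
#' * `flowpaths`: per id, `median_length` (m) and `median_travel_time` (h);
#' * `priors`: `rel_sd_L`, `rel_sd_v` (relative sds of the Gaussian
#'   geometry priors), `k_bounds`, `R_bounds` (uniform supports),
#'   `dh_stage1_bounds` (stage-1 log-uniform dispersion prior, m^2/h);
#' * `inference`: `n_chains`, `n_generations`, `burn_in`, `sigma_mode`;
#' * `noise`: `rel_sd` (measurement precision, also used for DT50
#'   detectability thresholds), `loq` (ug/L).
#'
#' @param path YAML file path.
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(version = 1,
       flowpaths = list(
         a = list(median_length = 0.050, median_travel_time = 11.5),
         b = list(median_length = 0.111, median_travel_time = 24.3),
         c = list(median_length = 0.166, median_travel_time = 43.3),
         d = list(median_length = 0.092, median_travel_time = 20.1)),
       priors = list(rel_sd_L = 0.2, rel_sd_v = 0.2,
                     k_bounds = c(1e-5, 4), R_bounds = c(1, 49),
                     dh_stage1_bounds = c(1e-6, 1e-2)),
       inference = list(n_chains = 20, n_generations = 4004,
                        burn_in = 0.5, sigma_mode = "relative"),
       noise = list(rel_sd = 0.05, loq = 0.01))
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_into <- function(base, new, prefix = "") {
    for (nm in names(new)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", prefix, nm)
      if (is.list(base[[nm]]) && is.list(new[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], new[[nm]],
                                 paste0(prefix, nm, "."))
      else base[[nm]] <- new[[nm]]
    }
    base
  }
  merge_into(default_config(), user)
}

#' @rdname default_config
#' @param config a configuration list.
#' @return `flowpaths_from_config()`: a named list of
#'   [flowpath_geometry()]s.
#' @export
flowpaths_from_config <- function(config = default_config()) {
  fps <- config$flowpaths
  stats::setNames(lapply(names(fps), function(id)
    flowpath_geometry(id, fps[[id]]$median_length,
                      fps[[id]]$median_travel_time)),
    names(fps))
}
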