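#' Default hyporheic flowpath geometries
#'
#' Median flowpath lengths and travel times from the sediment--water
#' interface to the four porewater samplers, as produced by the
#' particle-tracking hydrodynamic model of the flume experiment:
#' a (5 cm, 11.5 h), b (11.1 cm, 24.3 h), c (16.6 cm, 43.3 h) in bedform 1,
#' and d (9.2 cm, 20.1 h) in bedform 2. The median porewater velocity is the
#' quotient of the two medians.
#'
#' @return A named list of `flowpath_geometry` objects with ids
#'   `"a"`, `"b"`, `"c"`, `"d"`.
#' @examples
#' default_flowpaths()$a$median_velocity  # ~4.35e-3 m/h
#' @export
default_flowpaths <- function() {
  list(a = flowpath_geometry("a", 0.050, 11.5),
       b = flowpath_geometry("b", 0.111, 24.3),
       c = flowpath_geometry("c", 0.166, 43.3),
       d = flowpath_geometry("d", 0.092, 20.1))
}

#' Flowpath geometry
#'
#' @param id flowpath identifier (single string, conventionally
#'   `"a"`..`"d"`).
#' @param median_length median flowpath length (m).
#' @param median_travel_time median conservative-solute travel time (h).
#' @return An object of class `flowpath_geometry`; the derived
#'   `median_velocity` (m/h) equals `median_length / median_travel_time`.
#' @export
flowpath_geometry <- function(id, median_length, median_travel_time) {
  stopifnot(is.character(id), length(id) == 1L,
            median_length > 0, median_travel_time > 0)
  structure(list(id = id,
                 median_length = median_length,
                 median_travel_time = median_travel_time,
                 median_velocity = median_length / median_travel_time),
            class = "flowpath_geometry")
}

# Posterior medians and interquartile ranges of the hydrodynamic dispersion
# coefficient from the conservative-compound pre-run, per flowpath (m^2/h).
# Used as default Gaussian D_h priors in stage-2 fits.
.default_dh <- list(
  a = c(median = 1.5e-3, iqr = 8e-4),
  b = c(median = 1.1e-4, iqr = 5.1e-5),
  c = c(median = 5.3e-5, iqr = 6.7e-6),
  d = c(median = 2.4e-5, iqr = 1.4e-5))

# For a normal distribution IQR = 2 * qnorm(0.75) * sd ~= 1.349 * sd
.IQR_TO_SD <- 2 * stats::qnorm(0.75)

#' Prior specification for one transport parameter
#'
#' Supported families: `"gaussian"` (optionally truncated to `bounds`),
#' `"uniform"`, and `"loguniform"` (uniform in log space, used for the
#' stage-1 dispersion prior). `bounds` are hard support bounds; outside them
#' the log-density is `-Inf`.
#'
#' @param name parameter name.
#' @param family `"gaussian"`, `"uniform"` or `"loguniform"`.
#' @param location,scale mean and sd (gaussian family).
#' @param lower,upper support bounds (uniform families) or truncation
#'   bounds (gaussian; default `c(0, Inf)` keeps physical parameters
#'   positive).
#' @param chain_scale `"natural"` or `"log"`: the scale on which MCMC
#'   chains carry this parameter (the prior itself is unchanged; the
#'   Jacobian is accounted for). Parameters whose posteriors span orders of
#'   magnitude mix far better on the log scale. Log-uniform priors always
#'   use the log chain scale.
#' @return An object of class `prior_spec` with elements `name`, `family`,
#'   `lower`, `upper`, `chain_scale` and (gaussian) `location`, `scale`.
#' @export
prior_spec <- function(name, family = c("gaussian", "uniform", "loguniform"),
                       location = NULL, scale = NULL,
                       lower = NULL, upper = NULL,
                       chain_scale = c("natural", "log")) {
  family <- match.arg(family)
  chain_scale <- match.arg(chain_scale)
  if (family == "loguniform") chain_scale <- "log"
  if (family == "gaussian") {
    stopifnot(is.numeric(location), is.numeric(scale), scale > 0)
    if (is.null(lower)) lower <- 0
    if (is.null(upper)) upper <- Inf
  } else {
    stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
    if (family == "loguniform" && lower <= 0)
      stop("loguniform prior requires a positive lower bound")
  }
  if (chain_scale == "log" && is.numeric(lower) && lower <= 0)
    stop("log chain scale requires a positive lower support bound")
  structure(list(name = name, family = family,
                 location = location, scale = scale,
                 lower = lower, upper = upper,
                 chain_scale = chain_scale),
            class = "prior_spec")
}

#' @rdname prior_spec
#' @param spec a `prior_spec`.
#' @param n number of draws.
#' @export
sample_prior <- function(spec, n) {
  switch(spec$family,
    uniform = stats::runif(n, spec$lower, spec$upper),
    loguniform = exp(stats::runif(n, log(spec$lower), log(spec$upper))),
    gaussian = {
      # inverse-CDF sampling of the truncated normal
      plo <- stats::pnorm(spec$lower, spec$location, spec$scale)
      phi <- stats::pnorm(spec$upper, spec$location, spec$scale)
      stats::qnorm(stats::runif(n, plo, phi), spec$location, spec$scale)
    })
}

#' @rdname prior_spec
#' @param x value(s) at which to evaluate the log-density.
#' @export
log_prior_density <- function(spec, x) {
  out <- rep(-Inf, length(x))
  inside <- x >= spec$lower & x <= spec$upper
  if (!any(inside)) return(out)
  xi <- x[inside]
  out[inside] <- switch(spec$family,
    uniform = -log(spec$upper - spec$lower),
    loguniform = -log(xi) - log(log(spec$upper) - log(spec$lower)),
    gaussian = {
      z <- stats::pnorm(spec$upper, spec$location, spec$scale) -
        stats::pnorm(spec$lower, spec$location, spec$scale)
      stats::dnorm(xi, spec$location, spec$scale, log = TRUE) - log(z)
    })
  out
}

#' Build the prior set for one flowpath
#'
#' Constructs the named priors used in inference of the transport
#' parameters on one flowpath:
#' * `k` ~ Uniform(1e-5, 4) 1/h and `R` ~ Uniform(1, 49) (compound-specific
#'   parameters, deliberately uninformative);
#' * `L` and `v` ~ Gaussian around the flowpath's hydrodynamic-model
#'   medians, truncated at 0, with relative sd `rel_sd_L` / `rel_sd_v`
#'   (default 20%);
#' * `D_h` either a Gaussian informed by the conservative-compound pre-run
#'   (`dh_prior = "default"` uses the per-flowpath posterior medians with
#'   sd = IQR/1.349, or pass `dh_location`/`dh_scale`, e.g. from a stage-1
#'   posterior), or the wide stage-1 log-uniform prior over
#'   `[1e-6, 1e-2]` m^2/h (`dh_prior = "stage1"`).
#'
#' @param geom a [flowpath_geometry()].
#' @param dh_prior `"default"`, `"stage1"`, or `"manual"` (requires
#'   `dh_location` and `dh_scale`).
#' @param dh_location,dh_scale Gaussian D_h prior mean and sd (m^2/h) when
#'   `dh_prior = "manual"`.
#' @param rel_sd_L,rel_sd_v relative standard deviations of the L and v
#'   priors (fractions of the medians).
#' @param k_bounds,R_bounds hard uniform-prior bounds for k (1/h) and R (-).
#' @param k_prior_family `"uniform"` (default) or `"loguniform"`. The
#'   rate-constant bounds span 5.6 decades; a bound case where the data
#'   leave k unconstrained below some ceiling has its posterior median set
#'   almost entirely by this choice. The log-uniform option reproduces
#'   conservative-compound analyses that report medians far below the
#'   detectable rate (a positive lower bound like 1e-5 only carries
#'   information on the log scale).
#' @param dh_stage1_bounds bounds of the stage-1 log-uniform D_h prior
#'   (m^2/h).
#' @return An object of class `prior_set`: a named list of
#'   [prior_spec()]s for `k`, `R`, `v`, `L`, `D_h`.
#' @export
build_prior_set <- function(geom,
                            dh_prior = c("default", "stage1", "manual"),
                            dh_location = NULL, dh_scale = NULL,
                            rel_sd_L = 0.2, rel_sd_v = 0.2,
                            k_bounds = c(1e-5, 4), R_bounds = c(1, 49),
                            k_prior_family = c("uniform", "loguniform"),
                            dh_stage1_bounds = c(1e-6, 1e-2)) {
  stopifnot(inherits(geom, "flowpath_geometry"))
  dh_prior <- match.arg(dh_prior)
  k_prior_family <- match.arg(k_prior_family)
  dh <- switch(dh_prior,
    stage1 = prior_spec("D_h", "loguniform",
                        lower = dh_stage1_bounds[1],
                        upper = dh_stage1_bounds[2]),
    manual = {
      stopifnot(is.numeric(dh_location), is.numeric(dh_scale))
      prior_spec("D_h", "gaussian", location = dh_location,
                 scale = dh_scale, lower = 1e-9)
    },
    default = {
      def <- .default_dh[[geom$id]]
      if (is.null(def))
        stop(sprintf("no default D_h prior for flowpath '%s'; use dh_prior = \"manual\"",
                     geom$id))
      prior_spec("D_h", "gaussian", location = def[["median"]],
                 scale = def[["iqr"]] / .IQR_TO_SD, lower = 1e-9)
    })
  structure(list(
    k = prior_spec("k", k_prior_family,
                   lower = k_bounds[1], upper = k_bounds[2],
                   chain_scale = "log"),
    R = prior_spec("R", "uniform", lower = R_bounds[1], upper = R_bounds[2]),
    v = prior_spec("v", "gaussian", location = geom$median_velocity,
                   scale = rel_sd_v * geom$median_velocity, lower = 1e-12),
    L = prior_spec("L", "gaussian", location = geom$median_length,
                   scale = rel_sd_L * geom$median_length, lower = 1e-6),
    D_h = dh),
    class = "prior_set", flowpath = geom$id)
}

#' @rdname build_prior_set
#' @param priors a `prior_set`.
#' @param n draws per parameter.
#' @return `sample_prior_set()`: an n x 5 matrix of draws with parameter
#'   names as columns.
#' @export
sample_prior_set <- function(priors, n) {
  stopifnot(inherits(priors, "prior_set"))
  vapply(priors, sample_prior, numeric(n), n = n)
}
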