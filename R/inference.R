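#' Observed porewater breakthrough data for one compound on one flowpath
#'
#' Concentrations are expected post LOQ-substitution (values below the limit
#' of quantification replaced by `LOQ * 2^-0.5`, see [loq_substitute()]),
#' so all values are strictly positive. Times must lie within the 21-day
#' fit window.
#'
#' @param compound compound identifier.
#' @param flowpath flowpath identifier (`"a"`..`"d"`).
#' @param times observation times (h), within `[0, 504]`.
#' @param concentrations observed (substituted) concentrations (ug/L), > 0.
#' @param loq limit of quantification (ug/L).
#' @param censored logical flags: `TRUE` where the raw value was below LOQ
#'   and the stored value is the substituted `LOQ * 2^-0.5`.
#' @param rel_sd relative standard deviation of the measurement (compound
#'   metadata from analytical QA/QC), used by the relative-error likelihood
#'   and the DT50 detectability threshold.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(compound, flowpath, times, concentrations,
                            loq = 0, censored = rep(FALSE, length(times)),
                            rel_sd = 0.05) {
  stopifnot(length(times) == length(concentrations),
            length(censored) == length(times), loq >= 0)
  if (any(times < 0) || any(times > 504 + 1e-9))
    stop("observation times must lie within the 21-day fit window [0, 504 h]")
  if (any(concentrations <= 0))
    stop("concentrations must be > 0 after LOQ substitution")
  if (any(censored & abs(concentrations - loq * 2^-0.5) > 1e-9 * max(loq, 1)))
    stop("censored observations must equal LOQ * 2^-0.5")
  structure(list(compound = compound, flowpath = flowpath,
                 times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 loq = loq, censored = as.logical(censored),
                 rel_sd = rel_sd),
            class = "observation_set")
}

# Chain state transform: some parameters are carried in log space so
# differential-evolution proposals act on a roughly symmetric scale; the
# Jacobian of the transform is included in the chain-scale prior density.
.prior_is_log <- function(priors)
  vapply(priors, function(s) identical(s$chain_scale, "log"), logical(1))

.z_bounds <- function(spec) {
  if (identical(spec$chain_scale, "log")) c(log(spec$lower), log(spec$upper))
  else c(spec$lower, spec$upper)
}

# log prior density on the (possibly log-transformed) chain scale
.log_prior_z <- function(priors, z, is_log) {
  lp <- 0
  for (j in seq_along(priors)) {
    s <- priors[[j]]
    if (is_log[j]) {
      if (z[j] < log(s$lower) || z[j] > log(s$upper)) return(-Inf)
      # p_z(z) = p_x(exp(z)) * exp(z)
      d <- log_prior_density(s, exp(z[j])) + z[j]
    } else {
      d <- log_prior_density(s, z[j])
    }
    if (!is.finite(d)) return(-Inf)
    lp <- lp + d
  }
  lp
}

# Build a fast log-posterior closure over the chain-scale parameter vector.
# obs = NULL gives a constant likelihood (prior-only sampling).
.make_log_posterior <- function(obs, priors, boundary, grid,
                                sigma_mode = c("relative", "fixed",
                                               "marginal", "infer"),
                                sigma = NULL,
                                sigma_bounds = c(1e-4, 1e2)) {
  sigma_mode <- match.arg(sigma_mode)
  if (sigma_mode == "fixed" && (is.null(sigma) || sigma <= 0))
    stop("sigma_mode = \"fixed\" requires a positive sigma")
  is_log <- .prior_is_log(priors)
  pn <- names(priors)
  has_obs <- !is.null(obs)
  if (has_obs) {
    n <- length(obs$times)
    yobs <- obs$concentrations
    # precompute interpolation of the solver time axis onto observation times
    it <- findInterval(obs$times, grid$times, all.inside = TRUE)
    wt <- (obs$times - grid$times[it]) / diff(grid$times)[1]
    if (sigma_mode == "relative") {
      rel <- if (!is.null(sigma)) sigma else obs$rel_sd
      # per-point sd: relative error with an additive floor at half the LOQ
      # (measurement uncertainty never drops below the quantification scale)
      sig_i <- sqrt((rel * yobs)^2 + (obs$loq / 2)^2)
      sig_i <- pmax(sig_i, 1e-12)
      const_rel <- -sum(log(sig_i)) - 0.5 * n * log(2 * pi)
    }
  }
  d_phys <- length(priors)
  infer_sigma <- has_obs && sigma_mode == "infer"

  # returns c(log prior, log likelihood); the sampler tempers the
  # likelihood during burn-in, so the two parts are kept separate
  function(z) {
    lp <- .log_prior_z(priors, z[seq_len(d_phys)], is_log)
    if (!is.finite(lp)) return(c(-Inf, 0))
    if (infer_sigma) {
      lsig <- z[d_phys + 1L]
      if (lsig < log(sigma_bounds[1]) || lsig > log(sigma_bounds[2]))
        return(c(-Inf, 0))
    }
    if (!has_obs) return(c(lp, 0))
    x <- z[seq_len(d_phys)]
    x[is_log] <- exp(x[is_log])
    names(x) <- pn
    if (x[["L"]] >= grid$domain_length) return(c(-Inf, 0))
    pe <- x[["v"]] * grid$dx / x[["D_h"]]
    conc <- tryCatch(
      .ade_solve_cpp(x[["k"]], x[["R"]], x[["v"]], x[["D_h"]],
                     boundary$times, boundary$concentrations,
                     grid$domain_length, grid$n_cells,
                     grid$time_step, grid$duration,
                     x[["L"]], pe > 2, 0.5),
      error = function(e) NULL)
    if (is.null(conc)) {
      warning("forward solver failed; log-posterior set to -Inf", call. = FALSE)
      return(c(-Inf, 0))
    }
    fit <- conc[it] * (1 - wt) + conc[it + 1L] * wt
    ll <- switch(sigma_mode,
      relative = const_rel - 0.5 * sum(((yobs - fit) / sig_i)^2),
      # Jeffreys prior p(sigma) ~ 1/sigma integrated out analytically
      marginal = -0.5 * n * log(max(sum((yobs - fit)^2), 1e-300)),
      fixed = -0.5 * n * log(2 * pi * sigma^2) -
        sum((yobs - fit)^2) / (2 * sigma^2),
      infer = {
        s <- exp(z[d_phys + 1L])
        # log-uniform prior on sigma (constant in log sigma)
        -0.5 * n * log(2 * pi * s^2) - sum((yobs - fit)^2) / (2 * s^2)
      })
    c(lp, ll)
  }
}

#' Log-posterior density of transport parameters
#'
#' Log prior plus Gaussian log-likelihood of the observed breakthrough
#' concentrations given the forward model. Parameters outside the prior
#' support return `-Inf` (not an error), as required by the Metropolis
#' acceptance step. The error scale is treated according to `sigma_mode`:
#'
#' * `"relative"` (default): independent Gaussian residuals with per-point
#'   sd \eqn{\sigma_i = \sqrt{(\mathrm{relSD}\cdot y_i)^2 + (LOQ/2)^2}},
#'   i.e. the known measurement precision of the analytical method with an
#'   error floor at the quantification scale. This is the well-posed choice
#'   when few observations constrain five transport parameters.
#' * `"fixed"`: homoscedastic with a supplied absolute sigma.
#' * `"marginal"`: homoscedastic sigma integrated out analytically under
#'   the Jeffreys prior \eqn{p(\sigma) \propto 1/\sigma}, giving
#'   \eqn{\log L = -\tfrac{n}{2}\log \mathrm{SSR}} up to a constant. With
#'   very few observations per fit this posterior is heavy-tailed and can
#'   become nearly improper (the residual sum of squares can approach zero
#'   on an interpolating parameter manifold); prefer `"relative"`.
#' * `"infer"` (via [dream_sample()] only): sigma becomes an explicit chain
#'   parameter under a log-uniform prior.
#'
#' Left-censored observations enter through their substituted values.
#'
#' @param params a [transport_params()] or a named numeric vector with
#'   elements `k`, `R`, `v`, `L`, `D_h`.
#' @param obs an [observation_set()], or `NULL` for a constant likelihood
#'   (prior-only density).
#' @param priors a [build_prior_set()] result.
#' @param boundary a [boundary_series()].
#' @param grid the [spatial_grid()] used for the forward solve.
#' @param sigma_mode `"relative"`, `"fixed"` or `"marginal"`.
#' @param sigma absolute error scale (ug/L) for `"fixed"`, or an override
#'   of the observation set's relative SD for `"relative"`.
#' @return The (unnormalized) log-posterior density, a single number.
#' @export
log_posterior <- function(params, obs, priors, boundary,
                          grid = spatial_grid(n_cells = 50, time_step = 0.5),
                          sigma_mode = c("relative", "fixed", "marginal"),
                          sigma = NULL) {
  sigma_mode <- match.arg(sigma_mode)
  if (inherits(params, "transport_params")) params <- unlist(params)
  pn <- names(priors)
  if (!all(pn %in% names(params)))
    stop("params must provide named values for: ", paste(pn, collapse = ", "))
  z <- as.numeric(params[pn])
  is_log <- .prior_is_log(priors)
  z[is_log] <- log(z[is_log])
  f <- .make_log_posterior(obs, priors, boundary, grid, sigma_mode, sigma)
  sum(f(z))
}

#' Settings for the DREAM sampler
#'
#' Defaults follow the study setup: 20 chains and 2002 retained generations
#' per chain after a 50% burn-in (4004 generations), pooling to 40,040
#' posterior draws.
#'
#' @param n_chains number of parallel chains (default 20; must be at least
#'   `2 d + 1` for problem dimension d).
#' @param n_generations total generations per chain.
#' @param burn_in fraction of generations discarded as burn-in.
#' @param seed RNG seed; identical seed and settings give bit-identical
#'   chains.
#' @param grid forward-model [spatial_grid()] used during inference
#'   (coarser than the verification default, for speed).
#' @param sigma_mode `"marginal"`, `"fixed"` or `"infer"` (see
#'   [log_posterior()]).
#' @param sigma fixed error scale (ug/L) for `sigma_mode = "fixed"`.
#' @param delta_max maximum number of chain pairs in a proposal.
#' @param p_gamma1 probability of a gamma = 1 (mode-jumping) generation.
#' @param jitter relative scale of the small uniform scaling perturbation
#'   and additive noise applied to proposals.
#' @param n_cr number of crossover probabilities (CR = 1/n_cr .. 1).
#' @param outlier_check generation interval of burn-in outlier-chain
#'   correction.
#' @return A list of class `dream_settings`.
#' @export
dream_settings <- function(n_chains = 20, n_generations = 4004,
                           burn_in = 0.5, seed = 1,
                           grid = spatial_grid(n_cells = 50, time_step = 0.5),
                           sigma_mode = c("relative", "fixed", "marginal",
                                          "infer"),
                           sigma = NULL, delta_max = 3, p_gamma1 = 0.1,
                           jitter = 1e-6, n_cr = 3, outlier_check = 50) {
  structure(list(n_chains = as.integer(n_chains),
                 n_generations = as.integer(n_generations),
                 burn_in = burn_in, seed = seed, grid = grid,
                 sigma_mode = match.arg(sigma_mode), sigma = sigma,
                 delta_max = as.integer(delta_max), p_gamma1 = p_gamma1,
                 jitter = jitter, n_cr = as.integer(n_cr),
                 outlier_check = as.integer(outlier_check)),
            class = "dream_settings")
}

#' DREAM multi-chain MCMC sampling of transport parameters
#'
#' DiffeRential Evolution Adaptive Metropolis: each chain proposes a jump
#' built from the difference of randomly chosen pairs of other chains,
#' scaled by \eqn{\gamma = 2.38/\sqrt{2\delta d'}} (with ~10% of
#' generations at \eqn{\gamma = 1} to enable jumps between modes), applied
#' in a random parameter subspace selected by a crossover probability, and
#' accepted by the Metropolis rule. Aberrant (outlier) chains are reset to
#' the best chain during burn-in. Log-uniform parameters are carried in log
#' space internally.
#'
#' @param obs an [observation_set()], or `NULL` to sample the prior
#'   (constant likelihood).
#' @param priors a [build_prior_set()] result.
#' @param boundary a [boundary_series()] (ignored when `obs` is `NULL`).
#' @param settings a [dream_settings()] list.
#' @return An object of class `chain_ensemble`: `samples` (generations x
#'   chains x parameters array, natural scale), `log_post`, `retained`
#'   (generation indices kept after burn-in), `acceptance_rate` (post
#'   burn-in), `n_outlier_resets` and the settings used.
#' @export
dream_sample <- function(obs, priors, boundary = NULL,
                         settings = dream_settings()) {
  stopifnot(inherits(priors, "prior_set") || is.list(priors))
  s <- settings
  pn <- names(priors)
  infer_sigma <- !is.null(obs) && s$sigma_mode == "infer"
  d <- length(priors) + as.integer(infer_sigma)
  if (s$n_chains < 2L * d + 1L)
    stop(sprintf("need at least 2*d+1 = %d chains for dimension %d", 2 * d + 1, d))
  if (!is.null(obs) && max(obs$times) > s$grid$duration)
    stop("observation times exceed the simulated duration")

  lpfun <- .make_log_posterior(obs, priors, boundary, s$grid,
                               s$sigma_mode, s$sigma)
  is_log <- .prior_is_log(priors)
  cn <- if (infer_sigma) c(pn, "sigma") else pn

  set.seed(s$seed)
  m <- s$n_chains; ng <- s$n_generations
  # initial population from the priors (chain scale)
  Z <- matrix(0, m, d, dimnames = list(NULL, cn))
  for (j in seq_along(priors)) {
    x0 <- sample_prior(priors[[j]], m)
    Z[, j] <- if (is_log[j]) log(x0) else x0
  }
  if (infer_sigma) Z[, d] <- stats::runif(m, log(1e-2), log(1e1))
  pl <- t(apply(Z, 1, lpfun))  # columns: log prior, log likelihood
  # re-draw chains with -Inf starting density (e.g. failed solves)
  for (i in which(!is.finite(pl[, 1]))) {
    for (tries in 1:100) {
      for (j in seq_along(priors)) {
        x0 <- sample_prior(priors[[j]], 1)
        Z[i, j] <- if (is_log[j]) log(x0) else x0
      }
      pl[i, ] <- lpfun(Z[i, ])
      if (is.finite(pl[i, 1])) break
    }
  }

  # jitter scale per dimension, from prior support width
  width <- vapply(seq_along(priors), function(j) {
    b <- .z_bounds(priors[[j]])
    if (is.finite(b[2] - b[1])) b[2] - b[1] else 6 * priors[[j]]$scale
  }, numeric(1))
  if (infer_sigma) width <- c(width, log(1e2) - log(1e-4))

  samples <- array(NA_real_, c(ng, m, d), dimnames = list(NULL, NULL, cn))
  lp_hist <- matrix(NA_real_, ng, m)
  samples[1, , ] <- Z
  lp_hist[1, ] <- rowSums(pl)
  burn_gen <- floor(s$burn_in * ng)
  cr_values <- seq_len(s$n_cr) / s$n_cr
  n_acc <- 0L; n_prop <- 0L; n_resets <- 0L
  # jump-scale factor adapted towards a workable acceptance rate during
  # burn-in only (frozen afterwards, so the retained chain is Markovian)
  jump_f <- 1; w_acc <- 0L; w_prop <- 0L
  # likelihood tempering during the first 80% of burn-in: the target is
  # prior + beta * loglik with beta ramping 0.05 -> 1, which lets the
  # population locate sharp, well-separated posterior modes before the
  # exact (beta = 1) kernel takes over; retained samples are always beta = 1
  anneal_gens <- floor(0.8 * burn_gen)
  beta_of <- function(g) {
    if (g > anneal_gens || anneal_gens < 2L) return(1)
    min(1, (0.05 + 0.95 * (g / anneal_gens))^2)
  }

  for (g in 2:ng) {
    beta <- beta_of(g)
    gamma1_gen <- stats::runif(1) < s$p_gamma1
    for (i in seq_len(m)) {
      delta <- sample.int(s$delta_max, 1L)
      others <- sample((seq_len(m))[-i], 2L * delta)
      diffs <- colSums(Z[others[seq_len(delta)], , drop = FALSE]) -
        colSums(Z[others[delta + seq_len(delta)], , drop = FALSE])
      cr <- cr_values[sample.int(s$n_cr, 1L)]
      sub <- which(stats::runif(d) < cr)
      if (length(sub) == 0L) sub <- sample.int(d, 1L)
      gamma <- if (gamma1_gen) 1 else jump_f * 2.38 / sqrt(2 * delta * length(sub))
      e <- stats::runif(d, -0.05, 0.05)
      eps <- stats::rnorm(d, 0, s$jitter * width)
      zp <- Z[i, ]
      zp[sub] <- Z[i, sub] + (1 + e[sub]) * gamma * diffs[sub] + eps[sub]
      plp <- lpfun(zp)
      if (is.finite(plp[1]) &&
          log(stats::runif(1)) <
            (plp[1] + beta * plp[2]) - (pl[i, 1] + beta * pl[i, 2])) {
        Z[i, ] <- zp
        pl[i, ] <- plp
        if (g > burn_gen) n_acc <- n_acc + 1L else w_acc <- w_acc + 1L
      }
      if (g > burn_gen) n_prop <- n_prop + 1L else w_prop <- w_prop + 1L
    }
    lp <- pl[, 1] + beta * pl[, 2]
    # jump-scale adaptation and outlier-chain correction during burn-in
    if (g <= burn_gen && s$outlier_check > 0L && g %% s$outlier_check == 0L) {
      rate <- w_acc / max(w_prop, 1L)
      if (rate < 0.15) jump_f <- max(jump_f * 0.85, 0.05)
      else if (rate > 0.35) jump_f <- min(jump_f * 1.15, 3)
      w_acc <- 0L; w_prop <- 0L
      qs <- stats::quantile(lp, c(0.25, 0.75), names = FALSE)
      bad <- which(lp < qs[1] - 2 * (qs[2] - qs[1]))
      if (length(bad)) {
        best <- which.max(lp)
        for (i in bad) {
          Z[i, ] <- Z[best, ]
          pl[i, ] <- pl[best, ]
          n_resets <- n_resets + 1L
        }
        lp <- pl[, 1] + beta * pl[, 2]
      }
    }
    samples[g, , ] <- Z
    lp_hist[g, ] <- rowSums(pl)
  }

  # back-transform log-scale parameters to natural scale
  for (j in which(is_log)) samples[, , j] <- exp(samples[, , j])
  if (infer_sigma) samples[, , d] <- exp(samples[, , d])

  structure(list(samples = samples, log_post = lp_hist,
                 retained = (burn_gen + 1L):ng,
                 acceptance_rate = if (n_prop) n_acc / n_prop else NA_real_,
                 n_outlier_resets = n_resets,
                 param_names = cn, settings = s),
            class = "chain_ensemble")
}

#' Gelman--Rubin potential scale reduction factor
#'
#' Classical between/within-chain variance diagnostic computed on the
#' retained (post burn-in) samples; convergence is conventionally declared
#' when all parameters fall below `threshold` (default 1.2).
#'
#' @param ensemble a [dream_sample()] result.
#' @param threshold convergence threshold recorded in the output.
#' @return A named vector of PSRF values (one per parameter) with
#'   attributes `converged` (logical) and `threshold`. Zero-variance
#'   (degenerate) chains yield `NA` and `converged = NA`.
#' @export
gelman_rubin <- function(ensemble, threshold = 1.2) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  idx <- ensemble$retained
  if (length(idx) < 10L) stop("need at least 10 retained samples per chain")
  x <- ensemble$samples[idx, , , drop = FALSE]
  n <- dim(x)[1]; m <- dim(x)[2]; d <- dim(x)[3]
  if (m < 2L) stop("need at least 2 chains")
  rhat <- vapply(seq_len(d), function(j) {
    xj <- x[, , j]
    W <- mean(apply(xj, 2, stats::var))
    B <- n * stats::var(colMeans(xj))
    if (W <= 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  names(rhat) <- ensemble$param_names
  attr(rhat, "converged") <- if (anyNA(rhat)) NA else all(rhat < threshold)
  attr(rhat, "threshold") <- threshold
  rhat
}

#' Summarize a chain ensemble into posterior medians and IQRs
#'
#' Pools the retained samples of all chains and reports, per parameter, the
#' median and interquartile range, plus the Gelman--Rubin diagnostic and
#' the retained sample count.
#'
#' @param ensemble a [dream_sample()] result.
#' @param rhat_threshold convergence threshold passed to [gelman_rubin()].
#' @return An object of class `posterior_summary`: a list with a `table`
#'   data frame (parameter, median, iqr, q25, q75, rhat), `n_samples`,
#'   `converged`, `acceptance_rate`, and the pooled `draws` matrix.
#' @export
summarize_posterior <- function(ensemble, rhat_threshold = 1.2) {
  stopifnot(inherits(ensemble, "chain_ensemble"))
  idx <- ensemble$retained
  if (length(idx) == 0L) stop("no retained samples")
  d <- dim(ensemble$samples)[3]
  draws <- apply(ensemble$samples[idx, , , drop = FALSE], 3, as.numeric)
  colnames(draws) <- ensemble$param_names
  qs <- apply(draws, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  if (is.null(dim(qs))) qs <- matrix(qs, nrow = 3)
  rhat <- tryCatch(gelman_rubin(ensemble, rhat_threshold), error = function(e) {
    r <- rep(NA_real_, d)
    attr(r, "converged") <- NA
    r
  })
  tab <- data.frame(parameter = ensemble$param_names,
                    median = qs[2, ], q25 = qs[1, ], q75 = qs[3, ],
                    iqr = qs[3, ] - qs[1, ],
                    rhat = as.numeric(rhat),
                    row.names = NULL)
  structure(list(table = tab, n_samples = nrow(draws),
                 converged = attr(rhat, "converged"),
                 acceptance_rate = ensemble$acceptance_rate,
                 draws = draws),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary (%d pooled draws, acceptance %.2f, %s)\n",
              x$n_samples,
              x$acceptance_rate,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  print(transform(x$table,
                  median = signif(median, 4), q25 = signif(q25, 4),
                  q75 = signif(q75, 4), iqr = signif(iqr, 4),
                  rhat = round(rhat, 3)))
  invisible(x)
}

#' Two-stage calibration chained through a conservative reference compound
#'
#' Stage 1 fits the designated conservative reference compound on every
#' flowpath using a wide log-uniform dispersion prior; the hydrodynamic
#' dispersion coefficient D_h is identifiable there because the reference
#' compound is (nearly) non-reactive. Stage 2 then replaces the D_h prior
#' by a Gaussian matched to the stage-1 posterior (location = posterior
#' median, scale = posterior IQR / 1.349) and fits every other compound
#' independently per flowpath.
#'
#' @param dataset a list with elements `observations` (nested list
#'   `[[compound]][[flowpath]]` of [observation_set()]s), `boundaries`
#'   (list `[[compound]]` of [boundary_series()]) and `flowpaths` (named
#'   list of [flowpath_geometry()]s), as produced by [simulate_dataset()].
#' @param reference_compound name of the conservative reference compound;
#'   must be present on every flowpath in the dataset.
#' @param settings a [dream_settings()]; the seed is offset deterministically
#'   per compound and flowpath so fits are independent but reproducible.
#' @param prior_args extra arguments passed to [build_prior_set()]
#'   (e.g. relative prior sds).
#' @return A list of class `two_stage_fit`: `results` is a nested list
#'   `[[compound]][[flowpath]]` of [summarize_posterior()] objects,
#'   `dh_priors` the per-flowpath Gaussian D_h priors derived in stage 1,
#'   and `reference_compound` the reference used.
#' @export
two_stage_calibration <- function(dataset, reference_compound,
                                  settings = dream_settings(),
                                  prior_args = list()) {
  obs_all <- dataset$observations
  if (!reference_compound %in% names(obs_all))
    stop(sprintf(paste0("reference compound '%s' missing from the dataset; ",
                        "the two-stage D_h prior chain requires a conservative ",
                        "reference on every flowpath"), reference_compound))
  flowpaths <- dataset$flowpaths
  compounds <- names(obs_all)
  fit_one <- function(obs, priors, boundary, seed_offset) {
    s <- settings
    s$seed <- settings$seed + seed_offset
    summarize_posterior(dream_sample(obs, priors, boundary, s))
  }
  results <- stats::setNames(vector("list", length(compounds)), compounds)
  dh_priors <- list()
  # stage 1: conservative reference, wide dispersion prior
  ref_obs <- obs_all[[reference_compound]]
  results[[reference_compound]] <- list()
  for (fp in names(ref_obs)) {
    geom <- flowpaths[[fp]]
    if (is.null(geom)) stop(sprintf("no geometry for flowpath '%s'", fp))
    priors <- do.call(build_prior_set,
                      c(list(geom = geom, dh_prior = "stage1"), prior_args))
    fit <- fit_one(ref_obs[[fp]], priors,
                   dataset$boundaries[[reference_compound]],
                   seed_offset = match(fp, names(flowpaths)))
    results[[reference_compound]][[fp]] <- fit
    dh_row <- fit$table[fit$table$parameter == "D_h", ]
    dh_priors[[fp]] <- list(location = dh_row$median,
                            scale = dh_row$iqr / .IQR_TO_SD)
  }
  # stage 2: all other compounds with the chained Gaussian D_h prior
  for (cmp in setdiff(compounds, reference_compound)) {
    results[[cmp]] <- list()
    for (fp in names(obs_all[[cmp]])) {
      geom <- flowpaths[[fp]]
      dhp <- dh_priors[[fp]]
      if (is.null(dhp))
        stop(sprintf("no stage-1 D_h posterior for flowpath '%s' (reference compound not fitted there)", fp))
      priors <- do.call(build_prior_set,
                        c(list(geom = geom, dh_prior = "manual",
                               dh_location = dhp$location,
                               dh_scale = dhp$scale), prior_args))
      results[[cmp]][[fp]] <- fit_one(
        obs_all[[cmp]][[fp]], priors, dataset$boundaries[[cmp]],
        seed_offset = 100L * match(cmp, compounds) + match(fp, names(flowpaths)))
    }
  }
  structure(list(results = results, dh_priors = dh_priors,
                 reference_compound = reference_compound,
                 settings = settings),
            class = "two_stage_fit")
}
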