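# small helper: hand-built ensemble for diagnostic unit tests
fake_ensemble <- function(chains, retained_frac = 1) {
  ng <- nrow(chains[[1]])
  d <- ncol(chains[[1]])
  arr <- array(NA_real_, c(ng, length(chains), d),
               dimnames = list(NULL, NULL, colnames(chains[[1]])))
  for (i in seq_along(chains)) arr[, i, ] <- chains[[i]]
  structure(list(samples = arr,
                 log_post = matrix(0, ng, length(chains)),
                 retained = seq_len(ng),
                 acceptance_rate = 0.3, n_outlier_resets = 0L,
                 param_names = colnames(chains[[1]]),
                 settings = dream_settings(n_chains = length(chains),
                                           n_generations = ng)),
            class = "chain_ensemble")
}

test_that("log-posterior is -Inf outside the prior support, finite inside", {
  spec <- one_compound_spec(noise = 0, seed = 1)
  spec$compounds$x$loq <- 0
  ds <- simulate_dataset(spec)
  priors <- build_prior_set(default_flowpaths()$b)
  obs <- ds$observations$x$b
  good <- c(k = 0.0189, R = 1.1, v = 0.111 / 24.3, L = 0.111, D_h = 1.1e-4)
  expect_true(is.finite(log_posterior(good, obs, priors, ds$boundaries$x)))
  for (bad_change in list(c(k = 5), c(k = 5e-6), c(R = 0.5), c(R = 50),
                          c(D_h = -1e-4))) {
    bad <- good
    bad[names(bad_change)] <- bad_change
    expect_identical(log_posterior(bad, obs, priors, ds$boundaries$x), -Inf)
  }
})

test_that("noise-free data maximize the log-posterior at the truth", {
  spec <- one_compound_spec(k = 0.0189, R = 1.5, noise = 0, seed = 1)
  spec$compounds$x$loq <- 0
  ds <- simulate_dataset(spec)
  obs <- ds$observations$x$b
  priors <- build_prior_set(default_flowpaths()$b)
  truth <- c(k = 0.0189, R = 1.5, v = 0.111 / 24.3, L = 0.111, D_h = 1.1e-4)
  lp_truth <- log_posterior(truth, obs, priors, ds$boundaries$x,
                            sigma_mode = "fixed", sigma = 0.1)
  # brute-force grid scan around the truth in (k, R)
  for (fk in c(0.6, 0.8, 1.25, 1.6)) {
    for (fR in c(0.8, 1.2, 1.5)) {
      th <- truth
      th["k"] <- truth["k"] * fk
      th["R"] <- max(1, truth["R"] * fR)
      lp <- log_posterior(th, obs, priors, ds$boundaries$x,
                          sigma_mode = "fixed", sigma = 0.1)
      expect_lt(lp, lp_truth)
    }
  }
})

test_that("doubling a fixed sigma costs n log 2 at a perfect fit", {
  spec <- one_compound_spec(noise = 0, seed = 1)
  spec$compounds$x$loq <- 0
  ds <- simulate_dataset(spec)
  obs <- ds$observations$x$b
  # evaluate at the exact generating parameters on the generator grid so the
  # residuals vanish to solver tolerance
  priors <- build_prior_set(default_flowpaths()$b)
  truth <- c(k = 0.0189, R = 1, v = 0.111 / 24.3, L = 0.111, D_h = 1.1e-4)
  g <- spatial_grid(duration = 504)
  lp1 <- log_posterior(truth, obs, priors, ds$boundaries$x, grid = g,
                       sigma_mode = "fixed", sigma = 0.05)
  lp2 <- log_posterior(truth, obs, priors, ds$boundaries$x, grid = g,
                       sigma_mode = "fixed", sigma = 0.10)
  n <- length(obs$times)
  expect_equal(lp1 - lp2, n * log(2), tolerance = 1e-3)
})

test_that("a constant likelihood recovers the priors (prior-recovery)", {
  priors <- build_prior_set(default_flowpaths()$b)
  ens <- dream_sample(NULL, priors,
                      settings = dream_settings(n_generations = 1000, seed = 5))
  draws <- summarize_posterior(ens)$draws
  expect_gte(nrow(draws), 1e4)
  ks_R <- suppressWarnings(
    stats::ks.test(draws[, "R"], "punif", 1, 49)$statistic)
  expect_lt(as.numeric(ks_R), 0.05)
  ks_k <- suppressWarnings(
    stats::ks.test(draws[, "k"], "punif", 1e-5, 4)$statistic)
  expect_lt(as.numeric(ks_k), 0.05)
  # pooled uniform R draws have median ~25
  expect_equal(median(draws[, "R"]), 25, tolerance = 0.06)
})

test_that("sampling is bit-identical under identical seed and settings", {
  spec <- one_compound_spec(seed = 21)
  ds <- simulate_dataset(spec)
  priors <- build_prior_set(default_flowpaths()$b)
  s <- fast_settings(n_generations = 250, seed = 9)
  e1 <- dream_sample(ds$observations$x$b, priors, ds$boundaries$x, s)
  e2 <- dream_sample(ds$observations$x$b, priors, ds$boundaries$x, s)
  expect_identical(e1$samples, e2$samples)
  expect_identical(e1$log_post, e2$log_post)
})

test_that("the chain count must exceed twice the dimension", {
  priors <- build_prior_set(default_flowpaths()$a)
  expect_error(
    dream_sample(NULL, priors,
                 settings = dream_settings(n_chains = 10)),
    "2\\*d\\+1|chains")
})

test_that("Gelman-Rubin diagnostic separates mixed from disjoint chains", {
  set.seed(4)
  mixed <- fake_ensemble(lapply(1:4, function(i)
    matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("a", "b")))))
  rh <- gelman_rubin(mixed)
  expect_true(all(rh < 1.1))
  expect_true(attr(rh, "converged"))
  disjoint <- fake_ensemble(lapply(1:4, function(i)
    matrix(rnorm(600, mean = 10 * i), 300, 2,
           dimnames = list(NULL, c("a", "b")))))
  expect_true(all(gelman_rubin(disjoint) > 3))
  degen <- fake_ensemble(lapply(1:4, function(i)
    matrix(1, 300, 2, dimnames = list(NULL, c("a", "b")))))
  expect_true(anyNA(gelman_rubin(degen)))
})

test_that("posterior summaries report pooled medians and IQRs", {
  ens <- fake_ensemble(list(
    matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(NULL, "k")),
    matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(NULL, "k"))))
  s <- summarize_posterior(ens, rhat_threshold = 1.2)
  expect_equal(s$table$median, 3)
  expect_equal(s$table$iqr, 2)
  expect_equal(s$n_samples, 10)
})

test_that("default sampler settings pool 20 x 2002 = 40040 draws", {
  s <- dream_settings()
  retained <- s$n_generations - floor(s$burn_in * s$n_generations)
  expect_equal(retained, 2002)
  expect_equal(retained * s$n_chains, 40040)
})

test_that("two-stage calibration chains the dispersion prior", {
  # reference generated with known D_h on flowpath b; moderate degrader second
  fps <- default_flowpaths()["b"]
  spec <- scenario_spec(
    compounds = list(
      hct = list(k_sw = 0.002, loq = 0.01,
                 truth = list(b = list(k = 0, R = 1.2))),
      met = list(k_sw = 0.01, loq = 0.01,
                 truth = list(b = list(k = 0.02, R = 2)))),
    flowpaths = fps, seed = 31)
  ds <- simulate_dataset(spec)
  fit <- two_stage_calibration(ds, "hct", fast_settings(n_generations = 500))
  # stage-2 D_h prior location equals the stage-1 posterior median exactly
  st1 <- fit$results$hct$b$table
  expect_equal(fit$dh_priors$b$location,
               st1$median[st1$parameter == "D_h"])
  expect_equal(fit$dh_priors$b$scale,
               st1$iqr[st1$parameter == "D_h"] / (2 * qnorm(0.75)))
  expect_named(fit$results, c("hct", "met"))
  # acceptance rate in a healthy Metropolis range on both fits
  for (r in list(fit$results$hct$b, fit$results$met$b)) {
    expect_gt(r$acceptance_rate, 0.05)
    expect_lt(r$acceptance_rate, 0.6)
  }

  # a reference-only dataset is valid and returns only reference summaries
  ds_ref <- ds
  ds_ref$observations <- ds$observations["hct"]
  fit_ref <- two_stage_calibration(ds_ref, "hct",
                                   fast_settings(n_generations = 300))
  expect_named(fit_ref$results, "hct")

  # missing reference compound is a configuration error
  ds_bad <- ds
  ds_bad$observations <- ds$observations["met"]
  expect_error(two_stage_calibration(ds_bad, "hct", fast_settings()),
               "reference compound")
})
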