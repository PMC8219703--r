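test_that("half-life conversion is exact and monotone", {
  expect_equal(k_to_dt50(log(2)), 1)
  expect_equal(k_to_dt50(0.001), log(2) / 0.001)
  expect_equal(k_to_dt50(0.001), 693.1, tolerance = 1e-4)
  ks <- c(0.01, 0.02, 0.5)
  expect_true(all(diff(k_to_dt50(ks)) < 0))
  expect_error(k_to_dt50(0), "k must be")
  expect_error(k_to_dt50(-1), "k must be")
})

test_that("median DT50 equals DT50 of median k (monotone transform)", {
  set.seed(7)
  k_draws <- exp(rnorm(5001, log(0.02), 0.4))
  expect_equal(median(k_to_dt50(k_draws)), k_to_dt50(median(k_draws)),
               tolerance = 1e-9)
})

test_that("detectability threshold follows the 2x-precision construction", {
  # at rel_sd = 0.25 the -log(1 - 2*rel_sd) = log 2 factor cancels the
  # numerator's log 2, leaving the travel time itself
  expect_equal(dt50_threshold(0.25, log(2)), log(2), tolerance = 1e-12)
  expect_equal(dt50_threshold(0.25, 10), 10, tolerance = 1e-12)
  expect_equal(dt50_threshold(0.05, 11.5), 75.66, tolerance = 1e-3)
  taus <- c(11.5, 20.1, 24.3, 43.3)
  expect_true(all(diff(dt50_threshold(0.05, taus)) > 0))
  expect_error(dt50_threshold(0.5, 10), "rel_sd")
  expect_error(dt50_threshold(0.05, -1), "travel_time")
})

test_that("inf-masking is strict, suppresses the IQR, and is idempotent", {
  r <- compound_flowpath_result("x", "a", R_median = 1.2, R_iqr = 0.1,
                                k_median = log(2) / 800, k_iqr = 1e-4)
  m <- apply_inf_mask(r, 700)
  expect_identical(m$dt50_median, Inf)
  expect_true(m$dt50_masked)
  expect_true(is.na(m$dt50_iqr))
  expect_identical(apply_inf_mask(m, 700), m)
  # below and exactly at the threshold: unchanged
  r2 <- compound_flowpath_result("x", "a", 1.1, 0.13, log(2) / 6.63, 1e-3,
                                 dt50_median = 6.63, dt50_iqr = 0.58)
  expect_equal(apply_inf_mask(r2, 75.66)$dt50_median, 6.63)
  r3 <- compound_flowpath_result("x", "a", 1, 0, log(2) / 700, 0,
                                 dt50_median = 700)
  expect_equal(apply_inf_mask(r3, 700)$dt50_median, 700)
})

test_that("rmse matches closed forms and averages over flowpaths", {
  obs <- observation_set("x", "a", c(0, 24, 48), c(1, 2, 3))
  expect_equal(rmse(obs, c(1, 2, 3)), 0)
  expect_equal(rmse(observation_set("x", "a", c(0, 24), c(2, 2)), c(3, 1)), 1)
  expect_equal(rmse(obs, c(1, 2, 3) + 0.25), 0.25)
  curve <- breakthrough_curve(seq(0, 48, 0.5), rep(2, 97))
  expect_equal(rmse(obs, curve), sqrt(mean((c(1, 2, 3) - 2)^2)))
  expect_equal(average_rmse(c(1, 2, 3, 4)), 2.5)
  expect_error(rmse(obs, c(1, 2)), "cover")
})

test_that("results table renders Table-2 style cells and round-trips", {
  r1 <- compound_flowpath_result("acs", "a", 1.10, 0.13, log(2) / 6.63, 0.01,
                                 dt50_median = 6.63, dt50_iqr = 0.58,
                                 rmse = 1.5)
  r2 <- compound_flowpath_result("acs", "b", 1.00, 0.00, log(2) / 36.6, 0.01,
                                 dt50_median = 36.6, dt50_iqr = 2.45,
                                 rmse = 1.4)
  r3 <- apply_inf_mask(
    compound_flowpath_result("cfa", "a", 2.53, 0.84, log(2) / 900, 1e-4,
                             rmse = 0.9), 75.7)
  tab <- assemble_results_table(list(r1, r2, r3))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$R_a[tab$Compound == "acs"], "1.1 (0.13)")
  expect_equal(tab$DT50_a[tab$Compound == "acs"], "6.63 (0.58)")
  expect_equal(tab$DT50_a[tab$Compound == "cfa"], "Inf")
  # missing flowpath entries render as explicit gaps
  expect_equal(tab$R_c[1], "--")
  # round-trip the rendered cells
  parsed <- parse_result_cell(tab$DT50_a)
  expect_equal(parsed$median, c(6.63, Inf))
  expect_equal(parsed$iqr, c(0.58, NA))
  expect_equal(parse_result_cell("1.1 (0.13)")$median, 1.1)
  # shape: 1 compound column + 4 R + 4 DT50 + RMSE
  expect_equal(ncol(tab), 10)
})
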