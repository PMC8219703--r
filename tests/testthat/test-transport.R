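test_that("boundary interpolation is exact at samples and linear between", {
  s <- boundary_series(c(0, 24), c(11.5, 9.0))
  expect_equal(interpolate_boundary(s, 0), 11.5)
  expect_equal(interpolate_boundary(boundary_series(c(0, 24), c(10, 10)), 12), 10)
  expect_equal(interpolate_boundary(boundary_series(c(0, 24), c(10, 0)), 12), 5)
  expect_error(interpolate_boundary(s, 25), "extrapolate")
  expect_error(interpolate_boundary(s, -1), "extrapolate")
})

test_that("type constructors enforce physical invariants", {
  expect_error(transport_params(-0.1, 1, 0.004, 0.05, 1e-4), "k")
  expect_error(transport_params(0.1, 0.5, 0.004, 0.05, 1e-4), "R")
  expect_error(transport_params(0.1, 1, 0, 0.05, 1e-4), "v")
  expect_error(transport_params(0.1, 1, 0.004, 0.05, 0), "D_h")
  expect_error(spatial_grid(n_cells = 10), "n_cells")
  expect_error(boundary_series(c(1, 2), c(1, 1)), "start at time 0")
  expect_error(boundary_series(c(0, 2), c(1, -1)), "negative|>= 0")
})

test_that("zero boundary gives an identically zero curve", {
  p <- transport_params(0.05, 1.5, 0.004, 0.05, 1e-4)
  b <- boundary_series(c(0, 504), c(0, 0))
  curve <- solve_ade(p, b, fast_grid(48))
  expect_true(all(curve$concentrations == 0))
})

test_that("decay-free constant boundary approaches a uniform steady state", {
  p <- transport_params(0, 1, 0.004, 0.05, 1e-4)
  b <- boundary_series(c(0, 5000), c(10, 10))
  g <- spatial_grid(n_cells = 50, time_step = 0.5, duration = 2000)
  curve <- solve_ade(p, b, g)
  expect_equal(curve$concentrations[length(curve$times)], 10, tolerance = 1e-6)
})

test_that("numerical solution matches the analytic constant-boundary oracle", {
  p <- transport_params(k = 0.05, R = 1, v = 0.004, L = 0.05, D_h = 1e-4)
  b <- boundary_series(c(0, 504), c(11.5, 11.5))
  curve <- solve_ade(p, b, spatial_grid(0.25, 125, 0.1, 30))
  num <- stats::approx(curve$times, curve$concentrations, xout = 24)$y
  ana <- analytic_constant_bc(p, 11.5, 24)
  expect_lt(abs(num - ana) / 11.5, 0.01)
  # convergence: a 4x refined grid is at least 2x closer to the oracle
  fine <- solve_ade(p, b, spatial_grid(0.25, 500, 0.025, 30))
  num2 <- stats::approx(fine$times, fine$concentrations, xout = 24)$y
  expect_lt(abs(num2 - ana), 0.5 * abs(num - ana))
})

test_that("analytic solution limits: steady state and zero inlet", {
  p <- transport_params(k = 0.05, R = 1.3, v = 0.004, L = 0.05, D_h = 1e-4)
  tinf <- 1e8
  expect_equal(analytic_constant_bc(p, 11.5, tinf),
               11.5 * exp(p$L * (p$v - sqrt(p$v^2 + 4 * p$k * p$D_h)) /
                            (2 * p$D_h)),
               tolerance = 1e-9)
  p0 <- transport_params(k = 0, R = 1, v = 0.004, L = 0.05, D_h = 1e-4)
  expect_equal(analytic_constant_bc(p0, 10, tinf), 10, tolerance = 1e-9)
  expect_equal(analytic_constant_bc(p, 0, c(1, 10)), c(0, 0))
  expect_error(analytic_constant_bc(p, 10, 0), "t must be")
})

test_that("first temporal moment of a symmetric pulse is its centre", {
  tt <- seq(0, 20, 0.5)
  tri <- pmax(0, 1 - abs(tt - 10) / 3)
  expect_equal(temporal_moment(breakthrough_curve(tt, tri)), 10)
  expect_error(temporal_moment(breakthrough_curve(tt, tt * 0)), "mass")
})

test_that("conservative pulse arrives after the advective travel time", {
  # flowpath a median geometry: L = 5 cm, tau = 11.5 h => v = L/tau
  p <- transport_params(k = 0, R = 1, v = 0.05 / 11.5, L = 0.05, D_h = 1e-6)
  b <- boundary_series(c(0, 0.5, 1), c(0, 1, 0))
  g <- spatial_grid(0.25, 125, 0.05, 120)
  curve <- suppressWarnings(solve_ade(p, b, g))
  delay <- temporal_moment(curve) - temporal_moment(b)
  expect_equal(delay, 11.5, tolerance = 0.02 * 11.5)
})

test_that("first-moment delay scales linearly with retardation", {
  b <- boundary_series(c(0, 0.5, 1), c(0, 1, 0))
  delays <- vapply(c(1, 2, 4), function(R) {
    p <- transport_params(k = 0, R = R, v = 0.05 / 11.5, L = 0.05, D_h = 1e-6)
    g <- spatial_grid(0.25, 125, 0.05, 120 * R)
    curve <- suppressWarnings(solve_ade(p, b, g))
    temporal_moment(curve) - temporal_moment(b)
  }, numeric(1))
  expect_equal(delays / delays[1], c(1, 2, 4), tolerance = 0.02)
})

test_that("solution is pointwise non-increasing in k", {
  b <- boundary_series(c(0, 24, 48, 504) , c(11.5, 9, 8, 2))
  g <- fast_grid(200)
  ks <- c(0, 0.01, 0.05, 0.2)
  curves <- lapply(ks, function(k)
    solve_ade(transport_params(k, 1.3, 0.0046, 0.111, 1.1e-4), b, g))
  for (i in seq_len(length(ks) - 1)) {
    expect_true(all(curves[[i + 1]]$concentrations <=
                      curves[[i]]$concentrations + 1e-12))
  }
})

test_that("solver output is non-negative and linear in the boundary", {
  p <- transport_params(0.02, 1.5, 0.0046, 0.111, 1.1e-4)
  b <- boundary_series(c(0, 24, 48, 200), c(11.5, 2, 9, 0.5))
  g <- fast_grid(200)
  c1 <- solve_ade(p, b, g)
  expect_gte(min(c1$concentrations), -1e-9 * max(b$concentrations))
  b3 <- boundary_series(b$times, 3 * b$concentrations)
  c3 <- solve_ade(p, b3, g)
  expect_equal(c3$concentrations, 3 * c1$concentrations, tolerance = 1e-9)
})

test_that("high cell Peclet number warns and falls back to upwinding", {
  p <- transport_params(0, 1, 0.01, 0.05, 1e-6)  # Pe = 20 at dx = 2 mm
  b <- boundary_series(c(0, 100), c(10, 10))
  g <- spatial_grid(0.25, 125, 0.1, 50)
  expect_warning(solve_ade(p, b, g), "Peclet")
  expect_silent(solve_ade(p, b, g, quiet = TRUE))
  curve <- solve_ade(p, b, g, quiet = TRUE)
  expect_true(all(is.finite(curve$concentrations)))
  expect_gte(min(curve$concentrations), -1e-9 * 10)
})

test_that("observation point L must sit inside the domain", {
  b <- boundary_series(c(0, 100), c(10, 10))
  expect_error(
    solve_ade(transport_params(0, 1, 0.004, 0.3, 1e-4), b, fast_grid(10)),
    "domain")
})
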