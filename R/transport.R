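#' Transport parameters for one compound on one flowpath
#'
#' Bundles the physical parameters of the one-dimensional
#' advection--dispersion--retardation--decay equation
#' \deqn{R \frac{\partial c}{\partial t} =
#'   D_h \frac{\partial^2 c}{\partial x^2} -
#'   v \frac{\partial c}{\partial x} - k c}
#' describing reactive solute transport along a single hyporheic flowpath.
#'
#' @param k first-order removal rate constant (1/h), \eqn{k \ge 0}.
#' @param R retardation coefficient (dimensionless), \eqn{R \ge 1}.
#' @param v porewater velocity along the flowpath (m/h), \eqn{v > 0}.
#' @param L flowpath length from the sediment--water interface to the
#'   observation point (m).
#' @param D_h effective hydrodynamic dispersion coefficient (m^2/h),
#'   \eqn{D_h > 0}.
#' @return An object of class `transport_params`.
#' @examples
#' transport_params(k = 0.02, R = 1.5, v = 0.0046, L = 0.111, D_h = 1.1e-4)
#' @export
transport_params <- function(k, R, v, L, D_h) {
  stopifnot(is.numeric(k), is.numeric(R), is.numeric(v), is.numeric(L),
            is.numeric(D_h), length(k) == 1L, length(R) == 1L,
            length(v) == 1L, length(L) == 1L, length(D_h) == 1L)
  if (!is.finite(k) || k < 0) stop("k must be finite and >= 0")
  if (!is.finite(R) || R < 1) stop("R must be finite and >= 1")
  if (!is.finite(v) || v <= 0) stop("v must be finite and > 0")
  if (!is.finite(L) || L <= 0) stop("L must be finite and > 0")
  if (!is.finite(D_h) || D_h <= 0) stop("D_h must be finite and > 0")
  structure(list(k = k, R = R, v = v, L = L, D_h = D_h),
            class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Transport parameters:\n")
  cat(sprintf("  k   = %g 1/h   (DT50 %s h)\n", x$k,
              if (x$k > 0) format(log(2) / x$k, digits = 4) else "Inf"))
  cat(sprintf("  R   = %g\n  v   = %g m/h\n  L   = %g m\n  D_h = %g m^2/h\n",
              x$R, x$v, x$L, x$D_h))
  invisible(x)
}

#' Spatial and temporal discretization grid
#'
#' The default mirrors the flume-bedform setting: a 0.25 m domain with the
#' zero-gradient outlet at its far end, 125 cells (2 mm spacing) and a 0.1 h
#' time step over a 21 d (504 h) simulation window.
#'
#' @param domain_length domain length (m); the Neumann outlet sits here.
#' @param n_cells number of uniform cells (>= 20).
#' @param time_step time step (h).
#' @param duration simulated duration (h).
#' @return An object of class `spatial_grid`.
#' @export
spatial_grid <- function(domain_length = 0.25, n_cells = 125,
                         time_step = 0.1, duration = 504) {
  stopifnot(domain_length > 0, time_step > 0, duration > 0)
  n_cells <- as.integer(n_cells)
  if (n_cells < 20L) stop("n_cells must be >= 20")
  structure(list(domain_length = domain_length, n_cells = n_cells,
                 dx = domain_length / n_cells,
                 time_step = time_step, duration = duration,
                 times = seq(0, by = time_step,
                             length.out = ceiling(duration / time_step - 1e-9) + 1L)),
            class = "spatial_grid")
}

#' Time-varying surface-water boundary concentration record
#'
#' Surface-water concentrations sampled at discrete times serve as the
#' Dirichlet inlet boundary condition of the transport model; between samples
#' the boundary is interpolated linearly.
#'
#' @param times sampling times (h since injection), sorted, unique,
#'   starting at 0.
#' @param concentrations concentrations (ug/L), non-negative, same length.
#' @return An object of class `boundary_series`.
#' @export
boundary_series <- function(times, concentrations) {
  stopifnot(is.numeric(times), is.numeric(concentrations),
            length(times) == length(concentrations), length(times) >= 1L)
  if (times[1] != 0) stop("boundary series must start at time 0")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(concentrations < 0)) stop("boundary concentrations must be >= 0")
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations)),
            class = "boundary_series")
}

#' Interpolate the boundary series at arbitrary times
#'
#' Piecewise-linear interpolation between surface-water samples, exact at the
#' sample times. Requests outside the record are an error: the record defines
#' the boundary condition and is not extrapolated.
#'
#' @param series a [boundary_series()].
#' @param t time(s) in hours, within `[0, max(series$times)]`.
#' @return Concentration(s) in ug/L.
#' @export
interpolate_boundary <- function(series, t) {
  stopifnot(inherits(series, "boundary_series"))
  if (any(t < series$times[1] - 1e-12) ||
      any(t > series$times[length(series$times)] + 1e-12))
    stop("t outside the boundary record; refusing to extrapolate")
  if (length(series$times) == 1L) return(rep(series$concentrations, length(t)))
  stats::approx(series$times, series$concentrations, xout = t,
                rule = 2)$y
}

#' Simulated breakthrough curve at the observation point
#'
#' @param times time axis (h), sorted.
#' @param concentrations concentrations at x = L (ug/L).
#' @return An object of class `breakthrough_curve`.
#' @export
breakthrough_curve <- function(times, concentrations) {
  stopifnot(length(times) == length(concentrations))
  if (is.unsorted(times)) stop("times must be sorted")
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations)),
            class = "breakthrough_curve")
}

#' Solve the advection--dispersion--retardation--decay equation
#'
#' Semi-implicit (Crank--Nicolson) finite-difference solution of the 1-D
#' transport equation with a time-varying Dirichlet inlet, a zero-gradient
#' (Neumann) outlet at the far end of the domain, and a clean-sediment
#' initial condition \eqn{c(x,0)=0}. The matrix is tridiagonal and constant
#' in time, so each step is a single Thomas-algorithm solve (implemented in
#' compiled code). Advection is discretized centrally; when the cell Peclet
#' number \eqn{Pe = v\,\Delta x / D_h} exceeds `peclet_limit`, first-order
#' upwinding is used instead to suppress spurious oscillations (with a
#' warning unless `quiet = TRUE`).
#'
#' The observation point x = L is evaluated by linear interpolation between
#' the two bracketing nodes, because L is a continuous (inferred) parameter.
#' Boundary values are held at the last sample beyond the end of the
#' boundary record, so pulse experiments may be run past the record.
#'
#' @param params a [transport_params()] object; `params$L` must lie inside
#'   the domain.
#' @param boundary a [boundary_series()].
#' @param grid a [spatial_grid()].
#' @param upwind `"auto"` (default: upwind iff cell Peclet > `peclet_limit`),
#'   `"never"`, or `"always"`.
#' @param peclet_limit threshold on the cell Peclet number (default 2).
#' @param quiet suppress the Peclet warning (used inside MCMC loops).
#' @return A [breakthrough_curve()] on the grid's time axis.
#' @examples
#' p <- transport_params(k = 0.05, R = 1, v = 0.004, L = 0.05, D_h = 1e-4)
#' b <- boundary_series(c(0, 504), c(11.5, 11.5))
#' g <- spatial_grid(n_cells = 50, time_step = 0.5, duration = 48)
#' curve <- solve_ade(p, b, g)
#' @export
solve_ade <- function(params, boundary, grid = spatial_grid(),
                      upwind = c("auto", "never", "always"),
                      peclet_limit = 2, quiet = FALSE) {
  stopifnot(inherits(params, "transport_params"),
            inherits(boundary, "boundary_series"),
            inherits(grid, "spatial_grid"))
  upwind <- match.arg(upwind)
  if (params$L >= grid$domain_length)
    stop("flowpath length L must be smaller than the domain length")
  pe <- params$v * grid$dx / params$D_h
  use_upwind <- switch(upwind,
    always = TRUE,
    never = FALSE,
    auto = pe > peclet_limit)
  if (upwind == "auto" && use_upwind && !quiet)
    warning(sprintf(
      "cell Peclet number %.2f exceeds %g; falling back to upwind advection",
      pe, peclet_limit))
  conc <- .ade_solve_cpp(params$k, params$R, params$v, params$D_h,
                         boundary$times, boundary$concentrations,
                         grid$domain_length, grid$n_cells,
                         grid$time_step, grid$duration,
                         params$L, use_upwind, 0.5)
  if (any(!is.finite(conc))) stop("transport solver produced non-finite output")
  breakthrough_curve(grid$times, conc)
}

#' Analytic constant-boundary solution (verification oracle)
#'
#' Exact solution of the semi-infinite advection--dispersion--decay problem
#' with retardation, constant inlet concentration `c0` switched on at t = 0
#' and zero initial condition (the Ogata--Banks-type erfc expression with a
#' decay term):
#' \deqn{\frac{c(L,t)}{c_0} = \tfrac12 e^{(v-u)L/2D_h}\,
#'   \mathrm{erfc}\!\left(\frac{RL-ut}{2\sqrt{D_h R t}}\right) +
#'   \tfrac12 e^{(v+u)L/2D_h}\,
#'   \mathrm{erfc}\!\left(\frac{RL+ut}{2\sqrt{D_h R t}}\right)}
#' with \eqn{u = \sqrt{v^2 + 4 k D_h}}. Valid while the outlet boundary of
#' the finite-domain numerical model is not yet felt; used as the test
#' oracle for [solve_ade()]. The second (potentially overflowing) term is
#' evaluated on the log scale.
#'
#' @param params a [transport_params()].
#' @param c0 constant inlet concentration (ug/L).
#' @param t time(s) in hours, strictly positive.
#' @return Concentration(s) at x = L.
#' @export
analytic_constant_bc <- function(params, c0, t) {
  stopifnot(inherits(params, "transport_params"))
  if (any(t <= 0)) stop("t must be > 0")
  if (c0 == 0) return(rep(0, length(t)))
  v <- params$v; D <- params$D_h; L <- params$L; R <- params$R; k <- params$k
  u <- sqrt(v^2 + 4 * k * D)
  s <- 2 * sqrt(D * R * t)
  a1 <- (R * L - u * t) / s
  a2 <- (R * L + u * t) / s
  # erfc(x) = 2*pnorm(-x*sqrt(2)); log-scale for the growing exponential
  log_erfc <- function(x) log(2) + stats::pnorm(x * sqrt(2), lower.tail = FALSE,
                                                log.p = TRUE)
  term1 <- exp((v - u) * L / (2 * D) + log_erfc(a1))
  term2 <- exp((v + u) * L / (2 * D) + log_erfc(a2))
  0.5 * c0 * (term1 + term2)
}

#' Normalized temporal moment of a breakthrough curve
#'
#' For `order = 1` returns the concentration-weighted mean time
#' \eqn{\int t\,c\,dt / \int c\,dt} (trapezoidal integration). The
#' difference between outlet and inlet first moments of a conservative,
#' non-retarded pulse equals the mean advective travel time L/v; retardation
#' scales it by R.
#'
#' @param curve a [breakthrough_curve()] or [boundary_series()] holding a
#'   finite pulse (concentrations near zero at both ends of the record).
#' @param order moment order (non-negative integer); `order = 0` returns the
#'   unnormalized mass \eqn{\int c\,dt}.
#' @return The (normalized, for order >= 1) temporal moment.
#' @export
temporal_moment <- function(curve, order = 1) {
  stopifnot(order >= 0, order == round(order))
  t <- curve$times
  c <- curve$concentrations
  if (length(t) < 2L) stop("need at least two samples")
  trapz <- function(y) sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
  m0 <- trapz(c)
  if (m0 <= 0) stop("undefined moment: curve has no mass")
  if (order == 0) return(m0)
  trapz(t^order * c) / m0
}
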