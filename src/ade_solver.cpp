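#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear boundary interpolation; values are held constant beyond
// the last sample (the solver may be run past the boundary record, e.g. for
// pulse experiments where the inlet has returned to zero).
static inline double boundary_at(double t,
                                 const NumericVector& bt,
                                 const NumericVector& bc) {
  const int n = bt.size();
  if (t <= bt[0]) return bc[0];
  if (t >= bt[n - 1]) return bc[n - 1];
  // bt is sorted; binary search for the bracketing interval
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (bt[mid] <= t) lo = mid; else hi = mid;
  }
  double w = (t - bt[lo]) / (bt[hi] - bt[lo]);
  return bc[lo] + w * (bc[hi] - bc[lo]);
}

// Theta-scheme (default Crank-Nicolson) finite-difference solution of
//   R dc/dt = D d2c/dx2 - v dc/dx - k c ,  x in (0, Lx]
// with Dirichlet inlet c(0,t) from a piecewise-linear boundary series,
// zero-gradient (Neumann) outlet at x = Lx, and c(x,0) = 0.
//
// Spatial operator: central differences for diffusion; central or first-order
// upwind differences for advection (upwind = true). The system matrix is
// constant in time, so its Thomas-algorithm factorisation is computed once.
//
// Returns c(obs_x, t) on the time grid t = 0, dt, ..., nt*dt, with obs_x
// evaluated by linear interpolation between the bracketing nodes.
// [[Rcpp::export(name = ".ade_solve_cpp")]]
NumericVector ade_solve_cpp(double k, double R, double v, double D,
                            NumericVector btimes, NumericVector bconc,
                            double domain_length, int n_cells,
                            double dt, double duration,
                            double obs_x, bool upwind, double theta) {
  const int N = n_cells;               // unknown nodes 1..N (node 0 Dirichlet)
  const double dx = domain_length / N;
  const int nt = (int)std::ceil(duration / dt - 1e-9);

  // spatial-operator stencil A: lower, diag, upper for nodes 1..N
  std::vector<double> Al(N), Ad(N), Au(N);
  const double a_dif = D / (dx * dx);
  for (int i = 0; i < N; ++i) {
    if (upwind) {
      Al[i] = a_dif + v / dx;
      Ad[i] = -2.0 * a_dif - v / dx - k;
      Au[i] = a_dif;
    } else {
      Al[i] = a_dif + v / (2.0 * dx);
      Ad[i] = -2.0 * a_dif - k;
      Au[i] = a_dif - v / (2.0 * dx);
    }
  }
  // Neumann outlet (node N): ghost node c_{N+1} = c_{N-1}
  if (upwind) {
    Al[N - 1] = 2.0 * a_dif + v / dx;
    Ad[N - 1] = -2.0 * a_dif - v / dx - k;
  } else {
    Al[N - 1] = 2.0 * a_dif;
    Ad[N - 1] = -2.0 * a_dif - k;
  }
  Au[N - 1] = 0.0;

  // implicit matrix M = (R/dt) I - theta A ; Thomas factorisation (constant)
  const double rdt = R / dt;
  std::vector<double> ml(N), md(N), mu(N), cp(N);
  for (int i = 0; i < N; ++i) {
    ml[i] = -theta * Al[i];
    md[i] = rdt - theta * Ad[i];
    mu[i] = -theta * Au[i];
  }
  cp[0] = mu[0] / md[0];
  for (int i = 1; i < N; ++i)
    cp[i] = mu[i] / (md[i] - ml[i] * cp[i - 1]);

  // observation interpolation weights (node 0 at x=0 is the boundary itself)
  int jlo = (int)std::floor(obs_x / dx);
  if (jlo >= N) jlo = N - 1;
  if (jlo < 0) jlo = 0;
  const double whi = obs_x / dx - jlo;

  std::vector<double> c(N, 0.0), rhs(N), dp(N);
  NumericVector out(nt + 1);
  double b_now = boundary_at(0.0, btimes, bconc);
  out[0] = (obs_x <= 0.0) ? b_now : 0.0;  // c(x,0) = 0 for x > 0

  for (int n = 1; n <= nt; ++n) {
    const double t_new = n * dt;
    const double b_new = boundary_at(t_new, btimes, bconc);
    // explicit part: (R/dt + (1-theta) A) c^n  + boundary contributions
    const double om = 1.0 - theta;
    for (int i = 0; i < N; ++i) {
      const double cm1 = (i == 0) ? b_now : c[i - 1];
      const double cp1 = (i == N - 1) ? 0.0 : c[i + 1];
      rhs[i] = rdt * c[i] + om * (Al[i] * cm1 + Ad[i] * c[i] + Au[i] * cp1);
    }
    rhs[0] += theta * Al[0] * b_new;

    // Thomas solve
    dp[0] = rhs[0] / md[0];
    for (int i = 1; i < N; ++i)
      dp[i] = (rhs[i] - ml[i] * dp[i - 1]) / (md[i] - ml[i] * cp[i - 1]);
    c[N - 1] = dp[N - 1];
    for (int i = N - 2; i >= 0; --i)
      c[i] = dp[i] - cp[i] * c[i + 1];

    b_now = b_new;
    const double clo = (jlo == 0) ? b_now : c[jlo - 1];
    const double chi = c[jlo];
    out[n] = (1.0 - whi) * clo + whi * chi;
    if (obs_x <= 0.0) out[n] = b_now;
  }

  if (!std::isfinite(out[nt])) stop("transport solver produced non-finite output");
  return out;
}
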