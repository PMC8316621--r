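#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overflow-safe population sigmoid: zeta_max / (1 + exp(r * (nu_th - nu))).
static inline double sigm(double v, double r, double zmax, double vth) {
  double ex = r * (vth - v);
  if (ex > 500.0) ex = 500.0;
  if (ex < -500.0) ex = -500.0;
  return zmax / (1.0 + std::exp(ex));
}

// Euler-Maruyama integration of the coupled Jansen-Rit network.
// W: n x n normalized coupling matrix (zero diagonal). r0: per-node pyramidal
// sigmoid slope. States per node: x0..x3 (PSP block outputs) and y0..y3.
// The Gaussian input p(t) ~ N(mu, sigma) is redrawn each step and held over
// the step (piecewise-constant input): y1 += dt * A * a * (p + S(...)).
// Returns the retained EEG-like potential nu and pyramidal rate zeta
// (n x (n_steps - n_discard)), sampled at every step after the discard.
// [[Rcpp::export]]
List jr_integrate_cpp(NumericMatrix W, NumericVector r0, double alpha,
                      List params, double mu, double sigma,
                      double dt, int n_steps, int n_discard) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("coupling matrix must be square");
  if (r0.size() != n) stop("gain map length (%d) != node count (%d)",
                           (int)r0.size(), n);
  const double A = params["A"], B = params["B"], a = params["a"],
    b = params["b"], abar = params["a_bar"], C = params["C"],
    C1 = params["C1"], C2 = params["C2"], C3 = params["C3"],
    C4 = params["C4"], zmax = params["zeta_max"], vth = params["nu_th"],
    r1 = params["r1"], r2 = params["r2"];
  const int n_keep = n_steps - n_discard;
  if (n_keep <= 0) stop("discard must be shorter than duration");

  NumericMatrix nu_out(n, n_keep), zeta_out(n, n_keep);
  std::vector<double> x0(n, 0.0), x1(n, 0.0), x2(n, 0.0), x3(n, 0.0),
    y0(n, 0.0), y1(n, 0.0), y2(n, 0.0), y3(n, 0.0),
    z(n, 0.0), dy0(n), dy1(n), dy2(n), dy3(n);
  const double noise_amp = A * a * sigma * dt; // p(t) held over each step

  const double *Wp = W.begin(); // column-major
  for (int t = 0; t < n_steps; ++t) {
    // long-range input z_i = sum_j W_ij x3_j (column-wise for locality)
    std::fill(z.begin(), z.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double xj = x3[j];
      const double *col = Wp + (size_t)j * n;
      for (int i = 0; i < n; ++i) z[i] += col[i] * xj;
    }
    for (int i = 0; i < n; ++i) {
      double nu_i = C2 * x1[i] - C4 * x2[i] + C * alpha * z[i];
      double Spyr = sigm(nu_i, r0[i], zmax, vth);
      dy0[i] = A * a * Spyr - 2.0 * a * y0[i] - a * a * x0[i];
      dy1[i] = A * a * (mu + sigm(C1 * x0[i], r1, zmax, vth))
        - 2.0 * a * y1[i] - a * a * x1[i];
      dy2[i] = B * b * sigm(C3 * x0[i], r2, zmax, vth)
        - 2.0 * b * y2[i] - b * b * x2[i];
      dy3[i] = A * abar * Spyr - 2.0 * abar * y3[i] - abar * abar * x3[i];
      if (t >= n_discard) {
        nu_out(i, t - n_discard) = nu_i;
        zeta_out(i, t - n_discard) = sigm(nu_i, r0[i], zmax, vth);
      }
    }
    for (int i = 0; i < n; ++i) {
      x0[i] += dt * y0[i];
      x1[i] += dt * y1[i];
      x2[i] += dt * y2[i];
      x3[i] += dt * y3[i];
      y0[i] += dt * dy0[i];
      y1[i] += dt * dy1[i];
      if (sigma > 0.0) y1[i] += noise_amp * norm_rand();
      y2[i] += dt * dy2[i];
      y3[i] += dt * dy3[i];
    }
    if (t % 2000 == 0) {
      Rcpp::checkUserInterrupt();
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(x1[i]))
          stop("simulation diverged (non-finite state) at t = %.3f s, node %d",
               t * dt, i + 1);
    }
  }
  return List::create(_["nu"] = nu_out, _["zeta"] = zeta_out);
}

// Generalized hemodynamic model: firing rate zeta drives vasodilatory signal s,
// inflow f, volume v and deoxyhemoglobin q (Euler, step dt);
// BOLD = V0 [k1 (1-q) + k2 (1 - q/v) + k3 (1 - v)].
// init_steady = true starts each node at the steady state implied by its
// initial firing rate (emulating a long pre-discarded lead-in, so no shared
// onset transient leaks into the retained window); false starts from the
// rest state (0, 1, 1, 1).
// [[Rcpp::export]]
NumericMatrix bold_forward_cpp(NumericMatrix zeta, List params, double dt,
                               bool init_steady) {
  const int n = zeta.nrow(), T = zeta.ncol();
  const double tau_s = params["tau_s"], tau_f = params["tau_f"],
    tau_v = params["tau_v"], tau_q = params["tau_q"],
    kappa = params["kappa"], E0 = params["E0"], V0 = params["V0"],
    k1 = params["k1"], k2 = params["k2"], k3 = params["k3"];
  NumericMatrix bold(n, T);
  for (int i = 0; i < n; ++i) {
    double s = 0.0, f = 1.0, v = 1.0, q = 1.0;
    if (init_steady) {
      const double z0 = zeta(i, 0);
      f = 1.0 + tau_f * z0;          // s-dot = 0 with s = 0
      v = std::pow(f, kappa);        // v-dot = 0: outflow v^(1/kappa) = f
      q = v * (1.0 - std::pow(1.0 - E0, 1.0 / f)) / E0; // q-dot = 0
    }
    for (int t = 0; t < T; ++t) {
      bold(i, t) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
      double fe = f > 1e-9 ? f : 1e-9;
      double ve = v > 1e-9 ? v : 1e-9;
      double ds = zeta(i, t) - s / tau_s - (f - 1.0) / tau_f;
      double dfl = s;
      double dv = (f - std::pow(ve, 1.0 / kappa)) / tau_v;
      double dq = (f * (1.0 - std::pow(1.0 - E0, 1.0 / fe)) / E0
                   - q * std::pow(ve, 1.0 / kappa) / ve) / tau_q;
      s += dt * ds;
      f += dt * dfl;
      v += dt * dv;
      q += dt * dq;
      if (!std::isfinite(q))
        stop("hemodynamic state diverged at node %d, t = %.3f s", i + 1, t * dt);
    }
  }
  return bold;
}
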