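#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system. Overwrites nothing; O(n).
// lower: sub-diagonal (n-1), diag: main (n), upper: super-diagonal (n-1).
// [[Rcpp::export(name = ".cpp_thomas")]]
NumericVector cpp_thomas(NumericVector lower, NumericVector diag,
                         NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  if (rhs.size() != n) stop("rhs length must match diag length");
  if (n > 1 && (lower.size() != n - 1 || upper.size() != n - 1))
    stop("lower/upper must have length n - 1");
  std::vector<double> cp(n), dp(n);
  double piv = diag[0];
  if (piv == 0.0) stop("singular tridiagonal system: zero pivot at row 1");
  cp[0] = (n > 1) ? upper[0] / piv : 0.0;
  dp[0] = rhs[0] / piv;
  for (int i = 1; i < n; ++i) {
    piv = diag[i] - lower[i - 1] * cp[i - 1];
    if (piv == 0.0)
      stop("singular tridiagonal system: zero pivot at row %d", i + 1);
    cp[i] = (i < n - 1) ? upper[i] / piv : 0.0;
    dp[i] = (rhs[i] - lower[i - 1] * dp[i - 1]) / piv;
  }
  NumericVector x(n);
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return x;
}

static inline double clamp50(double u) {
  return u > 50.0 ? 50.0 : (u < -50.0 ? -50.0 : u);
}

// Implicit FVM time marching of the 1D diffusion equation with a
// semi-implicit Butler-Volmer flux condition at node 0 and Dirichlet
// far-field at node n-1. Potential E is the triangular waveform; the
// Butler-Volmer exponentials are evaluated at the new-step potential
// while the surface concentration enters implicitly, preserving the
// tridiagonal structure.
//
// Current sign convention (IUPAC): anodic positive, cathodic negative;
// i = -F * ECSA * D * (c[1]-c[0])/dz, where by the folded boundary row
// (c[1]-c[0])/dz equals the Butler-Volmer surface gradient.
//
// Returns samples at each recorded potential step (t, E, i) plus the
// final concentration field.
// [[Rcpp::export(name = ".cpp_simulate_cv")]]
List cpp_simulate_cv(double D, double k0, double alpha, double ECSA,
                     double c_b, double E_f0, double T_K,
                     double E_start, double E_L, double E_R, double v,
                     double E_step, int n_cycles, int dir_sign,
                     int n_points, double L, int substeps) {
  const double F = 96485.0, Rgas = 8.314;
  if (substeps < 1) stop("substeps must be >= 1");
  if (n_points < 3) stop("n_points must be >= 3");

  const int n = n_points;
  const double dz = L / (n - 1);
  const double W = E_R - E_L;
  const double period = 2.0 * W / v;
  const double dur = n_cycles * period;
  const double dt_rec = E_step / v;
  const int n_rec = (int)std::llround(dur / dt_rec);
  const double dt = dt_rec / substeps;
  const double r = D * dt / (dz * dz);
  const double f = F / (Rgas * T_K);
  const double xi0 = E_start - E_L;

  std::vector<double> c(n, c_b);
  NumericVector lower(n - 1), diag(n), upper(n - 1), rhs(n);

  // interior rows are constant in time
  for (int j = 1; j < n - 1; ++j) {
    lower[j - 1] = -r;
    diag[j] = 1.0 + 2.0 * r;
    upper[j] = -r;
  }
  diag[n - 1] = 1.0;
  lower[n - 2] = 0.0;

  NumericVector t_out(n_rec + 1), E_out(n_rec + 1), i_out(n_rec + 1);
  NumericVector ffar_out(n_rec + 1); // D * dc/dz at the far boundary
  IntegerVector cyc_out(n_rec + 1);

  // waveform at arbitrary t (floor-based modulo keeps m in [0, 2W))
  auto Eat = [&](double t) {
    double xi = xi0 + dir_sign * v * t;
    double p = 2.0 * W;
    double m = xi - p * std::floor(xi / p);
    return E_L + (m <= W ? m : p - m);
  };

  t_out[0] = 0.0;
  E_out[0] = E_start;
  i_out[0] = 0.0; // uniform initial field: zero Faradaic current
  ffar_out[0] = 0.0;
  cyc_out[0] = 1;

  int rec = 1;
  for (int m = 1; m <= n_rec; ++m) {
    for (int s = 1; s <= substeps; ++s) {
      double t_new = ((double)(m - 1) * substeps + s) * dt;
      double E = Eat(t_new);
      double u = clamp50(f * (E - E_f0));
      double ka = (k0 / D) * std::exp(clamp50(-alpha * u));
      double kc = (k0 / D) * std::exp(clamp50((1.0 - alpha) * u));
      // boundary row: (c1 - c0)/dz = ka*c0 - kc*(c_b - c0)
      diag[0] = 1.0 + dz * (ka + kc);
      upper[0] = -1.0;
      rhs[0] = dz * kc * c_b;
      for (int j = 1; j < n - 1; ++j) rhs[j] = c[j];
      rhs[n - 1] = c_b;
      NumericVector x = cpp_thomas(lower, diag, upper, rhs);
      for (int j = 0; j < n; ++j) {
        double val = x[j];
        if (!std::isfinite(val))
          stop("numerical failure: non-finite concentration at time %.6g s",
               t_new);
        c[j] = val;
      }
    }
    double t_new = m * dt_rec;
    t_out[rec] = t_new;
    E_out[rec] = Eat(t_new);
    i_out[rec] = -F * ECSA * D * (c[1] - c[0]) / dz;
    ffar_out[rec] = D * (c[n - 1] - c[n - 2]) / dz;
    int cyc = (int)std::floor((t_new - 1e-12) / period) + 1;
    if (cyc > n_cycles) cyc = n_cycles;
    cyc_out[rec] = cyc;
    ++rec;
  }

  return List::create(_["t"] = t_out, _["E"] = E_out, _["i"] = i_out,
                      _["cycle"] = cyc_out, _["flux_far"] = ffar_out,
                      _["c_final"] = NumericVector(c.begin(), c.end()));
}
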