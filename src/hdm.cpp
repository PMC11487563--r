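#include <Rcpp.h>
using namespace Rcpp;

// Hemodynamic state derivatives on the integration scale.
// x = (s, log f_in, log v, log q); flow, volume and deoxyhemoglobin are
// propagated in log space so their positivity is enforced by construction.
static inline void hdm_derivs_log(const double *x, const double z,
                                  const double *p, double *dx) {
  const double s = x[0];
  const double f = exp(x[1]);
  const double v = exp(x[2]);
  const double q = exp(x[3]);
  const double beta = p[0], kappa = p[1], gamma = p[2], transit = p[3];
  const double alpha = p[4], e0 = p[5];
  const double fout = pow(v, 1.0 / alpha);
  const double extraction = (1.0 - pow(1.0 - e0, 1.0 / f)) / e0;
  dx[0] = beta * z - kappa * s - gamma * (f - 1.0);
  dx[1] = s / f;
  dx[2] = transit * (f - fout) / v;
  dx[3] = transit * (f * extraction - fout * q / v) / q;
}

// Fixed-step classical Runge-Kutta integration of the hemodynamic system.
// pars = (beta, kappa, gamma, transit, alpha, e0, v0, theta0, r0, eps_h, te);
// z is the neural input per time bin (bin i covers [(i-1)*dt, i*dt)).
// Returns an (n+1) x 5 matrix of (y, s, f_in, v, q) at times 0, dt, ..., n*dt.
// [[Rcpp::export]]
NumericMatrix hdm_integrate_cpp(NumericVector pars, NumericVector z, double dt) {
  if (pars.size() != 11) stop("pars must have 11 elements");
  if (dt <= 0) stop("dt must be positive");
  const int n = z.size();
  double p[6] = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  const double v0 = pars[6], theta0 = pars[7], r0 = pars[8];
  const double eps_h = pars[9], te = pars[10];
  const double k1 = 4.3 * theta0 * p[5] * te;
  const double k2 = eps_h * r0 * p[5] * te;
  const double k3 = 1.0 - eps_h;

  NumericMatrix out(n + 1, 5);
  double x[4] = {0.0, 0.0, 0.0, 0.0};
  double d1[4], d2[4], d3[4], d4[4], xt[4];
  out(0, 0) = 0.0; out(0, 1) = 0.0; out(0, 2) = 1.0; out(0, 3) = 1.0; out(0, 4) = 1.0;

  // two RK4 substeps per bin: the input is constant within a bin, so this
  // refines accuracy without changing the input/output grid
  const double h = dt / 2.0;
  for (int i = 0; i < n; i++) {
    const double zi = z[i];
    for (int sub = 0; sub < 2; sub++) {
      hdm_derivs_log(x, zi, p, d1);
      for (int j = 0; j < 4; j++) xt[j] = x[j] + 0.5 * h * d1[j];
      hdm_derivs_log(xt, zi, p, d2);
      for (int j = 0; j < 4; j++) xt[j] = x[j] + 0.5 * h * d2[j];
      hdm_derivs_log(xt, zi, p, d3);
      for (int j = 0; j < 4; j++) xt[j] = x[j] + h * d3[j];
      hdm_derivs_log(xt, zi, p, d4);
      for (int j = 0; j < 4; j++)
        x[j] += h / 6.0 * (d1[j] + 2.0 * d2[j] + 2.0 * d3[j] + d4[j]);
    }

    bool bad = false;
    for (int j = 0; j < 4; j++)
      if (!std::isfinite(x[j]) || fabs(x[j]) > 25.0) bad = true;
    if (bad)
      stop("hemodynamic integration diverged (beta=%g, kappa=%g, transit=%g): "
           "state left the admissible region at t=%g s",
           p[0], p[1], p[3], (i + 1) * dt);

    const double f = exp(x[1]);
    const double v = exp(x[2]);
    const double q = exp(x[3]);
    out(i + 1, 0) = 100.0 * v0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    out(i + 1, 1) = x[0];
    out(i + 1, 2) = f;
    out(i + 1, 3) = v;
    out(i + 1, 4) = q;
  }
  return out;
}
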