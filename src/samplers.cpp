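#include <Rcpp.h>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama, unit friction) samplers for the toy
// systems. All randomness comes from R's generator so set.seed() in R
// governs reproducibility. Energies kcal/mol, kT = 0.0019872 * T.

// Sample x from U(x) = kc/2 (x - mu)^2 at temperature kT.
// Discards n_eq steps, then records every `thin`-th of n_collect steps.
// [[Rcpp::export]]
NumericVector cpp_langevin_harmonic(double kc, double mu, double kT,
                                    double dt, int n_eq, int n_collect,
                                    int thin, double x_init) {
  if (kc <= 0 || kT <= 0 || dt <= 0 || thin < 1)
    stop("cpp_langevin_harmonic: invalid parameters");
  double x = x_init;
  const double noise = std::sqrt(2.0 * kT * dt);
  for (int i = 0; i < n_eq; ++i)
    x += -kc * (x - mu) * dt + noise * norm_rand();
  int n_out = n_collect / thin;
  NumericVector out(n_out);
  int j = 0;
  for (int i = 1; i <= n_collect; ++i) {
    x += -kc * (x - mu) * dt + noise * norm_rand();
    if (i % thin == 0 && j < n_out) out[j++] = x;
  }
  return out;
}

// Multisite lambda dynamics: one coordinate x per site, one auxiliary theta
// per (site, substituent). lambda_i = exp(c sin theta_i) / sum_j, per site
// (implicit simplex constraint). Biased potential:
//   U = sum_s sum_i lambda_si * u_si(x_s) - sum b_si lambda_si,
//   u_si = e0_si + k_si/2 (x_s - x0_si)^2.
// Both x and theta are propagated by overdamped Langevin at the same kT.
// [[Rcpp::export]]
List cpp_msld(IntegerVector nsub, NumericVector kvec, NumericVector x0vec,
              NumericVector e0vec, NumericVector bias, double cexp,
              double kT, double dt_x, double dt_th,
              int n_eq, int n_collect, int thin,
              NumericVector theta_init, NumericVector x_init) {
  const int ns = nsub.size();
  int ntot = 0;
  for (int s = 0; s < ns; ++s) ntot += nsub[s];
  if (kvec.size() != ntot || x0vec.size() != ntot || e0vec.size() != ntot ||
      bias.size() != ntot || theta_init.size() != ntot || x_init.size() != ns)
    stop("cpp_msld: inconsistent dimensions");
  if (kT <= 0 || dt_x <= 0 || dt_th <= 0 || thin < 1)
    stop("cpp_msld: invalid parameters");

  std::vector<int> off(ns, 0);
  for (int s = 1; s < ns; ++s) off[s] = off[s - 1] + nsub[s - 1];

  std::vector<double> theta(theta_init.begin(), theta_init.end());
  std::vector<double> x(x_init.begin(), x_init.end());
  std::vector<double> lam(ntot), u(ntot);

  const double nx = std::sqrt(2.0 * kT * dt_x);
  const double nth = std::sqrt(2.0 * kT * dt_th);

  int n_out = n_collect / thin;
  NumericMatrix lam_out(n_out, ntot);
  NumericMatrix x_out(n_out, ns);
  int row = 0;

  const int n_total = n_eq + n_collect;
  for (int step = 1; step <= n_total; ++step) {
    for (int s = 0; s < ns; ++s) {
      const int m = nsub[s], o = off[s];
      // simplex weights via bounded exponentials (max-shifted for stability)
      double emax = -1e300;
      for (int i = 0; i < m; ++i) {
        double a = cexp * std::sin(theta[o + i]);
        if (a > emax) emax = a;
      }
      double zsum = 0.0;
      for (int i = 0; i < m; ++i) {
        lam[o + i] = std::exp(cexp * std::sin(theta[o + i]) - emax);
        zsum += lam[o + i];
      }
      double ubar = 0.0, fx = 0.0;
      for (int i = 0; i < m; ++i) {
        lam[o + i] /= zsum;
        const double dxi = x[s] - x0vec[o + i];
        u[o + i] = e0vec[o + i] + 0.5 * kvec[o + i] * dxi * dxi - bias[o + i];
        ubar += lam[o + i] * u[o + i];
        fx += lam[o + i] * kvec[o + i] * dxi;      // dU/dx_s
      }
      // coordinate update
      x[s] += -fx * dt_x + nx * norm_rand();
      // auxiliary updates: dU/dtheta_i = c cos(theta_i) lam_i (u_i - ubar)
      for (int i = 0; i < m; ++i) {
        const double grad = cexp * std::cos(theta[o + i]) * lam[o + i] *
                            (u[o + i] - ubar);
        theta[o + i] += -grad * dt_th + nth * norm_rand();
      }
    }
    if (step > n_eq) {
      const int i_col = step - n_eq;
      if (i_col % thin == 0 && row < n_out) {
        // recompute lambdas from the updated thetas so emitted frames are
        // exactly on the simplex
        for (int s = 0; s < ns; ++s) {
          const int m = nsub[s], o = off[s];
          double emax = -1e300;
          for (int i = 0; i < m; ++i) {
            double a = cexp * std::sin(theta[o + i]);
            if (a > emax) emax = a;
          }
          double zsum = 0.0;
          std::vector<double> tmp(m);
          for (int i = 0; i < m; ++i) {
            tmp[i] = std::exp(cexp * std::sin(theta[o + i]) - emax);
            zsum += tmp[i];
          }
          for (int i = 0; i < m; ++i) lam_out(row, o + i) = tmp[i] / zsum;
          x_out(row, s) = x[s];
        }
        ++row;
      }
    }
  }
  return List::create(_["lambda"] = lam_out, _["x"] = x_out,
                      _["theta_final"] = NumericVector(theta.begin(), theta.end()),
                      _["x_final"] = NumericVector(x.begin(), x.end()));
}
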