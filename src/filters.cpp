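#include <Rcpp.h>
using namespace Rcpp;

// Trial-wise belief filters for binary inputs. These loops sit inside the
// MAP objective and are called thousands of times per fit, hence C++.

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Binary Hierarchical Gaussian Filter, 2/3/4 levels.
// Level-2 state: tendency toward outcome 1 (logit scale); level 3: its
// log-volatility; level 4: drift of that volatility. kappa couples adjacent
// levels (fixed at 1 in the study configuration). omega_k is the constant
// log-volatility offset at level k; the top level always uses exp(omega)
// alone.
// Returns per-trial predictions, posteriors, prediction errors and the
// precision-weighted updates eps_k = mu_k - muhat_k, plus the effective
// level-2 learning rate alpha2 = 1/pi2. ok=false flags a rejected
// parameter point (non-positive precision somewhere).
// [[Rcpp::export]]
List hgf_filter_cpp(NumericVector u, int n_levels, double kappa,
                    double omega2, double omega3, double omega4,
                    double mu2_0, double sigma2_0,
                    double mu3_0, double sigma3_0,
                    double mu4_0, double sigma4_0) {
  int n = u.size();
  NumericVector muhat1(n), muhat2(n), mu2(n), sigma2(n), sigmahat2(n);
  NumericVector mu3(n), sigma3(n), mu4(n), sigma4(n);
  NumericVector delta1(n), delta2(n), eps2(n), eps3(n), alpha2(n);
  bool ok = true;

  double m2 = mu2_0, s2 = sigma2_0;
  double m3 = mu3_0, s3 = sigma3_0;
  double m4 = mu4_0, s4 = sigma4_0;

  for (int t = 0; t < n; ++t) {
    // predictions from previous posteriors
    double mh2 = m2, mh3 = m3, mh4 = m4;
    double mh1 = logistic(mh2);
    double v2 = (n_levels >= 3) ? std::exp(kappa * mh3 + omega2)
                                : std::exp(omega2);
    double sh2 = s2 + v2;
    if (!(sh2 > 0.0) || !R_finite(sh2)) { ok = false; break; }

    double d1 = u[t] - mh1;
    double pi2 = 1.0 / sh2 + mh1 * (1.0 - mh1);
    if (!(pi2 > 0.0) || !R_finite(pi2)) { ok = false; break; }
    double m2n = mh2 + d1 / pi2;
    double s2n = 1.0 / pi2;
    double d2 = (s2n + (m2n - mh2) * (m2n - mh2)) / sh2 - 1.0;

    double m3n = m3, s3n = s3, m4n = m4, s4n = s4;
    double d3 = 0.0;
    if (n_levels >= 3) {
      double v3 = (n_levels >= 4) ? std::exp(kappa * mh4 + omega3)
                                  : std::exp(omega3);
      double sh3 = s3 + v3;
      if (!(sh3 > 0.0) || !R_finite(sh3)) { ok = false; break; }
      double w2 = v2 / sh2;
      double pi3 = 1.0 / sh3 +
        0.5 * kappa * kappa * w2 * (w2 + (2.0 * w2 - 1.0) * d2);
      if (!(pi3 > 0.0) || !R_finite(pi3)) { ok = false; break; }
      m3n = mh3 + kappa / (2.0 * pi3) * w2 * d2;
      s3n = 1.0 / pi3;
      d3 = (s3n + (m3n - mh3) * (m3n - mh3)) / sh3 - 1.0;

      if (n_levels >= 4) {
        double sh4 = s4 + std::exp(omega4);
        if (!(sh4 > 0.0) || !R_finite(sh4)) { ok = false; break; }
        double w3 = v3 / sh3;
        double pi4 = 1.0 / sh4 +
          0.5 * kappa * kappa * w3 * (w3 + (2.0 * w3 - 1.0) * d3);
        if (!(pi4 > 0.0) || !R_finite(pi4)) { ok = false; break; }
        m4n = mh4 + kappa / (2.0 * pi4) * w3 * d3;
        s4n = 1.0 / pi4;
      }
    }

    muhat1[t] = mh1; muhat2[t] = mh2;
    mu2[t] = m2n; sigma2[t] = s2n; sigmahat2[t] = sh2;
    mu3[t] = m3n; sigma3[t] = s3n; mu4[t] = m4n; sigma4[t] = s4n;
    delta1[t] = d1; delta2[t] = d2;
    eps2[t] = m2n - mh2; eps3[t] = m3n - mh3;
    alpha2[t] = 1.0 / pi2;

    m2 = m2n; s2 = s2n; m3 = m3n; s3 = s3n; m4 = m4n; s4 = s4n;
  }

  return List::create(
    _["ok"] = ok, _["muhat1"] = muhat1, _["muhat2"] = muhat2,
    _["mu2"] = mu2, _["sigma2"] = sigma2, _["sigmahat2"] = sigmahat2,
    _["mu3"] = mu3, _["sigma3"] = sigma3,
    _["mu4"] = mu4, _["sigma4"] = sigma4,
    _["delta1"] = delta1, _["delta2"] = delta2,
    _["eps2"] = eps2, _["eps3"] = eps3, _["alpha2"] = alpha2);
}

// Rescorla-Wagner: V(t+1) = V(t) + alpha * (u(t) - V(t)).
// Returns the prediction for each trial (V before seeing u[t]) and the
// post-update value.
// [[Rcpp::export]]
List rw_filter_cpp(NumericVector u, double alpha, double v0) {
  int n = u.size();
  NumericVector vhat(n), v(n), delta(n);
  double V = v0;
  for (int t = 0; t < n; ++t) {
    vhat[t] = V;
    delta[t] = u[t] - V;
    V += alpha * delta[t];
    v[t] = V;
  }
  return List::create(_["vhat"] = vhat, _["v"] = v, _["delta"] = delta,
                      _["clipped"] = false);
}

// Sutton K1: state-dependent learning rate.
//   delta(t) = u(t) - V(t)
//   beta(t+1) = beta(t) + mu * delta(t) * h(t)
//   alpha(t+1) = exp(beta(t+1))            (clipped at 1, flagged)
//   V(t+1) = V(t) + alpha(t+1) * delta(t)
//   h(t+1) = (h(t) + alpha(t+1) * delta(t)) * max(0, 1 - alpha(t+1))
// [[Rcpp::export]]
List sk1_filter_cpp(NumericVector u, double mu, double beta0,
                    double v0, double h0) {
  int n = u.size();
  NumericVector vhat(n), v(n), delta(n), alpha(n);
  double V = v0, beta = beta0, h = h0;
  bool clipped = false;
  for (int t = 0; t < n; ++t) {
    vhat[t] = V;
    double d = u[t] - V;
    delta[t] = d;
    beta += mu * d * h;
    double a = std::exp(beta);
    if (a > 1.0) { a = 1.0; clipped = true; }
    V += a * d;
    h = (h + a * d) * std::max(0.0, 1.0 - a);
    alpha[t] = a;
    v[t] = V;
  }
  return List::create(_["vhat"] = vhat, _["v"] = v, _["delta"] = delta,
                      _["alpha"] = alpha, _["clipped"] = clipped);
}
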