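// Observation model: density of a measured amplitude A given k released
// vesicles. For k = 0 this is the Gaussian background noise; for k >= 1
// it is the convolution of a gamma(beta, lam) sum of quanta with the
// Gaussian noise, evaluated by Gauss-Legendre quadrature in log space on
// a window centred on the (log-concave) integrand's mode.
//
// Model invariant mu_a > sigma_a implies beta = k mu_a^2 / sigma_a^2 > 1
// for k >= 1, so the integrand has no endpoint singularity and is
// strictly log-concave: a fixed-order rule on mode +/- 12 sd is accurate
// to near machine precision.

#include <Rcpp.h>
#include <cmath>
#include <vector>

namespace synq {

// 64-point Gauss-Legendre nodes/weights on [-1, 1], computed once by
// Newton iteration on the Legendre polynomial.
struct GL {
  std::vector<double> x, w;
  GL(int n) : x(n), w(n) {
    for (int i = 0; i < n; ++i) {
      double t = std::cos(M_PI * (i + 0.75) / (n + 0.5));
      for (int it = 0; it < 100; ++it) {
        double p0 = 1.0, p1 = t;
        for (int j = 2; j <= n; ++j) {
          double p2 = ((2.0 * j - 1.0) * t * p1 - (j - 1.0) * p0) / j;
          p0 = p1; p1 = p2;
        }
        double dp = n * (t * p1 - p0) / (t * t - 1.0);
        double dt = p1 / dp;
        t -= dt;
        if (std::fabs(dt) < 1e-15) break;
      }
      double p0 = 1.0, p1 = t;
      for (int j = 2; j <= n; ++j) {
        double p2 = ((2.0 * j - 1.0) * t * p1 - (j - 1.0) * p0) / j;
        p0 = p1; p1 = p2;
      }
      double dp = n * (t * p1 - p0) / (t * t - 1.0);
      x[i] = t;
      w[i] = 2.0 / ((1.0 - t * t) * dp * dp);
    }
  }
};

static const GL gl64(64);

inline double log_gauss(double z, double sd) {
  return -0.5 * z * z / (sd * sd) - std::log(sd) - 0.5 * std::log(2.0 * M_PI);
}

// log P[A | k] for one amplitude; mu_a > sigma_a > 0, sigma_b > 0.
double amp_log_density(double A, int k, double mu_a, double sigma_a,
                       double sigma_b) {
  if (k == 0) return log_gauss(A, sigma_b);
  const double beta = k * mu_a * mu_a / (sigma_a * sigma_a);
  const double lam = mu_a / (sigma_a * sigma_a);
  const double sb2 = sigma_b * sigma_b;
  // mode of log f(y) = (beta-1) log y - lam y - (A-y)^2/(2 sb2):
  // y^2 - y (A - lam sb2) - (beta - 1) sb2 = 0, positive root.
  const double b = A - lam * sb2;
  const double disc = b * b + 4.0 * (beta - 1.0) * sb2;
  double ystar = 0.5 * (b + std::sqrt(disc));
  if (!(ystar > 0.0)) ystar = (beta - 1.0) / lam;  // defensive; disc > 0 when beta > 1
  const double curv = (beta - 1.0) / (ystar * ystar) + 1.0 / sb2;
  const double sd = 1.0 / std::sqrt(curv);
  double lo = ystar - 12.0 * sd;
  double hi = ystar + 12.0 * sd;
  if (lo < 0.0) lo = 0.0;
  if (hi <= lo) hi = lo + 12.0 * sd;
  const double half = 0.5 * (hi - lo), mid = 0.5 * (hi + lo);
  const double lgconst = beta * std::log(lam) - R::lgammafn(beta)
      - std::log(sigma_b) - 0.5 * std::log(2.0 * M_PI);
  // log-sum-exp over the quadrature nodes
  double mx = -INFINITY;
  double lf[64];
  for (int i = 0; i < 64; ++i) {
    double y = mid + half * gl64.x[i];
    double d = A - y;
    double v = (beta - 1.0) * std::log(y) - lam * y - 0.5 * d * d / sb2;
    lf[i] = v;
    if (v > mx) mx = v;
  }
  if (!std::isfinite(mx)) return -INFINITY;
  double s = 0.0;
  for (int i = 0; i < 64; ++i) s += gl64.w[i] * std::exp(lf[i] - mx);
  return lgconst + mx + std::log(half * s);
}

}  // namespace synq

// [[Rcpp::export(name = ".amp_log_density_cpp")]]
Rcpp::NumericVector amp_log_density_cpp(Rcpp::NumericVector A, int k,
                                        double mu_a, double sigma_a,
                                        double sigma_b) {
  int n = A.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = synq::amp_log_density(A[i], k, mu_a, sigma_a, sigma_b);
  return out;
}

// Density table: rows = amplitudes, cols = k in 0..k_max, natural scale.
// [[Rcpp::export(name = ".amp_density_table_cpp")]]
Rcpp::NumericMatrix amp_density_table_cpp(Rcpp::NumericVector A, int k_max,
                                          double mu_a, double sigma_a,
                                          double sigma_b) {
  int n = A.size();
  Rcpp::NumericMatrix out(n, k_max + 1);
  for (int k = 0; k <= k_max; ++k)
    for (int i = 0; i < n; ++i)
      out(i, k) = std::exp(synq::amp_log_density(A[i], k, mu_a, sigma_a, sigma_b));
  return out;
}
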