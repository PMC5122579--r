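// Exact correlated likelihood of an amplitude train as a scaled matrix
// product over hidden occupancy y in {0..n} (forward algorithm), and the
// uncorrelated factorised baseline that conditions on spike times only.
//
// State convention: v[y] is proportional to the joint density of the
// amplitudes observed so far and occupancy y just before the next spike;
// after each spike the vector is renormalised and the log of its sum
// accumulated, so the result stays finite for arbitrarily long trains.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "synq.h"

namespace synq {

Schedule schedule(const std::vector<double>& times, double tau_D,
                  double tau_F, double p0, double p1) {
  int M = times.size();
  Schedule s;
  s.u.resize(M);
  s.g.resize(M > 1 ? M - 1 : 0);
  double jump = (p1 - p0) / (1.0 - p0);
  s.u[0] = p0;
  for (int m = 0; m + 1 < M; ++m) {
    double T = times[m + 1] - times[m];
    double upost = s.u[m] + (1.0 - s.u[m]) * jump;
    s.u[m + 1] = p0 + (upost - p0) * std::exp(-T / tau_F);
    s.g[m] = 1.0 - std::exp(-T / tau_D);
  }
  return s;
}

// Pascal triangle of binomial coefficients, grown on demand.
static std::vector<std::vector<double> > pascal(1, std::vector<double>(1, 1.0));
static const std::vector<double>& choose_row(int n) {
  while ((int)pascal.size() <= n) {
    const std::vector<double>& prev = pascal.back();
    int m = pascal.size();
    std::vector<double> row(m + 1, 1.0);
    for (int k = 1; k < m; ++k) row[k] = prev[k - 1] + prev[k];
    pascal.push_back(row);
  }
  return pascal[n];
}

// bin[y * (n+1) + k] = C(y, k) p^k (1-p)^(y-k) for 0 <= k <= y <= n.
static void binom_table(int n, double p, std::vector<double>& bin) {
  std::vector<double> pk(n + 1), qk(n + 1);
  pk[0] = qk[0] = 1.0;
  for (int k = 1; k <= n; ++k) {
    pk[k] = pk[k - 1] * p;
    qk[k] = qk[k - 1] * (1.0 - p);
  }
  bin.assign((n + 1) * (n + 1), 0.0);
  for (int y = 0; y <= n; ++y) {
    const std::vector<double>& ch = choose_row(y);
    for (int k = 0; k <= y; ++k)
      bin[y * (n + 1) + k] = ch[k] * pk[k] * qk[y - k];
  }
}

double forward_loglik(const std::vector<double>& amps, const Schedule& s,
                      int n, const double* dens, int k_stride,
                      bool correlated) {
  const int M = amps.size();
  const int W = n + 1;
  std::vector<double> v(W, 0.0), w(W), rel, res;
  v[n] = 1.0;  // fully stocked start
  double logL = 0.0;
  for (int m = 0; m < M; ++m) {
    const double* Pm = dens + (size_t)m * k_stride;
    binom_table(n, s.u[m], rel);
    if (correlated) {
      if (m == M - 1) {
        // final row vector <L_M|_y = sum_k P[A_M|k] C(y,k) u^k (1-u)^(y-k)
        double tot = 0.0;
        for (int y = 0; y <= n; ++y) {
          double ly = 0.0;
          for (int k = 0; k <= y; ++k) ly += Pm[k] * rel[y * W + k];
          tot += ly * v[y];
        }
        if (!(tot > 0.0) || !std::isfinite(tot)) return -INFINITY;
        logL += std::log(tot);
      } else {
        binom_table(n, s.g[m], res);
        std::fill(w.begin(), w.end(), 0.0);
        for (int y = 0; y <= n; ++y) {
          if (v[y] == 0.0) continue;
          for (int k = 0; k <= y; ++k) {
            double a = Pm[k] * rel[y * W + k] * v[y];
            if (a == 0.0) continue;
            int e = n - y + k;  // empty sites just after release
            const double* rg = &res[e * W];
            // y' = y - k + j restocked, j = 0..e
            double* wp = &w[y - k];
            for (int j = 0; j <= e; ++j) wp[j] += a * rg[j];
          }
        }
        double sc = 0.0;
        for (int y = 0; y <= n; ++y) sc += w[y];
        if (!(sc > 0.0) || !std::isfinite(sc)) return -INFINITY;
        logL += std::log(sc);
        for (int y = 0; y <= n; ++y) v[y] = w[y] / sc;
      }
    } else {
      // uncorrelated: v holds the amplitude-independent occupancy law
      double lm = 0.0;
      for (int y = 0; y <= n; ++y) {
        if (v[y] == 0.0) continue;
        for (int k = 0; k <= y; ++k) lm += Pm[k] * rel[y * W + k] * v[y];
      }
      if (!(lm > 0.0) || !std::isfinite(lm)) return -INFINITY;
      logL += std::log(lm);
      if (m < M - 1) {
        binom_table(n, s.g[m], res);
        std::fill(w.begin(), w.end(), 0.0);
        for (int y = 0; y <= n; ++y) {
          if (v[y] == 0.0) continue;
          for (int k = 0; k <= y; ++k) {
            double a = rel[y * W + k] * v[y];
            if (a == 0.0) continue;
            int e = n - y + k;
            const double* rg = &res[e * W];
            double* wp = &w[y - k];
            for (int j = 0; j <= e; ++j) wp[j] += a * rg[j];
          }
        }
        double sc = 0.0;
        for (int y = 0; y <= n; ++y) sc += w[y];
        for (int y = 0; y <= n; ++y) v[y] = w[y] / sc;
      }
    }
  }
  return logL;
}

}  // namespace synq

// theta = c(n, tau_D, tau_F, p0, p1, mu_a, sigma_a, sigma_b)
static double sweep_loglik(const std::vector<double>& times,
                           const std::vector<double>& amps,
                           const Rcpp::NumericVector& theta,
                           bool correlated) {
  int n = (int)theta[0];
  synq::Schedule s = synq::schedule(times, theta[1], theta[2], theta[3], theta[4]);
  int M = amps.size();
  std::vector<double> dens((size_t)M * (n + 1));
  for (int m = 0; m < M; ++m)
    for (int k = 0; k <= n; ++k)
      dens[(size_t)m * (n + 1) + k] =
          std::exp(synq::amp_log_density(amps[m], k, theta[5], theta[6], theta[7]));
  return synq::forward_loglik(amps, s, n, dens.data(), n + 1, correlated);
}

// [[Rcpp::export(name = ".loglik_sweep_cpp")]]
double loglik_sweep_cpp(Rcpp::NumericVector times, Rcpp::NumericVector amps,
                        Rcpp::NumericVector theta, bool correlated) {
  std::vector<double> t(times.begin(), times.end());
  std::vector<double> a(amps.begin(), amps.end());
  return sweep_loglik(t, a, theta, correlated);
}

// [[Rcpp::export(name = ".loglik_dataset_cpp")]]
double loglik_dataset_cpp(Rcpp::List times_list, Rcpp::List amps_list,
                          Rcpp::NumericVector theta, bool correlated) {
  double ll = 0.0;
  for (int i = 0; i < times_list.size(); ++i) {
    Rcpp::NumericVector tv = times_list[i], av = amps_list[i];
    std::vector<double> t(tv.begin(), tv.end());
    std::vector<double> a(av.begin(), av.end());
    ll += sweep_loglik(t, a, theta, correlated);
    if (!std::isfinite(ll)) return ll;
  }
  return ll;
}
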