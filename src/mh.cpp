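// Grid-discretised Metropolis-Hastings over the eight-parameter space.
//
// Because the parameter space is a fixed grid, log-likelihoods are
// memoised per grid point, and the amplitude-density tables -- which
// depend only on (mu_a, sigma_a, sigma_b) and the observed amplitudes --
// are shared across all points that differ only in the dynamic
// parameters. Long chains therefore cost little more than the number of
// distinct grid points they visit.
//
// Randomness comes from R's own generator (unif_rand), so set.seed() in
// R makes chains bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
#include "synq.h"

namespace {

struct DensCache {
  // cols[k][i]: P[A_i | k] over all amplitudes, concatenated across sweeps
  std::vector<std::vector<double> > cols;
};

struct Problem {
  std::vector<std::vector<double> > times, amps;
  std::vector<double> all_amps;
  std::vector<size_t> offset;  // row offset of each sweep in all_amps
  std::vector<Rcpp::NumericVector> grid;  // 8 value vectors
  int variant;       // 0 dep-only, 1 dep-fac, 2 doubling
  bool correlated;
  std::unordered_map<uint64_t, double> ll_cache;
  std::unordered_map<uint32_t, DensCache> dens_cache;
  size_t n_evals = 0;
};

const int NP = 8;  // n, tau_D, tau_F, p0, p1, mu_a, sigma_a, sigma_b

uint64_t key_of(const std::vector<int>& idx) {
  uint64_t k = 0;
  for (int j = 0; j < NP; ++j) k |= (uint64_t)(idx[j] & 0xff) << (8 * j);
  return k;
}

// Build theta from grid indices, applying the variant's p1 tie.
bool theta_of(Problem& P, const std::vector<int>& idx, double* theta) {
  for (int j = 0; j < NP; ++j) theta[j] = P.grid[j][idx[j]];
  if (P.variant == 0) theta[4] = theta[3];
  else if (P.variant == 2) theta[4] = 2.0 * theta[3];
  // constraint predicates; grids are assumed positive and in range
  if (theta[4] >= 1.0) return false;
  if (P.variant == 1 && theta[3] >= theta[4]) return false;
  if (theta[5] <= theta[6]) return false;  // mu_a > sigma_a
  return true;
}

double eval_loglik(Problem& P, const std::vector<int>& idx,
                   const double* theta) {
  uint64_t key = key_of(idx);
  std::unordered_map<uint64_t, double>::iterator it = P.ll_cache.find(key);
  if (it != P.ll_cache.end()) return it->second;
  ++P.n_evals;
  int n = (int)theta[0];
  uint32_t dkey = ((uint32_t)idx[5] << 16) | ((uint32_t)idx[6] << 8) |
                  (uint32_t)idx[7];
  DensCache& dc = P.dens_cache[dkey];
  size_t NA = P.all_amps.size();
  while ((int)dc.cols.size() <= n) {
    int k = dc.cols.size();
    dc.cols.push_back(std::vector<double>(NA));
    std::vector<double>& col = dc.cols.back();
    for (size_t i = 0; i < NA; ++i)
      col[i] = std::exp(synq::amp_log_density(P.all_amps[i], k, theta[5],
                                              theta[6], theta[7]));
  }
  // assemble a row-major scratch table for the forward pass
  std::vector<double> dens(NA * (n + 1));
  for (int k = 0; k <= n; ++k)
    for (size_t i = 0; i < NA; ++i) dens[i * (n + 1) + k] = dc.cols[k][i];
  double ll = 0.0;
  for (size_t s = 0; s < P.times.size(); ++s) {
    synq::Schedule sc = synq::schedule(P.times[s], theta[1], theta[2],
                                       theta[3], theta[4]);
    ll += synq::forward_loglik(P.amps[s], sc,
                               n, dens.data() + P.offset[s] * (n + 1), n + 1,
                               P.correlated);
    if (!std::isfinite(ll)) break;
  }
  P.ll_cache[key] = ll;
  return ll;
}

}  // namespace

// [[Rcpp::export(name = ".mh_sampler_cpp")]]
Rcpp::List mh_sampler_cpp(Rcpp::List times_list, Rcpp::List amps_list,
                          Rcpp::List grid, Rcpp::IntegerVector free_dims,
                          int variant, bool correlated, int n_iter,
                          int burn_in, Rcpp::Nullable<Rcpp::IntegerVector> start) {
  Problem P;
  P.variant = variant;
  P.correlated = correlated;
  for (int i = 0; i < times_list.size(); ++i) {
    Rcpp::NumericVector tv = times_list[i], av = amps_list[i];
    P.times.push_back(std::vector<double>(tv.begin(), tv.end()));
    P.amps.push_back(std::vector<double>(av.begin(), av.end()));
    P.offset.push_back(P.all_amps.size());
    P.all_amps.insert(P.all_amps.end(), av.begin(), av.end());
  }
  for (int j = 0; j < NP; ++j) {
    Rcpp::NumericVector g = grid[j];
    if (g.size() < 1 || g.size() > 256)
      Rcpp::stop("each parameter grid must have 1..256 points");
    P.grid.push_back(g);
  }
  std::vector<int> nfree(free_dims.begin(), free_dims.end());
  if (nfree.empty()) Rcpp::stop("no free parameters");
  Rcpp::RNGScope scope;
  std::vector<int> idx(NP, 0);
  double theta[NP];
  if (start.isNotNull()) {
    Rcpp::IntegerVector st(start);
    for (int j = 0; j < NP; ++j) idx[j] = st[j];
    if (!theta_of(P, idx, theta))
      Rcpp::stop("supplied start point violates parameter constraints");
  } else {
    bool ok = false;
    for (int tries = 0; tries < 100000 && !ok; ++tries) {
      for (size_t j = 0; j < nfree.size(); ++j) {
        int d = nfree[j];
        idx[d] = (int)(R::unif_rand() * P.grid[d].size());
        if (idx[d] >= (int)P.grid[d].size()) idx[d] = P.grid[d].size() - 1;
      }
      ok = theta_of(P, idx, theta);
    }
    if (!ok) Rcpp::stop("could not find a valid initial grid point");
  }
  double ll = eval_loglik(P, idx, theta);
  int n_keep = n_iter - burn_in;
  Rcpp::NumericMatrix samples(n_keep, NP);
  Rcpp::NumericVector lls(n_keep);
  long accepted = 0;
  std::vector<int> prop(NP);
  double theta_prop[NP];
  for (int iter = 0; iter < n_iter; ++iter) {
    int d = nfree[(int)(R::unif_rand() * nfree.size()) % nfree.size()];
    int dir = (R::unif_rand() < 0.5) ? -1 : 1;
    prop = idx;
    prop[d] += dir;
    bool valid = prop[d] >= 0 && prop[d] < (int)P.grid[d].size() &&
                 theta_of(P, prop, theta_prop);
    if (valid) {
      double llp = eval_loglik(P, prop, theta_prop);
      if (std::log(R::unif_rand()) < llp - ll) {
        idx = prop;
        ll = llp;
        ++accepted;
      }
    }
    if (iter >= burn_in) {
      theta_of(P, idx, theta);
      for (int j = 0; j < NP; ++j) samples(iter - burn_in, j) = theta[j];
      lls[iter - burn_in] = ll;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("samples") = samples, Rcpp::Named("loglik") = lls,
      Rcpp::Named("accepted") = (double)accepted,
      Rcpp::Named("n_evals") = (double)P.n_evals);
}
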