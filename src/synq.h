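#ifndef SYNQ_H
#define SYNQ_H

#include <vector>

namespace synq {

double amp_log_density(double A, int k, double mu_a, double sigma_a,
                       double sigma_b);

// Deterministic release/restock schedules for the depression-facilitation
// model (depression-only and p1 = 2 p0 variants are special cases of the
// same recursion through the value of p1).
struct Schedule {
  std::vector<double> u;  // u_m just before each spike, length M
  std::vector<double> g;  // restock probability per interval, length M-1
};

Schedule schedule(const std::vector<double>& times, double tau_D,
                  double tau_F, double p0, double p1);

// Forward (matrix-product) log-likelihood of one sweep. dens is an
// (M x (k_stride)) row-major table of P[A_m | k] for k = 0..n (k_stride
// >= n + 1 allows shared, wider tables).
double forward_loglik(const std::vector<double>& amps, const Schedule& s,
                      int n, const double* dens, int k_stride,
                      bool correlated);

}  // namespace synq

#endif
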