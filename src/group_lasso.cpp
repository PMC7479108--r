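#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Group-lasso path by block coordinate descent, specialized to the
// multi-organ OU design: each group holds `m` columns (one per organ) and
// the column for organ k is nonzero only on organ k's block of N rows.
// Columns are pre-normalized to unit L2 norm, so the within-group Gram is
// the identity and the block update is an exact group soft-threshold.
//
// Xb:     N x p matrix; column j = g*m + k holds the nonzero block of the
//         design column (rows k*N .. k*N+N-1 of the stacked system).
// y:      stacked response, length N*m.
// lambda: decreasing penalty sequence (warm starts).
// Returns a p x length(lambda) coefficient matrix.
// [[Rcpp::export]]
NumericMatrix group_lasso_path_cpp(NumericMatrix Xb, NumericVector y,
                                   int m, NumericVector lambda,
                                   int max_iter, double tol) {
  const int N = Xb.nrow();
  const int p = Xb.ncol();
  const int G = p / m;
  std::vector<double> beta(p, 0.0);
  std::vector<double> r(y.begin(), y.end());
  std::vector<char> active(G, 0);
  NumericMatrix out(p, lambda.size());

  for (int li = 0; li < lambda.size(); ++li) {
    const double lam = lambda[li];
    bool full_sweep = true;
    for (int iter = 0; iter < max_iter; ++iter) {
      double maxdiff = 0.0;
      for (int g = 0; g < G; ++g) {
        if (!full_sweep && !active[g]) continue;
        double cnorm2 = 0.0;
        double c[16];
        for (int k = 0; k < m; ++k) {
          const int j = g * m + k;
          const double* xj = &Xb(0, j);
          const double* rk = &r[(size_t)k * N];
          double dot = 0.0;
          for (int i = 0; i < N; ++i) dot += xj[i] * rk[i];
          c[k] = dot + beta[j];
          cnorm2 += c[k] * c[k];
        }
        const double cnorm = std::sqrt(cnorm2);
        const double scale = (cnorm > lam) ? (1.0 - lam / cnorm) : 0.0;
        bool any_nonzero = false;
        for (int k = 0; k < m; ++k) {
          const int j = g * m + k;
          const double bnew = scale * c[k];
          const double diff = bnew - beta[j];
          if (diff != 0.0) {
            const double* xj = &Xb(0, j);
            double* rk = &r[(size_t)k * N];
            for (int i = 0; i < N; ++i) rk[i] -= xj[i] * diff;
            beta[j] = bnew;
            const double ad = std::fabs(diff);
            if (ad > maxdiff) maxdiff = ad;
          }
          if (beta[j] != 0.0) any_nonzero = true;
        }
        active[g] = any_nonzero ? 1 : 0;
      }
      if (maxdiff < tol) {
        if (full_sweep) break;   // converged on a full sweep
        full_sweep = true;       // verify with one more full sweep
      } else {
        full_sweep = false;      // iterate on the active set
      }
    }
    for (int j = 0; j < p; ++j) out(j, li) = beta[j];
  }
  return out;
}
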