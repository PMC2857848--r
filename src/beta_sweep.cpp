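#include <Rcpp.h>
using namespace Rcpp;

// One Gauss-Seidel sweep over marker effects with residual update.
// For each marker j (fixed ascending order, or a supplied order):
//   e <- e + x_j * beta_j                     (remove j's contribution)
//   C_j = x_j'x_j / sigma2e + 1 / var_j
//   r_j = x_j'e / sigma2e
//   beta_j ~ N(C_j^-1 r_j, C_j^-1)
//   e <- e - x_j * beta_j                     (restore)
// A zero-variance column (x_j'x_j = 0) collapses to a prior draw.
// Uses R's RNG so set.seed() governs the whole chain. beta and e are
// modified in place; callers pass copies they own.
// [[Rcpp::export]]
void beta_sweep_cpp(NumericMatrix X, NumericVector e, NumericVector beta,
                    NumericVector xtx, double sigma2e, NumericVector var_j,
                    IntegerVector order) {
  int n = X.nrow();
  int m = X.ncol();
  if (e.size() != n || beta.size() != m || xtx.size() != m ||
      var_j.size() != m)
    stop("dimension mismatch in beta sweep");
  for (int idx = 0; idx < m; ++idx) {
    int j = order[idx] - 1;
    const double *xj = &X(0, j);
    double bj = beta[j];
    double xe = 0.0;
    if (bj != 0.0) {
      for (int i = 0; i < n; ++i) {
        e[i] += xj[i] * bj;
        xe += xj[i] * e[i];
      }
    } else {
      for (int i = 0; i < n; ++i) xe += xj[i] * e[i];
    }
    double C = xtx[j] / sigma2e + 1.0 / var_j[j];
    double r = xe / sigma2e;
    double bnew = r / C + R::rnorm(0.0, 1.0) / std::sqrt(C);
    beta[j] = bnew;
    for (int i = 0; i < n; ++i) e[i] -= xj[i] * bnew;
  }
}
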