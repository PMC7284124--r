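#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Dual coordinate descent for the instance-weighted L1-loss linear SVM
//
//   min_w 0.5 ||w||^2 + sum_i C_i * max(0, 1 - y_i * w'x_i)
//
// solved in the dual (0 <= alpha_i <= C_i), one coordinate at a time with
// randomly permuted sweeps (Hsieh et al. 2008). The bias is handled by an
// augmented constant feature of value `bias_scale`, so it is (weakly)
// regularized; with bias_scale ~ 1 this is the standard large-margin bias
// approximation used by primal/dual linear solvers.
//
// Xt is p x n (observations in columns) so each coordinate update touches
// contiguous memory.
// [[Rcpp::export(name = ".dcd_svm")]]
List dcd_svm(const NumericMatrix& Xt, const NumericVector& y,
             const NumericVector& cost, double bias_scale,
             int max_epochs, double tol, int seed) {
  const int p = Xt.nrow(), n = Xt.ncol();
  std::vector<double> w(p, 0.0);
  double wb = 0.0; // weight on the augmented bias feature
  std::vector<double> alpha(n, 0.0), qii(n);

  for (int i = 0; i < n; ++i) {
    const double* xi = &Xt(0, i);
    double s = bias_scale * bias_scale;
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  bool converged = false;
  int epoch = 0;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = idx[t];
      const double* xi = &Xt(0, i);
      double g = wb * bias_scale;
      for (int j = 0; j < p; ++j) g += w[j] * xi[j];
      g = y[i] * g - 1.0;

      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      else if (alpha[i] >= cost[i] && g < 0.0) pg = 0.0;
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);

      if (std::fabs(pg) > 1e-14 && qii[i] > 0.0) {
        double a_new = alpha[i] - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > cost[i]) a_new = cost[i];
        const double d = (a_new - alpha[i]) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * xi[j];
          wb += d * bias_scale;
          alpha[i] = a_new;
        }
      }
    }
    if (max_pg < tol) { converged = true; break; }
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = wb * bias_scale,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch + 1,
                      _["converged"] = converged);
}
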