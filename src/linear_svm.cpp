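#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for a linear L1-loss support-vector classifier
// (Hsieh et al. 2008), with the bias handled as an augmented constant
// feature. Solves
//   min_w  0.5 ||w||^2 + C sum_i max(0, 1 - y_i w'x~_i),   x~_i = (x_i, 1)
// Deterministic: index order is shuffled by an internal LCG seeded from
// `seed`, so identical inputs give identical solutions.
//
// X is n x p (one row per training pattern), y must be +1/-1.
// Returns w of length p + 1; the last entry is the bias.
// [[Rcpp::export(name = ".svm_dualcd")]]
NumericVector svm_dualcd(NumericMatrix X, NumericVector y, double C,
                         double tol, int max_pass, int seed) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector w(p + 1);
  std::vector<double> alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0; // augmented bias feature
    for (int j = 0; j < p; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  unsigned long long state = (unsigned long long)seed * 2654435761ULL + 1ULL;
  for (int pass = 0; pass < max_pass; ++pass) {
    // Fisher-Yates with a private LCG (reproducible, no R RNG side effects)
    for (int i = n - 1; i > 0; --i) {
      state = state * 6364136223846793005ULL + 1442695040888963407ULL;
      int j = (int)((state >> 33) % (unsigned long long)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    double pg_max = -1e300, pg_min = 1e300;
    for (int k = 0; k < n; ++k) {
      int i = idx[k];
      double g = 0.0;
      for (int j = 0; j < p; ++j) g += w[j] * X(i, j);
      g += w[p];
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0 && g > 0.0) pg = 0.0;
      if (alpha[i] >= C && g < 0.0) pg = 0.0;
      if (pg > pg_max) pg_max = pg;
      if (pg < pg_min) pg_min = pg;
      if (pg != 0.0) {
        double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double d = (a_new - a_old) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * X(i, j);
          w[p] += d;
        }
      }
    }
    if (pg_max - pg_min < tol) break; // liblinear-style stopping rule
  }
  return w;
}
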