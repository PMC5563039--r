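#include <Rcpp.h>
using namespace Rcpp;

// Correlation of the permuted-layer distances a[k] = |xp[ii[k]] - xp[jj[k]]|
// with a pre-centered fixed-layer distance vector bc (sum(bc) == 0), in one
// pass: dot = sum(a * bc), and var(a) from its first two moments.
static inline double perm_stat(const double *xp, const int *ii, const int *jj,
                               int m, const double *bc, double bnorm) {
  double s1 = 0.0, s2 = 0.0, dot = 0.0;
  for (int k = 0; k < m; k++) {
    double a = std::fabs(xp[ii[k]] - xp[jj[k]]);
    s1 += a;
    s2 += a * a;
    dot += a * bc[k];
  }
  double ss = s2 - s1 * s1 / m;
  if (ss <= 0.0 || bnorm <= 0.0) return NA_REAL;
  return dot / (std::sqrt(ss) * bnorm);
}

// Fisher-Yates shuffle driven by R's RNG (reproducible under set.seed()).
static inline void shuffle(double *xp, int n) {
  for (int i = n - 1; i > 0; i--) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;  // guard against unif_rand() == 1.0
    double tmp = xp[i];
    xp[i] = xp[j];
    xp[j] = tmp;
  }
}

// Monte-Carlo Mantel permutation count for 1-D sample vectors. x: the
// permuted layer; dyv: centered upper-triangle Euclidean distances of the
// fixed layer; ii, jj: 0-based upper-triangle index pairs.
// [[Rcpp::export]]
List mantel_perm_kernel(NumericVector x, NumericVector dyv,
                        IntegerVector ii, IntegerVector jj, int nperm) {
  int n = x.size();
  int m = ii.size();
  const double *bc = REAL(dyv);
  const int *pi = INTEGER(ii);
  const int *pj = INTEGER(jj);
  double bnorm = 0.0;
  for (int k = 0; k < m; k++) bnorm += bc[k] * bc[k];
  bnorm = std::sqrt(bnorm);

  std::vector<double> xp(x.begin(), x.end());
  double obs = perm_stat(xp.data(), pi, pj, m, bc, bnorm);

  RNGScope rngScope;
  int count = 0;
  const double eps = 1e-12;
  for (int b = 0; b < nperm; b++) {
    shuffle(xp.data(), n);
    double s = perm_stat(xp.data(), pi, pj, m, bc, bnorm);
    if (!ISNAN(s) && s >= obs - eps) count++;
  }
  return List::create(_["r"] = obs, _["count"] = count);
}

// Mantel statistics for an explicit set of relabelings (rows of perm,
// 1-based), used for exhaustive enumeration at small n.
// [[Rcpp::export]]
NumericVector mantel_stat_perms(NumericVector x, NumericVector dyv,
                                IntegerVector ii, IntegerVector jj,
                                IntegerMatrix perm) {
  int n = x.size();
  int m = ii.size();
  int np = perm.nrow();
  const double *bc = REAL(dyv);
  const int *pi = INTEGER(ii);
  const int *pj = INTEGER(jj);
  double bnorm = 0.0;
  for (int k = 0; k < m; k++) bnorm += bc[k] * bc[k];
  bnorm = std::sqrt(bnorm);
  std::vector<double> xp(n);
  NumericVector out(np);
  for (int b = 0; b < np; b++) {
    for (int i = 0; i < n; i++) xp[i] = x[perm(b, i) - 1];
    out[b] = perm_stat(xp.data(), pi, pj, m, bc, bnorm);
  }
  return out;
}
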