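#include <Rcpp.h>
using namespace Rcpp;

// Complete-permutation accumulation over all K(K-1)/2 unordered pairs
// (k, k'). Permuted values are never materialized; the scan order is
// fixed (k ascending, k' > k) and accumulators are long double, so
// results do not depend on any chunking of the loop.

static inline long double io(long double L, long double a, long double b) {
  long double h = (a + b) / 2.0L;
  return (L - h) / (L + h);
}
static inline long double ia(long double a, long double b) {
  return (a - b) / (a + b);
}
static inline long double ic(long double L, long double a) {
  long double h = a / 2.0L;
  return (L - h) / (L + h);
}

// scheme codes: 1 = perm_A (swap A lengths), 2 = perm_B (swap B lengths),
// 3 = perm_both (swap both), 4 = perm_IA, 5 = perm_IC
static inline long double perm_value(int scheme, int k, int k2,
                                     const double* L, const double* a,
                                     const double* b) {
  switch (scheme) {
  case 1:
    return 0.5L * (io(L[k], a[k2], b[k]) + io(L[k2], a[k], b[k2]));
  case 2:
    return 0.5L * (io(L[k], a[k], b[k2]) + io(L[k2], a[k2], b[k]));
  case 3:
    return 0.5L * (io(L[k], a[k2], b[k2]) + io(L[k2], a[k], b[k]));
  case 4:
    return 0.5L * (ia(a[k], b[k2]) + ia(a[k2], b[k]));
  case 5:
    return 0.5L * (ic(L[k], a[k2]) + ic(L[k2], a[k]));
  default:
    return NA_REAL;
  }
}

// [[Rcpp::export(name = ".perm_core")]]
List perm_core(NumericVector L, NumericVector a, NumericVector b,
               NumericVector I, double I_mean, int scheme) {
  const int K = L.size();
  if (K < 3) stop("complete permutation requires K >= 3");
  const double* pL = L.begin();
  const double* pa = a.begin();
  const double* pb = b.begin();
  const double* pI = I.begin();
  const long double M = (long double)K * (K - 1) / 2.0L;

  // pass 1: permuted mean
  long double s1 = 0.0L;
  for (int k = 0; k < K - 1; ++k)
    for (int k2 = k + 1; k2 < K; ++k2)
      s1 += perm_value(scheme, k, k2, pL, pa, pb);
  long double mean_p = s1 / M;

  // pass 2: centered second moment and covariance sum
  long double s2 = 0.0L, s3 = 0.0L;
  for (int k = 0; k < K - 1; ++k) {
    long double dk = pI[k] - I_mean;
    for (int k2 = k + 1; k2 < K; ++k2) {
      long double d = perm_value(scheme, k, k2, pL, pa, pb) - mean_p;
      s2 += d * d;
      s3 += (dk + (pI[k2] - I_mean)) * d;
    }
  }
  long double var_p = s2 / (M - 1.0L);
  long double cov = 2.0L / ((long double)K * K * (K - 1)) * s3;

  return List::create(_["permuted_mean"] = (double)mean_p,
                      _["permuted_variance"] = (double)var_p,
                      _["covariance"] = (double)cov,
                      _["n_permuted_pairs"] = (double)M);
}
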