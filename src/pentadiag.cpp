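#include <Rcpp.h>
using namespace Rcpp;

// Solve A x = b for a symmetric positive-definite pentadiagonal A given by its
// main diagonal d0 (length n), first sub-diagonal d1 (n-1) and second
// sub-diagonal d2 (n-2), via an LDL^T factorization that exploits the
// bandwidth-2 structure. This is the inner system of the iteratively
// reweighted penalized least-squares baseline fit, (W + lambda * D'D) z = W y,
// which is pentadiagonal because D is the second-difference operator.
// [[Rcpp::export(rng = false)]]
NumericVector pentadiag_solve(NumericVector d0, NumericVector d1,
                              NumericVector d2, NumericVector b) {
  int n = d0.size();
  if (n < 3 || d1.size() != n - 1 || d2.size() != n - 2 || b.size() != n)
    stop("inconsistent band lengths");
  std::vector<double> D(n), L1(n, 0.0), L2(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double l1 = 0.0, l2 = 0.0;
    if (i >= 2) l2 = d2[i - 2] / D[i - 2];
    if (i >= 1) {
      double e = d1[i - 1];
      if (i >= 2) e -= L1[i - 1] * D[i - 2] * l2;
      l1 = e / D[i - 1];
    }
    double di = d0[i];
    if (i >= 1) di -= l1 * l1 * D[i - 1];
    if (i >= 2) di -= l2 * l2 * D[i - 2];
    if (di <= 0.0) stop("matrix is not positive definite");
    L1[i] = l1;
    L2[i] = l2;
    D[i] = di;
  }
  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) {
    double v = b[i];
    if (i >= 1) v -= L1[i] * z[i - 1];
    if (i >= 2) v -= L2[i] * z[i - 2];
    z[i] = v;
  }
  NumericVector x(n);
  for (int i = n - 1; i >= 0; --i) {
    double v = z[i] / D[i];
    if (i + 1 < n) v -= L1[i + 1] * x[i + 1];
    if (i + 2 < n) v -= L2[i + 2] * x[i + 2];
    x[i] = v;
  }
  return x;
}

// Residual b - A x of the pentadiagonal system, accumulated in extended
// precision. Used for iterative refinement: the penalized baseline system
// has condition number ~ lambda / p, and a working-precision residual would
// lose exactly the digits refinement is meant to recover.
// [[Rcpp::export(rng = false)]]
NumericVector pentadiag_residual(NumericVector d0, NumericVector d1,
                                 NumericVector d2, NumericVector x,
                                 NumericVector b) {
  int n = d0.size();
  NumericVector r(n);
  for (int i = 0; i < n; ++i) {
    long double acc = (long double)b[i] - (long double)d0[i] * x[i];
    if (i >= 1) acc -= (long double)d1[i - 1] * x[i - 1];
    if (i + 1 < n) acc -= (long double)d1[i] * x[i + 1];
    if (i >= 2) acc -= (long double)d2[i - 2] * x[i - 2];
    if (i + 2 < n) acc -= (long double)d2[i] * x[i + 2];
    r[i] = (double)acc;
  }
  return r;
}
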