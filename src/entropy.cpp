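#include <Rcpp.h>
#include <cmath>
#include <string>
using namespace Rcpp;

// Brute-force template-match counts for sample entropy.
// Counts pairs i<j of m- and (m+1)-templates with Chebyshev distance < r.
// Templates i = 0..N-m-1 for both lengths (Richman-Moorman convention),
// self-matches excluded.
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // templates of length m+1: indices 0..nt-1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) >= r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) < r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Fuzzy-entropy membership sums. Templates are mean-subtracted; the
// membership of a pair is exp(-(d/r)^gradient) with d the Chebyshev
// distance of the centred templates. Returns the pair-summed memberships
// (phi_{m+1}, phi_m) over templates i = 0..N-m-1, i < j.
// [[Rcpp::export(name = ".fuzzyen_sums_cpp")]]
NumericVector fuzzyen_sums_cpp(NumericVector x, int m, double r,
                               double gradient) {
  const int n = x.size();
  const int nt = n - m;
  std::vector<double> mean_m(nt), mean_m1(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    mean_m[i] = s / m;
    mean_m1[i] = (s + x[i + m]) / (m + 1);
  }
  const bool quad = gradient == 2.0;  // common default; avoids pow()
  const double inv_r = 1.0 / r;
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs((x[i + k] - mean_m[i]) - (x[j + k] - mean_m[j]));
        if (d > dm) dm = d;
      }
      double u = dm * inv_r;
      phi_m += std::exp(quad ? -(u * u) : -std::pow(u, gradient));
      double dm1 = 0.0;
      for (int k = 0; k <= m; ++k) {
        double d = std::fabs((x[i + k] - mean_m1[i]) - (x[j + k] - mean_m1[j]));
        if (d > dm1) dm1 = d;
      }
      double u1 = dm1 * inv_r;
      phi_m1 += std::exp(quad ? -(u1 * u1) : -std::pow(u1, gradient));
    }
  }
  return NumericVector::create(phi_m1, phi_m);
}

// Lempel-Ziv 1976 exhaustive-history phrase count of a 0/1 sequence
// (Kaspar-Schuster formulation).
// [[Rcpp::export(name = ".lz76_count_cpp")]]
int lz76_count_cpp(IntegerVector z) {
  const int n = z.size();
  if (n == 0) return 0;
  int c = 1;       // first symbol is always a phrase
  int i = 0;       // start of history
  int k = 1;       // length of current candidate extension
  int kmax = 1;
  int l = 1;       // start of the current phrase
  while (l + k <= n) {
    if (z[i + k - 1] == z[l + k - 1]) {
      ++k;
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {          // no prefix match anywhere: new phrase
        ++c;
        l += kmax;
        i = 0;
        k = 1;
        kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  if (k != 1) ++c;           // unfinished phrase at the end
  return c;
}
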