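#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shannon entropy (natural log) of ordinal-pattern frequencies of
// m-length delay vectors. Ties broken by order of occurrence (stable sort).
// [[Rcpp::export(name = ".pe_cpp")]]
double pe_cpp(NumericVector x, int m, int delay) {
  int n = x.size();
  int span = (m - 1) * delay;
  int nvec = n - span;
  if (nvec < 1) return NA_REAL;
  std::map<std::vector<int>, int> counts;
  std::vector<int> idx(m);
  for (int t = 0; t < nvec; ++t) {
    for (int k = 0; k < m; ++k) idx[k] = k;
    std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
      return x[t + a * delay] < x[t + b * delay];
    });
    counts[idx]++;
  }
  double h = 0.0;
  for (auto &kv : counts) {
    double p = static_cast<double>(kv.second) / nvec;
    h -= p * std::log(p);
  }
  return h;
}

// Approximate entropy, Phi_m - Phi_{m+1}, Chebyshev distance,
// self-matches included. r is an absolute tolerance. Both template lengths
// are counted in one pass; the Chebyshev loop exits early once d > r.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return NA_REAL;
  int nv_m = n - m + 1;             // templates of length m
  int nv_m1 = n - m;                // templates of length m + 1
  std::vector<int> cnt_m(nv_m, 0), cnt_m1(nv_m1, 0);
  for (int i = 0; i < nv_m; ++i) {
    cnt_m[i] += 1;                  // self-match
    if (i < nv_m1) cnt_m1[i] += 1;
    for (int j = i + 1; j < nv_m; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) { d = dd; if (d > r) break; }
      }
      if (d <= r) {
        ++cnt_m[i]; ++cnt_m[j];
        if (i < nv_m1 && j < nv_m1) {
          double dd = std::fabs(x[i + m] - x[j + m]);
          if (std::max(d, dd) <= r) { ++cnt_m1[i]; ++cnt_m1[j]; }
        }
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nv_m; ++i)
    phi_m += std::log(static_cast<double>(cnt_m[i]) / nv_m);
  for (int i = 0; i < nv_m1; ++i)
    phi_m1 += std::log(static_cast<double>(cnt_m1[i]) / nv_m1);
  return phi_m / nv_m - phi_m1 / nv_m1;
}

// Sample entropy, -log(A/B), self-matches excluded. Returns NA when A == 0.
// Constant signals (B > 0, A > 0, all matching) give 0 naturally.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return NA_REAL;
  int nvec = n - m;                  // templates comparable at both lengths
  long long A = 0, B = 0;
  for (int i = 0; i < nvec - 1; ++i) {
    for (int j = i + 1; j < nvec; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) { d = dd; if (d > r) break; }
      }
      if (d <= r) {
        ++B;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (std::max(d, dd) <= r) ++A;
      }
    }
  }
  if (B == 0 || A == 0) return NA_REAL;
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}

// LZ76 phrase-counting complexity of a 0/1 sequence.
// [[Rcpp::export(name = ".lz76_cpp")]]
int lz76_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, i = 0, k = 1, kmax = 1, l = 1;
  // classic Lempel-Ziv 1976 parsing (Kaspar & Schuster formulation)
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
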