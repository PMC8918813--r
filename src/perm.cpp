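#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Max ECDF difference over the pooled support, evaluated at the end of
// every tie group (the discrete two-sample KS statistic). `vals` must be
// sorted ascending; `lab[i]` is 1 when the i-th pooled value came from
// sample A.
static double ks2_stat(const double* vals, const int* lab, int na, int nb) {
  const int N = na + nb;
  int ca = 0, cb = 0;
  double d = 0.0;
  for (int i = 0; i < N; ++i) {
    if (lab[i]) ++ca; else ++cb;
    const bool group_end = (i == N - 1) || (vals[i + 1] != vals[i]);
    if (group_end) {
      const double diff = std::fabs((double)ca / na - (double)cb / nb);
      if (diff > d) d = diff;
    }
  }
  return d;
}

// Watson's two-sample U2 from sorted pooled values and group labels:
// U2 = (n m / N^2) * sum_k (d_k - dbar)^2 with d_k the ECDF difference
// at the k-th pooled order statistic.
static double watson_stat(const int* lab, int na, int nb) {
  const int N = na + nb;
  int ca = 0, cb = 0;
  double s = 0.0, s2 = 0.0;
  for (int i = 0; i < N; ++i) {
    if (lab[i]) ++ca; else ++cb;
    const double d = (double)ca / na - (double)cb / nb;
    s += d;
    s2 += d * d;
  }
  return (double)na * nb / ((double)N * N) * (s2 - s * s / N);
}

static void shuffle(std::vector<int>& lab) {
  const int N = (int)lab.size();
  for (int i = N - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(lab[i], lab[j]);
  }
}

// [[Rcpp::export(name = ".cpp_ks2_stat")]]
double cpp_ks2_stat(NumericVector sorted_vals, IntegerVector labels,
                    int na, int nb) {
  return ks2_stat(sorted_vals.begin(), labels.begin(), na, nb);
}

// Count of label permutations with D* >= observed (uses R's RNG stream).
// [[Rcpp::export(name = ".cpp_ks2_perm_count")]]
int cpp_ks2_perm_count(NumericVector sorted_vals, int na, int nb, int B,
                       double observed) {
  const int N = na + nb;
  std::vector<int> lab(N, 0);
  for (int i = 0; i < na; ++i) lab[i] = 1;
  const double thr = observed - 1e-12;
  int count = 0;
  for (int b = 0; b < B; ++b) {
    shuffle(lab);
    if (ks2_stat(sorted_vals.begin(), lab.data(), na, nb) >= thr) ++count;
  }
  return count;
}

// [[Rcpp::export(name = ".cpp_watson_stat")]]
double cpp_watson_stat(IntegerVector labels, int na, int nb) {
  return watson_stat(labels.begin(), na, nb);
}

// [[Rcpp::export(name = ".cpp_watson_perm_count")]]
int cpp_watson_perm_count(int na, int nb, int B, double observed) {
  const int N = na + nb;
  std::vector<int> lab(N, 0);
  for (int i = 0; i < na; ++i) lab[i] = 1;
  const double thr = observed - 1e-12;
  int count = 0;
  for (int b = 0; b < B; ++b) {
    shuffle(lab);
    if (watson_stat(lab.data(), na, nb) >= thr) ++count;
  }
  return count;
}
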