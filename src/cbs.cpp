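#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Maximal circular-arc statistic for one segment.
//
// For data x[0..n-1] with prefix sums S, every arc is described by a pair of
// cut positions 0 <= i < j <= n (arc = bins i..j-1, complement = the rest;
// width 1 <= w <= n-1).  The statistic is the absolute standardized mean
// difference between arc and complement,
//   T(i,j) = |(S[j]-S[i]) - w/n * S[n]| * sqrt(n / (w*(n-w))) ,
// i.e. the two-sample t numerator with unit variance.  Scaling by any
// permutation-invariant constant leaves the permutation p-value unchanged,
// so no variance estimate is needed here.
static double max_arc_stat(const std::vector<double> &x,
                           const std::vector<double> &fw,
                           int min_w, int *best_i, int *best_j) {
  const int n = (int)x.size();
  // drift-corrected prefix sums: a[k] = S[k] - k/n * S[n], so the arc
  // numerator (S[j]-S[i]) - w/n*S[n] is simply a[j]-a[i]
  std::vector<double> a(n + 1);
  double s = 0.0;
  for (int k = 0; k < n; ++k) { s += x[k]; a[k + 1] = s; }
  const double tot = s;
  for (int k = 0; k <= n; ++k) a[k] -= (double)k / n * tot;
  double best = -1.0;
  int bi = 0, bj = 0;
  const int wmax = n - min_w;
  for (int i = 0; i <= n - min_w; ++i) {
    const double ai = a[i];
    const int jhi = (i + wmax < n) ? i + wmax : n;
    for (int j = i + min_w; j <= jhi; ++j) {
      const double d = std::fabs(a[j] - ai) * fw[j - i];
      if (d > best) { best = d; bi = i; bj = j; }
    }
  }
  if (best_i) *best_i = bi;
  if (best_j) *best_j = bj;
  return best < 0.0 ? 0.0 : best;
}

// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan(NumericVector x, int min_w) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> fw(n + 1, 0.0);
  for (int w = 1; w < n; ++w) fw[w] = std::sqrt((double)n / ((double)w * (n - w)));
  int bi = 0, bj = 0;
  double stat = max_arc_stat(v, fw, min_w, &bi, &bj);
  return List::create(_["stat"] = stat, _["i"] = bi, _["j"] = bj);
}

// Sequential permutation test of the maximal arc statistic.
//
// Permutes bin values (R's RNG, so results are reproducible under
// set.seed), counting permutation maxima that reach the observed one.
// Early stopping:
//  * reject the split as soon as >= 5 exceedances put the running p-value
//    clearly above alpha;
//  * after `tail_n` scans with zero exceedances, resolve p below the 1/m
//    resolution with a Gumbel tail fitted to the permutation maxima
//    (moment estimates); otherwise run to `nperm` and report (X+1)/(m+1).
// [[Rcpp::export(name = ".cbs_perm_test")]]
List cbs_perm_test(NumericVector x, double alpha, int nperm, int tail_n,
                   int min_w) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::vector<double> fw(n + 1, 0.0);
  for (int w = 1; w < n; ++w) fw[w] = std::sqrt((double)n / ((double)w * (n - w)));

  int bi = 0, bj = 0;
  const double obs = max_arc_stat(v, fw, min_w, &bi, &bj);

  if (tail_n > nperm) tail_n = nperm;
  std::vector<double> maxima;
  maxima.reserve(tail_n);
  std::vector<double> perm(v);
  RNGScope scope;
  int X = 0, m = 0;
  double p = 1.0;
  bool done = false;
  while (m < nperm && !done) {
    ++m;
    // Fisher-Yates with R's RNG
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(perm[k], perm[idx]);
    }
    double s = max_arc_stat(perm, fw, min_w, NULL, NULL);
    if (m <= tail_n) maxima.push_back(s);
    if (s >= obs) ++X;

    if (X >= 5 && (double)X / m > alpha) { p = (double)X / m; done = true; }
    if (!done && m == tail_n) {
      if (X == 0) {
        double mean = 0.0;
        for (double z : maxima) mean += z;
        mean /= maxima.size();
        double var = 0.0;
        for (double z : maxima) var += (z - mean) * (z - mean);
        var /= (maxima.size() - 1);
        const double beta = std::sqrt(6.0 * var) / M_PI;
        const double mu = mean - 0.5772156649015329 * beta;
        const double zz = (obs - mu) / (beta > 0 ? beta : 1e-12);
        p = (zz > 30.0) ? std::exp(-zz) : 1.0 - std::exp(-std::exp(-zz));
        done = true;
      } else {
        double phat = (double)(X + 1) / (m + 1);
        if (phat > alpha) { p = phat; done = true; }
      }
    }
  }
  if (!done) p = (double)(X + 1) / (m + 1);
  return List::create(_["p"] = p, _["stat"] = obs, _["i"] = bi, _["j"] = bj,
                      _["n_perm_used"] = m, _["n_exceed"] = X);
}
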