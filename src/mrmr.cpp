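#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Rank-based quantile binning of one column into at most nbins bins
// (0-based).  Tied values always share a bin.
static void quantile_bin(const double* x, int n, int nbins, int* out) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  int prev_bin = 0;
  for (int pos = 0; pos < n; ++pos) {
    int bin = (int)((long long)pos * nbins / n);
    if (pos > 0 && x[ord[pos]] == x[ord[pos - 1]]) bin = prev_bin;
    out[ord[pos]] = bin;
    prev_bin = bin;
  }
}

// Plug-in mutual information (nats) between two discrete vectors with
// small alphabets.
static double mi_disc(const int* a, const int* b, int n, int ka, int kb,
                      std::vector<double>& joint) {
  std::fill(joint.begin(), joint.begin() + ka * kb, 0.0);
  std::vector<double> ma(ka, 0.0), mb(kb, 0.0);
  for (int i = 0; i < n; ++i) {
    joint[a[i] * kb + b[i]] += 1.0;
    ma[a[i]] += 1.0;
    mb[b[i]] += 1.0;
  }
  double mi = 0.0;
  for (int i = 0; i < ka; ++i) {
    if (ma[i] == 0.0) continue;
    for (int j = 0; j < kb; ++j) {
      double c = joint[i * kb + j];
      if (c > 0.0) mi += (c / n) * std::log(c * n / (ma[i] * mb[j]));
    }
  }
  return mi;
}

// Greedy mRMR (MID criterion: relevance minus mean redundancy) on
// quantile-binned features.  y must be 0/1.  Returns 1-based selected
// indices in selection order together with the criterion value at the
// moment of selection.  Ties break toward the lower column index.
// [[Rcpp::export]]
List mrmr_rank_cpp(NumericMatrix X, IntegerVector y, int k, int nbins) {
  const int n = X.nrow(), p = X.ncol();
  if (k > p) k = p;
  std::vector<int> bins(n * (size_t)p);
  for (int j = 0; j < p; ++j)
    quantile_bin(&X(0, j), n, nbins, &bins[(size_t)j * n]);
  std::vector<int> yy(n);
  for (int i = 0; i < n; ++i) yy[i] = y[i];
  std::vector<double> joint(nbins * nbins);
  std::vector<double> rel(p);
  for (int j = 0; j < p; ++j)
    rel[j] = mi_disc(&bins[(size_t)j * n], yy.data(), n, nbins, 2, joint);
  std::vector<bool> used(p, false);
  std::vector<double> red_sum(p, 0.0);
  IntegerVector order(k);
  NumericVector score(k);
  for (int step = 0; step < k; ++step) {
    int best = -1;
    double best_score = -INFINITY;
    for (int j = 0; j < p; ++j) {
      if (used[j]) continue;
      double s = step == 0 ? rel[j] : rel[j] - red_sum[j] / step;
      if (s > best_score) { best_score = s; best = j; }
    }
    used[best] = true;
    order[step] = best + 1;
    score[step] = best_score;
    if (step + 1 < k) {
      for (int j = 0; j < p; ++j) {
        if (used[j]) continue;
        red_sum[j] += mi_disc(&bins[(size_t)j * n], &bins[(size_t)best * n],
                              n, nbins, nbins, joint);
      }
    }
  }
  return List::create(_["order"] = order, _["score"] = score);
}
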