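#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Mirror (reflect-without-repeat) index into [0, n-1]; pad must be < n.
static inline int mirror_idx(int i, int n) {
  if (i < 0) i = -i;
  if (i >= n) i = 2 * n - 2 - i;
  return i;
}

// [[Rcpp::export]]
NumericMatrix conv2_mirror_cpp(NumericMatrix img, NumericMatrix kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kernel.nrow(), kc = kernel.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int a = 0; a < kr; ++a) {
        const int rr = mirror_idx(r + a - hr, nr);
        for (int b = 0; b < kc; ++b) {
          const int cc = mirror_idx(c + b - hc, nc);
          acc += img(rr, cc) * kernel(a, b);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Accumulator for a symmetric gray-level co-occurrence matrix with
// sparse reset between pixels.  Levels are 0-based internally; Haralick
// statistics use 1-based level indices.
struct GlcmAcc {
  int nlev;
  std::vector<double> p;        // nlev x nlev joint
  std::vector<int> touched;     // linear indices with p > 0
  std::vector<double> px;       // marginal
  std::vector<int> px_touched;
  std::vector<double> psum;     // p_{x+y}, index i+j (0-based -> 0..2nlev-2)
  std::vector<int> psum_touched;
  std::vector<double> pdiff;    // p_{|x-y|}, 0..nlev-1
  std::vector<int> pdiff_touched;
  double total;

  GlcmAcc(int nlev_) : nlev(nlev_), p(nlev_ * nlev_, 0.0),
    px(nlev_, 0.0), psum(2 * nlev_ - 1, 0.0), pdiff(nlev_, 0.0), total(0.0) {}

  void reset() {
    for (int idx : touched) p[idx] = 0.0;
    for (int i : px_touched) px[i] = 0.0;
    for (int k : psum_touched) psum[k] = 0.0;
    for (int k : pdiff_touched) pdiff[k] = 0.0;
    touched.clear(); px_touched.clear();
    psum_touched.clear(); pdiff_touched.clear();
    total = 0.0;
  }

  // one symmetric pair (counts both (a,b) and (b,a))
  void add(int a, int b) {
    int i1 = a * nlev + b, i2 = b * nlev + a;
    if (i2 == i1) {
      if (p[i1] == 0.0) touched.push_back(i1);
      p[i1] += 2.0;
    } else {
      if (p[i1] == 0.0) touched.push_back(i1);
      p[i1] += 1.0;
      if (p[i2] == 0.0) touched.push_back(i2);
      p[i2] += 1.0;
    }
    if (px[a] == 0.0) px_touched.push_back(a);
    px[a] += 1.0;
    if (px[b] == 0.0) px_touched.push_back(b);
    px[b] += 1.0;
    int s = a + b;
    if (psum[s] == 0.0) psum_touched.push_back(s);
    psum[s] += 2.0;
    int d = a > b ? a - b : b - a;
    if (pdiff[d] == 0.0) pdiff_touched.push_back(d);
    pdiff[d] += 2.0;
    total += 2.0;
  }

  // 13 statistics in the canonical order: energy, entropy, contrast,
  // correlation, variance, inverse difference moment, sum average,
  // sum variance, sum entropy, difference variance, difference entropy,
  // information measure of correlation 1 and 2.
  void stats(double* out) {
    for (int s = 0; s < 13; ++s) out[s] = 0.0;
    if (total <= 0.0) return;
    const double n = total;
    double energy = 0.0, entropy = 0.0, contrast = 0.0, idm = 0.0;
    double sum_ij = 0.0, hxy1 = 0.0;
    double mu = 0.0, hx = 0.0;
    for (int i : px_touched) {
      double q = px[i] / n;
      mu += (i + 1) * q;
      hx -= q * std::log(q);
    }
    double sigma2 = 0.0;
    for (int i : px_touched) {
      double q = px[i] / n;
      sigma2 += (i + 1 - mu) * (i + 1 - mu) * q;
    }
    double var_joint = 0.0;
    for (int idx : touched) {
      int i = idx / nlev, j = idx % nlev;
      double q = p[idx] / n;
      energy += q * q;
      entropy -= q * std::log(q);
      contrast += (double)(i - j) * (i - j) * q;
      idm += q / (1.0 + (double)(i - j) * (i - j));
      sum_ij += (double)(i + 1) * (j + 1) * q;
      var_joint += (i + 1 - mu) * (i + 1 - mu) * q;
      double m = (px[i] / n) * (px[j] / n);
      if (m > 0.0) hxy1 -= q * std::log(m);
    }
    double corr = 0.0;
    if (sigma2 > 0.0) corr = (sum_ij - mu * mu) / sigma2;  // sigma_x == sigma_y
    double sum_avg = 0.0, sum_ent = 0.0;
    for (int k : psum_touched) {
      double q = psum[k] / n;
      sum_avg += (k + 2) * q;          // 1-based levels: i + j in [2, 2 nlev]
      sum_ent -= q * std::log(q);
    }
    double sum_var = 0.0;
    for (int k : psum_touched) {
      double q = psum[k] / n;
      sum_var += (k + 2 - sum_avg) * (k + 2 - sum_avg) * q;
    }
    double dmu = 0.0, diff_ent = 0.0;
    for (int k : pdiff_touched) {
      double q = pdiff[k] / n;
      dmu += k * q;
      diff_ent -= q * std::log(q);
    }
    double diff_var = 0.0;
    for (int k : pdiff_touched) {
      double q = pdiff[k] / n;
      diff_var += (k - dmu) * (k - dmu) * q;
    }
    // hxy2 over outer product of marginals (symmetric: py == px)
    double hxy2 = 0.0;
    for (size_t ii = 0; ii < px_touched.size(); ++ii) {
      for (size_t jj = 0; jj < px_touched.size(); ++jj) {
        double m = (px[px_touched[ii]] / n) * (px[px_touched[jj]] / n);
        hxy2 -= m * std::log(m);
      }
    }
    double imc1 = 0.0;
    if (hx > 0.0) imc1 = (entropy - hxy1) / hx;
    double arg = 1.0 - std::exp(-2.0 * (hxy2 - entropy));
    double imc2 = arg > 0.0 ? std::sqrt(arg) : 0.0;
    out[0] = energy;   out[1] = entropy;  out[2] = contrast;
    out[3] = corr;     out[4] = var_joint; out[5] = idm;
    out[6] = sum_avg;  out[7] = sum_var;  out[8] = sum_ent;
    out[9] = diff_var; out[10] = diff_ent; out[11] = imc1; out[12] = imc2;
  }
};

// Windowed co-occurrence statistics over a quantized (0-based level) image.
// directions: integer flags for 0, 45, 90, 135 degree unit offsets.
// Returns an (nr, nc, 13) array.
// [[Rcpp::export]]
NumericVector glcm_window_stats_cpp(IntegerMatrix qimg, int nlev, int window,
                                    LogicalVector directions) {
  const int nr = qimg.nrow(), nc = qimg.ncol();
  const int h = window / 2;
  if (nlev < 2) stop("n_gray_levels must be >= 2");
  if (window > nr || window > nc) stop("window larger than image");
  // offsets in (row, col) for 0, 45, 90, 135 degrees
  const int orow[4] = {0, -1, -1, -1};
  const int ocol[4] = {1,  1,  0, -1};
  NumericVector out(nr * nc * 13);
  out.attr("dim") = Dimension(nr, nc, 13);
  GlcmAcc acc(nlev);
  std::vector<int> win(window * window);
  double st[13];
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      // gather mirror-padded window
      for (int a = 0; a < window; ++a) {
        int rr = mirror_idx(r + a - h, nr);
        for (int b = 0; b < window; ++b) {
          int cc = mirror_idx(c + b - h, nc);
          win[a * window + b] = qimg(rr, cc);
        }
      }
      acc.reset();
      for (int d = 0; d < 4; ++d) {
        if (!directions[d]) continue;
        for (int a = 0; a < window; ++a) {
          int a2 = a + orow[d];
          if (a2 < 0 || a2 >= window) continue;
          for (int b = 0; b < window; ++b) {
            int b2 = b + ocol[d];
            if (b2 < 0 || b2 >= window) continue;
            acc.add(win[a * window + b], win[a2 * window + b2]);
          }
        }
      }
      acc.stats(st);
      for (int s = 0; s < 13; ++s) out[r + nr * c + nr * nc * s] = st[s];
    }
  }
  return out;
}

// Per-pixel dominant gradient orientation: the principal right singular
// vector of the window x 2 matrix of (gx, gy) samples in the pixel's
// window, i.e. the leading eigenvector of the 2x2 windowed structure
// matrix [sum gx^2, sum gx gy; sum gx gy, sum gy^2].  Orientation is
// returned in [0, pi); all-zero gradient windows map to 0.
// [[Rcpp::export]]
NumericMatrix dominant_orientation_cpp(NumericMatrix gx, NumericMatrix gy,
                                       int window) {
  const int nr = gx.nrow(), nc = gx.ncol();
  const int h = window / 2;
  NumericMatrix theta(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double sxx = 0.0, sxy = 0.0, syy = 0.0;
      for (int a = -h; a <= h; ++a) {
        int rr = mirror_idx(r + a, nr);
        for (int b = -h; b <= h; ++b) {
          int cc = mirror_idx(c + b, nc);
          double x = gx(rr, cc), y = gy(rr, cc);
          sxx += x * x; sxy += x * y; syy += y * y;
        }
      }
      double th = 0.0;
      if (sxx + syy > 0.0) {
        // leading eigenvector of [[sxx, sxy], [sxy, syy]]
        double tr = sxx + syy;
        double det = sxx * syy - sxy * sxy;
        double disc = tr * tr - 4.0 * det;
        double lam = 0.5 * (tr + std::sqrt(disc > 0.0 ? disc : 0.0));
        double vx, vy;
        if (std::fabs(sxy) > 1e-300) {
          vx = lam - syy; vy = sxy;
        } else if (sxx >= syy) {
          vx = 1.0; vy = 0.0;
        } else {
          vx = 0.0; vy = 1.0;
        }
        th = std::atan2(vy, vx);
        if (th < 0.0) th += M_PI;
        if (th >= M_PI) th -= M_PI;
      }
      theta(r, c) = th;
    }
  }
  return theta;
}
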