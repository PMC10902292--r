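#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline interpolation through (xs, ys), evaluated at the
// integer grid 0..n-1. xs must be strictly increasing. Used for the upper
// and lower extrema envelopes during sifting.
static void spline_eval(const std::vector<double> &xs,
                        const std::vector<double> &ys,
                        std::vector<double> &out, int n) {
  int m = (int)xs.size();
  if (m == 2) { // linear fallback
    double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
    for (int i = 0; i < n; ++i) out[i] = ys[0] + slope * (i - xs[0]);
    return;
  }
  // second derivatives via tridiagonal solve (natural boundary)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), c(m);
  for (int i = 0; i < m - 1; ++i) h[i] = xs[i + 1] - xs[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((ys[i + 1] - ys[i]) / h[i] - (ys[i] - ys[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  l[m - 1] = 1.0; z[m - 1] = 0.0; c[m - 1] = 0.0;
  for (int j = m - 2; j >= 0; --j) c[j] = z[j] - mu[j] * c[j + 1];
  // evaluate; grid points are sorted so advance segment index linearly
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double x = (double)i;
    while (seg < m - 2 && x > xs[seg + 1]) ++seg;
    double dx = x - xs[seg];
    double b = (ys[seg + 1] - ys[seg]) / h[seg] - h[seg] * (c[seg + 1] + 2.0 * c[seg]) / 3.0;
    double d = (c[seg + 1] - c[seg]) / (3.0 * h[seg]);
    out[i] = ys[seg] + b * dx + c[seg] * dx * dx + d * dx * dx * dx;
  }
}

// Locate strict local maxima (sign = +1) or minima (sign = -1).
static void find_extrema(const std::vector<double> &x, int sign,
                         std::vector<int> &idx) {
  idx.clear();
  int n = (int)x.size();
  for (int i = 1; i < n - 1; ++i) {
    double a = sign * x[i];
    if (a > sign * x[i - 1] && a >= sign * x[i + 1]) {
      idx.push_back(i);
      // skip flat top
      while (i < n - 2 && x[i + 1] == x[i]) ++i;
    }
  }
}

// Envelope through extrema with end mirroring (reflect the two outermost
// extrema about each signal end to tame edge swings).
static bool envelope(const std::vector<double> &x, int sign,
                     std::vector<double> &env) {
  int n = (int)x.size();
  std::vector<int> idx;
  find_extrema(x, sign, idx);
  if ((int)idx.size() < 2) return false;
  std::vector<double> xs, ys;
  int m = (int)idx.size();
  // mirrored leading knots
  xs.push_back(-(double)idx[1]);          ys.push_back(x[idx[1]]);
  xs.push_back(-(double)idx[0]);          ys.push_back(x[idx[0]]);
  for (int k = 0; k < m; ++k) { xs.push_back((double)idx[k]); ys.push_back(x[idx[k]]); }
  xs.push_back(2.0 * (n - 1) - idx[m - 1]); ys.push_back(x[idx[m - 1]]);
  xs.push_back(2.0 * (n - 1) - idx[m - 2]); ys.push_back(x[idx[m - 2]]);
  // enforce strictly increasing (mirroring can tie when extremum sits at 0)
  for (size_t k = 1; k < xs.size(); ++k)
    if (xs[k] <= xs[k - 1]) xs[k] = xs[k - 1] + 1e-6;
  spline_eval(xs, ys, env, n);
  return true;
}

static int count_extrema(const std::vector<double> &x) {
  std::vector<int> up, dn;
  find_extrema(x, 1, up);
  find_extrema(x, -1, dn);
  return (int)(up.size() + dn.size());
}

// One EMD pass: sift out up to n_imfs IMFs, Cauchy-type stopping criterion
// sd_tol per sift, max_sift sift iterations per IMF.
static void emd_core(const std::vector<double> &input, int n_imfs,
                     double sd_tol, int max_sift,
                     std::vector< std::vector<double> > &imfs) {
  int n = (int)input.size();
  std::vector<double> resid(input), h(n), up(n), lo(n), prev(n);
  for (int k = 0; k < n_imfs; ++k) {
    if (count_extrema(resid) < 4) break;
    h = resid;
    for (int s = 0; s < max_sift; ++s) {
      if (!envelope(h, 1, up) || !envelope(h, -1, lo)) break;
      prev = h;
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = 0.5 * (up[i] + lo[i]);
        h[i] -= m;
        num += m * m;
        den += prev[i] * prev[i];
      }
      if (den > 0 && num / den < sd_tol) break;
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) resid[i] -= h[i];
  }
}

// [[Rcpp::export(name = ".emd_cpp")]]
NumericMatrix emd_cpp(NumericVector x, int n_imfs, double sd_tol, int max_sift) {
  int n = x.size();
  std::vector<double> in(x.begin(), x.end());
  std::vector< std::vector<double> > imfs;
  emd_core(in, n_imfs, sd_tol, max_sift, imfs);
  NumericMatrix out(n, n_imfs);
  for (int k = 0; k < (int)imfs.size(); ++k)
    for (int i = 0; i < n; ++i) out(i, k) = imfs[k][i];
  return out;
}

// Ensemble EMD: average of n_real decompositions of x + white noise with
// standard deviation noise_sd. Uses R's RNG so set.seed() governs it.
// [[Rcpp::export(name = ".eemd_cpp")]]
NumericMatrix eemd_cpp(NumericVector x, int n_imfs, int n_real,
                       double noise_sd, double sd_tol, int max_sift) {
  int n = x.size();
  NumericMatrix acc(n, n_imfs);
  std::vector<double> noisy(n);
  for (int r = 0; r < n_real; ++r) {
    for (int i = 0; i < n; ++i) noisy[i] = x[i] + (noise_sd > 0 ? R::rnorm(0.0, noise_sd) : 0.0);
    std::vector< std::vector<double> > imfs;
    emd_core(noisy, n_imfs, sd_tol, max_sift, imfs);
    for (int k = 0; k < (int)imfs.size() && k < n_imfs; ++k)
      for (int i = 0; i < n; ++i) acc(i, k) += imfs[k][i];
    if (r % 8 == 0) Rcpp::checkUserInterrupt();
  }
  for (int k = 0; k < n_imfs; ++k)
    for (int i = 0; i < n; ++i) acc(i, k) /= n_real;
  return acc;
}
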