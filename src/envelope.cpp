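#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Natural cubic spline machinery with the tridiagonal factorisation cached
// per knot set, so envelopes of several channels sharing the same extremum
// times reuse the factorisation and are evaluated in one pass.
struct NatSpline {
  std::vector<double> x, h, l, mu;                 // knots + factorisation
  std::vector<double> alpha, z;                    // solve workspace
  std::vector<std::vector<double> > cb, cc, cd;    // per-channel cubic coefs
  std::vector<std::vector<double> > ykn;           // per-channel knot values
  int m;

  void set_knots(const std::vector<double>& xt) {
    x = xt;
    m = (int)x.size();
    if (m < 3) return;
    h.assign(m - 1, 0.0);
    l.assign(m, 0.0);
    mu.assign(m, 0.0);
    for (int i = 0; i < m - 1; ++i) h[i] = x[i + 1] - x[i];
    l[0] = 1.0; mu[0] = 0.0;
    for (int i = 1; i < m - 1; ++i) {
      l[i] = 2.0 * (x[i + 1] - x[i - 1]) - h[i - 1] * mu[i - 1];
      mu[i] = h[i] / l[i];
    }
  }

  // solve the cubic coefficients for channel slot `slot` with values y
  void solve(int slot, const std::vector<double>& y) {
    if ((int)cb.size() <= slot) {
      cb.resize(slot + 1); cc.resize(slot + 1); cd.resize(slot + 1);
      ykn.resize(slot + 1);
    }
    ykn[slot] = y;
    std::vector<double>& b = cb[slot];
    std::vector<double>& c = cc[slot];
    std::vector<double>& d = cd[slot];
    b.assign(std::max(m - 1, 1), 0.0);
    c.assign(std::max(m, 1), 0.0);
    d.assign(std::max(m - 1, 1), 0.0);
    if (m == 2) {
      b[0] = (y[1] - y[0]) / (x[1] - x[0]);
      return;
    }
    alpha.assign(m, 0.0); z.assign(m, 0.0);
    for (int i = 1; i < m - 1; ++i)
      alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
    for (int i = 1; i < m - 1; ++i)
      z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
    c[m - 1] = 0.0;
    for (int j = m - 2; j >= 0; --j) c[j] = z[j] - mu[j] * c[j + 1];
    for (int j = 0; j < m - 1; ++j) {
      b[j] = (y[j + 1] - y[j]) / h[j] - h[j] * (c[j + 1] + 2.0 * c[j]) / 3.0;
      d[j] = (c[j + 1] - c[j]) / (3.0 * h[j]);
    }
  }
};

// Mirror-extend extremum sample indices about the endpoints 0 and n-1.
// src records which sample each (possibly reflected) knot takes its value
// from.
static void mirror_extend(const std::vector<int>& idx, int n,
                          std::vector<double>& xt, std::vector<int>& src) {
  const int m = (int)idx.size();
  xt.clear(); src.clear();
  for (int j = std::min(m, 2) - 1; j >= 0; --j)
    if (idx[j] > 0) { xt.push_back(-(double)idx[j]); src.push_back(idx[j]); }
  for (int j = 0; j < m; ++j) { xt.push_back((double)idx[j]); src.push_back(idx[j]); }
  std::size_t tail = xt.size();
  for (int j = std::max(0, m - 2); j < m; ++j)
    if (idx[j] < n - 1) {
      xt.push_back(2.0 * (n - 1) - (double)idx[j]);
      src.push_back(idx[j]);
    }
  // the two reflected right-tail times arrive in decreasing order
  if (xt.size() - tail == 2 && xt[tail] > xt[tail + 1]) {
    std::swap(xt[tail], xt[tail + 1]);
    std::swap(src[tail], src[tail + 1]);
  }
}

// Mean envelope of a multichannel signal for multivariate EMD sifting.
// For each projection direction the signal is projected, the projection's
// local extrema located (plateau-aware), and natural-cubic-spline envelopes
// of every channel interpolated at those times (mirror-extended at the
// boundaries).  Because spline interpolation is linear in the data, the
// projection's own envelope equals the projection of the channel envelopes,
// which yields the Rilling amplitude without extra spline fits.  Returns
// the direction-averaged envelope mean, the direction-averaged projection
// amplitude (upper minus lower, halved), and the minimum extremum count
// over directions.
// [[Rcpp::export]]
List memd_mean_env(NumericMatrix X, NumericMatrix dirs) {
  const int n = X.nrow(), nc = X.ncol(), nd = dirs.nrow();
  NumericMatrix env(n, nc);
  NumericVector amp(n);
  double* envp = REAL(env);
  double* ampp = REAL(amp);
  const double* Xp = REAL(X);
  const double* Dp = REAL(dirs);

  std::vector<double> p(n), yk;
  std::vector<int> imax, imin, src;
  std::vector<double> xt;
  NatSpline sp;
  // accumulate one direction's (upper+lower) envelopes before averaging
  std::vector<double> acc((std::size_t)n * nc);
  int min_ext = n, nvalid = 0;

  for (int dno = 0; dno < nd; ++dno) {
    for (int i = 0; i < n; ++i) p[i] = 0.0;
    for (int c = 0; c < nc; ++c) {
      const double w = Dp[dno + (std::size_t)c * nd];
      const double* xc = Xp + (std::size_t)c * n;
      for (int i = 0; i < n; ++i) p[i] += w * xc[i];
    }
    // plateau-aware extrema of the projection
    imax.clear(); imin.clear();
    int prev_s = 0, prev_i = -1;
    for (int i = 0; i < n - 1; ++i) {
      const double di = p[i + 1] - p[i];
      const int s = (di > 0) - (di < 0);
      if (s == 0) continue;
      if (prev_s > 0 && s < 0) imax.push_back((prev_i + 1 + i) / 2);
      else if (prev_s < 0 && s > 0) imin.push_back((prev_i + 1 + i) / 2);
      prev_s = s; prev_i = i;
    }
    const int ext = std::min((int)imax.size(), (int)imin.size());
    if (ext < min_ext) min_ext = ext;
    if ((int)imax.size() < 2 || (int)imin.size() < 2) continue;
    ++nvalid;

    // evaluate all channels' envelopes in one pass per extremum set
    for (int side = 0; side < 2; ++side) {
      const std::vector<int>& idx = side == 0 ? imax : imin;
      const double sgn = side == 0 ? 1.0 : -1.0;
      mirror_extend(idx, n, xt, src);
      sp.set_knots(xt);
      for (int c = 0; c < nc; ++c) {
        const double* xc = Xp + (std::size_t)c * n;
        yk.resize(src.size());
        for (std::size_t j = 0; j < src.size(); ++j) yk[j] = xc[src[j]];
        sp.solve(c, yk);
      }
      // single sweep over all sample points, all channels per interval
      int k = 0;
      const double* xp2 = sp.x.data();
      const int m = sp.m;
      for (int i = 0; i < n; ++i) {
        const double t = (double)i;
        while (k < m - 2 && t > xp2[k + 1]) ++k;
        const double dt = t - xp2[k];
        for (int c = 0; c < nc; ++c) {
          const double v = sp.ykn[c][k] +
            dt * (sp.cb[c][k] + dt * (sp.cc[c][k] + dt * sp.cd[c][k]));
          const double w = Dp[dno + (std::size_t)c * nd];
          const double half = 0.5 * v;
          acc[(std::size_t)c * n + i] = (side == 0)
            ? half
            : acc[(std::size_t)c * n + i] + half;
          ampp[i] += sgn * w * half;
          if (side == 1) envp[(std::size_t)c * n + i] += acc[(std::size_t)c * n + i];
        }
      }
    }
  }
  if (nvalid > 0) {
    const double inv = 1.0 / nvalid;
    for (int i = 0; i < n; ++i) ampp[i] *= inv;
    for (std::size_t i = 0; i < (std::size_t)n * nc; ++i) envp[i] *= inv;
  }
  return List::create(_["mean"] = env, _["amp"] = amp,
                      _["min_extrema"] = min_ext, _["n_valid"] = nvalid);
}
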