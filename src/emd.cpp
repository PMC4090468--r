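#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Empirical mode decomposition.  The sifting loop dominates the run time of
// the whole pipeline (it is executed for every channel of every 10-s window),
// hence the C++ implementation.  Envelopes are natural cubic splines through
// the interior extrema, mirror-extended by two extrema at each end to tame
// boundary swings.

static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& mx, std::vector<int>& mn) {
  const int n = (int)x.size();
  mx.clear(); mn.clear();
  for (int i = 1; i + 1 < n; ++i) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) mx.push_back(i);
    else if (x[i] < x[i - 1] && x[i] < x[i + 1]) mn.push_back(i);
  }
}

static int count_zero_crossings(const std::vector<double>& x) {
  int z = 0;
  for (size_t i = 1; i < x.size(); ++i)
    if ((x[i - 1] > 0 && x[i] < 0) || (x[i - 1] < 0 && x[i] > 0)) ++z;
  return z;
}

// Natural cubic spline through (t, y) (t strictly increasing), evaluated at
// s = 0, 1, ..., n-1.  Outside [t.front(), t.back()] the end polynomial is
// extended (mirror extension normally prevents this case).
static void nat_spline_eval(const std::vector<double>& t,
                            const std::vector<double>& y,
                            int n, std::vector<double>& out) {
  const int k = (int)t.size();
  out.assign(n, 0.0);
  if (k == 1) { std::fill(out.begin(), out.end(), y[0]); return; }
  if (k == 2) {
    const double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int s = 0; s < n; ++s) out[s] = y[0] + slope * (s - t[0]);
    return;
  }
  // second derivatives M, natural boundary (M[0] = M[k-1] = 0); scratch
  // buffers are reused across calls (R is single-threaded)
  static std::vector<double> h, alpha, l, mu, z, M;
  h.assign(k - 1, 0.0); alpha.assign(k, 0.0); l.assign(k, 0.0);
  mu.assign(k, 0.0); z.assign(k, 0.0); M.assign(k, 0.0);
  for (int i = 0; i < k - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < k - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];

  // evaluate interval by interval with precomputed cubic coefficients in
  // u = xs - t[j]:  S(u) = y[j] + c1 u + c2 u^2 + c3 u^3
  int j = 0;
  for (int s = 0; s < n; ) {
    const double xs = (double)s;
    while (j < k - 2 && t[j + 1] < xs) ++j;
    const double hj = h[j];
    const double c1 = (y[j + 1] - y[j]) / hj - hj * (2.0 * M[j] + M[j + 1]) / 6.0;
    const double c2 = M[j] / 2.0;
    const double c3 = (M[j + 1] - M[j]) / (6.0 * hj);
    const double tj = t[j];
    const double t_hi = (j < k - 2) ? t[j + 1] : 1e300;
    while (s < n && ((double)s <= t_hi || j >= k - 2)) {
      const double u = (double)s - tj;
      out[s] = y[j] + u * (c1 + u * (c2 + u * c3));
      ++s;
    }
  }
}

// Mirror-extend up to two extrema about each end of the signal, then fit the
// envelope spline.  idx holds interior extrema indices (ascending, size >= 2).
static void envelope(const std::vector<double>& x, const std::vector<int>& idx,
                     int n, std::vector<double>& env) {
  static std::vector<double> t, v;
  t.clear(); v.clear();
  const int m = std::min((int)idx.size(), 2);
  for (int j = m - 1; j >= 0; --j) {          // reflected about sample 0
    t.push_back(-(double)idx[j]);
    v.push_back(x[idx[j]]);
  }
  for (size_t j = 0; j < idx.size(); ++j) { t.push_back((double)idx[j]); v.push_back(x[idx[j]]); }
  for (int j = 0; j < m; ++j) {               // reflected about sample n-1
    t.push_back(2.0 * (n - 1) - (double)idx[idx.size() - 1 - j]);
    v.push_back(x[idx[idx.size() - 1 - j]]);
  }
  // enforce strict monotonicity (duplicates can only arise from degenerate
  // reflections); drop repeats
  static std::vector<double> tt, vv;
  tt.clear(); vv.clear();
  for (size_t i = 0; i < t.size(); ++i) {
    if (tt.empty() || t[i] > tt.back() + 1e-12) { tt.push_back(t[i]); vv.push_back(v[i]); }
  }
  nat_spline_eval(tt, vv, n, env);
}

// One sifting pass: detail = x - mean envelope.  status: 0 ok, 1 monotonic-like
// (fewer than 2 maxima or 2 minima).
// [[Rcpp::export]]
List sift_once_cpp(NumericVector x) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  std::vector<int> mx, mn;
  find_extrema(xv, mx, mn);
  if ((int)mx.size() < 2 || (int)mn.size() < 2)
    return List::create(_["status"] = 1);
  std::vector<double> upper, lower;
  envelope(xv, mx, n, upper);
  envelope(xv, mn, n, lower);
  NumericVector detail(n), menv(n);
  for (int i = 0; i < n; ++i) {
    menv[i] = 0.5 * (upper[i] + lower[i]);
    detail[i] = xv[i] - menv[i];
  }
  return List::create(_["status"] = 0, _["detail"] = detail, _["mean_env"] = menv);
}

// Full EMD.  Sifting of one IMF stops when the relative change between
// consecutive sift iterates falls below sd_tol AND the IMF criteria
// (|#maxima - #minima| <= 1, zero crossings within 1 of the extrema count)
// hold, or after max_sift passes.  The residual is what is left after
// subtracting the IMFs, so reconstruction is exact by construction.
// [[Rcpp::export]]
List emd_cpp(NumericVector x, int max_imf, double sd_tol, int max_sift) {
  const int n = x.size();
  std::vector<double> r(x.begin(), x.end());
  std::vector< std::vector<double> > imfs;
  std::vector<int> sift_counts;

  std::vector<int> mx, mn;
  std::vector<double> d, upper, lower, dnew(n);
  mx.reserve(n / 2); mn.reserve(n / 2);
  upper.reserve(n); lower.reserve(n);

  for (int k = 0; k < max_imf; ++k) {
    find_extrema(r, mx, mn);
    if ((int)mx.size() < 2 || (int)mn.size() < 2) break;  // monotonic-like residual

    d = r;
    int sift = 0;
    bool have_extrema = true;                 // extrema of d already in mx/mn
    while (true) {
      if (!have_extrema) find_extrema(d, mx, mn);
      if ((int)mx.size() < 2 || (int)mn.size() < 2) break;
      envelope(d, mx, n, upper);
      envelope(d, mn, n, lower);
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        const double m = 0.5 * (upper[i] + lower[i]);
        dnew[i] = d[i] - m;
        num += m * m;
        den += d[i] * d[i];
      }
      ++sift;
      const double sd = (den > 0.0) ? num / den : 0.0;
      find_extrema(dnew, mx, mn);             // extrema of the new iterate
      have_extrema = true;
      const int next = (int)mx.size() + (int)mn.size();
      const int nz = count_zero_crossings(dnew);
      const bool crit = std::abs((int)mx.size() - (int)mn.size()) <= 1 &&
                        std::abs(next - nz) <= 1;
      d.swap(dnew);
      if ((sd < sd_tol && crit) || sift >= max_sift) break;
    }
    imfs.push_back(d);
    sift_counts.push_back(sift);
    for (int i = 0; i < n; ++i) r[i] -= d[i];
  }

  List li(imfs.size());
  for (size_t k = 0; k < imfs.size(); ++k) li[k] = NumericVector(imfs[k].begin(), imfs[k].end());
  return List::create(_["imfs"] = li,
                      _["residual"] = NumericVector(r.begin(), r.end()),
                      _["sift_counts"] = IntegerVector(sift_counts.begin(), sift_counts.end()));
}
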