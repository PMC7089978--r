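// Multi-tau autocorrelator: m linear lags in the first octave, then m/2 new
// lags per octave with pairwise bin coarsening (bin width doubles each
// octave). Normalization is the fluctuation form with symmetric means over
// the overlapping head/tail segments at each lag, so g -> 0 at long lag and
// the zero-lag diffusion amplitude is ~ 1/N.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".multitau_kernel")]]
List multitau_kernel(NumericVector counts, int m, double bin_width,
                     double max_lag) {
  const R_xlen_t n0 = counts.size();
  std::vector<double> v(counts.begin(), counts.end());
  std::vector<double> out_lag, out_g;
  std::vector<int> out_level, out_k;

  double w = bin_width;
  int level = 0;
  while (true) {
    const R_xlen_t n = static_cast<R_xlen_t>(v.size());
    const int k_lo = (level == 0) ? 1 : m / 2 + 1;
    if (n < 2 * static_cast<R_xlen_t>(m)) break;

    double total = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) total += v[i];
    // cumulative sums of the first and last m elements for the symmetric means
    std::vector<double> headcum(m + 1, 0.0), tailcum(m + 1, 0.0);
    for (int k = 1; k <= m; ++k) {
      headcum[k] = headcum[k - 1] + v[k - 1];
      tailcum[k] = tailcum[k - 1] + v[n - k];
    }

    bool past_max = false;
    for (int k = k_lo; k <= m; ++k) {
      const double lag_s = k * w;
      if (lag_s > max_lag) { past_max = true; break; }
      const R_xlen_t nk = n - k;
      double s = 0.0;
      const double* a = v.data();
      const double* b = v.data() + k;
      for (R_xlen_t i = 0; i < nk; ++i) s += a[i] * b[i];
      const double mh = (total - tailcum[k]) / nk;
      const double mt = (total - headcum[k]) / nk;
      double g = NA_REAL;
      if (mh > 0.0 && mt > 0.0) g = s / nk / (mh * mt) - 1.0;
      out_lag.push_back(lag_s);
      out_g.push_back(g);
      out_level.push_back(level);
      out_k.push_back(k);
    }
    if (past_max) break;

    // coarsen: pairwise sums, bin width doubles
    const R_xlen_t nh = n / 2;
    for (R_xlen_t i = 0; i < nh; ++i) v[i] = v[2 * i] + v[2 * i + 1];
    v.resize(nh);
    w *= 2.0;
    ++level;
    if (nh < 2 * static_cast<R_xlen_t>(m)) break;
  }

  (void)n0;
  return List::create(_["lag"] = wrap(out_lag), _["g"] = wrap(out_g),
                      _["level"] = wrap(out_level), _["k"] = wrap(out_k));
}
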