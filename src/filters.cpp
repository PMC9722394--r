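#include <Rcpp.h>
using namespace Rcpp;

// Forward rolling max-min range over windows of w samples for every row of
// x; returns nrow(x) x (ncol(x) - w + 1).
// [[Rcpp::export]]
NumericMatrix cpp_roll_range(NumericMatrix x, int w) {
  const int nch = x.nrow(), n = x.ncol();
  const int m = n - w + 1;
  NumericMatrix out(nch, m);
  std::vector<double> buf(n);
  for (int ch = 0; ch < nch; ++ch) {
    for (int t = 0; t < n; ++t) buf[t] = x(ch, t);
    // simple sliding extrema; w is small (tens of samples)
    for (int s = 0; s < m; ++s) {
      double mx = buf[s], mn = buf[s];
      for (int k = 1; k < w; ++k) {
        const double v = buf[s + k];
        if (v > mx) mx = v;
        if (v < mn) mn = v;
      }
      out(ch, s) = mx - mn;
    }
  }
  return out;
}

// Zero-phase filtering of every row of x: forward pass with 2*max(na,nb)
// appended zeros, then a reversed pass, as in the usual filtfilt
// convention (zero initial conditions). Coefficients must be normalized
// (a[0] == 1).
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_rows(NumericVector b, NumericVector a,
                                NumericMatrix x) {
  const int nch = x.nrow(), n = x.ncol();
  const int nb = b.size(), na = a.size();
  const int pad = 2 * (na > nb ? na : nb);
  const int N = n + pad;
  NumericMatrix out(nch, n);
  std::vector<double> xr(N, 0.0), y(N), z(N);
  for (int ch = 0; ch < nch; ++ch) {
    for (int t = 0; t < n; ++t) xr[t] = x(ch, t);
    for (int t = n; t < N; ++t) xr[t] = 0.0;
    for (int t = 0; t < N; ++t) {
      double acc = b[0] * xr[t];
      for (int k = 1; k < nb && k <= t; ++k) acc += b[k] * xr[t - k];
      for (int k = 1; k < na && k <= t; ++k) acc -= a[k] * y[t - k];
      y[t] = acc;
    }
    // backward pass over reversed y
    for (int t = 0; t < N; ++t) {
      double acc = b[0] * y[N - 1 - t];
      for (int k = 1; k < nb && k <= t; ++k) acc += b[k] * y[N - 1 - (t - k)];
      for (int k = 1; k < na && k <= t; ++k) acc -= a[k] * z[t - k];
      z[t] = acc;
    }
    for (int t = 0; t < n; ++t) out(ch, t) = z[N - 1 - t];
  }
  return out;
}

// Optical density relative to the per-row mean: -log10(x / rowMean(x)).
// The caller guarantees strictly positive input.
// [[Rcpp::export]]
NumericMatrix cpp_od(NumericMatrix x) {
  const int nch = x.nrow(), n = x.ncol();
  NumericMatrix out(nch, n);
  const double l10 = std::log(10.0);
  for (int ch = 0; ch < nch; ++ch) {
    double mu = 0.0;
    for (int t = 0; t < n; ++t) mu += x(ch, t);
    mu /= n;
    const double lmu = std::log(mu);
    for (int t = 0; t < n; ++t)
      out(ch, t) = -(std::log(x(ch, t)) - lmu) / l10;
  }
  return out;
}

// Fused forward model: intensity(ch, t) = gain[ch] * (10^-(odHemo + odExtra)
// + sensor noise), drawing the noise from R's RNG in column-major order of
// the T x nch optical-density input.
// [[Rcpp::export]]
NumericMatrix cpp_intensity(NumericMatrix odHemo, NumericMatrix odExtra,
                            NumericVector gain, double noiseSd) {
  const int n = odHemo.nrow(), nch = odHemo.ncol();
  NumericMatrix out(nch, n);
  GetRNGstate();
  for (int ch = 0; ch < nch; ++ch) {
    const double g = gain[ch];
    const double *h = &odHemo(0, ch);
    const double *e = &odExtra(0, ch);
    for (int t = 0; t < n; ++t) {
      const double od = h[t] + e[t];
      out(ch, t) = g * (std::pow(10.0, -od) + norm_rand() * noiseSd);
    }
  }
  PutRNGstate();
  return out;
}

// Nuisance sinusoids plus linear drift, built in one pass:
// out(t, ch) = sum_c amp[c] * sin(2 pi freq[c] t / fs + phase(c, ch))
//            + (t / (n-1)) * slope[ch],  for a T x nch matrix.
// [[Rcpp::export]]
NumericMatrix cpp_od_extra(int n, NumericVector amp, NumericVector freq,
                           NumericMatrix phase, NumericVector slope,
                           double fs) {
  const int nch = slope.size(), ncomp = amp.size();
  NumericMatrix out(n, nch);
  const double twopi = 2.0 * M_PI;
  for (int ch = 0; ch < nch; ++ch) {
    double *o = &out(0, ch);
    const double ds = slope[ch] / (n - 1);
    for (int t = 0; t < n; ++t) o[t] = t * ds;
    for (int c = 0; c < ncomp; ++c) {
      const double w = twopi * freq[c] / fs, ph = phase(c, ch), A = amp[c];
      // recurrence for sin(w t + ph) avoids n*ncomp trig calls
      const double cw = std::cos(w), sw = std::sin(w);
      double s = std::sin(ph), cc = std::cos(ph);
      for (int t = 0; t < n; ++t) {
        o[t] += A * s;
        const double s2 = s * cw + cc * sw;
        cc = cc * cw - s * sw;
        s = s2;
      }
    }
  }
  return out;
}

// Modified Beer-Lambert inversion for channel x time matrices: applies the
// pre-inverted 2x2 extinction system to paired optical-density inputs.
// [[Rcpp::export]]
List cpp_mbll(NumericMatrix od1, NumericMatrix od2, double i11, double i12,
              double i21, double i22) {
  const R_xlen_t n = od1.size();
  NumericMatrix hbo(od1.nrow(), od1.ncol()), hbr(od1.nrow(), od1.ncol());
  const double *p1 = od1.begin(), *p2 = od2.begin();
  double *o = hbo.begin(), *r = hbr.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    o[i] = i11 * p1[i] + i12 * p2[i];
    r[i] = i21 * p1[i] + i22 * p2[i];
  }
  hbo.attr("dimnames") = od1.attr("dimnames");
  hbr.attr("dimnames") = od1.attr("dimnames");
  return List::create(_["hbo"] = hbo, _["hbr"] = hbr);
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// The pipeline churns through many multi-megabyte channel x time matrices
// per subject. With glibc defaults each of them is serviced by mmap and
// returned to the OS on free, so whole-cohort runs spend a large fraction
// of their time in page faults. Raising the mmap/trim thresholds keeps
// these blocks on the heap for reuse; no-op on non-glibc platforms.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 134217728);
  mallopt(M_TRIM_THRESHOLD, 134217728);
#endif
}
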