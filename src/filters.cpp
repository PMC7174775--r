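#include <Rcpp.h>
using namespace Rcpp;

// Multi-channel IIR filtering along the time axis of a channels x samples
// matrix (column-major, so the per-sample channel block is contiguous).
// Direct-form II transposed; a[0] need not be 1.

struct Coefs {
  std::vector<double> b, a;
  int nz;
  Coefs(NumericVector bv, NumericVector av) {
    nz = (int)std::max(bv.size(), av.size()) - 1;
    b.assign(nz + 1, 0.0);
    a.assign(nz + 1, 0.0);
    for (int i = 0; i < bv.size(); ++i) b[i] = bv[i] / av[0];
    for (int i = 0; i < av.size(); ++i) a[i] = av[i] / av[0];
  }
};

// One directional pass over samples step = +1 (forward) or -1 (backward).
// x, y are nchan x n; z is the nz x nchan state buffer (zeroed by caller).
static void pass_rows(const Coefs& cf, const double* x, double* y,
                      int nchan, int n, int step,
                      std::vector<double>& z) {
  std::fill(z.begin(), z.end(), 0.0);
  int nz = cf.nz;
  int i0 = (step > 0) ? 0 : n - 1;
  for (int s = 0; s < n; ++s) {
    const double* xi = x + (size_t)(i0 + step * s) * nchan;
    double* yi = y + (size_t)(i0 + step * s) * nchan;
    for (int k = 0; k < nz; ++k) {
      double* zk = &z[(size_t)k * nchan];
      double* zk1 = (k + 1 < nz) ? &z[(size_t)(k + 1) * nchan] : nullptr;
      double bk = cf.b[k + 1], ak = cf.a[k + 1];
      if (k == 0) {
        for (int c = 0; c < nchan; ++c) {
          double v = cf.b[0] * xi[c] + zk[c];
          yi[c] = v;
        }
      }
      if (zk1) {
        for (int c = 0; c < nchan; ++c)
          zk[c] = bk * xi[c] + zk1[c] - ak * yi[c];
      } else {
        for (int c = 0; c < nchan; ++c)
          zk[c] = bk * xi[c] - ak * yi[c];
      }
    }
    if (nz == 0) {
      for (int c = 0; c < nchan; ++c) yi[c] = cf.b[0] * xi[c];
    }
  }
}

// [[Rcpp::export(name = ".iir_rows")]]
NumericMatrix iir_rows(NumericVector b, NumericVector a, NumericMatrix x) {
  Coefs cf(b, a);
  int nchan = x.nrow(), n = x.ncol();
  NumericMatrix y(nchan, n);
  std::vector<double> z((size_t)std::max(cf.nz, 1) * nchan, 0.0);
  pass_rows(cf, REAL(x), REAL(y), nchan, n, 1, z);
  return y;
}

// Zero-phase (forward-backward) filtering with odd reflection padding of
// `npad` samples at each end, MATLAB-filtfilt style.
// [[Rcpp::export(name = ".filtfilt_rows")]]
NumericMatrix filtfilt_rows(NumericVector b, NumericVector a, NumericMatrix x,
                            int npad) {
  Coefs cf(b, a);
  int nchan = x.nrow(), n = x.ncol();
  if (npad >= n) stop("signal too short for zero-phase padding");
  int ne = n + 2 * npad;
  std::vector<double> xe((size_t)nchan * ne), ye((size_t)nchan * ne);
  const double* xp = REAL(x);
  // odd reflection: x[-i] = 2 x[0] - x[i]
  for (int i = 0; i < npad; ++i) {
    const double* first = xp;
    const double* mirr = xp + (size_t)(npad - i) * nchan;
    double* dst = xe.data() + (size_t)i * nchan;
    for (int c = 0; c < nchan; ++c) dst[c] = 2.0 * first[c] - mirr[c];
  }
  std::copy(xp, xp + (size_t)nchan * n, xe.data() + (size_t)npad * nchan);
  for (int i = 0; i < npad; ++i) {
    const double* last = xp + (size_t)(n - 1) * nchan;
    const double* mirr = xp + (size_t)(n - 2 - i) * nchan;
    double* dst = xe.data() + (size_t)(npad + n + i) * nchan;
    for (int c = 0; c < nchan; ++c) dst[c] = 2.0 * last[c] - mirr[c];
  }
  std::vector<double> z((size_t)std::max(cf.nz, 1) * nchan, 0.0);
  pass_rows(cf, xe.data(), ye.data(), nchan, ne, 1, z);
  pass_rows(cf, ye.data(), xe.data(), nchan, ne, -1, z);
  NumericMatrix y(nchan, n);
  std::copy(xe.data() + (size_t)npad * nchan,
            xe.data() + (size_t)(npad + n) * nchan, REAL(y));
  return y;
}

// Centered moving average along the time axis; positions whose window does
// not fit entirely inside the series are NA.
// [[Rcpp::export(name = ".moving_average_rows")]]
NumericMatrix moving_average_rows(NumericMatrix x, int w) {
  int nchan = x.nrow(), n = x.ncol();
  NumericMatrix y(nchan, n);
  std::fill(y.begin(), y.end(), NA_REAL);
  if (w < 1 || w > n) return y;
  int lead = (w - 1) / 2;
  std::vector<double> s(nchan, 0.0);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int i = 0; i < w; ++i) {
    const double* xi = xp + (size_t)i * nchan;
    for (int c = 0; c < nchan; ++c) s[c] += xi[c];
  }
  double* yl = yp + (size_t)lead * nchan;
  for (int c = 0; c < nchan; ++c) yl[c] = s[c] / w;
  for (int i = w; i < n; ++i) {
    const double* xin = xp + (size_t)i * nchan;
    const double* xout = xp + (size_t)(i - w) * nchan;
    double* yi = yp + (size_t)(lead + i - w + 1) * nchan;
    for (int c = 0; c < nchan; ++c) {
      s[c] += xin[c] - xout[c];
      yi[c] = s[c] / w;
    }
  }
  return y;
}
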