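#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structural similarity of 2D arrays: uniform win x win window, valid-region
// mean, stabilisation constants C1 = (0.01 L)^2, C2 = (0.03 L)^2, sample
// (n/(n-1)) covariance normalisation -- the standard reference formulation.
// Window sums via summed-area tables so the pairwise matrix stays tractable.

static void sat_build(const double *img, int nrow, int ncol,
                      std::vector<double> &sat) {
  const int sr = nrow + 1;
  for (int c = 0; c <= ncol; ++c) sat[(size_t)c * sr] = 0.0;
  for (int r = 0; r <= nrow; ++r) sat[r] = 0.0;
  for (int c = 1; c <= ncol; ++c) {
    double rowsum = 0.0;
    const double *col = img + (size_t)(c - 1) * nrow;
    double *s = &sat[(size_t)c * sr];
    const double *sprev = &sat[(size_t)(c - 1) * sr];
    for (int r = 1; r <= nrow; ++r) {
      rowsum += col[r - 1];
      s[r] = sprev[r] + rowsum;
    }
  }
}

static inline double sat_win(const std::vector<double> &sat, int sr,
                             int r0, int c0, int win) {
  return sat[(size_t)(c0 + win) * sr + (r0 + win)]
       - sat[(size_t)c0 * sr + (r0 + win)]
       - sat[(size_t)(c0 + win) * sr + r0]
       + sat[(size_t)c0 * sr + r0];
}

// window means of an image at all valid positions (length nval, col-major
// over (r0, c0))
static void win_means(const double *img, int nrow, int ncol, int win,
                      std::vector<double> &sat, double *out) {
  sat_build(img, nrow, ncol, sat);
  const int sr = nrow + 1;
  const double np = (double)win * win;
  int k = 0;
  for (int c0 = 0; c0 + win <= ncol; ++c0)
    for (int r0 = 0; r0 + win <= nrow; ++r0)
      out[k++] = sat_win(sat, sr, r0, c0, win) / np;
}

static double ssim_from_parts(const double *ux, const double *uy,
                              const double *vx, const double *vy,
                              const double *uxy_mean, int nval,
                              double cov_norm, double C1, double C2) {
  double acc = 0.0;
  for (int k = 0; k < nval; ++k) {
    double vxy = cov_norm * (uxy_mean[k] - ux[k] * uy[k]);
    double a1 = 2.0 * ux[k] * uy[k] + C1;
    double a2 = 2.0 * vxy + C2;
    double b1 = ux[k] * ux[k] + uy[k] * uy[k] + C1;
    double b2 = vx[k] + vy[k] + C2;
    acc += (a1 * a2) / (b1 * b2);
  }
  return acc / nval;
}

// [[Rcpp::export(name = ".ssim_pair_cpp")]]
double ssim_pair_cpp(NumericMatrix x, NumericMatrix y, int win, double L) {
  const int nrow = x.nrow(), ncol = x.ncol();
  const int nvr = nrow - win + 1, nvc = ncol - win + 1;
  const int nval = nvr * nvc;
  const double np = (double)win * win;
  const double cov_norm = np / (np - 1.0);
  const double C1 = (0.01 * L) * (0.01 * L), C2 = (0.03 * L) * (0.03 * L);
  std::vector<double> sat((size_t)(nrow + 1) * (ncol + 1));
  std::vector<double> ux(nval), uy(nval), uxx(nval), uyy(nval), uxy(nval);
  std::vector<double> tmp((size_t)nrow * ncol);

  win_means(x.begin(), nrow, ncol, win, sat, ux.data());
  win_means(y.begin(), nrow, ncol, win, sat, uy.data());
  for (size_t i = 0; i < tmp.size(); ++i) tmp[i] = x[i] * x[i];
  win_means(tmp.data(), nrow, ncol, win, sat, uxx.data());
  for (size_t i = 0; i < tmp.size(); ++i) tmp[i] = y[i] * y[i];
  win_means(tmp.data(), nrow, ncol, win, sat, uyy.data());
  for (size_t i = 0; i < tmp.size(); ++i) tmp[i] = x[i] * y[i];
  win_means(tmp.data(), nrow, ncol, win, sat, uxy.data());

  std::vector<double> vx(nval), vy(nval);
  for (int k = 0; k < nval; ++k) {
    vx[k] = cov_norm * (uxx[k] - ux[k] * ux[k]);
    vy[k] = cov_norm * (uyy[k] - uy[k] * uy[k]);
  }
  return ssim_from_parts(ux.data(), uy.data(), vx.data(), vy.data(),
                         uxy.data(), nval, cov_norm, C1, C2);
}

// Full pairwise SSIM matrix for n images stored as columns of H
// (npix = nrow*ncol rows). Per-image window means and variances are
// precomputed; each pair costs one product summed-area table.
// [[Rcpp::export(name = ".ssim_matrix_cpp")]]
NumericMatrix ssim_matrix_cpp(NumericMatrix H, int nrow, int ncol,
                              int win, double L) {
  const int n = H.ncol();
  const int npix = nrow * ncol;
  const int nvr = nrow - win + 1, nvc = ncol - win + 1;
  const int nval = nvr * nvc;
  const double np = (double)win * win;
  const double cov_norm = np / (np - 1.0);
  const double C1 = (0.01 * L) * (0.01 * L), C2 = (0.03 * L) * (0.03 * L);

  std::vector<double> sat((size_t)(nrow + 1) * (ncol + 1));
  std::vector<double> mu((size_t)n * nval), var((size_t)n * nval);
  std::vector<double> tmp((size_t)npix);
  std::vector<double> uxx(nval);

  for (int i = 0; i < n; ++i) {
    const double *img = &H(0, i);
    double *mi = &mu[(size_t)i * nval];
    win_means(img, nrow, ncol, win, sat, mi);
    for (int p = 0; p < npix; ++p) tmp[p] = img[p] * img[p];
    win_means(tmp.data(), nrow, ncol, win, sat, uxx.data());
    double *vi = &var[(size_t)i * nval];
    for (int k = 0; k < nval; ++k)
      vi[k] = cov_norm * (uxx[k] - mi[k] * mi[k]);
  }

  NumericMatrix out(n, n);
  std::vector<double> uxy(nval);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    const double *xi = &H(0, i);
    for (int j = i + 1; j < n; ++j) {
      const double *xj = &H(0, j);
      for (int p = 0; p < npix; ++p) tmp[p] = xi[p] * xj[p];
      win_means(tmp.data(), nrow, ncol, win, sat, uxy.data());
      double s = ssim_from_parts(&mu[(size_t)i * nval], &mu[(size_t)j * nval],
                                 &var[(size_t)i * nval], &var[(size_t)j * nval],
                                 uxy.data(), nval, cov_norm, C1, C2);
      out(i, j) = s;
      out(j, i) = s;
    }
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
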