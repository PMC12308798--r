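#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Radial-angular three-particle correlation accumulation for one molecule
// over frames. For each atom B of the selection, A is its nearest other
// selection atom (ties broken by lowest index); every selection atom C != B
// within the radial cutoff deposits weight 1 at (r_BC, cos theta_ABC).
// coords: n_atoms x 3 x n_frames (selection atoms only, one molecule).
// Returns nr x na count matrix (not yet normalised).
// [[Rcpp::export(name = ".g3_accumulate_cpp")]]
NumericMatrix g3_accumulate_cpp(NumericVector coords, int n_atoms,
                                int n_frames, double cutoff,
                                int nr, int na) {
  NumericMatrix out(nr, na);
  const double *xyz = coords.begin();
  const int stride_f = n_atoms * 3;

  for (int f = 0; f < n_frames; ++f) {
    const double *p = xyz + (size_t)f * stride_f;
    for (int b = 0; b < n_atoms; ++b) {
      const double bx = p[b], by = p[b + n_atoms], bz = p[b + 2 * n_atoms];
      // nearest neighbour A
      int a_idx = -1;
      double best = R_PosInf;
      for (int j = 0; j < n_atoms; ++j) {
        if (j == b) continue;
        double dx = p[j] - bx, dy = p[j + n_atoms] - by,
               dz = p[j + 2 * n_atoms] - bz;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best - 1e-12) { best = d2; a_idx = j; }
      }
      if (a_idx < 0) continue;
      double ax = p[a_idx] - bx, ay = p[a_idx + n_atoms] - by,
             az = p[a_idx + 2 * n_atoms] - bz;
      double an = std::sqrt(ax * ax + ay * ay + az * az);
      if (an <= 0) continue;
      ax /= an; ay /= an; az /= an;
      for (int c = 0; c < n_atoms; ++c) {
        if (c == b) continue;
        double cx = p[c] - bx, cy = p[c + n_atoms] - by,
               cz = p[c + 2 * n_atoms] - bz;
        double r = std::sqrt(cx * cx + cy * cy + cz * cz);
        if (r <= 0 || r > cutoff) continue;
        double ct = (ax * cx + ay * cy + az * cz) / r;
        if (ct > 1.0) ct = 1.0;
        if (ct < -1.0) ct = -1.0;
        int ri = (int)std::ceil(r / cutoff * nr) - 1;
        if (ri < 0) ri = 0;
        if (ri >= nr) ri = nr - 1;
        int ci = (int)std::floor((ct + 1.0) / 2.0 * na);
        if (ci >= na) ci = na - 1;
        out(ri, ci) += 1.0;
      }
    }
  }
  return out;
}
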