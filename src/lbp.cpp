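#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of the DIFFERENCE from the center intensity at (rr, cc)
// (0-based, fractional). Interpolating corner differences (rather than
// intensities) keeps d exactly 0 on constant neighborhoods even though the
// four bilinear weights need not sum to 1 in floating point. Index guards
// keep the second corner in-bounds when the fractional part is exactly 0
// (the margin guarantees that is the only way to touch the last row or
// column). The arithmetic order mirrors the naive R sampler exactly so the
// two routes are bit-identical.
static inline double bilinear_diff(const NumericMatrix& S, double rr,
                                   double cc, double center) {
  double r0 = std::floor(rr), c0 = std::floor(cc);
  double fr = rr - r0, fc = cc - c0;
  int i0 = (int)r0, j0 = (int)c0;
  int i1 = fr > 0 ? i0 + 1 : i0;
  int j1 = fc > 0 ? j0 + 1 : j0;
  return (1 - fr) * (1 - fc) * (S(i0, j0) - center) +
         fr * (1 - fc) * (S(i1, j0) - center) +
         (1 - fr) * fc * (S(i0, j1) - center) +
         fr * fc * (S(i1, j1) - center);
}

// Map of rotation-invariant uniform (riu2) LBP codes over the valid region
// of one slice. Offsets (dr, dc) are precomputed in R (shared with the naive
// route); margin = ceil(R). Output is (nr-2m) x (nc-2m), values in 0..P+1.
// [[Rcpp::export]]
IntegerMatrix lbp_codemap_cpp(NumericMatrix S, NumericVector dr,
                              NumericVector dc, int margin) {
  const int nr = S.nrow(), nc = S.ncol(), P = dr.size(), m = margin;
  if (nr < 2 * m + 1 || nc < 2 * m + 1)
    stop("slice too small for radius: need at least %d pixels per side", 2 * m + 1);
  IntegerMatrix out(nr - 2 * m, nc - 2 * m);
  for (int c = m; c < nc - m; ++c) {
    for (int r = m; r < nr - m; ++r) {
      const double center = S(r, c);
      int ones = 0, trans = 0, first = 0, prev = 0;
      for (int i = 0; i < P; ++i) {
        double d = bilinear_diff(S, r + dr[i], c + dc[i], center);
        int b = (d >= 0) ? 1 : 0;
        ones += b;
        if (i == 0) first = b; else trans += (b != prev);
        prev = b;
      }
      trans += (prev != first);  // circular wrap
      out(r - m, c - m) = (trans <= 2) ? ones : P + 1;
    }
  }
  return out;
}

// Pooled (P+2)-bin count histogram of riu2 codes over all slices of a 64^3
// patch along one orientation. axis: 0 = XY planes (pool over z),
// 1 = XZ planes (pool over y), 2 = YZ planes (pool over x).
// [[Rcpp::export]]
NumericVector lbp_top_hist_cpp(NumericVector patch, int axis, NumericVector dr,
                               NumericVector dc, int margin) {
  IntegerVector dims = patch.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int P = dr.size();
  NumericVector hist(P + 2);
  int n_slices = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  for (int s = 0; s < n_slices; ++s) {
    NumericMatrix S =
        (axis == 0) ? NumericMatrix(nx, ny) :
        (axis == 1) ? NumericMatrix(nx, nz) : NumericMatrix(ny, nz);
    if (axis == 0) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) S(i, j) = patch[i + nx * (j + (R_xlen_t)ny * s)];
    } else if (axis == 1) {
      for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) S(i, k) = patch[i + nx * (s + (R_xlen_t)ny * k)];
    } else {
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) S(j, k) = patch[s + nx * (j + (R_xlen_t)ny * k)];
    }
    IntegerMatrix codes = lbp_codemap_cpp(S, dr, dc, margin);
    for (int idx = 0; idx < codes.size(); ++idx) hist[codes[idx]] += 1.0;
  }
  return hist;
}
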