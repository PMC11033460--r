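// Low-level image kernels: binary morphology with arbitrary offset sets,
// dense 2-D convolution with reflected borders, affine warping, resizing,
// and the directed Hausdorff scan. All grids are row-major conceptually but
// stored as R column-major matrices; (i, j) = (row, col), 0-based here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Dilation as a Minkowski scatter: every foreground pixel stamps the
// (symmetric) structuring element around itself. Out-of-grid is dropped,
// which equals treating the outside as background.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate(const IntegerMatrix& m, const IntegerMatrix& off) {
  const int H = m.nrow(), W = m.ncol(), n = off.nrow();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (m(i, j) == 0) continue;
      for (int k = 0; k < n; ++k) {
        int ii = i + off(k, 0), jj = j + off(k, 1);
        if (ii >= 0 && ii < H && jj >= 0 && jj < W) out(ii, jj) = 1;
      }
    }
  }
  return out;
}

// Erosion: a pixel survives iff every offset lands on foreground inside the
// grid, so objects shrink at the image border (outside counts as 0).
// [[Rcpp::export]]
IntegerMatrix cpp_erode(const IntegerMatrix& m, const IntegerMatrix& off) {
  const int H = m.nrow(), W = m.ncol(), n = off.nrow();
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      bool keep = true;
      for (int k = 0; k < n && keep; ++k) {
        int ii = i + off(k, 0), jj = j + off(k, 1);
        keep = (ii >= 0 && ii < H && jj >= 0 && jj < W && m(ii, jj) == 1);
      }
      out(i, j) = keep ? 1 : 0;
    }
  }
  return out;
}

static inline int reflect_idx(int i, int n) {
  // symmetric reflection including the edge pixel: -1 -> 0, n -> n-1
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Dense correlation with reflected borders; kernels here are symmetric so
// correlation and convolution coincide.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_reflect(const NumericMatrix& x, const NumericMatrix& k) {
  const int H = x.nrow(), W = x.ncol();
  const int kh = k.nrow(), kw = k.ncol();
  const int ch = kh / 2, cw = kw / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int b = 0; b < kw; ++b) {
        int jj = reflect_idx(j + b - cw, W);
        for (int a = 0; a < kh; ++a) {
          int ii = reflect_idx(i + a - ch, H);
          s += k(a, b) * x(ii, jj);
        }
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Inverse-mapped affine warp: dst(i,j) samples src at M %*% (i,j) + t.
// Out-of-range samples are the constant `fill`; `nearest` toggles
// nearest-neighbour (masks) vs bilinear (images).
// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(const NumericMatrix& x, const NumericMatrix& M,
                              const NumericVector& t, bool nearest, double fill) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double si = M(0, 0) * i + M(0, 1) * j + t[0];
      double sj = M(1, 0) * i + M(1, 1) * j + t[1];
      if (nearest) {
        int ii = (int) std::lround(si), jj = (int) std::lround(sj);
        out(i, j) = (ii >= 0 && ii < H && jj >= 0 && jj < W) ? x(ii, jj) : fill;
      } else {
        int i0 = (int) std::floor(si), j0 = (int) std::floor(sj);
        double di = si - i0, dj = sj - j0, s = 0.0;
        for (int b = 0; b <= 1; ++b) {
          for (int a = 0; a <= 1; ++a) {
            double wgt = (a ? di : 1 - di) * (b ? dj : 1 - dj);
            int ii = i0 + a, jj = j0 + b;
            double v = (ii >= 0 && ii < H && jj >= 0 && jj < W) ? x(ii, jj) : fill;
            s += wgt * v;
          }
        }
        out(i, j) = s;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize(const NumericMatrix& x, int oh, int ow, bool nearest) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(oh, ow);
  const double si = (double) H / oh, sj = (double) W / ow;
  for (int j = 0; j < ow; ++j) {
    for (int i = 0; i < oh; ++i) {
      double fi = (i + 0.5) * si - 0.5, fj = (j + 0.5) * sj - 0.5;
      if (nearest) {
        int ii = std::min(std::max((int) std::lround(fi), 0), H - 1);
        int jj = std::min(std::max((int) std::lround(fj), 0), W - 1);
        out(i, j) = x(ii, jj);
      } else {
        int i0 = std::min(std::max((int) std::floor(fi), 0), H - 1);
        int j0 = std::min(std::max((int) std::floor(fj), 0), W - 1);
        int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        double di = std::min(std::max(fi - i0, 0.0), 1.0);
        double dj = std::min(std::max(fj - j0, 0.0), 1.0);
        out(i, j) = (1 - di) * (1 - dj) * x(i0, j0) + di * (1 - dj) * x(i1, j0) +
                    (1 - di) * dj * x(i0, j1) + di * dj * x(i1, j1);
      }
    }
  }
  return out;
}

// Symmetric Hausdorff distance between two point sets (n x 2 coordinate
// matrices), with an early break once the running minimum drops below the
// current maximum.
// [[Rcpp::export]]
double cpp_hausdorff(const NumericMatrix& X, const NumericMatrix& Y) {
  const int nx = X.nrow(), ny = Y.nrow();
  double h = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    const NumericMatrix& A = pass == 0 ? X : Y;
    const NumericMatrix& B = pass == 0 ? Y : X;
    for (int i = 0; i < (pass == 0 ? nx : ny); ++i) {
      double dmin = R_PosInf;
      for (int j = 0; j < (pass == 0 ? ny : nx); ++j) {
        double d0 = A(i, 0) - B(j, 0), d1 = A(i, 1) - B(j, 1);
        double d = d0 * d0 + d1 * d1;
        if (d < dmin) {
          dmin = d;
          if (dmin <= h) break;  // cannot raise the max any more
        }
      }
      if (dmin > h) h = dmin;
    }
  }
  return std::sqrt(h);
}
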