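// Low-level 2D raster kernels: polygon fill, grid resampling, affine warps.
// All index arguments are 0-based; matrices are column-major (row, col) as in R.
#include <Rcpp.h>
using namespace Rcpp;

// Even-odd (crossing number) point-in-polygon test for pixel centers.
// Polygon vertices are in continuous pixel coordinates where pixel (r, c)
// has its center at x = c, y = r.  The half-open crossing rule
// ((y1 > y) != (y2 > y), strict x comparison) makes boundary-grazing centers
// resolve deterministically: a center on an "entering" (upward-crossing on
// the left) edge counts inside, matching the documented rasterization rule.
// [[Rcpp::export(name = ".cpp_fill_polygon")]]
LogicalMatrix cpp_fill_polygon(NumericVector px, NumericVector py,
                               int nrow, int ncol) {
  LogicalMatrix out(nrow, ncol);
  int n = px.size();
  if (n < 3) return out;
  double ymin = *std::min_element(py.begin(), py.end());
  double ymax = *std::max_element(py.begin(), py.end());
  double xmin = *std::min_element(px.begin(), px.end());
  double xmax = *std::max_element(px.begin(), px.end());
  int r0 = std::max(0, (int)std::ceil(ymin - 1.0));
  int r1 = std::min(nrow - 1, (int)std::floor(ymax + 1.0));
  int c0 = std::max(0, (int)std::ceil(xmin - 1.0));
  int c1 = std::min(ncol - 1, (int)std::floor(xmax + 1.0));
  for (int r = r0; r <= r1; ++r) {
    double yc = (double)r;
    for (int c = c0; c <= c1; ++c) {
      double xc = (double)c;
      bool inside = false;
      for (int i = 0, j = n - 1; i < n; j = i++) {
        double yi = py[i], yj = py[j], xi = px[i], xj = px[j];
        if ((yi > yc) != (yj > yc)) {
          double xcross = xi + (yc - yi) / (yj - yi) * (xj - xi);
          if (xc < xcross) inside = !inside;
        }
      }
      if (inside) out(r, c) = true;
    }
  }
  // silence unused warnings for degenerate boxes
  (void)xmin; (void)xmax;
  return out;
}

// Bilinear resampling of a 2D image onto a 1 mm grid sharing the first pixel
// center with the input.  Output pixel (i, j) center sits at physical
// (i * 1 mm, j * 1 mm) from the first input pixel center; sampling clamps at
// the image border (constant extrapolation).
// [[Rcpp::export(name = ".cpp_resample_bilinear")]]
NumericMatrix cpp_resample_bilinear(NumericMatrix img,
                                    double row_sp, double col_sp,
                                    int out_rows, int out_cols) {
  int R = img.nrow(), C = img.ncol();
  NumericMatrix out(out_rows, out_cols);
  for (int j = 0; j < out_cols; ++j) {
    double ci = j / col_sp;
    if (ci < 0) ci = 0; if (ci > C - 1) ci = C - 1;
    int c0 = (int)std::floor(ci); int c1 = std::min(c0 + 1, C - 1);
    double wc = ci - c0;
    for (int i = 0; i < out_rows; ++i) {
      double ri = i / row_sp;
      if (ri < 0) ri = 0; if (ri > R - 1) ri = R - 1;
      int rr0 = (int)std::floor(ri); int rr1 = std::min(rr0 + 1, R - 1);
      double wr = ri - rr0;
      out(i, j) = (1 - wr) * (1 - wc) * img(rr0, c0) +
                  (1 - wr) * wc       * img(rr0, c1) +
                  wr       * (1 - wc) * img(rr1, c0) +
                  wr       * wc       * img(rr1, c1);
    }
  }
  return out;
}

// Nearest-neighbour variant for label images (stays binary).
// [[Rcpp::export(name = ".cpp_resample_nearest")]]
IntegerMatrix cpp_resample_nearest(IntegerMatrix img,
                                   double row_sp, double col_sp,
                                   int out_rows, int out_cols) {
  int R = img.nrow(), C = img.ncol();
  IntegerMatrix out(out_rows, out_cols);
  for (int j = 0; j < out_cols; ++j) {
    int c = (int)std::lround(j / col_sp);
    if (c < 0) c = 0; if (c > C - 1) c = C - 1;
    for (int i = 0; i < out_rows; ++i) {
      int r = (int)std::lround(i / row_sp);
      if (r < 0) r = 0; if (r > R - 1) r = R - 1;
      out(i, j) = img(r, c);
    }
  }
  return out;
}

// Sample img at arbitrary (row, col) fractional coordinates, bilinear with
// zero outside the image.  Used to map cropped probability maps back onto
// the native CT grid.
// [[Rcpp::export(name = ".cpp_sample_bilinear")]]
NumericMatrix cpp_sample_bilinear(NumericMatrix img,
                                  NumericVector row_coords,
                                  NumericVector col_coords) {
  int R = img.nrow(), C = img.ncol();
  int nr = row_coords.size(), nc = col_coords.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double ci = col_coords[j];
    if (ci < -0.5 || ci > C - 0.5) continue;
    for (int i = 0; i < nr; ++i) {
      double ri = row_coords[i];
      if (ri < -0.5 || ri > R - 0.5) continue;
      int r0 = (int)std::floor(ri), c0 = (int)std::floor(ci);
      double wr = ri - r0, wc = ci - c0;
      double v = 0.0;
      for (int dr = 0; dr <= 1; ++dr) {
        for (int dc = 0; dc <= 1; ++dc) {
          int rr = r0 + dr, cc = c0 + dc;
          if (rr < 0 || rr >= R || cc < 0 || cc >= C) continue;
          double w = (dr ? wr : 1 - wr) * (dc ? wc : 1 - wc);
          v += w * img(rr, cc);
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Affine warp of an image/label pair about the image center.  `A` is the
// 2x2 matrix and `t` the translation (in pixels) mapping OUTPUT pixel
// coordinates (relative to center) to INPUT coordinates.  Image sampled
// bilinearly (0 outside), label nearest-neighbour (0 outside).
// [[Rcpp::export(name = ".cpp_warp_pair")]]
List cpp_warp_pair(NumericMatrix img, IntegerMatrix lab,
                   NumericMatrix A, NumericVector t) {
  int R = img.nrow(), C = img.ncol();
  NumericMatrix oimg(R, C);
  IntegerMatrix olab(R, C);
  double cr = (R - 1) / 2.0, cc = (C - 1) / 2.0;
  for (int j = 0; j < C; ++j) {
    for (int i = 0; i < R; ++i) {
      double yr = i - cr, xc = j - cc;
      double ri = A(0, 0) * yr + A(0, 1) * xc + t[0] + cr;
      double ci = A(1, 0) * yr + A(1, 1) * xc + t[1] + cc;
      // bilinear image
      if (ri > -1 && ri < R && ci > -1 && ci < C) {
        int r0 = (int)std::floor(ri), c0 = (int)std::floor(ci);
        double wr = ri - r0, wc = ci - c0, v = 0.0;
        for (int dr = 0; dr <= 1; ++dr)
          for (int dc = 0; dc <= 1; ++dc) {
            int rr = r0 + dr, ccx = c0 + dc;
            if (rr < 0 || rr >= R || ccx < 0 || ccx >= C) continue;
            v += (dr ? wr : 1 - wr) * (dc ? wc : 1 - wc) * img(rr, ccx);
          }
        oimg(i, j) = v;
      }
      // nearest label
      int rn = (int)std::lround(ri), cn = (int)std::lround(ci);
      if (rn >= 0 && rn < R && cn >= 0 && cn < C) olab(i, j) = lab(rn, cn);
    }
  }
  return List::create(_["image"] = oimg, _["label"] = olab);
}
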