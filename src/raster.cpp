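#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Scanline even-odd polygon fill at pixel centers.
// Coordinates: x = column, y = row, 0-based; pixel (r, c) has center
// (c + 0.5, r + 0.5). A pixel is inside iff the number of polygon-edge
// crossings of the horizontal line y = r + 0.5 strictly to the left of
// the center is odd (half-open [x1, x2) fill between sorted crossings).
// [[Rcpp::export]]
LogicalMatrix polygon_fill(NumericVector xs, NumericVector ys,
                           int height, int width) {
  const int n = xs.size();
  LogicalMatrix out(height, width);
  if (n < 3) stop("polygon needs at least 3 vertices");
  std::vector<double> cross;
  cross.reserve(8);
  for (int r = 0; r < height; ++r) {
    const double y = r + 0.5;
    cross.clear();
    for (int i = 0; i < n; ++i) {
      const int j = (i + 1) % n;
      const double y1 = ys[i], y2 = ys[j];
      // half-open rule in y avoids double-counting vertices on the scanline
      if ((y1 <= y) != (y2 <= y)) {
        const double x1 = xs[i], x2 = xs[j];
        cross.push_back(x1 + (y - y1) * (x2 - x1) / (y2 - y1));
      }
    }
    if (cross.empty()) continue;
    std::sort(cross.begin(), cross.end());
    for (size_t k = 0; k + 1 < cross.size(); k += 2) {
      // centers c + 0.5 in [cross[k], cross[k+1])
      int c0 = (int)std::ceil(cross[k] - 0.5);
      int c1 = (int)std::ceil(cross[k + 1] - 0.5) - 1;
      if (c0 < 0) c0 = 0;
      if (c1 >= width) c1 = width - 1;
      for (int c = c0; c <= c1; ++c) out(r, c) = true;
    }
  }
  return out;
}

static inline double cross2(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

static bool segments_intersect(double p1x, double p1y, double p2x, double p2y,
                               double q1x, double q1y, double q2x, double q2y) {
  const double d1 = cross2(q1x, q1y, q2x, q2y, p1x, p1y);
  const double d2 = cross2(q1x, q1y, q2x, q2y, p2x, p2y);
  const double d3 = cross2(p1x, p1y, p2x, p2y, q1x, q1y);
  const double d4 = cross2(p1x, p1y, p2x, p2y, q2x, q2y);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
    return true;
  return false;
}

// TRUE if the closed polygon has no proper self-intersection between
// non-adjacent edges (shared endpoints of adjacent edges are allowed).
// [[Rcpp::export]]
bool polygon_is_simple(NumericVector xs, NumericVector ys) {
  const int n = xs.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      const int j2 = (j + 1) % n;
      if (i == j || i2 == j || i == j2) continue;  // adjacent edges
      if (segments_intersect(xs[i], ys[i], xs[i2], ys[i2],
                             xs[j], ys[j], xs[j2], ys[j2]))
        return false;
    }
  }
  return true;
}
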