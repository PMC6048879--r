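#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Uniform grid-bucket index over scattered points. Buckets are keyed by
// (ix, iy) packed into a 64-bit integer; bucket side is chosen by the
// caller (the search radius for fixed-radius queries, a density heuristic
// for nearest-neighbour queries). Exact results in both cases.

namespace {

inline long long packKey(long long ix, long long iy) {
  // offset to keep indices non-negative before packing
  return (ix + 2000000LL) * 4000003LL + (iy + 2000000LL);
}

struct GridIndex {
  double x0, y0, cell;
  std::unordered_map<long long, std::vector<int> > buckets;

  GridIndex(const NumericVector& x, const NumericVector& y, double cellSize) {
    cell = cellSize;
    x0 = R_PosInf; y0 = R_PosInf;
    const int n = x.size();
    for (int i = 0; i < n; ++i) {
      if (x[i] < x0) x0 = x[i];
      if (y[i] < y0) y0 = y[i];
    }
    buckets.reserve(n * 2 + 16);
    for (int i = 0; i < n; ++i) {
      long long ix = (long long)std::floor((x[i] - x0) / cell);
      long long iy = (long long)std::floor((y[i] - y0) / cell);
      buckets[packKey(ix, iy)].push_back(i);
    }
  }

  long long cellOf(double v, double origin) const {
    return (long long)std::floor((v - origin) / cell);
  }
};

} // namespace

// Radius-limited inverse distance weighting at query points.
// Returns NA where no site lies within `radius`. Sites within
// `eps` of the query are averaged arithmetically (coincidence rule).
// [[Rcpp::export]]
NumericVector cpp_idw(NumericVector sx, NumericVector sy, NumericVector sz,
                      NumericVector qx, NumericVector qy,
                      double radius, double power, double eps) {
  const int nq = qx.size();
  NumericVector out(nq, NA_REAL);
  if (sx.size() == 0) return out;

  GridIndex idx(sx, sy, radius);
  const double r2 = radius * radius;
  const double e2 = eps * eps;

  for (int q = 0; q < nq; ++q) {
    long long cx = idx.cellOf(qx[q], idx.x0);
    long long cy = idx.cellOf(qy[q], idx.y0);
    double wsum = 0.0, wzsum = 0.0;
    double coincSum = 0.0;
    int coincN = 0;
    bool any = false;
    for (long long ix = cx - 1; ix <= cx + 1; ++ix) {
      for (long long iy = cy - 1; iy <= cy + 1; ++iy) {
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
          idx.buckets.find(packKey(ix, iy));
        if (it == idx.buckets.end()) continue;
        const std::vector<int>& pts = it->second;
        for (size_t k = 0; k < pts.size(); ++k) {
          const int i = pts[k];
          const double dx = sx[i] - qx[q];
          const double dy = sy[i] - qy[q];
          const double d2 = dx * dx + dy * dy;
          if (d2 > r2) continue;
          any = true;
          if (d2 <= e2) {
            coincSum += sz[i];
            coincN += 1;
          } else {
            const double w = std::pow(std::sqrt(d2), -power);
            wsum += w;
            wzsum += w * sz[i];
          }
        }
      }
    }
    if (coincN > 0) {
      out[q] = coincSum / coincN;
    } else if (any) {
      out[q] = wzsum / wsum;
    }
  }
  return out;
}

// Exact Euclidean nearest-neighbour distance from each query to the site
// set, via expanding-ring search over the bucket grid.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector qx, NumericVector qy,
                          NumericVector sx, NumericVector sy) {
  const int nq = qx.size();
  const int ns = sx.size();
  NumericVector out(nq, NA_REAL);
  if (ns == 0) return out;

  // bucket side targeting O(1) sites per bucket
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < ns; ++i) {
    if (sx[i] < xmin) xmin = sx[i];
    if (sx[i] > xmax) xmax = sx[i];
    if (sy[i] < ymin) ymin = sy[i];
    if (sy[i] > ymax) ymax = sy[i];
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  double cell = span / std::max(1.0, std::sqrt((double)ns));
  if (!(cell > 0)) cell = 1.0;

  GridIndex idx(sx, sy, cell);
  long long icMax = (long long)std::floor((xmax - xmin) / cell);
  long long jcMax = (long long)std::floor((ymax - ymin) / cell);

  for (int q = 0; q < nq; ++q) {
    // start from the site-grid cell nearest the query; the query itself
    // may lie outside the site bounding box
    long long cx = idx.cellOf(qx[q], idx.x0);
    long long cy = idx.cellOf(qy[q], idx.y0);
    if (cx < 0) cx = 0; if (cx > icMax) cx = icMax;
    if (cy < 0) cy = 0; if (cy > jcMax) cy = jcMax;
    long long maxRing = std::max(std::max(cx, icMax - cx),
                                 std::max(cy, jcMax - cy));
    double best2 = std::numeric_limits<double>::infinity();
    for (long long ring = 0; ring <= maxRing + 1; ++ring) {
      // stop once every unscanned cell is provably farther than the best
      if (best2 < std::numeric_limits<double>::infinity()) {
        long long k = ring - 1;
        double bound = std::min(
          std::min(qx[q] - (idx.x0 + (double)(cx - k) * cell),
                   (idx.x0 + (double)(cx + k + 1) * cell) - qx[q]),
          std::min(qy[q] - (idx.y0 + (double)(cy - k) * cell),
                   (idx.y0 + (double)(cy + k + 1) * cell) - qy[q]));
        if (bound > 0 && best2 <= bound * bound) break;
      }
      for (long long ix = cx - ring; ix <= cx + ring; ++ix) {
        for (long long iy = cy - ring; iy <= cy + ring; ++iy) {
          if (std::max(std::llabs(ix - cx), std::llabs(iy - cy)) != ring)
            continue; // perimeter of the ring only
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            idx.buckets.find(packKey(ix, iy));
          if (it == idx.buckets.end()) continue;
          const std::vector<int>& pts = it->second;
          for (size_t k = 0; k < pts.size(); ++k) {
            const int i = pts[k];
            const double dx = sx[i] - qx[q];
            const double dy = sy[i] - qy[q];
            const double d2 = dx * dx + dy * dy;
            if (d2 < best2) best2 = d2;
          }
        }
      }
    }
    out[q] = std::sqrt(best2);
  }
  return out;
}
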