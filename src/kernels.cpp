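#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Inverse-distance-weighted resampling of a scattered height field onto a
// regular grid. Points are bucketed on a coarse grid; neighbours are gathered
// ring by ring outward from each cell so the k-nearest search stops as soon as
// no closer point can exist. Cells with no point within `radius` are invalid.
//
// Grid cell (i, j) (1-based in R, row i = y index, column j = x index) has its
// centre at (x0 + (j - 0.5) * dx, y0 + (i - 0.5) * dy).
// [[Rcpp::export(name = ".idwResampleCpp")]]
List idwResampleCpp(NumericVector px, NumericVector py, NumericVector pz,
                    double x0, double dx, int nx,
                    double y0, double dy, int ny,
                    int k, double radius) {
  const int n = px.size();
  NumericMatrix values(ny, nx);
  LogicalMatrix valid(ny, nx);
  if (k < 1) stop("k must be >= 1");
  if (radius <= 0) stop("radius must be > 0");

  // bucket grid over the point bounding box
  const double bs = radius / 3.0;
  double bx0 = R_PosInf, by0 = R_PosInf, bx1 = R_NegInf, by1 = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (px[i] < bx0) bx0 = px[i];
    if (px[i] > bx1) bx1 = px[i];
    if (py[i] < by0) by0 = py[i];
    if (py[i] > by1) by1 = py[i];
  }
  if (n == 0) { return List::create(_["values"] = values, _["valid"] = valid); }
  int nbx = (int)std::floor((bx1 - bx0) / bs) + 1;
  int nby = (int)std::floor((by1 - by0) / bs) + 1;
  std::vector< std::vector<int> > buckets((size_t)nbx * nby);
  for (int i = 0; i < n; ++i) {
    int bx = (int)std::floor((px[i] - bx0) / bs);
    int by = (int)std::floor((py[i] - by0) / bs);
    if (bx >= nbx) bx = nbx - 1;
    if (by >= nby) by = nby - 1;
    buckets[(size_t)by * nbx + bx].push_back(i);
  }

  const int maxRing = (int)std::ceil(radius / bs) + 1;
  const double r2 = radius * radius;
  std::vector<double> bd2(k);
  std::vector<int> bid(k);

  for (int gi = 0; gi < ny; ++gi) {
    for (int gj = 0; gj < nx; ++gj) {
      const double cx = x0 + (gj + 0.5) * dx;
      const double cy = y0 + (gi + 0.5) * dy;
      int found = 0;
      double worst = R_PosInf;
      const int cbx = (int)std::floor((cx - bx0) / bs);
      const int cby = (int)std::floor((cy - by0) / bs);
      for (int ring = 0; ring <= maxRing; ++ring) {
        // closest possible squared distance from centre to a point in this ring
        if (ring > 0) {
          double dmin = (ring - 1) * bs;
          if (found == k && dmin * dmin > worst) break;
          if (dmin * dmin > r2) break;
        }
        for (int byi = cby - ring; byi <= cby + ring; ++byi) {
          if (byi < 0 || byi >= nby) continue;
          for (int bxi = cbx - ring; bxi <= cbx + ring; ++bxi) {
            if (bxi < 0 || bxi >= nbx) continue;
            // only the ring boundary (interior was scanned in earlier rings)
            if (ring > 0 && std::abs(byi - cby) != ring && std::abs(bxi - cbx) != ring)
              continue;
            const std::vector<int>& b = buckets[(size_t)byi * nbx + bxi];
            for (size_t t = 0; t < b.size(); ++t) {
              const int p = b[t];
              const double ddx = px[p] - cx, ddy = py[p] - cy;
              const double d2 = ddx * ddx + ddy * ddy;
              if (d2 > r2) continue;
              if (found < k) {
                bd2[found] = d2; bid[found] = p; ++found;
                if (found == k) {
                  worst = 0.0;
                  for (int q = 0; q < k; ++q) if (bd2[q] > worst) worst = bd2[q];
                }
              } else if (d2 < worst) {
                int wq = 0; double wv = -1.0;
                for (int q = 0; q < k; ++q) if (bd2[q] > wv) { wv = bd2[q]; wq = q; }
                bd2[wq] = d2; bid[wq] = p;
                worst = 0.0;
                for (int q = 0; q < k; ++q) if (bd2[q] > worst) worst = bd2[q];
              }
            }
          }
        }
      }
      if (found == 0) { valid(gi, gj) = false; values(gi, gj) = NA_REAL; continue; }
      double wsum = 0.0, zsum = 0.0;
      bool exact = false;
      for (int q = 0; q < found; ++q) {
        if (bd2[q] < 1e-18) { values(gi, gj) = pz[bid[q]]; exact = true; break; }
        const double w = 1.0 / bd2[q];  // inverse squared distance
        wsum += w; zsum += w * pz[bid[q]];
      }
      if (!exact) values(gi, gj) = zsum / wsum;
      valid(gi, gj) = true;
    }
  }
  return List::create(_["values"] = values, _["valid"] = valid);
}

// CRC-32 (IEEE 802.3, as used by PNG chunks), table driven.
// [[Rcpp::export(name = ".crc32Cpp")]]
double crc32Cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int j = 0; j < 8; ++j)
        c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
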