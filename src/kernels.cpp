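#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Paint a polyline ribbon: mark every pixel whose center lies within
// half_width of any segment of the polyline. Coordinates are in pixel
// units; pixel (r, c) (1-based) has center (r - 0.5, c - 0.5).
// Returns the number of pixels newly set by this ribbon.
// [[Rcpp::export]]
int cpp_paint_ribbon(IntegerMatrix img, NumericVector rr, NumericVector cc,
                     double half_width, int value) {
  const int nr = img.nrow(), nc = img.ncol();
  const int nseg = rr.size() - 1;
  const double hw2 = half_width * half_width;
  int painted = 0;
  for (int s = 0; s < nseg; ++s) {
    double r0 = rr[s], c0 = cc[s], r1 = rr[s + 1], c1 = cc[s + 1];
    double dr = r1 - r0, dc = c1 - c0;
    double len2 = dr * dr + dc * dc;
    int rmin = std::max(0, (int)std::floor(std::min(r0, r1) - half_width - 1.0));
    int rmax = std::min(nr - 1, (int)std::ceil(std::max(r0, r1) + half_width + 1.0));
    int cmin = std::max(0, (int)std::floor(std::min(c0, c1) - half_width - 1.0));
    int cmax = std::min(nc - 1, (int)std::ceil(std::max(c0, c1) + half_width + 1.0));
    for (int c = cmin; c <= cmax; ++c) {
      double pc = c + 0.5;
      for (int r = rmin; r <= rmax; ++r) {
        double pr = r + 0.5;
        double t = 0.0;
        if (len2 > 0.0) {
          t = ((pr - r0) * dr + (pc - c0) * dc) / len2;
          t = std::min(1.0, std::max(0.0, t));
        }
        double qr = r0 + t * dr - pr, qc = c0 + t * dc - pc;
        if (qr * qr + qc * qc <= hw2 && img(r, c) != value) {
          img(r, c) = value;
          ++painted;
        }
      }
    }
  }
  return painted;
}

static inline int nb(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0;
}

// Zhang-Suen thinning: iteratively peel boundary pixels while preserving
// topology, yielding an (approximately) one-pixel-wide 8-connected skeleton
// that is a subset of the input mask.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  const int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          // neighbors clockwise from north: p2..p9
          int p2 = nb(m, r - 1, c),     p3 = nb(m, r - 1, c + 1);
          int p4 = nb(m, r, c + 1),     p5 = nb(m, r + 1, c + 1);
          int p6 = nb(m, r + 1, c),     p7 = nb(m, r + 1, c - 1);
          int p8 = nb(m, r, c - 1),     p9 = nb(m, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) m(kill[k].first, kill[k].second) = 0;
    }
  }
  return m;
}

// Reduced 8-adjacency degree: orthogonal links always count; a diagonal
// link is redundant (not counted) when either of the two orthogonal
// pixels it cuts across is itself set, since the connection then runs
// through that pixel. This removes the spurious junctions that staircase
// patterns of thinned skeletons otherwise produce.
// [[Rcpp::export]]
IntegerMatrix cpp_reduced_degree(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) { out(r, c) = 0; continue; }
      int s = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (dr == 0 && dc == 0) continue;
          if (!nb(mask, r + dr, c + dc)) continue;
          if (dr != 0 && dc != 0 &&
              (nb(mask, r + dr, c) || nb(mask, r, c + dc))) continue;
          ++s;
        }
      out(r, c) = s;
    }
  return out;
}
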