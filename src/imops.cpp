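#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pixel-level primitives for the segmentation pipeline. All masks are
// logical matrices; coordinates are 1-based on the R side.

static inline bool inb(int r, int c, int nr, int nc) {
  return r >= 0 && r < nr && c >= 0 && c < nc;
}

// Connected-component labeling by flood fill. connectivity is 4 or 8.
// Returns an integer matrix, 0 = background, components numbered from 1 in
// raster-scan order of their first pixel (deterministic).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 8 ? dr8 : dr4;
  const int *dc = connectivity == 8 ? dc8 : dc4;
  const int nn = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (inb(r2, c2, nr, nc) && mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Neighbourhood in Zhang-Suen order p2..p9 (N, NE, E, SE, S, SW, W, NW),
// using matrix convention row = y (downwards), col = x.
static inline void nbrs(const LogicalMatrix& m, int r, int c, int out[8]) {
  const int nr = m.nrow(), nc = m.ncol();
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int k = 0; k < 8; ++k) {
    int r2 = r + dr[k], c2 = c + dc[k];
    out[k] = (inb(r2, c2, nr, nc) && m(r2, c2)) ? 1 : 0;
  }
}

static inline int countB(const int p[8]) {
  int b = 0;
  for (int k = 0; k < 8; ++k) b += p[k];
  return b;
}

// number of 0->1 transitions around the cycle p2..p9,p2
static inline int countA(const int p[8]) {
  int a = 0;
  for (int k = 0; k < 8; ++k)
    if (p[k] == 0 && p[(k + 1) % 8] == 1) ++a;
  return a;
}

// Topology-preserving thinning (Zhang-Suen) followed by a sequential
// redundant-pixel cleanup so the result is strictly one pixel wide in the
// sense that every remaining pixel in a 2x2 foreground block is needed for
// connectivity.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  int p[8];
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!m(r, c)) continue;
          nbrs(m, r, c, p);
          int B = countB(p);
          if (B < 2 || B > 6) continue;
          if (countA(p) != 1) continue;
          // p2=p[0] N, p4=p[2] E, p6=p[4] S, p8=p[6] W
          if (step == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(r + c * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        m(kill[i] % nr, kill[i] / nr) = false;
    }
  }
  // sequential cleanup: a pixel whose foreground neighbours form a single
  // 8-connected component among themselves is redundant (its removal keeps
  // them mutually connected); endpoints (B < 2) are protected. Iterated in
  // deterministic raster order until stable, this collapses the staircase
  // and corner clusters thinning leaves behind into minimal chains.
  bool again = true;
  while (again) {
    again = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!m(r, c)) continue;
        nbrs(m, r, c, p);
        int B = countB(p);
        if (B < 2) continue;
        // removing a pixel with no 4-adjacent background would open a hole
        if (p[0] && p[2] && p[4] && p[6]) continue;
        // coordinates of foreground neighbours (Zhang-Suen order)
        const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
        const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
        int comp[8], fr[8], fc[8], nf = 0;
        for (int k = 0; k < 8; ++k) {
          if (!p[k]) continue;
          fr[nf] = dr[k]; fc[nf] = dc[k]; comp[nf] = nf; ++nf;
        }
        for (int a = 0; a < nf; ++a) {
          for (int b = a + 1; b < nf; ++b) {
            if (std::abs(fr[a] - fr[b]) <= 1 && std::abs(fc[a] - fc[b]) <= 1) {
              int ca = comp[a], cb = comp[b];
              if (ca != cb)
                for (int t = 0; t < nf; ++t)
                  if (comp[t] == cb) comp[t] = ca;
            }
          }
        }
        int ncomp = 0;
        for (int t = 0; t < nf; ++t) if (comp[t] == t) ++ncomp;
        if (ncomp == 1) {
          m(r, c) = false;
          again = true;
        }
      }
    }
  }
  return m;
}

// Grayscale min/max filter with a disk structuring element of the given
// integer radius (offsets with dr^2 + dc^2 <= radius^2). Border handled by
// ignoring out-of-image offsets.
// [[Rcpp::export]]
NumericMatrix cpp_disk_filter(const NumericMatrix& img, int radius, bool maximum) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> odr, odc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { odr.push_back(a); odc.push_back(b); }
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = img(r, c);
      for (size_t k = 0; k < odr.size(); ++k) {
        int r2 = r + odr[k], c2 = c + odc[k];
        if (!inb(r2, c2, nr, nc)) continue;
        double w = img(r2, c2);
        if (maximum ? (w > v) : (w < v)) v = w;
      }
      out(r, c) = v;
    }
  }
  return out;
}

// Binary disk dilation (radius in pixels).
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_mask(const LogicalMatrix& mask, int radius) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> odr, odc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { odr.push_back(a); odc.push_back(b); }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      for (size_t k = 0; k < odr.size(); ++k) {
        int r2 = r + odr[k], c2 = c + odc[k];
        if (inb(r2, c2, nr, nc)) out(r2, c2) = true;
      }
    }
  }
  return out;
}

// For each query point (row, col; possibly sub-pixel), the nearest wall
// pixel over all walls: returns the wall id and the distance in pixels.
// Strictly smaller distance wins; exact ties go to the smaller wall id.
// [[Rcpp::export]]
List cpp_nearest_wallpix(const NumericMatrix& pts, const NumericMatrix& wallpix,
                         const IntegerVector& wallid) {
  const int n = pts.nrow(), m = wallpix.nrow();
  IntegerVector best(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double bd = R_PosInf;
    int bid = NA_INTEGER;
    for (int j = 0; j < m; ++j) {
      double dr = pts(i, 0) - wallpix(j, 0);
      double dc = pts(i, 1) - wallpix(j, 1);
      double d2 = dr * dr + dc * dc;
      if (d2 < bd - 1e-12 || (std::abs(d2 - bd) <= 1e-12 && wallid[j] < bid)) {
        bd = d2;
        bid = wallid[j];
      }
    }
    best[i] = bid;
    dist[i] = m > 0 ? std::sqrt(bd) : NA_REAL;
  }
  return List::create(_["wall_id"] = best, _["dist_px"] = dist);
}
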