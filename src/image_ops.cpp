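// Low-level raster primitives for the segmentation / lineage pipeline.
// All functions use (row, col) 0-based indexing internally and 4-connectivity
// unless stated otherwise; every scan order is fixed so results are
// bit-reproducible.
#include <Rcpp.h>
#include <queue>
#include <map>
#include <cmath>
using namespace Rcpp;

static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

// Even-odd rule point-in-polygon rasterization. Polygons are rasterized in
// list order; later polygons never overwrite pixels already claimed (cells
// tile the plane, so contention only happens on shared-edge pixels and the
// smaller id wins because polys are passed sorted by id).
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_polygons(List polys, IntegerVector ids, int nrow,
                                     int ncol, double px, double ox,
                                     double oy) {
  IntegerMatrix lab(nrow, ncol);
  for (int k = 0; k < polys.size(); ++k) {
    NumericMatrix P = polys[k];
    int id = ids[k];
    int n = P.nrow();
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      xmin = std::min(xmin, P(i, 0));
      xmax = std::max(xmax, P(i, 0));
      ymin = std::min(ymin, P(i, 1));
      ymax = std::max(ymax, P(i, 1));
    }
    int c0 = std::max(0, (int)std::floor((xmin - ox) / px - 1));
    int c1 = std::min(ncol - 1, (int)std::ceil((xmax - ox) / px + 1));
    int r0 = std::max(0, (int)std::floor((ymin - oy) / px - 1));
    int r1 = std::min(nrow - 1, (int)std::ceil((ymax - oy) / px + 1));
    for (int r = r0; r <= r1; ++r) {
      double y = oy + (r + 0.5) * px;
      for (int c = c0; c <= c1; ++c) {
        if (lab(r, c) != 0) continue;
        double x = ox + (c + 0.5) * px;
        bool inside = false;
        for (int i = 0, j = n - 1; i < n; j = i++) {
          double xi = P(i, 0), yi = P(i, 1), xj = P(j, 0), yj = P(j, 1);
          if (((yi > y) != (yj > y)) &&
              (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
            inside = !inside;
        }
        if (inside) lab(r, c) = id;
      }
    }
  }
  return lab;
}

// Separable convolution with edge replication (used for Gaussian smoothing).
// [[Rcpp::export]]
NumericMatrix cpp_convolve_sep(NumericMatrix img, NumericVector kernel) {
  int nr = img.nrow(), nc = img.ncol(), m = kernel.size(), h = m / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double s = 0;
      for (int k = 0; k < m; ++k) {
        int cc = c + k - h;
        cc = std::max(0, std::min(nc - 1, cc));
        s += img(r, cc) * kernel[k];
      }
      tmp(r, c) = s;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int k = 0; k < m; ++k) {
        int rr = r + k - h;
        rr = std::max(0, std::min(nr - 1, rr));
        s += tmp(rr, c) * kernel[k];
      }
      out(r, c) = s;
    }
  return out;
}

// Morphological reconstruction by dilation (hybrid raster/FIFO algorithm).
// marker <= mask pointwise is assumed.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilate(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J = clone(marker);
  // raster scan (neighbours already visited: up, left)
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double v = J(r, c);
      if (r > 0) v = std::max(v, J(r - 1, c));
      if (c > 0) v = std::max(v, J(r, c - 1));
      J(r, c) = std::min(v, mask(r, c));
    }
  std::queue<std::pair<int, int> > fifo;
  // anti-raster scan (neighbours: down, right)
  for (int r = nr - 1; r >= 0; --r)
    for (int c = nc - 1; c >= 0; --c) {
      double v = J(r, c);
      if (r < nr - 1) v = std::max(v, J(r + 1, c));
      if (c < nc - 1) v = std::max(v, J(r, c + 1));
      J(r, c) = std::min(v, mask(r, c));
      bool push = false;
      if (r < nr - 1 && J(r + 1, c) < J(r, c) && J(r + 1, c) < mask(r + 1, c))
        push = true;
      if (c < nc - 1 && J(r, c + 1) < J(r, c) && J(r, c + 1) < mask(r, c + 1))
        push = true;
      if (push) fifo.push(std::make_pair(r, c));
    }
  while (!fifo.empty()) {
    int r = fifo.front().first, c = fifo.front().second;
    fifo.pop();
    for (int k = 0; k < 4; ++k) {
      int rr = r + DR4[k], cc = c + DC4[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        J(rr, cc) = std::min(J(r, c), mask(rr, cc));
        fifo.push(std::make_pair(rr, cc));
      }
    }
  }
  return J;
}

// Regional minima of f restricted to a mask, labelled 1..K in raster order of
// each minimum's first pixel. A regional minimum is a 4-connected flat zone
// with no lower neighbour inside the mask.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(NumericMatrix f, LogicalMatrix mask) {
  int nr = f.nrow(), nc = f.ncol();
  IntegerMatrix lab(nr, nc); // 0 = unvisited/background, -1 = not minimum
  int next = 0;
  std::vector<std::pair<int, int> > zone;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      // BFS over the flat zone of value v
      double v = f(r, c);
      bool is_min = true;
      zone.clear();
      std::queue<std::pair<int, int> > q;
      q.push(std::make_pair(r, c));
      lab(r, c) = -2; // in-progress
      while (!q.empty()) {
        int rr = q.front().first, cc = q.front().second;
        q.pop();
        zone.push_back(std::make_pair(rr, cc));
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + DR4[k], c2 = cc + DC4[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!mask(r2, c2)) continue;
          if (f(r2, c2) < v) is_min = false;
          if (f(r2, c2) == v && lab(r2, c2) == 0) {
            lab(r2, c2) = -2;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
      int assign = is_min ? ++next : -1;
      for (size_t i = 0; i < zone.size(); ++i)
        lab(zone[i].first, zone[i].second) = assign;
    }
  for (int i = 0; i < nr * nc; ++i)
    if (lab[i] < 0) lab[i] = 0;
  return lab;
}

struct PQItem {
  double v;
  long long t;
  int r, c, lab;
};
struct PQCmp {
  bool operator()(const PQItem& a, const PQItem& b) const {
    if (a.v != b.v) return a.v > b.v; // lowest value first
    return a.t > b.t;                 // FIFO tie-break
  }
};

// Meyer's marker-controlled watershed without watershed lines: every masked
// pixel ends up in exactly one basin.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix f, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = f.nrow(), nc = f.ncol();
  IntegerMatrix lab = clone(markers);
  std::priority_queue<PQItem, std::vector<PQItem>, PQCmp> pq;
  long long tick = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (lab(r, c) <= 0) continue;
      for (int k = 0; k < 4; ++k) {
        int rr = r + DR4[k], cc = c + DC4[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (mask(rr, cc) && lab(rr, cc) == 0) {
          PQItem it = {f(rr, cc), tick++, rr, cc, lab(r, c)};
          pq.push(it);
        }
      }
    }
  while (!pq.empty()) {
    PQItem it = pq.top();
    pq.pop();
    if (lab(it.r, it.c) != 0) continue;
    lab(it.r, it.c) = it.lab;
    for (int k = 0; k < 4; ++k) {
      int rr = it.r + DR4[k], cc = it.c + DC4[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) && lab(rr, cc) == 0) {
        PQItem nx = {f(rr, cc), tick++, rr, cc, it.lab};
        pq.push(nx);
      }
    }
  }
  return lab;
}

// 4-connected components of a logical mask, labelled 1..K in raster order.
// [[Rcpp::export]]
IntegerMatrix cpp_conncomp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      std::queue<std::pair<int, int> > q;
      q.push(std::make_pair(r, c));
      lab(r, c) = next;
      while (!q.empty()) {
        int rr = q.front().first, cc = q.front().second;
        q.pop();
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + DR4[k], c2 = cc + DC4[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
    }
  return lab;
}

// Fill holes: background components not connected to the image border become
// foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out = clone(mask);
  std::vector<bool> reach((size_t)nr * nc, false);
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if ((r == 0 || r == nr - 1 || c == 0 || c == nc - 1) && !mask(r, c) &&
          !reach[(size_t)c * nr + r]) {
        reach[(size_t)c * nr + r] = true;
        q.push(std::make_pair(r, c));
        while (!q.empty()) {
          int rr = q.front().first, cc = q.front().second;
          q.pop();
          for (int k = 0; k < 4; ++k) {
            int r2 = rr + DR4[k], c2 = cc + DC4[k];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (!mask(r2, c2) && !reach[(size_t)c2 * nr + r2]) {
              reach[(size_t)c2 * nr + r2] = true;
              q.push(std::make_pair(r2, c2));
            }
          }
        }
      }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (!mask(r, c) && !reach[(size_t)c * nr + r]) out(r, c) = true;
  return out;
}

// Pixels of a label map lying on a boundary (4-neighbour with a different
// value, or the image edge).
// [[Rcpp::export]]
LogicalMatrix cpp_boundary_mask(IntegerMatrix lab) {
  int nr = lab.nrow(), nc = lab.ncol();
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (lab(r, c) == 0) continue;
      bool b = false;
      for (int k = 0; k < 4 && !b; ++k) {
        int rr = r + DR4[k], cc = c + DC4[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc)
          b = true;
        else if (lab(rr, cc) != lab(r, c))
          b = true;
      }
      out(r, c) = b;
    }
  return out;
}

// Co-occurrence table of two equally-shaped label maps (0 entries included).
// [[Rcpp::export]]
DataFrame cpp_overlap_table(IntegerMatrix a, IntegerMatrix b) {
  std::map<std::pair<int, int>, int> tab;
  int n = a.size();
  for (int i = 0; i < n; ++i) tab[std::make_pair(a[i], b[i])]++;
  int m = tab.size();
  IntegerVector ai(m), bi(m), cnt(m);
  int j = 0;
  for (std::map<std::pair<int, int>, int>::iterator it = tab.begin();
       it != tab.end(); ++it, ++j) {
    ai[j] = it->first.first;
    bi[j] = it->first.second;
    cnt[j] = it->second;
  }
  return DataFrame::create(_["a"] = ai, _["b"] = bi, _["n"] = cnt);
}

// Counts of adjacent (4-conn) pixel pairs with different labels; used for the
// longest-shared-boundary merge rule and for cell adjacency.
// [[Rcpp::export]]
DataFrame cpp_adjacency_counts(IntegerMatrix lab) {
  std::map<std::pair<int, int>, int> tab;
  int nr = lab.nrow(), nc = lab.ncol();
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int v = lab(r, c);
      if (r + 1 < nr && lab(r + 1, c) != v)
        tab[std::make_pair(std::min(v, lab(r + 1, c)),
                           std::max(v, lab(r + 1, c)))]++;
      if (c + 1 < nc && lab(r, c + 1) != v)
        tab[std::make_pair(std::min(v, lab(r, c + 1)),
                           std::max(v, lab(r, c + 1)))]++;
    }
  int m = tab.size();
  IntegerVector ai(m), bi(m), cnt(m);
  int j = 0;
  for (std::map<std::pair<int, int>, int>::iterator it = tab.begin();
       it != tab.end(); ++it, ++j) {
    ai[j] = it->first.first;
    bi[j] = it->first.second;
    cnt[j] = it->second;
  }
  return DataFrame::create(_["a"] = ai, _["b"] = bi, _["n"] = cnt);
}

// Similarity transform of a label map by nearest-neighbour inverse mapping.
// Forward model (pixel units): p1 = s * R(p0 - ctr) + ctr + t.
// [[Rcpp::export]]
IntegerMatrix cpp_transform_labels(IntegerMatrix lm, double rot_deg,
                                   double scale, double dr, double dc,
                                   double ctr_r, double ctr_c, int out_nr,
                                   int out_nc) {
  double th = rot_deg * M_PI / 180.0, ct = std::cos(th), st = std::sin(th);
  int nr = lm.nrow(), nc = lm.ncol();
  IntegerMatrix out(out_nr, out_nc);
  for (int r = 0; r < out_nr; ++r)
    for (int c = 0; c < out_nc; ++c) {
      // invert: p0 = R^T (p1 - ctr - t) / s + ctr
      double yr = (r - ctr_r - dr) / scale, xc = (c - ctr_c - dc) / scale;
      double r0 = ct * yr + st * xc + ctr_r;
      double c0 = -st * yr + ct * xc + ctr_c;
      int ri = (int)std::lround(r0), ci = (int)std::lround(c0);
      if (ri >= 0 && ri < nr && ci >= 0 && ci < nc) out(r, c) = lm(ri, ci);
    }
  return out;
}

// Moore-neighbour (8-conn) outer boundary trace of the largest 4-connected
// region of a mask; returns 0-based (row, col) pixel coordinates in order.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  // start: first foreground pixel in raster order
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c)) {
        sr = r;
        sc = c;
        break;
      }
  if (sr < 0) return IntegerMatrix(0, 2);
  // Moore neighbourhood in clockwise order starting from W
  static const int MR[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int MC[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> rows, cols;
  int r = sr, c = sc, backtrack = 0; // entered from W
  rows.push_back(r);
  cols.push_back(c);
  int r_prev = sr, c_prev = sc;
  bool first = true;
  int guard = 8 * nr * nc;
  while (guard-- > 0) {
    bool found = false;
    int start = backtrack;
    for (int k = 0; k < 8; ++k) {
      int idx = (start + k) % 8;
      int rr = r + MR[idx], cc = c + MC[idx];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !mask(rr, cc)) continue;
      // Jacob's stopping: back at start entering the same way
      if (!first && rr == sr && cc == sc && r == r_prev && c == c_prev) {
      }
      // backtrack: neighbour index of the previous (background) position
      int bidx = (idx + 6) % 8; // two steps counter-clockwise
      r_prev = r;
      c_prev = c;
      r = rr;
      c = cc;
      backtrack = bidx;
      found = true;
      break;
    }
    if (!found) break; // isolated pixel
    if (r == sr && c == sc && rows.size() > 1) break;
    rows.push_back(r);
    cols.push_back(c);
    first = false;
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}
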