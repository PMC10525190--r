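#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Minimum-cost 8-connected path between two pixels on a per-pixel cost grid.
//
// Path cost = sum of cost(pixel) over every pixel entered (the start pixel is
// common to all paths and excluded) plus diag_penalty per diagonal step.
// All minimal 8-connected paths between two pixels share the same diagonal
// count, so the penalty never changes which straight path wins; it stops
// sub-penalty intensity fluctuations (noise) from pulling the path into
// zigzag detours. Ties are resolved lexicographically:
//   1. accumulated cost (tolerance tol_cost),
//   2. accumulated Euclidean step length (tolerance 1e-9),
//   3. accumulated squared deviation of entered pixels from the start-end
//      chord (strict), so degenerate shortest paths collapse onto the
//      digital straight segment,
//   4. fixed neighbour iteration order E, NE, N, NW, W, SW, S, SE
//      (first writer wins).
// Coordinates are 0-based (row, col).

static const int DR[8] = { 0, -1, -1, -1,  0,  1, 1, 1 };
static const int DC[8] = { 1,  1,  0, -1, -1, -1, 0, 1 };

struct QNode {
  double cost, len, dev;
  uint64_t seq;
  int idx;
};

struct QCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.len  != b.len)  return a.len  > b.len;
    if (a.dev  != b.dev)  return a.dev  > b.dev;
    return a.seq > b.seq;
  }
};

// [[Rcpp::export(name = ".min_cost_path_cpp")]]
IntegerMatrix min_cost_path_cpp(NumericMatrix cost,
                                int r0, int c0, int r1, int c1,
                                double tol_cost, double diag_penalty) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (r0 < 0 || r0 >= nr || c0 < 0 || c0 >= nc ||
      r1 < 0 || r1 >= nr || c1 < 0 || c1 >= nc)
    stop("path endpoints outside the cost grid");
  const int n = nr * nc;
  std::vector<double> dcost(n, R_PosInf), dlen(n, R_PosInf), ddev(n, R_PosInf);
  std::vector<int> parent(n, -1);
  std::vector<char> done(n, 0);

  // chord geometry for the deviation key
  const double ax = (double)r0, ay = (double)c0;
  double bx = (double)r1 - ax, by = (double)c1 - ay;
  double bn = std::sqrt(bx * bx + by * by);
  if (bn > 0) { bx /= bn; by /= bn; }
  const double tol_len = 1e-9;

  auto chord_dev2 = [&](int r, int c) {
    double px = r - ax, py = c - ay;
    double cross = px * by - py * bx;
    return cross * cross;
  };

  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  uint64_t seq = 0;
  int s = r0 + c0 * nr, t = r1 + c1 * nr;
  dcost[s] = 0.0; dlen[s] = 0.0; ddev[s] = 0.0;
  pq.push({0.0, 0.0, 0.0, seq++, s});

  while (!pq.empty()) {
    QNode top = pq.top(); pq.pop();
    int u = top.idx;
    if (done[u]) continue;
    done[u] = 1;
    if (u == t) break;
    int ur = u % nr, uc = u / nr;
    for (int k = 0; k < 8; ++k) {
      int vr = ur + DR[k], vc = uc + DC[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      int v = vr + vc * nr;
      if (done[v]) continue;
      bool diag = (DR[k] != 0 && DC[k] != 0);
      double step = diag ? M_SQRT2 : 1.0;
      double nc_ = dcost[u] + cost(vr, vc) + (diag ? diag_penalty : 0.0);
      double nl  = dlen[u] + step;
      double nd  = ddev[u] + chord_dev2(vr, vc);
      bool better;
      if (nc_ < dcost[v] - tol_cost) better = true;
      else if (nc_ > dcost[v] + tol_cost) better = false;
      else if (nl < dlen[v] - tol_len) better = true;
      else if (nl > dlen[v] + tol_len) better = false;
      else better = (nd < ddev[v]);
      if (better) {
        dcost[v] = nc_; dlen[v] = nl; ddev[v] = nd; parent[v] = u;
        pq.push({nc_, nl, nd, seq++, v});
      }
    }
  }

  if (!done[t]) stop("no path between the given pixels");
  std::vector<int> rev;
  for (int u = t; u != -1; u = parent[u]) rev.push_back(u);
  IntegerMatrix out(rev.size(), 2);
  for (size_t i = 0; i < rev.size(); ++i) {
    int u = rev[rev.size() - 1 - i];
    out(i, 0) = u % nr;
    out(i, 1) = u / nr;
  }
  return out;
}

// 8-connected component labelling of a logical mask (row-major flood fill,
// deterministic label order by column-major first pixel).
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
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
        int u = stack.back(); stack.pop_back();
        int ur = u % nr, uc = u / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int vr = ur + dr, vc = uc + dc;
            if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
            if (mask(vr, vc) && lab(vr, vc) == 0) {
              lab(vr, vc) = next;
              stack.push_back(vr + vc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Project query pixels onto a closed pixel polyline: for each query point
// the nearest point on any path segment (including the closing segment) is
// found and its cumulative arc-length parameter returned. Perpendicular
// structures project to (nearly) a single arc position regardless of the
// path's orientation on the pixel grid.
// [[Rcpp::export(name = ".project_polyline_cpp")]]
NumericVector project_polyline_cpp(IntegerVector qr, IntegerVector qc,
                                   IntegerVector pr, IntegerVector pc) {
  const int nq = qr.size(), np = pr.size();
  if (np == 0) stop("empty path");
  std::vector<double> arc(np + 1, 0.0), segl(np);
  for (int j = 0; j < np; ++j) {
    int j2 = (j + 1) % np;
    double dr = pr[j2] - pr[j], dc = pc[j2] - pc[j];
    segl[j] = std::sqrt(dr * dr + dc * dc);
    arc[j + 1] = arc[j] + segl[j];
  }
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf, bs = 0.0;
    for (int j = 0; j < np; ++j) {
      int j2 = (j + 1) % np;
      double ar = pr[j], ac = pc[j];
      double br = pr[j2] - ar, bc = pc[j2] - ac;
      double len2 = br * br + bc * bc;
      double t = 0.0;
      if (len2 > 0) {
        t = ((qr[i] - ar) * br + (qc[i] - ac) * bc) / len2;
        if (t < 0) t = 0; else if (t > 1) t = 1;
      }
      double dr = qr[i] - (ar + t * br), dc = qc[i] - (ac + t * bc);
      double d = dr * dr + dc * dc;
      if (d < best) { best = d; bs = arc[j] + t * segl[j]; }
    }
    out[i] = bs;
  }
  return out;
}
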