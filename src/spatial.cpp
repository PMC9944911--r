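#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact nearest-neighbour lookup on a uniform grid of buckets.
// Ties are broken by the lowest reference index, so results are
// independent of bucket traversal order.

// [[Rcpp::export(name = ".nn_index_grid")]]
IntegerVector nn_index_grid(NumericMatrix ref, NumericMatrix query, double cell) {
  const int nr = ref.nrow(), nq = query.nrow();
  if (nr == 0) stop("no reference points");
  if (cell <= 0) stop("cell size must be positive");

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = ref(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  int dim[3];
  for (int d = 0; d < 3; ++d)
    dim[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
  const size_t ncell = (size_t)dim[0] * dim[1] * dim[2];

  std::vector<int> cx(nr), cy(nr), cz(nr);
  std::vector<int> start(ncell + 1, 0);
  auto clampi = [](int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); };
  for (int i = 0; i < nr; ++i) {
    cx[i] = clampi((int)std::floor((ref(i, 0) - lo[0]) / cell), dim[0]);
    cy[i] = clampi((int)std::floor((ref(i, 1) - lo[1]) / cell), dim[1]);
    cz[i] = clampi((int)std::floor((ref(i, 2) - lo[2]) / cell), dim[2]);
    size_t c = ((size_t)cx[i] * dim[1] + cy[i]) * dim[2] + cz[i];
    start[c + 1]++;
  }
  for (size_t c = 0; c < ncell; ++c) start[c + 1] += start[c];
  std::vector<int> items(nr);
  { std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < nr; ++i) {
      size_t c = ((size_t)cx[i] * dim[1] + cy[i]) * dim[2] + cz[i];
      items[fill[c]++] = i;
    } }

  IntegerVector out(nq);
  const int maxr = dim[0] + dim[1] + dim[2] + 2;
  for (int q = 0; q < nq; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    int gx = clampi((int)std::floor((qx - lo[0]) / cell), dim[0]);
    int gy = clampi((int)std::floor((qy - lo[1]) / cell), dim[1]);
    int gz = clampi((int)std::floor((qz - lo[2]) / cell), dim[2]);
    double best = R_PosInf; int besti = -1;
    for (int r = 0; r <= maxr; ++r) {
      // ring r of cells at Chebyshev distance r from (gx,gy,gz)
      if (besti >= 0) {
        double dmin = (double)(r - 1) * cell;  // closest possible point in ring r
        if (dmin > 0 && dmin * dmin > best) break;
      }
      bool any_cell = false;
      for (int ix = gx - r; ix <= gx + r; ++ix) {
        if (ix < 0 || ix >= dim[0]) continue;
        for (int iy = gy - r; iy <= gy + r; ++iy) {
          if (iy < 0 || iy >= dim[1]) continue;
          bool face_xy = (std::abs(ix - gx) == r) || (std::abs(iy - gy) == r);
          for (int iz = gz - r; iz <= gz + r; ++iz) {
            if (iz < 0 || iz >= dim[2]) continue;
            if (!face_xy && std::abs(iz - gz) != r) continue;  // interior: already done
            any_cell = true;
            size_t c = ((size_t)ix * dim[1] + iy) * dim[2] + iz;
            for (int k = start[c]; k < start[c + 1]; ++k) {
              int i = items[k];
              double ddx = ref(i, 0) - qx, ddy = ref(i, 1) - qy, ddz = ref(i, 2) - qz;
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best || (d2 == best && i < besti)) { best = d2; besti = i; }
            }
          }
        }
      }
      if (!any_cell && besti >= 0) break;
    }
    out[q] = besti + 1;  // 1-based
  }
  return out;
}

// Sequential constrained-constructive tree growth for one perfusion
// territory.  Sites are inserted in the given order; each new site becomes
// a leaf attached by a side-branch bifurcation at the point of the existing
// tree nearest to it (the nearest segment is split there).  Produces a
// strictly binary tree with m leaves and 2m-1 segments.
//
// Returns 1-based parent/child indices; site = anchor site index per leaf
// (NA for internal segments).

// [[Rcpp::export(name = ".grow_cco")]]
List grow_cco(NumericVector entry, NumericMatrix sites, double frac_min) {
  const int m = sites.nrow();
  if (m < 1) stop("territory has no sites");
  const int n = 2 * m - 1;
  std::vector<double> px(n), py(n), pz(n), dx(n), dy(n), dz(n);
  std::vector<int> parent(n, -1), ch1(n, -1), ch2(n, -1), site(n, -1);

  px[0] = entry[0]; py[0] = entry[1]; pz[0] = entry[2];
  dx[0] = sites(0, 0); dy[0] = sites(0, 1); dz[0] = sites(0, 2);
  site[0] = 0;
  int cnt = 1;

  for (int k = 1; k < m; ++k) {
    const double sx = sites(k, 0), sy = sites(k, 1), sz = sites(k, 2);
    double best = R_PosInf, bt = 0.5; int be = 0;
    for (int e = 0; e < cnt; ++e) {
      const double ax = px[e], ay = py[e], az = pz[e];
      const double ux = dx[e] - ax, uy = dy[e] - ay, uz = dz[e] - az;
      const double L2 = ux * ux + uy * uy + uz * uz;
      double t = 0.5;
      if (L2 > 0) {
        t = ((sx - ax) * ux + (sy - ay) * uy + (sz - az) * uz) / L2;
        if (t < frac_min) t = frac_min;
        if (t > 1 - frac_min) t = 1 - frac_min;
      }
      const double wx = ax + t * ux - sx, wy = ay + t * uy - sy, wz = az + t * uz - sz;
      const double d2 = wx * wx + wy * wy + wz * wz;
      if (d2 < best) { best = d2; be = e; bt = t; }
    }
    // split segment be at X
    const double X = px[be] + bt * (dx[be] - px[be]);
    const double Y = py[be] + bt * (dy[be] - py[be]);
    const double Z = pz[be] + bt * (dz[be] - pz[be]);
    const int a = cnt++;  // continuation X -> old distal
    const int b = cnt++;  // new leaf X -> site k
    px[a] = X; py[a] = Y; pz[a] = Z;
    dx[a] = dx[be]; dy[a] = dy[be]; dz[a] = dz[be];
    ch1[a] = ch1[be]; ch2[a] = ch2[be]; site[a] = site[be];
    parent[a] = be;
    if (ch1[a] >= 0) { parent[ch1[a]] = a; parent[ch2[a]] = a; }
    px[b] = X; py[b] = Y; pz[b] = Z;
    dx[b] = sx; dy[b] = sy; dz[b] = sz;
    parent[b] = be; site[b] = k;
    dx[be] = X; dy[be] = Y; dz[be] = Z;
    ch1[be] = a; ch2[be] = b; site[be] = -1;
  }

  IntegerVector Rparent(n), Rch1(n), Rch2(n), Rsite(n);
  NumericMatrix prox(n, 3), dist(n, 3);
  for (int i = 0; i < n; ++i) {
    Rparent[i] = parent[i] < 0 ? NA_INTEGER : parent[i] + 1;
    Rch1[i] = ch1[i] < 0 ? NA_INTEGER : ch1[i] + 1;
    Rch2[i] = ch2[i] < 0 ? NA_INTEGER : ch2[i] + 1;
    Rsite[i] = site[i] < 0 ? NA_INTEGER : site[i] + 1;
    prox(i, 0) = px[i]; prox(i, 1) = py[i]; prox(i, 2) = pz[i];
    dist(i, 0) = dx[i]; dist(i, 1) = dy[i]; dist(i, 2) = dz[i];
  }
  return List::create(_["prox"] = prox, _["dist"] = dist,
                      _["parent"] = Rparent, _["child1"] = Rch1,
                      _["child2"] = Rch2, _["site"] = Rsite);
}

// Navigation index for a rooted tree given the 1-based parent vector:
// children (in id order), depth, preorder entry number tin, and
// tout = max tin in the subtree (so a subtree is the contiguous tin
// range [tin, tout]).  Errors on >2 children, cycles or disconnection.

// [[Rcpp::export(name = ".tree_index")]]
List tree_index(IntegerVector parent, int root) {
  const int n = parent.size();
  IntegerVector child1(n, NA_INTEGER), child2(n, NA_INTEGER),
      n_children(n, 0), depth(n, 0), tin(n, 0), tout(n, 0);
  for (int i = 0; i < n; ++i) {
    if (parent[i] == NA_INTEGER) continue;
    int p = parent[i] - 1;
    if (p < 0 || p >= n) stop("segment %d: parent out of range", i + 1);
    if (child1[p] == NA_INTEGER) child1[p] = i + 1;
    else if (child2[p] == NA_INTEGER) child2[p] = i + 1;
    else stop("segment %d has more than two children", p + 1);
    n_children[p]++;
  }
  std::vector<int> stack;
  stack.reserve(n);
  stack.push_back(root - 1);
  int counter = 0, visited = 0;
  std::vector<bool> seen(n, false);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (seen[v]) stop("tree contains a cycle");
    seen[v] = true;
    ++visited;
    tin[v] = ++counter;
    depth[v] = (parent[v] == NA_INTEGER) ? 0 : depth[parent[v] - 1] + 1;
    if (child2[v] != NA_INTEGER) stack.push_back(child2[v] - 1);
    if (child1[v] != NA_INTEGER) stack.push_back(child1[v] - 1);
  }
  if (visited < n) stop("tree is disconnected or contains a cycle");
  // tout via decreasing depth
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) { ord[i] = i; tout[i] = tin[i]; }
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return depth[a] > depth[b]; });
  for (int k = 0; k < n; ++k) {
    int v = ord[k];
    if (parent[v] != NA_INTEGER) {
      int p = parent[v] - 1;
      if (tout[v] > tout[p]) tout[p] = tout[v];
    }
  }
  return List::create(_["child1"] = child1, _["child2"] = child2,
                      _["n_children"] = n_children, _["depth"] = depth,
                      _["tin"] = tin, _["tout"] = tout);
}
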