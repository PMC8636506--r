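#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Threshold-free cluster enhancement of the positive part of a 3D map.
//
// TFCE(v) = sum over height steps h (midpoints (k - 1/2) * dh, h <= value(v))
//           of e(h)^E * h^H * dh,
// where e(h) is the voxel count of the connected component containing v in
// the supra-threshold set {value >= h}.
//
// Single pass over descending heights with an incremental union-find:
// voxels are activated in order of decreasing value; per-component
// increments are accumulated on component roots, with an offset correction
// at merge time so each voxel's total is the sum of root increments along
// its union path. Cost ~ O(V log V + steps * components).
//
// conn: 6, 18 or 26 neighbourhood.

static inline int find_root(std::vector<int> &parent, int x) {
  while (parent[x] != x) x = parent[x];
  return x;
}

// [[Rcpp::export(name = ".tfce_pos")]]
NumericVector tfce_pos(NumericVector img, IntegerVector dims,
                       double E, double H, double dh, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n);

  double vmax = 0.0;
  for (int i = 0; i < n; ++i) if (img[i] > vmax) vmax = img[i];
  if (vmax <= 0.0 || dh <= 0.0) return out;

  // neighbour offsets for the requested connectivity
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (conn == 6 && manh > 1) continue;
        if (conn == 18 && manh > 2) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  const int noff = (int) offx.size();

  // voxels with positive value, sorted by value descending
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (img[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return img[a] > img[b]; });

  std::vector<int> parent(n, -1);      // -1 = inactive
  std::vector<int> csize(n, 0);
  std::vector<double> acc(n, 0.0);     // accumulated increment, valid at roots
  std::vector<int> roots;              // current component roots (compacted lazily)

  const int K = (int) std::ceil(vmax / dh - 1e-12);
  size_t p = 0;  // pointer into `order`

  for (int k = K; k >= 1; --k) {
    const double h = (k - 0.5) * dh;
    if (h > vmax) continue;
    // activate voxels with value >= h
    while (p < order.size() && img[order[p]] >= h) {
      const int v = order[p++];
      parent[v] = v; csize[v] = 1; acc[v] = 0.0;
      roots.push_back(v);
      const int z = v / (nx * ny), rem = v % (nx * ny);
      const int y = rem / nx, x = rem % nx;
      for (int o = 0; o < noff; ++o) {
        const int xx = x + offx[o], yy = y + offy[o], zz = z + offz[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const int w = xx + nx * (yy + ny * zz);
        if (parent[w] < 0) continue;  // neighbour not yet active
        int ra = find_root(parent, v), rb = find_root(parent, w);
        if (ra == rb) continue;
        if (csize[ra] < csize[rb]) std::swap(ra, rb);
        parent[rb] = ra;
        acc[rb] -= acc[ra];  // preserve path sums across the merge
        csize[ra] += csize[rb];
      }
    }
    // drop stale roots, then add this height's increment per component
    size_t keep = 0;
    for (size_t r = 0; r < roots.size(); ++r)
      if (parent[roots[r]] == roots[r]) roots[keep++] = roots[r];
    roots.resize(keep);
    const double hterm = std::pow(h, H) * dh;
    for (size_t r = 0; r < roots.size(); ++r) {
      const int rt = roots[r];
      acc[rt] += std::pow((double) csize[rt], E) * hterm;
    }
  }

  // total for each active voxel = sum of acc along its union path
  for (int i = 0; i < n; ++i) {
    if (parent[i] < 0) continue;
    double s = 0.0;
    int x = i;
    while (true) { s += acc[x]; if (parent[x] == x) break; x = parent[x]; }
    out[i] = s;
  }
  return out;
}
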