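#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Geodesic path lengths through a voxel component: Dijkstra over the
// 26-neighbour voxel graph with physical (anisotropic) edge weights.
// Used for the longest-branch length: the maximum geodesic distance from the
// sarcolemmal attachment voxels (multi-source) to any voxel of the component.
// When no source is given, a double-sweep pseudo-diameter is returned.

namespace {

typedef std::pair<double, int> QN;

std::vector<double> dijkstra(const std::vector<int>& comp_idx,
                             const std::vector<int>& where,  // full-grid -> node id (+1), 0 = absent
                             const std::vector<int>& sources,
                             int nz, int ny, int nx,
                             double sz, double sy, double sx) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(comp_idx.size(), INF);
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
  for (size_t s = 0; s < sources.size(); ++s) {
    dist[sources[s]] = 0.0;
    pq.push(QN(0.0, sources[s]));
  }
  // 26 neighbour offsets with physical weights
  int dzs[26], dys[26], dxs[26]; double w[26]; int m = 0;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        if (az == 0 && ay == 0 && ax == 0) continue;
        dzs[m] = az; dys[m] = ay; dxs[m] = ax;
        w[m] = std::sqrt(az * az * sz * sz + ay * ay * sy * sy + ax * ax * sx * sx);
        ++m;
      }
  while (!pq.empty()) {
    QN top = pq.top(); pq.pop();
    double d = top.first; int u = top.second;
    if (d > dist[u]) continue;
    int lin = comp_idx[u];
    int z = lin % nz; int rest = lin / nz; int y = rest % ny; int x = rest / ny;
    for (int k = 0; k < m; ++k) {
      int zz = z + dzs[k], yy = y + dys[k], xx = x + dxs[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int nid = where[(size_t)zz + (size_t)nz * (yy + (size_t)ny * xx)];
      if (nid == 0) continue;
      --nid;
      double nd = d + w[k];
      if (nd < dist[nid]) { dist[nid] = nd; pq.push(QN(nd, nid)); }
    }
  }
  return dist;
}

} // namespace

// voxels: 1-based linear indices (R order, dim (nz,ny,nx)) of component voxels
// source: 1-based positions INTO voxels of the attachment voxels (may be empty)
// [[Rcpp::export(name = ".geodesic_longest")]]
double geodesic_longest(IntegerVector voxels, IntegerVector source,
                        IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const size_t nvox = voxels.size();
  if (nvox == 0) return NA_REAL;
  if (nvox == 1) return 0.0;
  std::vector<int> comp_idx(nvox);
  std::vector<int> where((size_t)nz * ny * nx, 0);
  for (size_t i = 0; i < nvox; ++i) {
    comp_idx[i] = voxels[i] - 1;
    where[(size_t)comp_idx[i]] = (int)i + 1;
  }
  std::vector<int> src;
  for (int i = 0; i < source.size(); ++i) src.push_back(source[i] - 1);
  if (src.empty()) {
    // pseudo-diameter: sweep from node 0, then from the farthest node
    std::vector<int> s0(1, 0);
    std::vector<double> d0 = dijkstra(comp_idx, where, s0, nz, ny, nx, sz, sy, sx);
    int far0 = 0; double best = -1.0;
    for (size_t i = 0; i < d0.size(); ++i)
      if (std::isfinite(d0[i]) && d0[i] > best) { best = d0[i]; far0 = (int)i; }
    std::vector<int> s1(1, far0);
    std::vector<double> d1 = dijkstra(comp_idx, where, s1, nz, ny, nx, sz, sy, sx);
    double out = 0.0;
    for (size_t i = 0; i < d1.size(); ++i)
      if (std::isfinite(d1[i]) && d1[i] > out) out = d1[i];
    return out;
  }
  std::vector<double> d = dijkstra(comp_idx, where, src, nz, ny, nx, sz, sy, sx);
  double out = 0.0;
  for (size_t i = 0; i < d.size(); ++i)
    if (std::isfinite(d[i]) && d[i] > out) out = d[i];
  return out;
}
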