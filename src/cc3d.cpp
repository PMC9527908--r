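#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on a 3D integer label grid stored in R's
// column-major order with dim = (nz, ny, nx): linear index z + nz*(y + ny*x).
// Components are formed over the union of "object" voxels (any label in
// obj_labels); 6- or 26-connectivity. For each component we also record
// whether any voxel is face-adjacent (6-neighbourhood, regardless of the
// component connectivity) to an extracellular voxel, and whether any voxel
// lies on an array face (the crop window boundary).

// [[Rcpp::export(name = ".cc3d_label")]]
List cc3d_label(IntegerVector vol, IntegerVector dims, IntegerVector obj_labels,
                int connectivity, int ec_label) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (vol.size() != n) stop("volume length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  // object membership lookup
  int maxlab = 0;
  for (R_xlen_t i = 0; i < n; ++i) if (vol[i] > maxlab) maxlab = vol[i];
  std::vector<char> isobj(maxlab + 1, 0);
  for (int j = 0; j < obj_labels.size(); ++j) {
    int l = obj_labels[j];
    if (l >= 0 && l <= maxlab) isobj[l] = 1;
  }

  IntegerVector comp(n, 0);
  std::vector<int> sizes;
  std::vector<char> tec, tbd;

  // neighbour offsets
  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        if (az == 0 && ay == 0 && ax == 0) continue;
        int man = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (connectivity == 6 && man != 1) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int nneigh = (int)dz.size();

  std::vector<R_xlen_t> stack;
  int next_id = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    int v = vol[start];
    if (v <= 0 || v > maxlab || !isobj[v] || comp[start] != 0) continue;
    ++next_id;
    int size = 0;
    char touch_ec = 0, touch_bd = 0;
    stack.clear();
    stack.push_back(start);
    comp[start] = next_id;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      ++size;
      int z = (int)(cur % nz);
      R_xlen_t rest = cur / nz;
      int y = (int)(rest % ny);
      int x = (int)(rest / ny);
      if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 || x == 0 || x == nx - 1)
        touch_bd = 1;
      // extracellular face adjacency (6-neighbourhood)
      if (!touch_ec) {
        static const int fz[6] = {-1, 1, 0, 0, 0, 0};
        static const int fy[6] = {0, 0, -1, 1, 0, 0};
        static const int fx[6] = {0, 0, 0, 0, -1, 1};
        for (int k = 0; k < 6; ++k) {
          int zz = z + fz[k], yy = y + fy[k], xx = x + fx[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          R_xlen_t idx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (vol[idx] == ec_label) { touch_ec = 1; break; }
        }
      }
      for (int k = 0; k < nneigh; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t idx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        int w = vol[idx];
        if (w > 0 && w <= maxlab && isobj[w] && comp[idx] == 0) {
          comp[idx] = next_id;
          stack.push_back(idx);
        }
      }
    }
    sizes.push_back(size);
    tec.push_back(touch_ec);
    tbd.push_back(touch_bd);
  }

  comp.attr("dim") = dims;
  return List::create(_["labels"] = comp,
                      _["n"] = next_id,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()),
                      _["touches_extracellular"] = LogicalVector(tec.begin(), tec.end()),
                      _["touches_boundary"] = LogicalVector(tbd.begin(), tbd.end()));
}
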