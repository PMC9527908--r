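#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sub-voxel iso-surface area of a binary 3D mask at the 0.5 level, computed on
// a 3x3x3 box-smoothed indicator with a marching-tetrahedra decomposition
// (each voxel cube split into 6 tetrahedra sharing the main diagonal).
// Anisotropic voxel spacing is honoured; mask dim = (nz, ny, nx), spacing =
// (sz, sy, sx) in the same axis order. Smoothing uses replicate padding at the
// array faces, so a component truncated by the crop window is left open there
// (no artificial cap face) while interfaces with background inside the array
// (including the extracellular partition) are meshed normally.

namespace {
struct P3 { double z, y, x; };

inline double triarea(const P3& a, const P3& b, const P3& c) {
  double uz = b.z - a.z, uy = b.y - a.y, ux = b.x - a.x;
  double vz = c.z - a.z, vy = c.y - a.y, vx = c.x - a.x;
  double cz = uy * vx - ux * vy;
  double cy = ux * vz - uz * vx;
  double cx = uz * vy - uy * vz;
  return 0.5 * std::sqrt(cz * cz + cy * cy + cx * cx);
}

inline P3 interp(const P3& a, const P3& b, double fa, double fb) {
  double t = (0.5 - fa) / (fb - fa);
  P3 p; p.z = a.z + t * (b.z - a.z); p.y = a.y + t * (b.y - a.y); p.x = a.x + t * (b.x - a.x);
  return p;
}
} // namespace

// [[Rcpp::export(name = ".mtetra_area")]]
double mtetra_area(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");

  auto raw = [&](int z, int y, int x) -> double {
    // replicate padding
    if (z < 0) z = 0; if (z >= nz) z = nz - 1;
    if (y < 0) y = 0; if (y >= ny) y = ny - 1;
    if (x < 0) x = 0; if (x >= nx) x = nx - 1;
    return mask[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] ? 1.0 : 0.0;
  };

  // smoothed field
  std::vector<float> f((size_t)n, 0.0f);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double s = 0.0;
        for (int a = -1; a <= 1; ++a)
          for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) s += raw(z + a, y + b, x + c);
        f[(size_t)z + (size_t)nz * (y + (size_t)ny * x)] = (float)(s / 27.0);
      }
  auto F = [&](int z, int y, int x) -> double {
    return f[(size_t)z + (size_t)nz * (y + (size_t)ny * x)];
  };

  // 6 tetrahedra per cube, all sharing the 0-6 diagonal; cube corner order:
  // 0:(0,0,0) 1:(1,0,0) 2:(1,1,0) 3:(0,1,0) 4:(0,0,1) 5:(1,0,1) 6:(1,1,1) 7:(0,1,1)
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};

  double area = 0.0;
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        double fv[8]; P3 pv[8];
        bool any = false, all = true;
        for (int k = 0; k < 8; ++k) {
          int dz = corner[k][0], dy = corner[k][1], dx = corner[k][2];
          fv[k] = F(z + dz, y + dy, x + dx);
          pv[k].z = (z + dz) * sz; pv[k].y = (y + dy) * sy; pv[k].x = (x + dx) * sx;
          if (fv[k] > 0.5) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (fv[T[k]] > 0.5) in[nin++] = T[k]; else out[nout++] = T[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            const int* base = (nin == 1) ? out : in;
            P3 p0 = interp(pv[apex], pv[base[0]], fv[apex], fv[base[0]]);
            P3 p1 = interp(pv[apex], pv[base[1]], fv[apex], fv[base[1]]);
            P3 p2 = interp(pv[apex], pv[base[2]], fv[apex], fv[base[2]]);
            area += triarea(p0, p1, p2);
          } else {
            // 2 in / 2 out: quad (a-c, a-d, b-d, b-c)
            int a = in[0], b = in[1], c = out[0], d = out[1];
            P3 pac = interp(pv[a], pv[c], fv[a], fv[c]);
            P3 pad = interp(pv[a], pv[d], fv[a], fv[d]);
            P3 pbd = interp(pv[b], pv[d], fv[b], fv[d]);
            P3 pbc = interp(pv[b], pv[c], fv[b], fv[c]);
            area += triarea(pac, pad, pbd);
            area += triarea(pac, pbd, pbc);
          }
        }
      }
  return area;
}
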