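#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Sub-voxel contour tracing on a binary 2D mask: the indicator is box-filtered
// (3x3, zero outside), then the 0.5 iso-level is extracted marching-squares
// style with linear interpolation along cell edges, and the resulting segments
// are stitched into closed polygons. The mask is implicitly padded by one zero
// ring so that every contour closes, including objects truncated at the slice
// edge. Returned vertex coordinates are 0-based voxel-centre (row, col) units.

namespace {

struct Seg { long long a, b; double ax, ay, bx, by; };

inline double fieldval(const std::vector<double>& f, int H, int W, int i, int j) {
  // padded coordinates: i,j in [-1, H] x [-1, W]; outside -> 0
  if (i < 0 || i >= H || j < 0 || j >= W) return 0.0;
  return f[(size_t)i * W + j];
}

} // namespace

// [[Rcpp::export(name = ".trace_contours")]]
List trace_contours(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // 3x3 box filter, zero padded
  std::vector<double> f((size_t)H * W, 0.0);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double s = 0.0;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b) {
          int ii = i + a, jj = j + b;
          if (ii >= 0 && ii < H && jj >= 0 && jj < W && mask(ii, jj)) s += 1.0;
        }
      f[(size_t)i * W + j] = s / 9.0;
    }

  const double iso = 0.5;
  // padded grid of corners: rows -1..H, cols -1..W  -> indices 0..H+1, 0..W+1
  const int PH = H + 2, PW = W + 2;
  auto val = [&](int pi, int pj) { return fieldval(f, H, W, pi - 1, pj - 1); };

  // global edge ids over padded grid:
  // horizontal edge (pi, pj)-(pi, pj+1): id = pi*(PW-1) + pj
  // vertical   edge (pi, pj)-(pi+1, pj): id = PH*(PW-1) + pi*PW + pj
  auto hid = [&](int pi, int pj) -> long long { return (long long)pi * (PW - 1) + pj; };
  auto vid = [&](int pi, int pj) -> long long {
    return (long long)PH * (PW - 1) + (long long)pi * PW + pj;
  };

  std::vector<Seg> segs;
  for (int pi = 0; pi < PH - 1; ++pi) {
    for (int pj = 0; pj < PW - 1; ++pj) {
      double v00 = val(pi, pj),     v01 = val(pi, pj + 1);
      double v10 = val(pi + 1, pj), v11 = val(pi + 1, pj + 1);
      int c = (v00 > iso ? 1 : 0) | (v01 > iso ? 2 : 0) |
              (v11 > iso ? 4 : 0) | (v10 > iso ? 8 : 0);
      if (c == 0 || c == 15) continue;
      // crossing points on the four cell edges (row, col in padded units)
      double tx, ty;
      // top edge: (pi,pj)-(pi,pj+1)
      double top_x = 0, top_y = 0, bot_x = 0, bot_y = 0, lef_x = 0, lef_y = 0, rig_x = 0, rig_y = 0;
      bool topc = (v00 > iso) != (v01 > iso);
      bool botc = (v10 > iso) != (v11 > iso);
      bool lefc = (v00 > iso) != (v10 > iso);
      bool rigc = (v01 > iso) != (v11 > iso);
      if (topc) { tx = (iso - v00) / (v01 - v00); top_y = pi;       top_x = pj + tx; }
      if (botc) { tx = (iso - v10) / (v11 - v10); bot_y = pi + 1;   bot_x = pj + tx; }
      if (lefc) { ty = (iso - v00) / (v10 - v00); lef_y = pi + ty;  lef_x = pj; }
      if (rigc) { ty = (iso - v01) / (v11 - v01); rig_y = pi + ty;  rig_x = pj + 1; }
      long long tope = hid(pi, pj), bote = hid(pi + 1, pj), lefe = vid(pi, pj), rige = vid(pi, pj + 1);

      auto add = [&](long long ea, double eax, double eay, long long eb, double ebx, double eby) {
        Seg s; s.a = ea; s.b = eb; s.ax = eax; s.ay = eay; s.bx = ebx; s.by = eby;
        segs.push_back(s);
      };

      switch (c) {
        case 1: case 14: add(tope, top_x, top_y, lefe, lef_x, lef_y); break;
        case 2: case 13: add(tope, top_x, top_y, rige, rig_x, rig_y); break;
        case 4: case 11: add(rige, rig_x, rig_y, bote, bot_x, bot_y); break;
        case 8: case 7:  add(lefe, lef_x, lef_y, bote, bot_x, bot_y); break;
        case 3: case 12: add(lefe, lef_x, lef_y, rige, rig_x, rig_y); break;
        case 6: case 9:  add(tope, top_x, top_y, bote, bot_x, bot_y); break;
        case 5: case 10: {
          // saddle: disambiguate with the cell-centre average
          double mid = 0.25 * (v00 + v01 + v10 + v11);
          bool centre_in = mid > iso;
          if ((c == 5) == centre_in) {
            add(tope, top_x, top_y, rige, rig_x, rig_y);
            add(lefe, lef_x, lef_y, bote, bot_x, bot_y);
          } else {
            add(tope, top_x, top_y, lefe, lef_x, lef_y);
            add(rige, rig_x, rig_y, bote, bot_x, bot_y);
          }
          break;
        }
      }
    }
  }

  // stitch segments into closed loops; every crossing edge touches exactly 2 segments
  std::unordered_map<long long, std::vector<int>> incident;
  incident.reserve(segs.size() * 2);
  for (int s = 0; s < (int)segs.size(); ++s) {
    incident[segs[s].a].push_back(s);
    incident[segs[s].b].push_back(s);
  }
  std::vector<char> used(segs.size(), 0);
  List out;
  for (int s0 = 0; s0 < (int)segs.size(); ++s0) {
    if (used[s0]) continue;
    std::vector<double> ys, xs;
    int cur = s0;
    long long enter = segs[s0].a;
    used[s0] = 1;
    ys.push_back(segs[s0].ay); xs.push_back(segs[s0].ax);
    long long exit_edge = segs[s0].b;
    double exy = segs[s0].by, exx = segs[s0].bx;
    while (true) {
      ys.push_back(exy); xs.push_back(exx);
      if (exit_edge == enter) break;  // loop closed
      const std::vector<int>& inc = incident[exit_edge];
      int nxt = -1;
      for (int cand : inc) if (!used[cand]) { nxt = cand; break; }
      if (nxt < 0) break;  // open chain (should not happen with padding)
      used[nxt] = 1;
      if (segs[nxt].a == exit_edge) {
        exit_edge = segs[nxt].b; exy = segs[nxt].by; exx = segs[nxt].bx;
      } else {
        exit_edge = segs[nxt].a; exy = segs[nxt].ay; exx = segs[nxt].ax;
      }
      cur = nxt;
    }
    (void)cur;
    int m = (int)ys.size();
    NumericMatrix poly(m, 2);
    for (int k = 0; k < m; ++k) {
      poly(k, 0) = ys[k] - 1.0;  // back to unpadded voxel-centre coordinates
      poly(k, 1) = xs[k] - 1.0;
    }
    colnames(poly) = CharacterVector::create("row", "col");
    out.push_back(poly);
  }
  return out;
}
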