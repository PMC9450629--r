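#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 3D binary thinning to a unit-width skeleton.
//
// Directional (6-subiteration) thinning: in each pass, border voxels of one
// face direction that are simple points and not curve endpoints are collected
// and then deleted one by one, re-checking simplicity at deletion time so that
// simultaneous deletion cannot break topology. Simplicity uses the classic
// (26,6) characterisation: a voxel is simple iff the foreground of its
// 26-neighbourhood (centre excluded) has exactly one 26-connected component
// AND the background of its 18-neighbourhood has exactly one 6-connected
// component that is 6-adjacent to the centre. Endpoints (<= 1 foreground
// 26-neighbour) are preserved so that open tube ends survive.

namespace {

struct Grid {
  std::vector<uint8_t> v; // padded by 1 on every side
  int dx, dy, dz;         // padded dims
  inline int idx(int x, int y, int z) const { return x + dx * (y + dy * z); }
};

// offsets of the 26 neighbours, order irrelevant
static const int NB26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1, 0},{0,-1, 0},{1,-1, 0},{-1,0, 0},        {1,0, 0},{-1,1, 0},{0,1, 0},{1,1, 0},
  {-1,-1, 1},{0,-1, 1},{1,-1, 1},{-1,0, 1},{0,0, 1},{1,0, 1},{-1,1, 1},{0,1, 1},{1,1, 1}
};
static const int FACE6[6][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}
};

inline int nb_lin(int ox, int oy, int oz) { // offset -> 0..26 within 3x3x3
  return (ox + 1) + 3 * ((oy + 1) + 3 * (oz + 1));
}

// number of foreground 26-neighbours
inline int fg_neighbours(const Grid &g, int x, int y, int z) {
  int n = 0;
  for (int i = 0; i < 26; ++i)
    n += g.v[g.idx(x + NB26[i][0], y + NB26[i][1], z + NB26[i][2])];
  return n;
}

// condition A: exactly one 26-component of foreground in N26* (centre removed)
bool one_fg_component(const uint8_t nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            int nx = cx + ox, ny = cy + oy, nz = cz + oz;
            if (nx < 0 || nx > 2 || ny < 0 || ny > 2 || nz < 0 || nz > 2) continue;
            int t = nx + 3 * ny + 9 * nz;
            if (t == 13 || t == c || seen[t] || !nb[t]) continue;
            seen[t] = true;
            stack[top++] = t;
          }
    }
  }
  return comps == 1;
}

// condition B: exactly one 6-component of background within the 18-neighbourhood
// that touches a face neighbour of the centre
bool one_bg_component(const uint8_t nb[27]) {
  // membership in N18: offsets with Chebyshev distance 1 that are not corners
  bool in18[27];
  for (int s = 0; s < 27; ++s) {
    int sx = s % 3 - 1, sy = (s / 3) % 3 - 1, sz = s / 9 - 1;
    int a = (sx != 0) + (sy != 0) + (sz != 0);
    in18[s] = (a >= 1 && a <= 2);
  }
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int f = 0; f < 6; ++f) {
    int s = nb_lin(FACE6[f][0], FACE6[f][1], FACE6[f][2]);
    if (nb[s] || seen[s]) continue; // want background face neighbours
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      static const int F[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int nx = cx + F[k][0], ny = cy + F[k][1], nz = cz + F[k][2];
        if (nx < 0 || nx > 2 || ny < 0 || ny > 2 || nz < 0 || nz > 2) continue;
        int t = nx + 3 * ny + 9 * nz;
        if (t == 13 || seen[t] || nb[t] || !in18[t]) continue;
        seen[t] = true;
        stack[top++] = t;
      }
    }
  }
  return comps == 1;
}

bool is_simple(const Grid &g, int x, int y, int z) {
  uint8_t nb[27];
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox)
        nb[nb_lin(ox, oy, oz)] = g.v[g.idx(x + ox, y + oy, z + oz)];
  return one_fg_component(nb) && one_bg_component(nb);
}

} // namespace

// [[Rcpp::export(name = ".thin_skeleton_cpp")]]
LogicalVector thin_skeleton_cpp(LogicalVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  Grid g;
  g.dx = d1 + 2; g.dy = d2 + 2; g.dz = d3 + 2;
  g.v.assign((size_t)g.dx * g.dy * g.dz, 0);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        R_xlen_t src = (R_xlen_t)x + (R_xlen_t)d1 * (y + (R_xlen_t)d2 * z);
        if (mask[src] == TRUE) g.v[g.idx(x + 1, y + 1, z + 1)] = 1;
      }

  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      const int fx = FACE6[dir][0], fy = FACE6[dir][1], fz = FACE6[dir][2];
      cand.clear();
      for (int z = 1; z <= d3; ++z)
        for (int y = 1; y <= d2; ++y)
          for (int x = 1; x <= d1; ++x) {
            int i = g.idx(x, y, z);
            if (!g.v[i]) continue;
            if (g.v[g.idx(x + fx, y + fy, z + fz)]) continue; // not a border in dir
            if (fg_neighbours(g, x, y, z) <= 1) continue;      // endpoint kept
            if (!is_simple(g, x, y, z)) continue;
            cand.push_back(i);
          }
      // sequential re-check before deletion
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k];
        int x = i % g.dx, y = (i / g.dx) % g.dy, z = i / (g.dx * g.dy);
        if (fg_neighbours(g, x, y, z) <= 1) continue;
        if (!is_simple(g, x, y, z)) continue;
        g.v[i] = 0;
        changed = true;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  LogicalVector out((R_xlen_t)d1 * d2 * d3);
  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x)
        out[(R_xlen_t)x + (R_xlen_t)d1 * (y + (R_xlen_t)d2 * z)] =
            g.v[g.idx(x + 1, y + 1, z + 1)] ? TRUE : FALSE;
  out.attr("dim") = dims;
  return out;
}
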