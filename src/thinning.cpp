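#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Topology-preserving 3D curve thinning (medial-axis skeletonization).
//
// A border voxel may be deleted only if it is a simple point in the
// (26, 6) adjacency pair, characterized locally (Bertrand & Malandain):
//   (1) the foreground voxels of the 26-neighborhood N26* form exactly one
//       26-connected component, and
//   (2) the background voxels of the 18-neighborhood N18 that are 6-adjacent
//       to the center form exactly one 6-connected component within N18.
// Curve endpoints (exactly one foreground 26-neighbor) are preserved.
// Deletion proceeds in six directional subiterations (U, D, N, S, E, W) with
// sequential re-checking, until a full cycle removes nothing.

namespace {

struct Vol {
  std::vector<unsigned char> v;
  int nz, ny, nx;
  inline bool fg(int z, int y, int x) const {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return false;
    return v[(size_t)z + (size_t)nz * (y + (size_t)ny * x)] != 0;
  }
  inline unsigned char &at(int z, int y, int x) {
    return v[(size_t)z + (size_t)nz * (y + (size_t)ny * x)];
  }
};

// offsets of the 3x3x3 neighborhood, index o = (dz+1) + 3*(dy+1) + 9*(dx+1)
inline int odz(int o) { return o % 3 - 1; }
inline int ody(int o) { return (o / 3) % 3 - 1; }
inline int odx(int o) { return o / 9 - 1; }
inline int oabs(int o) {
  return std::abs(odz(o)) + std::abs(ody(o)) + std::abs(odx(o));
}

int count_fg_neighbors(const Vol &vol, int z, int y, int x) {
  int c = 0;
  for (int o = 0; o < 27; ++o) {
    if (o == 13) continue;
    if (vol.fg(z + odz(o), y + ody(o), x + odx(o))) ++c;
  }
  return c;
}

// number of 26-connected components among the foreground 26-neighbors
int n_fg_components26(const bool nb[27]) {
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int a = stack[--top];
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || b == a || !nb[b] || seen[b]) continue;
        if (std::abs(odz(a) - odz(b)) <= 1 && std::abs(ody(a) - ody(b)) <= 1 &&
            std::abs(odx(a) - odx(b)) <= 1) {
          seen[b] = true;
          stack[top++] = b;
        }
      }
    }
  }
  return comp;
}

// number of 6-connected components of background within N18 that contain a
// face neighbor of the center
int n_bg_components6(const bool nb[27]) {
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || oabs(s) != 1 || nb[s] || seen[s]) continue;  // bg face nb
    ++comp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int a = stack[--top];
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || b == a || oabs(b) > 2 || nb[b] || seen[b]) continue;
        if (std::abs(odz(a) - odz(b)) + std::abs(ody(a) - ody(b)) +
                std::abs(odx(a) - odx(b)) == 1) {
          seen[b] = true;
          stack[top++] = b;
        }
      }
    }
  }
  return comp;
}

bool is_simple(const Vol &vol, int z, int y, int x) {
  bool nb[27];
  for (int o = 0; o < 27; ++o)
    nb[o] = vol.fg(z + odz(o), y + ody(o), x + odx(o));
  if (n_fg_components26(nb) != 1) return false;
  if (n_bg_components6(nb) != 1) return false;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  Vol vol;
  vol.nz = dims[0];
  vol.ny = dims[1];
  vol.nx = dims[2];
  vol.v.assign(mask.size(), 0);
  for (R_xlen_t i = 0; i < mask.size(); ++i) vol.v[i] = mask[i] ? 1 : 0;

  // directions (dz, dy, dx): up, down, north, south, east, west
  const int dir[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                         {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int x = 0; x < vol.nx; ++x)
        for (int y = 0; y < vol.ny; ++y)
          for (int z = 0; z < vol.nz; ++z) {
            if (!vol.fg(z, y, x)) continue;
            if (vol.fg(z + dir[d][0], y + dir[d][1], x + dir[d][2])) continue;
            if (count_fg_neighbors(vol, z, y, x) <= 1) continue;  // endpoint
            if (!is_simple(vol, z, y, x)) continue;
            cand.push_back(z + vol.nz * (y + vol.ny * x));
          }
      // sequential re-check: earlier deletions may invalidate later candidates
      for (int idx : cand) {
        int z = idx % vol.nz, rest = idx / vol.nz;
        int y = rest % vol.ny, x = rest / vol.ny;
        if (count_fg_neighbors(vol, z, y, x) <= 1) continue;
        if (!is_simple(vol, z, y, x)) continue;
        vol.at(z, y, x) = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = vol.v[i] != 0;
  out.attr("dim") = dims;
  return out;
}
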