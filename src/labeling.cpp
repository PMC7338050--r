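#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling of a logical volume.
// mask is indexed (z, y, x) column-major; connectivity is 6, 18 or 26.
// Labels are assigned in increasing linear-index scan order, starting at 1.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();

  // neighbor offsets for the requested connectivity
  std::vector<int> dz_, dy_, dx_;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dz_.push_back(dz); dy_.push_back(dy); dx_.push_back(dx);
      }
  const int nn = (int)dz_.size();

  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;
  int next_label = 0;
  std::queue<int> q;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    q.push((int)i);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cz = cur % nz, rest = cur / nz;
      int cy = rest % ny, cx = rest / ny;
      for (int k = 0; k < nn; ++k) {
        int z = cz + dz_[k], y = cy + dy_[k], x = cx + dx_[k];
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx)
          continue;
        int j = z + nz * (y + ny * x);
        if (mask[j] && labels[j] == 0) {
          labels[j] = next_label;
          q.push(j);
        }
      }
    }
  }
  return labels;
}
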