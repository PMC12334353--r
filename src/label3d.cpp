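// 3D connected-component labelling by breadth-first search.
// Labels are assigned in raster (linear index) order of each component's
// first voxel, matching the deterministic ordering contract.
#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims, int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2)) continue;
        offs.push_back({dx, dy, dz});
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    ++next;
    labels[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % d1), y = (int)((v / d1) % d2), z = (int)(v / ((R_xlen_t)d1 * d2));
      for (auto& o : offs) {
        int nx = x + o[0], ny = y + o[1], nz = z + o[2];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= d1 || ny >= d2 || nz >= d3) continue;
        R_xlen_t u = nx + (R_xlen_t)d1 * (ny + (R_xlen_t)d2 * nz);
        if (mask[u] && !labels[u]) { labels[u] = next; stack.push_back(u); }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}
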