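#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdlib>
using namespace Rcpp;

// 3D connected-component labeling of a binary mask by iterative flood fill.
// Components are numbered in raster-scan discovery order (x fastest, then y,
// then z), i.e. by the lexicographically smallest (z, y, x) voxel of each
// component. Connectivity 6 = faces, 18 = faces+edges, 26 = full neighborhood.
// [[Rcpp::export]]
IntegerVector ccl3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask size does not match dims");
  IntegerVector lab(n, 0);

  std::vector<std::array<int, 3> > nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        nb.push_back({{dx, dy, dz}});
      }

  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++cur;
    lab[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (size_t j = 0; j < nb.size(); ++j) {
        int X = x + nb[j][0], Y = y + nb[j][1], Z = z + nb[j][2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        R_xlen_t w = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
        if (mask[w] == TRUE && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
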