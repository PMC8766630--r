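#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Label connected components of a logical mask (2-D or 3-D array).
// connectivity: 2-D -> 4 or 8; 3-D -> 6, 18 or 26.
// [[Rcpp::export]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nd = dims.size();
  int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  long n = (long)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;

  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (nd == 2 && dz != 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nd == 2) {
          if (connectivity == 4 && manh > 1) continue;
        } else {
          if (connectivity == 6 && manh > 1) continue;
          if (connectivity == 18 && manh > 2) continue;
        }
        offs.push_back({dx, dy, dz});
      }

  int cur = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      int z = p / ((long)nx * ny);
      int rem = p - (long)z * nx * ny;
      int y = rem / nx, x = rem % nx;
      for (auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        long q = (long)zz * nx * ny + (long)yy * nx + xx;
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  lab.attr("n") = IntegerVector::create(cur);
  return lab;
}

// Mode label of the 3x3x3 neighborhood (excluding the voxel's own current
// label) for every voxel listed in `which0` (0-based linear indices).
// Ties break to the smallest label id. Labels taken from `vox` (snapshot).
// [[Rcpp::export]]
IntegerVector neighborhood_mode(IntegerVector vox, IntegerVector dims,
                                IntegerVector which0, int nclass) {
  int nx = dims[0], ny = dims[1], nz = dims.size() == 3 ? dims[2] : 1;
  IntegerVector out(which0.size());
  std::vector<int> cnt(nclass);
  for (int k = 0; k < which0.size(); ++k) {
    long p = which0[k];
    int z = p / ((long)nx * ny);
    int rem = p - (long)z * nx * ny;
    int y = rem / nx, x = rem % nx;
    std::fill(cnt.begin(), cnt.end(), 0);
    int own = vox[p];
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int v = vox[(long)zz * nx * ny + (long)yy * nx + xx];
          if (v >= 0 && v < nclass && v != own) cnt[v]++;
        }
    int best = own, bestc = 0;
    for (int c = 0; c < nclass; ++c)
      if (cnt[c] > bestc) { bestc = cnt[c]; best = c; }
    out[k] = best;
  }
  return out;
}
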