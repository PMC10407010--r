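#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D binary mask under 6/18/26
// connectivity, by iterative flood fill.  Returns an integer array of
// provisional component labels (1..n in discovery order); relabeling by
// size happens on the R side.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  out.attr("dim") = dims;

  // neighbor offsets
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int ord = std::abs(a) + std::abs(b) + std::abs(c);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int nnb = (int)dx.size();

  std::vector<R_xlen_t> stack;
  int label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || out[s] != 0) continue;
    ++label;
    out[s] = label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v - (R_xlen_t)z * nx * ny);
      int y = rem / nx;
      int x = rem - y * nx;
      for (int q = 0; q < nnb; ++q) {
        int xx = x + dx[q], yy = y + dy[q], zz = z + dz[q];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[w] && out[w] == 0) {
          out[w] = label;
          stack.push_back(w);
        }
      }
    }
  }
  return out;
}
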