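#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// reflect index into [0, n)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 3-D median filter with reflect padding; kernel k must be odd.
// [[Rcpp::export(name = ".median3d_cpp")]]
NumericVector median3d_cpp(NumericVector vol, int k) {
  IntegerVector dm = vol.attr("dim");
  const int nz = dm[0], ny = dm[1], nx = dm[2];
  const int h = k / 2;
  NumericVector out(vol.size());
  out.attr("dim") = dm;
  const int m = k * k * k;
  std::vector<double> buf(m);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int p = 0;
        for (int dx = -h; dx <= h; ++dx) {
          const int xx = reflect(x + dx, nx);
          for (int dy = -h; dy <= h; ++dy) {
            const int yy = reflect(y + dy, ny);
            const R_xlen_t base = (R_xlen_t)(xx * ny + yy) * nz;
            for (int dz = -h; dz <= h; ++dz) {
              buf[p++] = vol[base + reflect(z + dz, nz)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[(R_xlen_t)(x * ny + y) * nz + z] = buf[m / 2];
      }
    }
  }
  return out;
}

// 6-connected component labelling of a logical 3-D mask.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask) {
  IntegerVector dm = mask.attr("dim");
  const int nz = dm[0], ny = dm[1], nx = dm[2];
  IntegerVector lab(mask.size(), 0);
  lab.attr("dim") = dm;
  int cur = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t n = mask.size();
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      const int dz[6] = {1, -1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, 1, -1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        int zz = z + dz[d], yy = y + dy[d], xx = x + dx[d];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t w = (R_xlen_t)(xx * ny + yy) * nz + zz;
        if (mask[w] && !lab[w]) { lab[w] = cur; q.push(w); }
      }
    }
  }
  return lab;
}
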