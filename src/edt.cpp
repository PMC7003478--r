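#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f holds squared distances on input.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      if (f[v[k]] == INF) { // previous parabola is at +inf: drop it
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; goto placed; }
        k--;
        continue;
      }
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        if (k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; goto placed; }
        k--;
      } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
    placed:;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dv = q - (double)v[k];
    d[q] = dv * dv + f[v[k]];
  }
}

// Exact squared 3-D Euclidean distance transform of a binary mask.
// mask: integer array (non-zero = feature voxels); returns squared distance
// (in voxel units) from each voxel center to the nearest feature voxel center.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(IntegerVector mask, IntegerVector dims) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);

  // init: 0 at feature voxels, +inf elsewhere
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] != 0 ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      bool any = false;
      for (int xx = 0; xx < nx; xx++) { f[xx] = out[base + xx]; if (f[xx] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nx, v, z);
      for (int xx = 0; xx < nx; xx++) out[base + xx] = d[xx];
    }

  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int xx = 0; xx < nx; xx++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + xx;
      bool any = false;
      for (int yy = 0; yy < ny; yy++) { f[yy] = out[base + (R_xlen_t)yy * nx]; if (f[yy] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, ny, v, z);
      for (int yy = 0; yy < ny; yy++) out[base + (R_xlen_t)yy * nx] = d[yy];
    }

  // pass along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; yy++)
    for (int xx = 0; xx < nx; xx++) {
      R_xlen_t base = (R_xlen_t)yy * nx + xx;
      bool any = false;
      for (int zz = 0; zz < nz; zz++) { f[zz] = out[base + (R_xlen_t)zz * nxy]; if (f[zz] < INF) any = true; }
      if (!any) continue;
      dt1d(f, d, nz, v, z);
      for (int zz = 0; zz < nz; zz++) out[base + (R_xlen_t)zz * nxy] = d[zz];
    }

  out.attr("dim") = dims;
  return out;
}
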