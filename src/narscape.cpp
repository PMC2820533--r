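#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Squared Euclidean distance transform of a 3D grid, separable 1D passes
// (lower-envelope-of-parabolas method).  `feature` marks the voxels that
// distance is measured TO; every voxel receives the squared distance to the
// nearest feature voxel.  INF is a large finite sentinel so that arithmetic
// on empty scan lines stays well defined.
static const double DT_INF = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector feature, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (feature.size() != n) stop("feature length does not match dims");
  NumericVector out(n);
  bool any_feature = false;
  for (R_xlen_t i = 0; i < n; i++) {
    out[i] = feature[i] ? 0.0 : DT_INF;
    if (feature[i]) any_feature = true;
  }
  if (!any_feature) stop("distance transform undefined: no feature voxels");

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index in R's column-major layout)
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      for (int xx = 0; xx < nx; xx++) f[xx] = out[base + xx];
      dt1d(f, d, v, z, nx);
      for (int xx = 0; xx < nx; xx++) out[base + xx] = d[xx];
    }
  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int xx = 0; xx < nx; xx++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + xx;
      for (int yy = 0; yy < ny; yy++) f[yy] = out[base + (R_xlen_t)yy * nx];
      dt1d(f, d, v, z, ny);
      for (int yy = 0; yy < ny; yy++) out[base + (R_xlen_t)yy * nx] = d[yy];
    }
  // pass along z
  for (int yy = 0; yy < ny; yy++)
    for (int xx = 0; xx < nx; xx++) {
      R_xlen_t base = (R_xlen_t)yy * nx + xx;
      R_xlen_t step = (R_xlen_t)nx * ny;
      for (int zz = 0; zz < nz; zz++) f[zz] = out[base + zz * step];
      dt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; zz++) out[base + zz * step] = d[zz];
    }
  return out;
}

// 6-connected component labelling (breadth-first); labels are 1..k in
// decreasing-size-agnostic discovery order, background stays 0.
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  int current = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    current++;
    lab[i] = current;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t p = q.front();
      q.pop();
      int xx = (int)(p % nx);
      int yy = (int)((p / nx) % ny);
      int zz = (int)(p / sz);
      R_xlen_t nb[6];
      int ok[6];
      nb[0] = p - sx; ok[0] = xx > 0;
      nb[1] = p + sx; ok[1] = xx < nx - 1;
      nb[2] = p - sy; ok[2] = yy > 0;
      nb[3] = p + sy; ok[3] = yy < ny - 1;
      nb[4] = p - sz; ok[4] = zz > 0;
      nb[5] = p + sz; ok[5] = zz < nz - 1;
      for (int j = 0; j < 6; j++) {
        if (ok[j] && mask[nb[j]] && lab[nb[j]] == 0) {
          lab[nb[j]] = current;
          q.push(nb[j]);
        }
      }
    }
  }
  return lab;
}
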