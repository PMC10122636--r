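#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected component labeling of a voxel mask (face-connectivity 6 or
// full 26). img: integer vector (0 = void, nonzero = bone), column-major
// with dims dim. Returns per-voxel component label (0 for void), labels
// start at 1.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector img, IntegerVector dim,
                                   int connectivity = 26) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (img[s] == 0 || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int r = (int)(v % ((R_xlen_t)nx * ny));
      int j = r / nx, i = r % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 &&
                std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (img[w] != 0 && lab[w] == 0) {
              lab[w] = cur;
              stack.push_back(w);
            }
          }
    }
  }
  return lab;
}

// Mean intercept length along a set of directions by line probing.
// For each direction, line bundles are started from every entry face the
// direction points away from (one line per boundary voxel column) and
// marched with a step of half the smallest voxel edge, covering the whole
// volume. MIL(d) = total bone length / number of void-to-bone crossings.
// [[Rcpp::export]]
NumericVector mil_cpp(IntegerVector img, IntegerVector dim, NumericVector spacing,
                      NumericMatrix dirs) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double Lx = nx * sx, Ly = ny * sy, Lz = nz * sz;
  const double L[3] = {Lx, Ly, Lz};
  const double sp[3] = {sx, sy, sz};
  const int nvox[3] = {nx, ny, nz};
  const double h = 0.5 * std::min(sx, std::min(sy, sz));
  const int D = dirs.nrow();
  NumericVector out(D);

  for (int d = 0; d < D; ++d) {
    double u[3] = {dirs(d, 0), dirs(d, 1), dirs(d, 2)};
    double nrm = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    u[0] /= nrm; u[1] /= nrm; u[2] /= nrm;

    double bone_len = 0.0;
    R_xlen_t crossings = 0;

    for (int a = 0; a < 3; ++a) {
      if (std::fabs(u[a]) < 1e-9) continue;
      int b = (a + 1) % 3, c = (a + 2) % 3;
      for (int ib = 0; ib < nvox[b]; ++ib) {
        for (int ic = 0; ic < nvox[c]; ++ic) {
          double p[3];
          p[a] = (u[a] > 0) ? 0.0 : L[a] - 1e-9;
          p[b] = (ib + 0.5) * sp[b];
          p[c] = (ic + 0.5) * sp[c];
          bool prev = false;
          while (p[0] >= 0 && p[1] >= 0 && p[2] >= 0 &&
                 p[0] < Lx && p[1] < Ly && p[2] < Lz) {
            int i = (int)(p[0] / sx), j = (int)(p[1] / sy), k = (int)(p[2] / sz);
            if (i >= nx) i = nx - 1;
            if (j >= ny) j = ny - 1;
            if (k >= nz) k = nz - 1;
            bool bone = img[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] != 0;
            if (bone) {
              bone_len += h;
              if (!prev) ++crossings;
            }
            prev = bone;
            p[0] += h * u[0]; p[1] += h * u[1]; p[2] += h * u[2];
          }
        }
      }
    }
    out[d] = (crossings > 0) ? bone_len / (double)crossings
                             : std::sqrt(Lx * Lx + Ly * Ly + Lz * Lz);
  }
  return out;
}

// Bone volume fraction inside a sphere centered at each query point.
// img holds voxel values in [0,1]; voxel centers at origin + (idx + 0.5)*spacing.
// Returns NA when the sphere contains no voxel centers (entirely outside).
// [[Rcpp::export]]
NumericVector sphere_density_cpp(NumericVector img, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericMatrix centers, double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double r2 = radius * radius;
  const int m = centers.nrow();
  NumericVector out(m);

  for (int q = 0; q < m; ++q) {
    double cx = centers(q, 0) - origin[0];
    double cy = centers(q, 1) - origin[1];
    double cz = centers(q, 2) - origin[2];
    int i0 = (int)std::floor((cx - radius) / sx - 0.5), i1 = (int)std::ceil((cx + radius) / sx - 0.5);
    int j0 = (int)std::floor((cy - radius) / sy - 0.5), j1 = (int)std::ceil((cy + radius) / sy - 0.5);
    int k0 = (int)std::floor((cz - radius) / sz - 0.5), k1 = (int)std::ceil((cz + radius) / sz - 0.5);
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    if (j1 > ny - 1) j1 = ny - 1;
    if (k1 > nz - 1) k1 = nz - 1;
    double tot = 0.0, bone = 0.0;
    for (int k = k0; k <= k1; ++k) {
      double dz = (k + 0.5) * sz - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = (j + 0.5) * sy - cy;
        for (int i = i0; i <= i1; ++i) {
          double dx = (i + 0.5) * sx - cx;
          if (dx * dx + dy * dy + dz * dz <= r2) {
            tot += 1.0;
            bone += img[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
          }
        }
      }
    }
    out[q] = (tot > 0) ? bone / tot : NA_REAL;
  }
  return out;
}
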