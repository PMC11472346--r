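#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trilinear interpolation of a 3D field stored in R column-major order
// (x fastest, z slowest).  Coordinates are continuous voxel-center
// coordinates: voxel (i, j, k) (0-based) sits at (i, j, k).  Queries beyond
// the outermost voxel centers clamp to the edge value, so the interpolated
// field is defined on the full physical bounding box (centers +- 1/2 voxel).
static inline double trilinear(const double *v,
                               const int nx, const int ny, const int nz,
                               double ux, double uy, double uz) {
  if (ux < 0.0) ux = 0.0; else if (ux > nx - 1.0) ux = nx - 1.0;
  if (uy < 0.0) uy = 0.0; else if (uy > ny - 1.0) uy = ny - 1.0;
  if (uz < 0.0) uz = 0.0; else if (uz > nz - 1.0) uz = nz - 1.0;

  int i0 = (int)std::floor(ux); if (i0 > nx - 2) i0 = nx - 2;
  int j0 = (int)std::floor(uy); if (j0 > ny - 2) j0 = ny - 2;
  int k0 = (int)std::floor(uz); if (k0 > nz - 2) k0 = nz - 2;
  const double fx = ux - i0, fy = uy - j0, fz = uz - k0;

  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double *p000 = v + i0 + (R_xlen_t)nx * j0 + sxy * k0;

  const double c00 = p000[0]       * (1.0 - fx) + p000[1]          * fx;
  const double c10 = p000[nx]      * (1.0 - fx) + p000[nx + 1]     * fx;
  const double c01 = p000[sxy]     * (1.0 - fx) + p000[sxy + 1]    * fx;
  const double c11 = p000[sxy + nx] * (1.0 - fx) + p000[sxy + nx + 1] * fx;

  const double c0 = c00 * (1.0 - fy) + c10 * fy;
  const double c1 = c01 * (1.0 - fy) + c11 * fy;
  return c0 * (1.0 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector values, IntegerVector dim,
                                   NumericMatrix pts, NumericVector origin,
                                   double voxel_size) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(values);
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double ux = (pts(i, 0) - origin[0]) / voxel_size;
    const double uy = (pts(i, 1) - origin[1]) / voxel_size;
    const double uz = (pts(i, 2) - origin[2]) / voxel_size;
    out[i] = trilinear(v, nx, ny, nz, ux, uy, uz);
  }
  return out;
}

// Specular reflection of a coordinate into [lo, hi]; at most 10 folds, then
// clamps (only reachable for steps many box-lengths long).
static inline double reflect1(double x, const double lo, const double hi) {
  for (int it = 0; it < 10; ++it) {
    if (x < lo) x = 2.0 * lo - x;
    else if (x > hi) x = 2.0 * hi - x;
    else return x;
  }
  if (x < lo) x = lo; else if (x > hi) x = hi;
  return x;
}

// Random walk of n molecules through the pore space of a structure function.
// Each proposal is a fresh isotropic Gaussian step (per-axis sd `sigma`, all
// lengths in the same physical units as `origin`/`voxel_size`); proposals
// leaving the volume are specularly reflected about the outer faces before
// the solid test; proposals landing where the interpolated field is >= 0.5
// are discarded and redrawn from the same position, up to max_retries
// (after which the molecule keeps its position for that step).
// Uses R's RNG stream; draw order is molecule-major, three N(0, sigma)
// variates per proposal (x, y, z).
// [[Rcpp::export]]
List cpp_run_walk(NumericVector values, IntegerVector dim,
                  NumericVector origin, double voxel_size,
                  NumericMatrix start, int n_steps, double sigma,
                  int max_retries) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = REAL(values);
  const int n = start.nrow();

  const double lox = origin[0] - 0.5 * voxel_size;
  const double loy = origin[1] - 0.5 * voxel_size;
  const double loz = origin[2] - 0.5 * voxel_size;
  const double hix = origin[0] + (nx - 0.5) * voxel_size;
  const double hiy = origin[1] + (ny - 0.5) * voxel_size;
  const double hiz = origin[2] + (nz - 0.5) * voxel_size;

  NumericMatrix end(n, 3);
  double rejected = 0.0;
  int stuck = 0;

  for (int k = 0; k < n; ++k) {
    double x = start(k, 0), y = start(k, 1), z = start(k, 2);
    bool ever_stuck = false;
    for (int j = 0; j < n_steps; ++j) {
      int tries = 0;
      for (;;) {
        const double dx = R::rnorm(0.0, sigma);
        const double dy = R::rnorm(0.0, sigma);
        const double dz = R::rnorm(0.0, sigma);
        double px = reflect1(x + dx, lox, hix);
        double py = reflect1(y + dy, loy, hiy);
        double pz = reflect1(z + dz, loz, hiz);
        const double s = trilinear(v, nx, ny, nz,
                                   (px - origin[0]) / voxel_size,
                                   (py - origin[1]) / voxel_size,
                                   (pz - origin[2]) / voxel_size);
        if (s < 0.5) { x = px; y = py; z = pz; break; }
        rejected += 1.0;
        if (++tries >= max_retries) { ever_stuck = true; break; }
      }
    }
    if (ever_stuck) ++stuck;
    end(k, 0) = x; end(k, 1) = y; end(k, 2) = z;
    if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["end"] = end,
                      _["rejected_step_count"] = rejected,
                      _["stuck_count"] = stuck);
}

// Paint a solid sphere (value 1) into a voxel volume in place.  Center and
// radius are in continuous voxel-center coordinates (0-based).  Returns the
// number of voxels newly turned solid.
// [[Rcpp::export]]
double cpp_paint_sphere(NumericVector values, IntegerVector dim,
                        double cx, double cy, double cz, double r) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double *v = REAL(values);
  const double r2 = r * r;
  const int i0 = std::max(0, (int)std::ceil(cx - r));
  const int i1 = std::min(nx - 1, (int)std::floor(cx + r));
  const int j0 = std::max(0, (int)std::ceil(cy - r));
  const int j1 = std::min(ny - 1, (int)std::floor(cy + r));
  const int k0 = std::max(0, (int)std::ceil(cz - r));
  const int k1 = std::min(nz - 1, (int)std::floor(cz + r));
  double painted = 0.0;
  for (int k = k0; k <= k1; ++k) {
    const double dz2 = (k - cz) * (k - cz);
    for (int j = j0; j <= j1; ++j) {
      const double dyz2 = dz2 + (j - cy) * (j - cy);
      if (dyz2 > r2) continue;
      double *row = v + (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k;
      for (int i = i0; i <= i1; ++i) {
        if (dyz2 + (i - cx) * (i - cx) <= r2 && row[i] < 0.5) {
          row[i] = 1.0;
          painted += 1.0;
        }
      }
    }
  }
  return painted;
}
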