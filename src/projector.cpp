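// Fan-beam forward projection of material fraction maps and
// distance-weighted equiangular backprojection.
//
// Geometry: source rotates at radius `sid` around the isocenter; curved
// detector with equiangular columns at angular pitch `dgamma`. For view
// angle beta the source sits at sid * (cos beta, sin beta) and the central
// ray points toward the isocenter. Detector coordinate gamma increases
// counter-clockwise. Image convention: row 1 is the top of the image
// (y up), pixel centers at half-integer offsets from the grid center.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear sample of a column-major n x n map at grid coordinates
// (gx = column index, gy = row index), 0-based. Outside the grid -> 0.
static inline double sample_map(const double* m, int n, double gx, double gy) {
  if (gx < 0 || gy < 0 || gx > n - 1 || gy > n - 1) return 0.0;
  int c0 = (int)std::floor(gx), r0 = (int)std::floor(gy);
  int c1 = std::min(c0 + 1, n - 1), r1 = std::min(r0 + 1, n - 1);
  double fx = gx - c0, fy = gy - r0;
  double v00 = m[r0 + c0 * n], v10 = m[r1 + c0 * n];
  double v01 = m[r0 + c1 * n], v11 = m[r1 + c1 * n];
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

// [[Rcpp::export]]
NumericVector project_paths_cpp(List maps, int n, double pixel_mm,
                                double sid_mm, NumericVector betas,
                                NumericVector gammas, double step_mm) {
  const int n_mat = maps.size();
  const int n_views = betas.size();
  const int n_cols = gammas.size();
  std::vector<const double*> mp(n_mat);
  for (int m = 0; m < n_mat; ++m) {
    NumericMatrix mm = maps[m];
    mp[m] = REAL(mm);
  }
  NumericVector out(Dimension(n_views, n_cols, n_mat));
  double* op = REAL(out);
  const double R = 0.5 * n * pixel_mm;  // bounding circle of the grid
  const double half = (n - 1) / 2.0;

  for (int v = 0; v < n_views; ++v) {
    const double beta = betas[v];
    const double sx = sid_mm * std::cos(beta);
    const double sy = sid_mm * std::sin(beta);
    for (int c = 0; c < n_cols; ++c) {
      const double th = beta + M_PI + gammas[c];
      const double dx = std::cos(th), dy = std::sin(th);
      // intersect ray s + t*d with circle radius R about origin
      const double b = sx * dx + sy * dy;
      const double disc = b * b - (sx * sx + sy * sy - R * R);
      if (disc <= 0) continue;
      const double sq = std::sqrt(disc);
      double t0 = -b - sq, t1 = -b + sq;
      if (t1 <= 0) continue;
      if (t0 < 0) t0 = 0;
      const int nstep = (int)std::ceil((t1 - t0) / step_mm);
      const double dt = (t1 - t0) / nstep;
      for (int m = 0; m < n_mat; ++m) {
        double acc = 0.0;
        const double* map = mp[m];
        for (int k = 0; k < nstep; ++k) {
          const double t = t0 + (k + 0.5) * dt;
          const double x = sx + t * dx, y = sy + t * dy;
          const double gx = x / pixel_mm + half;
          const double gy = half - y / pixel_mm;
          acc += sample_map(map, n, gx, gy);
        }
        op[v + (size_t)n_views * (c + (size_t)n_cols * m)] = acc * dt;
      }
    }
  }
  return out;
}

// Equiangular fan-beam backprojection of filtered projections q
// (n_views x n_cols) onto an n_out x n_out grid centered at
// (cx_mm, cy_mm) with pixel size pixel_mm. Weight 1/L^2 with L the
// source-to-pixel distance; linear interpolation along the detector.
// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix q, double sid_mm,
                              NumericVector betas, double dgamma,
                              int n_cols, int n_out, double pixel_mm,
                              double cx_mm, double cy_mm) {
  const int n_views = betas.size();
  NumericMatrix img(n_out, n_out);
  const double dbeta = 2.0 * M_PI / n_views;
  const double half = (n_out - 1) / 2.0;
  const double gcenter = (n_cols + 1) / 2.0;  // 1-based center index

  std::vector<double> px(n_out), py(n_out);
  for (int i = 0; i < n_out; ++i) {
    px[i] = cx_mm + (i - half) * pixel_mm;        // column -> x
    py[i] = cy_mm + (half - i) * pixel_mm;        // row -> y
  }
  for (int v = 0; v < n_views; ++v) {
    const double beta = betas[v];
    const double sx = sid_mm * std::cos(beta);
    const double sy = sid_mm * std::sin(beta);
    const double central = beta + M_PI;
    const double* qv = &q(v, 0);
    for (int c = 0; c < n_out; ++c) {
      const double x = px[c];
      for (int r = 0; r < n_out; ++r) {
        const double vx = x - sx, vy = py[r] - sy;
        const double L2 = vx * vx + vy * vy;
        double gp = std::atan2(vy, vx) - central;
        while (gp > M_PI) gp -= 2.0 * M_PI;
        while (gp < -M_PI) gp += 2.0 * M_PI;
        const double idx = gp / dgamma + gcenter;  // 1-based fractional col
        if (idx < 1 || idx > n_cols) continue;
        const int i0 = (int)std::floor(idx);
        const int i1 = std::min(i0 + 1, n_cols);
        const double f = idx - i0;
        const double val = (1 - f) * qv[(size_t)(i0 - 1) * n_views] +
                           f * qv[(size_t)(i1 - 1) * n_views];
        img(r, c) += dbeta * val / L2;
      }
    }
  }
  return img;
}
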