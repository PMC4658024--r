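#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parallel-beam projector / backprojector pair.
//
// Shared coordinate convention (must stay consistent between the two
// kernels and the R-level geometry helpers):
//   * pixel (i = row, j = col), 0-based in C++; image centre at
//     ((n-1)/2, (n-1)/2) is the isocenter;
//   * physical x = (j - c) * pixel_size (cm), y = (i - c) * pixel_size;
//   * a view at angle theta (radians, CCW) measures line integrals along
//     rays x*cos(theta) + y*sin(theta) = t;
//   * detector k (0-based) sits at t_k = (k - (n_det-1)/2) * det_spacing.
//
// Forward projection is Joseph-style ray marching with bilinear sampling,
// clipped to the grid's circumscribed circle; back-projection is
// pixel-driven with linear detector interpolation.

// march one ray through `n_img` images sharing a grid, accumulating the
// bilinearly sampled line integral of each into acc[]
static inline void march_ray(const std::vector<const double *> &imgs,
                             std::vector<double> &acc, int n, double c,
                             double t, double ct, double st, double radius,
                             double ds, double inv_ps) {
  size_t n_img = imgs.size();
  for (size_t q = 0; q < n_img; ++q) acc[q] = 0.0;
  double half = std::sqrt(radius * radius - t * t);
  int n_step = (int)std::floor(2.0 * half / ds);
  if (n_step <= 0) return;
  double s = -half + 0.5 * ds;
  // point = t*(ct,st) + s*(-st,ct); advance by ds*(-st,ct)
  double ci = (t * ct - s * st) * inv_ps + c;
  double ri = (t * st + s * ct) * inv_ps + c;
  double dci = -st * ds * inv_ps;
  double dri = ct * ds * inv_ps;
  for (int m = 0; m < n_step; ++m, ci += dci, ri += dri) {
    int i0 = (int)std::floor(ri);
    int j0 = (int)std::floor(ci);
    if (i0 < 0 || i0 > n - 2 || j0 < 0 || j0 > n - 2) continue;
    double fi = ri - i0, fj = ci - j0;
    double w00 = (1 - fi) * (1 - fj), w01 = (1 - fi) * fj;
    double w10 = fi * (1 - fj), w11 = fi * fj;
    size_t base = (size_t)j0 * n + i0;  // column-major
    for (size_t q = 0; q < n_img; ++q) {
      const double *p = imgs[q] + base;
      acc[q] += w00 * p[0] + w10 * p[1] + w01 * p[n] + w11 * p[n + 1];
    }
  }
  for (size_t q = 0; q < n_img; ++q) acc[q] *= ds;
}

static List radon_impl(const std::vector<const double *> &imgs, int n,
                       const NumericVector &angles, int n_det,
                       double det_spacing, double pixel_size,
                       double step_frac, CharacterVector names) {
  int n_ang = angles.size();
  size_t n_img = imgs.size();
  std::vector<NumericMatrix> out;
  for (size_t q = 0; q < n_img; ++q) out.push_back(NumericMatrix(n_ang, n_det));
  double c = (n - 1) / 2.0;
  double det_c = (n_det - 1) / 2.0;
  double radius = 0.5 * std::sqrt(2.0) * n * pixel_size + pixel_size;
  double ds = step_frac * pixel_size;
  double inv_ps = 1.0 / pixel_size;
  std::vector<double> acc(n_img);
  for (int a = 0; a < n_ang; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int k = 0; k < n_det; ++k) {
      double t = (k - det_c) * det_spacing;
      if (std::fabs(t) >= radius) continue;
      march_ray(imgs, acc, n, c, t, ct, st, radius, ds, inv_ps);
      for (size_t q = 0; q < n_img; ++q) out[q](a, k) = acc[q];
    }
  }
  List res(n_img);
  for (size_t q = 0; q < n_img; ++q) res[q] = out[q];
  res.attr("names") = names;
  return res;
}

// [[Rcpp::export]]
NumericMatrix radon_forward(const NumericMatrix &img, const NumericVector &angles,
                            int n_det, double det_spacing, double pixel_size,
                            double step_frac) {
  std::vector<const double *> imgs(1, REAL(img));
  List res = radon_impl(imgs, img.nrow(), angles, n_det, det_spacing,
                        pixel_size, step_frac, CharacterVector::create("x"));
  return res[0];
}

// [[Rcpp::export]]
List radon_forward_multi(const List &images, const NumericVector &angles,
                         int n_det, double det_spacing, double pixel_size,
                         double step_frac) {
  size_t n_img = images.size();
  std::vector<const double *> imgs(n_img);
  int n = -1;
  for (size_t q = 0; q < n_img; ++q) {
    NumericMatrix m = images[q];
    if (n < 0) n = m.nrow();
    if (m.nrow() != n || m.ncol() != n)
      stop("all images must share one square grid");
    imgs[q] = REAL(m);
  }
  CharacterVector names(n_img);
  if (images.hasAttribute("names")) names = images.attr("names");
  return radon_impl(imgs, n, angles, n_det, det_spacing, pixel_size,
                    step_frac, names);
}

// [[Rcpp::export]]
NumericMatrix radon_back(const NumericMatrix &sino, const NumericVector &angles,
                         double det_spacing, int n, double pixel_size) {
  int n_ang = angles.size();
  int n_det = sino.ncol();
  NumericMatrix img(n, n);
  double *im = REAL(img);
  double c = (n - 1) / 2.0;
  double det_c = (n_det - 1) / 2.0;
  double inv_dt = 1.0 / det_spacing;
  for (int a = 0; a < n_ang; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    // view row a of the (n_ang x n_det) sinogram, contiguous copy
    std::vector<double> view(n_det);
    for (int k = 0; k < n_det; ++k) view[k] = sino(a, k);
    double dk_di = pixel_size * st * inv_dt;   // t step down a column
    for (int j = 0; j < n; ++j) {
      double x = (j - c) * pixel_size;
      double dk0 = (x * ct + (0 - c) * pixel_size * st) * inv_dt + det_c;
      double *col = im + (size_t)j * n;
      double dk = dk0;
      for (int i = 0; i < n; ++i, dk += dk_di) {
        int k0 = (int)std::floor(dk);
        if (k0 < 0 || k0 >= n_det - 1) continue;
        double f = dk - k0;
        col[i] += (1 - f) * view[k0] + f * view[k0 + 1];
      }
    }
  }
  return img;
}
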