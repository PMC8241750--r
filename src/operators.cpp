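// Low-level imaging operators: pixel-driven projection (Radon) with exact
// transpose, bilinear warps with exact transpose, Parzen-window NMI with
// analytic gradient, and separable reflect-boundary convolution.
// All coordinates are 0-based pixel units; R wrappers handle physical units.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel-driven forward projection. img: ny x nx, angles in radians.
// Each pixel centre projects to detector coordinate t = x*cos + y*sin
// (pixels, origin at image centre) and is split linearly between the two
// nearest detector bins. Mass-preserving: column sums of the operator are 1
// for pixels whose footprint stays inside the detector.
// [[Rcpp::export]]
NumericMatrix proj_forward_cpp(const NumericMatrix& img, const NumericVector& angles,
                               int nbins) {
  const int ny = img.nrow(), nx = img.ncol(), na = angles.size();
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cb = (nbins - 1) / 2.0;
  NumericMatrix sino(nbins, na);
  const double* im = &img(0, 0);
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    double* so = &sino(0, a);
    for (int c = 0; c < nx; ++c) {
      const double* col = im + (size_t)c * ny;
      double t = (c - cx) * ca - cy * sa + cb;
      for (int r = 0; r < ny; ++r, t += sa) {
        const double v = col[r];
        if (v == 0.0) continue;
        const int i0 = (int)std::floor(t);
        const double w = t - i0;
        if (i0 >= 0 && i0 < nbins)         so[i0]     += v * (1.0 - w);
        if (i0 + 1 >= 0 && i0 + 1 < nbins) so[i0 + 1] += v * w;
      }
    }
  }
  return sino;
}

// Exact transpose of proj_forward_cpp.
// [[Rcpp::export]]
NumericMatrix proj_adjoint_cpp(const NumericMatrix& sino, const NumericVector& angles,
                               int ny, int nx) {
  const int nbins = sino.nrow(), na = angles.size();
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cb = (nbins - 1) / 2.0;
  NumericMatrix img(ny, nx);
  double* im = &img(0, 0);
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    const double* so = &sino(0, a);
    for (int c = 0; c < nx; ++c) {
      double* col = im + (size_t)c * ny;
      double t = (c - cx) * ca - cy * sa + cb;
      for (int r = 0; r < ny; ++r, t += sa) {
        const int i0 = (int)std::floor(t);
        const double w = t - i0;
        double acc = 0.0;
        if (i0 >= 0 && i0 < nbins)         acc += so[i0] * (1.0 - w);
        if (i0 + 1 >= 0 && i0 + 1 < nbins) acc += so[i0 + 1] * w;
        col[r] += acc;
      }
    }
  }
  return img;
}

// Pull-back bilinear warp: out(r,c) = img(r + uy(r,c), c + ux(r,c)).
// Out-of-grid samples read zero (clamp = false, the reconstruction
// operator pair) or the clamped edge value (clamp = true, used for
// displacement-field algebra). Displacements in pixels.
// [[Rcpp::export]]
NumericMatrix warp_pull_cpp(const NumericMatrix& img, const NumericMatrix& ux,
                            const NumericMatrix& uy, bool clamp = false) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int c = 0; c < nx; ++c) {
    for (int r = 0; r < ny; ++r) {
      double ys = r + uy(r, c), xs = c + ux(r, c);
      if (clamp) {
        if (ys < 0) ys = 0; if (ys > ny - 1) ys = ny - 1;
        if (xs < 0) xs = 0; if (xs > nx - 1) xs = nx - 1;
      }
      const int y0 = (int)std::floor(ys), x0 = (int)std::floor(xs);
      const double fy = ys - y0, fx = xs - x0;
      double acc = 0.0;
      for (int dy = 0; dy <= 1; ++dy) {
        const int yy = y0 + dy;
        if (yy < 0 || yy >= ny) continue;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xx = x0 + dx;
          if (xx < 0 || xx >= nx) continue;
          acc += img(yy, xx) * wy * (dx ? fx : 1.0 - fx);
        }
      }
      out(r, c) = acc;
    }
  }
  return out;
}

// Exact transpose of warp_pull_cpp (scatter of the interpolation weights).
// [[Rcpp::export]]
NumericMatrix warp_pull_adjoint_cpp(const NumericMatrix& g, const NumericMatrix& ux,
                                    const NumericMatrix& uy) {
  const int ny = g.nrow(), nx = g.ncol();
  NumericMatrix out(ny, nx);
  for (int c = 0; c < nx; ++c) {
    for (int r = 0; r < ny; ++r) {
      const double v = g(r, c);
      if (v == 0.0) continue;
      const double ys = r + uy(r, c), xs = c + ux(r, c);
      const int y0 = (int)std::floor(ys), x0 = (int)std::floor(xs);
      const double fy = ys - y0, fx = xs - x0;
      for (int dy = 0; dy <= 1; ++dy) {
        const int yy = y0 + dy;
        if (yy < 0 || yy >= ny) continue;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xx = x0 + dx;
          if (xx < 0 || xx >= nx) continue;
          out(yy, xx) += v * wy * (dx ? fx : 1.0 - fx);
        }
      }
    }
  }
  return out;
}

// Nearest-neighbour pull-back warp for label maps. Fill value for
// out-of-grid samples.
// [[Rcpp::export]]
IntegerMatrix warp_nearest_cpp(const IntegerMatrix& img, const NumericMatrix& ux,
                               const NumericMatrix& uy, int fill) {
  const int ny = img.nrow(), nx = img.ncol();
  IntegerMatrix out(ny, nx);
  for (int c = 0; c < nx; ++c) {
    for (int r = 0; r < ny; ++r) {
      const int yy = (int)std::lround(r + uy(r, c));
      const int xx = (int)std::lround(c + ux(r, c));
      out(r, c) = (yy >= 0 && yy < ny && xx >= 0 && xx < nx) ? img(yy, xx) : fill;
    }
  }
  return out;
}

static inline double bspline3(double u) {
  const double au = std::fabs(u);
  if (au < 1.0) return (4.0 - 6.0 * au * au + 3.0 * au * au * au) / 6.0;
  if (au < 2.0) { const double t = 2.0 - au; return t * t * t / 6.0; }
  return 0.0;
}
static inline double bspline3_d(double u) {
  const double au = std::fabs(u), s = u < 0 ? -1.0 : 1.0;
  if (au < 1.0) return s * (-2.0 * au + 1.5 * au * au);
  if (au < 2.0) { const double t = 2.0 - au; return s * (-0.5 * t * t); }
  return 0.0;
}

// Negative normalised mutual information -(Hm + Hf)/Hj with a cubic B-spline
// Parzen window (partition of unity on the bin grid), plus its analytic
// gradient with respect to the moving-image intensities. Inputs must be
// pre-normalised to [0, 1]; nbins >= 8.
// [[Rcpp::export]]
List nmi_neg_grad_cpp(const NumericVector& mov, const NumericVector& fix, int nbins) {
  const int n = mov.size(), B = nbins;
  const double scale = B - 4.0;  // intensities map to bin coords in [1, B-3]
  NumericMatrix p(B, B);
  std::vector<double> zm(n), zf(n);
  for (int k = 0; k < n; ++k) {
    double vm = mov[k]; if (vm < 0) vm = 0; if (vm > 1) vm = 1;
    double vf = fix[k]; if (vf < 0) vf = 0; if (vf > 1) vf = 1;
    zm[k] = 1.0 + vm * scale;
    zf[k] = 1.0 + vf * scale;
    const int im = (int)std::floor(zm[k]), jf = (int)std::floor(zf[k]);
    for (int a = -1; a <= 2; ++a) {
      const double wm = bspline3(zm[k] - (im + a));
      if (wm == 0.0) continue;
      for (int b = -1; b <= 2; ++b) {
        const double wf = bspline3(zf[k] - (jf + b));
        if (wf != 0.0) p(im + a, jf + b) += wm * wf;
      }
    }
  }
  const double invn = 1.0 / n;
  NumericVector pm(B), pf(B);
  double Hj = 0.0;
  for (int i = 0; i < B; ++i)
    for (int j = 0; j < B; ++j) {
      const double pij = p(i, j) * invn;
      p(i, j) = pij;
      pm[i] += pij; pf[j] += pij;
      if (pij > 0) Hj -= pij * std::log(pij);
    }
  double Hm = 0.0, Hf = 0.0;
  for (int i = 0; i < B; ++i) {
    if (pm[i] > 0) Hm -= pm[i] * std::log(pm[i]);
    if (pf[i] > 0) Hf -= pf[i] * std::log(pf[i]);
  }
  const double nmi = (Hm + Hf) / Hj;
  // dNMI/dp_ij = [(Lm_i + Lf_j) * Hj - (Hm + Hf) * Lj_ij] / Hj^2
  // with Lm_i = -(log pm_i + 1) etc.
  const double tiny = 1e-300, Hj2 = Hj * Hj;
  std::vector<double> Lm(B), Lf(B);
  for (int i = 0; i < B; ++i) {
    Lm[i] = -(std::log(std::max(pm[i], tiny)) + 1.0);
    Lf[i] = -(std::log(std::max(pf[i], tiny)) + 1.0);
  }
  NumericVector grad(n);
  for (int k = 0; k < n; ++k) {
    const int im = (int)std::floor(zm[k]), jf = (int)std::floor(zf[k]);
    double g = 0.0;
    for (int a = -1; a <= 2; ++a) {
      const double dwm = bspline3_d(zm[k] - (im + a));
      if (dwm == 0.0) continue;
      double inner = 0.0;
      for (int b = -1; b <= 2; ++b) {
        const double wf = bspline3(zf[k] - (jf + b));
        if (wf == 0.0) continue;
        const double Lj = -(std::log(std::max(p(im + a, jf + b), tiny)) + 1.0);
        inner += wf * ((Lm[im + a] + Lf[jf + b]) * Hj - (Hm + Hf) * Lj);
      }
      g += dwm * inner;
    }
    grad[k] = -g * scale * invn / Hj2;  // gradient of -NMI
  }
  return List::create(_["value"] = -nmi, _["grad"] = grad,
                      _["nmi"] = nmi, _["Hm"] = Hm, _["Hf"] = Hf, _["Hj"] = Hj);
}

// Separable convolution with symmetric (edge-replicating) reflection.
// kernel must be odd-length; normalised kernels conserve the image sum.
// [[Rcpp::export]]
NumericMatrix conv_sep_reflect_cpp(const NumericMatrix& img, const NumericVector& kernel) {
  const int ny = img.nrow(), nx = img.ncol(), kl = kernel.size(), h = kl / 2;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  auto reflect = [](int i, int nn) {
    while (i < 0 || i >= nn) { if (i < 0) i = -i - 1; if (i >= nn) i = 2 * nn - i - 1; }
    return i;
  };
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) acc += img(reflect(r + t, ny), c) * kernel[t + h];
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      double acc = 0.0;
      for (int t = -h; t <= h; ++t) acc += tmp(r, reflect(c + t, nx)) * kernel[t + h];
      out(r, c) = acc;
    }
  return out;
}
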