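// Geometric resampling kernels: trilinear / nearest-neighbour volume sampling
// at arbitrary world points, 2D warping for augmentation, 3D connected
// components for centroid detection, and the phantom voxel classifier.
//
// Conventions: volumes are R arrays with dim (nx, ny, nz), column-major;
// world position of voxel (i,j,k) is origin + (i,j,k) * spacing
// (voxel-centre convention, 0-based indices).
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double get3(const double* v, int nx, int ny, int i, int j, int k) {
  return v[i + (size_t)nx * (j + (size_t)ny * k)];
}

// Sample a 3D volume at world points (n x 3), trilinear or nearest.
// Points outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, bool nearest, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  const int n = pts.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double fx = (pts(p, 0) - origin[0]) / spacing[0];
    double fy = (pts(p, 1) - origin[1]) / spacing[1];
    double fz = (pts(p, 2) - origin[2]) / spacing[2];
    if (nearest) {
      int i = (int)std::lround(fx), j = (int)std::lround(fy), k = (int)std::lround(fz);
      out[p] = (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
                 ? fill : get3(v, nx, ny, i, j, k);
    } else {
      if (fx < 0 || fy < 0 || fz < 0 || fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
        out[p] = fill; continue;
      }
      int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
      int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
          k1 = std::min(k0 + 1, nz - 1);
      double dx = fx - i0, dy = fy - j0, dz = fz - k0;
      double c00 = get3(v, nx, ny, i0, j0, k0) * (1 - dx) + get3(v, nx, ny, i1, j0, k0) * dx;
      double c10 = get3(v, nx, ny, i0, j1, k0) * (1 - dx) + get3(v, nx, ny, i1, j1, k0) * dx;
      double c01 = get3(v, nx, ny, i0, j0, k1) * (1 - dx) + get3(v, nx, ny, i1, j0, k1) * dx;
      double c11 = get3(v, nx, ny, i0, j1, k1) * (1 - dx) + get3(v, nx, ny, i1, j1, k1) * dx;
      double c0 = c00 * (1 - dy) + c10 * dy;
      double c1 = c01 * (1 - dy) + c11 * dy;
      out[p] = c0 * (1 - dz) + c1 * dz;
    }
  }
  return out;
}

// Sample a 2D image at fractional pixel coordinates (same length vectors,
// 0-based), bilinear or nearest.  Out-of-range -> fill.
// [[Rcpp::export]]
NumericVector cpp_sample_image(NumericMatrix img, NumericVector sx,
                               NumericVector sy, bool nearest, double fill) {
  const int H = img.nrow(), W = img.ncol();
  const int n = sx.size();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double fx = sx[p], fy = sy[p];
    if (nearest) {
      int i = (int)std::lround(fx), j = (int)std::lround(fy);
      out[p] = (i < 0 || j < 0 || i >= H || j >= W) ? fill : img(i, j);
    } else {
      if (fx < 0 || fy < 0 || fx > H - 1 || fy > W - 1) { out[p] = fill; continue; }
      int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy);
      int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      double dx = fx - i0, dy = fy - j0;
      out[p] = img(i0, j0) * (1 - dx) * (1 - dy) + img(i1, j0) * dx * (1 - dy) +
               img(i0, j1) * (1 - dx) * dy + img(i1, j1) * dx * dy;
    }
  }
  return out;
}

// Separable Gaussian blur of a 2D image; kernel truncated at 3 sigma.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int t = -r; t <= r; ++t) { ker[t + r] = std::exp(-0.5 * t * t / (sigma * sigma)); s += ker[t + r]; }
  for (double& k : ker) k /= s;
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0;
      for (int t = -r; t <= r; ++t) {
        int ii = std::min(std::max(i + t, 0), H - 1);
        a += ker[t + r] * img(ii, j);
      }
      tmp(i, j) = a;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double a = 0;
      for (int t = -r; t <= r; ++t) {
        int jj = std::min(std::max(j + t, 0), W - 1);
        a += ker[t + r] * tmp(i, jj);
      }
      out(i, j) = a;
    }
  return out;
}

// 3D connected components (26-connectivity) of a logical mask.
// Returns an integer array of component labels (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(mask.size(), 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++cur;
    stack.push_back(start);
    lab[start] = cur;
    while (!stack.empty()) {
      size_t p = stack.back(); stack.pop_back();
      int i = p % nx, j = (p / nx) % ny, k = p / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
            size_t q = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Phantom voxel classifier.  For every voxel, find the closest point on the
// finely sampled spinal curve, express the voxel in the local
// rotation-minimizing frame (u = lateral, v = antero-posterior), and assign a
// region code from simple analytic shapes:
//   0 background, 1 bone (vertebral body), 2 dural sac,
//   3 disc posterior margin, 4 ligamentum flavum, 5 disc body (intensity only)
// The dural-sac ellipse has area A(s) (passed per curve sample), aspect ratio
// `aspect` (minor/major), centred at (0, canal_v) in the local frame.
// [[Rcpp::export]]
IntegerVector cpp_phantom_regions(IntegerVector dim, NumericVector spacing,
                                  NumericVector origin,
                                  NumericMatrix cpts,   // Ns x 3 curve samples
                                  NumericMatrix ce1,    // Ns x 3 frame axis u
                                  NumericMatrix ce2,    // Ns x 3 frame axis v
                                  NumericVector area_s, // Ns dural-sac area (mm2)
                                  LogicalVector in_vertebra, // Ns
                                  LogicalVector in_disc,     // Ns
                                  double body_a, double body_b,
                                  double canal_v, double aspect,
                                  double lig_thick, double margin_anterior_v) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int Ns = cpts.nrow();
  IntegerVector out((size_t)nx * ny * nz, 0);
  // nearest curve-sample index per z slice of the volume (curve z increasing)
  std::vector<int> zidx(nz);
  {
    int c = 0;
    for (int k = 0; k < nz; ++k) {
      double z = origin[2] + k * spacing[2];
      while (c + 1 < Ns && std::abs(cpts(c + 1, 2) - z) <= std::abs(cpts(c, 2) - z)) ++c;
      zidx[k] = c;
    }
  }
  const double rmax = std::max(body_a, body_b) + std::abs(canal_v) + lig_thick + 12.0;
  const int win = 60; // +-15 mm at 0.25 mm curve sampling
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing[2];
    int c0 = std::max(0, zidx[k] - win), c1 = std::min(Ns - 1, zidx[k] + win);
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing[1];
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + i * spacing[0];
        // quick reject on distance to the slice's curve point
        double dxq = x - cpts(zidx[k], 0), dyq = y - cpts(zidx[k], 1);
        if (dxq * dxq + dyq * dyq > rmax * rmax) continue;
        // closest curve sample in the window
        int best = c0; double bd = 1e30;
        for (int c = c0; c <= c1; ++c) {
          double dx = x - cpts(c, 0), dy = y - cpts(c, 1), dz = z - cpts(c, 2);
          double d = dx * dx + dy * dy + dz * dz;
          if (d < bd) { bd = d; best = c; }
        }
        double dx = x - cpts(best, 0), dy = y - cpts(best, 1), dz = z - cpts(best, 2);
        double u = dx * ce1(best, 0) + dy * ce1(best, 1) + dz * ce1(best, 2);
        double v = dx * ce2(best, 0) + dy * ce2(best, 1) + dz * ce2(best, 2);
        int code = 0;
        double body = (u / body_a) * (u / body_a) + (v / body_b) * (v / body_b);
        // dural-sac ellipse at this arc position
        double A = area_s[best];
        double a = std::sqrt(A / (M_PI * aspect)), b = aspect * a;
        double du = u / a, dv = (v - canal_v) / b;
        double sac = du * du + dv * dv;
        double ao = a + lig_thick, bo = b + lig_thick;
        double duo = u / ao, dvo = (v - canal_v) / bo;
        if (body <= 1.0) {
          // bone inside a vertebra, disc tissue between vertebrae,
          // background beyond the ends of the stack
          code = in_vertebra[best] ? 1 : (in_disc[best] ? 5 : 0);
        } else if (sac <= 1.0) {
          code = 2;                                 // dural sac
        } else if (duo * duo + dvo * dvo <= 1.0 && v < canal_v) {
          code = 4;                                 // ligamentum flavum
        } else if (in_disc[best] && std::abs(u) <= body_a * 0.8 &&
                   v < -0.999 * body_b + 1e-9 && v >= margin_anterior_v &&
                   v > canal_v + b) {
          code = 3;                                 // disc posterior margin
        }
        out[i + (size_t)nx * (j + (size_t)ny * k)] = code;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
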