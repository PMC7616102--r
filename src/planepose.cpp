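#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a column-major (nx, ny, nz) grid at continuous
// 0-based voxel coordinates. Points outside the grid return `fill`.
static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const double* p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Sample a volume at arbitrary physical (mm) points.
// [[Rcpp::export]]
NumericVector sample_volume_mm_cpp(NumericVector vol, IntegerVector dims,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix pts_mm, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts_mm.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = (pts_mm(i, 0) - origin[0]) / spacing[0];
    double y = (pts_mm(i, 1) - origin[1]) / spacing[1];
    double z = (pts_mm(i, 2) - origin[2]) / spacing[2];
    out[i] = trilinear(v, nx, ny, nz, x, y, z, fill);
  }
  return out;
}

// Extract a batch of plane slices. `poses` has one row per slice:
// (tx, ty, tz, R[1..9] column-major). Pixel (row j, col i) of slice s maps to
// normalized point t + u_i * R[,1] + v_j * R[,2] with u, v in [-extent, extent]
// at half-pixel centers; normalized -> mm via center + p * mm_per_unit.
// Returns a (size*size*n) vector, each slice column-major (row = y, col = x).
// [[Rcpp::export]]
NumericVector extract_slices_cpp(NumericVector vol, IntegerVector dims,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector center_mm, NumericVector mm_per_unit,
                                 NumericMatrix poses, int size_px, double extent,
                                 double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = poses.nrow();
  NumericVector out((R_xlen_t)size_px * size_px * n);
  const double* v = vol.begin();
  double step = 2.0 * extent / size_px;
  std::vector<double> uu(size_px);
  for (int i = 0; i < size_px; ++i) uu[i] = -extent + (i + 0.5) * step;
  for (int s = 0; s < n; ++s) {
    double tx = poses(s, 0), ty = poses(s, 1), tz = poses(s, 2);
    double e1x = poses(s, 3), e1y = poses(s, 4), e1z = poses(s, 5);
    double e2x = poses(s, 6), e2y = poses(s, 7), e2z = poses(s, 8);
    double* img = out.begin() + (R_xlen_t)s * size_px * size_px;
    for (int i = 0; i < size_px; ++i) {       // columns = in-plane x
      double u = uu[i];
      double bx = tx + u * e1x, by = ty + u * e1y, bz = tz + u * e1z;
      for (int j = 0; j < size_px; ++j) {     // rows = in-plane y
        double vv = uu[j];
        double px = bx + vv * e2x, py = by + vv * e2y, pz = bz + vv * e2z;
        double mx = center_mm[0] + px * mm_per_unit[0];
        double my = center_mm[1] + py * mm_per_unit[1];
        double mz = center_mm[2] + pz * mm_per_unit[2];
        img[(R_xlen_t)i * size_px + j] =
          trilinear(v, nx, ny, nz,
                    (mx - origin[0]) / spacing[0],
                    (my - origin[1]) / spacing[1],
                    (mz - origin[2]) / spacing[2], fill);
      }
    }
  }
  return out;
}

// Fraction of an `ng` x `ng` grid of plane sample points that fall inside the
// brain mask (mask > 0.5, nearest-voxel lookup).
// [[Rcpp::export]]
double slice_mask_fraction_cpp(NumericVector mask, IntegerVector dims,
                               NumericVector spacing, NumericVector origin,
                               NumericVector center_mm, NumericVector mm_per_unit,
                               NumericVector pose, double extent, int ng) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* m = mask.begin();
  double step = 2.0 * extent / ng;
  int inside = 0;
  for (int i = 0; i < ng; ++i) {
    double u = -extent + (i + 0.5) * step;
    for (int j = 0; j < ng; ++j) {
      double vv = -extent + (j + 0.5) * step;
      double px = pose[0] + u * pose[3] + vv * pose[6];
      double py = pose[1] + u * pose[4] + vv * pose[7];
      double pz = pose[2] + u * pose[5] + vv * pose[8];
      double x = (center_mm[0] + px * mm_per_unit[0] - origin[0]) / spacing[0];
      double y = (center_mm[1] + py * mm_per_unit[1] - origin[1]) / spacing[1];
      double z = (center_mm[2] + pz * mm_per_unit[2] - origin[2]) / spacing[2];
      int ix = (int)std::lround(x), iy = (int)std::lround(y), iz = (int)std::lround(z);
      if (ix >= 0 && iy >= 0 && iz >= 0 && ix < nx && iy < ny && iz < nz &&
          m[ix + (R_xlen_t)nx * iy + (R_xlen_t)nx * ny * iz] > 0.5)
        inside++;
    }
  }
  return (double)inside / (ng * ng);
}

// Resample a volume onto a reference grid under an affine point map
// x_src_mm = A %*% x_ref_mm + b (A column-major 3x3).
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  IntegerVector ref_dims, NumericVector ref_spacing,
                                  NumericVector ref_origin, NumericVector A,
                                  NumericVector b, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int rx = ref_dims[0], ry = ref_dims[1], rz = ref_dims[2];
  NumericVector out((R_xlen_t)rx * ry * rz);
  const double* v = vol.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < rz; ++k) {
    double zr = ref_origin[2] + k * ref_spacing[2];
    for (int j = 0; j < ry; ++j) {
      double yr = ref_origin[1] + j * ref_spacing[1];
      for (int i = 0; i < rx; ++i, ++idx) {
        double xr = ref_origin[0] + i * ref_spacing[0];
        double xs = A[0] * xr + A[3] * yr + A[6] * zr + b[0];
        double ys = A[1] * xr + A[4] * yr + A[7] * zr + b[1];
        double zs = A[2] * xr + A[5] * yr + A[8] * zr + b[2];
        out[idx] = trilinear(v, nx, ny, nz,
                             (xs - origin[0]) / spacing[0],
                             (ys - origin[1]) / spacing[1],
                             (zs - origin[2]) / spacing[2], fill);
      }
    }
  }
  return out;
}

// im2col for batched 2D convolution. Input `x` is an (H, W, C, N) array
// (column-major). Output matrix is (C*k*k) rows by (Ho*Wo*N) columns, with
// column order: image-major, then output column, then output row. Row order
// within a column: channel-major, then kernel column, then kernel row.
// Zero padding of width `pad` on all sides; out-of-range taps read as zero.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, IntegerVector dims, int k, int stride,
                         int pad) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int rows = C * k * k;
  R_xlen_t cols = (R_xlen_t)Ho * Wo * N;
  NumericMatrix out(rows, cols);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (R_xlen_t)n * planeHW * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        double* oc = op + col * rows;
        int h0 = ho * stride - pad, w0 = wo * stride - pad;
        int r = 0;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            int h = h0 + kh;
            if (h < 0 || w < 0 || h >= H || w >= W) {
              for (int c = 0; c < C; ++c, ++r) oc[r] = 0.0;
            } else {
              const double* base = xn + (R_xlen_t)w * H + h;
              for (int c = 0; c < C; ++c, ++r) {
                oc[r] = base[(R_xlen_t)c * planeHW];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add column gradients back onto the input array.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, IntegerVector dims, int k, int stride,
                         int pad) {
  int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  int rows = C * k * k;
  NumericVector out((R_xlen_t)H * W * C * N);
  double* xp = out.begin();
  const double* op = cols.begin();
  const R_xlen_t planeHW = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    double* xn = xp + (R_xlen_t)n * planeHW * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        R_xlen_t col = (R_xlen_t)n * Ho * Wo + (R_xlen_t)wo * Ho + ho;
        const double* oc = op + col * rows;
        int h0 = ho * stride - pad, w0 = wo * stride - pad;
        int r = 0;
        for (int kw = 0; kw < k; ++kw) {
          int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            int h = h0 + kh;
            if (h < 0 || w < 0 || h >= H || w >= W) {
              r += C;
            } else {
              double* base = xn + (R_xlen_t)w * H + h;
              for (int c = 0; c < C; ++c, ++r) {
                base[(R_xlen_t)c * planeHW] += oc[r];
              }
            }
          }
        }
      }
    }
  }
  return out;
}
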