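#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Volumes are NumericVector with dim = c(nx, ny, nz), column-major,
// voxel coordinates zero-based. Out-of-grid samples contribute 0.

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  size_t sxy = (size_t)nx * ny;
  const double* p000 = v + x0 + (size_t)nx * y0 + sxy * z0;
  double c00 = v[x0 + (size_t)nx * y0 + sxy * z0] * (1 - fx) +
               v[x1 + (size_t)nx * y0 + sxy * z0] * fx;
  double c10 = v[x0 + (size_t)nx * y1 + sxy * z0] * (1 - fx) +
               v[x1 + (size_t)nx * y1 + sxy * z0] * fx;
  double c01 = v[x0 + (size_t)nx * y0 + sxy * z1] * (1 - fx) +
               v[x1 + (size_t)nx * y0 + sxy * z1] * fx;
  double c11 = v[x0 + (size_t)nx * y1 + sxy * z1] * (1 - fx) +
               v[x1 + (size_t)nx * y1 + sxy * z1] * fx;
  (void)p000;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double bilinear(const double* m, int nr, int nc, double r,
                              double c) {
  if (r < 0 || c < 0 || r > nr - 1 || c > nc - 1) return 0.0;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 == nr - 1 && nr > 1) r0--;
  if (c0 == nc - 1 && nc > 1) c0--;
  double fr = r - r0, fc = c - c0;
  int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
  double v00 = m[r0 + (size_t)nr * c0], v10 = m[r1 + (size_t)nr * c0];
  double v01 = m[r0 + (size_t)nr * c1], v11 = m[r1 + (size_t)nr * c1];
  return (v00 * (1 - fr) + v10 * fr) * (1 - fc) +
         (v01 * (1 - fr) + v11 * fr) * fc;
}

// out[x] = in(A x + b) with x the zero-based output voxel coordinate.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, NumericMatrix A,
                             NumericVector b, IntegerVector out_dim) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vol.begin();
  double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  size_t idx = 0;
  for (int k = 0; k < oz; k++)
    for (int j = 0; j < oy; j++)
      for (int i = 0; i < ox; i++, idx++) {
        double sx = a00 * i + a01 * j + a02 * k + b[0];
        double sy = a10 * i + a11 * j + a12 * k + b[1];
        double sz = a20 * i + a21 * j + a22 * k + b[2];
        out[idx] = trilinear(v, nx, ny, nz, sx, sy, sz);
      }
  out.attr("dim") = out_dim;
  return out;
}

// Projection about the z axis at azimuth alpha (radians):
// img[a, t] = sum_s vol(cx + t' cos a - s' sin a, cy + t' sin a + s' cos a, a_z)
// with a the axial (z) index and t the transverse index; t' , s' centered.
// slab_half < 0 means full-depth projection.
// [[Rcpp::export]]
NumericMatrix cpp_project_z(NumericVector vol, double alpha, double slab_half) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  const double* v = vol.begin();
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  double ct = (nx - 1) / 2.0;
  int smax = (slab_half < 0) ? (std::max(nx, ny) / 2 + 1) : (int)std::floor(slab_half);
  double ca = std::cos(alpha), sa = std::sin(alpha);
  NumericMatrix img(nz, nx);
  for (int t = 0; t < nx; t++) {
    double tc = t - ct;
    for (int s = -smax; s <= smax; s++) {
      double x = cx + tc * ca - s * sa;
      double y = cy + tc * sa + s * ca;
      if (x < 0 || y < 0 || x > nx - 1 || y > ny - 1) continue;
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
      if (x0 == nx - 1 && nx > 1) x0--;
      if (y0 == ny - 1 && ny > 1) y0--;
      double fx = x - x0, fy = y - y0;
      int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
      double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
      double w01 = (1 - fx) * fy, w11 = fx * fy;
      size_t sxy = (size_t)nx * ny;
      for (int a = 0; a < nz; a++) {
        const double* sl = v + sxy * a;
        img(a, t) += w00 * sl[x0 + (size_t)nx * y0] + w10 * sl[x1 + (size_t)nx * y0] +
                     w01 * sl[x0 + (size_t)nx * y1] + w11 * sl[x1 + (size_t)nx * y1];
      }
    }
  }
  return img;
}

// Back-projection: smear each image (axial x transverse) into the volume at
// its azimuth about z. imgs dim = c(n_axial, n_trans, n_img).
// [[Rcpp::export]]
NumericVector cpp_backproject_z(NumericVector imgs, NumericVector alphas,
                                NumericVector weights, int nx, int ny) {
  IntegerVector d = imgs.attr("dim");
  int na = d[0], nt = d[1], nimg = d[2];
  int nz = na;
  NumericVector out((size_t)nx * ny * nz);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, ct = (nt - 1) / 2.0;
  for (int m = 0; m < nimg; m++) {
    const double* img = imgs.begin() + (size_t)na * nt * m;
    double ca = std::cos(alphas[m]), sa = std::sin(alphas[m]);
    double w = weights[m];
    size_t idx = 0;
    for (int k = 0; k < nz; k++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, idx++) {
          double t = (i - cx) * ca + (j - cy) * sa + ct;
          if (t < 0 || t > nt - 1) continue;
          int t0 = (int)std::floor(t);
          if (t0 == nt - 1 && nt > 1) t0--;
          double ft = t - t0;
          out[idx] += w * (img[k + (size_t)na * t0] * (1 - ft) +
                           img[k + (size_t)na * (t0 + 1)] * ft);
        }
  }
  IntegerVector od = IntegerVector::create(nx, ny, nz);
  out.attr("dim") = od;
  return out;
}

// out(x) = img(R_theta (x - c) + c + shift); theta in radians.
// [[Rcpp::export]]
NumericMatrix cpp_transform2d(NumericMatrix img, double theta,
                              NumericVector shift) {
  int nr = img.nrow(), nc = img.ncol();
  double cr = (nr - 1) / 2.0, cc = (nc - 1) / 2.0;
  double ct = std::cos(theta), st = std::sin(theta);
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      double r = ct * (i - cr) - st * (j - cc) + cr + shift[0];
      double c = st * (i - cr) + ct * (j - cc) + cc + shift[1];
      out(i, j) = bilinear(img.begin(), nr, nc, r, c);
    }
  return out;
}

static inline double dot_shifted(const double* img, const double* ref, int na,
                                 int nt, int dz, int dx) {
  // sum over ref support of ref[a,t] * img[a+dz, t+dx]
  double s = 0.0;
  int a0 = std::max(0, -dz), a1 = std::min(na, na - dz);
  int t0 = std::max(0, -dx), t1 = std::min(nt, nt - dx);
  for (int t = t0; t < t1; t++) {
    const double* rc = ref + (size_t)na * t;
    const double* ic = img + (size_t)na * (t + dx) + dz;
    for (int a = a0; a < a1; a++) s += rc[a] * ic[a];
  }
  return s;
}

// Exhaustive locally normalized correlation alignment of an image stack
// against a bank of reference images over integer shifts.
// stack: raw zero-mean images (na, nt, nimg); refs: window^2-weighted,
// window-norm-normalized references (na, nt, nref); w2: the squared
// apodization window (na, nt). Score(ref, dz, dx) =
//   sum(ref * shifted image) / sqrt(sum(w2 * shifted image^2)),
// i.e. NCC between the windowed reference and the windowed shifted image.
// Returns per image: best ref (1-based), dz, dx, score, and the scores at
// dz +/- 1 and dx +/- 1 for the winning reference (parabolic sub-voxel
// interpolation).
// penalty_z / penalty_x: quadratic translation-prior coefficients; the
// score is NCC - penalty_z*dz^2 - penalty_x*dx^2, anchoring
// shift-degenerate matches (smooth filament images) near the prior
// center without overriding real signal. The axial prior is typically
// stronger: segment centers come from the traced centerline.
// [[Rcpp::export]]
NumericMatrix cpp_cc_align(NumericVector stack, NumericVector refs,
                           IntegerVector dzs, IntegerVector dxs,
                           NumericVector w2, double penalty_z = 0.0,
                           double penalty_x = 0.0) {
  IntegerVector ds = stack.attr("dim");
  IntegerVector dr = refs.attr("dim");
  int na = ds[0], nt = ds[1], nimg = ds[2], nref = dr[2];
  int nz = dzs.size(), nx = dxs.size();
  NumericMatrix out(nimg, 8);
  std::vector<double> den(nz * nx);
  // squared image under the shifted window, per shift
  std::vector<double> img2((size_t)na * nt);
  auto pen = [&](int dz, int dx) {
    return penalty_z * (double)dz * dz + penalty_x * (double)dx * dx;
  };
  for (int m = 0; m < nimg; m++) {
    const double* img = stack.begin() + (size_t)na * nt * m;
    for (size_t p = 0; p < (size_t)na * nt; p++) img2[p] = img[p] * img[p];
    auto den_at = [&](int dz, int dx) {
      double s = dot_shifted(img2.data(), w2.begin(), na, nt, dz, dx);
      return std::sqrt(std::max(s, 1e-12));
    };
    for (int iz = 0; iz < nz; iz++)
      for (int ix = 0; ix < nx; ix++)
        den[iz * nx + ix] = den_at(dzs[iz], dxs[ix]);
    double best = -1e300;
    int bref = 0, bdz = 0, bdx = 0;
    for (int r = 0; r < nref; r++) {
      const double* ref = refs.begin() + (size_t)na * nt * r;
      for (int iz = 0; iz < nz; iz++)
        for (int ix = 0; ix < nx; ix++) {
          double s = dot_shifted(img, ref, na, nt, dzs[iz], dxs[ix]) /
                     den[iz * nx + ix] - pen(dzs[iz], dxs[ix]);
          if (s > best) {
            best = s;
            bref = r;
            bdz = dzs[iz];
            bdx = dxs[ix];
          }
        }
    }
    const double* ref = refs.begin() + (size_t)na * nt * bref;
    out(m, 0) = bref + 1;
    out(m, 1) = bdz;
    out(m, 2) = bdx;
    out(m, 3) = best;
    out(m, 4) = dot_shifted(img, ref, na, nt, bdz - 1, bdx) / den_at(bdz - 1, bdx) - pen(bdz - 1, bdx);
    out(m, 5) = dot_shifted(img, ref, na, nt, bdz + 1, bdx) / den_at(bdz + 1, bdx) - pen(bdz + 1, bdx);
    out(m, 6) = dot_shifted(img, ref, na, nt, bdz, bdx - 1) / den_at(bdz, bdx - 1) - pen(bdz, bdx - 1);
    out(m, 7) = dot_shifted(img, ref, na, nt, bdz, bdx + 1) / den_at(bdz, bdx + 1) - pen(bdz, bdx + 1);
  }
  return out;
}

// 26-connected component labelling of a 3D logical mask (ints 0/1).
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t p = 0; p < n; p++) {
    if (!mask[p] || lab[p]) continue;
    cur++;
    stack.push_back(p);
    lab[p] = cur;
    while (!stack.empty()) {
      size_t q = stack.back();
      stack.pop_back();
      int i = q % nx, j = (q / nx) % ny, k = q / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t qq = ii + (size_t)nx * jj + (size_t)nx * ny * kk;
            if (mask[qq] && !lab[qq]) {
              lab[qq] = cur;
              stack.push_back(qq);
            }
          }
    }
  }
  lab.attr("dim") = d;
  return lab;
}

// Accumulate rotated copies of a subunit density into a volume.
// pos: n x 3 zero-based voxel coordinates of subunit centers;
// rot: 3x3xn rotation matrices (reference -> placed copy).
// The subunit is sampled at R^T (x - pos) + c_sub.
// [[Rcpp::export]]
NumericVector cpp_render_subunits(IntegerVector dim, NumericVector sub,
                                  NumericMatrix pos, NumericVector rot) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector sd = sub.attr("dim");
  int sx = sd[0], sy = sd[1], sz = sd[2];
  double csx = (sx - 1) / 2.0, csy = (sy - 1) / 2.0, csz = (sz - 1) / 2.0;
  double rad = 0.5 * std::sqrt((double)sx * sx + (double)sy * sy + (double)sz * sz);
  NumericVector out((size_t)nx * ny * nz);
  const double* sv = sub.begin();
  int n = pos.nrow();
  for (int m = 0; m < n; m++) {
    const double* R = rot.begin() + 9 * m;
    double px = pos(m, 0), py = pos(m, 1), pz = pos(m, 2);
    int i0 = std::max(0, (int)std::floor(px - rad)),
        i1 = std::min(nx - 1, (int)std::ceil(px + rad));
    int j0 = std::max(0, (int)std::floor(py - rad)),
        j1 = std::min(ny - 1, (int)std::ceil(py + rad));
    int k0 = std::max(0, (int)std::floor(pz - rad)),
        k1 = std::min(nz - 1, (int)std::ceil(pz + rad));
    for (int k = k0; k <= k1; k++)
      for (int j = j0; j <= j1; j++)
        for (int i = i0; i <= i1; i++) {
          double dx = i - px, dy = j - py, dz = k - pz;
          // R^T d
          double ux = R[0] * dx + R[1] * dy + R[2] * dz + csx;
          double uy = R[3] * dx + R[4] * dy + R[5] * dz + csy;
          double uz = R[6] * dx + R[7] * dy + R[8] * dz + csz;
          double val = trilinear(sv, sx, sy, sz, ux, uy, uz);
          if (val != 0.0)
            out[i + (size_t)nx * j + (size_t)nx * ny * k] += val;
        }
  }
  out.attr("dim") = dim;
  return out;
}
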