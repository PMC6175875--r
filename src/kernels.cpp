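#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column-major, 0-based voxel coordinates throughout; x is the fastest axis.

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, double fill) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 < -1 || y0 < -1 || z0 < -1 || x0 > nx - 1 || y0 > ny - 1 || z0 > nz - 1)
    return fill;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) { continue; }
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        acc += wx * wy * wz * v[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      }
    }
  }
  return acc; // corners outside the grid contribute zero
}

// Resample a volume through an affine map: out(x) = in(M (x - c_out) + c_in + t)
// M is 3x3 (row-major as passed: m[0..8] with rows), t a 3-vector.
// [[Rcpp::export]]
NumericVector cpp_affine_resample(NumericVector vol, IntegerVector dims,
                                  NumericVector m, NumericVector t,
                                  NumericVector c_out, NumericVector c_in,
                                  double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int k = 0; k < nz; ++k) {
    double zc = k - c_out[2];
    for (int j = 0; j < ny; ++j) {
      double yc = j - c_out[1];
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        double xc = i - c_out[0];
        double xs = m[0] * xc + m[1] * yc + m[2] * zc + c_in[0] + t[0];
        double ys = m[3] * xc + m[4] * yc + m[5] * zc + c_in[1] + t[1];
        double zs = m[6] * xc + m[7] * yc + m[8] * zc + c_in[2] + t[2];
        o[base + i] = trilinear(v, nx, ny, nz, xs, ys, zs, fill);
      }
    }
  }
  return out;
}

// Extract a cubic box centred (with sub-voxel precision) at pos from a tomogram.
// [[Rcpp::export]]
NumericVector cpp_extract_box(NumericVector tomo, IntegerVector dims,
                              NumericVector pos, int box, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)box * box * box);
  const double *v = tomo.begin();
  double *o = out.begin();
  double half = box / 2.0; // box centre voxel index = box/2 for even boxes
  for (int k = 0; k < box; ++k)
    for (int j = 0; j < box; ++j)
      for (int i = 0; i < box; ++i) {
        double xs = pos[0] + (i - half);
        double ys = pos[1] + (j - half);
        double zs = pos[2] + (k - half);
        o[i + (size_t)box * (j + (size_t)box * k)] =
          trilinear(v, nx, ny, nz, xs, ys, zs, fill);
      }
  return out;
}

// Project a volume along z after rotating it about the y axis by `angle_deg`
// (specimen tilt). Output is nx x ny.
// [[Rcpp::export]]
NumericMatrix cpp_tilt_project(NumericVector vol, IntegerVector dims,
                               double angle_deg) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double a = angle_deg * M_PI / 180.0;
  double ca = std::cos(a), sa = std::sin(a);
  double cx = nx / 2.0, cy = ny / 2.0, cz = nz / 2.0;
  NumericMatrix out(nx, ny);
  const double *v = vol.begin();
  // ray length: diagonal in xz
  int nray = (int)std::ceil(std::sqrt((double)nx * nx + (double)nz * nz)) + 2;
  double z0 = -nray / 2.0;
  for (int j = 0; j < ny; ++j) {
    double ys = j; // y unchanged by rotation about y
    for (int i = 0; i < nx; ++i) {
      double xc = i - cx;
      double acc = 0.0;
      for (int r = 0; r < nray; ++r) {
        double zc = z0 + r;
        // sample rotated specimen: in(Ry(-a) (x,_,z))
        double xs = ca * xc - sa * zc + cx;
        double zs = sa * xc + ca * zc + cz;
        acc += trilinear(v, nx, ny, nz, xs, ys, zs, 0.0);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Back-project a stack of (filtered) tilt images into a volume.
// images: nx x ny x ntilt array; angles in degrees about the y axis.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector images, IntegerVector imdims,
                              NumericVector angles, IntegerVector outdims) {
  int inx = imdims[0], iny = imdims[1], nt = imdims[2];
  int nx = outdims[0], ny = outdims[1], nz = outdims[2];
  NumericVector out((size_t)nx * ny * nz);
  double *o = out.begin();
  const double *im = images.begin();
  double cx = nx / 2.0, cz = nz / 2.0;
  double icx = inx / 2.0;
  for (int t = 0; t < nt; ++t) {
    double a = angles[t] * M_PI / 180.0;
    double ca = std::cos(a), sa = std::sin(a);
    const double *img = im + (size_t)inx * iny * t;
    for (int k = 0; k < nz; ++k) {
      double zc = k - cz;
      for (int j = 0; j < ny; ++j) {
        if (j >= iny) continue;
        size_t base = (size_t)nx * (j + (size_t)ny * k);
        for (int i = 0; i < nx; ++i) {
          double xc = i - cx;
          // forward: image(x') samples specimen at Ry(-a); adjoint uses Ry(+a)...
          // pixel x' s.t. rotated specimen point projects there: x' = ca*xc + sa*zc
          double xp = ca * xc + sa * zc + icx;
          int x0 = (int)std::floor(xp);
          if (x0 < 0 || x0 >= inx - 1) continue;
          double fx = xp - x0;
          o[base + i] += (1.0 - fx) * img[x0 + (size_t)inx * j] +
                         fx * img[x0 + 1 + (size_t)inx * j];
        }
      }
    }
  }
  return out;
}

// Add (or max-composite) a rotated kernel into a target volume at `pos`.
// out(x) = target(x) op kernel(M (x - pos) + c_k) for x near pos.
// [[Rcpp::export]]
void cpp_stamp_kernel(NumericVector target, IntegerVector dims,
                      NumericVector kernel, IntegerVector kdims,
                      NumericVector m, NumericVector pos, double weight,
                      bool use_max) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int kx = kdims[0], ky = kdims[1], kz = kdims[2];
  double ckx = kx / 2.0, cky = ky / 2.0, ckz = kz / 2.0;
  const double *kv = kernel.begin();
  double *tv = target.begin();
  // bounding radius of the kernel after rotation
  double rad = 0.5 * std::sqrt((double)kx * kx + (double)ky * ky + (double)kz * kz);
  int x0 = std::max(0, (int)std::floor(pos[0] - rad));
  int x1 = std::min(nx - 1, (int)std::ceil(pos[0] + rad));
  int y0 = std::max(0, (int)std::floor(pos[1] - rad));
  int y1 = std::min(ny - 1, (int)std::ceil(pos[1] + rad));
  int z0 = std::max(0, (int)std::floor(pos[2] - rad));
  int z1 = std::min(nz - 1, (int)std::ceil(pos[2] + rad));
  for (int k = z0; k <= z1; ++k) {
    double zc = k - pos[2];
    for (int j = y0; j <= y1; ++j) {
      double yc = j - pos[1];
      for (int i = x0; i <= x1; ++i) {
        double xc = i - pos[0];
        double xs = m[0] * xc + m[1] * yc + m[2] * zc + ckx;
        double ys = m[3] * xc + m[4] * yc + m[5] * zc + cky;
        double zs = m[6] * xc + m[7] * yc + m[8] * zc + ckz;
        double val = weight * trilinear(kv, kx, ky, kz, xs, ys, zs, 0.0);
        size_t idx = i + (size_t)nx * (j + (size_t)ny * k);
        if (use_max) {
          if (val > tv[idx]) tv[idx] = val;
        } else {
          tv[idx] += val;
        }
      }
    }
  }
}

// Minimum distance from every voxel to a polyline given by axis points
// (3 x npts matrix, voxel units). Returns a volume of distances.
// [[Rcpp::export]]
NumericVector cpp_polyline_distance(IntegerVector dims, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int np = pts.ncol();
  NumericVector out((size_t)nx * ny * nz);
  double *o = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double px = i, py = j, pz = k;
        double best = R_PosInf;
        for (int s = 0; s + 1 < np; ++s) {
          double ax = pts(0, s), ay = pts(1, s), az = pts(2, s);
          double bx = pts(0, s + 1), by = pts(1, s + 1), bz = pts(2, s + 1);
          double dx = bx - ax, dy = by - ay, dz = bz - az;
          double len2 = dx * dx + dy * dy + dz * dz;
          double tt = 0.0;
          if (len2 > 0)
            tt = ((px - ax) * dx + (py - ay) * dy + (pz - az) * dz) / len2;
          if (tt < 0) tt = 0; else if (tt > 1) tt = 1;
          double qx = ax + tt * dx - px, qy = ay + tt * dy - py,
                 qz = az + tt * dz - pz;
          double d2 = qx * qx + qy * qy + qz * qz;
          if (d2 < best) best = d2;
        }
        o[i + (size_t)nx * (j + (size_t)ny * k)] = std::sqrt(best);
      }
  return out;
}

// Greedy duplicate suppression: indices sorted by descending score are kept
// unless within min_sep of an already-kept record. Returns keep flags.
// [[Rcpp::export]]
LogicalVector cpp_greedy_suppress(NumericMatrix xyz, NumericVector score,
                                  double min_sep) {
  int n = xyz.nrow();
  IntegerVector ord(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    return score[a] > score[b];
  });
  LogicalVector keep(n, false);
  std::vector<int> kept;
  double ms2 = min_sep * min_sep;
  for (int r = 0; r < n; ++r) {
    int i = idx[r];
    bool ok = true;
    for (int kv : kept) {
      double dx = xyz(i, 0) - xyz(kv, 0);
      double dy = xyz(i, 1) - xyz(kv, 1);
      double dz = xyz(i, 2) - xyz(kv, 2);
      if (dx * dx + dy * dy + dz * dz < ms2) { ok = false; break; }
    }
    if (ok) { keep[i] = true; kept.push_back(i); }
  }
  return keep;
}

// 26-connected component labelling of a binary volume (flood fill).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t p = stack.back(); stack.pop_back();
      int i = p % nx, j = (p / nx) % ny, k = p / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            size_t q = ii + (size_t)nx * (jj + (size_t)ny * kk);
            if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
          }
    }
  }
  return lab;
}
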