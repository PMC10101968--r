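#include <Rcpp.h>
#include <queue>
#include <map>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays in column-major order: idx = i + Lx*(j + Ly*k).
// Geometry: x = rotation axis (slice index i), y = flow axis (j),
// z = optical axis (k). Rotations act on the (y, z) plane only.

static inline double deg2rad(double d) { return d * M_PI / 180.0; }

// Rotate a volume about the x-axis by angle_deg (object rotation),
// bilinear interpolation in (y, z), out-of-volume filled with `fill`.
// [[Rcpp::export]]
NumericVector cpp_rotate_x(const NumericVector& vol, const IntegerVector& dim,
                           double angle_deg, double fill) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  const double cy = 0.5 * (Ly - 1), cz = 0.5 * (Lz - 1);
  const double co = std::cos(deg2rad(angle_deg)), si = std::sin(deg2rad(angle_deg));
  NumericVector out(vol.size());
  for (int k = 0; k < Lz; ++k) {
    const double zc = k - cz;
    for (int j = 0; j < Ly; ++j) {
      const double yc = j - cy;
      const double sy = co * yc + si * zc + cy;
      const double sz = -si * yc + co * zc + cz;
      const int j0 = (int)std::floor(sy), k0 = (int)std::floor(sz);
      const double wy = sy - j0, wz = sz - k0;
      const double w00 = (1 - wy) * (1 - wz), w10 = wy * (1 - wz),
                   w01 = (1 - wy) * wz,       w11 = wy * wz;
      const bool aj0 = j0 >= 0 && j0 < Ly, aj1 = j0 + 1 >= 0 && j0 + 1 < Ly;
      const bool ak0 = k0 >= 0 && k0 < Lz, ak1 = k0 + 1 >= 0 && k0 + 1 < Lz;
      double* op = &out[(R_xlen_t)Lx * (j + (R_xlen_t)Ly * k)];
      const double* v00 = (aj0 && ak0) ? &vol[(R_xlen_t)Lx * (j0     + (R_xlen_t)Ly * k0)]       : nullptr;
      const double* v10 = (aj1 && ak0) ? &vol[(R_xlen_t)Lx * (j0 + 1 + (R_xlen_t)Ly * k0)]       : nullptr;
      const double* v01 = (aj0 && ak1) ? &vol[(R_xlen_t)Lx * (j0     + (R_xlen_t)Ly * (k0 + 1))] : nullptr;
      const double* v11 = (aj1 && ak1) ? &vol[(R_xlen_t)Lx * (j0 + 1 + (R_xlen_t)Ly * (k0 + 1))] : nullptr;
      for (int i = 0; i < Lx; ++i) {
        double a = w00 * (v00 ? v00[i] : fill) + w10 * (v10 ? v10[i] : fill)
                 + w01 * (v01 ? v01[i] : fill) + w11 * (v11 ? v11[i] : fill);
        op[i] = a;
      }
    }
  }
  return out;
}

// Forward projection (straight-ray): rotate by each angle, then sum over z.
// Input is the RI-contrast volume (background 0). Output (Lx, Ly, A).
// [[Rcpp::export]]
NumericVector cpp_radon_x(const NumericVector& vol, const IntegerVector& dim,
                          const NumericVector& angles_deg) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  const int A = angles_deg.size();
  const double cy = 0.5 * (Ly - 1), cz = 0.5 * (Lz - 1);
  NumericVector out((R_xlen_t)Lx * Ly * A);
  for (int a = 0; a < A; ++a) {
    const double co = std::cos(deg2rad(angles_deg[a])),
                 si = std::sin(deg2rad(angles_deg[a]));
    for (int k = 0; k < Lz; ++k) {
      const double zc = k - cz;
      for (int j = 0; j < Ly; ++j) {
        const double yc = j - cy;
        const double sy = co * yc + si * zc + cy;
        const double sz = -si * yc + co * zc + cz;
        const int j0 = (int)std::floor(sy), k0 = (int)std::floor(sz);
        const double wy = sy - j0, wz = sz - k0;
        double w00 = (1 - wy) * (1 - wz), w10 = wy * (1 - wz),
               w01 = (1 - wy) * wz,       w11 = wy * wz;
        const bool aj0 = j0 >= 0 && j0 < Ly, aj1 = j0 + 1 >= 0 && j0 + 1 < Ly;
        const bool ak0 = k0 >= 0 && k0 < Lz, ak1 = k0 + 1 >= 0 && k0 + 1 < Lz;
        if (!aj0 || !ak0) w00 = 0;
        if (!aj1 || !ak0) w10 = 0;
        if (!aj0 || !ak1) w01 = 0;
        if (!aj1 || !ak1) w11 = 0;
        if (w00 == 0 && w10 == 0 && w01 == 0 && w11 == 0) continue;
        double* op = &out[(R_xlen_t)Lx * (j + (R_xlen_t)Ly * a)];
        const double* v00 = w00 ? &vol[(R_xlen_t)Lx * (j0     + (R_xlen_t)Ly * k0)]       : nullptr;
        const double* v10 = w10 ? &vol[(R_xlen_t)Lx * (j0 + 1 + (R_xlen_t)Ly * k0)]       : nullptr;
        const double* v01 = w01 ? &vol[(R_xlen_t)Lx * (j0     + (R_xlen_t)Ly * (k0 + 1))] : nullptr;
        const double* v11 = w11 ? &vol[(R_xlen_t)Lx * (j0 + 1 + (R_xlen_t)Ly * (k0 + 1))] : nullptr;
        for (int i = 0; i < Lx; ++i) {
          double s = 0;
          if (v00) s += w00 * v00[i];
          if (v10) s += w10 * v10[i];
          if (v01) s += w01 * v01[i];
          if (v11) s += w11 * v11[i];
          op[i] += s;
        }
      }
    }
  }
  return out;
}

// Backprojection of ramp-filtered sinograms. filt is (Lx, Ly, A) — per
// x-slice, the filtered 1D projections (detector axis = y) for each angle.
// A volume point (y, z) reads detector coordinate t = cy + cos*yc - sin*zc,
// matching the forward map of cpp_radon_x. Scaling (pi / A) applied here.
// [[Rcpp::export]]
NumericVector cpp_backproject_x(const NumericVector& filt, const IntegerVector& dim,
                                const NumericVector& angles_deg) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  const int A = angles_deg.size();
  const double cy = 0.5 * (Ly - 1), cz = 0.5 * (Lz - 1);
  NumericVector out((R_xlen_t)Lx * Ly * Lz);
  for (int a = 0; a < A; ++a) {
    const double co = std::cos(deg2rad(angles_deg[a])),
                 si = std::sin(deg2rad(angles_deg[a]));
    for (int k = 0; k < Lz; ++k) {
      const double zc = k - cz;
      for (int j = 0; j < Ly; ++j) {
        const double yc = j - cy;
        const double t = cy + co * yc - si * zc;
        const int t0 = (int)std::floor(t);
        const double wt = t - t0;
        const bool a0 = t0 >= 0 && t0 < Ly, a1 = t0 + 1 >= 0 && t0 + 1 < Ly;
        if (!a0 && !a1) continue;
        double* op = &out[(R_xlen_t)Lx * (j + (R_xlen_t)Ly * k)];
        const double* f0 = a0 ? &filt[(R_xlen_t)Lx * (t0     + (R_xlen_t)Ly * a)] : nullptr;
        const double* f1 = a1 ? &filt[(R_xlen_t)Lx * (t0 + 1 + (R_xlen_t)Ly * a)] : nullptr;
        for (int i = 0; i < Lx; ++i) {
          double s = 0;
          if (f0) s += (1 - wt) * f0[i];
          if (f1) s += wt * f1[i];
          op[i] += s;
        }
      }
    }
  }
  const double sc = M_PI / A;
  for (R_xlen_t n = 0; n < out.size(); ++n) out[n] *= sc;
  return out;
}

// Trilinear resize to new extents (pixel-center alignment).
// [[Rcpp::export]]
NumericVector cpp_resize3(const NumericVector& vol, const IntegerVector& dim,
                          const IntegerVector& newdim) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  const int Mx = newdim[0], My = newdim[1], Mz = newdim[2];
  const double sx = (double)Lx / Mx, sy = (double)Ly / My, sz = (double)Lz / Mz;
  NumericVector out((R_xlen_t)Mx * My * Mz);
  std::vector<int> xi0(Mx); std::vector<double> xw(Mx);
  for (int i = 0; i < Mx; ++i) {
    double s = (i + 0.5) * sx - 0.5;
    if (s < 0) s = 0; if (s > Lx - 1) s = Lx - 1;
    xi0[i] = std::min((int)std::floor(s), Lx - 2 >= 0 ? Lx - 2 : 0);
    xw[i] = s - xi0[i];
  }
  for (int k = 0; k < Mz; ++k) {
    double s = (k + 0.5) * sz - 0.5;
    if (s < 0) s = 0; if (s > Lz - 1) s = Lz - 1;
    int k0 = std::min((int)std::floor(s), Lz - 2 >= 0 ? Lz - 2 : 0);
    double wz = s - k0;
    for (int j = 0; j < My; ++j) {
      double sj = (j + 0.5) * sy - 0.5;
      if (sj < 0) sj = 0; if (sj > Ly - 1) sj = Ly - 1;
      int j0 = std::min((int)std::floor(sj), Ly - 2 >= 0 ? Ly - 2 : 0);
      double wy = sj - j0;
      const int j1 = std::min(j0 + 1, Ly - 1), k1 = std::min(k0 + 1, Lz - 1);
      const double* v00 = &vol[(R_xlen_t)Lx * (j0 + (R_xlen_t)Ly * k0)];
      const double* v10 = &vol[(R_xlen_t)Lx * (j1 + (R_xlen_t)Ly * k0)];
      const double* v01 = &vol[(R_xlen_t)Lx * (j0 + (R_xlen_t)Ly * k1)];
      const double* v11 = &vol[(R_xlen_t)Lx * (j1 + (R_xlen_t)Ly * k1)];
      double* op = &out[(R_xlen_t)Mx * (j + (R_xlen_t)My * k)];
      for (int i = 0; i < Mx; ++i) {
        const int i0 = xi0[i], i1 = std::min(i0 + 1, Lx - 1);
        const double wx = xw[i];
        const double c00 = v00[i0] * (1 - wx) + v00[i1] * wx;
        const double c10 = v10[i0] * (1 - wx) + v10[i1] * wx;
        const double c01 = v01[i0] * (1 - wx) + v01[i1] * wx;
        const double c11 = v11[i0] * (1 - wx) + v11[i1] * wx;
        op[i] = (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
                (c01 * (1 - wy) + c11 * wy) * wz;
      }
    }
  }
  return out;
}

// Symmetric gray-level co-occurrence counts. levels: 1..P on the support,
// 0 = ignore. Offset (dx, dy, dz) is in voxels (direction * distance).
// [[Rcpp::export]]
NumericMatrix cpp_glcm(const IntegerVector& levels, const IntegerVector& dim,
                       int P, int dx, int dy, int dz) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  NumericMatrix counts(P, P);
  for (int k = 0; k < Lz; ++k) {
    const int k2 = k + dz;
    if (k2 < 0 || k2 >= Lz) continue;
    for (int j = 0; j < Ly; ++j) {
      const int j2 = j + dy;
      if (j2 < 0 || j2 >= Ly) continue;
      const int* lv = &levels[(R_xlen_t)Lx * (j + (R_xlen_t)Ly * k)];
      const int* lw = &levels[(R_xlen_t)Lx * (j2 + (R_xlen_t)Ly * k2)];
      const int ilo = std::max(0, -dx), ihi = std::min(Lx, Lx - dx);
      for (int i = ilo; i < ihi; ++i) {
        const int v = lv[i], w = lw[i + dx];
        if (v > 0 && w > 0) {
          counts(v - 1, w - 1) += 1.0;
          counts(w - 1, v - 1) += 1.0;
        }
      }
    }
  }
  return counts;
}

static inline R_xlen_t vidx(int i, int j, int k, int Lx, int Ly) {
  return i + (R_xlen_t)Lx * (j + (R_xlen_t)Ly * k);
}

// Largest 6-connected component of a binary mask.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(const LogicalVector& mask, const IntegerVector& dim) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  const R_xlen_t n = mask.size();
  std::vector<int> lab(n, 0);
  int nlab = 0, best = 0; R_xlen_t bestsize = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++nlab; R_xlen_t size = 0;
    lab[s] = nlab; q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop(); ++size;
      int i = cur % Lx, j = (cur / Lx) % Ly, k = cur / ((R_xlen_t)Lx * Ly);
      const int di[6] = {-1, 1, 0, 0, 0, 0}, dj[6] = {0, 0, -1, 1, 0, 0},
                dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= Lx || jj < 0 || jj >= Ly || kk < 0 || kk >= Lz) continue;
        R_xlen_t t = vidx(ii, jj, kk, Lx, Ly);
        if (mask[t] && !lab[t]) { lab[t] = nlab; q.push(t); }
      }
    }
    if (size > bestsize) { bestsize = size; best = nlab; }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (lab[s] == best) && best > 0;
  return out;
}

// Fill interior holes: background flood-filled from the volume boundary;
// anything not reached and not foreground becomes foreground. For a
// single-slice (Lz == 1) input only the in-plane border seeds the flood,
// so the function behaves as a 2D hole fill.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(const LogicalVector& mask, const IntegerVector& dim) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  const R_xlen_t n = mask.size();
  std::vector<char> outside(n, 0);
  std::queue<R_xlen_t> q;
  for (int k = 0; k < Lz; ++k)
    for (int j = 0; j < Ly; ++j)
      for (int i = 0; i < Lx; ++i) {
        bool border = i == 0 || i == Lx - 1 || j == 0 || j == Ly - 1;
        if (Lz > 1) border = border || k == 0 || k == Lz - 1;
        if (border) {
          R_xlen_t s = vidx(i, j, k, Lx, Ly);
          if (!mask[s] && !outside[s]) { outside[s] = 1; q.push(s); }
        }
      }
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i = cur % Lx, j = (cur / Lx) % Ly, k = cur / ((R_xlen_t)Lx * Ly);
    const int di[6] = {-1, 1, 0, 0, 0, 0}, dj[6] = {0, 0, -1, 1, 0, 0},
              dk[6] = {0, 0, 0, 0, -1, 1};
    for (int m = 0; m < 6; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= Lx || jj < 0 || jj >= Ly || kk < 0 || kk >= Lz) continue;
      R_xlen_t t = vidx(ii, jj, kk, Lx, Ly);
      if (!mask[t] && !outside[t]) { outside[t] = 1; q.push(t); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = mask[s] || !outside[s];
  return out;
}

// One pass of 6-connected binary dilation (op = 1) or erosion (op = 0).
// Single-slice inputs use the in-plane 4-neighbourhood.
// [[Rcpp::export]]
LogicalVector cpp_binary_morph(const LogicalVector& mask, const IntegerVector& dim, int op) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  const int nnb = (Lz == 1) ? 4 : 6;
  LogicalVector out(mask.size());
  for (int k = 0; k < Lz; ++k)
    for (int j = 0; j < Ly; ++j)
      for (int i = 0; i < Lx; ++i) {
        R_xlen_t s = vidx(i, j, k, Lx, Ly);
        bool acc = mask[s];
        const int di[6] = {-1, 1, 0, 0, 0, 0}, dj[6] = {0, 0, -1, 1, 0, 0},
                  dk[6] = {0, 0, 0, 0, -1, 1};
        for (int m = 0; m < nnb; ++m) {
          int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
          bool nb;
          if (ii < 0 || ii >= Lx || jj < 0 || jj >= Ly || kk < 0 || kk >= Lz)
            nb = false;  // outside the box counts as background
          else
            nb = mask[vidx(ii, jj, kk, Lx, Ly)];
          if (op == 1) acc = acc || nb; else acc = acc && nb;
        }
        out[s] = acc;
      }
  return out;
}

// Separable Gaussian smoothing (reflective boundaries); works for 2D
// inputs by passing Lz = 1.
// [[Rcpp::export]]
NumericVector cpp_smooth3(const NumericVector& vol, const IntegerVector& dim, double sigma) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double ks = 0;
  for (int m = -r; m <= r; ++m) { kern[m + r] = std::exp(-0.5 * m * m / (sigma * sigma)); ks += kern[m + r]; }
  for (auto& v : kern) v /= ks;
  auto reflect = [](int i, int L) {
    while (i < 0 || i >= L) { if (i < 0) i = -i - 1; if (i >= L) i = 2 * L - i - 1; }
    return i;
  };
  NumericVector a = clone(vol), b(vol.size());
  // x pass (stride 1)
  for (int k = 0; k < Lz; ++k)
    for (int j = 0; j < Ly; ++j) {
      const double* src = &a[(R_xlen_t)Lx * (j + (R_xlen_t)Ly * k)];
      double* dst = &b[(R_xlen_t)Lx * (j + (R_xlen_t)Ly * k)];
      for (int i = 0; i < Lx; ++i) {
        double s = 0;
        if (i >= r && i + r < Lx) {
          for (int m = -r; m <= r; ++m) s += kern[m + r] * src[i + m];
        } else {
          for (int m = -r; m <= r; ++m) s += kern[m + r] * src[reflect(i + m, Lx)];
        }
        dst[i] = s;
      }
    }
  // y pass: for each (k, j) accumulate over taps with contiguous i runs
  std::fill(a.begin(), a.end(), 0.0);
  for (int k = 0; k < Lz; ++k)
    for (int j = 0; j < Ly; ++j) {
      double* dst = &a[(R_xlen_t)Lx * (j + (R_xlen_t)Ly * k)];
      for (int m = -r; m <= r; ++m) {
        const double wgt = kern[m + r];
        const double* src = &b[(R_xlen_t)Lx * (reflect(j + m, Ly) + (R_xlen_t)Ly * k)];
        for (int i = 0; i < Lx; ++i) dst[i] += wgt * src[i];
      }
    }
  if (Lz == 1) return a;
  // z pass
  std::fill(b.begin(), b.end(), 0.0);
  for (int k = 0; k < Lz; ++k)
    for (int j = 0; j < Ly; ++j) {
      double* dst = &b[(R_xlen_t)Lx * (j + (R_xlen_t)Ly * k)];
      for (int m = -r; m <= r; ++m) {
        const double wgt = kern[m + r];
        const double* src = &a[(R_xlen_t)Lx * (j + (R_xlen_t)Ly * reflect(k + m, Lz))];
        for (int i = 0; i < Lx; ++i) dst[i] += wgt * src[i];
      }
    }
  return b;
}

// Surface area (3D) or perimeter (2D, Lz = 1) of a binary mask via the
// coarea formula: smooth the indicator with a Gaussian of `sigma`
// voxels, integrate the central-difference gradient magnitude. Result
// is in voxel units (multiply by pitch^2 resp. pitch in the caller).
// [[Rcpp::export]]
double cpp_coarea(const LogicalVector& mask, const IntegerVector& dim, double sigma) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  NumericVector ind(mask.size());
  for (R_xlen_t s = 0; s < mask.size(); ++s) ind[s] = mask[s] ? 1.0 : 0.0;
  NumericVector u = cpp_smooth3(ind, dim, sigma);
  double acc = 0;
  for (int k = 0; k < Lz; ++k)
    for (int j = 0; j < Ly; ++j)
      for (int i = 0; i < Lx; ++i) {
        const R_xlen_t s = i + (R_xlen_t)Lx * (j + (R_xlen_t)Ly * k);
        double gx = 0, gy = 0, gz = 0;
        if (i > 0 && i < Lx - 1) gx = 0.5 * (u[s + 1] - u[s - 1]);
        if (j > 0 && j < Ly - 1) gy = 0.5 * (u[s + Lx] - u[s - Lx]);
        if (Lz > 1 && k > 0 && k < Lz - 1)
          gz = 0.5 * (u[s + (R_xlen_t)Lx * Ly] - u[s - (R_xlen_t)Lx * Ly]);
        acc += std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return acc;
}

// ---- incremental 3D convex hull (volume only) -------------------------

struct HFace {
  int a, b, c;
  double nx, ny, nz, off;  // outward plane: n . x = off
  bool alive;
};

static inline void face_plane(const std::vector<double>& px, const std::vector<double>& py,
                              const std::vector<double>& pz, HFace& f,
                              double ix, double iy, double iz) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nx = uy * vz - uz * vy; f.ny = uz * vx - ux * vz; f.nz = ux * vy - uy * vx;
  f.off = f.nx * px[f.a] + f.ny * py[f.a] + f.nz * pz[f.a];
  // flip so the interior point is on the negative side
  if (f.nx * ix + f.ny * iy + f.nz * iz > f.off) {
    std::swap(f.b, f.c);
    f.nx = -f.nx; f.ny = -f.ny; f.nz = -f.nz; f.off = -f.off;
  }
}

// Convex hull of a 3D point cloud. Returns the hull volume and the
// outward face planes (nx, ny, nz, off with n . x <= off inside, n unit
// length). Degenerate (coplanar / collinear) inputs give volume 0 and
// no planes.
// [[Rcpp::export]]
List cpp_convex_hull(const NumericMatrix& pts, double eps_abs = -1.0) {
  const int n = pts.nrow();
  if (n < 4) return List::create(_["volume"] = 0.0,
                                 _["planes"] = NumericMatrix(0, 4));
  std::vector<double> px(n), py(n), pz(n);
  double mx = -1e300, mn = 1e300;
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    for (int d = 0; d < 3; ++d) { mx = std::max(mx, pts(i, d)); mn = std::min(mn, pts(i, d)); }
  }
  const double eps = (eps_abs > 0) ? eps_abs : 1e-9 * std::max(1.0, mx - mn);
  // initial tetrahedron
  int i0 = 0;
  for (int i = 1; i < n; ++i) if (px[i] < px[i0]) i0 = i;
  int i1 = -1; double best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::pow(px[i] - px[i0], 2) + std::pow(py[i] - py[i0], 2) + std::pow(pz[i] - pz[i0], 2);
    if (d > best) { best = d; i1 = i; }
  }
  if (best < eps * eps) return List::create(_["volume"] = 0.0, _["planes"] = NumericMatrix(0, 4));
  double ax = px[i1] - px[i0], ay = py[i1] - py[i0], az = pz[i1] - pz[i0];
  int i2 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double bx = px[i] - px[i0], by = py[i] - py[i0], bz = pz[i] - pz[i0];
    double cx = ay * bz - az * by, cy = az * bx - ax * bz, cz = ax * by - ay * bx;
    double d = cx * cx + cy * cy + cz * cz;
    if (d > best) { best = d; i2 = i; }
  }
  if (best < eps * eps) return List::create(_["volume"] = 0.0, _["planes"] = NumericMatrix(0, 4));
  double bx = px[i2] - px[i0], by = py[i2] - py[i0], bz = pz[i2] - pz[i0];
  double nx0 = ay * bz - az * by, ny0 = az * bx - ax * bz, nz0 = ax * by - ay * bx;
  int i3 = -1; best = -1;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(nx0 * (px[i] - px[i0]) + ny0 * (py[i] - py[i0]) + nz0 * (pz[i] - pz[i0]));
    if (d > best) { best = d; i3 = i; }
  }
  double nrm = std::sqrt(nx0 * nx0 + ny0 * ny0 + nz0 * nz0);
  if (best / std::max(nrm, 1e-300) < eps) return List::create(_["volume"] = 0.0, _["planes"] = NumericMatrix(0, 4));
  const double ix = (px[i0] + px[i1] + px[i2] + px[i3]) / 4.0;
  const double iy = (py[i0] + py[i1] + py[i2] + py[i3]) / 4.0;
  const double iz = (pz[i0] + pz[i1] + pz[i2] + pz[i3]) / 4.0;
  std::vector<HFace> faces;
  auto add_face = [&](int a, int b, int c) {
    HFace f; f.a = a; f.b = b; f.c = c; f.alive = true;
    face_plane(px, py, pz, f, ix, iy, iz);
    faces.push_back(f);
  };
  add_face(i0, i1, i2); add_face(i0, i1, i3); add_face(i0, i2, i3); add_face(i1, i2, i3);
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double nn = std::sqrt(faces[f].nx * faces[f].nx + faces[f].ny * faces[f].ny + faces[f].nz * faces[f].nz);
      double d = (faces[f].nx * px[p] + faces[f].ny * py[p] + faces[f].nz * pz[p] - faces[f].off) / std::max(nn, 1e-300);
      if (d > eps) visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    std::map<std::pair<int, int>, int> edges;
    for (int f : visible) {
      int vs[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        int u = vs[e], v = vs[(e + 1) % 3];
        edges[{std::min(u, v), std::max(u, v)}]++;
      }
      faces[f].alive = false;
    }
    for (auto& kv : edges)
      if (kv.second == 1) add_face(kv.first.first, kv.first.second, p);
    // periodic compaction keeps the scan cheap
    if (faces.size() > 4096) {
      std::vector<HFace> keep;
      for (auto& f : faces) if (f.alive) keep.push_back(f);
      faces.swap(keep);
    }
  }
  double vol6 = 0;
  int nf = 0;
  for (auto& f : faces) if (f.alive) ++nf;
  NumericMatrix planes(nf, 4);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    double axx = px[f.a] - ix, ayy = py[f.a] - iy, azz = pz[f.a] - iz;
    double bxx = px[f.b] - ix, byy = py[f.b] - iy, bzz = pz[f.b] - iz;
    double cxx = px[f.c] - ix, cyy = py[f.c] - iy, czz = pz[f.c] - iz;
    vol6 += axx * (byy * czz - bzz * cyy) - ayy * (bxx * czz - bzz * cxx) + azz * (bxx * cyy - byy * cxx);
    double nn = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
    if (nn <= 0) nn = 1;
    planes(r, 0) = f.nx / nn; planes(r, 1) = f.ny / nn;
    planes(r, 2) = f.nz / nn; planes(r, 3) = f.off / nn;
    ++r;
  }
  return List::create(_["volume"] = std::fabs(vol6) / 6.0,
                      _["planes"] = planes);
}

// Count lattice points (1..Lx, 1..Ly, 1..Lz, matching R voxel indices)
// inside the hull given by outward unit-normal planes. Per (j, k) column
// the admissible i-range is the intersection of per-plane half-line
// bounds, so the cost is faces x columns, not faces x voxels.
// [[Rcpp::export]]
double cpp_hull_voxel_count(const NumericMatrix& planes, const IntegerVector& dim) {
  const int Lx = dim[0], Ly = dim[1], Lz = dim[2];
  const int F = planes.nrow();
  if (F == 0) return 0.0;
  const double eps = 1e-7;
  double count = 0;
  for (int k = 1; k <= Lz; ++k)
    for (int j = 1; j <= Ly; ++j) {
      double lo = 1, hi = Lx;
      bool empty = false;
      for (int f = 0; f < F && !empty; ++f) {
        const double nx = planes(f, 0), rest = planes(f, 1) * j + planes(f, 2) * k,
                     off = planes(f, 3) + eps;
        if (std::fabs(nx) < 1e-14) {
          if (rest > off) empty = true;
        } else if (nx > 0) {
          hi = std::min(hi, (off - rest) / nx);
        } else {
          lo = std::max(lo, (off - rest) / nx);
        }
      }
      if (!empty) {
        const double a = std::ceil(lo - 1e-9), b = std::floor(hi + 1e-9);
        if (b >= a) count += b - a + 1;
      }
    }
  return count;
}

// Rasterize an ellipsoidal cell body with nucleus and spherical
// inclusions into an RI-contrast bounding-box volume. gx/gy/gz are the
// physical coordinates (um) of the bbox lattice; rot is the 3x3
// orientation matrix (rows map world -> body frame); semi the body
// semi-axes (um); ns the nucleus scale factor; inc is an n x 4 matrix
// of inclusion centres (body frame, um) and radii. Returns dn values
// (0 outside the body) and the body mask.
// [[Rcpp::export]]
List cpp_phantom_fill(const NumericVector& gx, const NumericVector& gy,
                      const NumericVector& gz, const NumericMatrix& rot,
                      const NumericVector& semi, double mean_dn,
                      double ns, double nuc_offset,
                      const NumericMatrix& inc, double inc_offset) {
  const int Lx = gx.size(), Ly = gy.size(), Lz = gz.size();
  const R_xlen_t n = (R_xlen_t)Lx * Ly * Lz;
  NumericVector dn(n);
  LogicalVector body(n);
  const int ni = inc.nrow();
  for (int k = 0; k < Lz; ++k)
    for (int j = 0; j < Ly; ++j) {
      R_xlen_t base = (R_xlen_t)Lx * (j + (R_xlen_t)Ly * k);
      for (int i = 0; i < Lx; ++i) {
        const double x = gx[i], y = gy[j], z = gz[k];
        const double u = rot(0, 0) * x + rot(0, 1) * y + rot(0, 2) * z;
        const double v = rot(1, 0) * x + rot(1, 1) * y + rot(1, 2) * z;
        const double w = rot(2, 0) * x + rot(2, 1) * y + rot(2, 2) * z;
        const double q = (u / semi[0]) * (u / semi[0]) +
                         (v / semi[1]) * (v / semi[1]) +
                         (w / semi[2]) * (w / semi[2]);
        if (q > 1.0) continue;
        body[base + i] = true;
        double val = mean_dn;
        if (q <= ns * ns) val += nuc_offset;
        for (int m = 0; m < ni; ++m) {
          const double du = u - inc(m, 0), dv = v - inc(m, 1),
                       dw = w - inc(m, 2), r = inc(m, 3);
          if (du * du + dv * dv + dw * dw <= r * r) val += inc_offset;
        }
        dn[base + i] = val;
      }
    }
  return List::create(_["dn"] = dn, _["body"] = body);
}
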