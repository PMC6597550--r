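// Core voxel routines: 3D connected components, binary morphology,
// triangulated iso-surface area, and phantom air-pocket stamping.
//
// All volumes use R's column-major layout with dim = c(nz, ny, nx):
// linear index = z + nz*y + nz*ny*x, slice axis (leaf depth) fastest.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// ---------------------------------------------------------------------------
// Connected component labelling (6 or 26 connectivity), BFS with explicit
// stack; labels are 1..k in first-encounter order (z fastest, then y, then x).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims, int connectivity) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && m != 1) continue;
        offs.push_back({dz, dy, dx});
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] || labels[i]) continue;
        ++next;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back(); stack.pop_back();
          int cz = (int)(cur % nz);
          int cy = (int)((cur / nz) % ny);
          int cx = (int)(cur / ((R_xlen_t)nz * ny));
          for (auto &o : offs) {
            int zz = cz + o[0], yy = cy + o[1], xx = cx + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            R_xlen_t j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && !labels[j]) { labels[j] = next; stack.push_back(j); }
          }
        }
      }
  return labels;
}

// ---------------------------------------------------------------------------
// Ball structuring-element offsets for radius r (Euclidean).
static std::vector<std::array<int,3>> ball_offsets(double r) {
  std::vector<std::array<int,3>> offs;
  int ri = (int)std::floor(r);
  double r2 = r * r;
  for (int dz = -ri; dz <= ri; ++dz)
    for (int dy = -ri; dy <= ri; ++dy)
      for (int dx = -ri; dx <= ri; ++dx)
        if (dz*dz + dy*dy + dx*dx <= r2) offs.push_back({dz, dy, dx});
  return offs;
}

// Binary dilation (outside the volume treated as background).
// [[Rcpp::export(name = ".bin_dilate_cpp")]]
LogicalVector bin_dilate_cpp(LogicalVector mask, IntegerVector dims, double radius) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  auto offs = ball_offsets(radius);
  LogicalVector out(n, false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i]) continue;
        for (auto &o : offs) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          out[idx3(zz, yy, xx, nz, ny)] = true;
        }
      }
  return out;
}

// Binary erosion; voxels outside the volume are treated as foreground so
// that closing is border-preserving on full-field slabs.
// [[Rcpp::export(name = ".bin_erode_cpp")]]
LogicalVector bin_erode_cpp(LogicalVector mask, IntegerVector dims, double radius) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  auto offs = ball_offsets(radius);
  LogicalVector out(n, false);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i]) continue;
        bool keep = true;
        for (auto &o : offs) {
          int zz = z + o[0], yy = y + o[1], xx = x + o[2];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (!mask[idx3(zz, yy, xx, nz, ny)]) { keep = false; break; }
        }
        out[i] = keep;
      }
  return out;
}

// Per-slice 2D hole filling: background 4-connected to the slice border
// stays background, enclosed background becomes foreground.
// [[Rcpp::export(name = ".fill_holes_slices_cpp")]]
LogicalVector fill_holes_slices_cpp(LogicalVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out(clone(mask));
  std::vector<uint8_t> reach((size_t)ny * nx);
  std::vector<std::pair<int,int>> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool border = (y == 0 || y == ny - 1 || x == 0 || x == nx - 1);
        if (border && !mask[idx3(z, y, x, nz, ny)] && !reach[(size_t)y + (size_t)ny * x]) {
          reach[(size_t)y + (size_t)ny * x] = 1;
          stack.push_back({y, x});
          while (!stack.empty()) {
            auto [cy, cx] = stack.back(); stack.pop_back();
            const int dy4[4] = {-1, 1, 0, 0}, dx4[4] = {0, 0, -1, 1};
            for (int k = 0; k < 4; ++k) {
              int yy = cy + dy4[k], xx = cx + dx4[k];
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
              size_t p = (size_t)yy + (size_t)ny * xx;
              if (!reach[p] && !mask[idx3(z, yy, xx, nz, ny)]) {
                reach[p] = 1;
                stack.push_back({yy, xx});
              }
            }
          }
        }
      }
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (!mask[idx3(z, y, x, nz, ny)] && !reach[(size_t)y + (size_t)ny * x])
          out[idx3(z, y, x, nz, ny)] = true;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Triangulated iso-surface area of the tissue-airspace interface.
//
// The binary airspace mask is smoothed with a separable 3x3x3 box mean
// (replicate padding), then the 0.5 iso-surface is triangulated by marching
// tetrahedra (6 tetrahedra per cell, linear edge interpolation). Cells whose
// corners contain no tissue voxel are skipped, which excludes airspace
// interfaces with the background. Raw voxel faces (6-adjacency air|tissue
// pairs) are counted as a diagnostic.
static void box_smooth_axis(std::vector<double> &src, std::vector<double> &dst,
                            int nz, int ny, int nx, int axis) {
  // replicate padding at the ends
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int zm = z, zp = z, ym = y, yp = y, xm = x, xp = x;
        if (axis == 0) { zm = std::max(z - 1, 0); zp = std::min(z + 1, nz - 1); }
        if (axis == 1) { ym = std::max(y - 1, 0); yp = std::min(y + 1, ny - 1); }
        if (axis == 2) { xm = std::max(x - 1, 0); xp = std::min(x + 1, nx - 1); }
        R_xlen_t i = idx3(z, y, x, nz, ny);
        dst[i] = (src[idx3(zm, ym, xm, nz, ny)] + src[i] +
                  src[idx3(zp, yp, xp, nz, ny)]) / 3.0;
      }
}

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double w0 = u[1]*v[2]-u[2]*v[1], w1 = u[2]*v[0]-u[0]*v[2], w2 = u[0]*v[1]-u[1]*v[0];
  return 0.5 * std::sqrt(w0*w0 + w1*w1 + w2*w2);
}

// [[Rcpp::export(name = ".surface_area_mt_cpp")]]
List surface_area_mt_cpp(LogicalVector air, LogicalVector tissue, IntegerVector dims,
                         bool smooth) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (air.size() != n || tissue.size() != n) stop("mask length does not match dims");

  std::vector<double> f(n), tmp(n);
  for (R_xlen_t i = 0; i < n; ++i) f[i] = air[i] ? 1.0 : 0.0;
  if (smooth) {
    box_smooth_axis(f, tmp, nz, ny, nx, 0);
    box_smooth_axis(tmp, f, nz, ny, nx, 1);
    box_smooth_axis(f, tmp, nz, ny, nx, 2);
    f.swap(tmp);
  }

  // cube corner offsets (z, y, x) and the 6-tetra decomposition around 0-6
  static const int CORNER[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int TETS[6][4] = {
    {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}};
  const double iso = 0.5;

  double total = 0.0;
  R_xlen_t ntri = 0;
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        double v[8];
        bool anyIn = false, allIn = true, anyTissue = false;
        for (int c = 0; c < 8; ++c) {
          R_xlen_t i = idx3(z + CORNER[c][0], y + CORNER[c][1], x + CORNER[c][2], nz, ny);
          v[c] = f[i];
          if (v[c] > iso) anyIn = true; else allIn = false;
          if (tissue[i]) anyTissue = true;
        }
        if (!anyIn || allIn || !anyTissue) continue;

        for (int t = 0; t < 6; ++t) {
          double tv[4]; double P[4][3];
          int nin = 0; int in_id[4], out_id[4]; int nout = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = TETS[t][c];
            tv[c] = v[cc];
            P[c][0] = z + CORNER[cc][0];
            P[c][1] = y + CORNER[cc][1];
            P[c][2] = x + CORNER[cc][2];
            if (tv[c] > iso) in_id[nin++] = c; else out_id[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          auto interp = [&](int a, int b, double out[3]) {
            double tt = (iso - tv[a]) / (tv[b] - tv[a]);
            for (int k = 0; k < 3; ++k) out[k] = P[a][k] + tt * (P[b][k] - P[a][k]);
          };
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in_id[0] : out_id[0];
            double p[3][3]; int m = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == apex) continue;
              interp(apex, c, p[m]); ++m;
            }
            total += tri_area(p[0], p[1], p[2]);
            ++ntri;
          } else { // 2 in, 2 out: quad split into two triangles
            int a = in_id[0], b = in_id[1], c = out_id[0], d = out_id[1];
            double p1[3], p2[3], p3[3], p4[3];
            interp(a, c, p1); interp(a, d, p2); interp(b, d, p3); interp(b, c, p4);
            total += tri_area(p1, p2, p3) + tri_area(p1, p3, p4);
            ntri += 2;
          }
        }
      }

  // raw voxel-face diagnostic: 6-adjacent air | tissue pairs
  R_xlen_t faces = 0;
  const int DZ[3] = {1, 0, 0}, DY[3] = {0, 1, 0}, DX[3] = {0, 0, 1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!air[i]) continue;
        for (int k = 0; k < 3; ++k) {
          for (int s = -1; s <= 1; s += 2) {
            int zz = z + s * DZ[k], yy = y + s * DY[k], xx = x + s * DX[k];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            if (tissue[idx3(zz, yy, xx, nz, ny)]) ++faces;
          }
        }
      }

  return List::create(_["area_voxel_units"] = total,
                      _["n_triangles"] = (double)ntri,
                      _["voxel_faces"] = (double)faces);
}

// ---------------------------------------------------------------------------
// Deficit-driven stamping of spherical air pockets into a label volume.
//
// labels: 0 background, 1 adaxial epidermis, 2 abaxial epidermis,
//         3 mesophyll tissue, 4 airspace.
// target_air: desired airspace voxel count per slice; pockets are stamped at
// the slice with the largest remaining deficit until every deficit drops
// below tol (voxels) or no further progress is possible. Sphere centres stay
// `margin` voxels away from the y/x borders; spheres are clipped to the
// mesophyll depth band [z0, z1] so the epidermis is never cut. Uses R's RNG.
// [[Rcpp::export(name = ".stamp_pockets_cpp")]]
List stamp_pockets_cpp(IntegerVector labels_in, IntegerVector dims,
                       NumericVector target_air, int z0, int z1,
                       double rmin, double rmax, int margin, double tol,
                       int max_iter) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector labels(clone(labels_in));
  std::vector<double> air(nz, 0.0);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        if (labels[idx3(z, y, x, nz, ny)] == 4) air[z] += 1.0;

  RNGScope scope;
  int placed = 0, iter = 0, stale = 0;
  const int stale_cap = 5000;
  while (iter < max_iter) {
    ++iter;
    // slice with largest deficit
    int zb = -1; double best = tol;
    for (int z = z0; z <= z1; ++z) {
      double d = target_air[z] - air[z];
      if (d > best) { best = d; zb = z; }
    }
    if (zb < 0) break;

    double r = rmin + unif_rand() * (rmax - rmin);
    // shrink the pocket until its per-slice cross-sections fit the remaining
    // deficits of every slice it touches; keeps converged slices from
    // overshooting their target (endgame pockets degrade to single voxels)
    const double allow = 12.0;
    while (r > 1.0) {
      bool fits = true;
      int ri_chk = (int)std::floor(r);
      for (int dz = -ri_chk; dz <= ri_chk && fits; ++dz) {
        int z = zb + dz;
        if (z < z0 || z > z1) continue;
        double cross = M_PI * (r * r - (double)dz * dz);
        if (cross > (target_air[z] - air[z]) + allow) fits = false;
      }
      if (fits) break;
      r -= 1.0;
    }
    if (r < 1.0) r = 1.0;
    int cy = margin + (int)std::floor(unif_rand() * (ny - 2 * margin));
    int cx = margin + (int)std::floor(unif_rand() * (nx - 2 * margin));
    if (cy > ny - 1 - margin) cy = ny - 1 - margin;
    if (cx > nx - 1 - margin) cx = nx - 1 - margin;

    int ri = (int)std::floor(r);
    double r2 = r * r;
    int added = 0;
    for (int dz = -ri; dz <= ri; ++dz) {
      int z = zb + dz;
      if (z < z0 || z > z1) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int y = cy + dy;
        if (y < margin || y > ny - 1 - margin) continue;
        for (int dx = -ri; dx <= ri; ++dx) {
          int x = cx + dx;
          if (x < margin || x > nx - 1 - margin) continue;
          if (dz*dz + dy*dy + dx*dx > r2) continue;
          R_xlen_t i = idx3(z, y, x, nz, ny);
          if (labels[i] == 3) {
            labels[i] = 4;
            air[z] += 1.0;
            ++added;
          }
        }
      }
    }
    if (added > 0) { ++placed; stale = 0; } else { ++stale; if (stale > stale_cap) break; }
  }

  return List::create(_["labels"] = labels, _["iterations"] = iter,
                      _["placed"] = placed);
}
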