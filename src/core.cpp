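#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Parallel-beam forward projection (Joseph's method) of a z-stack.
// vol: (nx, ny, nz) column-major; rotation axis = z.
// Returns (n_det, nz) line integrals in units of pixel length.
// Ray for detector bin d: points (cx + t*c - u*s, cy + t*s + u*c),
// t = d - cdet, direction (-s, c) with c = cos(theta), s = sin(theta).
// [[Rcpp::export]]
NumericMatrix cpp_project(NumericVector vol, int nx, int ny, int nz,
                          double theta, int n_det) {
  NumericMatrix out(n_det, nz);
  const double c = std::cos(theta), s = std::sin(theta);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double cdet = (n_det - 1) / 2.0;
  const double *v = vol.begin();
  const int nxy = nx * ny;

  if (std::fabs(c) >= std::fabs(s)) {
    // drive along y
    const double w = 1.0 / std::fabs(c);
    for (int d = 0; d < n_det; ++d) {
      const double t = d - cdet;
      for (int y = 0; y < ny; ++y) {
        // u from y, then x
        const double u = (y - cy - t * s) / c;
        const double x = cx + t * c - u * s;
        const int x0 = (int)std::floor(x);
        if (x0 < -1 || x0 > nx - 1) continue;
        const double fx = x - x0;
        const double w0 = w * (1.0 - fx), w1 = w * fx;
        const int base = nx * y;
        if (x0 >= 0 && x0 <= nx - 1 && x0 + 1 <= nx - 1) {
          for (int z = 0; z < nz; ++z) {
            const double *p = v + base + nxy * z + x0;
            out(d, z) += w0 * p[0] + w1 * p[1];
          }
        } else if (x0 == -1) {
          for (int z = 0; z < nz; ++z)
            out(d, z) += w1 * v[base + nxy * z + 0];
        } else { // x0 == nx-1
          for (int z = 0; z < nz; ++z)
            out(d, z) += w0 * v[base + nxy * z + x0];
        }
      }
    }
  } else {
    // drive along x
    const double w = 1.0 / std::fabs(s);
    for (int d = 0; d < n_det; ++d) {
      const double t = d - cdet;
      for (int x = 0; x < nx; ++x) {
        const double u = (cx + t * c - x) / s;
        const double y = cy + t * s + u * c;
        const int y0 = (int)std::floor(y);
        if (y0 < -1 || y0 > ny - 1) continue;
        const double fy = y - y0;
        const double w0 = w * (1.0 - fy), w1 = w * fy;
        if (y0 >= 0 && y0 + 1 <= ny - 1) {
          for (int z = 0; z < nz; ++z) {
            const double *p = v + nxy * z + x;
            out(d, z) += w0 * p[nx * y0] + w1 * p[nx * (y0 + 1)];
          }
        } else if (y0 == -1) {
          for (int z = 0; z < nz; ++z)
            out(d, z) += w1 * v[nxy * z + x];
        } else {
          for (int z = 0; z < nz; ++z)
            out(d, z) += w0 * v[nxy * z + x + nx * y0];
        }
      }
    }
  }
  return out;
}

// Backprojection of filtered sinograms for a whole stack.
// filt: (n_det, n_angles, nz); angles in radians; center_offset in pixels
// added to the detector midpoint. Returns (nx, ny, nz) (no angular scaling).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector filt, int n_det, int n_angles,
                              int nz, NumericVector angles, int nx, int ny,
                              double center_offset) {
  NumericVector out(R_xlen_t(nx) * ny * nz);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double cdet = (n_det - 1) / 2.0 + center_offset;
  const double *q = filt.begin();
  double *o = out.begin();
  const int nxy = nx * ny;
  for (int a = 0; a < n_angles; ++a) {
    const double c = std::cos(angles[a]), s = std::sin(angles[a]);
    for (int z = 0; z < nz; ++z) {
      const double *qa = q + n_det * (a + (R_xlen_t)n_angles * z);
      double *oz = o + (R_xlen_t)nxy * z;
      for (int y = 0; y < ny; ++y) {
        const double ty = (y - cy) * s + cdet;
        double *row = oz + nx * y;
        for (int x = 0; x < nx; ++x) {
          const double t = (x - cx) * c + ty;
          const int i0 = (int)std::floor(t);
          if (i0 < 0 || i0 >= n_det - 1) continue;
          const double f = t - i0;
          row[x] += qa[i0] * (1.0 - f) + qa[i0 + 1] * f;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Project two aligned volumes (delta and beta grids) in one geometry pass.
// [[Rcpp::export]]
List cpp_project2(NumericVector volA, NumericVector volB, int nx, int ny,
                  int nz, double theta, int n_det) {
  NumericMatrix outA(n_det, nz), outB(n_det, nz);
  const double c = std::cos(theta), s = std::sin(theta);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double cdet = (n_det - 1) / 2.0;
  const double *va = volA.begin(), *vb = volB.begin();
  const int nxy = nx * ny;
  const bool drive_y = std::fabs(c) >= std::fabs(s);
  const double w = 1.0 / std::max(std::fabs(c), std::fabs(s));
  const int nd = drive_y ? ny : nx;
  for (int d = 0; d < n_det; ++d) {
    const double t = d - cdet;
    for (int k = 0; k < nd; ++k) {
      double pos;
      int base_stride, step_stride, p0;
      if (drive_y) {
        const double u = (k - cy - t * s) / c;
        pos = cx + t * c - u * s;
        step_stride = 1;
        base_stride = nx * k;
      } else {
        const double u = (cx + t * c - k) / s;
        pos = cy + t * s + u * c;
        step_stride = nx;
        base_stride = k;
      }
      const int i0 = (int)std::floor(pos);
      const int lim = drive_y ? nx : ny;
      if (i0 < -1 || i0 > lim - 1) continue;
      const double f = pos - i0;
      const double w0 = w * (1.0 - f), w1 = w * f;
      if (i0 >= 0 && i0 + 1 <= lim - 1) {
        p0 = base_stride + i0 * step_stride;
        for (int z = 0; z < nz; ++z) {
          const R_xlen_t off = (R_xlen_t)nxy * z + p0;
          outA(d, z) += w0 * va[off] + w1 * va[off + step_stride];
          outB(d, z) += w0 * vb[off] + w1 * vb[off + step_stride];
        }
      } else if (i0 == -1) {
        p0 = base_stride;
        for (int z = 0; z < nz; ++z) {
          const R_xlen_t off = (R_xlen_t)nxy * z + p0;
          outA(d, z) += w1 * va[off];
          outB(d, z) += w1 * vb[off];
        }
      } else {
        p0 = base_stride + i0 * step_stride;
        for (int z = 0; z < nz; ++z) {
          const R_xlen_t off = (R_xlen_t)nxy * z + p0;
          outA(d, z) += w0 * va[off];
          outB(d, z) += w0 * vb[off];
        }
      }
    }
  }
  return List::create(Named("A") = outA, Named("B") = outB);
}

// ---- 3D squared Euclidean distance transform (Felzenszwalb-Huttenlocher) --

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zb, int n) {
  int k = 0;
  v[0] = 0;
  zb[0] = -HUGE_VAL;
  zb[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double sp;
    while (true) {
      sp = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
           (2.0 * q - 2.0 * v[k]);
      if (sp <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = sp;
    zb[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// mask: logical (nx,ny,nz). Returns squared distance (in voxels) of each
// foreground voxel to the nearest background voxel centre; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, int nx, int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // large finite sentinel instead of INF: the lower-envelope intersection
  // arithmetic must stay NaN-free for all-foreground rows
  const double BIG = 1e9;
  NumericVector g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  const int nxy = nx * ny;
  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double *row = g.begin() + (R_xlen_t)nxy * z + nx * y;
      for (int x = 0; x < nx; ++x) f[x] = row[x];
      dt1d(f, d, v, zb, nx);
      for (int x = 0; x < nx; ++x) row[x] = d[x];
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      double *col = g.begin() + (R_xlen_t)nxy * z + x;
      for (int y = 0; y < ny; ++y) f[y] = col[nx * y];
      dt1d(f, d, v, zb, ny);
      for (int y = 0; y < ny; ++y) col[nx * y] = d[y];
    }
  // along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double *col = g.begin() + nx * y + x;
      for (int z = 0; z < nz; ++z) f[z] = col[(R_xlen_t)nxy * z];
      dt1d(f, d, v, zb, nz);
      for (int z = 0; z < nz; ++z) col[(R_xlen_t)nxy * z] = d[z];
    }
  g.attr("dim") = IntegerVector::create(nx, ny, nz);
  return g;
}

// Distance-ridge voxels: foreground voxels whose EDT is >= all 26 neighbours.
// [[Rcpp::export]]
LogicalVector cpp_edt_ridge(NumericVector edt, LogicalVector mask,
                            int nx, int ny, int nz) {
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int nxy = nx * ny;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t i = x + nx * y + (R_xlen_t)nxy * z;
        if (!mask[i]) continue;
        const double e = edt[i];
        bool ridge = true;
        for (int dz = -1; dz <= 1 && ridge; ++dz)
          for (int dy = -1; dy <= 1 && ridge; ++dy)
            for (int dx = -1; dx <= 1 && ridge; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              if (edt[X + nx * Y + (R_xlen_t)nxy * Z] > e + 1e-9) ridge = false;
            }
        out[i] = ridge;
      }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Local thickness by sphere painting from ridge voxels.
// radius[i] = sqrt(edt_sq) at candidate centres (0 => not a centre).
// Each mask voxel v covered by a sphere (centre c, radius r(c)) receives
// diameter 2*r(c) - 1 voxels (the -1 converts centre-to-centre distance to
// an inscribed width in voxel units; a one-voxel line gets diameter 1).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector radius, LogicalVector mask,
                                  int nx, int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const int nxy = nx * ny;
  std::vector<R_xlen_t> idx;
  for (R_xlen_t i = 0; i < n; ++i)
    if (radius[i] > 0) idx.push_back(i);
  std::sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    return radius[a] > radius[b];
  });
  for (R_xlen_t ci : idx) {
    const double r = radius[ci];
    const double dia = 2.0 * r - 1.0;
    const int x0 = ci % nx, y0 = (ci / nx) % ny, z0 = ci / nxy;
    const int R = (int)std::floor(r);
    const double r2 = r * r + 1e-9;
    for (int dz = -R; dz <= R; ++dz) {
      const int Z = z0 + dz;
      if (Z < 0 || Z >= nz) continue;
      for (int dy = -R; dy <= R; ++dy) {
        const int Y = y0 + dy;
        if (Y < 0 || Y >= ny) continue;
        const double d2yz = (double)dz * dz + (double)dy * dy;
        if (d2yz > r2) continue;
        const int Rx = (int)std::floor(std::sqrt(r2 - d2yz));
        for (int dx = -Rx; dx <= Rx; ++dx) {
          const int X = x0 + dx;
          if (X < 0 || X >= nx) continue;
          const R_xlen_t j = X + nx * Y + (R_xlen_t)nxy * Z;
          if (mask[j] && out[j] < dia) out[j] = dia;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// 26-connected component labelling of a 3D logical mask (BFS).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int nx, int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  const int nxy = nx * ny;
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    stack.clear();
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      const R_xlen_t j = stack.back();
      stack.pop_back();
      const int x = j % nx, y = (j / nx) % ny, z = j / nxy;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
              continue;
            const R_xlen_t k = X + nx * Y + (R_xlen_t)nxy * Z;
            if (mask[k] && !lab[k]) {
              lab[k] = cur;
              stack.push_back(k);
            }
          }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}

// Stamp spheres along sampled centreline points into a logical grid,
// restricted to `allowed`; returns the linear indices (1-based) of newly
// set voxels.  Stamping halts once `target` newly set voxels fall inside
// `count_mask`, so a density target can be hit with voxel-level
// granularity.  cx, cy, cz in voxel coordinates (0-based centres), r in
// voxels.
// [[Rcpp::export]]
IntegerVector cpp_stamp_spheres(NumericVector cxs, NumericVector cys,
                                NumericVector czs, NumericVector rs,
                                LogicalVector occupied, LogicalVector allowed,
                                int nx, int ny, int nz,
                                Nullable<LogicalVector> count_mask,
                                double target) {
  const int nxy = nx * ny;
  std::vector<int> hit;
  const int np = cxs.size();
  LogicalVector cmask;
  const bool has_cmask = count_mask.isNotNull();
  if (has_cmask) cmask = count_mask.get();
  double counted = 0;
  for (int p = 0; p < np && counted < target; ++p) {
    const double r = std::max(rs[p], 0.5);
    const double r2 = r * r;
    const int x0 = (int)std::lround(cxs[p]), y0 = (int)std::lround(cys[p]),
              z0 = (int)std::lround(czs[p]);
    const int R = (int)std::ceil(r);
    for (int dz = -R; dz <= R; ++dz) {
      const int Z = z0 + dz;
      if (Z < 0 || Z >= nz) continue;
      const double zz = (z0 + dz - czs[p]);
      for (int dy = -R; dy <= R; ++dy) {
        const int Y = y0 + dy;
        if (Y < 0 || Y >= ny) continue;
        const double yy = (y0 + dy - cys[p]);
        for (int dx = -R; dx <= R; ++dx) {
          const int X = x0 + dx;
          if (X < 0 || X >= nx) continue;
          const double xx = (x0 + dx - cxs[p]);
          if (xx * xx + yy * yy + zz * zz > r2) continue;
          const R_xlen_t j = X + nx * Y + (R_xlen_t)nxy * Z;
          if (allowed[j] && !occupied[j]) {
            occupied[j] = true;
            hit.push_back((int)(j + 1));
            if (has_cmask ? cmask[j] : true) {
              counted += 1;
              if (counted >= target) break;
            }
          }
        }
        if (counted >= target) break;
      }
      if (counted >= target) break;
    }
  }
  return wrap(hit);
}
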