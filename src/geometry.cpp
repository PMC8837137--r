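#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---- small vector helpers -------------------------------------------------

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline void sub3(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}

// Closest point q on triangle (a, b, c) to p; returns squared distance.
// Ericson's region walk; vertex, edge and face cases all handled.
static double tri_closest(const double* p, const double* a, const double* b,
                          const double* c, double* q) {
  double ab[3], ac[3], ap[3];
  sub3(b, a, ab); sub3(c, a, ac); sub3(p, a, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3];
    sub3(p, b, bp);
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    double cp[3];
    sub3(p, c, cp);
    double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
    double vc = d1 * d4 - d3 * d2;
    double vb = d5 * d2 - d1 * d6;
    double va = d3 * d6 - d5 * d4;
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      double v = d1 / (d1 - d3);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k];
    } else if (d6 >= 0.0 && d5 <= d6) {
      q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
    } else if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
      double w = d2 / (d2 - d6);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ac[k];
    } else if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int k = 0; k < 3; ++k) q[k] = b[k] + w * (c[k] - b[k]);
    } else {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, w = vc * denom;
      for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k] + w * ac[k];
    }
  }
  double r[3] = { p[0] - q[0], p[1] - q[1], p[2] - q[2] };
  return dot3(r, r);
}

// ---- uniform grid over triangles for nearest-surface queries ---------------

struct TriGrid {
  const NumericMatrix& V;
  const IntegerMatrix& F;
  double lo[3], cell;
  int gd[3];
  std::vector<std::vector<int>> bins;
  std::vector<int> stamp;
  int generation;

  TriGrid(const NumericMatrix& vertices, const IntegerMatrix& faces)
    : V(vertices), F(faces), generation(0) {
    double hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int i = 0; i < V.nrow(); ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], V(i, k));
        hi[k] = std::max(hi[k], V(i, k));
      }
    double ext = 0.0;
    for (int k = 0; k < 3; ++k) ext = std::max(ext, hi[k] - lo[k]);
    int nf = F.nrow();
    // aim for O(1) triangles per cell without exploding the bin count
    double target = std::cbrt((double)std::max(nf, 1));
    cell = std::max(ext / std::min(64.0, target * 2.0), 1e-9);
    for (int k = 0; k < 3; ++k) {
      gd[k] = std::max(1, (int)std::floor((hi[k] - lo[k]) / cell) + 1);
      gd[k] = std::min(gd[k], 128);
    }
    bins.resize((size_t)gd[0] * gd[1] * gd[2]);
    stamp.assign(nf, -1);
    for (int f = 0; f < nf; ++f) {
      int cmin[3], cmax[3];
      for (int k = 0; k < 3; ++k) {
        double tlo = R_PosInf, thi = R_NegInf;
        for (int j = 0; j < 3; ++j) {
          double v = V(F(f, j), k);
          tlo = std::min(tlo, v); thi = std::max(thi, v);
        }
        cmin[k] = clampc((int)std::floor((tlo - lo[k]) / cell), k);
        cmax[k] = clampc((int)std::floor((thi - lo[k]) / cell), k);
      }
      for (int iz = cmin[2]; iz <= cmax[2]; ++iz)
        for (int iy = cmin[1]; iy <= cmax[1]; ++iy)
          for (int ix = cmin[0]; ix <= cmax[0]; ++ix)
            bins[idx(ix, iy, iz)].push_back(f);
    }
  }

  int clampc(int c, int k) const { return std::max(0, std::min(c, gd[k] - 1)); }
  size_t idx(int ix, int iy, int iz) const {
    return (size_t)ix + (size_t)gd[0] * (iy + (size_t)gd[1] * iz);
  }

  void scan_cell(int ix, int iy, int iz, const double* p, double& best2,
                 double* bestq) {
    const std::vector<int>& bin = bins[idx(ix, iy, iz)];
    double q[3], a[3], b[3], c[3];
    for (size_t t = 0; t < bin.size(); ++t) {
      int f = bin[t];
      if (stamp[f] == generation) continue;
      stamp[f] = generation;
      for (int k = 0; k < 3; ++k) {
        a[k] = V(F(f, 0), k); b[k] = V(F(f, 1), k); c[k] = V(F(f, 2), k);
      }
      double d2 = tri_closest(p, a, b, c, q);
      if (d2 < best2) {
        best2 = d2;
        bestq[0] = q[0]; bestq[1] = q[1]; bestq[2] = q[2];
      }
    }
  }

  // nearest surface point to p; returns squared distance
  double query(const double* p, double* bestq) {
    ++generation;
    int cc[3];
    double dout2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      cc[k] = clampc((int)std::floor((p[k] - lo[k]) / cell), k);
      double lok = lo[k] + cc[k] * cell, hik = lok + cell;
      double d = (p[k] < lok) ? lok - p[k] : (p[k] > hik ? p[k] - hik : 0.0);
      dout2 += d * d;
    }
    double dout = std::sqrt(dout2);
    double best2 = R_PosInf;
    int rmax = gd[0] + gd[1] + gd[2];
    for (int r = 0; r <= rmax; ++r) {
      double lb = std::max(dout, (r - 1) * cell);
      if (best2 < lb * lb) break;
      int xlo = cc[0] - r, xhi = cc[0] + r;
      int ylo = cc[1] - r, yhi = cc[1] + r;
      int zlo = cc[2] - r, zhi = cc[2] + r;
      for (int iz = std::max(0, zlo); iz <= std::min(gd[2] - 1, zhi); ++iz)
        for (int iy = std::max(0, ylo); iy <= std::min(gd[1] - 1, yhi); ++iy)
          for (int ix = std::max(0, xlo); ix <= std::min(gd[0] - 1, xhi); ++ix) {
            int ch = std::max(std::abs(ix - cc[0]),
                              std::max(std::abs(iy - cc[1]), std::abs(iz - cc[2])));
            if (ch != r) continue;
            scan_cell(ix, iy, iz, p, best2, bestq);
          }
    }
    return best2;
  }
};

// Unsigned distance from each query point to the nearest triangle of the
// mesh. Exact (grid-accelerated).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix points, NumericMatrix vertices,
                                      IntegerMatrix faces) {
  if (faces.nrow() == 0) stop("mesh has no faces");
  TriGrid grid(vertices, faces);
  const int np = points.nrow();
  NumericVector out(np);
  double q[3];
  for (int i = 0; i < np; ++i) {
    double p[3] = { points(i, 0), points(i, 1), points(i, 2) };
    out[i] = std::sqrt(grid.query(p, q));
  }
  return out;
}

// Closest point on the mesh surface for each query point (exact,
// grid-accelerated).
// [[Rcpp::export]]
NumericMatrix cpp_closest_points_on_mesh(NumericMatrix points,
                                         NumericMatrix vertices,
                                         IntegerMatrix faces) {
  if (faces.nrow() == 0) stop("mesh has no faces");
  TriGrid grid(vertices, faces);
  const int np = points.nrow();
  NumericMatrix out(np, 3);
  double q[3];
  for (int i = 0; i < np; ++i) {
    double p[3] = { points(i, 0), points(i, 1), points(i, 2) };
    grid.query(p, q);
    out(i, 0) = q[0]; out(i, 1) = q[1]; out(i, 2) = q[2];
  }
  return out;
}

// ---- ray-parity inside tests ----------------------------------------------

// Crossing heights of a vertical (+z) ray at (x, y) with the mesh.
// Returns false when the ray passes within eps of an edge/vertex or hits a
// near-degenerate projected triangle: callers must jitter and retry.
static bool ray_crossings(double x, double y, const NumericMatrix& vertices,
                          const IntegerMatrix& faces, double eps,
                          std::vector<double>& zs,
                          const std::vector<int>* subset = 0) {
  zs.clear();
  const int nf = subset ? (int)subset->size() : faces.nrow();
  for (int fi = 0; fi < nf; ++fi) {
    int f = subset ? (*subset)[fi] : fi;
    int i0 = faces(f, 0), i1 = faces(f, 1), i2 = faces(f, 2);
    double ax = vertices(i0, 0), ay = vertices(i0, 1), az = vertices(i0, 2);
    double bx = vertices(i1, 0), by = vertices(i1, 1), bz = vertices(i1, 2);
    double cx = vertices(i2, 0), cy = vertices(i2, 1), cz = vertices(i2, 2);
    double lox = std::min(ax, std::min(bx, cx)), hix = std::max(ax, std::max(bx, cx));
    double loy = std::min(ay, std::min(by, cy)), hiy = std::max(ay, std::max(by, cy));
    if (x < lox - eps || x > hix + eps || y < loy - eps || y > hiy + eps) continue;

    double s1 = (bx - ax) * (y - ay) - (by - ay) * (x - ax);
    double s2 = (cx - bx) * (y - by) - (cy - by) * (x - bx);
    double s3 = (ax - cx) * (y - cy) - (ay - cy) * (x - cx);
    double area2 = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    double scale = std::max(std::abs(area2), 1e-300);
    double tol = eps * std::sqrt(scale);
    bool pos = s1 > tol && s2 > tol && s3 > tol;
    bool neg = s1 < -tol && s2 < -tol && s3 < -tol;
    bool near_edge = std::abs(s1) <= tol || std::abs(s2) <= tol || std::abs(s3) <= tol;
    if (near_edge) {
      // only a problem if the point could plausibly touch the triangle
      double inside_ish = std::min(std::min(s1, s2), s3);
      double max_s = std::max(std::max(s1, s2), s3);
      if (!(inside_ish > tol) && !(max_s < -tol)) return false;
    }
    if (!pos && !neg) continue;
    // barycentric z of the intersection
    double w0 = s2 / area2, w1 = s3 / area2, w2 = s1 / area2;
    zs.push_back(w0 * az + w1 * bz + w2 * cz);
  }
  if (zs.size() % 2 != 0) return false;
  std::sort(zs.begin(), zs.end());
  return true;
}

// Voxelize a closed mesh on a regular grid: a voxel is inside iff its center
// is inside the surface (vertical-ray parity; degenerate columns are retried
// with a deterministic epsilon jitter).
// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix vertices, IntegerMatrix faces,
                           NumericVector origin, NumericVector spacing,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector vol(nx * ny * (R_xlen_t)nz);
  std::vector<double> zs;
  double base_eps = 1e-9 * std::max(spacing[0], std::max(spacing[1], spacing[2]));

  // bin triangles by the grid columns their xy bounding box (plus a jitter
  // margin) covers, so each column only tests nearby triangles
  std::vector<std::vector<int>> colbins((size_t)nx * ny);
  double margin = 0.3 * std::max(spacing[0], spacing[1]);
  for (int f = 0; f < faces.nrow(); ++f) {
    double lox = R_PosInf, hix = R_NegInf, loy = R_PosInf, hiy = R_NegInf;
    for (int j = 0; j < 3; ++j) {
      double vx = vertices(faces(f, j), 0), vy = vertices(faces(f, j), 1);
      lox = std::min(lox, vx); hix = std::max(hix, vx);
      loy = std::min(loy, vy); hiy = std::max(hiy, vy);
    }
    int cx0 = std::max(0, (int)std::ceil((lox - margin - origin[0]) / spacing[0]));
    int cx1 = std::min(nx - 1, (int)std::floor((hix + margin - origin[0]) / spacing[0]));
    int cy0 = std::max(0, (int)std::ceil((loy - margin - origin[1]) / spacing[1]));
    int cy1 = std::min(ny - 1, (int)std::floor((hiy + margin - origin[1]) / spacing[1]));
    for (int iy = cy0; iy <= cy1; ++iy)
      for (int ix = cx0; ix <= cx1; ++ix)
        colbins[ix + (size_t)nx * iy].push_back(f);
  }

  for (int iy = 0; iy < ny; ++iy) {
    double y = origin[1] + iy * spacing[1];
    for (int ix = 0; ix < nx; ++ix) {
      double x = origin[0] + ix * spacing[0];
      const std::vector<int>& bin = colbins[ix + (size_t)nx * iy];
      if (bin.empty()) continue;
      bool ok = ray_crossings(x, y, vertices, faces, base_eps, zs, &bin);
      int tries = 0;
      while (!ok && tries < 8) {
        ++tries;
        double eps = std::min(spacing[0], spacing[1]) * 1e-9 * std::pow(10.0, tries);
        double jx = x + eps * 0.7548776662466927;
        double jy = y + eps * 0.5698402909980532;
        ok = ray_crossings(jx, jy, vertices, faces, base_eps, zs, &bin);
      }
      if (!ok) continue;  // give up on a pathological column: leave empty
      size_t k = 0;
      for (int iz = 0; iz < nz && k < zs.size(); ++iz) {
        double z = origin[2] + iz * spacing[2];
        while (k < zs.size() && zs[k] < z) ++k;
        if (k < zs.size() && (k % 2) == 1)
          vol[ix + nx * (iy + (R_xlen_t)ny * iz)] = 1;
      }
    }
  }
  vol.attr("dim") = dims;
  return vol;
}

// Parity inside test for arbitrary points (vertical ray, jitter on ties).
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix points, NumericMatrix vertices,
                                 IntegerMatrix faces) {
  const int np = points.nrow();
  LogicalVector out(np);
  std::vector<double> zs;
  double base_eps = 1e-12;
  for (int i = 0; i < np; ++i) {
    double x = points(i, 0), y = points(i, 1), z = points(i, 2);
    bool ok = ray_crossings(x, y, vertices, faces, base_eps, zs);
    int tries = 0;
    while (!ok && tries < 12) {
      ++tries;
      double eps = std::pow(10.0, tries) * 1e-9;
      ok = ray_crossings(x + eps * 0.7548776662466927,
                         y + eps * 0.5698402909980532, vertices, faces,
                         base_eps, zs);
    }
    if (!ok) { out[i] = NA_LOGICAL; continue; }
    int below = 0;
    for (size_t k = 0; k < zs.size(); ++k) if (zs[k] < z) ++below;
    out[i] = (below % 2) == 1;
  }
  return out;
}

// ---- farthest-point sampling ----------------------------------------------

// Greedy farthest-point subsampling of a point cloud. Deterministic given the
// (1-based) start index; ties resolved to the lowest index.
// [[Rcpp::export]]
IntegerVector cpp_farthest_point_sampling(NumericMatrix points, int n, int start) {
  const int np = points.nrow();
  if (n > np) stop("cannot sample more points than available");
  IntegerVector sel(n);
  std::vector<double> mind2(np, R_PosInf);
  int cur = start - 1;
  sel[0] = cur + 1;
  for (int k = 1; k < n; ++k) {
    double px = points(cur, 0), py = points(cur, 1), pz = points(cur, 2);
    int best = -1;
    double bestd = -1.0;
    for (int i = 0; i < np; ++i) {
      double dx = points(i, 0) - px, dy = points(i, 1) - py, dz = points(i, 2) - pz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mind2[i]) mind2[i] = d2;
      if (mind2[i] > bestd) { bestd = mind2[i]; best = i; }
    }
    cur = best;
    sel[k] = cur + 1;
  }
  return sel;
}

// ---- CPD E-step ------------------------------------------------------------

// E-step sufficient statistics of rigid CPD: data X (N x 3), transformed
// centroids TY (M x 3), Gaussian variance sigma2, uniform outlier weight w
// spread over the reference measure `outlier_volume` (the standard choice is
// N, the data count). Returns Pt1 (N), P1 (M), PX (M x 3) and the
// observed-data log-likelihood.
//
// Kernels below exp(-45) cannot affect the sums at double precision, so
// pairs farther apart than sqrt(90 sigma2) are skipped; once that radius is
// small compared to the cloud extent, a uniform point grid over TY restricts
// the scan to nearby pairs.
// [[Rcpp::export]]
List cpp_cpd_estep(NumericMatrix X, NumericMatrix TY, double sigma2, double w,
                   double outlier_volume) {
  const int N = X.nrow(), M = TY.nrow();
  NumericVector Pt1(N), P1(M);
  NumericMatrix PX(M, 3);
  double c = 0.0;
  if (w > 0.0)
    c = std::pow(2.0 * M_PI * sigma2, 1.5) * (w / (1.0 - w)) * (double)M / outlier_volume;
  double inv2s2 = 1.0 / (2.0 * sigma2);
  double d2cut = 90.0 * sigma2;
  double radius = std::sqrt(d2cut);
  double loglik = 0.0;
  double lognorm = -1.5 * std::log(2.0 * M_PI * sigma2) - std::log((double)M);

  // bounding box of TY
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int m = 0; m < M; ++m)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], TY(m, k));
      hi[k] = std::max(hi[k], TY(m, k));
    }
  double ext = 0.0;
  for (int k = 0; k < 3; ++k) ext = std::max(ext, hi[k] - lo[k]);

  std::vector<int> cand(M);
  std::vector<double> ev(M);

  bool use_grid = radius < 0.25 * ext;
  std::vector<std::vector<int>> bins;
  int gd[3] = {1, 1, 1};
  double cell = radius;
  if (use_grid) {
    for (int k = 0; k < 3; ++k) {
      gd[k] = std::max(1, (int)std::floor((hi[k] - lo[k]) / cell) + 1);
      if (gd[k] > 128) { use_grid = false; break; }
    }
  }
  if (use_grid) {
    bins.resize((size_t)gd[0] * gd[1] * gd[2]);
    for (int m = 0; m < M; ++m) {
      int cx = std::min(gd[0] - 1, std::max(0, (int)std::floor((TY(m, 0) - lo[0]) / cell)));
      int cy = std::min(gd[1] - 1, std::max(0, (int)std::floor((TY(m, 1) - lo[1]) / cell)));
      int cz = std::min(gd[2] - 1, std::max(0, (int)std::floor((TY(m, 2) - lo[2]) / cell)));
      bins[cx + (size_t)gd[0] * (cy + (size_t)gd[1] * cz)].push_back(m);
    }
  }

  for (int n = 0; n < N; ++n) {
    double x0 = X(n, 0), x1 = X(n, 1), x2 = X(n, 2);
    int nc = 0;
    double sum = 0.0;
    if (use_grid) {
      int cx = (int)std::floor((x0 - lo[0]) / cell);
      int cy = (int)std::floor((x1 - lo[1]) / cell);
      int cz = (int)std::floor((x2 - lo[2]) / cell);
      for (int iz = std::max(0, cz - 1); iz <= std::min(gd[2] - 1, cz + 1); ++iz)
        for (int iy = std::max(0, cy - 1); iy <= std::min(gd[1] - 1, cy + 1); ++iy)
          for (int ix = std::max(0, cx - 1); ix <= std::min(gd[0] - 1, cx + 1); ++ix) {
            const std::vector<int>& bin = bins[ix + (size_t)gd[0] * (iy + (size_t)gd[1] * iz)];
            for (size_t t = 0; t < bin.size(); ++t) {
              int m = bin[t];
              double d0 = x0 - TY(m, 0), d1 = x1 - TY(m, 1), d2 = x2 - TY(m, 2);
              double d2sum = d0 * d0 + d1 * d1 + d2 * d2;
              if (d2sum > d2cut) continue;
              double v = std::exp(-d2sum * inv2s2);
              cand[nc] = m; ev[nc] = v; ++nc;
              sum += v;
            }
          }
    } else {
      for (int m = 0; m < M; ++m) {
        double d0 = x0 - TY(m, 0), d1 = x1 - TY(m, 1), d2 = x2 - TY(m, 2);
        double d2sum = d0 * d0 + d1 * d1 + d2 * d2;
        if (d2sum > d2cut) continue;
        double v = std::exp(-d2sum * inv2s2);
        cand[nc] = m; ev[nc] = v; ++nc;
        sum += v;
      }
    }
    double denom = sum + c;
    if (denom <= 0.0) { Pt1[n] = 0.0; continue; }
    Pt1[n] = sum / denom;
    double inv = 1.0 / denom;
    for (int t = 0; t < nc; ++t) {
      if (ev[t] == 0.0) continue;
      double p = ev[t] * inv;
      int m = cand[t];
      P1[m] += p;
      PX(m, 0) += p * x0;
      PX(m, 1) += p * x1;
      PX(m, 2) += p * x2;
    }
    loglik += std::log(denom) + lognorm;
  }
  return List::create(_["Pt1"] = Pt1, _["P1"] = P1, _["PX"] = PX,
                      _["loglik"] = loglik);
}

// ---- fully compiled ICP refinement -----------------------------------------

// Largest-eigenvalue eigenvector of a symmetric 4x4 matrix by cyclic Jacobi.
static void sym4_max_eigvec(double A[4][4], double v[4]) {
  double V[4][4] = {{1,0,0,0},{0,1,0,0},{0,0,1,0},{0,0,0,1}};
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 4; ++p)
      for (int q = p + 1; q < 4; ++q) off += A[p][q] * A[p][q];
    if (off < 1e-26) break;
    for (int p = 0; p < 4; ++p)
      for (int q = p + 1; q < 4; ++q) {
        if (std::abs(A[p][q]) < 1e-30) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::abs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 4; ++k) {
          double akp = A[k][p], akq = A[k][q];
          A[k][p] = c * akp - s * akq;
          A[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 4; ++k) {
          double apk = A[p][k], aqk = A[q][k];
          A[p][k] = c * apk - s * aqk;
          A[q][k] = s * apk + c * aqk;
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
  }
  int best = 0;
  for (int k = 1; k < 4; ++k) if (A[k][k] > A[best][best]) best = k;
  for (int k = 0; k < 4; ++k) v[k] = V[k][best];
}

// Kabsch/Horn rigid fit source -> target from centered cross-covariance H
// (H = sum target_i source_i^T, both centered). Quaternion method: always a
// proper rotation.
static void horn_rotation(const double H[3][3], double R[3][3]) {
  double Sxx = H[0][0], Sxy = H[0][1], Sxz = H[0][2];
  double Syx = H[1][0], Syy = H[1][1], Syz = H[1][2];
  double Szx = H[2][0], Szy = H[2][1], Szz = H[2][2];
  double N[4][4] = {
    { Sxx + Syy + Szz, Szy - Syz,       Sxz - Szx,       Syx - Sxy },
    { Szy - Syz,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz },
    { Sxz - Szx,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy },
    { Syx - Sxy,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz }};
  double q[4];
  sym4_max_eigvec(N, q);
  double w = q[0], x = q[1], y = q[2], z = q[3];
  double n = std::sqrt(w * w + x * x + y * y + z * z);
  w /= n; x /= n; y /= n; z /= n;
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

// Rodrigues: rotation matrix from a rotation vector.
static void rotvec_to_mat(const double w[3], double R[3][3]) {
  double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (th < 1e-300) {
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) R[a][b] = (a == b) ? 1.0 : 0.0;
    return;
  }
  double u[3] = { w[0] / th, w[1] / th, w[2] / th };
  double c = std::cos(th), s = std::sin(th), cc = 1.0 - c;
  R[0][0] = c + u[0] * u[0] * cc;
  R[0][1] = u[0] * u[1] * cc - u[2] * s;
  R[0][2] = u[0] * u[2] * cc + u[1] * s;
  R[1][0] = u[1] * u[0] * cc + u[2] * s;
  R[1][1] = c + u[1] * u[1] * cc;
  R[1][2] = u[1] * u[2] * cc - u[0] * s;
  R[2][0] = u[2] * u[0] * cc - u[1] * s;
  R[2][1] = u[2] * u[1] * cc + u[0] * s;
  R[2][2] = c + u[2] * u[2] * cc;
}

// Rotation vector of R (angle * unit axis).
static void mat_to_rotvec(const double R[3][3], double w[3]) {
  double ct = std::max(-1.0, std::min(1.0, (R[0][0] + R[1][1] + R[2][2] - 1.0) / 2.0));
  double v[3] = { (R[2][1] - R[1][2]) / 2.0, (R[0][2] - R[2][0]) / 2.0,
                  (R[1][0] - R[0][1]) / 2.0 };
  double st = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  double th = std::atan2(st, ct);
  double f = (st > 1e-300) ? th / st : 1.0;
  w[0] = v[0] * f; w[1] = v[1] * f; w[2] = v[2] * f;
}

struct IcpState {
  double R[3][3], t[3];
};

// one correspondence + fit pass; returns J = mean squared distance at the
// INPUT pose and writes the re-fitted pose to `out`
static double icp_pass(TriGrid& grid, const NumericMatrix& X,
                       const IcpState& pose, IcpState& out) {
  const int n = X.nrow();
  double mc[3] = {0, 0, 0}, mx[3] = {0, 0, 0};
  double J = 0.0;
  std::vector<double> cp(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    double d[3] = { X(i, 0) - pose.t[0], X(i, 1) - pose.t[1], X(i, 2) - pose.t[2] };
    double z[3] = { pose.R[0][0] * d[0] + pose.R[1][0] * d[1] + pose.R[2][0] * d[2],
                    pose.R[0][1] * d[0] + pose.R[1][1] * d[1] + pose.R[2][1] * d[2],
                    pose.R[0][2] * d[0] + pose.R[1][2] * d[1] + pose.R[2][2] * d[2] };
    double q[3];
    J += grid.query(z, q);
    for (int k = 0; k < 3; ++k) {
      cp[3 * (size_t)i + k] = q[k];
      mc[k] += q[k];
      mx[k] += X(i, k);
    }
  }
  for (int k = 0; k < 3; ++k) { mc[k] /= n; mx[k] /= n; }
  double H[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        H[a][b] += (X(i, a) - mx[a]) * (cp[3 * (size_t)i + b] - mc[b]);
  horn_rotation(H, out.R);
  for (int a = 0; a < 3; ++a)
    out.t[a] = mx[a] - (out.R[a][0] * mc[0] + out.R[a][1] * mc[1] +
                        out.R[a][2] * mc[2]);
  return J / n;
}

// pose delta new o old^-1 as a 6-vector (rotation vector, translation)
static void pose_delta(const IcpState& nw, const IcpState& od, double v[6]) {
  double dR[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      dR[a][b] = nw.R[a][0] * od.R[b][0] + nw.R[a][1] * od.R[b][1] +
                 nw.R[a][2] * od.R[b][2];
  mat_to_rotvec(dR, v);
  for (int a = 0; a < 3; ++a)
    v[3 + a] = nw.t[a] - (dR[a][0] * od.t[0] + dR[a][1] * od.t[1] +
                          dR[a][2] * od.t[2]);
}

// apply exp(alpha * v) on the left of pose
static void pose_step(const IcpState& pose, const double v[6], double alpha,
                      IcpState& out) {
  double w[3] = { alpha * v[0], alpha * v[1], alpha * v[2] };
  double dR[3][3];
  rotvec_to_mat(w, dR);
  for (int a = 0; a < 3; ++a) {
    for (int b = 0; b < 3; ++b)
      out.R[a][b] = dR[a][0] * pose.R[0][b] + dR[a][1] * pose.R[1][b] +
                    dR[a][2] * pose.R[2][b];
    out.t[a] = dR[a][0] * pose.t[0] + dR[a][1] * pose.t[1] +
               dR[a][2] * pose.t[2] + alpha * v[3 + a];
  }
}

// Iterative closest-point rigid polish: target-frame points X are matched to
// exact closest points on the model surface under the current pose
// (p -> R p + t, model -> target) and the corresponding-point LSQ transform
// is re-solved, until the pose change per iteration falls below `tolerance`
// (rotation angle in radians plus relative translation change). Linear
// convergence along surface-sliding modes is accelerated by geometric-series
// extrapolation along the converging screw direction (in the spirit of
// Besl-McKay), guarded by the mean-squared-distance objective: an
// extrapolated pose is kept only if it does not worsen the fit.
// [[Rcpp::export]]
List cpp_refine_icp(NumericMatrix vertices, IntegerMatrix faces,
                    NumericMatrix X, NumericMatrix R0, NumericVector t0,
                    int max_iterations, double tolerance, double scale_ref) {
  TriGrid grid(vertices, faces);
  IcpState pose, pose_new, pose_ext, pose_tmp;
  for (int a = 0; a < 3; ++a) {
    pose.t[a] = t0[a];
    for (int b = 0; b < 3; ++b) pose.R[a][b] = R0(a, b);
  }
  double vprev[6] = {0, 0, 0, 0, 0, 0};
  double nprev = 0.0;
  double Jcur = R_PosInf;
  int iters = 0;
  for (int it = 0; it < max_iterations; ++it) {
    ++iters;
    Jcur = icp_pass(grid, X, pose, pose_new);
    double v[6];
    pose_delta(pose_new, pose, v);
    double ang = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    double dt = std::sqrt(v[3] * v[3] + v[4] * v[4] + v[5] * v[5]);
    double nv = std::sqrt(ang * ang + (dt / scale_ref) * (dt / scale_ref));

    bool stepped = false;
    if (nprev > 0.0 && nv > 0.0 && nv < nprev) {
      double dotp = 0.0;
      double sc[6] = {1, 1, 1, 1 / scale_ref, 1 / scale_ref, 1 / scale_ref};
      for (int k = 0; k < 6; ++k) dotp += v[k] * vprev[k] * sc[k] * sc[k];
      double cosang = dotp / (nv * nprev);
      if (cosang > 0.9) {
        double rho = nv / nprev;
        double alpha = std::min(rho / (1.0 - rho), 40.0);
        if (alpha > 1.0) {
          pose_step(pose_new, v, alpha, pose_ext);
          double Jext = icp_pass(grid, X, pose_ext, pose_tmp);
          ++iters;
          if (Jext < Jcur) {
            // accept the extrapolated pose (and the fit computed from it)
            pose = pose_tmp;
            nprev = 0.0;  // restart the series detector
            stepped = true;
          }
        }
      }
    }
    if (!stepped) {
      pose = pose_new;
      for (int k = 0; k < 6; ++k) vprev[k] = v[k];
      nprev = nv;
      if (ang + dt / scale_ref < tolerance) break;
    }
  }
  NumericMatrix Rout(3, 3);
  NumericVector tout(3);
  for (int a = 0; a < 3; ++a) {
    tout[a] = pose.t[a];
    for (int b = 0; b < 3; ++b) Rout(a, b) = pose.R[a][b];
  }
  return List::create(_["rotation"] = Rout, _["translation"] = tout,
                      _["iterations"] = iters);
}
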