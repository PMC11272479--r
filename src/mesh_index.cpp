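// Uniform-grid spatial index over a triangle mesh, with closest-point and
// bidirectional ray-cast queries. Used by the ICP nearest-neighbour step and
// by the limb-normal deviation mapping, where brute force over all triangles
// would dominate the pipeline's run time.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 sub(const Vec3& a, const Vec3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 add(const Vec3& a, const Vec3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 scl(const Vec3& a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm2(const Vec3& a) { return dot(a, a); }

// Closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection, 5.1.5).
Vec3 closest_pt_triangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = sub(b, a), ac = sub(c, a), ap = sub(p, a);
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = sub(p, b);
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return add(a, scl(ab, v));
  }
  Vec3 cp = sub(p, c);
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return add(a, scl(ac, w));
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return add(b, scl(sub(c, b), w));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return add(a, add(scl(ab, v), scl(ac, w)));
}

// Moller-Trumbore ray/triangle intersection; returns t >= 0 or -1 on miss.
double ray_triangle(const Vec3& o, const Vec3& d,
                    const Vec3& a, const Vec3& b, const Vec3& c) {
  const double eps = 1e-12;
  Vec3 e1 = sub(b, a), e2 = sub(c, a);
  Vec3 pvec = cross(d, e2);
  double det = dot(e1, pvec);
  if (std::fabs(det) < eps) return -1.0;
  double inv = 1.0 / det;
  Vec3 tvec = sub(o, a);
  double u = dot(tvec, pvec) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  Vec3 qvec = cross(tvec, e1);
  double v = dot(d, qvec) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = dot(e2, qvec) * inv;
  return (t >= -1e-9) ? std::max(t, 0.0) : -1.0;
}

struct MeshIndex {
  std::vector<Vec3> V;
  std::vector<int> F;   // 3 * ntri, 0-based
  int ntri;
  // grid
  Vec3 lo, hi;
  double hx, hy, hz;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;
  mutable std::vector<int> stamp;
  mutable int stamp_id;

  int cidx(int ix, int iy, int iz) const { return (iz * ny + iy) * nx + ix; }

  void locate(const Vec3& p, int& ix, int& iy, int& iz) const {
    ix = std::min(nx - 1, std::max(0, (int)std::floor((p.x - lo.x) / hx)));
    iy = std::min(ny - 1, std::max(0, (int)std::floor((p.y - lo.y) / hy)));
    iz = std::min(nz - 1, std::max(0, (int)std::floor((p.z - lo.z) / hz)));
  }

  void build(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
    int nv = Vm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = v3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    ntri = Fm.nrow();
    F.resize(3 * (size_t)ntri);
    for (int i = 0; i < ntri; ++i) {
      for (int k = 0; k < 3; ++k) {
        int v = Fm(i, k);
        if (v == NA_INTEGER || v < 0 || v >= nv) {
          stop("mesh index: face vertex id out of range");
        }
        F[3 * (size_t)i + k] = v;
      }
    }
    lo = v3(R_PosInf, R_PosInf, R_PosInf);
    hi = v3(R_NegInf, R_NegInf, R_NegInf);
    for (int i = 0; i < nv; ++i) {
      lo.x = std::min(lo.x, V[i].x); lo.y = std::min(lo.y, V[i].y); lo.z = std::min(lo.z, V[i].z);
      hi.x = std::max(hi.x, V[i].x); hi.y = std::max(hi.y, V[i].y); hi.z = std::max(hi.z, V[i].z);
    }
    // pad so boundary queries stay in-grid
    double pad = 1e-6 + 1e-6 * std::max({hi.x - lo.x, hi.y - lo.y, hi.z - lo.z});
    lo = sub(lo, v3(pad, pad, pad));
    hi = add(hi, v3(pad, pad, pad));
    // target ~2 triangles per occupied cell, capped
    double target = std::cbrt(std::max(1.0, (double)ntri / 2.0));
    int n = std::max(1, std::min(64, (int)std::ceil(target)));
    nx = ny = nz = n;
    hx = (hi.x - lo.x) / nx; hy = (hi.y - lo.y) / ny; hz = (hi.z - lo.z) / nz;
    if (hx <= 0) hx = 1.0;
    if (hy <= 0) hy = 1.0;
    if (hz <= 0) hz = 1.0;
    cells.assign((size_t)nx * ny * nz, {});
    for (int f = 0; f < ntri; ++f) {
      const Vec3& a = V[F[3 * (size_t)f]];
      const Vec3& b = V[F[3 * (size_t)f + 1]];
      const Vec3& c = V[F[3 * (size_t)f + 2]];
      Vec3 tlo = v3(std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}), std::min({a.z, b.z, c.z}));
      Vec3 thi = v3(std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}), std::max({a.z, b.z, c.z}));
      int ix0, iy0, iz0, ix1, iy1, iz1;
      locate(tlo, ix0, iy0, iz0);
      locate(thi, ix1, iy1, iz1);
      for (int iz = iz0; iz <= iz1; ++iz)
        for (int iy = iy0; iy <= iy1; ++iy)
          for (int ix = ix0; ix <= ix1; ++ix)
            cells[cidx(ix, iy, iz)].push_back(f);
    }
    stamp.assign(ntri, -1);
    stamp_id = 0;
  }

  // closest point on the mesh surface to q
  void closest(const Vec3& q, Vec3& best_pt, double& best_d2, int& best_f) const {
    ++stamp_id;
    best_d2 = std::numeric_limits<double>::infinity();
    best_f = -1;
    int ix, iy, iz;
    locate(q, ix, iy, iz);
    int maxr = std::max({nx, ny, nz});
    for (int r = 0; r <= maxr; ++r) {
      bool any_cell = false;
      for (int dz = -r; dz <= r; ++dz) {
        int cz = iz + dz;
        if (cz < 0 || cz >= nz) continue;
        for (int dy = -r; dy <= r; ++dy) {
          int cy = iy + dy;
          if (cy < 0 || cy >= ny) continue;
          for (int dx = -r; dx <= r; ++dx) {
            // shell only
            if (std::max({std::abs(dx), std::abs(dy), std::abs(dz)}) != r) continue;
            int cx = ix + dx;
            if (cx < 0 || cx >= nx) continue;
            any_cell = true;
            const std::vector<int>& tri = cells[cidx(cx, cy, cz)];
            for (int f : tri) {
              if (stamp[f] == stamp_id) continue;
              stamp[f] = stamp_id;
              Vec3 cp = closest_pt_triangle(q, V[F[3 * (size_t)f]], V[F[3 * (size_t)f + 1]],
                                            V[F[3 * (size_t)f + 2]]);
              double d2 = norm2(sub(q, cp));
              if (d2 < best_d2 ||
                  (d2 == best_d2 && best_f >= 0 && f < best_f)) {
                best_d2 = d2;
                best_pt = cp;
                best_f = f;
              }
            }
          }
        }
      }
      if (best_f >= 0) {
        // margin: distance from q to the boundary of the searched cell block
        double mx = std::min(q.x - (lo.x + (ix - r) * hx), (lo.x + (ix + r + 1) * hx) - q.x);
        double my = std::min(q.y - (lo.y + (iy - r) * hy), (lo.y + (iy + r + 1) * hy) - q.y);
        double mz = std::min(q.z - (lo.z + (iz - r) * hz), (lo.z + (iz + r + 1) * hz) - q.z);
        double margin = std::min({mx, my, mz});
        if (margin > 0 && best_d2 <= margin * margin) return;
      }
      if (!any_cell && r > 0 && best_f >= 0) return;  // searched whole grid
    }
  }

  // first hit along ray (o, d), d unit; t in [0, tmax]; returns t or -1
  double raycast(const Vec3& o, const Vec3& d, double tmax, int& hit_f) const {
    ++stamp_id;
    hit_f = -1;
    // clip ray to grid box
    double t0 = 0.0, t1 = tmax;
    const double* op = &o.x;
    const double* dp = &d.x;
    const double* lp = &lo.x;
    const double* hp = &hi.x;
    for (int k = 0; k < 3; ++k) {
      if (std::fabs(dp[k]) < 1e-15) {
        if (op[k] < lp[k] || op[k] > hp[k]) return -1.0;
      } else {
        double ta = (lp[k] - op[k]) / dp[k];
        double tb = (hp[k] - op[k]) / dp[k];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
      }
    }
    if (t0 > t1) return -1.0;
    Vec3 p = add(o, scl(d, t0));
    int ix, iy, iz;
    locate(p, ix, iy, iz);
    int sx = (d.x > 0) - (d.x < 0), sy = (d.y > 0) - (d.y < 0), sz = (d.z > 0) - (d.z < 0);
    const double INF = std::numeric_limits<double>::infinity();
    double tdx = (sx != 0) ? hx / std::fabs(d.x) : INF;
    double tdy = (sy != 0) ? hy / std::fabs(d.y) : INF;
    double tdz = (sz != 0) ? hz / std::fabs(d.z) : INF;
    double tmx = (sx > 0) ? (lo.x + (ix + 1) * hx - o.x) / d.x
               : (sx < 0) ? (lo.x + ix * hx - o.x) / d.x : INF;
    double tmy = (sy > 0) ? (lo.y + (iy + 1) * hy - o.y) / d.y
               : (sy < 0) ? (lo.y + iy * hy - o.y) / d.y : INF;
    double tmz = (sz > 0) ? (lo.z + (iz + 1) * hz - o.z) / d.z
               : (sz < 0) ? (lo.z + iz * hz - o.z) / d.z : INF;
    double best_t = -1.0;
    double tcell = t0;
    while (true) {
      const std::vector<int>& tri = cells[cidx(ix, iy, iz)];
      for (int f : tri) {
        if (stamp[f] == stamp_id) continue;
        stamp[f] = stamp_id;
        double t = ray_triangle(o, d, V[F[3 * (size_t)f]], V[F[3 * (size_t)f + 1]],
                                V[F[3 * (size_t)f + 2]]);
        if (t >= 0 && t <= tmax && (best_t < 0 || t < best_t ||
                                    (t == best_t && f < hit_f))) {
          best_t = t;
          hit_f = f;
        }
      }
      if (best_t >= 0 && best_t <= tcell) return best_t;
      // step to the next cell
      if (tmx <= tmy && tmx <= tmz) {
        tcell = tmx; ix += sx; tmx += tdx;
        if (ix < 0 || ix >= nx) break;
      } else if (tmy <= tmz) {
        tcell = tmy; iy += sy; tmy += tdy;
        if (iy < 0 || iy >= ny) break;
      } else {
        tcell = tmz; iz += sz; tmz += tdz;
        if (iz < 0 || iz >= nz) break;
      }
      if (tcell > t1 + 1e-9) break;
    }
    return best_t;
  }
};

}  // namespace

// [[Rcpp::export]]
SEXP mesh_index_build(NumericMatrix V, IntegerMatrix F) {
  XPtr<MeshIndex> ptr(new MeshIndex(), true);
  ptr->build(V, F);
  return ptr;
}

// [[Rcpp::export]]
List mesh_index_closest(SEXP xp, NumericMatrix Q) {
  XPtr<MeshIndex> idx(xp);
  int n = Q.nrow();
  NumericMatrix P(n, 3);
  NumericVector dist(n);
  IntegerVector tri(n);
  for (int i = 0; i < n; ++i) {
    Vec3 q = v3(Q(i, 0), Q(i, 1), Q(i, 2));
    Vec3 cp; double d2; int f;
    idx->closest(q, cp, d2, f);
    P(i, 0) = cp.x; P(i, 1) = cp.y; P(i, 2) = cp.z;
    dist[i] = std::sqrt(d2);
    tri[i] = f + 1;  // 1-based for R
  }
  return List::create(_["point"] = P, _["distance"] = dist, _["triangle"] = tri);
}

// Cast a ray from each origin along +dir and -dir; return the signed distance
// t (along +dir) of the hit with smallest |t| within max_dist, NA if none.
// Ties between the two directions resolve to the positive t.
// [[Rcpp::export]]
List mesh_index_raycast(SEXP xp, NumericMatrix O, NumericMatrix D, double max_dist) {
  XPtr<MeshIndex> idx(xp);
  int n = O.nrow();
  NumericVector t_signed(n);
  IntegerVector tri(n);
  for (int i = 0; i < n; ++i) {
    Vec3 o = v3(O(i, 0), O(i, 1), O(i, 2));
    Vec3 d = v3(D(i, 0), D(i, 1), D(i, 2));
    int f_fwd, f_bwd;
    double t_fwd = idx->raycast(o, d, max_dist, f_fwd);
    double t_bwd = idx->raycast(o, scl(d, -1.0), max_dist, f_bwd);
    bool has_f = t_fwd >= 0, has_b = t_bwd >= 0;
    if (!has_f && !has_b) {
      t_signed[i] = NA_REAL;
      tri[i] = NA_INTEGER;
    } else if (has_f && (!has_b || t_fwd <= t_bwd)) {
      t_signed[i] = t_fwd;
      tri[i] = f_fwd + 1;
    } else {
      t_signed[i] = -t_bwd;
      tri[i] = f_bwd + 1;
    }
  }
  return List::create(_["t"] = t_signed, _["triangle"] = tri);
}
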