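// Voxel-level kernels: tube rasterization with partial-volume supersampling,
// seeded flood fill / connected components, squared Euclidean distance
// transform, and topology-preserving 3D thinning (distance-ordered homotopic
// thinning with curve-endpoint preservation).
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Tube geometry
// ---------------------------------------------------------------------------

struct Tube {
  int type;                 // 1 = straight segment, 2 = circular arc, 3 = polyline
  double b[3], a[3];        // straight: base point, unit axis
  double c[3], u[3], v[3];  // arc: center and orthonormal in-plane basis
  double R;                 // arc radius (of the centerline circle)
  double dAng;              // arc angular extent, radians, in (0, pi]
  double L;                 // total centerline length (mm)
  double r0, r1;            // lumen radius at s = 0 and s = L (linear taper)
  std::vector<double> pts;  // polyline vertices (flattened x,y,z)
  std::vector<double> cum;  // polyline cumulative arclength per vertex
  double lo[3], hi[3];      // world bbox of the tube (incl. radius)
};

static inline double dot3(const double* x, const double* y) {
  return x[0]*y[0] + x[1]*y[1] + x[2]*y[2];
}

static inline double tube_radius_at(const Tube& t, double s) {
  if (t.L <= 0) return t.r0;
  double f = s / t.L;
  if (f < 0) f = 0; if (f > 1) f = 1;
  return t.r0 + (t.r1 - t.r0) * f;
}

// exact inside test for a point (world mm); flat ends for straight and arc
static bool tube_inside(const Tube& t, const double* p) {
  if (p[0] < t.lo[0] || p[0] > t.hi[0] ||
      p[1] < t.lo[1] || p[1] > t.hi[1] ||
      p[2] < t.lo[2] || p[2] > t.hi[2]) return false;
  if (t.type == 1) {
    double d[3] = { p[0]-t.b[0], p[1]-t.b[1], p[2]-t.b[2] };
    double s = dot3(d, t.a);
    if (s < 0.0 || s > t.L) return false;
    double perp2 = dot3(d, d) - s*s;
    double r = tube_radius_at(t, s);
    return perp2 <= r*r;
  } else if (t.type == 2) {
    double q[3] = { p[0]-t.c[0], p[1]-t.c[1], p[2]-t.c[2] };
    double qu = dot3(q, t.u), qv = dot3(q, t.v);
    double w[3] = { t.u[1]*t.v[2]-t.u[2]*t.v[1],
                    t.u[2]*t.v[0]-t.u[0]*t.v[2],
                    t.u[0]*t.v[1]-t.u[1]*t.v[0] };
    double z = dot3(q, w);
    double phi = std::atan2(qv, qu);
    if (phi < 0.0 || phi > t.dAng) return false;
    double rho = std::sqrt(qu*qu + qv*qv);
    double s = t.R * phi;
    double r = tube_radius_at(t, s);
    double dr = rho - t.R;
    return (z*z + dr*dr) <= r*r;
  } else {
    // polyline: union of per-segment cylinders plus spheres at interior joints
    size_t n = t.pts.size() / 3;
    for (size_t i = 0; i + 1 < n; ++i) {
      const double* p0 = &t.pts[3*i];
      const double* p1 = &t.pts[3*(i+1)];
      double ax[3] = { p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2] };
      double len = std::sqrt(dot3(ax, ax));
      if (len <= 0) continue;
      ax[0] /= len; ax[1] /= len; ax[2] /= len;
      double d[3] = { p[0]-p0[0], p[1]-p0[1], p[2]-p0[2] };
      double s = dot3(d, ax);
      if (s >= 0.0 && s <= len) {
        double perp2 = dot3(d, d) - s*s;
        double r = tube_radius_at(t, t.cum[i] + s);
        if (perp2 <= r*r) return true;
      }
    }
    for (size_t i = 1; i + 1 < n; ++i) {   // interior joints only (flat global ends)
      const double* pj = &t.pts[3*i];
      double d[3] = { p[0]-pj[0], p[1]-pj[1], p[2]-pj[2] };
      double r = tube_radius_at(t, t.cum[i]);
      if (dot3(d, d) <= r*r) return true;
    }
    return false;
  }
}

static Tube parse_tube(const List& tl) {
  Tube t;
  t.type = as<int>(tl["type"]);
  t.r0 = as<double>(tl["r0"]);
  t.r1 = as<double>(tl["r1"]);
  t.L  = as<double>(tl["length"]);
  NumericVector lo = tl["bbox_lo"], hi = tl["bbox_hi"];
  for (int k = 0; k < 3; ++k) { t.lo[k] = lo[k]; t.hi[k] = hi[k]; }
  if (t.type == 1) {
    NumericVector b = tl["base"], a = tl["axis"];
    for (int k = 0; k < 3; ++k) { t.b[k] = b[k]; t.a[k] = a[k]; }
  } else if (t.type == 2) {
    NumericVector c = tl["center"], u = tl["u"], v = tl["v"];
    for (int k = 0; k < 3; ++k) { t.c[k] = c[k]; t.u[k] = u[k]; t.v[k] = v[k]; }
    t.R = as<double>(tl["arc_radius"]);
    t.dAng = as<double>(tl["arc_angle"]);
  } else {
    NumericMatrix pm = tl["points"];
    size_t n = pm.nrow();
    t.pts.resize(3*n);
    t.cum.resize(n);
    double acc = 0; t.cum[0] = 0;
    for (size_t i = 0; i < n; ++i) {
      t.pts[3*i] = pm(i,0); t.pts[3*i+1] = pm(i,1); t.pts[3*i+2] = pm(i,2);
      if (i > 0) {
        double dx = pm(i,0)-pm(i-1,0), dy = pm(i,1)-pm(i-1,1), dz = pm(i,2)-pm(i-1,2);
        acc += std::sqrt(dx*dx+dy*dy+dz*dz);
        t.cum[i] = acc;
      }
    }
  }
  return t;
}

static inline bool any_inside(const std::vector<Tube>& tubes, const double* p) {
  for (size_t i = 0; i < tubes.size(); ++i)
    if (tube_inside(tubes[i], p)) return true;
  return false;
}

// [[Rcpp::export]]
NumericVector cpp_rasterize(List tube_list, IntegerVector dims,
                            NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<Tube> tubes;
  for (int i = 0; i < tube_list.size(); ++i)
    tubes.push_back(parse_tube(tube_list[i]));
  NumericVector out((R_xlen_t)nx * ny * nz);

  // voxel-index bbox of all tubes, padded by one voxel
  int vlo[3] = {nx, ny, nz}, vhi[3] = {-1, -1, -1};
  for (size_t t = 0; t < tubes.size(); ++t)
    for (int k = 0; k < 3; ++k) {
      int a = (int)std::floor((tubes[t].lo[k] - origin[k]) / spacing[k]) - 1;
      int b = (int)std::ceil ((tubes[t].hi[k] - origin[k]) / spacing[k]) + 1;
      if (a < vlo[k]) vlo[k] = a;
      if (b > vhi[k]) vhi[k] = b;
    }
  for (int k = 0; k < 3; ++k) {
    if (vlo[k] < 0) vlo[k] = 0;
    int n = (k == 0 ? nx : (k == 1 ? ny : nz));
    if (vhi[k] > n - 1) vhi[k] = n - 1;
  }

  const double hx = spacing[0]/2, hy = spacing[1]/2, hz = spacing[2]/2;
  const double sub[3] = {-1.0/3.0, 0.0, 1.0/3.0};

  for (int k = vlo[2]; k <= vhi[2]; ++k)
    for (int j = vlo[1]; j <= vhi[1]; ++j)
      for (int i = vlo[0]; i <= vhi[0]; ++i) {
        double c[3] = { origin[0] + i*spacing[0],
                        origin[1] + j*spacing[1],
                        origin[2] + k*spacing[2] };
        // classify voxel by its 8 corners + center: uniform -> 0/1, mixed -> supersample
        int nin = 0, ntot = 0;
        for (int dz = -1; dz <= 1; dz += 2)
          for (int dy = -1; dy <= 1; dy += 2)
            for (int dx = -1; dx <= 1; dx += 2) {
              double p[3] = { c[0]+dx*hx, c[1]+dy*hy, c[2]+dz*hz };
              if (any_inside(tubes, p)) ++nin;
              ++ntot;
            }
        bool cin = any_inside(tubes, c);
        if (cin) ++nin;
        ++ntot;
        double frac;
        if (nin == ntot) frac = 1.0;
        else if (nin == 0) frac = 0.0;
        else {
          int m = 0;
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b)
              for (int d = 0; d < 3; ++d) {
                double p[3] = { c[0]+sub[a]*spacing[0],
                                c[1]+sub[b]*spacing[1],
                                c[2]+sub[d]*spacing[2] };
                if (any_inside(tubes, p)) ++m;
              }
          frac = m / 27.0;
        }
        out[(R_xlen_t)i + (R_xlen_t)nx*j + (R_xlen_t)nx*ny*k] = frac;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Connectivity
// ---------------------------------------------------------------------------

static void neighbor_offsets(int connectivity, std::vector<int>& dx,
                             std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6  && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// [[Rcpp::export]]
LogicalVector cpp_flood(LogicalVector mask, IntegerVector dims,
                        IntegerVector seed0, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  LogicalVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t s = (R_xlen_t)seed0[0] + (R_xlen_t)nx*seed0[1] + (R_xlen_t)nx*ny*seed0[2];
  if (!mask[s]) return out;
  std::vector<char> vis((size_t)nx*ny*nz, 0);
  std::queue<R_xlen_t> q;
  q.push(s); vis[s] = 1;
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    out[cur] = true;
    int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx*ny));
    for (size_t m = 0; m < dx.size(); ++m) {
      int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t idx = (R_xlen_t)ii + (R_xlen_t)nx*jj + (R_xlen_t)nx*ny*kk;
      if (!vis[idx] && mask[idx]) { vis[idx] = 1; q.push(idx); }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> dx, dy, dz;
  neighbor_offsets(connectivity, dx, dy, dz);
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  int next = 0;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    std::queue<R_xlen_t> q;
    q.push(s); lab[s] = next;
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx*ny));
      for (size_t m = 0; m < dx.size(); ++m) {
        int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t idx = (R_xlen_t)ii + (R_xlen_t)nx*jj + (R_xlen_t)nx*ny*kk;
        if (mask[idx] && lab[idx] == 0) { lab[idx] = next; q.push(idx); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic spacing supported.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double>& f, std::vector<double>& d, double w) {
  const int n = (int)f.size();
  d.assign(n, 0.0);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2*q*q) - (f[p] + w2*p*p)) / (2.0*w2*(q - p));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q; z[k] = s; z[k+1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k+1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2*dq*dq + f[v[k]];
  }
}

// squared distance (mm^2) from each foreground voxel to the nearest background
static void edt_sq(const std::vector<char>& fg, int nx, int ny, int nz,
                   const double* spacing, std::vector<double>& out) {
  const double BIG = 1e30;
  out.assign((size_t)nx*ny*nz, 0.0);
  for (size_t i = 0; i < out.size(); ++i) out[i] = fg[i] ? BIG : 0.0;
  std::vector<double> f, d;
  // x pass
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)nx*j + (size_t)nx*ny*k;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // y pass
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx*ny*k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (size_t)nx*j];
      dt1d(f, d, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (size_t)nx*j] = d[j];
    }
  // z pass
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)nx*j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (size_t)nx*ny*k];
      dt1d(f, d, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + (size_t)nx*ny*k] = d[k];
    }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> fg((size_t)nx*ny*nz);
  for (size_t i = 0; i < fg.size(); ++i) fg[i] = mask[i] ? 1 : 0;
  std::vector<double> d;
  double sp[3] = { spacing[0], spacing[1], spacing[2] };
  edt_sq(fg, nx, ny, nz, sp, d);
  NumericVector out((R_xlen_t)nx*ny*nz);
  for (size_t i = 0; i < d.size(); ++i) out[i] = d[i];
  return out;
}

// ---------------------------------------------------------------------------
// 3D thinning
// ---------------------------------------------------------------------------

// cube index helpers: 3x3x3 neighborhood flattened as (dx+1) + 3*(dy+1) + 9*(dz+1)
static inline int cube_idx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// simple-point test (Bertrand & Malandain characterization):
//  (a) exactly one 26-connected foreground component in N26 \ {center}
//  (b) exactly one 6-connected background component in N18 that is 6-adjacent
//      to the center
static bool is_simple(const char* cube) {
  // (a) 26-connectivity of foreground among the 26 neighbors
  char lab[27]; for (int i = 0; i < 27; ++i) lab[i] = 0;
  int comp_fg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !cube[i] || lab[i]) continue;
    ++comp_fg;
    if (comp_fg > 1) return false;
    // BFS
    int stack[27], top = 0;
    stack[top++] = i; lab[i] = 1;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int ni = x + 3*y + 9*z;
            if (ni == 13 || ni == cur) continue;
            if (cube[ni] && !lab[ni]) { lab[ni] = 1; stack[top++] = ni; }
          }
    }
  }
  if (comp_fg != 1) return false;

  // (b) 6-connectivity of background within N18, components touching a face
  // neighbor of the center
  static const int face[6] = { cube_idx(-1,0,0), cube_idx(1,0,0),
                               cube_idx(0,-1,0), cube_idx(0,1,0),
                               cube_idx(0,0,-1), cube_idx(0,0,1) };
  char in18[27]; char lab2[27];
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int m = std::abs(x) + std::abs(y) + std::abs(z);
    in18[i] = (m >= 1 && m <= 2) ? 1 : 0;
    lab2[i] = 0;
  }
  int comp_bg = 0;
  for (int fi = 0; fi < 6; ++fi) {
    int start = face[fi];
    if (cube[start] || lab2[start]) continue;
    ++comp_bg;
    if (comp_bg > 1) return false;
    int stack[27], top = 0;
    stack[top++] = start; lab2[start] = 1;
    while (top) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      static const int fdx[6] = {1,-1,0,0,0,0};
      static const int fdy[6] = {0,0,1,-1,0,0};
      static const int fdz[6] = {0,0,0,0,1,-1};
      for (int m = 0; m < 6; ++m) {
        int x = cx + fdx[m], y = cy + fdy[m], z = cz + fdz[m];
        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
        int ni = x + 3*y + 9*z;
        if (!in18[ni] || ni == 13) continue;
        if (!cube[ni] && !lab2[ni]) { lab2[ni] = 1; stack[top++] = ni; }
      }
    }
  }
  return comp_bg == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> fg(n);
  for (size_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  std::vector<double> dt;
  // normalize by the smallest spacing: the thinning order only needs
  // relative distances, and normalized values make the order invariant
  // under uniform scaling of the grid
  double smin = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  double sp[3] = { spacing[0] / smin, spacing[1] / smin, spacing[2] / smin };
  edt_sq(fg, nx, ny, nz, sp, dt);

  std::vector<size_t> order;
  order.reserve(n / 4);
  for (size_t i = 0; i < n; ++i) if (fg[i]) order.push_back(i);
  std::stable_sort(order.begin(), order.end(),
                   [&dt](size_t a, size_t b) { return dt[a] < dt[b]; });

  auto fill_cube = [&](size_t idx, char* cube) {
    int i = (int)(idx % nx), j = (int)((idx / nx) % ny), k = (int)(idx / ((size_t)nx*ny));
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int ii = i + dx, jj = j + dy, kk = k + dz;
          char val = 0;
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            val = fg[(size_t)ii + (size_t)nx*jj + (size_t)nx*ny*kk];
          cube[cube_idx(dx, dy, dz)] = val;
        }
  };

  // directional sub-iterations (U, D, N, S, E, W) within each sweep keep the
  // erosion balanced so the skeleton stays centered; voxels are visited in
  // increasing distance-transform order (distance-ordered homotopic thinning)
  static const int fo[6] = { cube_idx(-1,0,0), cube_idx(1,0,0),
                             cube_idx(0,-1,0), cube_idx(0,1,0),
                             cube_idx(0,0,-1), cube_idx(0,0,1) };
  bool changed = true;
  char cube[27];
  std::vector<size_t> cand;
  cand.reserve(order.size() / 8 + 16);
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      // freeze the candidate border set for this subpass so erosion removes
      // at most one voxel layer per direction per sweep
      cand.clear();
      for (size_t oi = 0; oi < order.size(); ++oi) {
        size_t idx = order[oi];
        if (!fg[idx]) continue;
        fill_cube(idx, cube);
        if (!cube[fo[dir]]) cand.push_back(idx);
      }
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        size_t idx = cand[ci];
        if (!fg[idx]) continue;
        fill_cube(idx, cube);
        // endpoint: <= 1 foreground 26-neighbor
        int nn = 0;
        for (int m = 0; m < 27; ++m) if (m != 13 && cube[m]) ++nn;
        if (nn <= 1) continue;
        if (!is_simple(cube)) continue;
        fg[idx] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out((R_xlen_t)n);
  for (size_t i = 0; i < n; ++i) out[i] = fg[i] != 0;
  return out;
}
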