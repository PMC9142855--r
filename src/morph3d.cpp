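// Low-level 3D image primitives: exact squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm), connected-component
// labelling, cubical-complex Euler characteristic, marching-tetrahedra
// isosurface area, inscribed-sphere local thickness, and separable Gaussian
// blur. All arrays are R column-major with dim = (nx, ny, nz).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e20;

// 1D squared distance transform of sampled function f, result in d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// FALSE voxel. Voxels outside the volume are treated as FALSE, i.e. the
// border acts as background; pad beforehand if that is not wanted.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? INF : 0.0;

  // along x
  for (int kz = 0; kz < nz; kz++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * kz);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; i++) {
        // implicit background just outside the row ends
        double db = std::min((double)(i + 1) * (i + 1),
                             (double)(nx - i) * (nx - i));
        out[base + i] = std::min(d[i], db);
      }
    }
  // along y
  for (int kz = 0; kz < nz; kz++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * kz;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; j++) {
        double db = std::min((double)(j + 1) * (j + 1),
                             (double)(ny - j) * (ny - j));
        out[base + (R_xlen_t)nx * j] = std::min(d[j], db);
      }
    }
  // along z
  R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int kz = 0; kz < nz; kz++) f[kz] = out[base + stride * kz];
      dt1d(f, d, nz, v, z);
      for (int kz = 0; kz < nz; kz++) {
        double db = std::min((double)(kz + 1) * (kz + 1),
                             (double)(nz - kz) * (nz - kz));
        out[base + stride * kz] = std::min(d[kz], db);
      }
    }
  return out;
}

// Squared EDT with the volume border treated as foreground continuation
// (distances only to FALSE voxels inside the array).
// [[Rcpp::export]]
NumericVector edt_sq_open_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? INF : 0.0;
  for (int kz = 0; kz < nz; kz++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * kz);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  for (int kz = 0; kz < nz; kz++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * kz;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int kz = 0; kz < nz; kz++) f[kz] = out[base + stride * kz];
      dt1d(f, d, nz, v, z);
      for (int kz = 0; kz < nz; kz++) out[base + stride * kz] = d[kz];
    }
  return out;
}

// Connected-component labelling, connectivity 6 or 26, labels 1..k by
// discovery order, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        if (a == 0 && b == 0 && c == 0) continue;
        int man = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && man != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  int nb = (int)dx.size();
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int t = 0; t < nb; t++) {
        int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] && !lab[q]) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Counts of vertices, edges, faces, cells of the cubical complex formed by
// the closed unit cubes of foreground voxels. chi = V - E + F - C. This
// pairs with 26-connectivity of the foreground.
// [[Rcpp::export]]
NumericVector euler_counts_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  auto fg = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] != 0;
  };
  double V = 0, E = 0, F = 0, C = 0;
  for (int k = 0; k <= nz; k++)
    for (int j = 0; j <= ny; j++)
      for (int i = 0; i <= nx; i++) {
        // vertex (i,j,k): adjacent voxels (i-1..i, j-1..j, k-1..k)
        bool any = false;
        for (int a = i - 1; a <= i && !any; a++)
          for (int b = j - 1; b <= j && !any; b++)
            for (int c = k - 1; c <= k && !any; c++)
              if (fg(a, b, c)) any = true;
        if (any) V += 1;
        // edges emanating in +x, +y, +z from this vertex
        if (i < nx) { // x-edge: voxels (i, j-1..j, k-1..k)
          bool e = false;
          for (int b = j - 1; b <= j && !e; b++)
            for (int c = k - 1; c <= k && !e; c++)
              if (fg(i, b, c)) e = true;
          if (e) E += 1;
        }
        if (j < ny) {
          bool e = false;
          for (int a = i - 1; a <= i && !e; a++)
            for (int c = k - 1; c <= k && !e; c++)
              if (fg(a, j, c)) e = true;
          if (e) E += 1;
        }
        if (k < nz) {
          bool e = false;
          for (int a = i - 1; a <= i && !e; a++)
            for (int b = j - 1; b <= j && !e; b++)
              if (fg(a, b, k)) e = true;
          if (e) E += 1;
        }
        // faces with lower-left vertex here, normal z / y / x
        if (i < nx && j < ny) { // z-normal face: voxels (i,j,k-1..k)
          if (fg(i, j, k - 1) || fg(i, j, k)) F += 1;
        }
        if (i < nx && k < nz) {
          if (fg(i, j - 1, k) || fg(i, j, k)) F += 1;
        }
        if (j < ny && k < nz) {
          if (fg(i - 1, j, k) || fg(i, j, k)) F += 1;
        }
        if (i < nx && j < ny && k < nz && fg(i, j, k)) C += 1;
      }
  return NumericVector::create(V, E, F, C);
}

// ---- marching tetrahedra isosurface area ----------------------------------

static inline void interp(const double p1[3], const double p2[3], double v1,
                          double v2, double level, double out[3]) {
  double t = (level - v1) / (v2 - v1);
  for (int d = 0; d < 3; d++) out[d] = p1[d] + t * (p2[d] - p1[d]);
}

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3], v[3], w[3];
  for (int d = 0; d < 3; d++) { u[d] = b[d] - a[d]; v[d] = c[d] - a[d]; }
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// area of the iso-level surface within one tetrahedron
static double tet_area(const double p[4][3], const double val[4],
                       double level) {
  bool in[4];
  int nin = 0;
  for (int t = 0; t < 4; t++) {
    in[t] = val[t] > level;
    if (in[t]) nin++;
  }
  if (nin == 0 || nin == 4) return 0.0;
  int a[4], b[4], na = 0, nb2 = 0;
  for (int t = 0; t < 4; t++) (in[t] ? a[na++] : b[nb2++]) = t;
  if (nin == 1 || nin == 3) {
    int lone = (nin == 1) ? a[0] : b[0];
    int other[3];
    int c = 0;
    for (int t = 0; t < 4; t++)
      if (t != lone) other[c++] = t;
    double q[3][3];
    for (int t = 0; t < 3; t++)
      interp(p[lone], p[other[t]], val[lone], val[other[t]], level, q[t]);
    return tri_area(q[0], q[1], q[2]);
  }
  // 2-2: quad with corners on edges a0-b0, a0-b1, a1-b1, a1-b0
  double q[4][3];
  interp(p[a[0]], p[b[0]], val[a[0]], val[b[0]], level, q[0]);
  interp(p[a[0]], p[b[1]], val[a[0]], val[b[1]], level, q[1]);
  interp(p[a[1]], p[b[1]], val[a[1]], val[b[1]], level, q[2]);
  interp(p[a[1]], p[b[0]], val[a[1]], val[b[0]], level, q[3]);
  return tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
}

// Total area (voxel^2 units) of the triangulated iso-level surface, by
// 6-tetrahedra decomposition of each 2x2x2 cell. Values outside the grid
// are treated as the minimum (background), closing the surface at borders.
// [[Rcpp::export]]
double marching_area_cpp(NumericVector vol, IntegerVector dim, double level,
                         double outside) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  auto at = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
      return outside;
    return vol[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  // cube corner order: bit0 = x, bit1 = y, bit2 = z
  static const int tets[6][4] = {{0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
                                 {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};
  double total = 0.0;
  for (int k = -1; k < nz; k++)
    for (int j = -1; j < ny; j++)
      for (int i = -1; i < nx; i++) {
        double cv[8];
        double cp[8][3];
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; c++) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          cv[c] = at(ci, cj, ck);
          cp[c][0] = ci; cp[c][1] = cj; cp[c][2] = ck;
          if (cv[c] > level) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; t++) {
          double p[4][3], v[4];
          for (int c = 0; c < 4; c++) {
            int idx = tets[t][c];
            v[c] = cv[idx];
            for (int d = 0; d < 3; d++) p[c][d] = cp[idx][d];
          }
          total += tet_area(p, v, level);
        }
      }
  return total;
}

// ---- local thickness -------------------------------------------------------

// Hildebrand-Rüegsegger local thickness: per foreground voxel, the diameter
// of the largest sphere that contains it and fits in the structure.
// `radius` is the (unsquared) EDT of the mask. Redundant sphere centres
// (spheres contained in a neighbour's sphere) are pruned before painting.
// Output in voxel units, with the half-voxel boundary offset applied
// (a slab of t voxels reports thickness t).
//
// `tol` (voxels) trades speed for a bounded approximation: a centre whose
// sphere is already covered to within `tol` of its radius by previously
// painted (larger) spheres is skipped, so map values are exact for tol = 0
// and within 2*tol voxels of exact otherwise.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, NumericVector radius,
                                  IntegerVector dim, double tol = 0.0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n, 0.0);
  struct Center { double r; int i, j, k; };
  std::vector<Center> centers;
  // Distance-ridge pruning with exact discrete-ball containment: centre c
  // is redundant if a 26-neighbour n's discrete sphere contains c's
  // discrete sphere. For squared radius rc2 and neighbour offset d, the
  // discrete ball B(c, rc) lies inside B(n, rn) iff
  // rn2 >= max{ |v - d|^2 : |v|^2 <= rc2, v integer }, precomputed per
  // offset class (face / edge / corner). Containment is transitive, so
  // painting only the surviving (ridge) centres reproduces the full map.
  R_xlen_t n_all = n;
  int maxRsq = 0;
  // radii can be unbounded when the mask has no background at all; cap at
  // the volume diagonal, beyond which every sphere covers everything
  double capR2 = (double)nx * nx + (double)ny * ny + (double)nz * nz;
  std::vector<int> rsq(n_all, 0);
  for (R_xlen_t s = 0; s < n_all; s++)
    if (mask[s]) {
      double r2v = radius[s] * radius[s];
      if (r2v > capR2) r2v = capR2;
      int v = (int)std::lround(r2v);
      rsq[s] = v;
      if (v > maxRsq) maxRsq = v;
    }
  int rmax = (int)std::floor(std::sqrt((double)maxRsq)) + 1;
  // largest representable sum of one / two squares <= s
  std::vector<int> oneSqMax(maxRsq + 1), twoSqMax(maxRsq + 1);
  {
    std::vector<char> isTwo(maxRsq + 1, 0);
    for (int a = 0; a * a <= maxRsq; a++)
      for (int b = a; a * a + b * b <= maxRsq; b++)
        isTwo[a * a + b * b] = 1;
    int best1 = 0, best2 = 0;
    for (int s = 0; s <= maxRsq; s++) {
      int rt = (int)std::floor(std::sqrt((double)s) + 1e-9);
      if (rt * rt > best1) best1 = rt * rt;
      if (isTwo[s]) best2 = s;
      oneSqMax[s] = best1;
      twoSqMax[s] = best2;
    }
  }
  std::vector<int> coverFace(maxRsq + 1), coverEdge(maxRsq + 1),
    coverCorner(maxRsq + 1);
  for (int rc2 = 0; rc2 <= maxRsq; rc2++) {
    int mf = 0;
    for (int u1 = -rmax; u1 <= rmax; u1++) {
      int rem = rc2 - u1 * u1;
      if (rem < 0) continue;
      int val = (u1 + 1) * (u1 + 1) + twoSqMax[rem];
      if (val > mf) mf = val;
    }
    coverFace[rc2] = mf;
    int me = 0, mc = 0;
    for (int u1 = -rmax; u1 <= rmax; u1++) {
      int r1 = rc2 - u1 * u1;
      if (r1 < 0) continue;
      int p1 = (u1 + 1) * (u1 + 1);
      for (int u2 = -rmax; u2 <= rmax; u2++) {
        int rem = r1 - u2 * u2;
        if (rem < 0) continue;
        int p2 = (u2 + 1) * (u2 + 1);
        int ve = p1 + p2 + oneSqMax[rem];
        if (ve > me) me = ve;
        int u3 = (int)std::floor(std::sqrt((double)rem) + 1e-9);
        int vc = p1 + p2 + (u3 + 1) * (u3 + 1);
        if (vc > mc) mc = vc;
      }
    }
    coverEdge[rc2] = me;
    coverCorner[rc2] = mc;
  }
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t s = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[s]) continue;
        int rc2 = rsq[s];
        bool dominated = false;
        for (int a = -1; a <= 1 && !dominated; a++)
          for (int b = -1; b <= 1 && !dominated; b++)
            for (int c = -1; c <= 1 && !dominated; c++) {
              if (a == 0 && b == 0 && c == 0) continue;
              int ii = i + a, jj = j + b, kk = k + c;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                  kk >= nz)
                continue;
              R_xlen_t q = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              if (!mask[q]) continue;
              int cls = a * a + b * b + c * c;
              int need = cls == 1 ? coverFace[rc2] :
                         cls == 2 ? coverEdge[rc2] : coverCorner[rc2];
              if (rsq[q] >= need) dominated = true;
            }
        if (!dominated)
          centers.push_back({std::sqrt((double)rc2), i, j, k});
      }
  std::sort(centers.begin(), centers.end(),
            [](const Center& x, const Center& y) { return x.r > y.r; });
  if (std::getenv("BONEMORPH_THICKNESS_DEBUG")) {
    double volsum = 0;
    for (const Center& c : centers) volsum += 4.19 * c.r * c.r * c.r;
    Rprintf("local_thickness: %d fg, %d ridge centres, est paint %.2e\n",
            (int)std::count(mask.begin(), mask.end(), TRUE),
            (int)centers.size(), volsum);
  }
  // depth[x] = max over painted spheres of (r' - |x - c'|); a pending
  // centre with depth >= its own radius has its whole sphere inside an
  // already-painted one and can be skipped exactly (containment again)
  std::vector<double> depth(n_all, -1.0);
  std::vector<double> sqrtTab(maxRsq + 1);
  for (int s = 0; s <= maxRsq; s++) sqrtTab[s] = std::sqrt((double)s);
  for (const Center& c : centers) {
    // the boundary lies half a voxel beyond background centres, so the
    // inscribed diameter is 2r - 1; coverage uses the full centre-to-centre
    // radius r, mirroring how the mask itself samples continuous shapes
    double diam = 2.0 * c.r - 1.0;
    if (diam <= 0) diam = 1.0;
    R_xlen_t s0 = c.i + (R_xlen_t)nx * (c.j + (R_xlen_t)ny * c.k);
    if (depth[s0] >= c.r - tol - 1e-9) {
      if (th[s0] < diam) th[s0] = diam;
      continue;
    }
    int R = (int)std::floor(c.r + 1e-6);
    double r2 = (c.r + 1e-6) * (c.r + 1e-6);
    int alo = std::max(-R, -c.i), ahi = std::min(R, nx - 1 - c.i);
    int blo = std::max(-R, -c.j), bhi = std::min(R, ny - 1 - c.j);
    int clo = std::max(-R, -c.k), chi = std::min(R, nz - 1 - c.k);
    for (int a = alo; a <= ahi; a++)
      for (int b = blo; b <= bhi; b++) {
        int ab2 = a * a + b * b;
        if ((double)ab2 > r2) continue;
        R_xlen_t base = (c.i + a) +
          (R_xlen_t)nx * ((c.j + b) + (R_xlen_t)ny * c.k);
        for (int cc = clo; cc <= chi; cc++) {
          int d2 = ab2 + cc * cc;
          if ((double)d2 > r2) continue;
          R_xlen_t q = base + (R_xlen_t)nx * ny * cc;
          if (!mask[q]) continue;
          if (th[q] < diam) th[q] = diam;
          double dep = c.r - sqrtTab[d2];
          if (depth[q] < dep) depth[q] = dep;
        }
      }
    if (th[s0] < diam) th[s0] = diam;
  }
  return th;
}

// Separable Gaussian blur, kernel truncated at `radius` voxels and
// renormalised (also at volume borders).
// [[Rcpp::export]]
NumericVector gaussian_blur3d_cpp(NumericVector vol, IntegerVector dim,
                                  double sigma, int radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> kern(2 * radius + 1);
  for (int t = -radius; t <= radius; t++)
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
  NumericVector a(vol);
  NumericVector b(n);
  int dims[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int axis = 0; axis < 3; axis++) {
    int len = dims[axis];
    R_xlen_t str = strides[axis];
    for (R_xlen_t s = 0; s < n; s++) {
      int i = (int)((s / str) % len);
      double acc = 0, wsum = 0;
      int lo = std::max(-radius, -i), hi = std::min(radius, len - 1 - i);
      for (int t = lo; t <= hi; t++) {
        double w = kern[t + radius];
        acc += w * a[s + (R_xlen_t)t * str];
        wsum += w;
      }
      b[s] = acc / wsum;
    }
    std::copy(b.begin(), b.end(), a.begin());
  }
  return a;
}
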