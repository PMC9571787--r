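#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Uniform-grid acceleration structure over triangles, used for
// point-to-surface correspondence (ICP), inside/outside parity tests and
// column voxelization. Rebuilt per call-site via an external pointer.

struct TriGrid {
  std::vector<double> vx, vy, vz;          // vertices
  std::vector<int> fa, fb, fc;             // faces
  double lo[3], hi[3];                     // mesh bbox
  double cell;                             // 3D cell edge length
  int gd[3];                               // 3D grid dims
  std::vector<std::vector<int>> cells;     // 3D cells -> triangle ids
  double cell2;                            // 2D (x,y) cell size
  int g2[2];
  std::vector<std::vector<int>> cells2;    // 2D cells -> triangle ids
};

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Ericson: closest point on triangle (a,b,c) to p
static void closest_on_tri(const double* p, const double* a, const double* b,
                           const double* c, double* out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i]-a[i]; ac[i] = c[i]-a[i]; ap[i] = p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i]=a[i]+v*ab[i];
    return;
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i]=a[i]+w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i]=b[i]+w*(c[i]-b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i]=a[i]+ab[i]*v+ac[i]*w;
}

// [[Rcpp::export]]
SEXP cpp_trigrid_new(const NumericMatrix& V, const IntegerMatrix& F) {
  TriGrid* g = new TriGrid();
  int nv = V.nrow(), nf = F.nrow();
  g->vx.resize(nv); g->vy.resize(nv); g->vz.resize(nv);
  for (int i = 0; i < nv; ++i) { g->vx[i]=V(i,0); g->vy[i]=V(i,1); g->vz[i]=V(i,2); }
  g->fa.resize(nf); g->fb.resize(nf); g->fc.resize(nf);
  for (int f = 0; f < nf; ++f) { g->fa[f]=F(f,0); g->fb[f]=F(f,1); g->fc[f]=F(f,2); }
  for (int a = 0; a < 3; ++a) {
    g->lo[a] = std::numeric_limits<double>::infinity();
    g->hi[a] = -std::numeric_limits<double>::infinity();
  }
  for (int i = 0; i < nv; ++i) {
    g->lo[0] = std::min(g->lo[0], g->vx[i]); g->hi[0] = std::max(g->hi[0], g->vx[i]);
    g->lo[1] = std::min(g->lo[1], g->vy[i]); g->hi[1] = std::max(g->hi[1], g->vy[i]);
    g->lo[2] = std::min(g->lo[2], g->vz[i]); g->hi[2] = std::max(g->hi[2], g->vz[i]);
  }
  double ext[3];
  for (int a = 0; a < 3; ++a) ext[a] = std::max(g->hi[a] - g->lo[a], 1e-9);
  // aim for ~ nf cells
  double target = std::cbrt(ext[0]*ext[1]*ext[2] / std::max(nf, 1));
  g->cell = std::max(target, 1e-6);
  for (int a = 0; a < 3; ++a)
    g->gd[a] = clampi((int)std::ceil(ext[a] / g->cell), 1, 256);
  g->cells.assign((size_t)g->gd[0]*g->gd[1]*g->gd[2], {});
  auto cidx = [&](double x, int a) {
    return clampi((int)((x - g->lo[a]) / g->cell), 0, g->gd[a]-1);
  };
  for (int f = 0; f < nf; ++f) {
    int ia = g->fa[f], ib = g->fb[f], ic = g->fc[f];
    double bx0 = std::min({g->vx[ia], g->vx[ib], g->vx[ic]});
    double bx1 = std::max({g->vx[ia], g->vx[ib], g->vx[ic]});
    double by0 = std::min({g->vy[ia], g->vy[ib], g->vy[ic]});
    double by1 = std::max({g->vy[ia], g->vy[ib], g->vy[ic]});
    double bz0 = std::min({g->vz[ia], g->vz[ib], g->vz[ic]});
    double bz1 = std::max({g->vz[ia], g->vz[ib], g->vz[ic]});
    for (int k = cidx(bz0,2); k <= cidx(bz1,2); ++k)
      for (int j = cidx(by0,1); j <= cidx(by1,1); ++j)
        for (int i = cidx(bx0,0); i <= cidx(bx1,0); ++i)
          g->cells[(size_t)i + (size_t)j*g->gd[0] + (size_t)k*g->gd[0]*g->gd[1]].push_back(f);
  }
  // 2D (x,y) bins for ray-parity along +z
  double area2 = ext[0]*ext[1] / std::max(nf, 1);
  g->cell2 = std::max(std::sqrt(area2), 1e-6);
  g->g2[0] = clampi((int)std::ceil(ext[0] / g->cell2), 1, 1024);
  g->g2[1] = clampi((int)std::ceil(ext[1] / g->cell2), 1, 1024);
  g->cells2.assign((size_t)g->g2[0]*g->g2[1], {});
  auto c2 = [&](double x, int a) {
    return clampi((int)((x - g->lo[a]) / g->cell2), 0, g->g2[a]-1);
  };
  for (int f = 0; f < nf; ++f) {
    int ia = g->fa[f], ib = g->fb[f], ic = g->fc[f];
    double bx0 = std::min({g->vx[ia], g->vx[ib], g->vx[ic]});
    double bx1 = std::max({g->vx[ia], g->vx[ib], g->vx[ic]});
    double by0 = std::min({g->vy[ia], g->vy[ib], g->vy[ic]});
    double by1 = std::max({g->vy[ia], g->vy[ib], g->vy[ic]});
    for (int j = c2(by0,1); j <= c2(by1,1); ++j)
      for (int i = c2(bx0,0); i <= c2(bx1,0); ++i)
        g->cells2[(size_t)i + (size_t)j*g->g2[0]].push_back(f);
  }
  XPtr<TriGrid> ptr(g, true);
  return ptr;
}

static void grid_closest(const TriGrid* g, const double* p, double* best_pt,
                         double* best_d) {
  *best_d = std::numeric_limits<double>::infinity();
  // start from the cell containing (the clamp of) p, expand shells
  int ci[3];
  ci[0] = clampi((int)((p[0]-g->lo[0])/g->cell), 0, g->gd[0]-1);
  ci[1] = clampi((int)((p[1]-g->lo[1])/g->cell), 0, g->gd[1]-1);
  ci[2] = clampi((int)((p[2]-g->lo[2])/g->cell), 0, g->gd[2]-1);
  int maxr = std::max({g->gd[0], g->gd[1], g->gd[2]});
  // distance from p to the grid box (outside queries need an offset)
  double dbox = 0.0;
  for (int a = 0; a < 3; ++a) {
    if (p[a] < g->lo[a]) dbox = std::max(dbox, g->lo[a]-p[a]);
    if (p[a] > g->hi[a]) dbox = std::max(dbox, p[a]-g->hi[a]);
  }
  double q[3];
  for (int r = 0; r <= maxr; ++r) {
    bool any_cell = false;
    for (int dk = -r; dk <= r; ++dk) {
      int k = ci[2]+dk; if (k < 0 || k >= g->gd[2]) continue;
      for (int dj = -r; dj <= r; ++dj) {
        int j = ci[1]+dj; if (j < 0 || j >= g->gd[1]) continue;
        // iterate only the shell: full rows on the cube faces, else the
        // two end columns
        int step = (std::abs(dk) == r || std::abs(dj) == r || r == 0) ? 1 : 2 * r;
        for (int di = -r; di <= r; di += step) {
          int i = ci[0]+di; if (i < 0 || i >= g->gd[0]) continue;
          any_cell = true;
          const std::vector<int>& tri = g->cells[(size_t)i + (size_t)j*g->gd[0] + (size_t)k*g->gd[0]*g->gd[1]];
          for (int f : tri) {
            double a[3] = {g->vx[g->fa[f]], g->vy[g->fa[f]], g->vz[g->fa[f]]};
            double b[3] = {g->vx[g->fb[f]], g->vy[g->fb[f]], g->vz[g->fb[f]]};
            double c[3] = {g->vx[g->fc[f]], g->vy[g->fc[f]], g->vz[g->fc[f]]};
            closest_on_tri(p, a, b, c, q);
            double d = std::sqrt((q[0]-p[0])*(q[0]-p[0]) + (q[1]-p[1])*(q[1]-p[1]) + (q[2]-p[2])*(q[2]-p[2]));
            if (d < *best_d) { *best_d = d; best_pt[0]=q[0]; best_pt[1]=q[1]; best_pt[2]=q[2]; }
          }
        }
      }
    }
    // cells in shell r+1 are at least r*cell - dbox away from p
    if (std::isfinite(*best_d) && *best_d <= (double)r * g->cell - dbox) break;
    // ring entirely off-grid: all larger rings are off-grid too
    if (!any_cell && r > 0 && std::isfinite(*best_d)) break;
  }
}

// [[Rcpp::export]]
List cpp_trigrid_closest(SEXP ptr, const NumericMatrix& P) {
  XPtr<TriGrid> g(ptr);
  int n = P.nrow();
  NumericMatrix Q(n, 3);
  NumericVector D(n);
  double p[3], bp[3], bd;
  for (int i = 0; i < n; ++i) {
    p[0]=P(i,0); p[1]=P(i,1); p[2]=P(i,2);
    grid_closest(g, p, bp, &bd);
    Q(i,0)=bp[0]; Q(i,1)=bp[1]; Q(i,2)=bp[2]; D[i]=bd;
  }
  return List::create(_["points"] = Q, _["dist"] = D);
}

// parity of +z ray crossings for a point, using the 2D bins
static bool point_inside(const TriGrid* g, double px, double py, double pz) {
  if (px < g->lo[0] || px > g->hi[0] || py < g->lo[1] || py > g->hi[1] ||
      pz < g->lo[2] || pz > g->hi[2]) return false;
  int i = clampi((int)((px-g->lo[0])/g->cell2), 0, g->g2[0]-1);
  int j = clampi((int)((py-g->lo[1])/g->cell2), 0, g->g2[1]-1);
  const std::vector<int>& tri = g->cells2[(size_t)i + (size_t)j*g->g2[0]];
  int crossings = 0;
  for (int f : tri) {
    double ax = g->vx[g->fa[f]], ay = g->vy[g->fa[f]], az = g->vz[g->fa[f]];
    double bx = g->vx[g->fb[f]], by = g->vy[g->fb[f]], bz = g->vz[g->fb[f]];
    double cx = g->vx[g->fc[f]], cy = g->vy[g->fc[f]], cz = g->vz[g->fc[f]];
    double d = (bx-ax)*(cy-ay) - (by-ay)*(cx-ax);
    if (d == 0.0) continue;  // vertical triangle: zero measure
    double u = ((px-ax)*(cy-ay) - (py-ay)*(cx-ax)) / d;
    double v = ((bx-ax)*(py-ay) - (by-ay)*(px-ax)) / d;
    if (u < 0 || v < 0 || u + v > 1) continue;
    double z = az + u*(bz-az) + v*(cz-az);
    if (z > pz) ++crossings;
  }
  return (crossings % 2) == 1;
}

// [[Rcpp::export]]
LogicalVector cpp_trigrid_inside(SEXP ptr, const NumericMatrix& P) {
  XPtr<TriGrid> g(ptr);
  int n = P.nrow();
  LogicalVector out(n);
  // tiny deterministic jitter avoids exact edge/vertex hits
  const double jx = 1.234567e-7, jy = 2.345678e-7;
  for (int i = 0; i < n; ++i)
    out[i] = point_inside(g, P(i,0)+jx, P(i,1)+jy, P(i,2));
  return out;
}

// Voxelize onto an axis-aligned grid (identity direction): voxel center
// (i,j,k) at origin + spacing * (i,j,k). Column parity fill along z.
// [[Rcpp::export]]
LogicalVector cpp_trigrid_voxelize(SEXP ptr, const IntegerVector& dims,
                                   const NumericVector& spacing,
                                   const NumericVector& origin) {
  XPtr<TriGrid> g(ptr);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const double jx = 1.234567e-7, jy = 2.345678e-7;
  std::vector<double> zc;
  for (int j = 0; j < ny; ++j) {
    double py = origin[1] + spacing[1]*j + jy;
    for (int i = 0; i < nx; ++i) {
      double px = origin[0] + spacing[0]*i + jx;
      if (px < g->lo[0] || px > g->hi[0] || py < g->lo[1] || py > g->hi[1]) continue;
      int ci = clampi((int)((px-g->lo[0])/g->cell2), 0, g->g2[0]-1);
      int cj = clampi((int)((py-g->lo[1])/g->cell2), 0, g->g2[1]-1);
      const std::vector<int>& tri = g->cells2[(size_t)ci + (size_t)cj*g->g2[0]];
      if (tri.empty()) continue;
      zc.clear();
      for (int f : tri) {
        double ax = g->vx[g->fa[f]], ay = g->vy[g->fa[f]], az = g->vz[g->fa[f]];
        double bx = g->vx[g->fb[f]], by = g->vy[g->fb[f]], bz = g->vz[g->fb[f]];
        double cx = g->vx[g->fc[f]], cy = g->vy[g->fc[f]], cz = g->vz[g->fc[f]];
        double d = (bx-ax)*(cy-ay) - (by-ay)*(cx-ax);
        if (d == 0.0) continue;
        double u = ((px-ax)*(cy-ay) - (py-ay)*(cx-ax)) / d;
        double v = ((bx-ax)*(py-ay) - (by-ay)*(px-ax)) / d;
        if (u < 0 || v < 0 || u + v > 1) continue;
        zc.push_back(az + u*(bz-az) + v*(cz-az));
      }
      if (zc.size() < 2) continue;
      std::sort(zc.begin(), zc.end());
      for (size_t s = 0; s + 1 < zc.size(); s += 2) {
        int k0 = (int)std::ceil((zc[s]   - origin[2]) / spacing[2]);
        int k1 = (int)std::floor((zc[s+1] - origin[2]) / spacing[2]);
        if (k1 < 0 || k0 > nz-1) continue;
        k0 = clampi(k0, 0, nz-1); k1 = clampi(k1, 0, nz-1);
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)i + (R_xlen_t)j*nx + (R_xlen_t)k*nx*ny] = true;
      }
    }
  }
  return out;
}
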