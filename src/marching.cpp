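#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Marching tetrahedra over a scalar grid. Each cube is split into the six
// tetrahedra sharing the main diagonal (0,0,0)-(1,1,1); face diagonals of
// adjacent cubes coincide, and iso-crossing vertices are interpolated once
// per canonical grid edge, so the welded output is watertight by
// construction. Triangles are wound outward (away from the >= iso region).
//
// vals: numeric array of dims (nx, ny, nz), column-major (R layout).
// Physical position of grid point (i,j,k) (0-based):
//   p = origin + D %*% (spacing * (i,j,k))
// [[Rcpp::export]]
List cpp_marching_tets(const NumericVector& vals, const IntegerVector& dims,
                       const NumericVector& spacing, const NumericVector& origin,
                       const NumericMatrix& direction, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t NXY = (int64_t)nx * ny;
  auto lin = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)j * nx + (int64_t)k * NXY;
  };

  // the six tetrahedra: paths 0 -> a -> b -> 7 over cube corners (bit-coded
  // x = 1, y = 2, z = 4)
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
  };

  std::vector<double> VX, VY, VZ;
  std::vector<int> FT;
  std::unordered_map<int64_t, int> edge_vertex;
  const int64_t NPTS = (int64_t)nx * ny * NXY;  // large stride base for keys
  (void)NPTS;

  // physical coords of a grid point
  auto phys = [&](int i, int j, int k, double* out) {
    double u = spacing[0] * i, v = spacing[1] * j, w = spacing[2] * k;
    out[0] = origin[0] + direction(0,0)*u + direction(0,1)*v + direction(0,2)*w;
    out[1] = origin[1] + direction(1,0)*u + direction(1,1)*v + direction(1,2)*w;
    out[2] = origin[2] + direction(2,0)*u + direction(2,1)*v + direction(2,2)*w;
  };

  auto edge_pt = [&](int64_t la, int64_t lb, double va, double vb,
                     const double* pa, const double* pb) -> int {
    int64_t lo = la < lb ? la : lb, hi = la < lb ? lb : la;
    // canonical order: interpolate from lo to hi
    const double *plo, *phi;
    double vlo, vhi;
    if (la < lb) { plo = pa; phi = pb; vlo = va; vhi = vb; }
    else         { plo = pb; phi = pa; vlo = vb; vhi = va; }
    int64_t key = lo * ((int64_t)nx * ny * nz) + hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (iso - vlo) / (vhi - vlo);
    int idx = (int)VX.size();
    VX.push_back(plo[0] + t * (phi[0] - plo[0]));
    VY.push_back(plo[1] + t * (phi[1] - plo[1]));
    VZ.push_back(plo[2] + t * (phi[2] - plo[2]));
    edge_vertex[key] = idx;
    return idx;
  };

  // orient (p,q,r) so the normal points away from the inside reference point
  auto emit_tri = [&](int p, int q, int r, const double* inside) {
    if (p == q || q == r || p == r) return;  // degenerate after welding
    double ux = VX[q]-VX[p], uy = VY[q]-VY[p], uz = VZ[q]-VZ[p];
    double vx = VX[r]-VX[p], vy = VY[r]-VY[p], vz = VZ[r]-VZ[p];
    double nxv = uy*vz - uz*vy, nyv = uz*vx - ux*vz, nzv = ux*vy - uy*vx;
    double gx = inside[0] - (VX[p]+VX[q]+VX[r])/3.0;
    double gy = inside[1] - (VY[p]+VY[q]+VY[r])/3.0;
    double gz = inside[2] - (VZ[p]+VZ[q]+VZ[r])/3.0;
    if (nxv*gx + nyv*gy + nzv*gz > 0) { int t = q; q = r; r = t; }
    FT.push_back(p); FT.push_back(q); FT.push_back(r);
  };

  double cp[8][3];
  double cv[8];
  int64_t cl[8];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          cl[c] = lin(ci, cj, ck);
          cv[c] = vals[cl[c]];
          if (cv[c] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          phys(ci, cj, ck, cp[c]);
        }
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int in_idx[4], out_idx[4];
          int nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cv[T[c]] >= iso) in_idx[nin++] = T[c];
            else out_idx[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          double inside[3];
          inside[0] = inside[1] = inside[2] = 0.0;
          for (int c = 0; c < nin; ++c)
            for (int a = 0; a < 3; ++a) inside[a] += cp[in_idx[c]][a];
          for (int a = 0; a < 3; ++a) inside[a] /= nin;
          if (nin == 1) {
            int A = in_idx[0];
            int e0 = edge_pt(cl[A], cl[out_idx[0]], cv[A], cv[out_idx[0]], cp[A], cp[out_idx[0]]);
            int e1 = edge_pt(cl[A], cl[out_idx[1]], cv[A], cv[out_idx[1]], cp[A], cp[out_idx[1]]);
            int e2 = edge_pt(cl[A], cl[out_idx[2]], cv[A], cv[out_idx[2]], cp[A], cp[out_idx[2]]);
            emit_tri(e0, e1, e2, inside);
          } else if (nin == 3) {
            int A = out_idx[0];
            int e0 = edge_pt(cl[A], cl[in_idx[0]], cv[A], cv[in_idx[0]], cp[A], cp[in_idx[0]]);
            int e1 = edge_pt(cl[A], cl[in_idx[1]], cv[A], cv[in_idx[1]], cp[A], cp[in_idx[1]]);
            int e2 = edge_pt(cl[A], cl[in_idx[2]], cv[A], cv[in_idx[2]], cp[A], cp[in_idx[2]]);
            emit_tri(e0, e1, e2, inside);
          } else {  // nin == 2: quad between the two inside and two outside
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int eAC = edge_pt(cl[A], cl[C], cv[A], cv[C], cp[A], cp[C]);
            int eAD = edge_pt(cl[A], cl[D], cv[A], cv[D], cp[A], cp[D]);
            int eBC = edge_pt(cl[B], cl[C], cv[B], cv[C], cp[B], cp[C]);
            int eBD = edge_pt(cl[B], cl[D], cv[B], cv[D], cp[B], cp[D]);
            emit_tri(eAC, eBC, eBD, inside);
            emit_tri(eAC, eBD, eAD, inside);
          }
        }
      }

  int nvtx = (int)VX.size();
  NumericMatrix Vout(nvtx, 3);
  for (int i = 0; i < nvtx; ++i) { Vout(i,0) = VX[i]; Vout(i,1) = VY[i]; Vout(i,2) = VZ[i]; }
  IntegerMatrix Fout(FT.size() / 3, 3);
  for (size_t i = 0; i < FT.size() / 3; ++i)
    for (int c = 0; c < 3; ++c) Fout(i, c) = FT[3*i + c];
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
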