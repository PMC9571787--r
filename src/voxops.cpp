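#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

// 26-connected component labelling of a 3D logical array (column-major).
// Labels are 1..n_components in discovery order; background is 0.
// [[Rcpp::export]]
IntegerVector cpp_label3d(const LogicalVector& mask, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n);
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    stack.clear();
    stack.push_back(s);
    labels[s] = next_label;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            R_xlen_t idx = (R_xlen_t)ii + (R_xlen_t)jj*nx + (R_xlen_t)kk*nx*ny;
            if (mask[idx] && labels[idx] == 0) {
              labels[idx] = next_label;
              stack.push_back(idx);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// Binary dilation (op = 1) or erosion (op = 0) with a ball of physical
// radius `radius_mm` on an anisotropic grid.
// [[Rcpp::export]]
LogicalVector cpp_ball_morph(const LogicalVector& mask, const IntegerVector& dims,
                             const NumericVector& spacing, double radius_mm,
                             int op) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  // offsets of the ball structuring element
  int rx = (int)std::floor(radius_mm / spacing[0] + 1e-9);
  int ry = (int)std::floor(radius_mm / spacing[1] + 1e-9);
  int rz = (int)std::floor(radius_mm / spacing[2] + 1e-9);
  std::vector<int> ox, oy, oz;
  for (int dk = -rz; dk <= rz; ++dk)
    for (int dj = -ry; dj <= ry; ++dj)
      for (int di = -rx; di <= rx; ++di) {
        double d2 = di*spacing[0]*di*spacing[0] + dj*spacing[1]*dj*spacing[1] +
                    dk*spacing[2]*dk*spacing[2];
        if (d2 <= radius_mm * radius_mm + 1e-9) {
          ox.push_back(di); oy.push_back(dj); oz.push_back(dk);
        }
      }
  LogicalVector out(n);
  const size_t no = ox.size();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)j*nx + (R_xlen_t)k*nx*ny;
        if (op == 1) {            // dilation: set if any neighbour set
          if (mask[idx]) { out[idx] = true; continue; }
          bool hit = false;
          for (size_t o = 0; o < no && !hit; ++o) {
            int ii = i + ox[o], jj = j + oy[o], kk = k + oz[o];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            if (mask[(R_xlen_t)ii + (R_xlen_t)jj*nx + (R_xlen_t)kk*nx*ny]) hit = true;
          }
          out[idx] = hit;
        } else {                  // erosion: set only if all neighbours set
          if (!mask[idx]) { out[idx] = false; continue; }
          bool all = true;
          for (size_t o = 0; o < no && all; ++o) {
            int ii = i + ox[o], jj = j + oy[o], kk = k + oz[o];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) { all = false; break; }
            if (!mask[(R_xlen_t)ii + (R_xlen_t)jj*nx + (R_xlen_t)kk*nx*ny]) all = false;
          }
          out[idx] = all;
        }
      }
  return out;
}

// Peel depth: layer 1 = voxels with a 6-neighbour outside the mask (or at the
// array border), layer 2 = voxels exposed after removing layer 1, etc.
// [[Rcpp::export]]
IntegerVector cpp_peel_layers(const LogicalVector& mask, const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector layer(n);
  std::queue<R_xlen_t> q;
  const int DI[6] = {1,-1,0,0,0,0}, DJ[6] = {0,0,1,-1,0,0}, DK[6] = {0,0,0,0,1,-1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i = (int)(s % nx), j = (int)((s / nx) % ny), k = (int)(s / ((R_xlen_t)nx * ny));
    bool boundary = false;
    for (int d = 0; d < 6 && !boundary; ++d) {
      int ii = i + DI[d], jj = j + DJ[d], kk = k + DK[d];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) { boundary = true; break; }
      if (!mask[(R_xlen_t)ii + (R_xlen_t)jj*nx + (R_xlen_t)kk*nx*ny]) boundary = true;
    }
    if (boundary) { layer[s] = 1; q.push(s); }
  }
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx * ny));
    for (int d = 0; d < 6; ++d) {
      int ii = i + DI[d], jj = j + DJ[d], kk = k + DK[d];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t idx = (R_xlen_t)ii + (R_xlen_t)jj*nx + (R_xlen_t)kk*nx*ny;
      if (mask[idx] && layer[idx] == 0) {
        layer[idx] = layer[cur] + 1;
        q.push(idx);
      }
    }
  }
  return layer;
}

// Trilinear resampling of a scalar volume onto a new grid sharing the same
// physical frame (identity direction handled on the R side; both grids are
// expressed in the volume's index space here). `coords` maps output voxel
// index to fractional input index per axis.
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(const NumericVector& vals, const IntegerVector& dims,
                                     const NumericVector& xi, const NumericVector& yi,
                                     const NumericVector& zi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = xi.size(), oy = yi.size(), oz = zi.size();
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k) {
    double z = zi[k];
    int z0 = (int)std::floor(z); double fz = z - z0;
    if (z0 < 0) { z0 = 0; fz = 0; } if (z0 > nz - 2) { z0 = nz - 2; fz = 1; }
    if (nz == 1) { z0 = 0; fz = 0; }
    for (int j = 0; j < oy; ++j) {
      double y = yi[j];
      int y0 = (int)std::floor(y); double fy = y - y0;
      if (y0 < 0) { y0 = 0; fy = 0; } if (y0 > ny - 2) { y0 = ny - 2; fy = 1; }
      if (ny == 1) { y0 = 0; fy = 0; }
      for (int i = 0; i < ox; ++i) {
        double x = xi[i];
        int x0 = (int)std::floor(x); double fx = x - x0;
        if (x0 < 0) { x0 = 0; fx = 0; } if (x0 > nx - 2) { x0 = nx - 2; fx = 1; }
        if (nx == 1) { x0 = 0; fx = 0; }
        int x1 = nx == 1 ? x0 : x0 + 1, y1 = ny == 1 ? y0 : y0 + 1, z1 = nz == 1 ? z0 : z0 + 1;
        auto at = [&](int a, int b, int c) {
          return vals[(R_xlen_t)a + (R_xlen_t)b*nx + (R_xlen_t)c*nx*ny];
        };
        double v =
          at(x0,y0,z0)*(1-fx)*(1-fy)*(1-fz) + at(x1,y0,z0)*fx*(1-fy)*(1-fz) +
          at(x0,y1,z0)*(1-fx)*fy*(1-fz)     + at(x1,y1,z0)*fx*fy*(1-fz) +
          at(x0,y0,z1)*(1-fx)*(1-fy)*fz     + at(x1,y0,z1)*fx*(1-fy)*fz +
          at(x0,y1,z1)*(1-fx)*fy*fz         + at(x1,y1,z1)*fx*fy*fz;
        out[(R_xlen_t)i + (R_xlen_t)j*ox + (R_xlen_t)k*ox*oy] = v;
      }
    }
  }
  return out;
}
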