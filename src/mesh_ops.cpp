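#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Signed volume by the divergence theorem: sum of signed tetrahedra to the
// origin. Positive for outward-wound watertight meshes.
// [[Rcpp::export]]
double cpp_signed_volume(const NumericMatrix& V, const IntegerMatrix& F) {
  double vol = 0.0;
  for (int f = 0; f < F.nrow(); ++f) {
    int a = F(f, 0), b = F(f, 1), c = F(f, 2);
    double ax = V(a,0), ay = V(a,1), az = V(a,2);
    double bx = V(b,0), by = V(b,1), bz = V(b,2);
    double cx = V(c,0), cy = V(c,1), cz = V(c,2);
    vol += ax * (by * cz - bz * cy)
         - ay * (bx * cz - bz * cx)
         + az * (bx * cy - by * cx);
  }
  return vol / 6.0;
}

// Edge bookkeeping for manifold checks. Returns counts of edges whose
// incident-face count differs from 2, and of directed edges seen more than
// once (winding inconsistency).
// [[Rcpp::export]]
List cpp_edge_audit(const IntegerMatrix& F, int n_vertices) {
  std::unordered_map<int64_t, int> undirected;
  std::unordered_map<int64_t, int> directed;
  int64_t N = (int64_t)n_vertices;
  for (int f = 0; f < F.nrow(); ++f) {
    for (int e = 0; e < 3; ++e) {
      int64_t a = F(f, e), b = F(f, (e + 1) % 3);
      int64_t lo = a < b ? a : b, hi = a < b ? b : a;
      undirected[lo * N + hi] += 1;
      directed[a * N + b] += 1;
    }
  }
  int boundary = 0, nonmanifold = 0;
  for (auto& kv : undirected) {
    if (kv.second == 1) ++boundary;
    else if (kv.second != 2) ++nonmanifold;
  }
  int bad_winding = 0;
  for (auto& kv : directed) if (kv.second > 1) ++bad_winding;
  return List::create(_["boundary_edges"] = boundary,
                      _["nonmanifold_edges"] = nonmanifold,
                      _["duplicated_directed_edges"] = bad_winding);
}

// Cut a watertight mesh with a plane, capping both halves with an identical
// (reversed) fan triangulation of the cut loops so that the two enclosed
// volumes partition the input volume exactly up to float error.
// The "neg" output is the side with dot(v - point, normal) < 0.
// [[Rcpp::export]]
List cpp_plane_cut(const NumericMatrix& V, const IntegerMatrix& F,
                   const NumericVector& point, const NumericVector& normal) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<double> d(nv);
  double scale = 0.0;
  for (int i = 0; i < nv; ++i) {
    double di = (V(i,0) - point[0]) * normal[0] +
                (V(i,1) - point[1]) * normal[1] +
                (V(i,2) - point[2]) * normal[2];
    d[i] = di;
    double m = std::fabs(V(i,0)) + std::fabs(V(i,1)) + std::fabs(V(i,2));
    if (m > scale) scale = m;
  }
  // nudge exactly-on-plane vertices off the plane so every vertex has a sign
  double eps = (scale + 1.0) * 1e-12;
  for (int i = 0; i < nv; ++i) if (std::fabs(d[i]) < eps) d[i] = eps;

  // shared vertex pool: originals first, intersection points appended
  std::vector<double> PX, PY, PZ;
  PX.reserve(nv + 64); PY.reserve(nv + 64); PZ.reserve(nv + 64);
  for (int i = 0; i < nv; ++i) { PX.push_back(V(i,0)); PY.push_back(V(i,1)); PZ.push_back(V(i,2)); }
  std::unordered_map<int64_t, int> edge_cache;
  auto cut_point = [&](int a, int b) -> int {
    int64_t lo = a < b ? a : b, hi = a < b ? b : a;
    int64_t key = lo * (int64_t)nv + hi;
    auto it = edge_cache.find(key);
    if (it != edge_cache.end()) return it->second;
    double t = d[lo] / (d[lo] - d[hi]);
    int idx = (int)PX.size();
    PX.push_back(PX[lo] + t * (PX[hi] - PX[lo]));
    PY.push_back(PY[lo] + t * (PY[hi] - PY[lo]));
    PZ.push_back(PZ[lo] + t * (PZ[hi] - PZ[lo]));
    edge_cache[key] = idx;
    return idx;
  };

  std::vector<int> Fpos, Fneg;               // face index triples
  // directed cut segments on the plane, oriented as seen from the positive side
  std::vector<std::pair<int,int>> segs;

  auto emit = [&](std::vector<int>& dst, int a, int b, int c) {
    dst.push_back(a); dst.push_back(b); dst.push_back(c);
  };

  for (int f = 0; f < nf; ++f) {
    int vi[3] = { F(f,0), F(f,1), F(f,2) };
    bool pos[3];
    int npos = 0;
    for (int k = 0; k < 3; ++k) { pos[k] = d[vi[k]] > 0; if (pos[k]) ++npos; }
    if (npos == 3) { emit(Fpos, vi[0], vi[1], vi[2]); continue; }
    if (npos == 0) { emit(Fneg, vi[0], vi[1], vi[2]); continue; }
    // rotate so that the lone vertex (on the minority side) is vi[0]
    bool lone_positive = (npos == 1);
    int lone = -1;
    for (int k = 0; k < 3; ++k) if (pos[k] == lone_positive) lone = k;
    int a = vi[lone], b = vi[(lone + 1) % 3], c = vi[(lone + 2) % 3];
    int iab = cut_point(a, b), ica = cut_point(c, a);
    if (lone_positive) {
      emit(Fpos, a, iab, ica);
      emit(Fneg, iab, b, c);
      emit(Fneg, iab, c, ica);
      // boundary of positive piece crosses a->b at iab .. c->a at ica;
      // directed along the positive face winding: ica -> iab ... wait:
      // positive triangle is (a, iab, ica); its edge on the plane is iab->ica.
      segs.push_back(std::make_pair(iab, ica));
    } else {
      emit(Fneg, a, iab, ica);
      emit(Fpos, iab, b, c);
      emit(Fpos, iab, c, ica);
      // positive quad (iab,b,c,ica); plane edge directed ica->iab
      segs.push_back(std::make_pair(ica, iab));
    }
  }

  // chain directed segments into loops and fan-triangulate about each
  // loop centroid; cap faces added to the positive side as-is and reversed
  // to the negative side.
  std::unordered_map<int,int> nxt;
  for (auto& s : segs) nxt[s.first] = s.second;
  std::vector<std::vector<int>> loops;
  std::unordered_map<int,bool> used;
  for (auto& s : segs) {
    if (used.count(s.first)) continue;
    std::vector<int> loop;
    int start = s.first, cur = start;
    size_t guard = segs.size() + 2;
    while (guard-- > 0) {
      loop.push_back(cur);
      used[cur] = true;
      auto it = nxt.find(cur);
      if (it == nxt.end()) { loop.clear(); break; }  // open chain: skip
      cur = it->second;
      if (cur == start) break;
    }
    if (loop.size() >= 3) loops.push_back(loop);
  }
  for (auto& loop : loops) {
    double cx = 0, cy = 0, cz = 0;
    for (int id : loop) { cx += PX[id]; cy += PY[id]; cz += PZ[id]; }
    double n = (double)loop.size();
    int cid = (int)PX.size();
    PX.push_back(cx / n); PY.push_back(cy / n); PZ.push_back(cz / n);
    int m = (int)loop.size();
    for (int k = 0; k < m; ++k) {
      int a = loop[k], b = loop[(k + 1) % m];
      // seg direction a->b bounds the positive piece with outward normal
      // pointing along -plane-normal; the cap of the positive piece must
      // face -normal: fan (a, b, cid) reversed appropriately below.
      emit(Fpos, b, a, cid);
      emit(Fneg, a, b, cid);
    }
  }

  int np = (int)PX.size();
  NumericMatrix P(np, 3);
  for (int i = 0; i < np; ++i) { P(i,0) = PX[i]; P(i,1) = PY[i]; P(i,2) = PZ[i]; }
  IntegerMatrix Mpos(Fpos.size() / 3, 3), Mneg(Fneg.size() / 3, 3);
  for (size_t i = 0; i < Fpos.size() / 3; ++i)
    for (int k = 0; k < 3; ++k) Mpos(i, k) = Fpos[3*i + k];
  for (size_t i = 0; i < Fneg.size() / 3; ++i)
    for (int k = 0; k < 3; ++k) Mneg(i, k) = Fneg[3*i + k];
  return List::create(_["vertices"] = P, _["faces_pos"] = Mpos,
                      _["faces_neg"] = Mneg, _["n_loops"] = (int)loops.size());
}
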