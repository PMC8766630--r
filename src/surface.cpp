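#include <Rcpp.h>
#include "geom.h"
#include <map>
#include <array>
#include <cmath>
using namespace Rcpp;

// --- Isosurface extraction ---------------------------------------------
// Tetrahedral variant of marching cubes: every sample cube is split into
// the 6 Kuhn tetrahedra sharing the main diagonal (consistent across
// neighboring cubes, hence watertight, manifold output). Vertices are
// placed by linear interpolation on grid edges; triangles are oriented
// with normals pointing from values above the iso level to values below.

struct MTState {
  std::map<std::pair<long,long>, int> vtx; // grid edge -> vertex id
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  const double *val;
  double iso;
  int nx, ny, nz;
  long gid(int x, int y, int z) const {
    return (long)z * nx * ny + (long)y * nx + x;
  }
  int edge_vertex(long a, long b, double ta[3], double tb[3]) {
    if (a > b) { std::swap(a, b); std::swap(ta, tb); }
    auto key = std::make_pair(a, b);
    auto it = vtx.find(key);
    if (it != vtx.end()) return it->second;
    double va = val[a], vb = val[b];
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int id = vx.size();
    vx.push_back(ta[0] + t * (tb[0] - ta[0]));
    vy.push_back(ta[1] + t * (tb[1] - ta[1]));
    vz.push_back(ta[2] + t * (tb[2] - ta[2]));
    vtx[key] = id;
    return id;
  }
  void emit(int a, int b, int c, const double in_pt[3]) {
    // orient so the normal points away from the "inside" (>= iso) point
    double ux = vx[b]-vx[a], uy = vy[b]-vy[a], uz = vz[b]-vz[a];
    double wx = vx[c]-vx[a], wy = vy[c]-vy[a], wz = vz[c]-vz[a];
    double nxv = uy*wz - uz*wy, nyv = uz*wx - ux*wz, nzv = ux*wy - uy*wx;
    double cx = (vx[a]+vx[b]+vx[c])/3.0 - in_pt[0];
    double cy = (vy[a]+vy[b]+vy[c])/3.0 - in_pt[1];
    double cz = (vz[a]+vz[b]+vz[c])/3.0 - in_pt[2];
    if (nxv*cx + nyv*cy + nzv*cz < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  }
};

// [[Rcpp::export]]
List marching_tets(NumericVector field, IntegerVector dims, double iso,
                   NumericVector origin, NumericVector spacing) {
  MTState st;
  st.val = REAL(field);
  st.iso = iso;
  st.nx = dims[0]; st.ny = dims[1]; st.nz = dims[2];
  // cube corner offsets, bit order x + 2y + 4z
  const int cx[8] = {0,1,0,1,0,1,0,1};
  const int cy[8] = {0,0,1,1,0,0,1,1};
  const int cz[8] = {0,0,0,0,1,1,1,1};
  // 6 Kuhn tetrahedra sharing the 0-7 diagonal
  const int tets[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  for (int z = 0; z < st.nz - 1; ++z)
    for (int y = 0; y < st.ny - 1; ++y)
      for (int x = 0; x < st.nx - 1; ++x) {
        long g[8]; double p[8][3]; bool in[8]; int nin_cube = 0;
        for (int c = 0; c < 8; ++c) {
          g[c] = st.gid(x + cx[c], y + cy[c], z + cz[c]);
          p[c][0] = origin[0] + (x + cx[c]) * spacing[0];
          p[c][1] = origin[1] + (y + cy[c]) * spacing[1];
          p[c][2] = origin[2] + (z + cz[c]) * spacing[2];
          in[c] = st.val[g[c]] >= iso;
          nin_cube += in[c];
        }
        if (nin_cube == 0 || nin_cube == 8) continue;
        for (int tt = 0; tt < 6; ++tt) {
          const int *T = tets[tt];
          int ins[4], outs[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (in[T[k]]) ins[ni++] = T[k]; else outs[no++] = T[k];
          }
          if (ni == 0 || ni == 4) continue;
          double ipt[3] = {0,0,0};
          for (int k = 0; k < ni; ++k)
            for (int d = 0; d < 3; ++d) ipt[d] += p[ins[k]][d] / ni;
          if (ni == 1) {
            int a = st.edge_vertex(g[ins[0]], g[outs[0]], p[ins[0]], p[outs[0]]);
            int b = st.edge_vertex(g[ins[0]], g[outs[1]], p[ins[0]], p[outs[1]]);
            int c = st.edge_vertex(g[ins[0]], g[outs[2]], p[ins[0]], p[outs[2]]);
            st.emit(a, b, c, ipt);
          } else if (ni == 3) {
            int a = st.edge_vertex(g[ins[0]], g[outs[0]], p[ins[0]], p[outs[0]]);
            int b = st.edge_vertex(g[ins[1]], g[outs[0]], p[ins[1]], p[outs[0]]);
            int c = st.edge_vertex(g[ins[2]], g[outs[0]], p[ins[2]], p[outs[0]]);
            st.emit(a, b, c, ipt);
          } else { // ni == 2: quad split into two triangles
            int a = st.edge_vertex(g[ins[0]], g[outs[0]], p[ins[0]], p[outs[0]]);
            int b = st.edge_vertex(g[ins[0]], g[outs[1]], p[ins[0]], p[outs[1]]);
            int c = st.edge_vertex(g[ins[1]], g[outs[1]], p[ins[1]], p[outs[1]]);
            int d = st.edge_vertex(g[ins[1]], g[outs[0]], p[ins[1]], p[outs[0]]);
            st.emit(a, b, c, ipt);
            st.emit(a, c, d, ipt);
          }
        }
      }
  int nv = st.vx.size(), nf = st.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i,0) = st.vx[i]; V(i,1) = st.vy[i]; V(i,2) = st.vz[i];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i,0) = st.tri[3*i] + 1; F(i,1) = st.tri[3*i+1] + 1;
    F(i,2) = st.tri[3*i+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// --- Ray casting -------------------------------------------------------

// Parity (crossing-number) inside test for a set of points against a
// watertight triangle mesh. Ray direction is fixed and irrational-ish to
// dodge edge/vertex degeneracies.
// [[Rcpp::export]]
LogicalVector inside_points(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  LogicalVector out(np);
  double d[3] = {0.5408803, 0.6154323, 0.5735763};
  std::vector<std::array<double,3>> vv(V.nrow());
  for (int i = 0; i < V.nrow(); ++i)
    vv[i] = {V(i,0), V(i,1), V(i,2)};
  for (int i = 0; i < np; ++i) {
    double o[3] = {P(i,0), P(i,1), P(i,2)};
    int cnt = 0; double t;
    for (int f = 0; f < nf; ++f) {
      if (rf_ray_tri(o, d, vv[F(f,0)-1].data(), vv[F(f,1)-1].data(),
                  vv[F(f,2)-1].data(), t))
        ++cnt;
    }
    out[i] = (cnt % 2) == 1;
  }
  return out;
}

// First triangle hit along direction `d` from each origin, within maxdist.
// Returns distance (or -1) and the 1-based index of the triangle hit.
// [[Rcpp::export]]
List ray_first_hit(NumericMatrix O, NumericMatrix D, NumericMatrix V,
                   IntegerMatrix F, double maxdist) {
  int np = O.nrow(), nf = F.nrow();
  NumericVector dist(np, -1.0);
  IntegerVector hit(np, 0);
  for (int i = 0; i < np; ++i) {
    double o[3] = {O(i,0), O(i,1), O(i,2)};
    double len = std::sqrt(D(i,0)*D(i,0)+D(i,1)*D(i,1)+D(i,2)*D(i,2));
    double d[3] = {D(i,0)/len, D(i,1)/len, D(i,2)/len};
    double best = maxdist; bool found = false; int bidx = 0;
    double t;
    for (int f = 0; f < nf; ++f) {
      double v0[3] = {V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
      double v1[3] = {V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
      double v2[3] = {V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
      if (rf_ray_tri(o, d, v0, v1, v2, t) && t <= best) {
        best = t; found = true; bidx = f + 1;
      }
    }
    if (found) { dist[i] = best; hit[i] = bidx; }
  }
  return List::create(_["dist"] = dist, _["tri"] = hit);
}

// For each box (center rows C, half-size h scalar per row), does any
// triangle of (V,F) intersect it?
// [[Rcpp::export]]
LogicalVector boxes_cut(NumericMatrix C, NumericVector hs, NumericMatrix V,
                        IntegerMatrix F) {
  int nb = C.nrow(), nf = F.nrow();
  LogicalVector out(nb, false);
  // precompute triangle bounding boxes for quick reject
  std::vector<std::array<double,6>> tb(nf);
  for (int f = 0; f < nf; ++f) {
    for (int k = 0; k < 3; ++k) {
      double a = V(F(f,0)-1,k), b = V(F(f,1)-1,k), c = V(F(f,2)-1,k);
      tb[f][k] = std::min(a, std::min(b, c));
      tb[f][k+3] = std::max(a, std::max(b, c));
    }
  }
  for (int i = 0; i < nb; ++i) {
    double c[3] = {C(i,0), C(i,1), C(i,2)};
    double h[3] = {hs[i], hs[i], hs[i]};
    for (int f = 0; f < nf; ++f) {
      bool rej = false;
      for (int k = 0; k < 3; ++k)
        if (tb[f][k] > c[k]+h[k] || tb[f][k+3] < c[k]-h[k]) { rej = true; break; }
      if (rej) continue;
      double v0[3] = {V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
      double v1[3] = {V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
      double v2[3] = {V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
      if (rf_tri_box(c, h, v0, v1, v2)) { out[i] = true; break; }
    }
  }
  return out;
}
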