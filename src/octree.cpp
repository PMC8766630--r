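#include <Rcpp.h>
#include "geom.h"
#include <vector>
#include <cmath>
using namespace Rcpp;

// Hierarchical Cartesian (octree) mesh generation from a watertight
// triangle surface. Starting from one root cube enclosing the geometry,
// all cells of a level are subdivided into 8 children; children entirely
// outside the geometry are deleted. Cut cells carry per-triangle lists so
// intersection tests and inside/outside decisions only consult local
// triangles; a child of an interior (non-cut, inside) cell is interior
// without any test.

struct OctCell {
  int level;
  long ix, iy, iz;        // integer coordinates at `level`
  int parent;             // index into cell array, -1 for root
  bool cut;               // intersects the surface
  bool leaf;
  std::vector<int> tris;  // surface triangles overlapping the cell (cut only)
};

static void cell_center(const OctCell &c, const double o[3], double root_edge,
                        double out[3], double &half) {
  double dx = root_edge / std::pow(2.0, c.level);
  half = dx / 2.0;
  out[0] = o[0] + (c.ix + 0.5) * dx;
  out[1] = o[1] + (c.iy + 0.5) * dx;
  out[2] = o[2] + (c.iz + 0.5) * dx;
}

// exact parity (ray-casting) inside test against the full surface;
// triangle bounding boxes are used to prune via a ray/slab test
struct InsideTester {
  const Rcpp::NumericMatrix &V;
  const Rcpp::IntegerMatrix &F;
  std::vector<std::array<double,6>> tb;
  double d[3] = {0.5408803, 0.6154323, 0.5735763};
  InsideTester(const Rcpp::NumericMatrix &V_, const Rcpp::IntegerMatrix &F_)
      : V(V_), F(F_), tb(F_.nrow()) {
    for (int f = 0; f < F.nrow(); ++f)
      for (int k = 0; k < 3; ++k) {
        double a = V(F(f,0)-1,k), b = V(F(f,1)-1,k), c = V(F(f,2)-1,k);
        tb[f][k] = std::min(a, std::min(b, c));
        tb[f][k+3] = std::max(a, std::max(b, c));
      }
  }
  bool inside(const double p[3]) const {
    int cnt = 0; double t;
    for (int f = 0; f < F.nrow(); ++f) {
      // slab test: does the forward ray touch the triangle bbox?
      double t0 = -1e300, t1 = 1e300;
      bool miss = false;
      for (int k = 0; k < 3; ++k) {
        double lo = (tb[f][k] - p[k]) / d[k], hi = (tb[f][k+3] - p[k]) / d[k];
        if (lo > hi) std::swap(lo, hi);
        t0 = std::max(t0, lo); t1 = std::min(t1, hi);
        if (t0 > t1 || t1 < 0) { miss = true; break; }
      }
      if (miss) continue;
      double v0[3] = {V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
      double v1[3] = {V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
      double v2[3] = {V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
      if (rf_ray_tri(p, d, v0, v1, v2, t)) ++cnt;
    }
    return (cnt % 2) == 1;
  }
};

// [[Rcpp::export]]
List octree_generate_cpp(NumericMatrix V, IntegerMatrix F,
                         NumericVector origin, double root_edge,
                         int l_uniform, int l_final, bool boundary_refine,
                         Nullable<NumericMatrix> patches_) {
  InsideTester tester(V, F);
  std::vector<OctCell> cells;
  OctCell root;
  root.level = 0; root.ix = root.iy = root.iz = 0; root.parent = -1;
  root.cut = true; root.leaf = true;
  root.tris.resize(F.nrow());
  for (int f = 0; f < F.nrow(); ++f) root.tris[f] = f;
  cells.push_back(root);

  NumericMatrix patches = patches_.isNotNull() ? NumericMatrix(patches_)
                                               : NumericMatrix(0, 6);
  const double o[3] = {origin[0], origin[1], origin[2]};

  std::vector<int> current; current.push_back(0);
  for (int lvl = 1; lvl <= l_final; ++lvl) {
    std::vector<int> next;
    bool uniform_phase = lvl <= l_uniform;
    for (int ci : current) {
      // refinement decision past the uniform phase
      if (!uniform_phase) {
        bool refine = false;
        if (boundary_refine && cells[ci].cut) refine = true;
        if (!refine && patches.nrow() > 0) {
          double cc[3], half;
          cell_center(cells[ci], o, root_edge, cc, half);
          for (int pr = 0; pr < patches.nrow(); ++pr) {
            if (cc[0] >= patches(pr,0) && cc[0] <= patches(pr,3) &&
                cc[1] >= patches(pr,1) && cc[1] <= patches(pr,4) &&
                cc[2] >= patches(pr,2) && cc[2] <= patches(pr,5)) {
              refine = true; break;
            }
          }
        }
        if (!refine) continue;
      }
      cells[ci].leaf = false;
      int n_children = 0;
      double child_dx = root_edge / std::pow(2.0, lvl);
      for (int k = 0; k < 8; ++k) {
        OctCell ch;
        ch.level = lvl;
        ch.ix = 2*cells[ci].ix + (k & 1);
        ch.iy = 2*cells[ci].iy + ((k >> 1) & 1);
        ch.iz = 2*cells[ci].iz + ((k >> 2) & 1);
        ch.parent = ci;
        ch.leaf = true;
        double cc[3] = {o[0] + (ch.ix + 0.5) * child_dx,
                        o[1] + (ch.iy + 0.5) * child_dx,
                        o[2] + (ch.iz + 0.5) * child_dx};
        double h[3] = {child_dx/2, child_dx/2, child_dx/2};
        if (!cells[ci].cut) {
          ch.cut = false; // interior parent: child interior, keep
        } else {
          // collect local triangles
          for (int f : cells[ci].tris) {
            double v0[3] = {V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
            double v1[3] = {V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
            double v2[3] = {V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
            if (rf_tri_box(cc, h, v0, v1, v2)) ch.tris.push_back(f);
          }
          ch.cut = !ch.tris.empty();
          if (!ch.cut) {
            // delete children located outside the geometry
            if (!tester.inside(cc)) continue;
          }
        }
        int id = cells.size();
        cells.push_back(std::move(ch));
        next.push_back(id);
        ++n_children;
      }
      if (n_children == 0) cells[ci].leaf = true;
    }
    current.swap(next);
    if (current.empty()) break;
  }

  int n = cells.size();
  IntegerVector lv(n), parent(n);
  NumericVector cx(n), cy(n), cz(n), dxs(n);
  LogicalVector cut(n), leaf(n);
  for (int i = 0; i < n; ++i) {
    double cc[3], half;
    cell_center(cells[i], o, root_edge, cc, half);
    lv[i] = cells[i].level;
    parent[i] = cells[i].parent + 1; // 1-based, 0 = none
    cx[i] = cc[0]; cy[i] = cc[1]; cz[i] = cc[2];
    dxs[i] = 2*half;
    cut[i] = cells[i].cut;
    leaf[i] = cells[i].leaf;
  }
  IntegerVector iix(n), iiy(n), iiz(n);
  for (int i = 0; i < n; ++i) {
    iix[i] = cells[i].ix; iiy[i] = cells[i].iy; iiz[i] = cells[i].iz;
  }

  // wall distances for cut leaves: fraction q of the link length along each
  // of the 27 lattice directions to the first local triangle hit, plus the
  // triangle index of the overall nearest hit (to carry patch labels)
  std::vector<int> cutleaf;
  for (int i = 0; i < n; ++i)
    if (cells[i].leaf && cells[i].cut) cutleaf.push_back(i);
  int ncut = cutleaf.size();
  NumericMatrix qmat(ncut, 27);
  std::fill(qmat.begin(), qmat.end(), NA_REAL);
  IntegerVector nearest_tri(ncut, 0);
  for (int k = 0; k < ncut; ++k) {
    const OctCell &c = cells[cutleaf[k]];
    double cc[3], half;
    cell_center(c, o, root_edge, cc, half);
    double dx = 2*half;
    double bestq = 1e300;
    for (int i = 0; i < 27; ++i) {
      int exd = i % 3 - 1, eyd = (i / 3) % 3 - 1, ezd = i / 9 - 1;
      if (!exd && !eyd && !ezd) continue;
      double len = std::sqrt((double)(exd*exd + eyd*eyd + ezd*ezd)) * dx;
      double d[3] = {exd/std::sqrt((double)(exd*exd+eyd*eyd+ezd*ezd)),
                     eyd/std::sqrt((double)(exd*exd+eyd*eyd+ezd*ezd)),
                     ezd/std::sqrt((double)(exd*exd+eyd*eyd+ezd*ezd))};
      double best = len; bool found = false; int btri = 0; double t;
      for (int f : c.tris) {
        double v0[3] = {V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
        double v1[3] = {V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
        double v2[3] = {V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
        if (rf_ray_tri(cc, d, v0, v1, v2, t) && t <= best) {
          best = t; found = true; btri = f + 1;
        }
      }
      if (found) {
        qmat(k, i) = best / len;
        if (best / len < bestq) { bestq = best / len; nearest_tri[k] = btri; }
      }
    }
  }
  IntegerVector cutleaf1(ncut);
  for (int k = 0; k < ncut; ++k) cutleaf1[k] = cutleaf[k] + 1;

  return List::create(
    _["level"] = lv, _["ix"] = iix, _["iy"] = iiy, _["iz"] = iiz,
    _["parent"] = parent, _["cx"] = cx, _["cy"] = cy, _["cz"] = cz,
    _["dx"] = dxs, _["cut"] = cut, _["leaf"] = leaf,
    _["cut_leaf"] = cutleaf1, _["q"] = qmat, _["nearest_tri"] = nearest_tri);
}

// For each point, scan the 27 lattice link directions: distance fraction
// q of the link length (|xi| * dx) to the first surface hit, and the
// triangle index of that hit. Triangle bounding boxes prune via a
// ray/slab test. Used to (re)derive wall distances and boundary-patch
// labels for the solver lattice.
// [[Rcpp::export]]
List link_scan_cpp(NumericMatrix P, double dx, NumericMatrix V,
                   IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  std::vector<std::array<double,6>> tb(nf);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      double a = V(F(f,0)-1,k), b = V(F(f,1)-1,k), c = V(F(f,2)-1,k);
      tb[f][k] = std::min(a, std::min(b, c));
      tb[f][k+3] = std::max(a, std::max(b, c));
    }
  NumericMatrix qmat(np, 27);
  std::fill(qmat.begin(), qmat.end(), NA_REAL);
  IntegerMatrix tri(np, 27);
  for (int i = 0; i < np; ++i) {
    double o[3] = {P(i,0), P(i,1), P(i,2)};
    for (int dir = 0; dir < 27; ++dir) {
      int exd = dir % 3 - 1, eyd = (dir / 3) % 3 - 1, ezd = dir / 9 - 1;
      if (!exd && !eyd && !ezd) continue;
      double nl = std::sqrt((double)(exd*exd + eyd*eyd + ezd*ezd));
      double len = nl * dx;
      double d[3] = {exd/nl, eyd/nl, ezd/nl};
      double best = len; bool found = false; int btri = 0; double t;
      for (int f = 0; f < nf; ++f) {
        double t0 = 0, t1 = best;
        bool miss = false;
        for (int k = 0; k < 3; ++k) {
          if (d[k] == 0) {
            if (o[k] < tb[f][k] - 1e-12 || o[k] > tb[f][k+3] + 1e-12) {
              miss = true; break;
            }
            continue;
          }
          double lo = (tb[f][k] - o[k]) / d[k], hi = (tb[f][k+3] - o[k]) / d[k];
          if (lo > hi) std::swap(lo, hi);
          t0 = std::max(t0, lo); t1 = std::min(t1, hi);
          if (t0 > t1) { miss = true; break; }
        }
        if (miss) continue;
        double v0[3] = {V(F(f,0)-1,0), V(F(f,0)-1,1), V(F(f,0)-1,2)};
        double v1[3] = {V(F(f,1)-1,0), V(F(f,1)-1,1), V(F(f,1)-1,2)};
        double v2[3] = {V(F(f,2)-1,0), V(F(f,2)-1,1), V(F(f,2)-1,2)};
        if (rf_ray_tri(o, d, v0, v1, v2, t) && t <= best) {
          best = t; found = true; btri = f + 1;
        }
      }
      if (found) { qmat(i, dir) = best / len; tri(i, dir) = btri; }
    }
  }
  return List::create(_["q"] = qmat, _["tri"] = tri);
}
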