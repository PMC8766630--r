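#ifndef RHINOFLOW_GEOM_H
#define RHINOFLOW_GEOM_H
#include <cmath>
#include <algorithm>

// Moeller-Trumbore ray/triangle intersection; returns t > 0 on hit.
inline bool rf_ray_tri(const double o[3], const double d[3],
                       const double *v0, const double *v1, const double *v2,
                       double &t) {
  const double EPS = 1e-12;
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int k = 0; k < 3; ++k) { e1[k] = v1[k]-v0[k]; e2[k] = v2[k]-v0[k]; }
  pv[0] = d[1]*e2[2]-d[2]*e2[1];
  pv[1] = d[2]*e2[0]-d[0]*e2[2];
  pv[2] = d[0]*e2[1]-d[1]*e2[0];
  double det = e1[0]*pv[0]+e1[1]*pv[1]+e1[2]*pv[2];
  if (std::fabs(det) < EPS) return false;
  double inv = 1.0/det;
  for (int k = 0; k < 3; ++k) tv[k] = o[k]-v0[k];
  double u = (tv[0]*pv[0]+tv[1]*pv[1]+tv[2]*pv[2])*inv;
  if (u < -1e-10 || u > 1+1e-10) return false;
  qv[0] = tv[1]*e1[2]-tv[2]*e1[1];
  qv[1] = tv[2]*e1[0]-tv[0]*e1[2];
  qv[2] = tv[0]*e1[1]-tv[1]*e1[0];
  double v = (d[0]*qv[0]+d[1]*qv[1]+d[2]*qv[2])*inv;
  if (v < -1e-10 || u+v > 1+1e-10) return false;
  t = (e2[0]*qv[0]+e2[1]*qv[1]+e2[2]*qv[2])*inv;
  return t > 1e-10;
}

// Akenine-Moeller triangle/axis-aligned-box separating axis test.
inline bool rf_tri_box(const double c[3], const double h[3],
                       const double *u0, const double *u1, const double *u2) {
  double v0[3], v1[3], v2[3];
  for (int k = 0; k < 3; ++k) {
    v0[k] = u0[k]-c[k]; v1[k] = u1[k]-c[k]; v2[k] = u2[k]-c[k];
  }
  for (int k = 0; k < 3; ++k) {
    double mn = std::min(v0[k], std::min(v1[k], v2[k]));
    double mx = std::max(v0[k], std::max(v1[k], v2[k]));
    if (mn > h[k] || mx < -h[k]) return false;
  }
  double e0[3], e1[3], e2[3];
  for (int k = 0; k < 3; ++k) {
    e0[k] = v1[k]-v0[k]; e1[k] = v2[k]-v1[k]; e2[k] = v0[k]-v2[k];
  }
  double n[3] = {e0[1]*e1[2]-e0[2]*e1[1], e0[2]*e1[0]-e0[0]*e1[2],
                 e0[0]*e1[1]-e0[1]*e1[0]};
  double d = n[0]*v0[0]+n[1]*v0[1]+n[2]*v0[2];
  double r = h[0]*std::fabs(n[0])+h[1]*std::fabs(n[1])+h[2]*std::fabs(n[2]);
  if (std::fabs(d) > r) return false;
  const double *E[3] = {e0, e1, e2};
  const double *Vv[3] = {v0, v1, v2};
  for (int ei = 0; ei < 3; ++ei) {
    const double *e = E[ei];
    for (int k = 0; k < 3; ++k) {
      int a = (k+1)%3, b = (k+2)%3;
      double ax[3] = {0,0,0};
      ax[a] = -e[b]; ax[b] = e[a];
      double p0 = ax[0]*Vv[0][0]+ax[1]*Vv[0][1]+ax[2]*Vv[0][2];
      double p1 = ax[0]*Vv[1][0]+ax[1]*Vv[1][1]+ax[2]*Vv[1][2];
      double p2 = ax[0]*Vv[2][0]+ax[1]*Vv[2][1]+ax[2]*Vv[2][2];
      double mn = std::min(p0, std::min(p1, p2));
      double mx = std::max(p0, std::max(p1, p2));
      double rr = h[0]*std::fabs(ax[0])+h[1]*std::fabs(ax[1])+h[2]*std::fabs(ax[2]);
      if (mn > rr || mx < -rr) return false;
    }
  }
  return true;
}
#endif
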