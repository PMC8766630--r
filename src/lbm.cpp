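#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// D3Q27 thermal lattice-Boltzmann stepper (BGK for the particle
// distributions f, total-energy distributions h on the same lattice).
// Direction index i in 0..26 encodes the velocity (dx,dy,dz) with
// dx = i%3-1, dy = (i/3)%3-1, dz = i/9-1; the rest direction is i=13 and
// the opposite of i is 26-i. c_s^2 = 1/3, dt = dx = 1 (lattice units).
//
// Boundary handling:
//  * missing neighbor + wall link: Bouzidi linear interpolated bounce-back
//    for f (two branches, q<1/2 and q>=1/2); interpolated anti-bounce-back
//    enforcing the wall total energy (temperature T_wall) for h.
//  * open cells (otype>0): after streaming, all populations are rebuilt by
//    non-equilibrium extrapolation from the interior neighbor, with the
//    density given by the group's mode: fixed pressure offset, the
//    Saint-Venant/Wantzel relation (nostrils), or a volume-flux controller
//    that adapts the pressure from the Reynolds-number error each step.

static const double CS2 = 1.0 / 3.0;

struct Lat {
  int ex[27], ey[27], ez[27];
  double w[27];
  Lat() {
    for (int i = 0; i < 27; ++i) {
      ex[i] = i % 3 - 1; ey[i] = (i / 3) % 3 - 1; ez[i] = i / 9 - 1;
      int m = std::abs(ex[i]) + std::abs(ey[i]) + std::abs(ez[i]);
      w[i] = (m == 0) ? 8.0/27.0 : (m == 1) ? 2.0/27.0 :
             (m == 2) ? 1.0/54.0 : 1.0/216.0;
    }
  }
};
static Lat L;

static inline void feq27(double rho, double vx, double vy, double vz,
                         double *F) {
  double v2 = vx*vx + vy*vy + vz*vz;
  for (int i = 0; i < 27; ++i) {
    double ev = L.ex[i]*vx + L.ey[i]*vy + L.ez[i]*vz;
    F[i] = rho * L.w[i] * (1.0 + 3.0*ev + 4.5*ev*ev - 1.5*v2);
  }
}

// total-energy equilibrium; E = (D/2) R T + v^2/2, D = 3
static inline void heq27(double rho, double vx, double vy, double vz,
                         double T, double Rlat, const double *F, double *H) {
  double v2 = vx*vx + vy*vy + vz*vz;
  double E = 1.5 * Rlat * T + 0.5 * v2;
  for (int i = 0; i < 27; ++i) {
    double ev = L.ex[i]*vx + L.ey[i]*vy + L.ez[i]*vz;
    double xi2 = L.ex[i]*L.ex[i] + L.ey[i]*L.ey[i] + L.ez[i]*L.ez[i];
    H[i] = rho * L.w[i] * (ev + ev*ev/CS2 - v2 + 0.5*(xi2 - 3.0*CS2))
           + E * F[i];
  }
}

// [[Rcpp::export]]
NumericVector d3q27_weights_cpp() {
  NumericVector w(27);
  for (int i = 0; i < 27; ++i) w[i] = L.w[i];
  return w;
}

// [[Rcpp::export]]
List lbm_run_cpp(IntegerMatrix nb, NumericMatrix qmat,
                 IntegerVector otype, IntegerVector onormal,
                 List open_groups,
                 Nullable<NumericMatrix> f0, Nullable<NumericMatrix> h0,
                 double omega, double omega_t, bool thermal,
                 double Rlat, double T0, NumericVector T_wall, double gamma_sv,
                 int n_iter, int avg_iter, int monitor_every) {
  int nc = nb.nrow();
  int ng = open_groups.size();
  std::vector<int> gmode(ng); std::vector<double> gdp(ng), gre(ng), gdh(ng),
      ggain(ng), gsign(ng), gT(ng), gpctrl(ng, 0.0);
  for (int g = 0; g < ng; ++g) {
    List gg = open_groups[g];
    gmode[g] = as<int>(gg["mode"]);
    gdp[g]   = gg.containsElementNamed("dp") ? as<double>(gg["dp"]) : 0.0;
    gre[g]   = gg.containsElementNamed("re_target") ? as<double>(gg["re_target"]) : 0.0;
    gdh[g]   = gg.containsElementNamed("d_h") ? as<double>(gg["d_h"]) : 1.0;
    ggain[g] = gg.containsElementNamed("gain") ? as<double>(gg["gain"]) : 1e-6;
    gsign[g] = gg.containsElementNamed("sign") ? as<double>(gg["sign"]) : -1.0;
    gT[g]    = gg.containsElementNamed("T") ? as<double>(gg["T"]) : NA_REAL;
    if (gg.containsElementNamed("p0")) gpctrl[g] = as<double>(gg["p0"]);
  }
  double nu_lat = CS2 * (1.0/omega - 0.5);

  // flat state arrays
  std::vector<double> f(nc*27), fn(nc*27), h, hn;
  if (thermal) { h.resize(nc*27); hn.resize(nc*27); }
  if (f0.isNotNull()) {
    NumericMatrix F0(f0);
    for (int c = 0; c < nc; ++c)
      for (int i = 0; i < 27; ++i) f[c*27+i] = F0(c, i);
  } else {
    double Fi[27]; feq27(1.0, 0, 0, 0, Fi);
    for (int c = 0; c < nc; ++c)
      for (int i = 0; i < 27; ++i) f[c*27+i] = Fi[i];
  }
  if (thermal) {
    if (h0.isNotNull()) {
      NumericMatrix H0(h0);
      for (int c = 0; c < nc; ++c)
        for (int i = 0; i < 27; ++i) h[c*27+i] = H0(c, i);
    } else {
      double Fi[27], Hi[27];
      feq27(1.0, 0, 0, 0, Fi);
      heq27(1.0, 0, 0, 0, T0, Rlat, Fi, Hi);
      for (int c = 0; c < nc; ++c)
        for (int i = 0; i < 27; ++i) h[c*27+i] = Hi[i];
    }
  }

  // neighbor table to raw int, 0-based with -1 absent
  std::vector<int> NB(nc*27);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < 27; ++i) NB[c*27+i] = nb(c, i);
  std::vector<double> QQ(nc*27, 0.5);
  for (int c = 0; c < nc; ++c)
    for (int i = 0; i < 27; ++i) {
      double qv = qmat(c, i);
      QQ[c*27+i] = (R_IsNA(qv) || qv <= 0 || qv > 1) ? 0.5 : qv;
    }

  // moments cache per cell (of pre-collision state)
  std::vector<double> rho(nc), vx(nc), vy(nc), vz(nc), TT(nc, T0);

  // averaging accumulators
  std::vector<double> a_rho(nc, 0), a_vx(nc, 0), a_vy(nc, 0), a_vz(nc, 0),
      a_T(nc, 0);
  long n_avg = 0;

  // monitor storage
  std::vector<double> mon_step, mon_mass;
  std::vector<std::vector<double>> mon_p(ng), mon_vn(ng), mon_re(ng),
      mon_pc(ng), mon_T(ng);

  // per-group open cell lists
  std::vector<std::vector<int>> gcells(ng);
  for (int c = 0; c < nc; ++c)
    if (otype[c] > 0) gcells[otype[c]-1].push_back(c);

  int total = n_iter + avg_iter;
  bool diverged = false;
  double Fi[27], Hi[27], Fn[27], Hn[27];

  for (int it = 0; it < total && !diverged; ++it) {
    // --- moments + collide (in place) ---
    for (int c = 0; c < nc; ++c) {
      double *fc = &f[c*27];
      double r = 0, jx = 0, jy = 0, jz = 0;
      for (int i = 0; i < 27; ++i) {
        r += fc[i];
        jx += L.ex[i]*fc[i]; jy += L.ey[i]*fc[i]; jz += L.ez[i]*fc[i];
      }
      if (!(r > 0) || !std::isfinite(r)) { diverged = true; break; }
      double ux = jx/r, uy = jy/r, uz = jz/r;
      rho[c] = r; vx[c] = ux; vy[c] = uy; vz[c] = uz;
      feq27(r, ux, uy, uz, Fi);
      if (thermal) {
        double *hc = &h[c*27];
        double he = 0;
        for (int i = 0; i < 27; ++i) he += hc[i];
        double v2 = ux*ux + uy*uy + uz*uz;
        double Tc = (he/r - 0.5*v2) / (1.5*Rlat);
        TT[c] = Tc;
        heq27(r, ux, uy, uz, Tc, Rlat, Fi, Hi);
        double dw = omega_t - omega;
        for (int i = 0; i < 27; ++i) {
          double ev = L.ex[i]*ux + L.ey[i]*uy + L.ez[i]*uz;
          hc[i] += omega_t*(Hi[i] - hc[i])
                   + dw * (ev - 0.5*v2) * (fc[i] - Fi[i]);
        }
      }
      for (int i = 0; i < 27; ++i) fc[i] += omega*(Fi[i] - fc[i]);
    }
    if (diverged) break;

    // --- stream + wall bounce-back ---
    for (int c = 0; c < nc; ++c) {
      const double *fc = &f[c*27];
      fn[c*27+13] = fc[13];
      if (thermal) hn[c*27+13] = h[c*27+13];
      bool open_c = otype[c] > 0;
      for (int i = 0; i < 27; ++i) {
        if (i == 13) continue;
        int n = NB[c*27+i];
        if (n >= 0) {
          fn[n*27+i] = fc[i];
          if (thermal) hn[n*27+i] = h[c*27+i];
        } else if (!open_c) {
          // wall link: Bouzidi for f
          int io = 26 - i;
          double qv = QQ[c*27+i];
          int up = NB[c*27+io]; // fluid neighbor upstream (c - xi_i)
          double val;
          if (qv < 0.5 && up >= 0 && otype[up] == 0) {
            val = 2.0*qv*fc[i] + (1.0-2.0*qv)*f[up*27+i];
          } else if (qv >= 0.5) {
            val = fc[i]/(2.0*qv) + (1.0 - 1.0/(2.0*qv))*fc[io];
          } else {
            val = fc[i]; // halfway fallback
          }
          fn[c*27+io] = val;
          if (thermal) {
            // anti-bounce-back against the wall total energy at T_wall
            feq27(rho[c], 0, 0, 0, Fn);
            heq27(rho[c], 0, 0, 0, T_wall[c], Rlat, Fn, Hn);
            hn[c*27+io] = -h[c*27+i] + 2.0*Hn[i];
          }
        }
        // open cells: populations rebuilt below
      }
    }

    // --- controller update (volume-flux groups) ---
    for (int g = 0; g < ng; ++g) {
      if (gmode[g] != 3) continue;
      double vn = 0; int cnt = 0;
      for (int c : gcells[g]) {
        int inner = NB[c*27 + onormal[c]];
        if (inner < 0) inner = c;
        double nxv = L.ex[onormal[c]], nyv = L.ey[onormal[c]],
               nzv = L.ez[onormal[c]];
        double nl = std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
        vn += (vx[inner]*nxv + vy[inner]*nyv + vz[inner]*nzv) / nl;
        ++cnt;
      }
      if (cnt) vn /= cnt;
      double re_cur = std::fabs(vn) * gdh[g] / nu_lat;
      gpctrl[g] += gsign[g] * ggain[g] * (gre[g] - re_cur);
    }

    // --- open boundary cells: non-equilibrium extrapolation ---
    for (int g = 0; g < ng; ++g) {
      for (int c : gcells[g]) {
        int inner = NB[c*27 + onormal[c]];
        if (inner < 0) inner = c;
        double *fi = &fn[inner*27];
        double r = 0, jx = 0, jy = 0, jz = 0;
        for (int i = 0; i < 27; ++i) {
          r += fi[i];
          jx += L.ex[i]*fi[i]; jy += L.ey[i]*fi[i]; jz += L.ez[i]*fi[i];
        }
        if (!(r > 0)) { diverged = true; break; }
        double ux = jx/r, uy = jy/r, uz = jz/r;
        double rb;
        if (gmode[g] == 1) {          // fixed pressure offset
          rb = 1.0 + gdp[g] / CS2;
        } else if (gmode[g] == 2) {   // Saint-Venant/Wantzel
          double mom2 = (r*ux)*(r*ux) + (r*uy)*(r*uy) + (r*uz)*(r*uz);
          double br = 1.0 - (gamma_sv - 1.0)/(2.0*gamma_sv) * (3.0/(r*r)) * mom2;
          if (br <= 0) { diverged = true; break; }
          rb = std::pow(br, gamma_sv/(gamma_sv - 1.0));
        } else {                      // controller-adapted pressure
          rb = 1.0 + gpctrl[g] / CS2;
        }
        feq27(r, ux, uy, uz, Fi);
        feq27(rb, ux, uy, uz, Fn);
        double *fb = &fn[c*27];
        for (int i = 0; i < 27; ++i) fb[i] = Fn[i] + (fi[i] - Fi[i]);
        if (thermal) {
          double *hi = &hn[inner*27];
          double he = 0;
          for (int i = 0; i < 27; ++i) he += hi[i];
          double v2 = ux*ux + uy*uy + uz*uz;
          double Tn = (he/r - 0.5*v2) / (1.5*Rlat);
          double Tb = R_IsNA(gT[g]) ? Tn : gT[g];
          heq27(r, ux, uy, uz, Tn, Rlat, Fi, Hi);
          heq27(rb, ux, uy, uz, Tb, Rlat, Fn, Hn);
          double *hb = &hn[c*27];
          for (int i = 0; i < 27; ++i) hb[i] = Hn[i] + (hi[i] - Hi[i]);
        }
      }
      if (diverged) break;
    }
    if (diverged) break;

    f.swap(fn);
    if (thermal) h.swap(hn);

    // --- averaging (over the last avg_iter iterations) ---
    if (it >= n_iter) {
      ++n_avg;
      for (int c = 0; c < nc; ++c) {
        const double *fc = &f[c*27];
        double r = 0, jx = 0, jy = 0, jz = 0;
        for (int i = 0; i < 27; ++i) {
          r += fc[i];
          jx += L.ex[i]*fc[i]; jy += L.ey[i]*fc[i]; jz += L.ez[i]*fc[i];
        }
        double ux = jx/r, uy = jy/r, uz = jz/r;
        a_rho[c] += r; a_vx[c] += ux; a_vy[c] += uy; a_vz[c] += uz;
        if (thermal) {
          const double *hc = &h[c*27];
          double he = 0;
          for (int i = 0; i < 27; ++i) he += hc[i];
          a_T[c] += (he/r - 0.5*(ux*ux+uy*uy+uz*uz)) / (1.5*Rlat);
        }
      }
    }

    // --- monitors ---
    if (monitor_every > 0 && ((it + 1) % monitor_every == 0)) {
      double mass = 0;
      for (int c = 0; c < nc; ++c)
        for (int i = 0; i < 27; ++i) mass += f[c*27+i];
      mon_step.push_back(it + 1);
      mon_mass.push_back(mass);
      for (int g = 0; g < ng; ++g) {
        double pm = 0, vm = 0, tm = 0; int cnt = 0;
        for (int c : gcells[g]) {
          const double *fc = &f[c*27];
          double r = 0, jx = 0, jy = 0, jz = 0;
          for (int i = 0; i < 27; ++i) {
            r += fc[i];
            jx += L.ex[i]*fc[i]; jy += L.ey[i]*fc[i]; jz += L.ez[i]*fc[i];
          }
          pm += r * CS2;
          double nxv = L.ex[onormal[c]], nyv = L.ey[onormal[c]],
                 nzv = L.ez[onormal[c]];
          double nl = std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
          vm += (jx*nxv + jy*nyv + jz*nzv) / (r*nl);
          if (thermal) {
            const double *hc = &h[c*27];
            double he = 0;
            for (int i = 0; i < 27; ++i) he += hc[i];
            tm += (he/r - 0.5*(jx*jx+jy*jy+jz*jz)/(r*r)) / (1.5*Rlat);
          }
          ++cnt;
        }
        if (cnt) { pm /= cnt; vm /= cnt; tm /= cnt; }
        mon_p[g].push_back(pm);
        mon_vn[g].push_back(vm);
        mon_re[g].push_back(std::fabs(vm) * gdh[g] / nu_lat);
        mon_pc[g].push_back(gpctrl[g]);
        mon_T[g].push_back(tm);
      }
    }
  }

  // final moments
  NumericVector out_rho(nc), out_T(nc);
  NumericMatrix out_v(nc, 3), out_f(nc, 27), out_h(thermal ? nc : 0, thermal ? 27 : 0);
  NumericVector av_rho(nc), av_T(nc);
  NumericMatrix av_v(nc, 3);
  for (int c = 0; c < nc; ++c) {
    const double *fc = &f[c*27];
    double r = 0, jx = 0, jy = 0, jz = 0;
    for (int i = 0; i < 27; ++i) {
      out_f(c, i) = fc[i];
      r += fc[i];
      jx += L.ex[i]*fc[i]; jy += L.ey[i]*fc[i]; jz += L.ez[i]*fc[i];
    }
    out_rho[c] = r;
    out_v(c,0) = jx/r; out_v(c,1) = jy/r; out_v(c,2) = jz/r;
    if (thermal) {
      const double *hc = &h[c*27];
      double he = 0;
      for (int i = 0; i < 27; ++i) { out_h(c, i) = hc[i]; he += hc[i]; }
      double v2 = out_v(c,0)*out_v(c,0)+out_v(c,1)*out_v(c,1)+out_v(c,2)*out_v(c,2);
      out_T[c] = (he/r - 0.5*v2) / (1.5*Rlat);
    }
    if (n_avg > 0) {
      av_rho[c] = a_rho[c]/n_avg;
      av_v(c,0) = a_vx[c]/n_avg; av_v(c,1) = a_vy[c]/n_avg;
      av_v(c,2) = a_vz[c]/n_avg;
      if (thermal) av_T[c] = a_T[c]/n_avg;
    }
  }

  List mons = List::create(
    _["step"] = wrap(mon_step), _["mass"] = wrap(mon_mass));
  List gm(ng);
  for (int g = 0; g < ng; ++g)
    gm[g] = List::create(_["p_stat"] = wrap(mon_p[g]),
                         _["v_n"] = wrap(mon_vn[g]),
                         _["re"] = wrap(mon_re[g]),
                         _["p_ctrl"] = wrap(mon_pc[g]),
                         _["T"] = wrap(mon_T[g]));
  NumericVector pc(ng);
  for (int g = 0; g < ng; ++g) pc[g] = gpctrl[g];
  return List::create(
    _["f"] = out_f, _["h"] = out_h,
    _["rho"] = out_rho, _["v"] = out_v, _["T"] = out_T,
    _["avg_rho"] = av_rho, _["avg_v"] = av_v, _["avg_T"] = av_T,
    _["n_avg"] = (double)n_avg,
    _["monitors"] = mons, _["group_monitors"] = gm,
    _["p_ctrl"] = pc, _["diverged"] = diverged);
}
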