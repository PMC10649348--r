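// Staggered-grid incompressible two-phase solver kernels:
//  - explicit upwind momentum predictor with variable density/viscosity,
//    CSF surface tension and an optional near-wall momentum sink
//  - variable-coefficient pressure projection (red/black SOR, warm start)
//  - donor-acceptor VOF advection with coupled fibrinogen transport
//  - explicit in-phase species diffusion
//
// Conventions (0-based): u(i,j), i = 0..nx, face between cells (i-1,j),(i,j);
// v(i,j), j = 0..ny, face between (i,j-1),(i,j); cell fields are nx x ny.
// Left edge (x = 0) is a symmetry plane; right column is the bone wall.
//
// All hot-loop state lives in plain std::vector buffers (allocated once per
// advance call); R objects are only touched at the interface.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const int CFLUID = 0, CIMPLANT = 1, CBONE = 2,
                 CIN_APEX = 3, CIN_BONE = 4, COUTLET = 5;

static inline bool is_solid(int c) { return c == CIMPLANT || c == CBONE; }
static inline bool is_mom(int c) { return c == CFLUID || c == COUTLET; }
static inline bool is_wet(int c) { return !is_solid(c); }

typedef std::vector<double> vec;

struct Par {
  double h, rho_b, mu_b, rho_g, mu_g, sigma, theta_imp, theta_bone;
  double inlet_speed, Y0, p_tol; int p_maxit, smooth_passes;
  bool pressure_inlet; double p_inlet;
};

static Par read_par(const List& par) {
  Par p;
  p.h = as<double>(par["h"]);
  p.rho_b = as<double>(par["rho_b"]); p.mu_b = as<double>(par["mu_b"]);
  p.rho_g = as<double>(par["rho_g"]); p.mu_g = as<double>(par["mu_g"]);
  p.sigma = as<double>(par["sigma"]);
  p.theta_imp = as<double>(par["theta_imp"]);
  p.theta_bone = as<double>(par["theta_bone"]);
  p.inlet_speed = as<double>(par["inlet_speed"]);
  p.Y0 = as<double>(par["Y0"]);
  p.p_tol = as<double>(par["p_tol"]);
  p.p_maxit = as<int>(par["p_maxit"]);
  p.smooth_passes = as<int>(par["smooth_passes"]);
  p.pressure_inlet = as<bool>(par["pressure_inlet"]);
  p.p_inlet = as<double>(par["p_inlet"]);
  return p;
}

// Grid-sized working set. u has stride nx+1 (ny rows); v stride nx (ny+1
// rows); cell arrays stride nx (ny rows).
struct Work {
  int nx, ny;
  std::vector<int> cls;
  vec u, v, p, a, c, sink;
  // scratch
  vec us, vs, as_, tmp, nxm, nym, kap, Fx, Fy;
  vec bx, by, btop, rhs, diag, rr, zz, pk, Apk, icd, yv;
  vec fu, fv, fyu, fyv, dc, Y;
  std::vector<char> hasn, hask, horiz;
  Work(int nx_, int ny_) : nx(nx_), ny(ny_) {
    int nc = nx * ny, nu = (nx + 1) * ny, nv = nx * (ny + 1);
    cls.assign(nc, 0);
    u.assign(nu, 0); v.assign(nv, 0); p.assign(nc, 0);
    a.assign(nc, 0); c.assign(nc, 0); sink.assign(nc, 0);
    us.assign(nu, 0); vs.assign(nv, 0);
    as_.assign(nc, 0); tmp.assign(nc, 0);
    nxm.assign(nc, 0); nym.assign(nc, 0); kap.assign(nc, 0);
    Fx.assign(nu, 0); Fy.assign(nv, 0);
    bx.assign(nu, 0); by.assign(nv, 0); btop.assign(nx, 0);
    rhs.assign(nc, 0); diag.assign(nc, 0);
    rr.assign(nc, 0); zz.assign(nc, 0); pk.assign(nc, 0); Apk.assign(nc, 0);
    icd.assign(nc, 0); yv.assign(nc, 0);
    fu.assign(nu, 0); fv.assign(nv, 0); fyu.assign(nu, 0); fyv.assign(nv, 0);
    dc.assign(nc, 0); Y.assign(nc, 0);
    hasn.assign(nc, 0); hask.assign(nc, 0); horiz.assign(nc, 1);
  }
  inline int IC(int i, int j) const { return j * nx + i; }
  inline int IU(int i, int j) const { return j * (nx + 1) + i; }
  inline int IV(int i, int j) const { return j * nx + i; }
};

static inline double mixr(double a, const Par& p) {
  return a * p.rho_b + (1.0 - a) * p.rho_g;
}
static inline double mixm(double a, const Par& p) {
  return a * p.mu_b + (1.0 - a) * p.mu_g;
}

static double max_speed(const Work& w) {
  double m = 0.0;
  for (double x : w.u) m = std::max(m, std::fabs(x));
  for (double x : w.v) m = std::max(m, std::fabs(x));
  return m;
}

// ---- boundary handling -----------------------------------------------------

static void apply_velocity_bc(Work& w, vec& u, vec& v, const Par& p,
                              bool top_zero_gradient) {
  int nx = w.nx, ny = w.ny;
  const std::vector<int>& cls = w.cls;
  for (int j = 0; j < ny; ++j) {
    u[w.IU(0, j)] = 0.0;           // symmetry plane
    u[w.IU(nx, j)] = 0.0;          // behind the bone column
    for (int i = 1; i < nx; ++i) {
      int cl = cls[w.IC(i - 1, j)], cr = cls[w.IC(i, j)];
      if (is_solid(cl) || is_solid(cr)) { u[w.IU(i, j)] = 0.0; continue; }
      bool wl = is_mom(cl) || (p.pressure_inlet && cl == CIN_APEX);
      bool wr = is_mom(cr) || (p.pressure_inlet && cr == CIN_APEX);
      if (wl && wr) continue;                     // active face
      if (cr == CIN_BONE && is_mom(cl)) { u[w.IU(i, j)] = -p.inlet_speed; continue; }
      if (cl == CIN_BONE && is_mom(cr)) { u[w.IU(i, j)] = p.inlet_speed; continue; }
      u[w.IU(i, j)] = 0.0;
    }
  }
  for (int i = 0; i < nx; ++i) {
    if (cls[w.IC(i, 0)] == CIN_APEX && !p.pressure_inlet)
      v[w.IV(i, 0)] = p.inlet_speed;
    else v[w.IV(i, 0)] = 0.0;
    // top edge: zero-gradient predictor guess above outlet cells; after the
    // projection the corrected outflow must be preserved
    if (cls[w.IC(i, ny - 1)] == COUTLET) {
      if (top_zero_gradient) v[w.IV(i, ny)] = v[w.IV(i, ny - 1)];
    } else v[w.IV(i, ny)] = 0.0;
    for (int j = 1; j < ny; ++j) {
      int cb = cls[w.IC(i, j - 1)], ct = cls[w.IC(i, j)];
      if (is_solid(cb) || is_solid(ct)) { v[w.IV(i, j)] = 0.0; continue; }
      bool wb = is_mom(cb) || (p.pressure_inlet && cb == CIN_APEX);
      bool wt = is_mom(ct) || (p.pressure_inlet && ct == CIN_APEX);
      if (wb && wt) continue;
      if (cb == CIN_APEX && is_mom(ct)) { v[w.IV(i, j)] = p.inlet_speed; continue; }
      if (ct == CIN_APEX && is_mom(cb)) { v[w.IV(i, j)] = -p.inlet_speed; continue; }
      v[w.IV(i, j)] = 0.0;
    }
  }
}

// ---- curvature and surface tension ----------------------------------------

static void curvature_force(Work& w, const Par& p) {
  int nx = w.nx, ny = w.ny;
  double h = p.h;
  const std::vector<int>& cls = w.cls;
  std::fill(w.Fx.begin(), w.Fx.end(), 0.0);
  std::fill(w.Fy.begin(), w.Fy.end(), 0.0);
  if (p.sigma <= 0) return;
  std::copy(w.a.begin(), w.a.end(), w.as_.begin());
  // Laplacian smoothing over wet cells (solid ghosts = zero-gradient)
  for (int pass = 0; pass < p.smooth_passes; ++pass) {
    for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      int ic = w.IC(i, j);
      if (!is_wet(cls[ic])) { w.tmp[ic] = w.as_[ic]; continue; }
      double s = 2.0 * w.as_[ic], wt = 2.0;
      if (i > 0 && is_wet(cls[ic - 1]))       { s += w.as_[ic - 1]; wt += 1; }
      if (i < nx - 1 && is_wet(cls[ic + 1]))  { s += w.as_[ic + 1]; wt += 1; }
      if (j > 0 && is_wet(cls[ic - nx]))      { s += w.as_[ic - nx]; wt += 1; }
      if (j < ny - 1 && is_wet(cls[ic + nx])) { s += w.as_[ic + nx]; wt += 1; }
      w.tmp[ic] = s / wt;
    }
    std::swap(w.as_, w.tmp);
  }
  // cell normals (unit, pointing into the liquid)
  std::fill(w.hasn.begin(), w.hasn.end(), 0);
  auto ag = [&](int i, int j, int ic0) -> double {
    if (i < 0 || i >= nx || j < 0 || j >= ny) return w.as_[ic0];
    int ic = w.IC(i, j);
    return is_wet(cls[ic]) ? w.as_[ic] : w.as_[ic0];
  };
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    if (!is_wet(cls[ic])) continue;
    double gx = (ag(i + 1, j, ic) - ag(i - 1, j, ic)) / (2 * h);
    double gy = (ag(i, j + 1, ic) - ag(i, j - 1, ic)) / (2 * h);
    double g = std::sqrt(gx * gx + gy * gy);
    if (g < 1e-3 / h) continue;
    double nxv = gx / g, nyv = gy / g;
    // contact-angle re-orientation in wall-adjacent interface cells
    bool near_imp = false, near_bone = false;
    double wx = 0, wy = 0;
    if (i > 0 && is_solid(cls[ic - 1]))       { wx += 1; (cls[ic-1]==CIMPLANT?near_imp:near_bone)=true; }
    if (i < nx - 1 && is_solid(cls[ic + 1]))  { wx -= 1; (cls[ic+1]==CIMPLANT?near_imp:near_bone)=true; }
    if (j > 0 && is_solid(cls[ic - nx]))      { wy += 1; (cls[ic-nx]==CIMPLANT?near_imp:near_bone)=true; }
    if (j < ny - 1 && is_solid(cls[ic + nx])) { wy -= 1; (cls[ic+nx]==CIMPLANT?near_imp:near_bone)=true; }
    if ((near_imp || near_bone) && w.as_[ic] > 0.005 && w.as_[ic] < 0.995) {
      double wn = std::sqrt(wx * wx + wy * wy);
      if (wn > 0) {
        wx /= wn; wy /= wn;
        double th = near_imp ? p.theta_imp : p.theta_bone;
        double gxg = -nxv, gyg = -nyv;       // direction into gas
        double dot = gxg * wx + gyg * wy;
        double tx = gxg - dot * wx, ty = gyg - dot * wy;
        double tn = std::sqrt(tx * tx + ty * ty);
        if (tn < 1e-12) { tx = -wy; ty = wx; tn = 1.0; }
        else { tx /= tn; ty /= tn; }
        double ngx = std::cos(th) * wx + std::sin(th) * tx;
        double ngy = std::cos(th) * wy + std::sin(th) * ty;
        nxv = -ngx; nyv = -ngy;
      }
    }
    w.nxm[ic] = nxv; w.nym[ic] = nyv; w.hasn[ic] = 1;
  }
  // curvature = -div(n_liq), face-averaged normals, zero-gradient ghosts
  auto nfc = [&](const vec& nm, int i, int j, int i2, int j2) -> double {
    bool a = (i >= 0 && i < nx && j >= 0 && j < ny) && w.hasn[w.IC(i, j)];
    bool b = (i2 >= 0 && i2 < nx && j2 >= 0 && j2 < ny) && w.hasn[w.IC(i2, j2)];
    if (a && b) return 0.5 * (nm[w.IC(i, j)] + nm[w.IC(i2, j2)]);
    if (a) return nm[w.IC(i, j)];
    if (b) return nm[w.IC(i2, j2)];
    return 0.0;
  };
  std::fill(w.kap.begin(), w.kap.end(), 0.0);
  std::fill(w.hask.begin(), w.hask.end(), 0);
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    if (!w.hasn[ic]) continue;
    double ddx = (nfc(w.nxm, i, j, i + 1, j) - nfc(w.nxm, i - 1, j, i, j)) / h;
    double ddy = (nfc(w.nym, i, j, i, j + 1) - nfc(w.nym, i, j - 1, i, j)) / h;
    w.kap[ic] = -(ddx + ddy);
    w.hask[ic] = 1;
  }
  // face force densities from the sharp alpha gradient
  for (int j = 0; j < ny; ++j) for (int i = 1; i < nx; ++i) {
    int l = w.IC(i - 1, j), r = w.IC(i, j);
    if (!is_wet(cls[l]) || !is_wet(cls[r])) continue;
    if (!w.hask[l] && !w.hask[r]) continue;
    double kf = w.hask[l] && w.hask[r] ? 0.5 * (w.kap[l] + w.kap[r])
                                       : (w.hask[l] ? w.kap[l] : w.kap[r]);
    w.Fx[w.IU(i, j)] = p.sigma * kf * (w.a[r] - w.a[l]) / h;
  }
  for (int j = 1; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int b = w.IC(i, j - 1), t = w.IC(i, j);
    if (!is_wet(cls[b]) || !is_wet(cls[t])) continue;
    if (!w.hask[b] && !w.hask[t]) continue;
    double kf = w.hask[b] && w.hask[t] ? 0.5 * (w.kap[b] + w.kap[t])
                                       : (w.hask[b] ? w.kap[b] : w.kap[t]);
    w.Fy[w.IV(i, j)] = p.sigma * kf * (w.a[t] - w.a[b]) / h;
  }
}

// ---- momentum predictor ----------------------------------------------------

static void predict(Work& w, const Par& p, double dt) {
  int nx = w.nx, ny = w.ny;
  double h = p.h;
  const std::vector<int>& cls = w.cls;
  std::copy(w.u.begin(), w.u.end(), w.us.begin());
  std::copy(w.v.begin(), w.v.end(), w.vs.begin());
  auto wetc = [&](int i, int j) {
    return i >= 0 && i < nx && j >= 0 && j < ny && is_wet(cls[w.IC(i, j)]);
  };
  auto wmom = [&](int c) {
    return is_mom(c) || (p.pressure_inlet && c == CIN_APEX);
  };
  for (int j = 0; j < ny; ++j) for (int i = 1; i < nx; ++i) {
    if (!wmom(cls[w.IC(i - 1, j)]) || !wmom(cls[w.IC(i, j)])) continue;
    double aL = w.a[w.IC(i - 1, j)], aR = w.a[w.IC(i, j)];
    double rho = 0.5 * (mixr(aL, p) + mixr(aR, p));
    double mu = 0.5 * (mixm(aL, p) + mixm(aR, p));
    double uc = w.u[w.IU(i, j)];
    double uW = w.u[w.IU(i - 1, j)], uE = w.u[w.IU(i + 1, j)];
    bool wallN = !wetc(i - 1, j + 1) && !wetc(i, j + 1);
    bool wallS = !wetc(i - 1, j - 1) && !wetc(i, j - 1);
    double uN = (j + 1 < ny) ? w.u[w.IU(i, j + 1)] : uc;
    double uS = (j - 1 >= 0) ? w.u[w.IU(i, j - 1)] : uc;
    if (wallN && j + 1 < ny) uN = -uc;
    if (wallS) uS = -uc;
    double dudx = uc > 0 ? (uc - uW) / h : (uE - uc) / h;
    double vf = 0.25 * (w.v[w.IV(i - 1, j)] + w.v[w.IV(i - 1, j + 1)] +
                        w.v[w.IV(i, j)] + w.v[w.IV(i, j + 1)]);
    double dudy = vf > 0 ? (uc - uS) / h : (uN - uc) / h;
    double lap = (uE - 2 * uc + uW + uN - 2 * uc + uS) / (h * h);
    double acc = -(uc * dudx + vf * dudy) + mu / rho * lap +
                 w.Fx[w.IU(i, j)] / rho;
    double un = uc + dt * acc;
    double lam = std::max(w.sink[w.IC(i - 1, j)], w.sink[w.IC(i, j)]);
    if (lam > 0) un /= (1.0 + dt * lam);
    w.us[w.IU(i, j)] = un;
  }
  for (int j = 1; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    if (!wmom(cls[w.IC(i, j - 1)]) || !wmom(cls[w.IC(i, j)])) continue;
    double aB = w.a[w.IC(i, j - 1)], aT = w.a[w.IC(i, j)];
    double rho = 0.5 * (mixr(aB, p) + mixr(aT, p));
    double mu = 0.5 * (mixm(aB, p) + mixm(aT, p));
    double vc = w.v[w.IV(i, j)];
    double vS = w.v[w.IV(i, j - 1)], vN = w.v[w.IV(i, j + 1)];
    bool wallE = !wetc(i + 1, j - 1) && !wetc(i + 1, j);
    bool wallW = !wetc(i - 1, j - 1) && !wetc(i - 1, j);
    double vE = (i + 1 < nx) ? w.v[w.IV(i + 1, j)] : vc;
    double vW = (i - 1 >= 0) ? w.v[w.IV(i - 1, j)] : vc;  // symmetry: zero-grad
    if (wallE) vE = -vc;
    if (wallW && i > 0) vW = -vc;
    double dvdy = vc > 0 ? (vc - vS) / h : (vN - vc) / h;
    double uf = 0.25 * (w.u[w.IU(i, j - 1)] + w.u[w.IU(i + 1, j - 1)] +
                        w.u[w.IU(i, j)] + w.u[w.IU(i + 1, j)]);
    double dvdx = uf > 0 ? (vc - vW) / h : (vE - vc) / h;
    double lap = (vE - 2 * vc + vW + vN - 2 * vc + vS) / (h * h);
    double acc = -(uf * dvdx + vc * dvdy) + mu / rho * lap +
                 w.Fy[w.IV(i, j)] / rho;
    double vn = vc + dt * acc;
    double lam = std::max(w.sink[w.IC(i, j - 1)], w.sink[w.IC(i, j)]);
    if (lam > 0) vn /= (1.0 + dt * lam);
    w.vs[w.IV(i, j)] = vn;
  }
  apply_velocity_bc(w, w.us, w.vs, p, true);
}

// ---- pressure projection ---------------------------------------------------

// On exit w.us/w.vs are divergence-free in all mom cells and w.p holds the
// pressure (warm-started). Returns iterations; res_out = residual / rhsnorm.
static int project(Work& w, const Par& p, double dt, double& res_out) {
  int nx = w.nx, ny = w.ny;
  double h = p.h, h2 = h * h;
  const std::vector<int>& cls = w.cls;
  std::fill(w.bx.begin(), w.bx.end(), 0.0);
  std::fill(w.by.begin(), w.by.end(), 0.0);
  std::fill(w.btop.begin(), w.btop.end(), 0.0);
  // face mobility beta = 1 / (rho (1 + lambda dt)): the implicit momentum
  // sink of the porous roughness layer must damp the pressure correction
  // exactly as it damps the predictor, or near-wall flow bypasses the drag
  auto wetp = [&](int c) { return is_mom(c) || (p.pressure_inlet && c == CIN_APEX); };
  for (int j = 0; j < ny; ++j) for (int i = 1; i < nx; ++i) {
    int cl = cls[w.IC(i - 1, j)], cr = cls[w.IC(i, j)];
    if (wetp(cl) && wetp(cr)) {
      double lam = std::max(w.sink[w.IC(i - 1, j)], w.sink[w.IC(i, j)]);
      w.bx[w.IU(i, j)] = 1.0 / ((0.5 * (mixr(w.a[w.IC(i - 1, j)], p) +
                                        mixr(w.a[w.IC(i, j)], p))) *
                                (1.0 + lam * dt));
    }
  }
  for (int j = 1; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int cb = cls[w.IC(i, j - 1)], ct = cls[w.IC(i, j)];
    if (wetp(cb) && wetp(ct)) {
      double lam = std::max(w.sink[w.IC(i, j - 1)], w.sink[w.IC(i, j)]);
      w.by[w.IV(i, j)] = 1.0 / ((0.5 * (mixr(w.a[w.IC(i, j - 1)], p) +
                                        mixr(w.a[w.IC(i, j)], p))) *
                                (1.0 + lam * dt));
    }
  }
  for (int i = 0; i < nx; ++i)
    if (cls[w.IC(i, ny - 1)] == COUTLET)
      w.btop[i] = 1.0 / mixr(w.a[w.IC(i, ny - 1)], p);
  double rhsnorm = 0.0;
  int ncells = 0;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    if (!is_mom(cls[ic])) { w.diag[ic] = 0; w.rhs[ic] = 0; continue; }
    double div = (w.us[w.IU(i + 1, j)] - w.us[w.IU(i, j)]) / h +
                 (w.vs[w.IV(i, j + 1)] - w.vs[w.IV(i, j)]) / h;
    w.rhs[ic] = div / dt;
    double d = w.bx[w.IU(i, j)] + w.bx[w.IU(i + 1, j)] +
               w.by[w.IV(i, j)] + w.by[w.IV(i, j + 1)];
    if (j == ny - 1 && cls[ic] == COUTLET) d += 2.0 * w.btop[i];
    w.diag[ic] = d;
    rhsnorm += w.rhs[ic] * w.rhs[ic];
    ++ncells;
  }
  rhsnorm = std::sqrt(rhsnorm);
  // absolute target: the residual equals the post-correction div/dt, so aim
  // for scaled divergence |div| h / U_ref <= p_tol
  double uref = std::max(max_speed(w), std::max(p.inlet_speed, 1e-12));
  double target = p.p_tol * uref / (h * dt) *
                  std::sqrt((double)std::max(ncells, 1));
  // Jacobi-preconditioned conjugate gradients on the SPD form
  //   (diag p_c - sum beta p_nb) / h^2 = -rhs + (Dirichlet terms) / h^2.
  // Robust to the strong density-coefficient jumps across the interface.
  auto pdir = [&](int i, int j) -> double {   // known Dirichlet neighbour value
    if (i < 0 || i >= nx || j < 0 || j >= ny) return 0.0;
    return cls[w.IC(i, j)] == CIN_APEX ? p.p_inlet : 0.0;
  };
  auto matvec = [&](const vec& x, vec& y) {
    for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      int ic = w.IC(i, j);
      if (!is_mom(cls[ic]) || w.diag[ic] <= 0) { y[ic] = 0; continue; }
      double s = w.diag[ic] * x[ic];
      if (w.bx[w.IU(i, j)] > 0 && i > 0 && is_mom(cls[ic - 1]))
        s -= w.bx[w.IU(i, j)] * x[ic - 1];
      if (w.bx[w.IU(i + 1, j)] > 0 && i + 1 < nx && is_mom(cls[ic + 1]))
        s -= w.bx[w.IU(i + 1, j)] * x[ic + 1];
      if (w.by[w.IV(i, j)] > 0 && j > 0 && is_mom(cls[ic - nx]))
        s -= w.by[w.IV(i, j)] * x[ic - nx];
      if (w.by[w.IV(i, j + 1)] > 0 && j + 1 < ny && is_mom(cls[ic + nx]))
        s -= w.by[w.IV(i, j + 1)] * x[ic + nx];
      y[ic] = s / h2;
    }
  };
  // rhs of the SPD system into w.tmp
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    if (!is_mom(cls[ic]) || w.diag[ic] <= 0) { w.tmp[ic] = 0; continue; }
    double b = -w.rhs[ic];
    if (w.bx[w.IU(i, j)] > 0 && !(i > 0 && is_mom(cls[w.IC(i - 1, j)])))
      b += w.bx[w.IU(i, j)] * pdir(i - 1, j) / h2;
    if (w.bx[w.IU(i + 1, j)] > 0 && !(i + 1 < nx && is_mom(cls[w.IC(i + 1, j)])))
      b += w.bx[w.IU(i + 1, j)] * pdir(i + 1, j) / h2;
    if (w.by[w.IV(i, j)] > 0 && !(j > 0 && is_mom(cls[w.IC(i, j - 1)])))
      b += w.by[w.IV(i, j)] * pdir(i, j - 1) / h2;
    if (w.by[w.IV(i, j + 1)] > 0 && !(j + 1 < ny && is_mom(cls[w.IC(i, j + 1)])))
      b += w.by[w.IV(i, j + 1)] * pdir(i, j + 1) / h2;
    w.tmp[ic] = b;
  }
  // incomplete Cholesky IC(0) factor of the (h^2-scaled) 5-point matrix
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    if (!is_mom(cls[ic]) || w.diag[ic] <= 0) { w.icd[ic] = 0; continue; }
    double val = w.diag[ic];
    if (i > 0 && is_mom(cls[ic - 1]) && w.icd[ic - 1] > 0) {
      double lcw = -w.bx[w.IU(i, j)] / w.icd[ic - 1];
      val -= lcw * lcw;
    }
    if (j > 0 && is_mom(cls[ic - nx]) && w.icd[ic - nx] > 0) {
      double lcs = -w.by[w.IV(i, j)] / w.icd[ic - nx];
      val -= lcs * lcs;
    }
    w.icd[ic] = std::sqrt(std::max(val, 0.05 * w.diag[ic]));
  }
  auto apply_ic = [&](const vec& r, vec& z) {
    // forward solve L y = r
    for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      int ic = w.IC(i, j);
      if (w.icd[ic] <= 0) { w.yv[ic] = 0; continue; }
      double s = r[ic];
      if (i > 0 && w.icd[ic - 1] > 0 && w.bx[w.IU(i, j)] > 0 && is_mom(cls[ic - 1]))
        s += w.bx[w.IU(i, j)] / w.icd[ic - 1] * w.yv[ic - 1];
      if (j > 0 && w.icd[ic - nx] > 0 && w.by[w.IV(i, j)] > 0 && is_mom(cls[ic - nx]))
        s += w.by[w.IV(i, j)] / w.icd[ic - nx] * w.yv[ic - nx];
      w.yv[ic] = s / w.icd[ic];
    }
    // backward solve L^T z = y
    for (int j = ny - 1; j >= 0; --j) for (int i = nx - 1; i >= 0; --i) {
      int ic = w.IC(i, j);
      if (w.icd[ic] <= 0) { z[ic] = 0; continue; }
      double s = w.yv[ic];
      if (i + 1 < nx && w.icd[ic + 1] > 0 && w.bx[w.IU(i + 1, j)] > 0 && is_mom(cls[ic + 1]))
        s += w.bx[w.IU(i + 1, j)] / w.icd[ic] * z[ic + 1];
      if (j + 1 < ny && w.icd[ic + nx] > 0 && w.by[w.IV(i, j + 1)] > 0 && is_mom(cls[ic + nx]))
        s += w.by[w.IV(i, j + 1)] / w.icd[ic] * z[ic + nx];
      z[ic] = s / w.icd[ic];
    }
  };
  matvec(w.p, w.Apk);
  double rz = 0.0;
  for (int ic = 0; ic < nx * ny; ++ic) {
    if (w.diag[ic] <= 0 || !is_mom(cls[ic])) { w.rr[ic] = 0; w.zz[ic] = 0; w.pk[ic] = 0; continue; }
    w.rr[ic] = w.tmp[ic] - w.Apk[ic];
  }
  apply_ic(w.rr, w.zz);
  for (int ic = 0; ic < nx * ny; ++ic) {
    if (w.diag[ic] <= 0 || !is_mom(cls[ic])) continue;
    w.pk[ic] = w.zz[ic];
    rz += w.rr[ic] * w.zz[ic];
  }
  int it = 0; double resn = 0.0;
  for (int ic = 0; ic < nx * ny; ++ic) resn += w.rr[ic] * w.rr[ic];
  resn = std::sqrt(resn);
  for (it = 0; it < p.p_maxit && resn > target; ++it) {
    matvec(w.pk, w.Apk);
    double pAp = 0.0;
    for (int ic = 0; ic < nx * ny; ++ic) pAp += w.pk[ic] * w.Apk[ic];
    if (pAp <= 0) break;
    double alpha_cg = rz / pAp;
    double rz_new = 0.0, rnorm = 0.0;
    for (int ic = 0; ic < nx * ny; ++ic) {
      if (w.diag[ic] <= 0 || !is_mom(cls[ic])) continue;
      w.p[ic] += alpha_cg * w.pk[ic];
      w.rr[ic] -= alpha_cg * w.Apk[ic];
      rnorm += w.rr[ic] * w.rr[ic];
    }
    apply_ic(w.rr, w.zz);
    for (int ic = 0; ic < nx * ny; ++ic) {
      if (w.diag[ic] <= 0 || !is_mom(cls[ic])) continue;
      rz_new += w.rr[ic] * w.zz[ic];
    }
    resn = std::sqrt(rnorm);
    double beta_cg = rz > 0 ? rz_new / rz : 0.0;
    rz = rz_new;
    for (int ic = 0; ic < nx * ny; ++ic) {
      if (w.diag[ic] <= 0 || !is_mom(cls[ic])) continue;
      w.pk[ic] = w.zz[ic] + beta_cg * w.pk[ic];
    }
  }
  res_out = rhsnorm > 0 ? resn / rhsnorm : 0.0;
  // neighbour pressure with Dirichlet inlet handling (for the correction)
  auto pnb = [&](int i, int j) -> double {
    if (i < 0 || i >= nx || j < 0 || j >= ny) return 0.0;
    int ic = w.IC(i, j);
    if (is_mom(cls[ic])) return w.p[ic];
    if (cls[ic] == CIN_APEX) return p.p_inlet;
    return 0.0;
  };
  // velocity correction
  for (int j = 0; j < ny; ++j) for (int i = 1; i < nx; ++i) {
    if (w.bx[w.IU(i, j)] <= 0) continue;
    double pl = pnb(i - 1, j), pr = pnb(i, j);
    if (is_mom(cls[w.IC(i - 1, j)])) pl = w.p[w.IC(i - 1, j)];
    if (is_mom(cls[w.IC(i, j)])) pr = w.p[w.IC(i, j)];
    w.us[w.IU(i, j)] -= dt * w.bx[w.IU(i, j)] * (pr - pl) / h;
  }
  for (int j = 1; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    if (w.by[w.IV(i, j)] <= 0) continue;
    w.vs[w.IV(i, j)] -= dt * w.by[w.IV(i, j)] * (pnb(i, j) - pnb(i, j - 1)) / h;
  }
  for (int i = 0; i < nx; ++i)
    if (w.btop[i] > 0)
      w.vs[w.IV(i, ny)] -= dt * w.btop[i] * (0.0 - w.p[w.IC(i, ny - 1)]) * 2.0 / h;
  return it;
}

static double max_divergence(const Work& w, double h) {
  double m = 0.0;
  for (int j = 0; j < w.ny; ++j) for (int i = 0; i < w.nx; ++i) {
    if (!is_mom(w.cls[w.IC(i, j)])) continue;
    double d = std::fabs((w.u[w.IU(i + 1, j)] - w.u[w.IU(i, j)]) / h +
                         (w.v[w.IV(i, j + 1)] - w.v[w.IV(i, j)]) / h);
    if (d > m) m = d;
  }
  return m;
}

// ---- VOF + species advection ----------------------------------------------

// Piecewise-linear (PLIC, Youngs) interface geometry helpers. The liquid
// occupies {m1 x + m2 y <= s} in the unit cell with m1, m2 >= 0 and
// m1 + m2 = 1 after axis flips.

// area of {m1 x + m2 y <= s} in the unit square
static double area_under(double m1, double m2, double s) {
  if (s <= 0) return 0.0;
  if (s >= 1) return 1.0;
  double mn = std::min(m1, m2), mx = std::max(m1, m2);
  if (mx <= 0) return 1.0;
  if (mn < 1e-12) return std::min(s / mx, 1.0);
  if (s <= mn) return s * s / (2.0 * mn * mx);
  if (s <= mx) return (s - mn / 2.0) / mx;
  double r = 1.0 - s;
  return 1.0 - r * r / (2.0 * mn * mx);
}

// inverse: line constant s giving liquid area a
static double line_const(double m1, double m2, double a) {
  double mn = std::min(m1, m2), mx = std::max(m1, m2);
  if (mn < 1e-12) return a * mx;
  double A1 = mn / (2.0 * mx);
  if (a <= A1) return std::sqrt(2.0 * a * mn * mx);
  if (a <= 1.0 - A1) return a * mx + mn / 2.0;
  return 1.0 - std::sqrt(2.0 * (1.0 - a) * mn * mx);
}

// liquid area in the strip [a0,b0] x [0,1] (flipped coordinates, m >= 0)
static double strip_area(double m1, double m2, double s, double a0, double b0) {
  double wdt = b0 - a0;
  if (wdt <= 0) return 0.0;
  double denom = m1 * wdt + m2;
  if (denom < 1e-300) return 0.0;
  double A = area_under(m1 * wdt / denom, m2 / denom, (s - m1 * a0) / denom);
  return wdt * A;
}

// PLIC flux (cell-volume fraction) leaving the donor through a face during
// one sweep; c = |u| dt / h, (gx, gy) = grad(alpha) in the donor (into the
// liquid). dir: 0 = +x, 1 = -x, 2 = +y, 3 = -y side of the donor cell.
static double plic_flux(double alpha, double gx, double gy, double c, int dir) {
  if (c <= 0) return 0.0;
  if (alpha <= 1e-10) return 0.0;
  if (alpha >= 1.0 - 1e-10) return c;
  double mx = -gx, my = -gy;                      // points away from liquid
  double n1 = std::fabs(mx) + std::fabs(my);
  if (n1 < 1e-300) return alpha * c;              // no orientation: upwind
  mx /= n1; my /= n1;
  double m1 = std::fabs(mx), m2 = std::fabs(my);
  double s = line_const(m1, m2, alpha);
  double a0, b0;
  bool flipx = mx < 0, flipy = my < 0;
  if (dir == 0 || dir == 1) {
    bool high_side = (dir == 0);
    if (flipx) high_side = !high_side;            // flipped x' = 1 - x
    a0 = high_side ? 1.0 - c : 0.0;
    b0 = high_side ? 1.0 : c;
    return strip_area(m1, m2, s, a0, b0);
  } else {
    bool high_side = (dir == 2);
    if (flipy) high_side = !high_side;
    a0 = high_side ? 1.0 - c : 0.0;
    b0 = high_side ? 1.0 : c;
    // swap axes so the strip is in the first coordinate
    return strip_area(m2, m1, s, a0, b0);
  }
}

// Youngs gradient of alpha with zero-gradient solid ghosts
static inline void alpha_grad(const Work& w, const std::vector<int>& cls,
                              int i, int j, double& gx, double& gy) {
  int nx = w.nx, ny = w.ny, ic = w.IC(i, j);
  auto av = [&](int ii, int jj) {
    if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) return w.a[ic];
    int k = jj * nx + ii;
    return is_wet(cls[k]) ? w.a[k] : w.a[ic];
  };
  gx = (av(i + 1, j) - av(i - 1, j)) / 2.0;
  gy = (av(i, j + 1) - av(i, j - 1)) / 2.0;
}

// One directional PLIC sweep (sweep_x true: x direction) updating alpha and
// the species load with the Weymouth-Yue dilatation field cwy (fixed per
// full step). Boundary fluxes are accumulated into budget.
static void plic_sweep(Work& w, const Par& p, double dt, bool sweep_x,
                       const std::vector<char>& cwy, double* budget) {
  int nx = w.nx, ny = w.ny;
  double h = p.h;
  const std::vector<int>& cls = w.cls;
  std::fill(w.fu.begin(), w.fu.end(), 0.0);
  std::fill(w.fv.begin(), w.fv.end(), 0.0);
  std::fill(w.fyu.begin(), w.fyu.end(), 0.0);
  std::fill(w.fyv.begin(), w.fyv.end(), 0.0);
  auto cellY = [&](int ic) {
    return w.a[ic] > 1e-10 ? std::min(w.c[ic] / w.a[ic], 1.0) : 0.0;
  };
  if (sweep_x) {
    for (int j = 0; j < ny; ++j) for (int i = 1; i < nx; ++i) {
      double uf = w.u[w.IU(i, j)];
      if (uf == 0.0) continue;
      int di = uf > 0 ? i - 1 : i;
      int icd = w.IC(di, j), ica = w.IC(uf > 0 ? i : i - 1, j);
      if (is_solid(cls[icd]) || is_solid(cls[ica])) continue;
      double c = std::fabs(uf) * dt / h;
      bool d_inlet = cls[icd] == CIN_APEX || cls[icd] == CIN_BONE;
      double f, yD;
      if (d_inlet) { f = c; yD = p.Y0; }
      else {
        double gx, gy;
        alpha_grad(w, cls, di, j, gx, gy);
        f = plic_flux(w.a[icd], gx, gy, c, uf > 0 ? 0 : 1);
        yD = cellY(icd);
      }
      w.fu[w.IU(i, j)] = (uf > 0 ? f : -f);
      w.fyu[w.IU(i, j)] = (uf > 0 ? f : -f) * yD;
    }
  } else {
    for (int j = 1; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      double vf = w.v[w.IV(i, j)];
      if (vf == 0.0) continue;
      int dj = vf > 0 ? j - 1 : j;
      int icd = w.IC(i, dj), ica = w.IC(i, vf > 0 ? j : j - 1);
      if (is_solid(cls[icd]) || is_solid(cls[ica])) continue;
      double c = std::fabs(vf) * dt / h;
      bool d_inlet = cls[icd] == CIN_APEX || cls[icd] == CIN_BONE;
      double f, yD;
      if (d_inlet) { f = c; yD = p.Y0; }
      else {
        double gx, gy;
        alpha_grad(w, cls, i, dj, gx, gy);
        f = plic_flux(w.a[icd], gx, gy, c, vf > 0 ? 2 : 3);
        yD = cellY(icd);
      }
      w.fv[w.IV(i, j)] = (vf > 0 ? f : -f);
      w.fyv[w.IV(i, j)] = (vf > 0 ? f : -f) * yD;
    }
    // top open faces: outflow with the donor's reconstruction
    for (int i = 0; i < nx; ++i) {
      int ic = w.IC(i, ny - 1);
      if (cls[ic] != COUTLET) continue;
      double vf = w.v[w.IV(i, ny)];
      if (vf <= 0) continue;
      double c = vf * dt / h;
      double gx, gy;
      alpha_grad(w, cls, i, ny - 1, gx, gy);
      double f = plic_flux(w.a[ic], gx, gy, c, 2);
      w.fv[w.IV(i, ny)] = f;
      w.fyv[w.IV(i, ny)] = f * cellY(ic);
    }
  }
  // apply with the dilatation correction; the dilatation uses the same
  // effective face velocities as the fluxes (zero on solid and closed
  // boundary faces) so inconsistent wall-face values cannot unbalance it
  auto ueff = [&](int i, int j) -> double {
    if (i <= 0 || i >= nx) return 0.0;
    if (is_solid(cls[w.IC(i - 1, j)]) || is_solid(cls[w.IC(i, j)])) return 0.0;
    return w.u[w.IU(i, j)];
  };
  auto veff = [&](int i, int j) -> double {
    if (j <= 0) return 0.0;
    if (j >= ny) return cls[w.IC(i, ny - 1)] == COUTLET ? w.v[w.IV(i, ny)] : 0.0;
    if (is_solid(cls[w.IC(i, j - 1)]) || is_solid(cls[w.IC(i, j)])) return 0.0;
    return w.v[w.IV(i, j)];
  };
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    if (!is_mom(cls[ic])) continue;
    double dil, dF, dFy;
    double Yc = cellY(ic);
    if (sweep_x) {
      dil = (ueff(i + 1, j) - ueff(i, j)) * dt / h;
      dF = w.fu[w.IU(i, j)] - w.fu[w.IU(i + 1, j)];
      dFy = w.fyu[w.IU(i, j)] - w.fyu[w.IU(i + 1, j)];
    } else {
      dil = (veff(i, j + 1) - veff(i, j)) * dt / h;
      dF = w.fv[w.IV(i, j)] - w.fv[w.IV(i, j + 1)];
      dFy = w.fyv[w.IV(i, j)] - w.fyv[w.IV(i, j + 1)];
    }
    w.a[ic] += dF + (cwy[ic] ? dil : 0.0);
    w.c[ic] += dFy + (cwy[ic] ? dil * Yc : 0.0);
    if (w.a[ic] < 0) {
      if (w.a[ic] < -1e-6) stop("VOF boundedness violated: alpha = %g at (%d,%d)", w.a[ic], i, j);
      w.a[ic] = 0.0;
    }
    if (w.a[ic] > 1) {
      if (w.a[ic] > 1 + 1e-6) stop("VOF boundedness violated: alpha = %g at (%d,%d)", w.a[ic], i, j);
      w.a[ic] = 1.0;
    }
    if (w.c[ic] < 0) w.c[ic] = 0.0;
  }
  // budget bookkeeping across inlet faces and the open top
  double ain = 0, cin = 0, aout = 0, cout = 0;
  if (sweep_x) {
    for (int j = 0; j < ny; ++j) for (int i = 1; i < nx; ++i) {
      int cl = cls[w.IC(i - 1, j)], cr = cls[w.IC(i, j)];
      bool li = cl == CIN_APEX || cl == CIN_BONE;
      bool ri = cr == CIN_APEX || cr == CIN_BONE;
      if (li == ri) continue;
      double s = li ? 1.0 : -1.0;
      ain += s * w.fu[w.IU(i, j)]; cin += s * w.fyu[w.IU(i, j)];
    }
  } else {
    for (int j = 1; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      int cb = cls[w.IC(i, j - 1)], ct = cls[w.IC(i, j)];
      bool bi = cb == CIN_APEX || cb == CIN_BONE;
      bool ti = ct == CIN_APEX || ct == CIN_BONE;
      if (bi == ti) continue;
      double s = bi ? 1.0 : -1.0;
      ain += s * w.fv[w.IV(i, j)]; cin += s * w.fyv[w.IV(i, j)];
    }
    for (int i = 0; i < nx; ++i) {
      if (cls[w.IC(i, ny - 1)] != COUTLET) continue;
      aout += w.fv[w.IV(i, ny)];
      cout += w.fyv[w.IV(i, ny)];
    }
  }
  budget[0] += ain * h * h; budget[1] += aout * h * h;
  budget[2] += cin * h * h; budget[3] += cout * h * h;
}

// Split geometric (PLIC) advection of alpha and the fibrinogen load
// C = alpha * Y; the sweep order alternates with the step parity.
static void advect(Work& w, const Par& p, double dt, double* budget,
                   int parity) {
  int nx = w.nx, ny = w.ny;
  const std::vector<int>& cls = w.cls;
  // Weymouth-Yue dilatation marker, fixed over both sweeps
  std::vector<char> cwy((size_t)nx * ny, 0);
  for (int k = 0; k < nx * ny; ++k) cwy[k] = w.a[k] >= 0.5 ? 1 : 0;
  bool x_first = (parity & 1) == 0;
  plic_sweep(w, p, dt, x_first, cwy, budget);
  plic_sweep(w, p, dt, !x_first, cwy, budget);
  // reset reservoirs and solids
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j), c0 = cls[ic];
    if (c0 == CIN_APEX || c0 == CIN_BONE) { w.a[ic] = 1.0; w.c[ic] = p.Y0; }
    if (is_solid(c0)) { w.a[ic] = 0.0; w.c[ic] = 0.0; }
  }
}

// (retained) donor-acceptor advection: compressive algebraic fallback used
// for cross-checks.
static void advect_da(Work& w, const Par& p, double dt, double* budget) {
  int nx = w.nx, ny = w.ny;
  double h = p.h;
  const std::vector<int>& cls = w.cls;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    auto av = [&](int ii, int jj) {
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) return w.a[ic];
      int k = w.IC(ii, jj);
      return is_wet(cls[k]) ? w.a[k] : w.a[ic];
    };
    double gx = av(i + 1, j) - av(i - 1, j), gy = av(i, j + 1) - av(i, j - 1);
    w.horiz[ic] = std::fabs(gx) >= std::fabs(gy);
  }
  std::fill(w.fu.begin(), w.fu.end(), 0.0);
  std::fill(w.fv.begin(), w.fv.end(), 0.0);
  std::fill(w.fyu.begin(), w.fyu.end(), 0.0);
  std::fill(w.fyv.begin(), w.fyv.end(), 0.0);
  auto donor_frac = [&](double aD, double aA, bool donor_horiz, bool sweep_x,
                        double c) -> double {
    bool upw = sweep_x ? donor_horiz : !donor_horiz;
    if (upw) return aD * c;                       // interface faces the flow
    double cf = std::max((1.0 - aA) * c - (1.0 - aD), 0.0);
    return std::min(aA * c + cf, aD);
  };
  auto cellY = [&](int ic) {
    return w.a[ic] > 1e-10 ? w.c[ic] / w.a[ic] : 0.0;
  };
  for (int j = 0; j < ny; ++j) for (int i = 1; i < nx; ++i) {
    double uf = w.u[w.IU(i, j)];
    if (uf == 0.0) continue;
    int di = uf > 0 ? i - 1 : i, ai = uf > 0 ? i : i - 1;
    int icd = w.IC(di, j), ica = w.IC(ai, j);
    if (is_solid(cls[icd]) || is_solid(cls[ica])) continue;
    double c = std::fabs(uf) * dt / h;
    bool d_inlet = cls[icd] == CIN_APEX || cls[icd] == CIN_BONE;
    double aD = d_inlet ? 1.0 : w.a[icd];
    double yD = d_inlet ? p.Y0 : cellY(icd);
    double f = d_inlet ? aD * c
                       : donor_frac(aD, w.a[ica], w.horiz[icd], true, c);
    w.fu[w.IU(i, j)] = (uf > 0 ? f : -f);
    w.fyu[w.IU(i, j)] = (uf > 0 ? f : -f) * yD;
  }
  for (int j = 1; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    double vf = w.v[w.IV(i, j)];
    if (vf == 0.0) continue;
    int dj = vf > 0 ? j - 1 : j, aj = vf > 0 ? j : j - 1;
    int icd = w.IC(i, dj), ica = w.IC(i, aj);
    if (is_solid(cls[icd]) || is_solid(cls[ica])) continue;
    double c = std::fabs(vf) * dt / h;
    bool d_inlet = cls[icd] == CIN_APEX || cls[icd] == CIN_BONE;
    double aD = d_inlet ? 1.0 : w.a[icd];
    double yD = d_inlet ? p.Y0 : cellY(icd);
    double f = d_inlet ? aD * c
                       : donor_frac(aD, w.a[ica], w.horiz[icd], false, c);
    w.fv[w.IV(i, j)] = (vf > 0 ? f : -f);
    w.fyv[w.IV(i, j)] = (vf > 0 ? f : -f) * yD;
  }
  // top open faces: pure outflow upwind
  for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, ny - 1);
    if (cls[ic] != COUTLET) continue;
    double vf = w.v[w.IV(i, ny)];
    if (vf <= 0) continue;
    double c = vf * dt / h;
    w.fv[w.IV(i, ny)] = w.a[ic] * c;
    w.fyv[w.IV(i, ny)] = w.a[ic] * c * cellY(ic);
  }
  // donor-availability / acceptor-capacity limiting by flux scaling
  // (alternating Sinkhorn-style passes; converges geometrically at CFL < 0.5)
  for (int pass = 0; pass < 24; ++pass) {
    bool changed = false;
    for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      int ic = w.IC(i, j);
      if (!is_mom(cls[ic])) continue;
      int iW = w.IU(i, j), iE = w.IU(i + 1, j), iS = w.IV(i, j), iN = w.IV(i, j + 1);
      double fW = w.fu[iW], fE = w.fu[iE], fS = w.fv[iS], fN = w.fv[iN];
      double out = std::max(-fW, 0.0) + std::max(fE, 0.0) +
                   std::max(-fS, 0.0) + std::max(fN, 0.0);
      double in = std::max(fW, 0.0) + std::max(-fE, 0.0) +
                  std::max(fS, 0.0) + std::max(-fN, 0.0);
      if (out > 0 && w.a[ic] + in - out < -1e-14) {
        double sc = std::max((w.a[ic] + in) / out, 0.0);
        changed = true;
        if (fW < 0) { w.fu[iW] *= sc; w.fyu[iW] *= sc; }
        if (fE > 0) { w.fu[iE] *= sc; w.fyu[iE] *= sc; }
        if (fS < 0) { w.fv[iS] *= sc; w.fyv[iS] *= sc; }
        if (fN > 0) { w.fv[iN] *= sc; w.fyv[iN] *= sc; }
      }
      fW = w.fu[iW]; fE = w.fu[iE]; fS = w.fv[iS]; fN = w.fv[iN];
      out = std::max(-fW, 0.0) + std::max(fE, 0.0) +
            std::max(-fS, 0.0) + std::max(fN, 0.0);
      in = std::max(fW, 0.0) + std::max(-fE, 0.0) +
           std::max(fS, 0.0) + std::max(-fN, 0.0);
      double over = w.a[ic] + in - out - 1.0;
      if (over > 1e-14 && in > 0) {
        double sci = std::max((1.0 - w.a[ic] + out) / in, 0.0);
        changed = true;
        if (fW > 0) { w.fu[iW] *= sci; w.fyu[iW] *= sci; }
        if (fE < 0) { w.fu[iE] *= sci; w.fyu[iE] *= sci; }
        if (fS > 0) { w.fv[iS] *= sci; w.fyv[iS] *= sci; }
        if (fN < 0) { w.fv[iN] *= sci; w.fyv[iN] *= sci; }
      }
    }
    if (!changed) break;
  }
  // apply
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    if (!is_mom(cls[ic])) continue;
    int iW = w.IU(i, j), iE = w.IU(i + 1, j), iS = w.IV(i, j), iN = w.IV(i, j + 1);
    w.a[ic] += w.fu[iW] - w.fu[iE] + w.fv[iS] - w.fv[iN];
    w.c[ic] += w.fyu[iW] - w.fyu[iE] + w.fyv[iS] - w.fyv[iN];
    if (w.a[ic] < 0 && w.a[ic] > -1e-12) w.a[ic] = 0.0;
    if (w.a[ic] > 1 && w.a[ic] < 1 + 1e-12) w.a[ic] = 1.0;
    if (w.c[ic] < 0 && w.c[ic] > -1e-12) w.c[ic] = 0.0;
    if (w.a[ic] < -1e-9 || w.a[ic] > 1 + 1e-9)
      stop("VOF boundedness violated: alpha = %f at (%d,%d)", w.a[ic], i, j);
  }
  // budgets: fluxes across inlet-cell faces and the top open faces
  double ain = 0, cin = 0, aout = 0, cout = 0;
  for (int j = 0; j < ny; ++j) for (int i = 1; i < nx; ++i) {
    int cl = cls[w.IC(i - 1, j)], cr = cls[w.IC(i, j)];
    bool li = cl == CIN_APEX || cl == CIN_BONE;
    bool ri = cr == CIN_APEX || cr == CIN_BONE;
    if (li == ri) continue;
    double s = li ? 1.0 : -1.0;                   // + means into the domain
    ain += s * w.fu[w.IU(i, j)]; cin += s * w.fyu[w.IU(i, j)];
  }
  for (int j = 1; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int cb = cls[w.IC(i, j - 1)], ct = cls[w.IC(i, j)];
    bool bi = cb == CIN_APEX || cb == CIN_BONE;
    bool ti = ct == CIN_APEX || ct == CIN_BONE;
    if (bi == ti) continue;
    double s = bi ? 1.0 : -1.0;
    ain += s * w.fv[w.IV(i, j)]; cin += s * w.fyv[w.IV(i, j)];
  }
  for (int i = 0; i < nx; ++i) {
    if (cls[w.IC(i, ny - 1)] != COUTLET) continue;
    aout += w.fv[w.IV(i, ny)];
    cout += w.fyv[w.IV(i, ny)];
  }
  budget[0] += ain * h * h; budget[1] += aout * h * h;
  budget[2] += cin * h * h; budget[3] += cout * h * h;
  // reset reservoirs and solids
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j), c0 = cls[ic];
    if (c0 == CIN_APEX || c0 == CIN_BONE) { w.a[ic] = 1.0; w.c[ic] = p.Y0; }
    if (is_solid(c0)) { w.a[ic] = 0.0; w.c[ic] = 0.0; }
  }
}

// explicit diffusion of Y within the blood phase; flux blocked by air/solid
static void diffuse_species(Work& w, const Par& p, double D, double dt) {
  if (D <= 0) return;
  int nx = w.nx, ny = w.ny;
  double h = p.h;
  const std::vector<int>& cls = w.cls;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    w.Y[ic] = w.a[ic] > 1e-10 ? w.c[ic] / w.a[ic] : 0.0;
  }
  std::fill(w.dc.begin(), w.dc.end(), 0.0);
  for (int j = 0; j < ny; ++j) for (int i = 1; i < nx; ++i) {
    int l = w.IC(i - 1, j), r = w.IC(i, j);
    if (!is_wet(cls[l]) || !is_wet(cls[r])) continue;
    double af = std::min(w.a[l], w.a[r]);
    if (af < 1e-10) continue;
    double flx = D * af * (w.Y[r] - w.Y[l]) / h * dt / h;
    w.dc[l] += flx; w.dc[r] -= flx;
  }
  for (int j = 1; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int b = w.IC(i, j - 1), t = w.IC(i, j);
    if (!is_wet(cls[b]) || !is_wet(cls[t])) continue;
    double af = std::min(w.a[b], w.a[t]);
    if (af < 1e-10) continue;
    double flx = D * af * (w.Y[t] - w.Y[b]) / h * dt / h;
    w.dc[b] += flx; w.dc[t] -= flx;
  }
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    int ic = w.IC(i, j);
    if (!is_mom(cls[ic])) continue;
    w.c[ic] += w.dc[ic];
    if (w.c[ic] < 0 && w.c[ic] > -1e-12) w.c[ic] = 0.0;
  }
}

static double stable_dt(const Work& w, const Par& p, double dt_ref, double cfl) {
  double dt = dt_ref;
  double um = max_speed(w);
  if (um > 0) dt = std::min(dt, cfl * p.h / um);
  if (p.sigma > 0) {
    // capillary limit with the denser-phase density
    dt = std::min(dt, std::sqrt(p.rho_b * p.h * p.h * p.h / (2.0 * M_PI * p.sigma)));
  }
  double numax = std::max(p.mu_b / p.rho_b, p.mu_g / p.rho_g);
  dt = std::min(dt, 0.8 * p.h * p.h / (4.0 * numax));
  return dt;
}

// ---- R interface -----------------------------------------------------------

static void load_work(Work& w, const NumericMatrix& u, const NumericMatrix& v,
                      const NumericMatrix& pres, const NumericMatrix& alpha,
                      const NumericMatrix& C, const IntegerMatrix& cls,
                      const NumericMatrix& sink) {
  std::copy(u.begin(), u.end(), w.u.begin());
  std::copy(v.begin(), v.end(), w.v.begin());
  std::copy(pres.begin(), pres.end(), w.p.begin());
  std::copy(alpha.begin(), alpha.end(), w.a.begin());
  std::copy(C.begin(), C.end(), w.c.begin());
  std::copy(cls.begin(), cls.end(), w.cls.begin());
  std::copy(sink.begin(), sink.end(), w.sink.begin());
}

static NumericMatrix to_mat(const vec& x, int nr, int nc) {
  NumericMatrix m(nr, nc);
  std::copy(x.begin(), x.end(), m.begin());
  return m;
}

// Note: R matrices are column-major with dim (nx, ny[+1]) etc., matching the
// row-stride layout used by Work (index (i,j) -> j*stride + i).

// [[Rcpp::export]]
List cpp_curvature_force(NumericMatrix alpha, IntegerMatrix cls, List par) {
  Par p = read_par(par);
  int nx = cls.nrow(), ny = cls.ncol();
  Work w(nx, ny);
  std::copy(alpha.begin(), alpha.end(), w.a.begin());
  std::copy(cls.begin(), cls.end(), w.cls.begin());
  double sig = p.sigma;
  if (sig <= 0) p.sigma = 1.0;   // emit curvature even for sigma = 0
  curvature_force(w, p);
  if (sig <= 0) {
    for (double& x : w.Fx) x *= 0.0;
    for (double& x : w.Fy) x *= 0.0;
  }
  return List::create(_["kappa"] = to_mat(w.kap, nx, ny),
                      _["Fx"] = to_mat(w.Fx, nx + 1, ny),
                      _["Fy"] = to_mat(w.Fy, nx, ny + 1));
}

// [[Rcpp::export]]
List cpp_step_flow(NumericMatrix u, NumericMatrix v, NumericMatrix pres,
                   NumericMatrix alpha, IntegerMatrix cls,
                   NumericMatrix sink, List par, double dt,
                   NumericMatrix Fx, NumericMatrix Fy) {
  Par p = read_par(par);
  int nx = cls.nrow(), ny = cls.ncol();
  Work w(nx, ny);
  NumericMatrix zeroC(nx, ny);
  load_work(w, u, v, pres, alpha, zeroC, cls, sink);
  std::copy(Fx.begin(), Fx.end(), w.Fx.begin());
  std::copy(Fy.begin(), Fy.end(), w.Fy.begin());
  apply_velocity_bc(w, w.u, w.v, p, true);
  predict(w, p, dt);
  double res = 0.0;
  int it = project(w, p, dt, res);
  std::swap(w.u, w.us); std::swap(w.v, w.vs);
  apply_velocity_bc(w, w.u, w.v, p, false);
  double mdiv = max_divergence(w, p.h);
  for (double x : w.u) if (!std::isfinite(x)) stop("non-finite velocity after step");
  for (double x : w.v) if (!std::isfinite(x)) stop("non-finite velocity after step");
  return List::create(_["u"] = to_mat(w.u, nx + 1, ny),
                      _["v"] = to_mat(w.v, nx, ny + 1),
                      _["p"] = to_mat(w.p, nx, ny),
                      _["iterations"] = it, _["residual"] = res,
                      _["max_divergence"] = mdiv);
}

// [[Rcpp::export]]
List cpp_advect_vof(NumericMatrix alpha, NumericMatrix C,
                    NumericMatrix u, NumericMatrix v,
                    IntegerMatrix cls, List par, double dt,
                    int parity = 0) {
  Par p = read_par(par);
  int nx = cls.nrow(), ny = cls.ncol();
  Work w(nx, ny);
  NumericMatrix zeroP(nx, ny), zeroS(nx, ny);
  load_work(w, u, v, zeroP, alpha, C, cls, zeroS);
  double budget[4] = {0, 0, 0, 0};
  advect(w, p, dt, budget, parity);
  return List::create(_["alpha"] = to_mat(w.a, nx, ny),
                      _["C"] = to_mat(w.c, nx, ny),
                      _["alpha_in"] = budget[0], _["alpha_out"] = budget[1],
                      _["C_in"] = budget[2], _["C_out"] = budget[3]);
}

// compressive algebraic (donor-acceptor) transport: independent cross-check
// [[Rcpp::export]]
List cpp_advect_vof_da(NumericMatrix alpha, NumericMatrix C,
                       NumericMatrix u, NumericMatrix v,
                       IntegerMatrix cls, List par, double dt) {
  Par p = read_par(par);
  int nx = cls.nrow(), ny = cls.ncol();
  Work w(nx, ny);
  NumericMatrix zeroP(nx, ny), zeroS(nx, ny);
  load_work(w, u, v, zeroP, alpha, C, cls, zeroS);
  double budget[4] = {0, 0, 0, 0};
  advect_da(w, p, dt, budget);
  return List::create(_["alpha"] = to_mat(w.a, nx, ny),
                      _["C"] = to_mat(w.c, nx, ny),
                      _["alpha_in"] = budget[0], _["alpha_out"] = budget[1],
                      _["C_in"] = budget[2], _["C_out"] = budget[3]);
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse_species(NumericMatrix C, NumericMatrix alpha,
                                  IntegerMatrix cls, List par,
                                  double D, double dt) {
  Par p = read_par(par);
  int nx = cls.nrow(), ny = cls.ncol();
  Work w(nx, ny);
  std::copy(alpha.begin(), alpha.end(), w.a.begin());
  std::copy(C.begin(), C.end(), w.c.begin());
  std::copy(cls.begin(), cls.end(), w.cls.begin());
  diffuse_species(w, p, D, dt);
  return to_mat(w.c, nx, ny);
}

// [[Rcpp::export]]
double cpp_stable_dt(NumericMatrix u, NumericMatrix v, List par,
                     double dt_ref, double cfl) {
  Par p = read_par(par);
  int ny = u.ncol(), nx = u.nrow() - 1;
  Work w(nx, ny);
  std::copy(u.begin(), u.end(), w.u.begin());
  std::copy(v.begin(), v.end(), w.v.begin());
  return stable_dt(w, p, dt_ref, cfl);
}

// Fused time loop: advances until t >= t_target, accumulating budgets.
// [[Rcpp::export]]
List cpp_advance(NumericMatrix u, NumericMatrix v, NumericMatrix pres,
                 NumericMatrix alpha, NumericMatrix C,
                 IntegerMatrix cls, NumericMatrix sink, List par,
                 double t_now, double t_target, double dt_ref, double cfl,
                 double D, NumericVector budget_in, int max_steps) {
  Par p = read_par(par);
  int nx = cls.nrow(), ny = cls.ncol();
  Work w(nx, ny);
  load_work(w, u, v, pres, alpha, C, cls, sink);
  double budget[4];
  for (int k = 0; k < 4; ++k) budget[k] = budget_in[k];
  apply_velocity_bc(w, w.u, w.v, p, true);
  double t = t_now;
  int steps = 0, last_iters = 0;
  double last_res = 0.0;
  double prev_cin = budget[2], prev_flow = NA_REAL, conv_metric = NA_REAL;
  while (t < t_target - 1e-15 && steps < max_steps) {
    double dt = stable_dt(w, p, dt_ref, cfl);
    if (t + dt > t_target) dt = t_target - t;
    if (!(dt > 0) || !std::isfinite(dt)) stop("non-positive or non-finite time step");
    curvature_force(w, p);
    predict(w, p, dt);
    double res = 0.0;
    last_iters = project(w, p, dt, res);
    std::swap(w.u, w.us); std::swap(w.v, w.vs);
    apply_velocity_bc(w, w.u, w.v, p, false);
    last_res = res;
    advect(w, p, dt, budget, steps & 1);
    diffuse_species(w, p, D, dt);
    double flow = (budget[2] - prev_cin) / dt;
    if (std::isfinite(prev_flow) && std::fabs(prev_flow) > 1e-300)
      conv_metric = std::fabs(flow - prev_flow) / std::fabs(prev_flow);
    prev_flow = flow; prev_cin = budget[2];
    t += dt; ++steps;
    if (steps % 500 == 0) {
      for (double x : w.u) if (!std::isfinite(x)) stop("non-finite velocity at t=%f", t);
      Rcpp::checkUserInterrupt();
    }
  }
  double mdiv = max_divergence(w, p.h);
  return List::create(_["u"] = to_mat(w.u, nx + 1, ny),
                      _["v"] = to_mat(w.v, nx, ny + 1),
                      _["p"] = to_mat(w.p, nx, ny),
                      _["alpha"] = to_mat(w.a, nx, ny),
                      _["C"] = to_mat(w.c, nx, ny), _["t"] = t,
                      _["steps"] = steps,
                      _["budget"] = NumericVector(budget, budget + 4),
                      _["iterations"] = last_iters, _["residual"] = last_res,
                      _["max_divergence"] = mdiv,
                      _["convergence_metric"] = conv_metric,
                      _["max_speed"] = max_speed(w));
}
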