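// One time step of the staggered-grid (MAC) projection solver for the
// incompressible Navier-Stokes equations on a voxelized domain.
//
//   rho (du/dt + u . grad u) = -grad p + mu lap u,   div u = 0
//
// Explicit first-order upwind advection and explicit diffusion build a
// provisional velocity; a pressure Poisson solve (Jacobi-preconditioned
// conjugate gradients on the masked 7-point Laplacian) projects it onto the
// divergence-free space. Walls are immersed stair-step no-slip (velocity on
// solid-adjacent faces held at zero), the inlet is a prescribed plug
// velocity on cap faces, and outlet caps carry Dirichlet pressure supplied
// by the Windkessel models (applied at the cap face, half a cell from the
// adjacent cell center).
//
// Face type coding: 0 fixed zero (wall/solid/exterior), 1 interior unknown,
// 2 inlet cap (z faces only), >= 3 outlet cap, outlet id = type - 3.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Grid {
  int nx, ny, nz;
  R_xlen_t nc, nu, nv, nw;
  inline R_xlen_t C(int i, int j, int k) const {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  }
  inline R_xlen_t U(int i, int j, int k) const {
    return i + (R_xlen_t)(nx + 1) * (j + (R_xlen_t)ny * k);
  }
  inline R_xlen_t V(int i, int j, int k) const {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)(ny + 1) * k);
  }
  inline R_xlen_t W(int i, int j, int k) const {
    return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  }
};

// [[Rcpp::export]]
List ns_step_cpp(NumericVector u, NumericVector v, NumericVector w,
                 NumericVector p, IntegerVector mask, IntegerVector futype,
                 IntegerVector fvtype, IntegerVector fwtype,
                 IntegerVector dims, double h, double dt, double rho,
                 double mu, double win, NumericVector pout,
                 NumericVector fbody, double cg_tol, int cg_maxit) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  g.nc = (R_xlen_t)nx * ny * nz;
  const double nu_kin = mu / rho;
  const double ih = 1.0 / h;

  std::vector<double> us(u.begin(), u.end());
  std::vector<double> vs(v.begin(), v.end());
  std::vector<double> ws(w.begin(), w.end());

  // --- provisional velocity: advect + diffuse interior faces -------------
  // u faces
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        R_xlen_t f = g.U(i, j, k);
        if (futype[f] != 1) continue;
        double uc = u[f];
        double um = u[g.U(i - 1, j, k)];
        double up = u[g.U(i + 1, j, k)];
        double ujm = (j > 0) ? u[g.U(i, j - 1, k)] : 0.0;
        double ujp = (j < ny - 1) ? u[g.U(i, j + 1, k)] : 0.0;
        double ukm = (k > 0) ? u[g.U(i, j, k - 1)] : 0.0;
        double ukp = (k < nz - 1) ? u[g.U(i, j, k + 1)] : 0.0;
        double vat = 0.25 * (v[g.V(i - 1, j, k)] + v[g.V(i - 1, j + 1, k)] +
                             v[g.V(i, j, k)] + v[g.V(i, j + 1, k)]);
        double wat = 0.25 * (w[g.W(i - 1, j, k)] + w[g.W(i - 1, j, k + 1)] +
                             w[g.W(i, j, k)] + w[g.W(i, j, k + 1)]);
        double adv = uc * (uc > 0 ? (uc - um) : (up - uc)) * ih +
                     vat * (vat > 0 ? (uc - ujm) : (ujp - uc)) * ih +
                     wat * (wat > 0 ? (uc - ukm) : (ukp - uc)) * ih;
        // diffusion: tangential neighbors across a wall are mirrored (-uc)
        // so the no-slip surface sits on the stair-step face itself
        double djm = (j > 0 && futype[g.U(i, j - 1, k)] == 1) ? ujm : -uc;
        double djp = (j < ny - 1 && futype[g.U(i, j + 1, k)] == 1) ? ujp : -uc;
        double dkm = (k > 0 && futype[g.U(i, j, k - 1)] == 1) ? ukm : -uc;
        double dkp = (k < nz - 1 && futype[g.U(i, j, k + 1)] == 1) ? ukp : -uc;
        double lap = (um + up + djm + djp + dkm + dkp - 6.0 * uc) * ih * ih;
        us[f] = uc + dt * (-adv + nu_kin * lap + fbody[0] / rho);
      }
  // v faces
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t f = g.V(i, j, k);
        if (fvtype[f] != 1) continue;
        double vc = v[f];
        double vm = v[g.V(i, j - 1, k)];
        double vp = v[g.V(i, j + 1, k)];
        double vim = (i > 0) ? v[g.V(i - 1, j, k)] : 0.0;
        double vip = (i < nx - 1) ? v[g.V(i + 1, j, k)] : 0.0;
        double vkm = (k > 0) ? v[g.V(i, j, k - 1)] : 0.0;
        double vkp = (k < nz - 1) ? v[g.V(i, j, k + 1)] : 0.0;
        double uat = 0.25 * (u[g.U(i, j - 1, k)] + u[g.U(i + 1, j - 1, k)] +
                             u[g.U(i, j, k)] + u[g.U(i + 1, j, k)]);
        double wat = 0.25 * (w[g.W(i, j - 1, k)] + w[g.W(i, j - 1, k + 1)] +
                             w[g.W(i, j, k)] + w[g.W(i, j, k + 1)]);
        double adv = uat * (uat > 0 ? (vc - vim) : (vip - vc)) * ih +
                     vc * (vc > 0 ? (vc - vm) : (vp - vc)) * ih +
                     wat * (wat > 0 ? (vc - vkm) : (vkp - vc)) * ih;
        double dim_ = (i > 0 && fvtype[g.V(i - 1, j, k)] == 1) ? vim : -vc;
        double dip = (i < nx - 1 && fvtype[g.V(i + 1, j, k)] == 1) ? vip : -vc;
        double dkm = (k > 0 && fvtype[g.V(i, j, k - 1)] == 1) ? vkm : -vc;
        double dkp = (k < nz - 1 && fvtype[g.V(i, j, k + 1)] == 1) ? vkp : -vc;
        double lap = (vm + vp + dim_ + dip + dkm + dkp - 6.0 * vc) * ih * ih;
        vs[f] = vc + dt * (-adv + nu_kin * lap + fbody[1] / rho);
      }
  // w faces (interior only here; caps handled after)
  for (int k = 1; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t f = g.W(i, j, k);
        if (fwtype[f] != 1) continue;
        double wc = w[f];
        double wm = w[g.W(i, j, k - 1)];
        double wp = w[g.W(i, j, k + 1)];
        double wim = (i > 0) ? w[g.W(i - 1, j, k)] : 0.0;
        double wip = (i < nx - 1) ? w[g.W(i + 1, j, k)] : 0.0;
        double wjm = (j > 0) ? w[g.W(i, j - 1, k)] : 0.0;
        double wjp = (j < ny - 1) ? w[g.W(i, j + 1, k)] : 0.0;
        double uat = 0.25 * (u[g.U(i, j, k - 1)] + u[g.U(i + 1, j, k - 1)] +
                             u[g.U(i, j, k)] + u[g.U(i + 1, j, k)]);
        double vat = 0.25 * (v[g.V(i, j, k - 1)] + v[g.V(i, j + 1, k - 1)] +
                             v[g.V(i, j, k)] + v[g.V(i, j + 1, k)]);
        double adv = uat * (uat > 0 ? (wc - wim) : (wip - wc)) * ih +
                     vat * (vat > 0 ? (wc - wjm) : (wjp - wc)) * ih +
                     wc * (wc > 0 ? (wc - wm) : (wp - wc)) * ih;
        double dim_ = (i > 0 && fwtype[g.W(i - 1, j, k)] == 1) ? wim : -wc;
        double dip = (i < nx - 1 && fwtype[g.W(i + 1, j, k)] == 1) ? wip : -wc;
        double djm = (j > 0 && fwtype[g.W(i, j - 1, k)] == 1) ? wjm : -wc;
        double djp = (j < ny - 1 && fwtype[g.W(i, j + 1, k)] == 1) ? wjp : -wc;
        double lap = (wm + wp + dim_ + dip + djm + djp - 6.0 * wc) * ih * ih;
        ws[f] = wc + dt * (-adv + nu_kin * lap + fbody[2] / rho);
      }
  // cap faces: inlet prescribed, outlet keeps old value (pressure correction
  // below supplies the momentum balance at the cap)
  for (int kk = 0; kk <= nz; kk += nz)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t f = g.W(i, j, kk);
        int t = fwtype[f];
        if (t == 2) ws[f] = win;
        else if (t >= 3) ws[f] = w[f];
        else if (t == 0) ws[f] = 0.0;
      }

  // --- pressure Poisson --------------------------------------------------
  // A p = b with A_cc = (#fluid-fluid faces) + 2 (#outlet faces),
  // off-diagonal -1 across fluid-fluid faces,
  // b_c = -(rho h^2 / dt) div(u*) + 2 sum(p_out over outlet faces).
  std::vector<R_xlen_t> cells;
  cells.reserve(g.nc / 4);
  for (R_xlen_t c = 0; c < g.nc; ++c)
    if (mask[c] == 1) cells.push_back(c);
  const size_t nf = cells.size();

  // adjacency of fluid-fluid couplings, precomputed once per step so the
  // Krylov loops are tight gather/scatter passes
  std::vector<R_xlen_t> nbl(3 * nf, -1), nbu(3 * nf, -1);
  for (size_t m = 0; m < nf; ++m) {
    R_xlen_t c = cells[m];
    int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / ((R_xlen_t)nx * ny));
    if (futype[g.U(i, j, k)] == 1) nbl[3 * m] = g.C(i - 1, j, k);
    if (fvtype[g.V(i, j, k)] == 1) nbl[3 * m + 1] = g.C(i, j - 1, k);
    if (fwtype[g.W(i, j, k)] == 1) nbl[3 * m + 2] = g.C(i, j, k - 1);
    if (futype[g.U(i + 1, j, k)] == 1) nbu[3 * m] = g.C(i + 1, j, k);
    if (fvtype[g.V(i, j + 1, k)] == 1) nbu[3 * m + 1] = g.C(i, j + 1, k);
    if (fwtype[g.W(i, j, k + 1)] == 1) nbu[3 * m + 2] = g.C(i, j, k + 1);
  }

  std::vector<double> diag(g.nc, 0.0), b(g.nc, 0.0);
  double scale = rho * h / dt;  // (rho h^2 / dt) * div, with div carrying 1/h
  for (size_t m = 0; m < nf; ++m) {
    R_xlen_t c = cells[m];
    int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / ((R_xlen_t)nx * ny));
    double div = (us[g.U(i + 1, j, k)] - us[g.U(i, j, k)]) +
                 (vs[g.V(i, j + 1, k)] - vs[g.V(i, j, k)]) +
                 (ws[g.W(i, j, k + 1)] - ws[g.W(i, j, k)]);
    double d = 0.0, rhs = -scale * div;
    if (futype[g.U(i, j, k)] == 1) d += 1.0;
    if (futype[g.U(i + 1, j, k)] == 1) d += 1.0;
    if (fvtype[g.V(i, j, k)] == 1) d += 1.0;
    if (fvtype[g.V(i, j + 1, k)] == 1) d += 1.0;
    int tb = fwtype[g.W(i, j, k)], tt = fwtype[g.W(i, j, k + 1)];
    if (tb == 1) d += 1.0;
    else if (tb >= 3) { d += 2.0; rhs += 2.0 * pout[tb - 3]; }
    if (tt == 1) d += 1.0;
    else if (tt >= 3) { d += 2.0; rhs += 2.0 * pout[tt - 3]; }
    diag[c] = d;
    b[c] = rhs;
  }

  // PCG with a symmetric Gauss-Seidel (SSOR, omega = 1) preconditioner,
  // warm-started from the previous pressure.
  std::vector<double> x(p.begin(), p.end());
  std::vector<double> r(g.nc, 0.0), z(g.nc, 0.0), q(g.nc, 0.0), d(g.nc, 0.0);
  double bnorm = 0.0;
  for (size_t m = 0; m < nf; ++m) bnorm += b[cells[m]] * b[cells[m]];
  bnorm = std::sqrt(bnorm);
  int iters = 0;
  double relres = 0.0;

  auto applyA = [&](const std::vector<double>& in, std::vector<double>& out) {
    for (size_t m = 0; m < nf; ++m) {
      R_xlen_t c = cells[m];
      double acc = diag[c] * in[c];
      for (int q2 = 0; q2 < 3; ++q2) {
        R_xlen_t lo = nbl[3 * m + q2], up = nbu[3 * m + q2];
        if (lo >= 0) acc -= in[lo];
        if (up >= 0) acc -= in[up];
      }
      out[c] = acc;
    }
  };
  // z = M^-1 r with M = (D+L) D^-1 (D+U); cells are swept in linear order
  auto applyM = [&](const std::vector<double>& r_in, std::vector<double>& z_out) {
    for (size_t m = 0; m < nf; ++m) {
      R_xlen_t c = cells[m];
      double acc = r_in[c];
      for (int q2 = 0; q2 < 3; ++q2) {
        R_xlen_t lo = nbl[3 * m + q2];
        if (lo >= 0) acc += z_out[lo];
      }
      z_out[c] = acc / diag[c];
    }
    for (size_t m = nf; m-- > 0;) {
      R_xlen_t c = cells[m];
      double acc = 0.0;
      for (int q2 = 0; q2 < 3; ++q2) {
        R_xlen_t up = nbu[3 * m + q2];
        if (up >= 0) acc += z_out[up];
      }
      z_out[c] += acc / diag[c];
    }
  };

  if (bnorm < 1e-300) {
    for (R_xlen_t c = 0; c < g.nc; ++c) x[c] = 0.0;
  } else {
    applyA(x, q);
    for (size_t m = 0; m < nf; ++m) {
      R_xlen_t c = cells[m];
      r[c] = b[c] - q[c];
    }
    applyM(r, z);
    double rz = 0.0;
    for (size_t m = 0; m < nf; ++m) {
      R_xlen_t c = cells[m];
      d[c] = z[c];
      rz += r[c] * z[c];
    }
    for (iters = 0; iters < cg_maxit; ++iters) {
      double rn = 0.0;
      for (size_t m = 0; m < nf; ++m) rn += r[cells[m]] * r[cells[m]];
      relres = std::sqrt(rn) / bnorm;
      if (relres <= cg_tol) break;
      applyA(d, q);
      double dq = 0.0;
      for (size_t m = 0; m < nf; ++m) dq += d[cells[m]] * q[cells[m]];
      if (dq == 0.0) break;
      double alpha = rz / dq;
      for (size_t m = 0; m < nf; ++m) {
        R_xlen_t c = cells[m];
        x[c] += alpha * d[c];
        r[c] -= alpha * q[c];
      }
      applyM(r, z);
      double rznew = 0.0;
      for (size_t m = 0; m < nf; ++m) rznew += r[cells[m]] * z[cells[m]];
      double beta = rznew / rz;
      rz = rznew;
      for (size_t m = 0; m < nf; ++m) {
        R_xlen_t c = cells[m];
        d[c] = z[c] + beta * d[c];
      }
    }
  }

  // --- velocity correction ----------------------------------------------
  double dtrh = dt / (rho * h);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        R_xlen_t f = g.U(i, j, k);
        if (futype[f] == 1)
          u[f] = us[f] - dtrh * (x[g.C(i, j, k)] - x[g.C(i - 1, j, k)]);
        else u[f] = 0.0;
      }
  for (int k = 0; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t f = g.V(i, j, k);
        if (fvtype[f] == 1)
          v[f] = vs[f] - dtrh * (x[g.C(i, j, k)] - x[g.C(i, j - 1, k)]);
        else v[f] = 0.0;
      }
  for (int k = 1; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t f = g.W(i, j, k);
        if (fwtype[f] == 1)
          w[f] = ws[f] - dtrh * (x[g.C(i, j, k)] - x[g.C(i, j, k - 1)]);
        else w[f] = 0.0;
      }
  int nout = pout.size();
  NumericVector outflux(nout);
  double influx = 0.0, umax = 0.0;
  for (int kk = 0; kk <= nz; kk += nz)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t f = g.W(i, j, kk);
        int t = fwtype[f];
        if (t == 2) {
          w[f] = win;
          influx += win * h * h;  // inlet caps sit at the bottom, +z inflow
        } else if (t >= 3) {
          int o = t - 3;
          if (kk == 0) {
            double pc = x[g.C(i, j, 0)];
            w[f] = ws[f] - dtrh * 2.0 * (pc - pout[o]);
            outflux[o] += -w[f] * h * h;  // outward normal -z
          } else {
            double pc = x[g.C(i, j, nz - 1)];
            w[f] = ws[f] - dtrh * 2.0 * (pout[o] - pc);
            outflux[o] += w[f] * h * h;  // outward normal +z
          }
        } else if (t == 0) {
          w[f] = 0.0;
        }
      }

  // post-projection divergence and velocity extrema
  double maxdiv = 0.0;
  for (size_t m = 0; m < nf; ++m) {
    R_xlen_t c = cells[m];
    int i = (int)(c % nx), j = (int)((c / nx) % ny), k = (int)(c / ((R_xlen_t)nx * ny));
    double div = ((u[g.U(i + 1, j, k)] - u[g.U(i, j, k)]) +
                  (v[g.V(i, j + 1, k)] - v[g.V(i, j, k)]) +
                  (w[g.W(i, j, k + 1)] - w[g.W(i, j, k)])) * ih;
    if (std::fabs(div) > maxdiv) maxdiv = std::fabs(div);
    double au = std::fabs(u[g.U(i, j, k)]), au2 = std::fabs(u[g.U(i + 1, j, k)]);
    double av = std::fabs(v[g.V(i, j, k)]), av2 = std::fabs(v[g.V(i, j + 1, k)]);
    double aw = std::fabs(w[g.W(i, j, k)]), aw2 = std::fabs(w[g.W(i, j, k + 1)]);
    double loc = std::max(std::max(std::max(au, au2), std::max(av, av2)),
                          std::max(aw, aw2));
    if (loc > umax) umax = loc;
  }

  for (R_xlen_t c = 0; c < g.nc; ++c) p[c] = x[c];

  return List::create(_["maxdiv"] = maxdiv, _["umax"] = umax,
                      _["iters"] = iters, _["relres"] = relres,
                      _["influx"] = influx, _["outflux"] = outflux);
}
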