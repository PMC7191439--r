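// Steady incompressible axisymmetric RANS solver.
//
// Finite-volume discretization on a structured body-fitted grid in (x, r)
// with full 2*pi-revolution metrics (Pappus cell volumes, conical face
// areas). Collocated variable arrangement; SIMPLE pressure-velocity coupling
// with Rhie-Chow momentum-interpolated face fluxes; second-order upwind
// convection via deferred correction; over-relaxed non-orthogonality
// treatment for diffusion. Turbulence closure: Wilcox k-omega integrated to
// the wall (omega fixed in wall-adjacent cells from the smooth-wall
// asymptote 6*nu/(beta*y^2)).
//
// Momentum inner solves: alternating-direction line TDMA sweeps.
// Pressure correction: Jacobi-preconditioned conjugate gradients (the
// 5-point operator is symmetric positive definite with the outlet held at
// fixed pressure).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Geo {
  int ni, nj, nc, nfe, nfn;
  const double *xc, *rc, *vol;
  const double *Sex, *Ser, *xfe, *rfe;
  const double *Snx, *Snr, *xfn, *rfn;
  const double *sumSx, *sumSr, *wall_y;

  inline int C(int i, int j) const { return i + j * ni; }
  inline int FE(int i, int j) const { return i + j * (ni + 1); }
  inline int FN(int i, int j) const { return i + j * ni; }
};

// precomputed per-face interpolation / diffusion geometry
struct FaceGeo {
  std::vector<double> wE, EfE, dEx, dEr, tEx, tEr;   // interior east faces
  std::vector<double> wN, EfN, dNx, dNr, tNx, tNr;   // interior north faces
  std::vector<double> EfIn, EfOut, EfWall;           // boundary faces
};

FaceGeo face_geometry(const Geo &g) {
  FaceGeo fg;
  int ni = g.ni, nj = g.nj;
  fg.wE.assign(g.nfe, 0.0); fg.EfE.assign(g.nfe, 0.0);
  fg.dEx.assign(g.nfe, 0.0); fg.dEr.assign(g.nfe, 0.0);
  fg.tEx.assign(g.nfe, 0.0); fg.tEr.assign(g.nfe, 0.0);
  fg.wN.assign(g.nfn, 0.0); fg.EfN.assign(g.nfn, 0.0);
  fg.dNx.assign(g.nfn, 0.0); fg.dNr.assign(g.nfn, 0.0);
  fg.tNx.assign(g.nfn, 0.0); fg.tNr.assign(g.nfn, 0.0);
  fg.EfIn.assign(nj, 0.0); fg.EfOut.assign(nj, 0.0); fg.EfWall.assign(ni, 0.0);

  for (int j = 0; j < nj; ++j) {
    for (int i = 1; i < ni; ++i) {
      int f = g.FE(i, j), P = g.C(i - 1, j), N = g.C(i, j);
      double dx = g.xc[N] - g.xc[P], dr = g.rc[N] - g.rc[P];
      double Sx = g.Sex[f], Sr = g.Ser[f];
      double SdS = Sx * Sx + Sr * Sr, Sdd = Sx * dx + Sr * dr;
      double Ef = SdS / Sdd;
      double dPf = std::hypot(g.xfe[f] - g.xc[P], g.rfe[f] - g.rc[P]);
      double dNf = std::hypot(g.xfe[f] - g.xc[N], g.rfe[f] - g.rc[N]);
      fg.wE[f] = dNf / (dPf + dNf);
      fg.EfE[f] = Ef; fg.dEx[f] = dx; fg.dEr[f] = dr;
      fg.tEx[f] = Sx - Ef * dx; fg.tEr[f] = Sr - Ef * dr;
    }
    {  // inlet face, owner (0, j)
      int f = g.FE(0, j), P = g.C(0, j);
      double dbx = g.xc[P] - g.xfe[f], dbr = g.rc[P] - g.rfe[f];
      double Sx = g.Sex[f], Sr = g.Ser[f];
      fg.EfIn[j] = (Sx * Sx + Sr * Sr) / std::abs(Sx * dbx + Sr * dbr);
    }
    {  // outlet face, owner (ni-1, j)
      int f = g.FE(ni, j), P = g.C(ni - 1, j);
      double dbx = g.xfe[f] - g.xc[P], dbr = g.rfe[f] - g.rc[P];
      double Sx = g.Sex[f], Sr = g.Ser[f];
      fg.EfOut[j] = (Sx * Sx + Sr * Sr) / std::abs(Sx * dbx + Sr * dbr);
    }
  }
  for (int i = 0; i < ni; ++i) {
    for (int j = 1; j < nj; ++j) {
      int f = g.FN(i, j), P = g.C(i, j - 1), N = g.C(i, j);
      double dx = g.xc[N] - g.xc[P], dr = g.rc[N] - g.rc[P];
      double Sx = g.Snx[f], Sr = g.Snr[f];
      double SdS = Sx * Sx + Sr * Sr, Sdd = Sx * dx + Sr * dr;
      double Ef = SdS / Sdd;
      double dPf = std::hypot(g.xfn[f] - g.xc[P], g.rfn[f] - g.rc[P]);
      double dNf = std::hypot(g.xfn[f] - g.xc[N], g.rfn[f] - g.rc[N]);
      fg.wN[f] = dNf / (dPf + dNf);
      fg.EfN[f] = Ef; fg.dNx[f] = dx; fg.dNr[f] = dr;
      fg.tNx[f] = Sx - Ef * dx; fg.tNr[f] = Sr - Ef * dr;
    }
    {  // wall face, owner (i, nj-1)
      int f = g.FN(i, nj), P = g.C(i, nj - 1);
      double dbx = g.xfn[f] - g.xc[P], dbr = g.rfn[f] - g.rc[P];
      double Sx = g.Snx[f], Sr = g.Snr[f];
      fg.EfWall[i] = (Sx * Sx + Sr * Sr) / std::abs(Sx * dbx + Sr * dbr);
    }
  }
  return fg;
}

// boundary-closure codes for Green-Gauss gradients
enum BC { ZGRAD = 0, DIRI = 1 };

struct GradBC {
  int west; const double *west_val;   // per-j values when Dirichlet
  int east; double east_val;
  int north; double north_val;
};

void gradient(const Geo &g, const FaceGeo &fg, const std::vector<double> &phi,
              const GradBC &bc, std::vector<double> &gx, std::vector<double> &gr) {
  int ni = g.ni, nj = g.nj;
  std::fill(gx.begin(), gx.end(), 0.0);
  std::fill(gr.begin(), gr.end(), 0.0);
  for (int j = 0; j < nj; ++j) {
    for (int i = 1; i < ni; ++i) {
      int f = g.FE(i, j), P = g.C(i - 1, j), N = g.C(i, j);
      double w = fg.wE[f];
      double pf = w * phi[P] + (1.0 - w) * phi[N];
      gx[P] += pf * g.Sex[f]; gr[P] += pf * g.Ser[f];
      gx[N] -= pf * g.Sex[f]; gr[N] -= pf * g.Ser[f];
    }
    {  // inlet: outward normal is -S
      int f = g.FE(0, j), P = g.C(0, j);
      double pb = (bc.west == DIRI) ? bc.west_val[j] : phi[P];
      gx[P] -= pb * g.Sex[f]; gr[P] -= pb * g.Ser[f];
    }
    {  // outlet
      int f = g.FE(ni, j), P = g.C(ni - 1, j);
      double pb = (bc.east == DIRI) ? bc.east_val : phi[P];
      gx[P] += pb * g.Sex[f]; gr[P] += pb * g.Ser[f];
    }
  }
  for (int i = 0; i < ni; ++i) {
    for (int j = 1; j < nj; ++j) {
      int f = g.FN(i, j), P = g.C(i, j - 1), N = g.C(i, j);
      double w = fg.wN[f];
      double pf = w * phi[P] + (1.0 - w) * phi[N];
      gx[P] += pf * g.Snx[f]; gr[P] += pf * g.Snr[f];
      gx[N] -= pf * g.Snx[f]; gr[N] -= pf * g.Snr[f];
    }
    {  // wall (axis face has zero area and is skipped)
      int f = g.FN(i, nj), P = g.C(i, nj - 1);
      double pb = (bc.north == DIRI) ? bc.north_val : phi[P];
      gx[P] += pb * g.Snx[f]; gr[P] += pb * g.Snr[f];
    }
  }
  for (int c = 0; c < g.nc; ++c) {
    gx[c] = (gx[c] - phi[c] * g.sumSx[c]) / g.vol[c];
    gr[c] = (gr[c] - phi[c] * g.sumSr[c]) / g.vol[c];
  }
}

// alternating line-TDMA sweeps along radial lines
void line_solve(const Geo &g, const std::vector<double> &aP,
                const std::vector<double> &aW, const std::vector<double> &aE,
                const std::vector<double> &aS, const std::vector<double> &aN,
                const std::vector<double> &b, std::vector<double> &phi,
                int nsweep) {
  int ni = g.ni, nj = g.nj;
  std::vector<double> low(nj), diag(nj), up(nj), rhs(nj), sol(nj), cp(nj), dp(nj);
  for (int s = 0; s < nsweep; ++s) {
    bool fwd = (s % 2 == 0);
    for (int ii = 0; ii < ni; ++ii) {
      int i = fwd ? ii : (ni - 1 - ii);
      for (int j = 0; j < nj; ++j) {
        int c = g.C(i, j);
        low[j] = aS[c]; diag[j] = aP[c]; up[j] = aN[c];
        double r = b[c];
        if (i > 0) r -= aW[c] * phi[g.C(i - 1, j)];
        if (i < ni - 1) r -= aE[c] * phi[g.C(i + 1, j)];
        rhs[j] = r;
      }
      // Thomas algorithm
      cp[0] = up[0] / diag[0];
      dp[0] = rhs[0] / diag[0];
      for (int j = 1; j < nj; ++j) {
        double m = diag[j] - low[j] * cp[j - 1];
        cp[j] = up[j] / m;
        dp[j] = (rhs[j] - low[j] * dp[j - 1]) / m;
      }
      sol[nj - 1] = dp[nj - 1];
      for (int j = nj - 2; j >= 0; --j) sol[j] = dp[j] - cp[j] * sol[j + 1];
      for (int j = 0; j < nj; ++j) phi[g.C(i, j)] = sol[j];
    }
  }
}

// Jacobi-preconditioned CG for the SPD pressure-correction operator
// y = diag.x - sum_f a_f x_nb ; returns final max-norm residual
double pcg(const Geo &g, const std::vector<double> &diag,
           const std::vector<double> &ae, const std::vector<double> &an,
           const std::vector<double> &b, std::vector<double> &x,
           double tol_abs, int max_it, double rel_tol = 0.0) {
  int ni = g.ni, nj = g.nj, nc = g.nc;
  std::vector<double> r(nc), z(nc), p(nc), Ap(nc);
  std::fill(x.begin(), x.end(), 0.0);
  r = b;
  double rmax = 0.0;
  for (int c = 0; c < nc; ++c) rmax = std::max(rmax, std::abs(r[c]));
  tol_abs = std::max(tol_abs, rel_tol * rmax);
  if (rmax <= tol_abs) return rmax;
  double rz = 0.0;
  for (int c = 0; c < nc; ++c) { z[c] = r[c] / diag[c]; rz += r[c] * z[c]; }
  p = z;
  for (int it = 0; it < max_it; ++it) {
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        int c = g.C(i, j);
        double v = diag[c] * p[c];
        if (i > 0)      v -= ae[g.FE(i, j)] * p[g.C(i - 1, j)];
        if (i < ni - 1) v -= ae[g.FE(i + 1, j)] * p[g.C(i + 1, j)];
        if (j > 0)      v -= an[g.FN(i, j)] * p[g.C(i, j - 1)];
        if (j < nj - 1) v -= an[g.FN(i, j + 1)] * p[g.C(i, j + 1)];
        Ap[c] = v;
      }
    double pAp = 0.0;
    for (int c = 0; c < nc; ++c) pAp += p[c] * Ap[c];
    if (pAp <= 0.0) break;
    double alpha = rz / pAp;
    rmax = 0.0;
    for (int c = 0; c < nc; ++c) {
      x[c] += alpha * p[c];
      r[c] -= alpha * Ap[c];
      rmax = std::max(rmax, std::abs(r[c]));
    }
    if (rmax <= tol_abs) return rmax;
    double rz_new = 0.0;
    for (int c = 0; c < nc; ++c) { z[c] = r[c] / diag[c]; rz_new += r[c] * z[c]; }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int c = 0; c < nc; ++c) p[c] = z[c] + beta * p[c];
  }
  return rmax;
}

inline double upw(double F, double phiP, double phiN) {
  return F >= 0.0 ? phiP : phiN;
}

}  // namespace

// [[Rcpp::export]]
List cpp_simple_solve(List mesh, List bc, List fluid, List settings) {
  NumericMatrix xc = mesh["xc"], rc = mesh["rc"], vol = mesh["vol"];
  NumericMatrix Sex = mesh["Se_x"], Ser = mesh["Se_r"];
  NumericMatrix xfe = mesh["xfe"], rfe = mesh["rfe"];
  NumericMatrix Snx = mesh["Sn_x"], Snr = mesh["Sn_r"];
  NumericMatrix xfn = mesh["xfn"], rfn = mesh["rfn"];
  NumericMatrix sumSx = mesh["sumS_x"], sumSr = mesh["sumS_r"];
  NumericVector wall_y = mesh["wall_y"];

  Geo g;
  g.ni = as<int>(mesh["ni"]); g.nj = as<int>(mesh["nj"]);
  g.nc = g.ni * g.nj;
  g.nfe = (g.ni + 1) * g.nj; g.nfn = g.ni * (g.nj + 1);
  g.xc = xc.begin(); g.rc = rc.begin(); g.vol = vol.begin();
  g.Sex = Sex.begin(); g.Ser = Ser.begin(); g.xfe = xfe.begin(); g.rfe = rfe.begin();
  g.Snx = Snx.begin(); g.Snr = Snr.begin(); g.xfn = xfn.begin(); g.rfn = rfn.begin();
  g.sumSx = sumSx.begin(); g.sumSr = sumSr.begin();
  g.wall_y = wall_y.begin();

  const double rho = as<double>(fluid["rho"]);
  const double mu = as<double>(fluid["mu"]);

  NumericVector u_in = bc["u_in"];           // per inlet face (length nj)
  const double k_in = as<double>(bc["k_in"]);
  const double om_in = as<double>(bc["omega_in"]);

  const double tol = as<double>(settings["tol"]);
  const int max_iter = as<int>(settings["max_iter"]);
  const int min_iter = as<int>(settings["min_iter"]);
  const double au = as<double>(settings["relax_u"]);
  const double ap_rel = as<double>(settings["relax_p"]);
  const double akw = as<double>(settings["relax_kw"]);
  const bool laminar = as<bool>(settings["laminar"]);
  const bool sou = as<bool>(settings["sou"]);
  const bool quad_wall = as<bool>(settings["quad_wall"]);
  const int nsweep = as<int>(settings["n_sweeps"]);
  const double beta = as<double>(settings["beta"]);
  const double beta_star = as<double>(settings["beta_star"]);
  const double alpha_w = as<double>(settings["alpha"]);
  const double sigma = as<double>(settings["sigma"]);
  const double sigma_star = as<double>(settings["sigma_star"]);

  const int ni = g.ni, nj = g.nj, nc = g.nc;
  FaceGeo fg = face_geometry(g);

  std::vector<double> u(nc), v(nc, 0.0), p(nc, 0.0), k(nc), om(nc), mut(nc);
  std::vector<double> me(g.nfe, 0.0), mn(g.nfn, 0.0);
  std::vector<double> invA(nc, 0.0);

  // inlet mass fluxes (fixed)
  double m_in_tot = 0.0;
  for (int j = 0; j < nj; ++j) {
    int f = g.FE(0, j);
    me[f] = rho * u_in[j] * Sex(0, j);
    m_in_tot += me[f];
  }
  const double m_ref = std::max(std::abs(m_in_tot), 1e-30);

  // initial fields: plug flow scaled per axial station to carry m_in_tot
  for (int i = 0; i < ni; ++i) {
    double Acol = 0.0;
    for (int j = 0; j < nj; ++j) Acol += 0.5 * (Sex(i, j) + Sex(i + 1, j));
    double u0 = (Acol > 0) ? m_in_tot / (rho * Acol) : 0.0;
    for (int j = 0; j < nj; ++j) u[g.C(i, j)] = u0;
  }
  for (int c = 0; c < nc; ++c) {
    k[c] = laminar ? 0.0 : k_in;
    om[c] = laminar ? 1.0 : om_in;
    mut[c] = laminar ? 0.0 : rho * k[c] / om[c];
  }
  // initial interior/outlet fluxes from the plug field
  for (int j = 0; j < nj; ++j) {
    for (int i = 1; i < ni; ++i) {
      int f = g.FE(i, j), P = g.C(i - 1, j), N = g.C(i, j);
      double w = fg.wE[f];
      double uf = w * u[P] + (1 - w) * u[N], vf = w * v[P] + (1 - w) * v[N];
      me[f] = rho * (uf * Sex(i, j) + vf * Ser(i, j));
    }
    int f = g.FE(ni, j), P = g.C(ni - 1, j);
    me[f] = rho * (u[P] * Sex(ni, j) + v[P] * Ser(ni, j));
  }

  // wall-adjacent omega from the smooth-wall low-Re asymptote
  std::vector<double> om_wall(ni);
  for (int i = 0; i < ni; ++i)
    om_wall[i] = 6.0 * mu / (rho * beta * wall_y[i] * wall_y[i]);

  std::vector<double> aP(nc), aW(nc), aE(nc), aS(nc), aN(nc), b(nc);
  std::vector<double> gx(nc), gr(nc), gpx(nc), gpr(nc);
  std::vector<double> gux(nc), gur(nc), gvx(nc), gvr(nc);
  std::vector<double> u_old(nc), v_old(nc), p_old(nc), k_old(nc), om_old(nc);
  std::vector<double> pp(nc), diagP(nc), aPe(g.nfe, 0.0), aPn(g.nfn, 0.0), bP(nc);

  const double u_ref = std::max(*std::max_element(u_in.begin(), u_in.end()), 1e-30);
  const double p_ref = std::max(rho * u_ref * u_ref, 1e-30);
  const double k_ref = std::max(k_in, 1e-30);
  const double om_ref = std::max(om_in, 1e-30);

  NumericMatrix hist(max_iter, 6);
  int iter = 0, n_clip_k = 0, n_clip_om = 0;
  bool converged = false;

  GradBC bc_u = {DIRI, u_in.begin(), ZGRAD, 0.0, DIRI, 0.0};
  std::vector<double> zerosj(nj, 0.0);
  GradBC bc_v = {DIRI, zerosj.data(), ZGRAD, 0.0, DIRI, 0.0};
  GradBC bc_p = {ZGRAD, nullptr, DIRI, 0.0, ZGRAD, 0.0};
  GradBC bc_pp = {ZGRAD, nullptr, DIRI, 0.0, ZGRAD, 0.0};

  auto mu_eff_face_e = [&](int f, int i, int j) {
    if (laminar) return mu;
    double w = fg.wE[f];
    return mu + w * mut[g.C(i - 1, j)] + (1 - w) * mut[g.C(i, j)];
  };
  auto mu_eff_face_n = [&](int f, int i, int j) {
    if (laminar) return mu;
    double w = fg.wN[f];
    return mu + w * mut[g.C(i, j - 1)] + (1 - w) * mut[g.C(i, j)];
  };

  // assemble and solve one momentum component; comp = 0 (u) or 1 (v)
  auto momentum = [&](int comp, std::vector<double> &phi,
                      const std::vector<double> &gphix,
                      const std::vector<double> &gphir) {
    std::fill(aW.begin(), aW.end(), 0.0); std::fill(aE.begin(), aE.end(), 0.0);
    std::fill(aS.begin(), aS.end(), 0.0); std::fill(aN.begin(), aN.end(), 0.0);
    std::fill(b.begin(), b.end(), 0.0);
    std::vector<double> aC(nc, 0.0);

    for (int j = 0; j < nj; ++j) {
      for (int i = 1; i < ni; ++i) {
        int f = g.FE(i, j), P = g.C(i - 1, j), N = g.C(i, j);
        double F = me[f];
        double D = mu_eff_face_e(f, i, j) * fg.EfE[f];
        aC[P] += D + std::max(F, 0.0);
        aE[P] -= D + std::max(-F, 0.0);
        aC[N] += D + std::max(-F, 0.0);
        aW[N] -= D + std::max(F, 0.0);
        if (sou) {
          int U = (F >= 0.0) ? P : N;
          double hi = phi[U] + gphix[U] * (g.xfe[f] - g.xc[U]) +
                      gphir[U] * (g.rfe[f] - g.rc[U]);
          double corr = F * (hi - phi[U]);
          b[P] -= corr; b[N] += corr;
        }
        double w = fg.wE[f];
        double gfx = w * gphix[P] + (1 - w) * gphix[N];
        double gfr = w * gphir[P] + (1 - w) * gphir[N];
        double dcorr = mu_eff_face_e(f, i, j) * (gfx * fg.tEx[f] + gfr * fg.tEr[f]);
        b[P] += dcorr; b[N] -= dcorr;
      }
      {  // inlet: Dirichlet value, fixed inflow
        int f = g.FE(0, j), P = g.C(0, j);
        double phib = (comp == 0) ? u_in[j] : 0.0;
        double D = (laminar ? mu : mu + mut[P]) * fg.EfIn[j];
        aC[P] += D; b[P] += D * phib;
        double Fout = -me[f];
        if (Fout > 0) aC[P] += Fout; else b[P] -= Fout * phib;
      }
      {  // outlet: zero-gradient, convective outflow
        int f = g.FE(ni, j), P = g.C(ni - 1, j);
        double Fout = me[f];
        if (Fout > 0) aC[P] += Fout;
      }
    }
    for (int i = 0; i < ni; ++i) {
      for (int j = 1; j < nj; ++j) {
        int f = g.FN(i, j), P = g.C(i, j - 1), N = g.C(i, j);
        double F = mn[f];
        double D = mu_eff_face_n(f, i, j) * fg.EfN[f];
        aC[P] += D + std::max(F, 0.0);
        aN[P] -= D + std::max(-F, 0.0);
        aC[N] += D + std::max(-F, 0.0);
        aS[N] -= D + std::max(F, 0.0);
        if (sou) {
          int U = (F >= 0.0) ? P : N;
          double hi = phi[U] + gphix[U] * (g.xfn[f] - g.xc[U]) +
                      gphir[U] * (g.rfn[f] - g.rc[U]);
          double corr = F * (hi - phi[U]);
          b[P] -= corr; b[N] += corr;
        }
        double w = fg.wN[f];
        double gfx = w * gphix[P] + (1 - w) * gphix[N];
        double gfr = w * gphir[P] + (1 - w) * gphir[N];
        double dcorr = mu_eff_face_n(f, i, j) * (gfx * fg.tNx[f] + gfr * fg.tNr[f]);
        b[P] += dcorr; b[N] -= dcorr;
      }
      {  // wall: no-slip (viscosity at the wall is molecular)
        int fP = g.C(i, nj - 1);
        double D = mu * fg.EfWall[i];
        aC[fP] += D;
        if (quad_wall && nj >= 3) {
          // deferred quadratic one-sided wall gradient (2nd-order wall flux)
          int f = g.FN(i, nj);
          double Aw = std::hypot(g.Snx[f], g.Snr[f]);
          double nxh = g.Snx[f] / Aw, nrh = g.Snr[f] / Aw;
          int P2 = g.C(i, nj - 2);
          double y1 = g.wall_y[i];
          double y2 = (g.xfn[f] - g.xc[P2]) * nxh + (g.rfn[f] - g.rc[P2]) * nrh;
          double phi1 = phi[fP], phi2 = phi[P2];
          double gquad = (phi1 * y2 * y2 - phi2 * y1 * y1) /
                         (y1 * y2 * (y2 - y1));
          // outward diffusive flux: -Gamma * A * dphi/dy_wall
          double flux_quad = -mu * Aw * gquad;
          double flux_lin = -D * phi1;
          b[fP] -= (flux_quad - flux_lin);
        }
      }
    }

    // sources: pressure gradient; radial geometric sink for v
    for (int c = 0; c < nc; ++c) {
      if (comp == 0) b[c] -= gpx[c] * g.vol[c];
      else {
        b[c] -= gpr[c] * g.vol[c];
        double mue = laminar ? mu : mu + mut[c];
        aC[c] += mue * g.vol[c] / (g.rc[c] * g.rc[c]);
      }
    }
    // under-relaxation
    for (int c = 0; c < nc; ++c) {
      double apc = aC[c] / au;
      b[c] += (1.0 - au) * apc * phi[c];
      aP[c] = apc;
    }
    if (comp == 0)
      for (int c = 0; c < nc; ++c) invA[c] = 1.0 / aP[c];
    line_solve(g, aP, aW, aE, aS, aN, b, phi, nsweep);
  };

  // scalar transport for k / omega
  auto turb_scalar = [&](int which, std::vector<double> &phi) {
    std::fill(aW.begin(), aW.end(), 0.0); std::fill(aE.begin(), aE.end(), 0.0);
    std::fill(aS.begin(), aS.end(), 0.0); std::fill(aN.begin(), aN.end(), 0.0);
    std::fill(b.begin(), b.end(), 0.0);
    std::vector<double> aC(nc, 0.0);
    double sig = (which == 0) ? sigma_star : sigma;
    double phib_in = (which == 0) ? k_in : om_in;

    for (int j = 0; j < nj; ++j) {
      for (int i = 1; i < ni; ++i) {
        int f = g.FE(i, j), P = g.C(i - 1, j), N = g.C(i, j);
        double F = me[f];
        double w = fg.wE[f];
        double mutf = w * mut[P] + (1 - w) * mut[N];
        double D = (mu + sig * mutf) * fg.EfE[f];
        aC[P] += D + std::max(F, 0.0);
        aE[P] -= D + std::max(-F, 0.0);
        aC[N] += D + std::max(-F, 0.0);
        aW[N] -= D + std::max(F, 0.0);
      }
      {
        int f = g.FE(0, j), P = g.C(0, j);
        double D = (mu + sig * mut[P]) * fg.EfIn[j];
        aC[P] += D; b[P] += D * phib_in;
        double Fout = -me[f];
        if (Fout > 0) aC[P] += Fout; else b[P] -= Fout * phib_in;
      }
      {
        int f = g.FE(ni, j), P = g.C(ni - 1, j);
        double Fout = me[f];
        if (Fout > 0) aC[P] += Fout;
      }
    }
    for (int i = 0; i < ni; ++i) {
      for (int j = 1; j < nj; ++j) {
        int f = g.FN(i, j), P = g.C(i, j - 1), N = g.C(i, j);
        double F = mn[f];
        double w = fg.wN[f];
        double mutf = w * mut[P] + (1 - w) * mut[N];
        double D = (mu + sig * mutf) * fg.EfN[f];
        aC[P] += D + std::max(F, 0.0);
        aN[P] -= D + std::max(-F, 0.0);
        aC[N] += D + std::max(-F, 0.0);
        aS[N] -= D + std::max(F, 0.0);
      }
      if (which == 0) {  // k = 0 at the wall
        int P = g.C(i, nj - 1);
        aC[P] += (mu + sig * mut[P]) * fg.EfWall[i];
      }
    }
    // production / destruction
    for (int c = 0; c < nc; ++c) {
      double Phi2 = 2.0 * (gux[c] * gux[c] + gvr[c] * gvr[c] +
                           (v[c] / g.rc[c]) * (v[c] / g.rc[c])) +
                    (gur[c] + gvx[c]) * (gur[c] + gvx[c]);
      double Pk_raw = mut[c] * Phi2;
      double Pk_cap = 10.0 * beta_star * rho * k[c] * om[c];
      double Pk = std::min(Pk_raw, Pk_cap);
      if (which == 0) {
        b[c] += Pk * g.vol[c];
        aC[c] += beta_star * rho * om[c] * g.vol[c];
      } else {
        double src = (Pk_raw <= Pk_cap)
          ? alpha_w * rho * Phi2 * g.vol[c]
          : alpha_w * 10.0 * beta_star * rho * om[c] * om[c] * g.vol[c];
        b[c] += src;
        aC[c] += 2.0 * beta * rho * om[c] * g.vol[c];
        b[c] += beta * rho * om[c] * om[c] * g.vol[c];
      }
    }
    if (which == 1) {  // pin omega in wall-adjacent cells
      for (int i = 0; i < ni; ++i) {
        int c = g.C(i, nj - 1);
        aC[c] = 1.0; aW[c] = aE[c] = aS[c] = aN[c] = 0.0;
        b[c] = om_wall[i];
      }
    }
    for (int c = 0; c < nc; ++c) {
      double apc = aC[c] / akw;
      b[c] += (1.0 - akw) * apc * phi[c];
      aP[c] = apc;
    }
    if (which == 1) {  // keep wall pins exact under relaxation
      for (int i = 0; i < ni; ++i) {
        int c = g.C(i, nj - 1);
        aP[c] = 1.0; b[c] = om_wall[i];
      }
    }
    line_solve(g, aP, aW, aE, aS, aN, b, phi, nsweep);
  };

  // pressure-correction assembly + solve + corrections; returns max residual
  auto pressure_step = [&](double tol_abs, int max_cg, bool relax_pressure,
                           double rel_tol = 0.0) {
    std::fill(diagP.begin(), diagP.end(), 0.0);
    std::fill(aPe.begin(), aPe.end(), 0.0);
    std::fill(aPn.begin(), aPn.end(), 0.0);
    // Rhie-Chow face fluxes
    for (int j = 0; j < nj; ++j) {
      for (int i = 1; i < ni; ++i) {
        int f = g.FE(i, j), P = g.C(i - 1, j), N = g.C(i, j);
        double w = fg.wE[f];
        double uf = w * u[P] + (1 - w) * u[N], vf = w * v[P] + (1 - w) * v[N];
        double df = w * invA[P] * g.vol[P] + (1 - w) * invA[N] * g.vol[N];
        double gpfx = w * gpx[P] + (1 - w) * gpx[N];
        double gpfr = w * gpr[P] + (1 - w) * gpr[N];
        double mstar = rho * (uf * Sex(i, j) + vf * Ser(i, j));
        double corr = rho * df * fg.EfE[f] *
          ((p[N] - p[P]) - (gpfx * fg.dEx[f] + gpfr * fg.dEr[f]));
        me[f] = mstar - corr;
        aPe[f] = rho * df * fg.EfE[f];
      }
      {  // outlet: zero-gradient star flux, p' = 0 beyond
        int f = g.FE(ni, j), P = g.C(ni - 1, j);
        me[f] = rho * (u[P] * Sex(ni, j) + v[P] * Ser(ni, j));
        diagP[P] += rho * invA[P] * g.vol[P] * fg.EfOut[j];
      }
    }
    for (int i = 0; i < ni; ++i) {
      for (int j = 1; j < nj; ++j) {
        int f = g.FN(i, j), P = g.C(i, j - 1), N = g.C(i, j);
        double w = fg.wN[f];
        double uf = w * u[P] + (1 - w) * u[N], vf = w * v[P] + (1 - w) * v[N];
        double df = w * invA[P] * g.vol[P] + (1 - w) * invA[N] * g.vol[N];
        double gpfx = w * gpx[P] + (1 - w) * gpx[N];
        double gpfr = w * gpr[P] + (1 - w) * gpr[N];
        double mstar = rho * (uf * Snx(i, j) + vf * Snr(i, j));
        double corr = rho * df * fg.EfN[f] *
          ((p[N] - p[P]) - (gpfx * fg.dNx[f] + gpfr * fg.dNr[f]));
        mn[f] = mstar - corr;
        aPn[f] = rho * df * fg.EfN[f];
      }
    }
    // continuity imbalance (outward sum) and diagonal
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        int c = g.C(i, j);
        double imb = me[g.FE(i + 1, j)] - me[g.FE(i, j)] +
                     mn[g.FN(i, j + 1)] - mn[g.FN(i, j)];
        bP[c] = -imb;
        diagP[c] += aPe[g.FE(i, j)] + aPe[g.FE(i + 1, j)] +
                    aPn[g.FN(i, j)] + aPn[g.FN(i, j + 1)];
      }
    double res = pcg(g, diagP, aPe, aPn, bP, pp, tol_abs, max_cg, rel_tol);
    // correct pressure, fluxes, velocities
    double arel = relax_pressure ? ap_rel : 1.0;
    for (int c = 0; c < nc; ++c) p[c] += arel * pp[c];
    for (int j = 0; j < nj; ++j) {
      for (int i = 1; i < ni; ++i) {
        int f = g.FE(i, j);
        me[f] += aPe[f] * (pp[g.C(i - 1, j)] - pp[g.C(i, j)]);
      }
      int f = g.FE(ni, j), P = g.C(ni - 1, j);
      me[f] += rho * invA[P] * g.vol[P] * fg.EfOut[j] * pp[P];
    }
    for (int i = 0; i < ni; ++i)
      for (int j = 1; j < nj; ++j) {
        int f = g.FN(i, j);
        mn[f] += aPn[f] * (pp[g.C(i, j - 1)] - pp[g.C(i, j)]);
      }
    gradient(g, fg, pp, bc_pp, gx, gr);
    for (int c = 0; c < nc; ++c) {
      u[c] -= invA[c] * g.vol[c] * gx[c];
      v[c] -= invA[c] * g.vol[c] * gr[c];
    }
    return res;
  };

  for (iter = 0; iter < max_iter; ++iter) {
    u_old = u; v_old = v; p_old = p; k_old = k; om_old = om;

    gradient(g, fg, p, bc_p, gpx, gpr);
    gradient(g, fg, u, bc_u, gux, gur);
    gradient(g, fg, v, bc_v, gvx, gvr);

    momentum(0, u, gux, gur);
    momentum(1, v, gvx, gvr);

    pressure_step(std::max(1e-11 * m_ref, 1e-300), 600, true, 0.02);
    gradient(g, fg, p, bc_p, gpx, gpr);

    if (!laminar) {
      gradient(g, fg, u, bc_u, gux, gur);
      gradient(g, fg, v, bc_v, gvx, gvr);
      turb_scalar(1, om);
      turb_scalar(0, k);
      double k_floor = 1e-12 * k_ref, om_floor = 1e-8 * om_ref;
      for (int c = 0; c < nc; ++c) {
        if (k[c] < k_floor) { k[c] = k_floor; ++n_clip_k; }
        if (om[c] < om_floor) { om[c] = om_floor; ++n_clip_om; }
        mut[c] = rho * k[c] / om[c];
      }
    }

    // inter-iteration relative variation per field
    double ru = 0, rv = 0, rp = 0, rk = 0, rom = 0, rcont = 0;
    for (int c = 0; c < nc; ++c) {
      ru += std::abs(u[c] - u_old[c]);
      rv += std::abs(v[c] - v_old[c]);
      rp += std::abs(p[c] - p_old[c]);
      rk += std::abs(k[c] - k_old[c]);
      rom += std::abs(om[c] - om_old[c]);
      rcont = std::max(rcont, std::abs(bP[c]));
    }
    ru /= nc * u_ref; rv /= nc * u_ref; rp /= nc * p_ref;
    rk /= nc * k_ref; rom /= nc * om_ref; rcont /= m_ref;
    hist(iter, 0) = ru; hist(iter, 1) = rv; hist(iter, 2) = rp;
    hist(iter, 3) = rk; hist(iter, 4) = rom; hist(iter, 5) = rcont;

    if (!std::isfinite(ru + rv + rp + rk + rom))
      stop("solver diverged (non-finite field) at iteration %d", iter + 1);

    double rmax = std::max({ru, rv, rp, laminar ? 0.0 : rk,
                            laminar ? 0.0 : rom});
    if (iter + 1 >= min_iter && rmax < tol) { converged = true; ++iter; break; }
  }

  // final tight mass-conservation pass
  gradient(g, fg, p, bc_p, gpx, gpr);
  double final_res = pressure_step(1e-13 * m_ref, 20000, false);

  double m_out_tot = 0.0;
  for (int j = 0; j < nj; ++j) m_out_tot += me[g.FE(ni, j)];
  double max_imb = 0.0;
  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < ni; ++i) {
      double imb = me[g.FE(i + 1, j)] - me[g.FE(i, j)] +
                   mn[g.FN(i, j + 1)] - mn[g.FN(i, j)];
      max_imb = std::max(max_imb, std::abs(imb));
    }

  auto to_mat = [&](const std::vector<double> &x) {
    NumericMatrix m(ni, nj);
    std::copy(x.begin(), x.end(), m.begin());
    return m;
  };
  NumericMatrix me_m(ni + 1, nj), mn_m(ni, nj + 1);
  std::copy(me.begin(), me.end(), me_m.begin());
  std::copy(mn.begin(), mn.end(), mn_m.begin());

  int nh = std::max(iter, 1);
  NumericMatrix hist_out(nh, 6);
  for (int r = 0; r < nh; ++r)
    for (int cI = 0; cI < 6; ++cI) hist_out(r, cI) = hist(r, cI);

  return List::create(
    _["u"] = to_mat(u), _["v"] = to_mat(v), _["p"] = to_mat(p),
    _["k"] = to_mat(k), _["omega"] = to_mat(om), _["mu_t"] = to_mat(mut),
    _["me"] = me_m, _["mn"] = mn_m,
    _["history"] = hist_out, _["iterations"] = iter,
    _["converged"] = converged,
    _["inlet_flux"] = m_in_tot, _["outlet_flux"] = m_out_tot,
    _["max_cell_imbalance"] = max_imb, _["pressure_residual"] = final_res,
    _["clipped_k"] = n_clip_k, _["clipped_omega"] = n_clip_om);
}

// [[Rcpp::export]]
List cpp_cell_gradient(List mesh, NumericMatrix phi, int bc_west,
                       NumericVector west_val, int bc_east, double east_val,
                       int bc_north, double north_val) {
  NumericMatrix xc = mesh["xc"], rc = mesh["rc"], vol = mesh["vol"];
  NumericMatrix Sex = mesh["Se_x"], Ser = mesh["Se_r"];
  NumericMatrix xfe = mesh["xfe"], rfe = mesh["rfe"];
  NumericMatrix Snx = mesh["Sn_x"], Snr = mesh["Sn_r"];
  NumericMatrix xfn = mesh["xfn"], rfn = mesh["rfn"];
  NumericMatrix sumSx = mesh["sumS_x"], sumSr = mesh["sumS_r"];
  NumericVector wall_y = mesh["wall_y"];
  Geo g;
  g.ni = as<int>(mesh["ni"]); g.nj = as<int>(mesh["nj"]);
  g.nc = g.ni * g.nj; g.nfe = (g.ni + 1) * g.nj; g.nfn = g.ni * (g.nj + 1);
  g.xc = xc.begin(); g.rc = rc.begin(); g.vol = vol.begin();
  g.Sex = Sex.begin(); g.Ser = Ser.begin(); g.xfe = xfe.begin(); g.rfe = rfe.begin();
  g.Snx = Snx.begin(); g.Snr = Snr.begin(); g.xfn = xfn.begin(); g.rfn = rfn.begin();
  g.sumSx = sumSx.begin(); g.sumSr = sumSr.begin();
  g.wall_y = wall_y.begin();
  FaceGeo fg = face_geometry(g);
  std::vector<double> ph(phi.begin(), phi.end()), gx(g.nc), gr(g.nc);
  GradBC gbc = {bc_west, west_val.begin(), bc_east, east_val, bc_north, north_val};
  gradient(g, fg, ph, gbc, gx, gr);
  NumericMatrix gxm(g.ni, g.nj), grm(g.ni, g.nj);
  std::copy(gx.begin(), gx.end(), gxm.begin());
  std::copy(gr.begin(), gr.end(), grm.begin());
  return List::create(_["gx"] = gxm, _["gr"] = grm);
}
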