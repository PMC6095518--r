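// Finite-difference kernels on the regular 3D grid.
//
// All fields are column-major 3D arrays (nx, ny, nz), voxel (i,j,k) centred at
// ((i+0.5)dx, (j+0.5)dx, (k+0.5)dx) with 0-based indices here.
//
// Boundary closure on the six box faces:
//  - scalars reflect evenly (ghost = nearest interior value): homogeneous
//    Neumann for gradients and the 7-point Laplacian;
//  - the normal component of a flux reflects oddly (ghost = -nearest value):
//    zero normal flux, which makes the grid sum of any flux divergence vanish
//    identically (discrete conservation).

#include <RcppArmadillo.h>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int reflect(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

#define IDX(i, j, k) ((i) + nx * ((j) + (size_t)ny * (k)))

static void lap_raw(const double* f, double* out, int nx, int ny, int nz, double dx) {
  const double idx2 = 1.0 / (dx * dx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double c = f[IDX(i, j, k)];
        double s = f[IDX(reflect(i + 1, nx), j, k)] + f[IDX(reflect(i - 1, nx), j, k)]
                 + f[IDX(i, reflect(j + 1, ny), k)] + f[IDX(i, reflect(j - 1, ny), k)]
                 + f[IDX(i, j, reflect(k + 1, nz))] + f[IDX(i, j, reflect(k - 1, nz))]
                 - 6.0 * c;
        out[IDX(i, j, k)] = s * idx2;
      }
}

static void grad_raw(const double* f, double* gx, double* gy, double* gz,
                     int nx, int ny, int nz, double dx) {
  const double h = 1.0 / (2.0 * dx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t id = IDX(i, j, k);
        gx[id] = (f[IDX(reflect(i + 1, nx), j, k)] - f[IDX(reflect(i - 1, nx), j, k)]) * h;
        gy[id] = (f[IDX(i, reflect(j + 1, ny), k)] - f[IDX(i, reflect(j - 1, ny), k)]) * h;
        gz[id] = (f[IDX(i, j, reflect(k + 1, nz))] - f[IDX(i, j, reflect(k - 1, nz))]) * h;
      }
}

// central-difference divergence with the even (Neumann) reflection: exact
// zero for constant vector fields; div(grad f) agrees with the 7-point
// Laplacian to O(dx^2) on smooth fields
static void div_raw(const double* vx, const double* vy, const double* vz,
                    double* out, int nx, int ny, int nz, double dx) {
  const double h = 1.0 / (2.0 * dx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double sx = vx[IDX(reflect(i + 1, nx), j, k)] - vx[IDX(reflect(i - 1, nx), j, k)];
        double sy = vy[IDX(i, reflect(j + 1, ny), k)] - vy[IDX(i, reflect(j - 1, ny), k)];
        double sz = vz[IDX(i, j, reflect(k + 1, nz))] - vz[IDX(i, j, reflect(k - 1, nz))];
        out[IDX(i, j, k)] = (sx + sy + sz) * h;
      }
}

static void check_dims(const IntegerVector& dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (dim[0] < 8 || dim[1] < 8 || dim[2] < 8)
    stop("grid smaller than stencil support: all dimensions must be >= 8");
}

// [[Rcpp::export]]
NumericVector cpp_laplacian(NumericVector f, IntegerVector dim, double dx) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(f.size());
  lap_raw(REAL(f), REAL(out), nx, ny, nz, dx);
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gradient(NumericVector f, IntegerVector dim, double dx) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n * 3);
  grad_raw(REAL(f), REAL(out), REAL(out) + n, REAL(out) + 2 * n, nx, ny, nz, dx);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_divergence(NumericVector v, IntegerVector dim, double dx) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  div_raw(REAL(v), REAL(v) + n, REAL(v) + 2 * n, REAL(out), nx, ny, nz, dx);
  out.attr("dim") = dim;
  return out;
}

// flux j_a = T_ab d_b s, then divergence of j (zero-flux closure).
// T is (nx, ny, nz, 3, 3) with T[,,,a,b] = T_ab.
//
// Discretized in conservative (face-flux) form: the normal flux through each
// interior cell face combines the two-point normal derivative with the
// face-averaged tangential derivatives and the face-averaged tensor;
// boundary faces carry zero flux. This reduces exactly to the 7-point
// Laplacian when T is the identity and its grid sum telescopes to zero for
// any T and s.
static void aniso_raw(const double* T, const double* s, double* out,
                      double* wrk, int nx, int ny, int nz, double dx) {
  size_t n = (size_t)nx * ny * nz;
  double *gx = wrk, *gy = wrk + n, *gz = wrk + 2 * n;
  grad_raw(s, gx, gy, gz, nx, ny, nz, dx);  // cell-centred tangential parts
  const double* g[3] = {gx, gy, gz};
  const double* Tc[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      Tc[a][b] = T + ((size_t)a + 3 * (size_t)b) * n;  // column-major: dims 4,5
  const int stride[3] = {1, nx, nx * ny};
  const double idx = 1.0 / dx, idx2 = 1.0 / (dx * dx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t id = IDX(i, j, k);
        const int pos[3] = {i, j, k};
        const int nmax[3] = {nx, ny, nz};
        double acc = 0.0;
        for (int a = 0; a < 3; ++a) {
          const size_t st = (size_t)stride[a];
          double jp = 0.0, jm = 0.0;
          if (pos[a] + 1 < nmax[a]) {  // face a+ : between id and id + st
            const size_t q = id + st;
            jp = 0.5 * (Tc[a][a][id] + Tc[a][a][q]) * (s[q] - s[id]) * idx2 * dx;
            for (int b = 0; b < 3; ++b) {
              if (b == a) continue;
              jp += 0.5 * (Tc[a][b][id] + Tc[a][b][q]) * 0.5 * (g[b][id] + g[b][q]);
            }
          }
          if (pos[a] - 1 >= 0) {  // face a- : between id - st and id
            const size_t q = id - st;
            jm = 0.5 * (Tc[a][a][q] + Tc[a][a][id]) * (s[id] - s[q]) * idx2 * dx;
            for (int b = 0; b < 3; ++b) {
              if (b == a) continue;
              jm += 0.5 * (Tc[a][b][q] + Tc[a][b][id]) * 0.5 * (g[b][q] + g[b][id]);
            }
          }
          acc += (jp - jm) * idx;
        }
        out[id] = acc;
      }
}

// [[Rcpp::export]]
NumericVector cpp_aniso_div(NumericVector T, NumericVector s, IntegerVector dim, double dx) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  if ((size_t)T.size() != 9 * n) stop("tensor field has wrong size");
  for (R_xlen_t t = 0; t < T.size(); ++t)
    if (!std::isfinite(T[t])) stop("non-finite tensor entries");
  std::vector<double> wrk(6 * n);
  NumericVector out(n);
  aniso_raw(REAL(T), REAL(s), REAL(out), wrk.data(), nx, ny, nz, dx);
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// BVAM reaction-diffusion integrator (explicit Euler)
//   du/dt = D lap u + eta (u + a v - c u v - u v^2)
//   dv/dt =   lap v + eta (b v + h u + c u v + u v^2)
// ---------------------------------------------------------------------------

// masked diffusion: conservative face-flux form of div(chi * grad f) given
// precomputed face mobilities (cx at x+ faces, etc.); with chi == 1 this is
// exactly the 7-point Laplacian.
struct FaceMob {
  std::vector<double> cx, cy, cz;
  FaceMob(const double* chi, int nx, int ny, int nz)
      : cx((size_t)nx * ny * nz, 0.0), cy((size_t)nx * ny * nz, 0.0),
        cz((size_t)nx * ny * nz, 0.0) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const size_t id = IDX(i, j, k);
          if (i + 1 < nx) cx[id] = 0.5 * (chi[id] + chi[id + 1]);
          if (j + 1 < ny) cy[id] = 0.5 * (chi[id] + chi[id + nx]);
          if (k + 1 < nz) cz[id] = 0.5 * (chi[id] + chi[id + (size_t)nx * ny]);
        }
  }
};

static void masked_lap_raw(const double* f, const FaceMob& fm, double* out,
                           int nx, int ny, int nz, double dx) {
  const double idx2 = 1.0 / (dx * dx);
  const size_t sy = nx, sz = (size_t)nx * ny;
  const double *cx = fm.cx.data(), *cy = fm.cy.data(), *cz = fm.cz.data();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const size_t row = sy * j + sz * k;
      for (int i = 0; i < nx; ++i) {
        const size_t id = row + i;
        double acc = 0.0;
        if (i + 1 < nx) acc += cx[id] * (f[id + 1] - f[id]);
        if (i > 0) acc -= cx[id - 1] * (f[id] - f[id - 1]);
        if (j + 1 < ny) acc += cy[id] * (f[id + sy] - f[id]);
        if (j > 0) acc -= cy[id - sy] * (f[id] - f[id - sy]);
        if (k + 1 < nz) acc += cz[id] * (f[id + sz] - f[id]);
        if (k > 0) acc -= cz[id - sz] * (f[id] - f[id - sz]);
        out[id] = acc * idx2;
      }
    }
}

// [[Rcpp::export]]
List cpp_bvam_run(NumericVector u0, NumericVector v0, IntegerVector dim, double dx,
                  double a, double b, double c, double h, double D, double eta,
                  double dt, int nsteps, Nullable<NumericVector> chi_ = R_NilValue) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector u = clone(u0), v = clone(v0);
  std::vector<double> lu(n), lv(n);
  double* up = REAL(u);
  double* vp = REAL(v);
  const bool masked = chi_.isNotNull();
  NumericVector chi_v;
  const double* chip = NULL;
  std::unique_ptr<FaceMob> fm;
  if (masked) {
    chi_v = chi_.get();
    if ((size_t)chi_v.size() != n) stop("chi has wrong size");
    chip = REAL(chi_v);
    fm.reset(new FaceMob(chip, nx, ny, nz));
  }
  for (int step = 0; step < nsteps; ++step) {
    if (masked) {
      masked_lap_raw(up, *fm, lu.data(), nx, ny, nz, dx);
      masked_lap_raw(vp, *fm, lv.data(), nx, ny, nz, dx);
    } else {
      lap_raw(up, lu.data(), nx, ny, nz, dx);
      lap_raw(vp, lv.data(), nx, ny, nz, dx);
    }
    for (size_t id = 0; id < n; ++id) {
      const double uu = up[id], vv = vp[id], uv = uu * vv;
      const double w = masked ? chip[id] : 1.0;
      up[id] = uu + dt * (D * lu[id] + w * eta * (uu + a * vv - c * uv - uv * vv));
      vp[id] = vv + dt * (lv[id] + w * eta * (b * vv + h * uu + c * uv + uv * vv));
    }
    if ((step & 63) == 0 || step == nsteps - 1) {
      if (!std::isfinite(up[0]) || !std::isfinite(up[n / 2]))
        stop("reaction-diffusion integration diverged in field 'u' at step %d", step);
      if (!std::isfinite(vp[0]) || !std::isfinite(vp[n / 2]))
        stop("reaction-diffusion integration diverged in field 'v' at step %d", step);
    }
  }
  for (size_t id = 0; id < n; ++id) {
    if (!std::isfinite(up[id])) stop("reaction-diffusion integration diverged in field 'u'");
    if (!std::isfinite(vp[id])) stop("reaction-diffusion integration diverged in field 'v'");
  }
  u.attr("dim") = dim;
  v.attr("dim") = dim;
  return List::create(_["u"] = u, _["v"] = v);
}

// ---------------------------------------------------------------------------
// Free energy pieces (shared by the stress tensor and the mechanical stepper)
//   Phi    = -phi + phi^3 - eps^2 lap phi
//   PhiSC  = Phi - eps * beta * u^2 * (phi^2 - 1)
//   mu_phi = 2[(3 phi^2 - 1 - 2 phi eps beta u^2) PhiSC - eps^2 lap PhiSC]
//            + rho_phi lap phi
//   mu_u   = -4 eps (phi^2 - 1) beta u PhiSC + rho_u lap u
// ---------------------------------------------------------------------------

struct EnergyWork {
  std::vector<double> lap_phi, phisc, lap_phisc, mu_phi, lap_u, mu_u;
  explicit EnergyWork(size_t n)
      : lap_phi(n), phisc(n), lap_phisc(n), mu_phi(n), lap_u(n), mu_u(n) {}
};

static void energy_terms(const double* phi, const double* u, EnergyWork& w,
                         int nx, int ny, int nz, double dx,
                         double eps, double beta, double rho_phi, double rho_u) {
  size_t n = (size_t)nx * ny * nz;
  lap_raw(phi, w.lap_phi.data(), nx, ny, nz, dx);
  for (size_t id = 0; id < n; ++id) {
    const double p = phi[id];
    const double Phi = -p + p * p * p - eps * eps * w.lap_phi[id];
    w.phisc[id] = Phi - eps * beta * u[id] * u[id] * (p * p - 1.0);
  }
  lap_raw(w.phisc.data(), w.lap_phisc.data(), nx, ny, nz, dx);
  lap_raw(u, w.lap_u.data(), nx, ny, nz, dx);
  for (size_t id = 0; id < n; ++id) {
    const double p = phi[id], uu = u[id];
    w.mu_phi[id] = 2.0 * ((3.0 * p * p - 1.0 - 2.0 * p * eps * beta * uu * uu) * w.phisc[id]
                          - eps * eps * w.lap_phisc[id])
                   + rho_phi * w.lap_phi[id];
    w.mu_u[id] = -4.0 * eps * (p * p - 1.0) * beta * uu * w.phisc[id] + rho_u * w.lap_u[id];
  }
}

// Raw stress tensor (not symmetrized), from the energy density
//   L = PhiSC^2 - 1/2 rho_phi |grad phi|^2 - 1/2 rho_u |grad u|^2
// sigma_ab = (L - phi mu_phi) delta_ab + rho_phi d_a(phi) d_b(phi)
//            - 2 eps^2 d_b(PhiSC) d_a(phi) + 2 eps^2 PhiSC d_a d_b(phi)
static void stress_raw(const double* phi, const double* u, double* sig,
                       int nx, int ny, int nz, double dx,
                       double eps, double beta, double rho_phi, double rho_u) {
  size_t n = (size_t)nx * ny * nz;
  EnergyWork w(n);
  energy_terms(phi, u, w, nx, ny, nz, dx, eps, beta, rho_phi, rho_u);
  std::vector<double> gpx(n), gpy(n), gpz(n), gux(n), guy(n), guz(n),
      gsx(n), gsy(n), gsz(n);
  grad_raw(phi, gpx.data(), gpy.data(), gpz.data(), nx, ny, nz, dx);
  grad_raw(u, gux.data(), guy.data(), guz.data(), nx, ny, nz, dx);
  grad_raw(w.phisc.data(), gsx.data(), gsy.data(), gsz.data(), nx, ny, nz, dx);
  const double* gp[3] = {gpx.data(), gpy.data(), gpz.data()};
  const double* gs[3] = {gsx.data(), gsy.data(), gsz.data()};

  // Hessian of phi (central differences, even reflection)
  const double idx2 = 1.0 / (dx * dx), iq = 1.0 / (4.0 * dx * dx);
  std::vector<double> hess(6 * n);  // xx, yy, zz, xy, xz, yz
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const size_t id = IDX(i, j, k);
        const double c = phi[id];
        int ip = reflect(i + 1, nx), im = reflect(i - 1, nx);
        int jp = reflect(j + 1, ny), jm = reflect(j - 1, ny);
        int kp = reflect(k + 1, nz), km = reflect(k - 1, nz);
        hess[id]         = (phi[IDX(ip, j, k)] - 2 * c + phi[IDX(im, j, k)]) * idx2;
        hess[id + n]     = (phi[IDX(i, jp, k)] - 2 * c + phi[IDX(i, jm, k)]) * idx2;
        hess[id + 2 * n] = (phi[IDX(i, j, kp)] - 2 * c + phi[IDX(i, j, km)]) * idx2;
        hess[id + 3 * n] = (phi[IDX(ip, jp, k)] - phi[IDX(ip, jm, k)]
                            - phi[IDX(im, jp, k)] + phi[IDX(im, jm, k)]) * iq;
        hess[id + 4 * n] = (phi[IDX(ip, j, kp)] - phi[IDX(ip, j, km)]
                            - phi[IDX(im, j, kp)] + phi[IDX(im, j, km)]) * iq;
        hess[id + 5 * n] = (phi[IDX(i, jp, kp)] - phi[IDX(i, jp, km)]
                            - phi[IDX(i, jm, kp)] + phi[IDX(i, jm, km)]) * iq;
      }
  static const int hidx[3][3] = {{0, 3, 4}, {3, 1, 5}, {4, 5, 2}};
  for (int b = 0; b < 3; ++b)
    for (int a = 0; a < 3; ++a) {
      double* s_ab = sig + ((size_t)a + 3 * (size_t)b) * n;
      const double* hab = hess.data() + (size_t)hidx[a][b] * n;
      const bool diag = (a == b);
      for (size_t id = 0; id < n; ++id) {
        const double L = w.phisc[id] * w.phisc[id]
            - 0.5 * rho_phi * (gpx[id] * gpx[id] + gpy[id] * gpy[id] + gpz[id] * gpz[id])
            - 0.5 * rho_u * (gux[id] * gux[id] + guy[id] * guy[id] + guz[id] * guz[id]);
        double v = rho_phi * gp[a][id] * gp[b][id]
                 - 2.0 * eps * eps * gs[b][id] * gp[a][id]
                 + 2.0 * eps * eps * w.phisc[id] * hab[id];
        if (diag) v += L - phi[id] * w.mu_phi[id];
        s_ab[id] = v;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_stress(NumericVector phi, NumericVector u, IntegerVector dim, double dx,
                         double eps, double beta, double rho_phi, double rho_u) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector sig(9 * n);
  stress_raw(REAL(phi), REAL(u), REAL(sig), nx, ny, nz, dx, eps, beta, rho_phi, rho_u);
  for (size_t t = 0; t < 9 * n; ++t)
    if (!std::isfinite(REAL(sig)[t])) {
      size_t id = t % n;
      stop("non-finite stress at voxel (%d, %d, %d)",
           (int)(id % nx) + 1, (int)((id / nx) % ny) + 1, (int)(id / ((size_t)nx * ny)) + 1);
    }
  sig.attr("dim") = IntegerVector::create(nx, ny, nz, 3, 3);
  return sig;
}

// [[Rcpp::export]]
List cpp_energy_terms(NumericVector phi, NumericVector u, IntegerVector dim, double dx,
                      double eps, double beta, double rho_phi, double rho_u) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  EnergyWork w(n);
  energy_terms(REAL(phi), REAL(u), w, nx, ny, nz, dx, eps, beta, rho_phi, rho_u);
  NumericVector phisc(w.phisc.begin(), w.phisc.end());
  NumericVector mu_phi(w.mu_phi.begin(), w.mu_phi.end());
  NumericVector mu_u(w.mu_u.begin(), w.mu_u.end());
  phisc.attr("dim") = dim;
  mu_phi.attr("dim") = dim;
  mu_u.attr("dim") = dim;
  return List::create(_["phisc"] = phisc, _["mu_phi"] = mu_phi, _["mu_u"] = mu_u);
}

// ---------------------------------------------------------------------------
// Curvature tensor of the phase-field interface.
// Outward unit normal nvec = -grad phi / |grad phi| (phi > 0 inside), then
// Q_ab = (delta_ag - n_a n_g) d_g n_b, H = trace(Q) / 2.
// Only defined on the interface band |phi| < band; NaN elsewhere.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_curvature(NumericVector phi, IntegerVector dim, double dx, double band) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const double* p = REAL(phi);
  std::vector<double> gx(n), gy(n), gz(n), n1(n), n2(n), n3(n);
  grad_raw(p, gx.data(), gy.data(), gz.data(), nx, ny, nz, dx);
  const double tol = 1e-10;
  for (size_t id = 0; id < n; ++id) {
    double g = std::sqrt(gx[id] * gx[id] + gy[id] * gy[id] + gz[id] * gz[id]);
    if (g > tol) {
      n1[id] = -gx[id] / g;
      n2[id] = -gy[id] / g;
      n3[id] = -gz[id] / g;
    } else {
      n1[id] = n2[id] = n3[id] = 0.0;
    }
  }
  // gradients of the normal components: dn[g][b] = d_g n_b
  std::vector<double> dn(9 * n);
  const double* nc[3] = {n1.data(), n2.data(), n3.data()};
  for (int b = 0; b < 3; ++b)
    grad_raw(nc[b], dn.data() + (0 + 3 * (size_t)b) * n,
             dn.data() + (1 + 3 * (size_t)b) * n,
             dn.data() + (2 + 3 * (size_t)b) * n, nx, ny, nz, dx);
  NumericVector Q(9 * n), H(n);
  double* q = REAL(Q);
  double* hh = REAL(H);
  for (size_t id = 0; id < n; ++id) {
    double gmag = std::sqrt(gx[id] * gx[id] + gy[id] * gy[id] + gz[id] * gz[id]);
    bool ok = std::fabs(p[id]) < band && gmag > tol;
    if (!ok) {
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          q[((size_t)a + 3 * (size_t)b) * n + id] = NA_REAL;
      hh[id] = NA_REAL;
      continue;
    }
    const double nv[3] = {n1[id], n2[id], n3[id]};
    double tr = 0.0;
    for (int b = 0; b < 3; ++b) {
      for (int a = 0; a < 3; ++a) {
        double val = dn[((size_t)a + 3 * (size_t)b) * n + id];  // d_a n_b
        double proj = 0.0;
        for (int g = 0; g < 3; ++g)
          proj += nv[g] * dn[((size_t)g + 3 * (size_t)b) * n + id];
        val -= nv[a] * proj;  // (delta_ag - n_a n_g) d_g n_b
        q[((size_t)a + 3 * (size_t)b) * n + id] = val;
        if (a == b) tr += val;
      }
    }
    hh[id] = 0.5 * tr;
  }
  Q.attr("dim") = IntegerVector::create(nx, ny, nz, 3, 3);
  H.attr("dim") = dim;
  return List::create(_["Q"] = Q, _["H"] = H);
}

// ---------------------------------------------------------------------------
// Mechanical integrator: explicit Euler on the coupled master equations
//   dphi/dt = D_phi lap(mu_phi) + m u^2 + kappa m G + s_phi
//   du/dt   = gamma div(sigma_sym grad mu_u) + G + s_u
// sigma_sym is the symmetrized stress tensor, recomputed every stress_every
// steps (it varies on the slow mechanical time scale).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_mech_run(NumericVector phi0, NumericVector u0, IntegerVector dim, double dx,
                  double eps, double beta, double gamma, double m, double kappa,
                  double D_phi, double rho_phi, double rho_u,
                  NumericVector G, NumericVector s_phi, NumericVector s_u,
                  double dt, int nsteps, int stress_every) {
  check_dims(dim);
  if (stress_every < 1) stop("stress_every must be >= 1");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector phi = clone(phi0), u = clone(u0);
  double* pp = REAL(phi);
  double* up = REAL(u);
  const double* Gp = REAL(G);
  const double* sphip = REAL(s_phi);
  const double* sup = REAL(s_u);
  EnergyWork w(n);
  std::vector<double> sig(9 * n), sig_sym(9 * n), lap_mu(n), aniso(n), wrk(6 * n);
  for (int step = 0; step < nsteps; ++step) {
    if (step % stress_every == 0) {
      stress_raw(pp, up, sig.data(), nx, ny, nz, dx, eps, beta, rho_phi, rho_u);
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double* sab = sig_sym.data() + ((size_t)a + 3 * (size_t)b) * n;
          const double* r1 = sig.data() + ((size_t)a + 3 * (size_t)b) * n;
          const double* r2 = sig.data() + ((size_t)b + 3 * (size_t)a) * n;
          for (size_t id = 0; id < n; ++id) sab[id] = 0.5 * (r1[id] + r2[id]);
        }
    }
    energy_terms(pp, up, w, nx, ny, nz, dx, eps, beta, rho_phi, rho_u);
    lap_raw(w.mu_phi.data(), lap_mu.data(), nx, ny, nz, dx);
    aniso_raw(sig_sym.data(), w.mu_u.data(), aniso.data(), wrk.data(), nx, ny, nz, dx);
    for (size_t id = 0; id < n; ++id) {
      pp[id] += dt * (D_phi * lap_mu[id] + m * up[id] * up[id] + kappa * m * Gp[id] + sphip[id]);
      up[id] += dt * (gamma * aniso[id] + Gp[id] + sup[id]);
    }
    if ((step & 31) == 0 || step == nsteps - 1) {
      if (!std::isfinite(pp[n / 2])) stop("mechanical integration diverged in field 'phi' at step %d", step);
      if (!std::isfinite(up[n / 2])) stop("mechanical integration diverged in field 'u' at step %d", step);
    }
  }
  for (size_t id = 0; id < n; ++id) {
    if (!std::isfinite(pp[id])) stop("mechanical integration diverged in field 'phi'");
    if (!std::isfinite(up[id])) stop("mechanical integration diverged in field 'u'");
  }
  phi.attr("dim") = dim;
  u.attr("dim") = dim;
  return List::create(_["phi"] = phi, _["u"] = u);
}

// ---------------------------------------------------------------------------
// Per-voxel eigendecomposition of the symmetrized tensor field.
// Eigenvalues sorted descending; each eigenvector's largest-magnitude
// component is made positive (deterministic sign convention).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_principal(NumericVector T, IntegerVector dim) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  if ((size_t)T.size() != 9 * n) stop("tensor field has wrong size");
  const double* tp = REAL(T);
  NumericVector vals(3 * n), vecs(9 * n);
  double* valp = REAL(vals);
  double* vecp = REAL(vecs);
  arma::mat33 A;
  arma::vec3 ev;
  arma::mat33 V;
  for (size_t id = 0; id < n; ++id) {
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double t1 = tp[((size_t)a + 3 * (size_t)b) * n + id];
        double t2 = tp[((size_t)b + 3 * (size_t)a) * n + id];
        A(a, b) = 0.5 * (t1 + t2);
      }
    arma::eig_sym(ev, V, A);  // ascending
    for (int r = 0; r < 3; ++r) {
      int src = 2 - r;  // descending
      valp[(size_t)r * n + id] = ev(src);
      double c0 = V(0, src), c1 = V(1, src), c2 = V(2, src);
      double m0 = std::fabs(c0), m1 = std::fabs(c1), m2 = std::fabs(c2);
      double lead = (m0 >= m1 && m0 >= m2) ? c0 : (m1 >= m2 ? c1 : c2);
      double sgn = (lead < 0) ? -1.0 : 1.0;
      vecp[((size_t)0 + 3 * (size_t)r) * n + id] = sgn * c0;
      vecp[((size_t)1 + 3 * (size_t)r) * n + id] = sgn * c1;
      vecp[((size_t)2 + 3 * (size_t)r) * n + id] = sgn * c2;
    }
  }
  vals.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  vecs.attr("dim") = IntegerVector::create(nx, ny, nz, 3, 3);
  return List::create(_["magnitudes"] = vals, _["directions"] = vecs);
}

// ---------------------------------------------------------------------------
// Trilinear interpolation of a voxel-centred field at physical points.
// Voxel (i,j,k) (0-based) sits at ((i+0.5)dx, ...). NA voxels propagate.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector f, IntegerVector dim, double dx,
                            NumericMatrix pts) {
  check_dims(dim);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* fp = REAL(f);
  int np = pts.nrow();
  NumericVector out(np);
  for (int q = 0; q < np; ++q) {
    double xs = pts(q, 0) / dx - 0.5, ys = pts(q, 1) / dx - 0.5, zs = pts(q, 2) / dx - 0.5;
    int i0 = (int)std::floor(xs), j0 = (int)std::floor(ys), k0 = (int)std::floor(zs);
    double fx = xs - i0, fy = ys - j0, fz = zs - k0;
    double acc = 0.0;
    bool bad = false;
    for (int dk = 0; dk < 2 && !bad; ++dk)
      for (int dj = 0; dj < 2 && !bad; ++dj)
        for (int di = 0; di < 2 && !bad; ++di) {
          int ii = reflect(i0 + di, nx), jj = reflect(j0 + dj, ny), kk = reflect(k0 + dk, nz);
          double v = fp[IDX(ii, jj, kk)];
          if (!std::isfinite(v)) { bad = true; break; }
          double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          acc += wgt * v;
        }
    out[q] = bad ? NA_REAL : acc;
  }
  return out;
}
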