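#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Thomas algorithm core: solves a tridiagonal system in place.
// a: sub-diagonal (a[0] unused), b: diagonal, c: super-diagonal (c[n-1] unused),
// d: rhs, overwritten with the solution. cp: workspace of length n.
static void thomas(int n, const double* a, const double* b, const double* c,
                   double* d, double* cp) {
  double piv = b[0];
  if (std::fabs(piv) < 1e-300) stop("tdma: zero pivot at row 1");
  cp[0] = c[0] / piv;
  d[0] = d[0] / piv;
  for (int i = 1; i < n; ++i) {
    piv = b[i] - a[i] * cp[i - 1];
    if (std::fabs(piv) < 1e-300) stop("tdma: zero pivot at row " + std::to_string(i + 1));
    cp[i] = c[i] / piv;
    d[i] = (d[i] - a[i] * d[i - 1]) / piv;
  }
  for (int i = n - 2; i >= 0; --i) d[i] -= cp[i] * d[i + 1];
}

// [[Rcpp::export]]
NumericVector tdma_cpp(NumericVector lower, NumericVector diag,
                       NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  NumericVector x = clone(rhs);
  std::vector<double> cp(n);
  thomas(n, lower.begin(), diag.begin(), upper.begin(), x.begin(), cp.data());
  return x;
}

// Transformed Laplacian L[f] = f_xx - B f_e - 2 Q f_xe + A f_ee on interior
// nodes (boundary entries returned as zero). x = xi direction (rows), e = eta
// direction (columns). A = Q^2 + a_eta D^2, B = P - 2 Q R.
// [[Rcpp::export]]
NumericMatrix laplacian_cpp(NumericMatrix f, NumericMatrix A, NumericMatrix B,
                            NumericMatrix Qm, double dxi, double deta) {
  int nx = f.nrow(), ny = f.ncol();
  NumericMatrix L(nx, ny);
  double idx2 = 1.0 / (dxi * dxi), ide2 = 1.0 / (deta * deta);
  double ide = 1.0 / (2.0 * deta), imix = 1.0 / (4.0 * dxi * deta);
  for (int j = 1; j < ny - 1; ++j) {
    for (int i = 1; i < nx - 1; ++i) {
      double fxx = (f(i + 1, j) - 2.0 * f(i, j) + f(i - 1, j)) * idx2;
      double fee = (f(i, j + 1) - 2.0 * f(i, j) + f(i, j - 1)) * ide2;
      double fe  = (f(i, j + 1) - f(i, j - 1)) * ide;
      double fxe = (f(i + 1, j + 1) - f(i + 1, j - 1) -
                    f(i - 1, j + 1) + f(i - 1, j - 1)) * imix;
      L(i, j) = fxx - B(i, j) * fe - 2.0 * Qm(i, j) * fxe + A(i, j) * fee;
    }
  }
  return L;
}

// Iterative eta-line relaxation (SLOR) for the stream-function Poisson
// equation L[psi] = -omega. Each axial sweep solves one eta line implicitly
// by the Thomas algorithm with the axial and mixed-derivative couplings
// taken from the latest available values (Gauss-Seidel in xi), then
// over-relaxes by `relax`. Boundary values of psi (inlet column, wall rows)
// are Dirichlet; the outlet column is zero-gradient (copied each sweep).
// [[Rcpp::export]]
List poisson_slor_cpp(NumericMatrix psi_in, NumericMatrix omega,
                      NumericMatrix A, NumericMatrix B, NumericMatrix Qm,
                      double dxi, double deta, double tol, int maxit,
                      double relax) {
  NumericMatrix psi = clone(psi_in);
  const int nx = psi.nrow(), ny = psi.ncol();
  const int m = ny - 2;
  std::vector<double> a(m), b(m), c(m), d(m), cp(m);
  const double idx2 = 1.0 / (dxi * dxi), ide2 = 1.0 / (deta * deta);
  const double ide = 1.0 / (2.0 * deta), imix = 1.0 / (4.0 * dxi * deta);
  double *P = psi.begin();
  const double *O = omega.begin(), *Ap = A.begin(), *Bp = B.begin(),
               *Qp = Qm.begin();
  NumericVector hist(maxit);
  double res = R_PosInf;
  int it = 0;
  bool conv = false;
  for (it = 0; it < maxit; ++it) {
    for (int i = 1; i < nx - 1; ++i) {
      for (int j = 1; j < ny - 1; ++j) {
        const int q = j * nx + i;      // (i, j)
        const double Ah = Ap[q] * ide2;
        const double Bh = Bp[q] * ide;
        const int k = j - 1;
        a[k] = Ah + Bh;
        c[k] = Ah - Bh;
        b[k] = -2.0 * Ah - 2.0 * idx2;
        const double fxe = (P[q + nx + 1] - P[q - nx + 1] -
                            P[q + nx - 1] + P[q - nx - 1]) * imix;
        d[k] = -O[q] - (P[q - 1] + P[q + 1]) * idx2 + 2.0 * Qp[q] * fxe;
      }
      d[0]     -= a[0] * P[i];
      d[m - 1] -= c[m - 1] * P[(ny - 1) * nx + i];
      thomas(m, a.data(), b.data(), c.data(), d.data(), cp.data());
      for (int j = 1; j < ny - 1; ++j) {
        const int q = j * nx + i;
        P[q] += relax * (d[j - 1] - P[q]);
      }
    }
    for (int j = 0; j < ny; ++j) P[j * nx + nx - 1] = P[j * nx + nx - 2];
    // residual of the full equation with current psi
    res = 0.0;
    for (int j = 1; j < ny - 1; ++j) {
      const double *pm = P + (j - 1) * nx, *p0 = P + j * nx,
                   *pp = P + (j + 1) * nx;
      const double *oj = O + j * nx, *aj = Ap + j * nx, *bj = Bp + j * nx,
                   *qj = Qp + j * nx;
      for (int i = 1; i < nx - 1; ++i) {
        const double fxx = (p0[i + 1] - 2.0 * p0[i] + p0[i - 1]) * idx2;
        const double fee = (pp[i] - 2.0 * p0[i] + pm[i]) * ide2;
        const double fe  = (pp[i] - pm[i]) * ide;
        const double fxe = (pp[i + 1] - pm[i + 1] -
                            pp[i - 1] + pm[i - 1]) * imix;
        const double r = fxx - bj[i] * fe - 2.0 * qj[i] * fxe +
                         aj[i] * fee + oj[i];
        const double ar = std::fabs(r);
        if (ar > res) res = ar;
      }
    }
    hist[it] = res;
    if (res < tol) { conv = true; ++it; break; }
  }
  return List::create(_["psi"] = psi, _["iterations"] = it,
                      _["residual"] = res, _["converged"] = conv,
                      _["history"] = hist[Range(0, std::max(it - 1, 0))]);
}

// One ADI time step (Douglas-Gunn approximate factorization of backward
// Euler, delta form) for a transported scalar f obeying
//   St f_t + u f_x + W f_e = nu f_xx - 2 nu Q f_xe + A f_ee + S + lam f
// where W already contains the metric first-order contribution
// (v D - u Q + nu (P - 2 Q R)) and A = nu (Q^2 + a_eta D^2).
// With N(f) the full spatial right-hand side at the old level, the two
// factored sweeps are
//   (St/dt - Axi - lam) df* = N(f^l) + d(boundary forcing)
//   (St/dt - Aeta)      df  = (St/dt) df*
//   f^(l+1) = f^l + df
// Each sweep is one TDMA line solve per grid line: xi-implicit first, then
// eta-implicit; both advection directions are implicit in the increment,
// the mixed derivative is explicit. Dirichlet inlet column f_in and wall
// rows f_low/f_up (values at the new level); zero-gradient outlet.
// With upwind = true the implicit increment operators use first-order
// upwind advection while N(f) keeps the central fluxes (deferred
// correction).
// [[Rcpp::export]]
NumericMatrix adi_advance_cpp(NumericMatrix f0, NumericMatrix u, NumericMatrix W,
                              NumericMatrix A, NumericMatrix Qm, NumericMatrix S,
                              double dxi, double deta, double dt, double St,
                              double nu, double lam,
                              NumericVector f_in, NumericVector f_low,
                              NumericVector f_up, bool upwind) {
  const int nx = f0.nrow(), ny = f0.ncol();
  const double stc = St / dt;
  const double idx2 = 1.0 / (dxi * dxi), ide2 = 1.0 / (deta * deta);
  const double idx = 1.0 / (2.0 * dxi), ide = 1.0 / (2.0 * deta);
  const double imix = 1.0 / (4.0 * dxi * deta);

  const double *F0 = f0.begin(), *U = u.begin(), *Wp = W.begin(),
               *Ap = A.begin(), *Qp = Qm.begin(), *Sp = S.begin();

  // full explicit right-hand side at the old level (interior)
  NumericMatrix Nrhs(nx, ny);
  double *Np = Nrhs.begin();
  for (int j = 1; j < ny - 1; ++j) {
    const double *fm = F0 + (j - 1) * nx, *f = F0 + j * nx,
                 *fp = F0 + (j + 1) * nx;
    const double *uj = U + j * nx, *wj = Wp + j * nx, *aj = Ap + j * nx,
                 *qj = Qp + j * nx, *sj = Sp + j * nx;
    double *nj = Np + j * nx;
    for (int i = 1; i < nx - 1; ++i) {
      const double fxx = (f[i + 1] - 2.0 * f[i] + f[i - 1]) * idx2;
      const double fx  = (f[i + 1] - f[i - 1]) * idx;
      const double fee = (fp[i] - 2.0 * f[i] + fm[i]) * ide2;
      const double fe  = (fp[i] - fm[i]) * ide;
      const double fxe = (fp[i + 1] - fm[i + 1] - fp[i - 1] + fm[i - 1]) * imix;
      nj[i] = -uj[i] * fx - wj[i] * fe + nu * fxx + aj[i] * fee -
              2.0 * nu * qj[i] * fxe + sj[i] + lam * f[i];
    }
  }

  // ---- sweep 1: xi-implicit increment df* ----
  NumericMatrix dfs(nx, ny);  // zero-initialized: homogeneous walls for now
  double *DS = dfs.begin();
  {
    const int m = nx - 2;
    std::vector<double> a(m), b(m), c(m), d(m), cp(m);
    for (int j = 1; j < ny - 1; ++j) {
      const double *uj = U + j * nx;
      const double *nj = Np + j * nx;
      const double din = f_in[j] - F0[j * nx];  // inlet increment (Dirichlet)
      for (int i = 1; i < nx - 1; ++i) {
        const int k = i - 1;
        const double uu = uj[i];
        if (upwind) {
          const double up = std::max(uu, 0.0), um = std::min(uu, 0.0);
          a[k] = -nu * idx2 - up / dxi;
          c[k] = -nu * idx2 + um / dxi;
          b[k] = stc + 2.0 * nu * idx2 + std::fabs(uu) / dxi - lam;
        } else {
          a[k] = -nu * idx2 - uu * idx;
          c[k] = -nu * idx2 + uu * idx;
          b[k] = stc + 2.0 * nu * idx2 - lam;
        }
        d[k] = nj[i];
      }
      d[0] -= a[0] * din;
      b[m - 1] += c[m - 1];  // zero-gradient outlet folded into diagonal
      thomas(m, a.data(), b.data(), c.data(), d.data(), cp.data());
      double *dj = DS + j * nx;
      for (int i = 1; i < nx - 1; ++i) dj[i] = d[i - 1];
    }
  }

  // ---- sweep 2: eta-implicit increment df ----
  NumericMatrix f1(nx, ny);
  double *F1 = f1.begin();
  {
    const int m = ny - 2;
    std::vector<double> a(m), b(m), c(m), d(m), cp(m);
    for (int i = 1; i < nx - 1; ++i) {
      const double dlow = f_low[i] - F0[i];
      const double dup = f_up[i] - F0[(ny - 1) * nx + i];
      for (int j = 1; j < ny - 1; ++j) {
        const int k = j - 1;
        const int q = j * nx + i;
        const double ww = Wp[q];
        const double Ah = Ap[q] * ide2;
        if (upwind) {
          const double wp = std::max(ww, 0.0), wm = std::min(ww, 0.0);
          a[k] = -Ah - wp / deta;
          c[k] = -Ah + wm / deta;
          b[k] = stc + 2.0 * Ah + std::fabs(ww) / deta;
        } else {
          a[k] = -Ah - ww * ide;
          c[k] = -Ah + ww * ide;
          b[k] = stc + 2.0 * Ah;
        }
        d[k] = stc * DS[q];
      }
      d[0]     -= a[0] * dlow;
      d[m - 1] -= c[m - 1] * dup;
      thomas(m, a.data(), b.data(), c.data(), d.data(), cp.data());
      for (int j = 1; j < ny - 1; ++j) {
        const int q = j * nx + i;
        F1[q] = F0[q] + d[j - 1];
      }
    }
    for (int i = 0; i < nx; ++i) {
      f1(i, 0) = f_low[i];
      f1(i, ny - 1) = f_up[i];
    }
    for (int j = 0; j < ny; ++j) f1(0, j) = f_in[j];
    for (int j = 0; j < ny; ++j) f1(nx - 1, j) = f1(nx - 2, j);
  }
  return f1;
}

// Second-order first derivative along eta (columns): central interior,
// one-sided three-point at the walls.
// [[Rcpp::export]]
NumericMatrix deriv_eta_cpp(NumericMatrix f, double deta) {
  int nx = f.nrow(), ny = f.ncol();
  NumericMatrix g(nx, ny);
  double ide = 1.0 / (2.0 * deta);
  for (int i = 0; i < nx; ++i) {
    g(i, 0) = (-3.0 * f(i, 0) + 4.0 * f(i, 1) - f(i, 2)) * ide;
    for (int j = 1; j < ny - 1; ++j)
      g(i, j) = (f(i, j + 1) - f(i, j - 1)) * ide;
    g(i, ny - 1) = (3.0 * f(i, ny - 1) - 4.0 * f(i, ny - 2) + f(i, ny - 3)) * ide;
  }
  return g;
}

// Second-order first derivative along xi (rows).
// [[Rcpp::export]]
NumericMatrix deriv_xi_cpp(NumericMatrix f, double dxi) {
  int nx = f.nrow(), ny = f.ncol();
  NumericMatrix g(nx, ny);
  double idx = 1.0 / (2.0 * dxi);
  for (int j = 0; j < ny; ++j) {
    g(0, j) = (-3.0 * f(0, j) + 4.0 * f(1, j) - f(2, j)) * idx;
    for (int i = 1; i < nx - 1; ++i)
      g(i, j) = (f(i + 1, j) - f(i - 1, j)) * idx;
    g(nx - 1, j) = (3.0 * f(nx - 1, j) - 4.0 * f(nx - 2, j) + f(nx - 3, j)) * idx;
  }
  return g;
}

// Second derivative along eta, central interior; wall values use the
// one-sided second-order formula assuming f_eta = 0 at the wall (no-slip),
// as required by the wall-vorticity closure.
// [[Rcpp::export]]
NumericMatrix second_deriv_eta_cpp(NumericMatrix f, double deta) {
  int nx = f.nrow(), ny = f.ncol();
  NumericMatrix g(nx, ny);
  double ide2 = 1.0 / (deta * deta);
  for (int i = 0; i < nx; ++i) {
    g(i, 0) = (8.0 * f(i, 1) - f(i, 2) - 7.0 * f(i, 0)) * 0.5 * ide2;
    for (int j = 1; j < ny - 1; ++j)
      g(i, j) = (f(i, j + 1) - 2.0 * f(i, j) + f(i, j - 1)) * ide2;
    g(i, ny - 1) = (8.0 * f(i, ny - 2) - f(i, ny - 3) - 7.0 * f(i, ny - 1)) * 0.5 * ide2;
  }
  return g;
}
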