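#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 4-point degree-2 Gauss rule per tetrahedron (barycentric permutations of
// (a,b,b,b), a = 0.58541020, b = 0.13819660), weight V/4 each.
// [[Rcpp::export]]
List cpp_tet_ips(NumericMatrix nodes, IntegerMatrix tets) {
  const double a = 0.5854101966249685, b = 0.1381966011250105;
  const int T = tets.nrow();
  NumericMatrix pos(4 * T, 3);
  NumericVector w(4 * T);
  IntegerVector elem(4 * T);
  for (int t = 0; t < T; ++t) {
    double X[4][3];
    for (int v = 0; v < 4; ++v)
      for (int d = 0; d < 3; ++d) X[v][d] = nodes(tets(t, v) - 1, d);
    double e1[3], e2[3], e3[3];
    for (int d = 0; d < 3; ++d) {
      e1[d] = X[1][d] - X[0][d];
      e2[d] = X[2][d] - X[0][d];
      e3[d] = X[3][d] - X[0][d];
    }
    double det = e1[0] * (e2[1] * e3[2] - e2[2] * e3[1]) -
                 e1[1] * (e2[0] * e3[2] - e2[2] * e3[0]) +
                 e1[2] * (e2[0] * e3[1] - e2[1] * e3[0]);
    double V = det / 6.0;
    if (V <= 0)
      stop("tetrahedron %d has non-positive volume (%g); fix orientation", t + 1, V);
    double bc[4];
    for (int g = 0; g < 4; ++g) {
      for (int v = 0; v < 4; ++v) bc[v] = b;
      bc[g] = a;
      for (int d = 0; d < 3; ++d) {
        double x = 0;
        for (int v = 0; v < 4; ++v) x += bc[v] * X[v][d];
        pos(4 * t + g, d) = x;
      }
      w[4 * t + g] = V / 4.0;
      elem[4 * t + g] = t + 1;
    }
  }
  return List::create(_["points"] = pos, _["weights"] = w, _["element"] = elem);
}

// neo-Hookean (decoupled, compressible) first Piola-Kirchhoff stress and
// stored energy density from the deformation gradient (column-major 3x3).
static double neo_hookean(const double F[9], double mu, double kappa,
                          double P[9]) {
  double C[9];  // C = F^T F (column-major, symmetric)
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[3 * i + k] * F[3 * j + k];
      C[3 * j + i] = s;
    }
  double J = F[0] * (F[4] * F[8] - F[7] * F[5]) -
             F[3] * (F[1] * F[8] - F[7] * F[2]) +
             F[6] * (F[1] * F[5] - F[4] * F[2]);
  if (!(J > 0)) return R_NegInf;
  double trC = C[0] + C[4] + C[8];
  // inverse of C
  double Ci[9];
  double dC = C[0] * (C[4] * C[8] - C[7] * C[5]) -
              C[3] * (C[1] * C[8] - C[7] * C[2]) +
              C[6] * (C[1] * C[5] - C[4] * C[2]);
  Ci[0] = (C[4] * C[8] - C[7] * C[5]) / dC;
  Ci[3] = -(C[3] * C[8] - C[6] * C[5]) / dC;
  Ci[6] = (C[3] * C[7] - C[6] * C[4]) / dC;
  Ci[1] = Ci[3];  // symmetric
  Ci[4] = (C[0] * C[8] - C[6] * C[2]) / dC;
  Ci[7] = -(C[0] * C[7] - C[6] * C[1]) / dC;
  Ci[2] = Ci[6];
  Ci[5] = Ci[7];
  Ci[8] = (C[0] * C[4] - C[3] * C[1]) / dC;
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double S[9];
  for (int k = 0; k < 9; ++k)
    S[k] = mu * Jm23 * (-(trC / 3.0) * Ci[k]) + kappa * J * (J - 1.0) * Ci[k];
  S[0] += mu * Jm23;
  S[4] += mu * Jm23;
  S[8] += mu * Jm23;
  // P = F S
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[3 * k + i] * S[3 * j + k];
      P[3 * j + i] = s;
    }
  double W = 0.5 * mu * (Jm23 * trC - 3.0) + 0.5 * kappa * (J - 1.0) * (J - 1.0);
  return W;
}

// [[Rcpp::export]]
List cpp_pk2_stress(NumericVector Fv, double E, double nu) {
  double mu = E / (2.0 * (1.0 + nu)), kappa = E / (3.0 * (1.0 - 2.0 * nu));
  double F[9], P[9];
  for (int k = 0; k < 9; ++k) F[k] = Fv[k];
  double W = neo_hookean(F, mu, kappa, P);
  if (!R_FINITE(W)) stop("deformation gradient has non-positive determinant");
  // recover S = F^{-1} P
  double Fi[9];
  double dF = F[0] * (F[4] * F[8] - F[7] * F[5]) -
              F[3] * (F[1] * F[8] - F[7] * F[2]) +
              F[6] * (F[1] * F[5] - F[4] * F[2]);
  Fi[0] = (F[4] * F[8] - F[7] * F[5]) / dF;
  Fi[3] = -(F[3] * F[8] - F[6] * F[5]) / dF;
  Fi[6] = (F[3] * F[7] - F[6] * F[4]) / dF;
  Fi[1] = -(F[1] * F[8] - F[7] * F[2]) / dF;
  Fi[4] = (F[0] * F[8] - F[6] * F[2]) / dF;
  Fi[7] = -(F[0] * F[7] - F[6] * F[1]) / dF;
  Fi[2] = (F[1] * F[5] - F[4] * F[2]) / dF;
  Fi[5] = -(F[0] * F[5] - F[3] * F[2]) / dF;
  Fi[8] = (F[0] * F[4] - F[3] * F[1]) / dF;
  NumericMatrix S(3, 3), Pm(3, 3);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += Fi[3 * k + i] * P[3 * j + k];
      S(i, j) = s;
      Pm(i, j) = P[3 * j + i];
    }
  return List::create(_["S"] = S, _["P"] = Pm, _["energy_density"] = W);
}

// Total-Lagrangian internal nodal forces, strain energy and deformation
// gradients for a meshless model described by CSR shape data at integration
// points.
// dphi: trial gradients (deformation); dphi_t: test gradients (assembly).
// They coincide for the plain Bubnov-Galerkin operator; the solver passes
// variationally corrected test gradients to restore integration consistency.
static double forces_core(const IntegerVector &off, const IntegerVector &ids,
                          const NumericMatrix &dphi, const NumericMatrix &dphi_t,
                          const NumericVector &w,
                          const NumericVector &mu, const NumericVector &kappa,
                          const std::vector<double> &U, int N,
                          std::vector<double> &f, double *minJ,
                          std::vector<double> *Fout) {
  const int nip = off.size() - 1;
  std::fill(f.begin(), f.end(), 0.0);
  double Wtot = 0.0;
  double mj = R_PosInf;
  for (int ip = 0; ip < nip; ++ip) {
    double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    for (int t = off[ip]; t < off[ip + 1]; ++t) {
      int a = ids[t] - 1;
      double g0 = dphi(t, 0), g1 = dphi(t, 1), g2 = dphi(t, 2);
      double u0 = U[a], u1 = U[N + a], u2 = U[2 * N + a];
      F[0] += u0 * g0; F[3] += u0 * g1; F[6] += u0 * g2;
      F[1] += u1 * g0; F[4] += u1 * g1; F[7] += u1 * g2;
      F[2] += u2 * g0; F[5] += u2 * g1; F[8] += u2 * g2;
    }
    double P[9];
    double Wd = neo_hookean(F, mu[ip], kappa[ip], P);
    if (!R_FINITE(Wd)) return R_NegInf;
    double J = F[0] * (F[4] * F[8] - F[7] * F[5]) -
               F[3] * (F[1] * F[8] - F[7] * F[2]) +
               F[6] * (F[1] * F[5] - F[4] * F[2]);
    mj = std::min(mj, J);
    Wtot += w[ip] * Wd;
    for (int t = off[ip]; t < off[ip + 1]; ++t) {
      int a = ids[t] - 1;
      double g0 = dphi_t(t, 0), g1 = dphi_t(t, 1), g2 = dphi_t(t, 2);
      f[a]         += w[ip] * (P[0] * g0 + P[3] * g1 + P[6] * g2);
      f[N + a]     += w[ip] * (P[1] * g0 + P[4] * g1 + P[7] * g2);
      f[2 * N + a] += w[ip] * (P[2] * g0 + P[5] * g1 + P[8] * g2);
    }
    if (Fout) for (int k = 0; k < 9; ++k) (*Fout)[(size_t)9 * ip + k] = F[k];
  }
  if (minJ) *minJ = mj;
  return Wtot;
}

// [[Rcpp::export]]
List cpp_internal_forces(IntegerVector off, IntegerVector ids,
                         NumericMatrix dphi, NumericMatrix dphi_t,
                         NumericVector w,
                         NumericVector mu, NumericVector kappa,
                         NumericMatrix Umat, bool want_F = false) {
  const int N = Umat.nrow();
  std::vector<double> U((size_t)3 * N), f((size_t)3 * N);
  for (int a = 0; a < N; ++a)
    for (int d = 0; d < 3; ++d) U[(size_t)d * N + a] = Umat(a, d);
  double minJ;
  const int nip = off.size() - 1;
  std::vector<double> Fg;
  if (want_F) Fg.resize((size_t)9 * nip);
  double W = forces_core(off, ids, dphi, dphi_t, w, mu, kappa, U, N, f, &minJ,
                         want_F ? &Fg : nullptr);
  if (W == R_NegInf)
    stop("non-positive Jacobian encountered while evaluating internal forces");
  NumericMatrix fm(N, 3);
  for (int a = 0; a < N; ++a)
    for (int d = 0; d < 3; ++d) fm(a, d) = f[(size_t)d * N + a];
  List out = List::create(_["forces"] = fm, _["energy"] = W, _["min_J"] = minJ);
  if (want_F) {
    NumericMatrix Fm(9, nip);
    for (int ip = 0; ip < nip; ++ip)
      for (int k = 0; k < 9; ++k) Fm(k, ip) = Fg[(size_t)9 * ip + k];
    out["F"] = Fm;
  }
  return out;
}

// Explicit central-difference iteration with adaptive dynamic relaxation
// (mass-proportional damping estimated from a Rayleigh quotient of successive
// force/displacement increments). Masses are scaled so the unit pseudo-time
// step is stable. Prescribed nodes track a smooth 3-4-5 polynomial ramp of
// the target displacement.
// [[Rcpp::export]]
List cpp_adr_solve(IntegerVector off, IntegerVector ids, NumericMatrix dphi,
                   NumericMatrix dphi_t, NumericVector w, NumericVector mu, NumericVector kappa,
                   int N, LogicalVector fixed, NumericMatrix target,
                   int ramp_steps, int max_steps, double tol, int patience,
                   double mass_scale, double damp_max_frac) {
  const double dt = 1.0;
  // diagonal stiffness estimate -> scaled nodal mass
  std::vector<double> mass(N, 0.0);
  const int nip = off.size() - 1;
  for (int ip = 0; ip < nip; ++ip) {
    double cmod = kappa[ip] + 2.0 * mu[ip];
    for (int t = off[ip]; t < off[ip + 1]; ++t) {
      int a = ids[t] - 1;
      double g2 = dphi(t, 0) * dphi(t, 0) + dphi(t, 1) * dphi(t, 1) +
                  dphi(t, 2) * dphi(t, 2);
      double h2 = dphi_t(t, 0) * dphi_t(t, 0) + dphi_t(t, 1) * dphi_t(t, 1) +
                  dphi_t(t, 2) * dphi_t(t, 2);
      mass[a] += w[ip] * cmod * std::max(g2, h2);
    }
  }
  double mmax = 0;
  for (int a = 0; a < N; ++a) mmax = std::max(mmax, mass[a]);
  for (int a = 0; a < N; ++a)
    mass[a] = mass_scale * dt * dt * std::max(mass[a], 1e-8 * mmax);

  std::vector<double> U((size_t)3 * N, 0.0), V((size_t)3 * N, 0.0),
      f((size_t)3 * N, 0.0), fprev((size_t)3 * N, 0.0),
      dU((size_t)3 * N, 0.0);
  NumericVector energy(max_steps), incr(max_steps);
  double c = 0.0;
  const double cmax = damp_max_frac * 2.0 / dt;
  int consec = 0, nsteps = 0;
  bool converged = false;
  double W = 0, minJ = 1;

  for (int step = 1; step <= max_steps; ++step) {
    double tau = ramp_steps > 0 ? std::min(1.0, (double)step / ramp_steps) : 1.0;
    double xi = tau * tau * tau * (10.0 + tau * (-15.0 + 6.0 * tau));
    std::copy(f.begin(), f.end(), fprev.begin());
    W = forces_core(off, ids, dphi, dphi_t, w, mu, kappa, U, N, f, &minJ, nullptr);
    if (W == R_NegInf || !R_FINITE(W))
      stop("MTLED diverged at step %d (non-positive Jacobian); reduce the load "
           "increment or increase damping/mass scaling", step);
    // adapt damping from a Rayleigh quotient of the force change over the
    // last displacement increment (Underwood-style local stiffness estimate)
    if (step > 2) {
      double num = 0, den = 0;
      for (int a = 0; a < N; ++a) {
        if (fixed[a]) continue;
        for (int d = 0; d < 3; ++d) {
          size_t i = (size_t)d * N + a;
          num += (f[i] - fprev[i]) * dU[i];
          den += mass[a] * dU[i] * dU[i];
        }
      }
      if (den > 0 && num > 0) {
        double lam = num / den;
        c = std::min(2.0 * std::sqrt(lam), cmax);
      }
    }
    double kin = 0, mx = 0;
    for (int a = 0; a < N; ++a) {
      if (fixed[a]) {
        for (int d = 0; d < 3; ++d) {
          size_t i = (size_t)d * N + a;
          double unew = xi * target(a, d);
          dU[i] = unew - U[i];
          V[i] = dU[i] / dt;
          U[i] = unew;
        }
        continue;
      }
      for (int d = 0; d < 3; ++d) {
        size_t i = (size_t)d * N + a;
        double acc = -f[i] / mass[a];
        V[i] = ((1.0 - c * dt / 2.0) * V[i] + dt * acc) / (1.0 + c * dt / 2.0);
        double du = dt * V[i];
        dU[i] = du;
        U[i] += du;
        kin += 0.5 * mass[a] * V[i] * V[i];
        mx = std::max(mx, std::abs(du));
      }
    }
    energy[step - 1] = W + kin;
    incr[step - 1] = mx;
    nsteps = step;
    if (step > ramp_steps) {
      if (mx < tol) ++consec; else consec = 0;
      if (consec >= patience) { converged = true; break; }
    }
  }

  // final force evaluation at the converged configuration
  W = forces_core(off, ids, dphi, dphi_t, w, mu, kappa, U, N, f, &minJ, nullptr);
  NumericMatrix Um(N, 3), fm(N, 3);
  for (int a = 0; a < N; ++a)
    for (int d = 0; d < 3; ++d) {
      Um(a, d) = U[(size_t)d * N + a];
      fm(a, d) = f[(size_t)d * N + a];
    }
  return List::create(_["U"] = Um, _["forces"] = fm, _["energy"] = energy[Range(0, nsteps - 1)],
                      _["max_increment"] = incr[Range(0, nsteps - 1)],
                      _["steps"] = nsteps, _["converged"] = converged,
                      _["strain_energy"] = W, _["min_J"] = minJ,
                      _["damping"] = c);
}
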