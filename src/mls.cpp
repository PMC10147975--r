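#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- small dense helpers (4x4 SPD) -------------------------------------

static bool chol4(const double A[4][4], double L[4][4]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) L[i][j] = 0.0;
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i][i] = std::sqrt(s);
      } else {
        L[i][j] = s / L[j][j];
      }
    }
  }
  return true;
}

static void chol4_solve(const double L[4][4], const double b[4], double x[4]) {
  double y[4];
  for (int i = 0; i < 4; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i][k] * y[k];
    y[i] = s / L[i][i];
  }
  for (int i = 3; i >= 0; --i) {
    double s = y[i];
    for (int k = i + 1; k < 4; ++k) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
}

struct NodeBins {
  double x0[3], cell;
  int nb[3];
  std::vector<std::vector<int>> bins;
  void build(const NumericMatrix &nodes, double cell_size) {
    cell = cell_size;
    double hi[3];
    for (int d = 0; d < 3; ++d) { x0[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int a = 0; a < nodes.nrow(); ++a)
      for (int d = 0; d < 3; ++d) {
        x0[d] = std::min(x0[d], nodes(a, d));
        hi[d] = std::max(hi[d], nodes(a, d));
      }
    for (int d = 0; d < 3; ++d)
      nb[d] = std::max(1, (int)std::floor((hi[d] - x0[d]) / cell) + 1);
    bins.assign((size_t)nb[0] * nb[1] * nb[2], {});
    for (int a = 0; a < nodes.nrow(); ++a) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        c[d] = (int)std::floor((nodes(a, d) - x0[d]) / cell);
        c[d] = std::max(0, std::min(nb[d] - 1, c[d]));
      }
      bins[((size_t)c[2] * nb[1] + c[1]) * nb[0] + c[0]].push_back(a);
    }
  }
  template <class F>
  void near(const double *p, double radius, F fn) const {
    int lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::max(0, (int)std::floor((p[d] - radius - x0[d]) / cell));
      hi[d] = std::min(nb[d] - 1, (int)std::floor((p[d] + radius - x0[d]) / cell));
    }
    for (int k = lo[2]; k <= hi[2]; ++k)
      for (int j = lo[1]; j <= hi[1]; ++j)
        for (int i = lo[0]; i <= hi[0]; ++i)
          for (int a : bins[((size_t)k * nb[1] + j) * nb[0] + i]) fn(a);
  }
};

// Moving least squares shape functions with linear basis p = (1,x,y,z) and a
// quartic spline weight w(q) = 1 - 6q^2 + 8q^3 - 3q^4 on q = |x - x_a|/r_a.
// Nodes flagged `singular` use the near-singular weight w(q)/(q^2 + eps^2),
// which makes the approximation (almost) interpolating there, so prescribed
// nodal values are imposed directly. The basis is shifted and scaled at each
// evaluation point for conditioning; gradients are analytic.
//
// Returns CSR-style arrays: offsets (0-based, length M+1), node ids
// (1-based), shape values phi, and gradients dphi (len x 3, 1/mm).
// [[Rcpp::export]]
List cpp_mls_shape(NumericMatrix nodes, NumericVector radii,
                   LogicalVector singular, NumericMatrix pts,
                   double sing_eps = 1e-4) {
  const int N = nodes.nrow(), M = pts.nrow();
  double rmax = 0.0, rmean = 0.0;
  for (int a = 0; a < N; ++a) { rmax = std::max(rmax, radii[a]); rmean += radii[a]; }
  rmean /= std::max(1, N);
  NodeBins bins;
  bins.build(nodes, std::max(rmax, 1e-12));

  std::vector<int> offsets(M + 1, 0), ids;
  std::vector<double> phi, dphi;
  ids.reserve((size_t)M * 16);
  phi.reserve((size_t)M * 16);
  dphi.reserve((size_t)M * 48);

  std::vector<int> supp;
  const double eps2 = sing_eps * sing_eps;

  for (int p = 0; p < M; ++p) {
    double X[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    supp.clear();
    bins.near(X, rmax, [&](int a) {
      double dx = nodes(a, 0) - X[0], dy = nodes(a, 1) - X[1], dz = nodes(a, 2) - X[2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < radii[a] * radii[a]) supp.push_back(a);
    });
    int ns = supp.size();
    if (ns < 4)
      stop("MLS support has only %d nodes at point %d; increase the support radius",
           ns, p + 1);
    const double s = rmean;  // basis length scale

    // weights, weight gradients, shifted basis per support node
    std::vector<double> W(ns), dW(3 * ns), P(4 * ns);
    for (int t = 0; t < ns; ++t) {
      int a = supp[t];
      double dx = nodes(a, 0) - X[0], dy = nodes(a, 1) - X[1], dz = nodes(a, 2) - X[2];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double r = radii[a], q = d / r;
      double w = 1.0 + q * q * (-6.0 + q * (8.0 - 3.0 * q));
      double dwdq = q * (-12.0 + q * (24.0 - 12.0 * q));
      if (singular[a]) {
        double den = q * q + eps2;
        double ws = w / den;
        double dws = (dwdq * den - 2.0 * q * w) / (den * den);
        w = ws; dwdq = dws;
      }
      // d q / d x_i = -(x_a - x)_i / (d * r); gradient of w wrt eval point x
      double gfac = (d > 1e-14) ? dwdq / (d * r) : 0.0;
      W[t] = w;
      dW[3 * t + 0] = -gfac * dx;
      dW[3 * t + 1] = -gfac * dy;
      dW[3 * t + 2] = -gfac * dz;
      P[4 * t + 0] = 1.0;
      P[4 * t + 1] = dx / s;
      P[4 * t + 2] = dy / s;
      P[4 * t + 3] = dz / s;
    }

    double A[4][4] = {{0}};
    for (int t = 0; t < ns; ++t)
      for (int i = 0; i < 4; ++i)
        for (int j = i; j < 4; ++j)
          A[i][j] += W[t] * P[4 * t + i] * P[4 * t + j];
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < i; ++j) A[i][j] = A[j][i];

    double L[4][4];
    if (!chol4(A, L))
      stop("MLS moment matrix is singular at point %d (co-planar support?)", p + 1);

    double e1[4] = {1, 0, 0, 0}, gam[4];
    chol4_solve(L, e1, gam);

    // dA/dx_i and dgamma_i = -A^{-1} dA_i gamma
    double dgam[3][4];
    for (int i = 0; i < 3; ++i) {
      double dA[4][4] = {{0}};
      for (int t = 0; t < ns; ++t) {
        double dPi[4] = {0, 0, 0, 0};
        dPi[i + 1] = -1.0 / s;  // d/dx_i of (x_a - x)/s
        double wi = dW[3 * t + i];
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b)
            dA[a][b] += wi * P[4 * t + a] * P[4 * t + b] +
                        W[t] * (dPi[a] * P[4 * t + b] + P[4 * t + a] * dPi[b]);
      }
      double rhs[4] = {0, 0, 0, 0};
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) rhs[a] += dA[a][b] * gam[b];
      double sol[4];
      chol4_solve(L, rhs, sol);
      for (int a = 0; a < 4; ++a) dgam[i][a] = -sol[a];
    }

    for (int t = 0; t < ns; ++t) {
      double wp[4];
      for (int a = 0; a < 4; ++a) wp[a] = W[t] * P[4 * t + a];
      double ph = 0.0;
      for (int a = 0; a < 4; ++a) ph += gam[a] * wp[a];
      ids.push_back(supp[t] + 1);
      phi.push_back(ph);
      for (int i = 0; i < 3; ++i) {
        double dPi[4] = {0, 0, 0, 0};
        dPi[i + 1] = -1.0 / s;
        double g = 0.0;
        for (int a = 0; a < 4; ++a) {
          g += dgam[i][a] * wp[a];
          g += gam[a] * (dW[3 * t + i] * P[4 * t + a] + W[t] * dPi[a]);
        }
        dphi.push_back(g);
      }
    }
    offsets[p + 1] = ids.size();
  }

  int len = ids.size();
  IntegerVector off(offsets.begin(), offsets.end());
  IntegerVector id(ids.begin(), ids.end());
  NumericVector ph(phi.begin(), phi.end());
  NumericMatrix dp(len, 3);
  for (int t = 0; t < len; ++t)
    for (int i = 0; i < 3; ++i) dp(t, i) = dphi[3 * t + i];
  return List::create(_["offsets"] = off, _["ids"] = id,
                      _["phi"] = ph, _["dphi"] = dp);
}
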