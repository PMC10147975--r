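#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a 3D boolean mask with 6/18/26
// connectivity. Components are numbered 1..K in order of their first voxel
// in raster (column-major) scan order, which makes the labelling
// deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ad == 0) continue;
        if (connectivity == 6 && ad > 1) continue;
        if (connectivity == 18 && ad > 2) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++next;
    labels[s] = next;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front(); q.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (auto &d : nb) {
        int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        size_t t = ((size_t)kk * ny + jj) * nx + ii;
        if (mask[t] && !labels[t]) { labels[t] = next; q.push(t); }
      }
    }
  }
  return labels;
}

// Dilate a mask by a fixed set of integer voxel offsets (precomputed from a
// metric ball in world mm).
// [[Rcpp::export]]
LogicalVector cpp_dilate_offsets(LogicalVector mask, IntegerVector dims,
                                 IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int m = offsets.nrow();
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int i = s % nx, j = (s / nx) % ny, k = s / ((size_t)nx * ny);
    for (int o = 0; o < m; ++o) {
      int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      out[((size_t)kk * ny + jj) * nx + ii] = true;
    }
  }
  return out;
}

// Eigen-decomposition of many symmetric 3x3 matrices (packed
// xx,xy,xz,yy,yz,zz) by cyclic Jacobi rotations. Returns eigenvalues in
// descending order and the matching eigenvectors (columns).
// [[Rcpp::export]]
List cpp_sym3_eig(NumericMatrix t6) {
  const int n = t6.ncol();
  NumericMatrix evals(3, n), evecs(9, n);
  for (int c = 0; c < n; ++c) {
    double a[3][3] = {{t6(0, c), t6(1, c), t6(2, c)},
                      {t6(1, c), t6(3, c), t6(4, c)},
                      {t6(2, c), t6(4, c), t6(5, c)}};
    double v[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    for (int sweep = 0; sweep < 50; ++sweep) {
      double off = std::abs(a[0][1]) + std::abs(a[0][2]) + std::abs(a[1][2]);
      if (off < 1e-15 * (std::abs(a[0][0]) + std::abs(a[1][1]) + std::abs(a[2][2]) + 1e-300))
        break;
      for (int p = 0; p < 2; ++p)
        for (int q = p + 1; q < 3; ++q) {
          if (std::abs(a[p][q]) < 1e-300) continue;
          double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
          double t = (theta >= 0 ? 1.0 : -1.0) /
                     (std::abs(theta) + std::sqrt(theta * theta + 1.0));
          double cth = 1.0 / std::sqrt(t * t + 1.0), s = t * cth;
          for (int k = 0; k < 3; ++k) {
            double akp = a[k][p], akq = a[k][q];
            a[k][p] = cth * akp - s * akq;
            a[k][q] = s * akp + cth * akq;
          }
          for (int k = 0; k < 3; ++k) {
            double apk = a[p][k], aqk = a[q][k];
            a[p][k] = cth * apk - s * aqk;
            a[q][k] = s * apk + cth * aqk;
          }
          for (int k = 0; k < 3; ++k) {
            double vkp = v[k][p], vkq = v[k][q];
            v[k][p] = cth * vkp - s * vkq;
            v[k][q] = s * vkp + cth * vkq;
          }
        }
    }
    int ord[3] = {0, 1, 2};
    double d[3] = {a[0][0], a[1][1], a[2][2]};
    for (int i = 0; i < 2; ++i)
      for (int j = i + 1; j < 3; ++j)
        if (d[ord[j]] > d[ord[i]]) std::swap(ord[i], ord[j]);
    for (int i = 0; i < 3; ++i) {
      evals(i, c) = d[ord[i]];
      for (int k = 0; k < 3; ++k) evecs(3 * i + k, c) = v[k][ord[i]];
    }
  }
  return List::create(_["values"] = evals, _["vectors"] = evecs);
}

// Preservation-of-principal-direction tensor reorientation. t6 holds packed
// tensors, F the local forward-map Jacobians (column-major 3x3 per column).
// Eigenvalues are preserved exactly; the eigenframe is rotated so that e1 ->
// F e1 / |F e1| and e2 -> Gram-Schmidt projection of F e2.
// [[Rcpp::export]]
NumericMatrix cpp_ppd(NumericMatrix t6, NumericMatrix F) {
  List eig = cpp_sym3_eig(t6);
  NumericMatrix evals = eig["values"], evecs = eig["vectors"];
  const int n = t6.ncol();
  NumericMatrix out(6, n);
  for (int c = 0; c < n; ++c) {
    double l1 = evals(0, c), l2 = evals(1, c), l3 = evals(2, c);
    double e1[3], e2[3];
    for (int k = 0; k < 3; ++k) { e1[k] = evecs(k, c); e2[k] = evecs(3 + k, c); }
    double Fm[9];
    for (int k = 0; k < 9; ++k) Fm[k] = F(k, c);
    auto mul = [&](const double *x, double *y) {
      for (int i = 0; i < 3; ++i)
        y[i] = Fm[i] * x[0] + Fm[3 + i] * x[1] + Fm[6 + i] * x[2];
    };
    double n1[3], f2[3];
    mul(e1, n1); mul(e2, f2);
    double nn = std::sqrt(n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2]);
    bool iso = std::abs(l1 - l3) <= 1e-14 * std::max(std::abs(l1), 1e-300);
    if (nn < 1e-14 || iso) {
      // isotropic tensor or degenerate Jacobian: identity reorientation
      for (int k = 0; k < 3; ++k) { n1[k] = e1[k]; f2[k] = e2[k]; }
      nn = 1.0;
    }
    for (int k = 0; k < 3; ++k) n1[k] /= nn;
    double dot = n1[0] * f2[0] + n1[1] * f2[1] + n1[2] * f2[2];
    double p2[3];
    for (int k = 0; k < 3; ++k) p2[k] = f2[k] - dot * n1[k];
    double pn = std::sqrt(p2[0] * p2[0] + p2[1] * p2[1] + p2[2] * p2[2]);
    if (pn < 1e-14) {
      // fall back to any vector orthogonal to n1
      double ax[3] = {1, 0, 0};
      if (std::abs(n1[0]) > 0.9) { ax[0] = 0; ax[1] = 1; }
      p2[0] = n1[1] * ax[2] - n1[2] * ax[1];
      p2[1] = n1[2] * ax[0] - n1[0] * ax[2];
      p2[2] = n1[0] * ax[1] - n1[1] * ax[0];
      pn = std::sqrt(p2[0] * p2[0] + p2[1] * p2[1] + p2[2] * p2[2]);
    }
    for (int k = 0; k < 3; ++k) p2[k] /= pn;
    double n3[3] = {n1[1] * p2[2] - n1[2] * p2[1],
                    n1[2] * p2[0] - n1[0] * p2[2],
                    n1[0] * p2[1] - n1[1] * p2[0]};
    double D[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        D[i][j] = l1 * n1[i] * n1[j] + l2 * p2[i] * p2[j] + l3 * n3[i] * n3[j];
    out(0, c) = D[0][0]; out(1, c) = D[0][1]; out(2, c) = D[0][2];
    out(3, c) = D[1][1]; out(4, c) = D[1][2]; out(5, c) = D[2][2];
  }
  return out;
}
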