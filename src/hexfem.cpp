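#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int HEXOFF[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                                 {0,0,1},{1,0,1},{1,1,1},{0,1,1}};

// One trilinear hexahedron per masked voxel, vertices at voxel corners.
// Shared corners are merged; node ids follow corner-lattice raster order so
// the mesh is reproducible. Returns 0-based corner lattice indices per node
// and 1-based element connectivity (VTK hexahedron ordering).
// [[Rcpp::export]]
List cpp_hexmesh_from_mask(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int lx = nx + 1, ly = ny + 1, lz = nz + 1;
  std::vector<int> node_map((size_t)lx * ly * lz, 0);
  size_t nvox = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t v = ((size_t)k * ny + j) * nx + i;
        if (!mask[v]) continue;
        ++nvox;
        for (int c = 0; c < 8; ++c) {
          size_t l = ((size_t)(k + HEXOFF[c][2]) * ly + (j + HEXOFF[c][1])) * lx +
                     (i + HEXOFF[c][0]);
          node_map[l] = 1;
        }
      }
  if (nvox == 0) stop("empty mask: no hexahedral elements to create");
  int nn = 0;
  for (size_t l = 0; l < node_map.size(); ++l)
    if (node_map[l]) node_map[l] = ++nn;
  IntegerMatrix nodes(nn, 3);
  {
    int id = 0;
    for (int k = 0; k < lz; ++k)
      for (int j = 0; j < ly; ++j)
        for (int i = 0; i < lx; ++i) {
          size_t l = ((size_t)k * ly + j) * lx + i;
          if (node_map[l]) {
            nodes(id, 0) = i; nodes(id, 1) = j; nodes(id, 2) = k;
            ++id;
          }
        }
  }
  IntegerMatrix elems(nvox, 8);
  IntegerVector voxel(nvox);
  size_t e = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t v = ((size_t)k * ny + j) * nx + i;
        if (!mask[v]) continue;
        for (int c = 0; c < 8; ++c) {
          size_t l = ((size_t)(k + HEXOFF[c][2]) * ly + (j + HEXOFF[c][1])) * lx +
                     (i + HEXOFF[c][0]);
          elems(e, c) = node_map[l];
        }
        voxel[e] = (int)v + 1;
        ++e;
      }
  IntegerVector nm(node_map.begin(), node_map.end());
  return List::create(_["nodes_ijk"] = nodes, _["elems"] = elems,
                      _["voxel"] = voxel, _["node_map"] = nm);
}

// reference gradient matrices G[alpha][beta](a,b) = int dNa/dxalpha dNb/dxbeta
// over a box hx x hy x hz, by 2x2x2 Gauss (exact for these integrands)
static void box_G(double hx, double hy, double hz, double G[3][3][8][8]) {
  const double gp[2] = {0.5 - 0.5 / std::sqrt(3.0), 0.5 + 0.5 / std::sqrt(3.0)};
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      for (int i = 0; i < 8; ++i)
        for (int j = 0; j < 8; ++j) G[a][b][i][j] = 0.0;
  double h[3] = {hx, hy, hz};
  double vol = hx * hy * hz;
  for (int gx = 0; gx < 2; ++gx)
    for (int gy = 0; gy < 2; ++gy)
      for (int gz = 0; gz < 2; ++gz) {
        double xi[3] = {gp[gx], gp[gy], gp[gz]};
        double dN[8][3];
        for (int c = 0; c < 8; ++c) {
          double f[3], df[3];
          for (int d = 0; d < 3; ++d) {
            f[d] = HEXOFF[c][d] ? xi[d] : 1.0 - xi[d];
            df[d] = (HEXOFF[c][d] ? 1.0 : -1.0) / h[d];
          }
          dN[c][0] = df[0] * f[1] * f[2];
          dN[c][1] = f[0] * df[1] * f[2];
          dN[c][2] = f[0] * f[1] * df[2];
        }
        double w = vol / 8.0;
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            for (int i = 0; i < 8; ++i)
              for (int j = 0; j < 8; ++j)
                G[a][b][i][j] += w * dN[i][a] * dN[j][b];
      }
}

static inline int popcount32(unsigned int x) {
#ifdef __GNUC__
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { c += x & 1u; x >>= 1; } return c;
#endif
}

// Assemble the stiffness matrix K_ab = sum_e int grad(Na) . sigma_e grad(Nb)
// directly into CSR storage. sig6 holds one packed conductivity tensor per
// element (expressed in voxel-index axes), sizes (S/m). Spacing in mm;
// resulting K in S*mm units.
// [[Rcpp::export]]
List cpp_hex_assemble(IntegerMatrix nodes_ijk, IntegerMatrix elems,
                      NumericMatrix sig6, NumericVector spacing,
                      IntegerVector lattice_dims, IntegerVector node_map) {
  const int nn = nodes_ijk.nrow();
  const size_t ne = elems.nrow();
  const int lx = lattice_dims[0], ly = lattice_dims[1];
  double G[3][3][8][8];
  box_G(spacing[0], spacing[1], spacing[2], G);

  // adjacency bitmask over the 27 lattice offsets per node
  std::vector<unsigned int> adj(nn, 0u);
  auto offidx = [](int d0, int d1, int d2) {
    return (d0 + 1) + 3 * (d1 + 1) + 9 * (d2 + 1);
  };
  for (size_t e = 0; e < ne; ++e)
    for (int a = 0; a < 8; ++a) {
      int na = elems(e, a) - 1;
      for (int b = 0; b < 8; ++b) {
        int o = offidx(HEXOFF[b][0] - HEXOFF[a][0], HEXOFF[b][1] - HEXOFF[a][1],
                       HEXOFF[b][2] - HEXOFF[a][2]);
        adj[na] |= (1u << o);
      }
    }
  std::vector<size_t> row_ptr(nn + 1, 0);
  for (int a = 0; a < nn; ++a)
    row_ptr[a + 1] = row_ptr[a] + popcount32(adj[a]);
  size_t nnz = row_ptr[nn];
  std::vector<int> col(nnz);
  std::vector<double> val(nnz, 0.0);
  for (int a = 0; a < nn; ++a) {
    size_t pos = row_ptr[a];
    int i = nodes_ijk(a, 0), j = nodes_ijk(a, 1), k = nodes_ijk(a, 2);
    for (int o = 0; o < 27; ++o) {
      if (!(adj[a] & (1u << o))) continue;
      int d0 = o % 3 - 1, d1 = (o / 3) % 3 - 1, d2 = o / 9 - 1;
      size_t l = ((size_t)(k + d2) * ly + (j + d1)) * lx + (i + d0);
      col[pos++] = node_map[l] - 1;  // 0-based
    }
  }
  // accumulate element contributions
  for (size_t e = 0; e < ne; ++e) {
    double s[3][3] = {{sig6(0, e), sig6(1, e), sig6(2, e)},
                      {sig6(1, e), sig6(3, e), sig6(4, e)},
                      {sig6(2, e), sig6(4, e), sig6(5, e)}};
    double Ke[8][8];
    for (int i = 0; i < 8; ++i)
      for (int j = 0; j < 8; ++j) {
        double x = 0;
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) x += s[a][b] * G[a][b][i][j];
        Ke[i][j] = x;
      }
    for (int a = 0; a < 8; ++a) {
      int na = elems(e, a) - 1;
      for (int b = 0; b < 8; ++b) {
        int o = offidx(HEXOFF[b][0] - HEXOFF[a][0], HEXOFF[b][1] - HEXOFF[a][1],
                       HEXOFF[b][2] - HEXOFF[a][2]);
        size_t slot = row_ptr[na] +
                      popcount32(adj[na] & ((1u << o) - 1u));
        val[slot] += Ke[a][b];
      }
    }
  }
  NumericVector rp(row_ptr.begin(), row_ptr.end());
  IntegerVector ci(col.begin(), col.end());
  NumericVector x(val.begin(), val.end());
  return List::create(_["row_ptr"] = rp, _["col"] = ci, _["val"] = x,
                      _["n"] = nn);
}

// gradient of the infinite-medium anisotropic dipole potential
struct DipolePhi {
  double T[3][3], mt[3], C, r0[3];
  void init(NumericMatrix sigma0, NumericVector pos, NumericVector mom) {
    double s[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) s[i][j] = sigma0(i, j);
    double det = s[0][0] * (s[1][1] * s[2][2] - s[2][1] * s[1][2]) -
                 s[0][1] * (s[1][0] * s[2][2] - s[2][0] * s[1][2]) +
                 s[0][2] * (s[1][0] * s[2][1] - s[2][0] * s[1][1]);
    if (!(det > 0)) stop("source conductivity tensor must be positive definite");
    T[0][0] = (s[1][1] * s[2][2] - s[2][1] * s[1][2]) / det;
    T[0][1] = -(s[0][1] * s[2][2] - s[0][2] * s[2][1]) / det;
    T[0][2] = (s[0][1] * s[1][2] - s[0][2] * s[1][1]) / det;
    T[1][0] = T[0][1];
    T[1][1] = (s[0][0] * s[2][2] - s[0][2] * s[2][0]) / det;
    T[1][2] = -(s[0][0] * s[1][2] - s[0][2] * s[1][0]) / det;
    T[2][0] = T[0][2];
    T[2][1] = T[1][2];
    T[2][2] = (s[0][0] * s[1][1] - s[0][1] * s[1][0]) / det;
    for (int i = 0; i < 3; ++i) {
      mt[i] = 0;
      for (int j = 0; j < 3; ++j) mt[i] += T[i][j] * mom[j];
      r0[i] = pos[i];
    }
    C = 1.0 / (4.0 * M_PI * std::sqrt(det));
  }
  void grad(const double *x, double *g) const {
    double sdl[3] = {x[0] - r0[0], x[1] - r0[1], x[2] - r0[2]};
    double Ts[3];
    for (int i = 0; i < 3; ++i)
      Ts[i] = T[i][0] * sdl[0] + T[i][1] * sdl[1] + T[i][2] * sdl[2];
    double rho2 = sdl[0] * Ts[0] + sdl[1] * Ts[1] + sdl[2] * Ts[2];
    double rho = std::sqrt(rho2), rho3 = rho2 * rho, rho5 = rho3 * rho2;
    double ms = mt[0] * sdl[0] + mt[1] * sdl[1] + mt[2] * sdl[2];
    for (int i = 0; i < 3; ++i)
      g[i] = C * (mt[i] / rho3 - 3.0 * ms * Ts[i] / rho5);
  }
};

// Full-subtraction right-hand side:
//   b_a = -int_Omega grad(Na) . (sigma - sigma0) grad(phi_inf)
//         - int_dOmega Na (sigma0 grad(phi_inf) . n)
// Volume term integrated with 2x2x2 Gauss on elements whose tensor differs
// from sigma0; boundary term with 2x2 Gauss on exterior voxel faces.
// All geometry in voxel-index axes (conductivities pre-rotated by caller).
// [[Rcpp::export]]
NumericVector cpp_hex_rhs(IntegerMatrix nodes_ijk, IntegerMatrix elems,
                          NumericMatrix sig6, LogicalVector mask,
                          IntegerVector dims, IntegerVector voxel_of_elem,
                          NumericVector spacing, NumericVector origin0,
                          NumericMatrix sigma0, NumericVector dipole_pos,
                          NumericVector dipole_mom, int nn, double difftol) {
  DipolePhi phi;
  phi.init(sigma0, dipole_pos, dipole_mom);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  NumericVector b(nn);
  const double gp[2] = {0.5 - 0.5 / std::sqrt(3.0), 0.5 + 0.5 / std::sqrt(3.0)};
  double s0[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) s0[i][j] = sigma0(i, j);

  // volume term
  const size_t ne = elems.nrow();
  for (size_t e = 0; e < ne; ++e) {
    double ds[3][3] = {{sig6(0, e) - s0[0][0], sig6(1, e) - s0[0][1], sig6(2, e) - s0[0][2]},
                       {sig6(1, e) - s0[1][0], sig6(3, e) - s0[1][1], sig6(4, e) - s0[1][2]},
                       {sig6(2, e) - s0[2][0], sig6(4, e) - s0[2][1], sig6(5, e) - s0[2][2]}};
    double mx = 0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) mx = std::max(mx, std::abs(ds[i][j]));
    if (mx <= difftol) continue;
    int v = voxel_of_elem[e] - 1;
    int vi = v % nx, vj = (v / nx) % ny, vk = v / (nx * ny);
    double x0 = origin0[0] + vi * hx, y0 = origin0[1] + vj * hy,
           z0 = origin0[2] + vk * hz;  // element min corner (voxel center - h/2)
    double w = hx * hy * hz / 8.0;
    for (int gx = 0; gx < 2; ++gx)
      for (int gy = 0; gy < 2; ++gy)
        for (int gz = 0; gz < 2; ++gz) {
          double xi[3] = {gp[gx], gp[gy], gp[gz]};
          double xg[3] = {x0 + xi[0] * hx, y0 + xi[1] * hy, z0 + xi[2] * hz};
          double g[3];
          phi.grad(xg, g);
          double Mv[3];
          for (int i = 0; i < 3; ++i)
            Mv[i] = ds[i][0] * g[0] + ds[i][1] * g[1] + ds[i][2] * g[2];
          for (int c = 0; c < 8; ++c) {
            double f[3], df[3];
            double h[3] = {hx, hy, hz};
            for (int d = 0; d < 3; ++d) {
              f[d] = HEXOFF[c][d] ? xi[d] : 1.0 - xi[d];
              df[d] = (HEXOFF[c][d] ? 1.0 : -1.0) / h[d];
            }
            double dN[3] = {df[0] * f[1] * f[2], f[0] * df[1] * f[2],
                            f[0] * f[1] * df[2]};
            b[elems(e, c) - 1] -=
                w * (dN[0] * Mv[0] + dN[1] * Mv[1] + dN[2] * Mv[2]);
          }
        }
  }

  // boundary term over exterior faces
  auto in_mask = [&](int i, int j, int k) {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return (bool)mask[((size_t)k * ny + j) * nx + i];
  };
  static const int facedir[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  // local corner ids of each face (consistent with HEXOFF)
  static const int facecorn[6][4] = {{0,3,7,4},{1,2,6,5},{0,1,5,4},{3,2,6,7},
                                     {0,1,2,3},{4,5,6,7}};
  for (size_t e = 0; e < ne; ++e) {
    int v = voxel_of_elem[e] - 1;
    int vi = v % nx, vj = (v / nx) % ny, vk = v / (nx * ny);
    for (int fidx = 0; fidx < 6; ++fidx) {
      if (in_mask(vi + facedir[fidx][0], vj + facedir[fidx][1],
                  vk + facedir[fidx][2]))
        continue;
      int axis = fidx / 2;
      double sgn = (fidx % 2) ? 1.0 : -1.0;
      double h[3] = {hx, hy, hz};
      int ua = (axis + 1) % 3, va = (axis + 2) % 3;
      double area = h[ua] * h[va];
      double nvec[3] = {0, 0, 0};
      nvec[axis] = sgn;
      double x0[3] = {origin0[0] + vi * hx, origin0[1] + vj * hy,
                      origin0[2] + vk * hz};
      for (int g1 = 0; g1 < 2; ++g1)
        for (int g2 = 0; g2 < 2; ++g2) {
          double xi[3];
          xi[axis] = (fidx % 2) ? 1.0 : 0.0;
          xi[ua] = gp[g1];
          xi[va] = gp[g2];
          double xg[3] = {x0[0] + xi[0] * hx, x0[1] + xi[1] * hy,
                          x0[2] + xi[2] * hz};
          double g[3];
          phi.grad(xg, g);
          double flux = 0;
          for (int i = 0; i < 3; ++i)
            flux += nvec[i] * (s0[i][0] * g[0] + s0[i][1] * g[1] + s0[i][2] * g[2]);
          double w = area / 4.0;
          for (int fc = 0; fc < 4; ++fc) {
            int c = facecorn[fidx][fc];
            double Na = 1.0;
            for (int d = 0; d < 3; ++d)
              Na *= HEXOFF[c][d] ? xi[d] : 1.0 - xi[d];
            b[elems(e, c) - 1] -= w * Na * flux;
          }
        }
    }
  }
  return b;
}

// Jacobi-preconditioned conjugate gradients on CSR storage, with the
// constant null space of the pure-Neumann operator projected out of the
// right-hand side and the preconditioned residual.
// [[Rcpp::export]]
List cpp_cg(NumericVector row_ptr, IntegerVector col, NumericVector val,
            NumericVector bb, double tol, int maxit) {
  const int n = row_ptr.size() - 1;
  std::vector<double> b(bb.begin(), bb.end());
  double mean = 0;
  for (int i = 0; i < n; ++i) mean += b[i];
  mean /= n;
  for (int i = 0; i < n; ++i) b[i] -= mean;
  std::vector<double> diag(n);
  for (int i = 0; i < n; ++i) {
    double d = 0;
    for (size_t s = (size_t)row_ptr[i]; s < (size_t)row_ptr[i + 1]; ++s)
      if (col[s] == i) d = val[s];
    diag[i] = d > 0 ? d : 1.0;
  }
  std::vector<double> x(n, 0.0), r(b), z(n), p(n), Ap(n);
  double bnorm = 0;
  for (int i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0) {
    NumericVector xr(n);
    return List::create(_["x"] = xr, _["iterations"] = 0, _["relres"] = 0.0);
  }
  auto precond = [&]() {
    double zm = 0;
    for (int i = 0; i < n; ++i) { z[i] = r[i] / diag[i]; zm += z[i]; }
    zm /= n;
    for (int i = 0; i < n; ++i) z[i] -= zm;
  };
  precond();
  std::copy(z.begin(), z.end(), p.begin());
  double rz = 0;
  for (int i = 0; i < n; ++i) rz += r[i] * z[i];
  double relres = 1.0;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (size_t t = (size_t)row_ptr[i]; t < (size_t)row_ptr[i + 1]; ++t)
        s += val[t] * p[col[t]];
      Ap[i] = s;
    }
    double pAp = 0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0) break;
    double alpha = rz / pAp;
    double rn = 0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rn += r[i] * r[i];
    }
    relres = std::sqrt(rn) / bnorm;
    if (relres < tol) break;
    precond();
    double rznew = 0;
    for (int i = 0; i < n; ++i) rznew += r[i] * z[i];
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  double xm = 0;
  for (int i = 0; i < n; ++i) xm += x[i];
  xm /= n;
  NumericVector xr(n);
  for (int i = 0; i < n; ++i) xr[i] = x[i] - xm;
  return List::create(_["x"] = xr, _["iterations"] = std::min(it, maxit),
                      _["relres"] = relres);
}

// Trilinear sampling of a node field of the voxel hex mesh at continuous
// index coordinates (voxel centres at integers). Points in unmasked voxels
// are snapped up to `snap` voxels.
// [[Rcpp::export]]
NumericVector cpp_hex_sample(IntegerVector node_map, LogicalVector mask,
                             IntegerVector dims, NumericVector values,
                             NumericMatrix idx, double snap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int lx = nx + 1, ly = ny + 1;
  const int n = idx.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    // element coordinates: voxel v contains index range [v-0.5, v+0.5]
    double xi = idx(p, 0), yj = idx(p, 1), zk = idx(p, 2);
    int i = (int)std::floor(xi + 0.5), j = (int)std::floor(yj + 0.5),
        k = (int)std::floor(zk + 0.5);
    auto ok = [&](int a, int b, int c) {
      return a >= 0 && b >= 0 && c >= 0 && a < nx && b < ny && c < nz &&
             mask[((size_t)c * ny + b) * nx + a];
    };
    if (!ok(i, j, k)) {
      // snap to the nearest masked voxel within `snap`
      double best = R_PosInf;
      int bi = -1, bj = -1, bk = -1;
      int rad = (int)std::ceil(snap) + 1;
      for (int dk = -rad; dk <= rad; ++dk)
        for (int dj = -rad; dj <= rad; ++dj)
          for (int di = -rad; di <= rad; ++di) {
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (!ok(ii, jj, kk)) continue;
            double cx = std::max(std::abs(xi - ii), std::max(std::abs(yj - jj), std::abs(zk - kk)));
            if (cx < best) { best = cx; bi = ii; bj = jj; bk = kk; }
          }
      if (bi < 0 || best > snap + 0.5)
        stop("sample point %d is outside the mesh (nearest masked voxel %.2f voxels away)",
             p + 1, best);
      i = bi; j = bj; k = bk;
      xi = std::min(std::max(xi, i - 0.5), i + 0.5);
      yj = std::min(std::max(yj, j - 0.5), j + 0.5);
      zk = std::min(std::max(zk, k - 0.5), k + 0.5);
    }
    double fx = xi - (i - 0.5), fy = yj - (j - 0.5), fz = zk - (k - 0.5);
    double acc = 0;
    for (int c = 0; c < 8; ++c) {
      size_t l = ((size_t)(k + HEXOFF[c][2]) * ly + (j + HEXOFF[c][1])) * lx +
                 (i + HEXOFF[c][0]);
      int id = node_map[l];
      if (id == 0) stop("internal error: missing node while sampling");
      double wgt = (HEXOFF[c][0] ? fx : 1 - fx) * (HEXOFF[c][1] ? fy : 1 - fy) *
                   (HEXOFF[c][2] ? fz : 1 - fz);
      acc += wgt * values[id - 1];
    }
    out[p] = acc;
  }
  return out;
}
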