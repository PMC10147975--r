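#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on the Kuhn 6-tet
// decomposition of each cell (all tets share the cell diagonal v0-v6, so
// face diagonals match between neighbouring cells and the surface is
// watertight). Vertices are returned in continuous 0-based index
// coordinates; triangles are oriented so normals point from values above the
// isovalue (inside) towards values below it (outside is flipped by caller if
// needed).
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = REAL(field);
  auto lin = [&](int i, int j, int k) -> long long {
    return ((long long)k * ny + j) * nx + i;
  };
  // cube corners (Kuhn ordering)
  static const int corner[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                                   {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  std::unordered_map<unsigned long long, int> edge_vert;
  std::vector<double> verts;
  std::vector<int> tris;

  auto edge_vertex = [&](long long ga, long long gb, double da, double db,
                         const double *pa, const double *pb) -> int {
    if (ga > gb) { std::swap(ga, gb); std::swap(da, db); std::swap(pa, pb); }
    unsigned long long key = ((unsigned long long)ga << 32) ^ (unsigned long long)gb;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = (iso - da) / (db - da);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int id = (int)(verts.size() / 3);
    verts.push_back(pa[0] + t * (pb[0] - pa[0]));
    verts.push_back(pa[1] + t * (pb[1] - pa[1]));
    verts.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vert[key] = id;
    return id;
  };

  auto emit = [&](int a, int b, int c, const double *inw) {
    // orient triangle so its normal has negative dot with direction toward
    // the inside (i.e. normal points outward, away from values > iso)
    double *A = &verts[3 * a], *B = &verts[3 * b], *C = &verts[3 * c];
    double u[3] = {B[0]-A[0], B[1]-A[1], B[2]-A[2]};
    double v[3] = {C[0]-A[0], C[1]-A[1], C[2]-A[2]};
    double nrm[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0]};
    double cx = (A[0]+B[0]+C[0])/3.0, cy = (A[1]+B[1]+C[1])/3.0, cz = (A[2]+B[2]+C[2])/3.0;
    double din[3] = {inw[0]-cx, inw[1]-cy, inw[2]-cz};
    double d = nrm[0]*din[0] + nrm[1]*din[1] + nrm[2]*din[2];
    if (d > 0) std::swap(b, c);
    tris.push_back(a); tris.push_back(b); tris.push_back(c);
  };

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        double cd[8]; long long cg[8]; double cp[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + corner[c][0], cj = j + corner[c][1], ck = k + corner[c][2];
          cg[c] = lin(ci, cj, ck);
          cd[c] = f[cg[c]];
          cp[c][0] = ci; cp[c][1] = cj; cp[c][2] = ck;
          (cd[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int in[4], nin = 0;
          for (int c = 0; c < 4; ++c)
            if (cd[T[c]] > iso) in[nin++] = c;
          if (nin == 0 || nin == 4) continue;
          // centroid of inside vertices used for orientation
          double cen[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) cen[d] += cp[T[in[c]]][d] / nin;
          auto ev = [&](int a, int b) {
            return edge_vertex(cg[T[a]], cg[T[b]], cd[T[a]], cd[T[b]],
                               cp[T[a]], cp[T[b]]);
          };
          if (nin == 1) {
            int a = in[0];
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != a) o[m++] = c;
            emit(ev(a, o[0]), ev(a, o[1]), ev(a, o[2]), cen);
          } else if (nin == 3) {
            int a = -1;
            for (int c = 0; c < 4; ++c) {
              bool isin = false;
              for (int q = 0; q < nin; ++q) if (in[q] == c) isin = true;
              if (!isin) a = c;
            }
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != a) o[m++] = c;
            emit(ev(a, o[0]), ev(a, o[1]), ev(a, o[2]), cen);
          } else { // nin == 2: quad split into two triangles
            int a = in[0], b = in[1];
            int o[2], m = 0;
            for (int c = 0; c < 4; ++c) if (c != a && c != b) o[m++] = c;
            int v00 = ev(a, o[0]), v01 = ev(a, o[1]);
            int v10 = ev(b, o[0]), v11 = ev(b, o[1]);
            emit(v00, v01, v11, cen);
            emit(v00, v11, v10, cen);
          }
        }
      }

  int nv = verts.size() / 3, nt = tris.size() / 3;
  NumericMatrix V(nv, 3);
  IntegerMatrix Tr(nt, 3);
  for (int a = 0; a < nv; ++a)
    for (int d = 0; d < 3; ++d) V(a, d) = verts[3 * a + d];
  for (int a = 0; a < nt; ++a)
    for (int d = 0; d < 3; ++d) Tr(a, d) = tris[3 * a + d] + 1;
  return List::create(_["vertices"] = V, _["triangles"] = Tr);
}

static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  // Ericson's point-triangle closest point
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=a[i]; return; }
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=b[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i]=a[i]+v*ab[i];
    return;
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=c[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i]=a[i]+w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i]=b[i]+w*(c[i]-b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i]=a[i]+ab[i]*v+ac[i]*w;
}

// Closest point on a triangle mesh for each query point: returns the foot
// point, distance and 1-based triangle index.
// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix pts, NumericMatrix verts, IntegerMatrix tris) {
  const int n = pts.nrow(), m = tris.nrow();
  NumericMatrix foot(n, 3);
  NumericVector dist(n);
  IntegerVector tri(n);
  // triangle bounding spheres for cheap rejection
  std::vector<double> cx(m), cy(m), cz(m), rad(m);
  for (int t = 0; t < m; ++t) {
    int ia = tris(t,0)-1, ib = tris(t,1)-1, ic = tris(t,2)-1;
    double a[3] = {verts(ia,0), verts(ia,1), verts(ia,2)};
    double b[3] = {verts(ib,0), verts(ib,1), verts(ib,2)};
    double c[3] = {verts(ic,0), verts(ic,1), verts(ic,2)};
    cx[t] = (a[0]+b[0]+c[0])/3; cy[t]=(a[1]+b[1]+c[1])/3; cz[t]=(a[2]+b[2]+c[2])/3;
    double r2 = 0;
    double da = (a[0]-cx[t])*(a[0]-cx[t])+(a[1]-cy[t])*(a[1]-cy[t])+(a[2]-cz[t])*(a[2]-cz[t]);
    double db = (b[0]-cx[t])*(b[0]-cx[t])+(b[1]-cy[t])*(b[1]-cy[t])+(b[2]-cz[t])*(b[2]-cz[t]);
    double dc = (c[0]-cx[t])*(c[0]-cx[t])+(c[1]-cy[t])*(c[1]-cy[t])+(c[2]-cz[t])*(c[2]-cz[t]);
    r2 = std::max(da, std::max(db, dc));
    rad[t] = std::sqrt(r2);
  }
  for (int p = 0; p < n; ++p) {
    double P[3] = {pts(p,0), pts(p,1), pts(p,2)};
    double best = R_PosInf, bf[3] = {0,0,0};
    int bt = 0;
    for (int t = 0; t < m; ++t) {
      double dx = P[0]-cx[t], dy = P[1]-cy[t], dz = P[2]-cz[t];
      double dc = std::sqrt(dx*dx+dy*dy+dz*dz) - rad[t];
      if (dc * dc >= best && dc > 0) continue;
      int ia = tris(t,0)-1, ib = tris(t,1)-1, ic = tris(t,2)-1;
      double a[3] = {verts(ia,0), verts(ia,1), verts(ia,2)};
      double b[3] = {verts(ib,0), verts(ib,1), verts(ib,2)};
      double c[3] = {verts(ic,0), verts(ic,1), verts(ic,2)};
      double q[3];
      closest_on_tri(P, a, b, c, q);
      double d2 = (P[0]-q[0])*(P[0]-q[0])+(P[1]-q[1])*(P[1]-q[1])+(P[2]-q[2])*(P[2]-q[2]);
      if (d2 < best) { best = d2; bt = t; bf[0]=q[0]; bf[1]=q[1]; bf[2]=q[2]; }
    }
    foot(p,0)=bf[0]; foot(p,1)=bf[1]; foot(p,2)=bf[2];
    dist[p] = std::sqrt(best);
    tri[p] = bt + 1;
  }
  return List::create(_["point"] = foot, _["distance"] = dist, _["triangle"] = tri);
}

// Voxelise a closed triangle mesh by ray-parity. Vertices must already be in
// continuous index coordinates. axis selects the ray direction (0, 1 or 2).
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix verts, IntegerMatrix tris,
                           IntegerVector dims, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  LogicalVector out(n, false);
  // permutation: ray along `axis`; (u,v) are the other two axes
  int ua = (axis + 1) % 3, va = (axis + 2) % 3;
  int du = (ua == 0 ? nx : (ua == 1 ? ny : nz));
  int dv = (va == 0 ? nx : (va == 1 ? ny : nz));
  std::vector<std::vector<double>> crossings((size_t)du * dv);
  const double eps = 1e-9;
  for (int t = 0; t < tris.nrow(); ++t) {
    int ia = tris(t,0)-1, ib = tris(t,1)-1, ic = tris(t,2)-1;
    double A[3] = {verts(ia,0), verts(ia,1), verts(ia,2)};
    double B[3] = {verts(ib,0), verts(ib,1), verts(ib,2)};
    double C[3] = {verts(ic,0), verts(ic,1), verts(ic,2)};
    double au = A[ua], av = A[va], bu = B[ua], bv = B[va], cu = C[ua], cv = C[va];
    int u0 = (int)std::ceil(std::min(au, std::min(bu, cu)) - eps);
    int u1 = (int)std::floor(std::max(au, std::max(bu, cu)) + eps);
    int v0 = (int)std::ceil(std::min(av, std::min(bv, cv)) - eps);
    int v1 = (int)std::floor(std::max(av, std::max(bv, cv)) + eps);
    u0 = std::max(u0, 0); u1 = std::min(u1, du - 1);
    v0 = std::max(v0, 0); v1 = std::min(v1, dv - 1);
    for (int u = u0; u <= u1; ++u)
      for (int v = v0; v <= v1; ++v) {
        // 2D barycentric test with a tiny offset to dodge edge-on hits
        double pu = u + 1e-7, pv = v + 3e-7;
        double d = (bv - cv) * (au - cu) + (cu - bu) * (av - cv);
        if (std::abs(d) < 1e-300) continue;
        double w1 = ((bv - cv) * (pu - cu) + (cu - bu) * (pv - cv)) / d;
        double w2 = ((cv - av) * (pu - cu) + (au - cu) * (pv - cv)) / d;
        double w3 = 1.0 - w1 - w2;
        if (w1 < 0 || w2 < 0 || w3 < 0) continue;
        double w = w1 * A[axis] + w2 * B[axis] + w3 * C[axis];
        crossings[(size_t)v * du + u].push_back(w);
      }
  }
  int dw = (axis == 0 ? nx : (axis == 1 ? ny : nz));
  for (int v = 0; v < dv; ++v)
    for (int u = 0; u < du; ++u) {
      auto &cr = crossings[(size_t)v * du + u];
      if (cr.empty()) continue;
      std::sort(cr.begin(), cr.end());
      size_t ci = 0;
      bool inside = false;
      for (int w = 0; w < dw; ++w) {
        while (ci < cr.size() && cr[ci] < w) { inside = !inside; ++ci; }
        if (inside) {
          int ijk[3];
          ijk[axis] = w; ijk[ua] = u; ijk[va] = v;
          out[((size_t)ijk[2] * ny + ijk[1]) * nx + ijk[0]] = true;
        }
      }
    }
  return out;
}
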