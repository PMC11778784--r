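#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Arrays follow R's [y, x, z] layout: linear index = j + ny*(i + nx*k),
// 0-based j (row/y), i (col/x), k (slice/z). All physical outputs are in
// micrometres, points ordered (x, y, z).

// ---------------------------------------------------------------- utilities

static inline double sqdist3(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// squared distance point -> triangle (Ericson, Real-Time Collision Detection)
static double d2_point_tri(const double* p, const double* a, const double* b,
                           const double* c) {
  double ab[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double ac[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double ap[3] = { p[0]-a[0], p[1]-a[1], p[2]-a[2] };
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) return sqdist3(p, a);

  double bp[3] = { p[0]-b[0], p[1]-b[1], p[2]-b[2] };
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) return sqdist3(p, b);

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double q[3] = { a[0]+v*ab[0], a[1]+v*ab[1], a[2]+v*ab[2] };
    return sqdist3(p, q);
  }

  double cp[3] = { p[0]-c[0], p[1]-c[1], p[2]-c[2] };
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) return sqdist3(p, c);

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double q[3] = { a[0]+w*ac[0], a[1]+w*ac[1], a[2]+w*ac[2] };
    return sqdist3(p, q);
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = { b[0]+w*(c[0]-b[0]), b[1]+w*(c[1]-b[1]), b[2]+w*(c[2]-b[2]) };
    return sqdist3(p, q);
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = { a[0]+ab[0]*v+ac[0]*w, a[1]+ab[1]*v+ac[1]*w,
                  a[2]+ab[2]*v+ac[2]*w };
  return sqdist3(p, q);
}

// ------------------------------------------------------- marching tetrahedra

// Iso-surface of a binary field at level 0.5 via a 6-tetrahedron cube split
// sharing the main diagonal; the split's face diagonals are translation
// invariant, so the surface is watertight. Vertices sit at midpoints of
// in/out voxel-centre pairs and are deduplicated by voxel pair, giving
// bit-deterministic output. Caller passes a zero-padded array.
// [[Rcpp::export(name = ".cpp_march_tets")]]
List march_tets(LogicalVector mask, NumericVector dims, NumericVector spacing,
                NumericVector origin) {
  const int ny = (int)dims[0], nx = (int)dims[1], nz = (int)dims[2];
  const double dy = spacing[0], dx = spacing[1], dz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int* m = LOGICAL(mask);
  const int64_t N = (int64_t)ny * nx * nz;

  auto lin = [&](int j, int i, int k) -> int64_t {
    return (int64_t)j + (int64_t)ny * ((int64_t)i + (int64_t)nx * k);
  };

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tris;

  auto vpos = [&](int64_t id, double* out) {
    int64_t k = id / ((int64_t)ny * nx);
    int64_t r = id % ((int64_t)ny * nx);
    int64_t i = r / ny, j = r % ny;
    out[0] = ox + i * dx; out[1] = oy + j * dy; out[2] = oz + k * dz;
  };

  auto edge_vertex = [&](int64_t a, int64_t b) -> int {
    if (a > b) std::swap(a, b);
    uint64_t key = (uint64_t)a * (uint64_t)N + (uint64_t)b;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double pa[3], pb[3];
    vpos(a, pa); vpos(b, pb);
    int id = (int)vx.size();
    vx.push_back(0.5 * (pa[0] + pb[0]));
    vy.push_back(0.5 * (pa[1] + pb[1]));
    vz.push_back(0.5 * (pa[2] + pb[2]));
    vmap.emplace(key, id);
    return id;
  };

  // push a triangle oriented so that its normal points away from an inside
  // corner of the solid
  auto push_tri = [&](int v0, int v1, int v2, const double* inside_pt) {
    double p0[3] = { vx[v0], vy[v0], vz[v0] };
    double p1[3] = { vx[v1], vy[v1], vz[v1] };
    double p2[3] = { vx[v2], vy[v2], vz[v2] };
    double e1[3] = { p1[0]-p0[0], p1[1]-p0[1], p1[2]-p0[2] };
    double e2[3] = { p2[0]-p0[0], p2[1]-p0[1], p2[2]-p0[2] };
    double n[3] = { e1[1]*e2[2]-e1[2]*e2[1], e1[2]*e2[0]-e1[0]*e2[2],
                    e1[0]*e2[1]-e1[1]*e2[0] };
    double cen[3] = { (p0[0]+p1[0]+p2[0])/3.0, (p0[1]+p1[1]+p2[1])/3.0,
                      (p0[2]+p1[2]+p2[2])/3.0 };
    double d[3] = { inside_pt[0]-cen[0], inside_pt[1]-cen[1], inside_pt[2]-cen[2] };
    if (n[0]*d[0] + n[1]*d[1] + n[2]*d[2] > 0.0) std::swap(v1, v2);
    tris.push_back(v0); tris.push_back(v1); tris.push_back(v2);
  };

  // 6-tet split of a cube with corner bits (x=bit0, y=bit1, z=bit2),
  // all tets sharing diagonal 0-7
  static const int TET[6][4] = {
    {0,5,1,7}, {0,1,3,7}, {0,3,2,7}, {0,2,6,7}, {0,6,4,7}, {0,4,5,7}
  };

  for (int k = 0; k + 1 < nz; ++k) {
    for (int i = 0; i + 1 < nx; ++i) {
      for (int j = 0; j + 1 < ny; ++j) {
        int64_t cid[8];
        int cin[8];
        int any = 0, all = 1;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          cid[c] = lin(j + dj, i + di, k + dk);
          cin[c] = m[cid[c]] ? 1 : 0;
          any |= cin[c]; all &= cin[c];
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4], ins[4], nin = 0;
          for (int c = 0; c < 4; ++c) {
            id[c] = TET[t][c];
            ins[c] = cin[id[c]];
            nin += ins[c];
          }
          if (nin == 0 || nin == 4) continue;
          int in_idx[4], out_idx[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            if (ins[c]) in_idx[ni++] = id[c]; else out_idx[no++] = id[c];
          }
          double ipt[3];
          vpos(cid[in_idx[0]], ipt);
          if (nin == 1) {
            int A = in_idx[0];
            int e0 = edge_vertex(cid[A], cid[out_idx[0]]);
            int e1 = edge_vertex(cid[A], cid[out_idx[1]]);
            int e2 = edge_vertex(cid[A], cid[out_idx[2]]);
            push_tri(e0, e1, e2, ipt);
          } else if (nin == 3) {
            int D = out_idx[0];
            int e0 = edge_vertex(cid[D], cid[in_idx[0]]);
            int e1 = edge_vertex(cid[D], cid[in_idx[1]]);
            int e2 = edge_vertex(cid[D], cid[in_idx[2]]);
            push_tri(e0, e1, e2, ipt);
          } else { // 2 in / 2 out
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int eAC = edge_vertex(cid[A], cid[C]);
            int eAD = edge_vertex(cid[A], cid[D]);
            int eBD = edge_vertex(cid[B], cid[D]);
            int eBC = edge_vertex(cid[B], cid[C]);
            push_tri(eAC, eAD, eBD, ipt);
            push_tri(eAC, eBD, eBC, ipt);
          }
        }
      }
    }
  }

  int nv = (int)vx.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v,0)=vx[v]; V(v,1)=vy[v]; V(v,2)=vz[v]; }
  int nf = (int)tris.size() / 3;
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f) {
    F(f,0) = tris[3*f] + 1; F(f,1) = tris[3*f+1] + 1; F(f,2) = tris[3*f+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ------------------------------------------------------------ Taubin smooth

// shrink-free lambda/mu smoothing with uniform weights
// [[Rcpp::export(name = ".cpp_taubin")]]
NumericMatrix taubin_smooth(NumericMatrix V, IntegerMatrix F, int iterations,
                            double lambda, double mu) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<std::vector<int> > adj(nv);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int v = 0; v < nv; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  std::vector<double> X(nv), Y(nv), Z(nv), X2(nv), Y2(nv), Z2(nv);
  for (int v = 0; v < nv; ++v) { X[v]=V(v,0); Y[v]=V(v,1); Z[v]=V(v,2); }
  auto pass = [&](double w) {
    for (int v = 0; v < nv; ++v) {
      size_t n = adj[v].size();
      if (n == 0) { X2[v]=X[v]; Y2[v]=Y[v]; Z2[v]=Z[v]; continue; }
      double mx=0, my=0, mz=0;
      for (int u : adj[v]) { mx+=X[u]; my+=Y[u]; mz+=Z[u]; }
      mx/=n; my/=n; mz/=n;
      X2[v] = X[v] + w*(mx - X[v]);
      Y2[v] = Y[v] + w*(my - Y[v]);
      Z2[v] = Z[v] + w*(mz - Z[v]);
    }
    X.swap(X2); Y.swap(Y2); Z.swap(Z2);
  };
  for (int it = 0; it < iterations; ++it) { pass(lambda); pass(mu); }
  NumericMatrix out(nv, 3);
  for (int v = 0; v < nv; ++v) { out(v,0)=X[v]; out(v,1)=Y[v]; out(v,2)=Z[v]; }
  return out;
}

// ------------------------------------------------- Euclidean distance field

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 double w2) {
  static const double INF = 1e30;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2*q*q) - (f[v[k]] + w2*v[k]*v[k])) / (2.0*w2*(q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k+1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k+1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// anisotropic EDT: distance (um) from each foreground voxel centre to the
// nearest background voxel centre (Felzenszwalb-Huttenlocher per axis)
// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector edt3d(LogicalVector mask, NumericVector dims,
                    NumericVector spacing) {
  const int ny = (int)dims[0], nx = (int)dims[1], nz = (int)dims[2];
  const double dy = spacing[0], dx = spacing[1], dz = spacing[2];
  const int* m = LOGICAL(mask);
  const double INF = 1e30;
  int64_t N = (int64_t)ny * nx * nz;
  std::vector<double> D(N);
  for (int64_t p = 0; p < N; ++p) D[p] = m[p] ? INF : 0.0;

  auto lin = [&](int j, int i, int k) -> int64_t {
    return (int64_t)j + (int64_t)ny * ((int64_t)i + (int64_t)nx * k);
  };

  int nmax = std::max(ny, std::max(nx, nz));
  std::vector<double> f(nmax), d(nmax);
  // y axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = D[lin(j,i,k)];
      dt1d(f, d, ny, dy*dy);
      for (int j = 0; j < ny; ++j) D[lin(j,i,k)] = d[j];
    }
  // x axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = D[lin(j,i,k)];
      dt1d(f, d, nx, dx*dx);
      for (int i = 0; i < nx; ++i) D[lin(j,i,k)] = d[i];
    }
  // z axis
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      for (int k = 0; k < nz; ++k) f[k] = D[lin(j,i,k)];
      dt1d(f, d, nz, dz*dz);
      for (int k = 0; k < nz; ++k) D[lin(j,i,k)] = d[k];
    }

  NumericVector out(N);
  for (int64_t p = 0; p < N; ++p) out[p] = std::sqrt(D[p]);
  return out;
}

// ------------------------------------------------------------ grid Dijkstra

// minimum-cost path on the 26-connected foreground voxel graph,
// edge cost = step length / (eps + mean inscribed radius of endpoints)
// [[Rcpp::export(name = ".cpp_dijkstra_grid")]]
IntegerVector dijkstra_grid(LogicalVector mask, NumericVector radius,
                            NumericVector dims, NumericVector spacing,
                            double eps, double start0, double end0) {
  const int ny = (int)dims[0], nx = (int)dims[1], nz = (int)dims[2];
  const double dy = spacing[0], dx = spacing[1], dz = spacing[2];
  const int* m = LOGICAL(mask);
  const double* R = REAL(radius);
  const int64_t N = (int64_t)ny * nx * nz;
  const int64_t s = (int64_t)start0, e = (int64_t)end0;

  struct Off { int dj, di, dk; double len; };
  std::vector<Off> offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        if (!dj && !di && !dk) continue;
        double len = std::sqrt(dj*dy*dj*dy + di*dx*di*dx + dk*dz*dk*dz);
        offs.push_back({dj, di, dk, len});
      }

  std::vector<double> dist(N, 1e300);
  std::vector<int64_t> prev(N, -1);
  typedef std::pair<double, int64_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[s] = 0.0;
  pq.push(QE(0.0, s));

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int64_t u = top.second;
    if (top.first > dist[u]) continue;
    if (u == e) break;
    int64_t k = u / ((int64_t)ny * nx);
    int64_t r = u % ((int64_t)ny * nx);
    int64_t i = r / ny, j = r % ny;
    for (const Off& o : offs) {
      int jj = (int)j + o.dj, ii = (int)i + o.di, kk = (int)k + o.dk;
      if (jj < 0 || jj >= ny || ii < 0 || ii >= nx || kk < 0 || kk >= nz)
        continue;
      int64_t v = (int64_t)jj + (int64_t)ny * ((int64_t)ii + (int64_t)nx * kk);
      if (!m[v]) continue;
      double cost = o.len / (eps + 0.5 * (R[u] + R[v]));
      double nd = dist[u] + cost;
      if (nd < dist[v]) {
        dist[v] = nd;
        prev[v] = u;
        pq.push(QE(nd, v));
      }
    }
  }

  if (dist[e] >= 1e299) return IntegerVector(0);
  std::vector<int> path;
  for (int64_t u = e; u != -1; u = prev[u]) path.push_back((int)u);
  std::reverse(path.begin(), path.end());
  return wrap(path); // 0-based linear indices
}

// ----------------------------------------------- connected components (3D)

// 6-connected labelling, labels 1..L in scan order (deterministic)
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector label3d(LogicalVector mask, NumericVector dims) {
  const int ny = (int)dims[0], nx = (int)dims[1], nz = (int)dims[2];
  const int* m = LOGICAL(mask);
  const int64_t N = (int64_t)ny * nx * nz;
  IntegerVector lab(N, 0);
  int* L = INTEGER(lab);
  int next = 0;
  std::vector<int64_t> stack;
  const int dj[6] = {1,-1,0,0,0,0};
  const int di[6] = {0,0,1,-1,0,0};
  const int dk[6] = {0,0,0,0,1,-1};
  for (int64_t p = 0; p < N; ++p) {
    if (!m[p] || L[p]) continue;
    ++next;
    stack.push_back(p);
    L[p] = next;
    while (!stack.empty()) {
      int64_t u = stack.back(); stack.pop_back();
      int64_t k = u / ((int64_t)ny * nx);
      int64_t r = u % ((int64_t)ny * nx);
      int64_t i = r / ny, j = r % ny;
      for (int q = 0; q < 6; ++q) {
        int jj = (int)j + dj[q], ii = (int)i + di[q], kk = (int)k + dk[q];
        if (jj < 0 || jj >= ny || ii < 0 || ii >= nx || kk < 0 || kk >= nz)
          continue;
        int64_t v = (int64_t)jj + (int64_t)ny * ((int64_t)ii + (int64_t)nx * kk);
        if (m[v] && !L[v]) { L[v] = next; stack.push_back(v); }
      }
    }
  }
  return lab;
}

// -------------------------------------------------------- distance queries

// min distance of each query point to a triangle soup: exact minimum via
// an AABB tree (median split over triangle centroids, branch-and-bound
// nearest query)
struct BVHNode { double lo[3], hi[3]; int left, right, begin, end; };

static double d2_point_box(const double* p, const double* lo,
                           const double* hi) {
  double d2 = 0.0;
  for (int d = 0; d < 3; ++d) {
    double v = p[d] < lo[d] ? lo[d] - p[d] : (p[d] > hi[d] ? p[d] - hi[d] : 0.0);
    d2 += v * v;
  }
  return d2;
}

// [[Rcpp::export(name = ".cpp_points_to_mesh")]]
NumericVector points_to_mesh(NumericMatrix P, NumericMatrix V,
                             IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  std::vector<double> TA(3*nf), TB(3*nf), TC(3*nf), cen(3*nf);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0)-1, b = F(f,1)-1, c = F(f,2)-1;
    for (int d = 0; d < 3; ++d) {
      TA[3*f+d] = V(a,d); TB[3*f+d] = V(b,d); TC[3*f+d] = V(c,d);
      cen[3*f+d] = (TA[3*f+d] + TB[3*f+d] + TC[3*f+d]) / 3.0;
    }
  }
  std::vector<int> order(nf);
  for (int f = 0; f < nf; ++f) order[f] = f;
  std::vector<BVHNode> nodes;
  nodes.reserve(2 * nf / 8 + 4);

  // recursive build with an explicit work stack
  struct Task { int begin, end, parent, slot; };
  std::vector<Task> work;
  work.push_back({0, nf, -1, 0});
  while (!work.empty()) {
    Task t = work.back(); work.pop_back();
    BVHNode nd;
    for (int d = 0; d < 3; ++d) { nd.lo[d] = 1e300; nd.hi[d] = -1e300; }
    for (int q = t.begin; q < t.end; ++q) {
      int f = order[q];
      for (int d = 0; d < 3; ++d) {
        double mn = std::min(TA[3*f+d], std::min(TB[3*f+d], TC[3*f+d]));
        double mx = std::max(TA[3*f+d], std::max(TB[3*f+d], TC[3*f+d]));
        if (mn < nd.lo[d]) nd.lo[d] = mn;
        if (mx > nd.hi[d]) nd.hi[d] = mx;
      }
    }
    int id = (int)nodes.size();
    if (t.parent >= 0) {
      if (t.slot == 0) nodes[t.parent].left = id;
      else nodes[t.parent].right = id;
    }
    if (t.end - t.begin <= 8) {
      nd.left = nd.right = -1; nd.begin = t.begin; nd.end = t.end;
      nodes.push_back(nd);
      continue;
    }
    // split along the widest axis of the centroid extent
    double clo[3] = {1e300,1e300,1e300}, chi[3] = {-1e300,-1e300,-1e300};
    for (int q = t.begin; q < t.end; ++q) {
      int f = order[q];
      for (int d = 0; d < 3; ++d) {
        if (cen[3*f+d] < clo[d]) clo[d] = cen[3*f+d];
        if (cen[3*f+d] > chi[d]) chi[d] = cen[3*f+d];
      }
    }
    int axis = 0;
    for (int d = 1; d < 3; ++d)
      if (chi[d] - clo[d] > chi[axis] - clo[axis]) axis = d;
    int mid = (t.begin + t.end) / 2;
    std::nth_element(order.begin() + t.begin, order.begin() + mid,
                     order.begin() + t.end,
                     [&](int a, int b) { return cen[3*a+axis] < cen[3*b+axis]; });
    nd.begin = nd.end = -1;
    nodes.push_back(nd);
    work.push_back({t.begin, mid, id, 0});
    work.push_back({mid, t.end, id, 1});
  }

  NumericVector out(np);
  std::vector<int> stack;
  stack.reserve(64);
  for (int p = 0; p < np; ++p) {
    double pt[3] = { P(p,0), P(p,1), P(p,2) };
    double best2 = 1e300;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      const BVHNode& nd = nodes[id];
      if (d2_point_box(pt, nd.lo, nd.hi) >= best2) continue;
      if (nd.left < 0) {
        for (int q = nd.begin; q < nd.end; ++q) {
          int f = order[q];
          double d2 = d2_point_tri(pt, &TA[3*f], &TB[3*f], &TC[3*f]);
          if (d2 < best2) best2 = d2;
        }
      } else {
        double dl = d2_point_box(pt, nodes[nd.left].lo, nodes[nd.left].hi);
        double dr = d2_point_box(pt, nodes[nd.right].lo, nodes[nd.right].hi);
        // push the farther child first so the nearer is explored first
        if (dl < dr) { stack.push_back(nd.right); stack.push_back(nd.left); }
        else { stack.push_back(nd.left); stack.push_back(nd.right); }
      }
    }
    out[p] = std::sqrt(best2);
  }
  return out;
}

// min distance of each query point to a polyline (segment-wise)
// [[Rcpp::export(name = ".cpp_points_to_polyline")]]
NumericVector points_to_polyline(NumericMatrix P, NumericMatrix L) {
  int np = P.nrow(), nl = L.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double pt[3] = { P(p,0), P(p,1), P(p,2) };
    double best = 1e300;
    for (int s = 0; s + 1 < nl; ++s) {
      double a[3] = { L(s,0), L(s,1), L(s,2) };
      double b[3] = { L(s+1,0), L(s+1,1), L(s+1,2) };
      double ab[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
      double ap[3] = { pt[0]-a[0], pt[1]-a[1], pt[2]-a[2] };
      double denom = ab[0]*ab[0] + ab[1]*ab[1] + ab[2]*ab[2];
      double t = denom > 0 ? (ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2])/denom : 0.0;
      if (t < 0) t = 0; if (t > 1) t = 1;
      double q[3] = { a[0]+t*ab[0], a[1]+t*ab[1], a[2]+t*ab[2] };
      double d2 = sqdist3(pt, q);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// ------------------------------------------------------- polygon scan fill

// even-odd scanline fill of one closed polygon at integer pixel centres;
// pixels whose centre lies on the boundary are filled (eps inclusion)
// [[Rcpp::export(name = ".cpp_fill_polygon")]]
LogicalMatrix fill_polygon(NumericVector pr, NumericVector pc, int nr,
                           int nc) {
  LogicalMatrix out(nr, nc);
  int n = pr.size();
  if (n < 3) return out;
  const double eps = 1e-9;
  std::vector<double> xs;
  for (int y = 1; y <= nr; ++y) {
    xs.clear();
    double Y = (double)y;
    for (int e = 0; e + 1 < n; ++e) {
      double r1 = pr[e], c1 = pc[e], r2 = pr[e+1], c2 = pc[e+1];
      if ((r1 > Y) != (r2 > Y)) {
        double t = (Y - r1) / (r2 - r1);
        xs.push_back(c1 + t * (c2 - c1));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t q = 0; q + 1 < xs.size(); q += 2) {
      int j0 = (int)std::ceil(xs[q] - eps);
      int j1 = (int)std::floor(xs[q+1] + eps);
      if (j0 < 1) j0 = 1;
      if (j1 > nc) j1 = nc;
      for (int j = j0; j <= j1; ++j) out(y - 1, j - 1) = true;
    }
  }
  // boundary pixels belong to the filled region: mark pixel centres lying
  // exactly on an edge (relevant for integer-coordinate manual polygons;
  // iso-contours at half-integer positions never hit centres)
  for (int e = 0; e + 1 < n; ++e) {
    double r1 = pr[e], c1 = pc[e], r2 = pr[e+1], c2 = pc[e+1];
    if (std::abs(r2 - r1) < eps) {                 // horizontal edge
      double rr = std::round(r1);
      if (std::abs(rr - r1) < eps && rr >= 1 && rr <= nr) {
        int a = (int)std::ceil(std::min(c1, c2) - eps);
        int b = (int)std::floor(std::max(c1, c2) + eps);
        for (int c = std::max(1, a); c <= std::min(nc, b); ++c)
          out((int)rr - 1, c - 1) = true;
      }
    } else {
      int a = (int)std::ceil(std::min(r1, r2) - eps);
      int b = (int)std::floor(std::max(r1, r2) + eps);
      for (int rr = std::max(1, a); rr <= std::min(nr, b); ++rr) {
        double t = (rr - r1) / (r2 - r1);
        if (t < -eps || t > 1 + eps) continue;
        double cc = c1 + t * (c2 - c1);
        double cr = std::round(cc);
        if (std::abs(cr - cc) < eps && cr >= 1 && cr <= nc)
          out(rr - 1, (int)cr - 1) = true;
      }
    }
  }
  return out;
}
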