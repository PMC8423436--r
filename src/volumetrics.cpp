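#include <Rcpp.h>
#include <queue>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// 26-connected component labelling of a binary 3D field.
// Returns per-component voxel counts and a flag for contact with any grid face.
// [[Rcpp::export]]
List cpp_cc_label(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n);
  std::vector<int> counts, touch;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++cur;
    counts.push_back(0);
    touch.push_back(0);
    stack.clear();
    stack.push_back(s);
    labels[s] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      counts[cur - 1]++;
      if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)
        touch[cur - 1] = 1;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            if (!di && !dj && !dk) continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && !labels[w]) {
              labels[w] = cur;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return List::create(_["labels"] = labels, _["n"] = cur,
                      _["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["touches"] = LogicalVector(touch.begin(), touch.end()));
}

// One pass over a labelled volume: per-label voxel count, bounding box
// (1-based, inclusive) and grid-face contact.
// [[Rcpp::export]]
List cpp_label_stats(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int maxlab = 0;
  for (R_xlen_t s = 0; s < n; ++s)
    if (labels[s] > maxlab) maxlab = labels[s];
  IntegerVector count(maxlab), touch(maxlab);
  IntegerMatrix bbox(maxlab, 6);
  for (int l = 0; l < maxlab; ++l) {
    bbox(l, 0) = nx + 1; bbox(l, 1) = 0;
    bbox(l, 2) = ny + 1; bbox(l, 3) = 0;
    bbox(l, 4) = nz + 1; bbox(l, 5) = 0;
  }
  R_xlen_t s = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++s) {
        int l = labels[s];
        if (l <= 0) continue;
        --l;
        count[l]++;
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)
          touch[l] = 1;
        if (i + 1 < bbox(l, 0)) bbox(l, 0) = i + 1;
        if (i + 1 > bbox(l, 1)) bbox(l, 1) = i + 1;
        if (j + 1 < bbox(l, 2)) bbox(l, 2) = j + 1;
        if (j + 1 > bbox(l, 3)) bbox(l, 3) = j + 1;
        if (k + 1 < bbox(l, 4)) bbox(l, 4) = k + 1;
        if (k + 1 > bbox(l, 5)) bbox(l, 5) = k + 1;
      }
  return List::create(_["count"] = count, _["touches"] = touch, _["bbox"] = bbox);
}

// Separable Gaussian smoothing, sigma in voxels per axis, zero padding
// (background outside the grid).
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector field, IntegerVector dims, NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(field.begin(), field.end()), b(n);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * rad + 1);
    double tot = 0;
    for (int t = -rad; t <= rad; ++t) {
      ker[t + rad] = std::exp(-0.5 * t * t / (s * s));
      tot += ker[t + rad];
    }
    for (double &w : ker) w /= tot;
    const int len = nd[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    const int d1 = (ax == 0) ? 1 : 0;
    const int d2 = (ax == 2) ? 1 : 2;
    for (int q = 0; q < nd[d2]; ++q)
      for (int p = 0; p < nd[d1]; ++p) {
        R_xlen_t base = (R_xlen_t)p * stride[d1] + (R_xlen_t)q * stride[d2];
        for (int i = 0; i < len; ++i) {
          double acc = 0;
          int t0 = std::max(-rad, -i), t1 = std::min(rad, len - 1 - i);
          for (int t = t0; t <= t1; ++t)
            acc += ker[t + rad] * a[base + (R_xlen_t)(i + t) * st];
          b[base + (R_xlen_t)i * st] = acc;
        }
      }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

static const double DT_INF = 1e30;

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double s2) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double inter;
    while (true) {
      int vk = v[k];
      inter = ((f[q] + s2 * q * q) - (f[vk] + s2 * vk * vk)) / (2.0 * s2 * (q - vk));
      if (inter <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = s2 * dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (physical units) from each foreground voxel to
// the nearest background voxel center; anisotropic spacing respected.
// [[Rcpp::export]]
NumericVector cpp_sqedt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(n);
  for (R_xlen_t s = 0; s < n; ++s) a[s] = mask[s] ? DT_INF : 0.0;
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  int maxd = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxd), d(maxd), z(maxd + 1);
  std::vector<int> v(maxd);
  for (int ax = 0; ax < 3; ++ax) {
    const int len = nd[ax];
    const R_xlen_t st = stride[ax];
    const double s2 = spacing[ax] * spacing[ax];
    const int d1 = (ax == 0) ? 1 : 0;
    const int d2 = (ax == 2) ? 1 : 2;
    for (int q = 0; q < nd[d2]; ++q)
      for (int p = 0; p < nd[d1]; ++p) {
        R_xlen_t base = (R_xlen_t)p * stride[d1] + (R_xlen_t)q * stride[d2];
        bool any_fin = false;
        for (int i = 0; i < len; ++i) {
          f[i] = a[base + (R_xlen_t)i * st];
          if (f[i] < DT_INF) any_fin = true;
        }
        if (!any_fin) continue;  // no background reachable through this line yet
        dt1d(f, d, v, z, len, s2);
        for (int i = 0; i < len; ++i) a[base + (R_xlen_t)i * st] = d[i];
      }
  }
  return NumericVector(a.begin(), a.end());
}

// Dijkstra shortest paths over foreground voxels, 26-neighbourhood, edge
// weight = physical step length times the mean of the endpoint node costs
// (cost length 0 means uniform). Returns distances (Inf if unreachable /
// background) and 1-based parents (0 = none).
// [[Rcpp::export]]
List cpp_dijkstra(LogicalVector mask, IntegerVector dims, NumericVector spacing,
                  int source, NumericVector cost) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const bool has_cost = cost.size() == n;
  NumericVector dist(n, R_PosInf);
  IntegerVector parent(n);
  double step[3][3][3];
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        step[di + 1][dj + 1][dk + 1] = std::sqrt(
            di * di * spacing[0] * spacing[0] + dj * dj * spacing[1] * spacing[1] +
            dk * dk * spacing[2] * spacing[2]);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  if (source < 0 || source >= n || !mask[source])
    stop("dijkstra source is not a foreground voxel");
  dist[source] = 0.0;
  pq.push(Node(0.0, source));
  while (!pq.empty()) {
    Node t = pq.top();
    pq.pop();
    R_xlen_t u = t.second;
    if (t.first > dist[u]) continue;
    int i = (int)(u % nx), j = (int)((u / nx) % ny), k = (int)(u / ((R_xlen_t)nx * ny));
    double cu = has_cost ? cost[u] : 1.0;
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          if (!di && !dj && !dk) continue;
          R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
          if (!mask[w]) continue;
          double cw = has_cost ? cost[w] : 1.0;
          double nd2 = dist[u] + step[di + 1][dj + 1][dk + 1] * 0.5 * (cu + cw);
          if (nd2 < dist[w]) {
            dist[w] = nd2;
            parent[w] = (int)(u + 1);
            pq.push(Node(nd2, w));
          }
        }
      }
    }
  }
  return List::create(_["dist"] = dist, _["parent"] = parent);
}

// Iso-surface by marching tetrahedra on the Freudenthal 6-tet cube split.
// Grid point (i,j,k) (0-based) sits at origin + ((i+0.5)sx,(j+0.5)sy,(k+0.5)sz)
// (voxel-center convention). Triangles oriented with outward normals
// (inside = field > level). Vertices welded by grid-edge identity, so closed
// level sets give watertight meshes.
// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims, NumericVector spacing,
                    NumericVector origin, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  static const int COFF[8][3] = {{0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
                                 {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
  static const int TETS[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                                 {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  const uint64_t NT = (uint64_t)nx * ny * nz;
  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  double cval[8], cpos[8][3];
  uint64_t cid[8];

  auto vertex_on_edge = [&](int a, int b) -> int {
    uint64_t ga = cid[a], gb = cid[b];
    uint64_t key = ga < gb ? ga * NT + gb : gb * NT + ga;
    std::unordered_map<uint64_t, int>::iterator it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (level - cval[a]) / (cval[b] - cval[a]);
    int id = (int)vx.size();
    vx.push_back(cpos[a][0] + t * (cpos[b][0] - cpos[a][0]));
    vy.push_back(cpos[a][1] + t * (cpos[b][1] - cpos[a][1]));
    vz.push_back(cpos[a][2] + t * (cpos[b][2] - cpos[a][2]));
    vmap.emplace(key, id);
    return id;
  };
  auto emit = [&](int A, int B, int C, const double *inPt) {
    double e1x = vx[B] - vx[A], e1y = vy[B] - vy[A], e1z = vz[B] - vz[A];
    double e2x = vx[C] - vx[A], e2y = vy[C] - vy[A], e2z = vz[C] - vz[A];
    double nxv = e1y * e2z - e1z * e2y;
    double nyv = e1z * e2x - e1x * e2z;
    double nzv = e1x * e2y - e1y * e2x;
    double gx = (vx[A] + vx[B] + vx[C]) / 3.0 - inPt[0];
    double gy = (vy[A] + vy[B] + vy[C]) / 3.0 - inPt[1];
    double gz = (vz[A] + vz[B] + vz[C]) / 3.0 - inPt[2];
    if (nxv * gx + nyv * gy + nzv * gz < 0) std::swap(B, C);
    tri.push_back(A);
    tri.push_back(B);
    tri.push_back(C);
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + COFF[c][0], cj = j + COFF[c][1], ck = k + COFF[c][2];
          uint64_t g = (uint64_t)ci + (uint64_t)nx * ((uint64_t)cj + (uint64_t)ny * ck);
          cid[c] = g;
          cval[c] = field[(R_xlen_t)g];
          if (cval[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int c = 0; c < 8; ++c) {
          cpos[c][0] = origin[0] + (i + COFF[c][0] + 0.5) * sx;
          cpos[c][1] = origin[1] + (j + COFF[c][1] + 0.5) * sy;
          cpos[c][2] = origin[2] + (k + COFF[c][2] + 0.5) * sz;
        }
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int in[4], out[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cval[T[c]] > level) in[nin++] = T[c]; else out[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1) {
            int A = in[0];
            emit(vertex_on_edge(A, out[0]), vertex_on_edge(A, out[1]),
                 vertex_on_edge(A, out[2]), cpos[A]);
          } else if (nin == 3) {
            int D = out[0];
            emit(vertex_on_edge(in[0], D), vertex_on_edge(in[1], D),
                 vertex_on_edge(in[2], D), cpos[in[0]]);
          } else {
            int A = in[0], B = in[1], C = out[0], D = out[1];
            int vac = vertex_on_edge(A, C), vad = vertex_on_edge(A, D);
            int vbc = vertex_on_edge(B, C), vbd = vertex_on_edge(B, D);
            emit(vac, vad, vbd, cpos[A]);
            emit(vac, vbd, vbc, cpos[A]);
          }
        }
      }

  int nV = (int)vx.size(), nF = (int)tri.size() / 3;
  NumericMatrix verts(nV, 3);
  for (int v = 0; v < nV; ++v) {
    verts(v, 0) = vx[v];
    verts(v, 1) = vy[v];
    verts(v, 2) = vz[v];
  }
  IntegerMatrix faces(nF, 3);
  for (int f2 = 0; f2 < nF; ++f2) {
    faces(f2, 0) = tri[3 * f2] + 1;
    faces(f2, 1) = tri[3 * f2 + 1] + 1;
    faces(f2, 2) = tri[3 * f2 + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
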