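// Voxel-grid kernels shared by the centerline and calcium modules:
// exact anisotropic Euclidean distance transform, Dijkstra shortest paths
// on the 26-connected voxel graph, connected-component labeling, and the
// region-growing fixpoint. All tie-breaking is lexicographic in the
// linearized voxel index so results are bit-reproducible.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double BIG = 1e20;

// 1-D squared distance transform (Felzenszwalb & Huttenlocher), sample
// locations at i*sp so anisotropic spacing is handled exactly.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double sp) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double xq = q * sp, s;
    while (true) {
      double xp = v[k] * sp;
      s = ((f[q] + xq * xq) - (f[v[k]] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double x = q * sp;
    while (z[k + 1] < x) k++;
    double dx = x - v[k] * sp;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest voxel
// where mask == 0. Voxels of an all-foreground image get BIG.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] == 0 ? 0.0 : BIG;

  std::vector<double> f(std::max(n1, std::max(n2, n3)));
  std::vector<double> d(f.size());

  // pass along x (fastest-varying)
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; i++) f[i] = out[base + i];
      dt1d(f, d, n1, spacing[0]);
      for (int i = 0; i < n1; i++) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, n2, spacing[1]);
      for (int j = 0; j < n2; j++) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // pass along z
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      R_xlen_t stride = (R_xlen_t)n1 * n2;
      for (int k = 0; k < n3; k++) f[k] = out[base + stride * k];
      dt1d(f, d, n3, spacing[2]);
      for (int k = 0; k < n3; k++) out[base + stride * k] = d[k];
    }
  return out;
}

struct Nbr {
  int di, dj, dk;
  double len;
};

static std::vector<Nbr> neighbors26(const NumericVector& spacing) {
  std::vector<Nbr> nb;
  for (int dk = -1; dk <= 1; dk++)
    for (int dj = -1; dj <= 1; dj++)
      for (int di = -1; di <= 1; di++) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        double dx = di * spacing[0], dy = dj * spacing[1], dz = dk * spacing[2];
        Nbr b;
        b.di = di;
        b.dj = dj;
        b.dk = dk;
        b.len = std::sqrt(dx * dx + dy * dy + dz * dz);
        nb.push_back(b);
      }
  return nb;
}

// Dijkstra over mask voxels, 26-connectivity, edge weight =
// euclidean step * (cost[u] + cost[v]) / 2. cost may be length 1
// (uniform) or one value per voxel. seed is a 0-based linear index.
// Ties between equal tentative distances keep the smaller parent index.
// [[Rcpp::export(name = ".dijkstra_cpp")]]
List dijkstra_cpp(IntegerVector mask, IntegerVector dim,
                  NumericVector spacing, int seed, NumericVector cost) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const bool unif = cost.size() == 1;
  if (seed < 0 || seed >= n || mask[seed] == 0)
    stop("seed voxel outside the mask");

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> parent(n, -1);
  std::vector<Nbr> nb = neighbors26(spacing);

  typedef std::pair<double, int> QE;  // (dist, idx): ties pop smaller idx
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[seed] = 0.0;
  pq.push(QE(0.0, seed));

  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    int k = u / (n1 * n2);
    int r = u - k * n1 * n2;
    int j = r / n1;
    int i = r - j * n1;
    double cu = unif ? cost[0] : cost[u];
    for (size_t m = 0; m < nb.size(); m++) {
      int ii = i + nb[m].di, jj = j + nb[m].dj, kk = k + nb[m].dk;
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      int v = ii + n1 * (jj + n2 * kk);
      if (mask[v] == 0) continue;
      double cv = unif ? cost[0] : cost[v];
      double w = nb[m].len * 0.5 * (cu + cv);
      double nd = dist[u] + w;
      if (nd < dist[v] || (nd == dist[v] && parent[v] > u)) {
        dist[v] = nd;
        parent[v] = u;
        pq.push(QE(nd, v));
      }
    }
  }
  return List::create(Named("dist") = NumericVector(dist.begin(), dist.end()),
                      Named("parent") = IntegerVector(parent.begin(), parent.end()));
}

// 26-connected component labeling; labels assigned by BFS in lexicographic
// scan order, so label 1 contains the lowest linear index of any component.
// [[Rcpp::export(name = ".label_cc_cpp")]]
IntegerVector label_cc_cpp(IntegerVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(n, 0);
  std::vector<int> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    queue.clear();
    queue.push_back((int)s);
    size_t head = 0;
    while (head < queue.size()) {
      int u = queue[head++];
      int k = u / (n1 * n2);
      int r = u - k * n1 * n2;
      int j = r / n1;
      int i = r - j * n1;
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
              continue;
            int v = ii + n1 * (jj + n2 * kk);
            if (mask[v] != 0 && lab[v] == 0) {
              lab[v] = next;
              queue.push_back(v);
            }
          }
    }
  }
  return lab;
}

// Region-growing fixpoint: starting from seed voxels, repeatedly absorb
// 26-neighbors inside `allowed` whose image value exceeds `thr`, until no
// voxel can be added. BFS order; the fixpoint itself is order-independent.
// [[Rcpp::export(name = ".grow_cpp")]]
IntegerVector grow_cpp(NumericVector image, IntegerVector seeds,
                       IntegerVector allowed, IntegerVector dim, double thr) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector out(n, 0);
  std::vector<int> queue;
  for (R_xlen_t s = 0; s < n; s++)
    if (seeds[s] != 0) {
      out[s] = 1;
      queue.push_back((int)s);
    }
  size_t head = 0;
  while (head < queue.size()) {
    int u = queue[head++];
    int k = u / (n1 * n2);
    int r = u - k * n1 * n2;
    int j = r / n1;
    int i = r - j * n1;
    for (int dk = -1; dk <= 1; dk++)
      for (int dj = -1; dj <= 1; dj++)
        for (int di = -1; di <= 1; di++) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
            continue;
          int v = ii + n1 * (jj + n2 * kk);
          if (out[v] == 0 && allowed[v] != 0 && image[v] > thr) {
            out[v] = 1;
            queue.push_back(v);
          }
        }
  }
  return out;
}
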