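// 3-D volume primitives: exact Euclidean distance transform
// (Felzenszwalb-Huttenlocher, separable), connected-component labelling and
// marker-based watershed flooding. 2-D images are handled as single-slice
// volumes by the R callers.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared-distance lower envelope
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims) {
  int nr = dims[0], nc = dims[1], nz = dims[2];
  size_t n = (size_t)nr * nc * nz;
  // large finite stand-in for "no background yet": IEEE inf would produce
  // inf - inf = NaN inside the lower-envelope intersections
  const double FAR = 1e15;
  std::vector<double> d(n);
  for (size_t i = 0; i < n; i++) d[i] = mask[i] ? FAR : 0.0;
  auto idx = [&](int r, int c, int z) {
    return (size_t)r + (size_t)nr * c + (size_t)nr * nc * z;
  };
  std::vector<double> f(std::max(nr, std::max(nc, nz))),
      o(std::max(nr, std::max(nc, nz)));
  // rows
  for (int z = 0; z < nz; z++)
    for (int c = 0; c < nc; c++) {
      for (int r = 0; r < nr; r++) f[r] = d[idx(r, c, z)];
      edt1d(f, o, nr);
      for (int r = 0; r < nr; r++) d[idx(r, c, z)] = o[r];
    }
  // cols
  for (int z = 0; z < nz; z++)
    for (int r = 0; r < nr; r++) {
      for (int c = 0; c < nc; c++) f[c] = d[idx(r, c, z)];
      edt1d(f, o, nc);
      for (int c = 0; c < nc; c++) d[idx(r, c, z)] = o[c];
    }
  // slices
  if (nz > 1)
    for (int c = 0; c < nc; c++)
      for (int r = 0; r < nr; r++) {
        for (int z = 0; z < nz; z++) f[z] = d[idx(r, c, z)];
        edt1d(f, o, nz);
        for (int z = 0; z < nz; z++) d[idx(r, c, z)] = o[z];
      }
  NumericVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = std::sqrt(d[i]);
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dims,
                      int connectivity) {
  int nr = dims[0], nc = dims[1], nz = dims[2];
  size_t n = (size_t)nr * nc * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::vector<int> dr, dc, dz;
  for (int z = -1; z <= 1; z++)
    for (int c = -1; c <= 1; c++)
      for (int r = -1; r <= 1; r++) {
        if (r == 0 && c == 0 && z == 0) continue;
        int manh = std::abs(r) + std::abs(c) + std::abs(z);
        if (connectivity == 6 && manh > 1) continue;
        dr.push_back(r); dc.push_back(c); dz.push_back(z);
      }
  int next = 0;
  std::vector<size_t> stack;
  auto idx = [&](int r, int c, int z) {
    return (size_t)r + (size_t)nr * c + (size_t)nr * nc * z;
  };
  for (size_t start = 0; start < n; start++) {
    if (!mask[start] || lab[start]) continue;
    next++;
    lab[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int z = cur / ((size_t)nr * nc);
      int rem = cur % ((size_t)nr * nc);
      int c = rem / nr, r = rem % nr;
      for (size_t k = 0; k < dr.size(); k++) {
        int r2 = r + dr[k], c2 = c + dc[k], z2 = z + dz[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || z2 < 0 || z2 >= nz)
          continue;
        size_t j = idx(r2, c2, z2);
        if (mask[j] && !lab[j]) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// marker-based watershed: flood `mask` from labelled `markers`, visiting
// voxels in decreasing `height` order (priority flood). Deterministic:
// ties broken by linear index.
// [[Rcpp::export(name = ".watershed3d")]]
IntegerVector watershed3d(NumericVector height, IntegerVector markers,
                          LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  int nr = dims[0], nc = dims[1], nz = dims[2];
  size_t n = (size_t)nr * nc * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;
  std::vector<int> dr, dc, dz;
  for (int z = -1; z <= 1; z++)
    for (int c = -1; c <= 1; c++)
      for (int r = -1; r <= 1; r++) {
        if (r == 0 && c == 0 && z == 0) continue;
        int manh = std::abs(r) + std::abs(c) + std::abs(z);
        if (connectivity == 6 && manh > 1) continue;
        dr.push_back(r); dc.push_back(c); dz.push_back(z);
      }
  typedef std::pair<double, size_t> Node;  // (-height, index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (size_t i = 0; i < n; i++)
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(Node(-height[i], i));
    }
  auto idx = [&](int r, int c, int z) {
    return (size_t)r + (size_t)nr * c + (size_t)nr * nc * z;
  };
  while (!pq.empty()) {
    size_t cur = pq.top().second;
    pq.pop();
    int z = cur / ((size_t)nr * nc);
    int rem = cur % ((size_t)nr * nc);
    int c = rem / nr, r = rem % nr;
    for (size_t k = 0; k < dr.size(); k++) {
      int r2 = r + dr[k], c2 = c + dc[k], z2 = z + dz[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || z2 < 0 || z2 >= nz)
        continue;
      size_t j = idx(r2, c2, z2);
      if (mask[j] && lab[j] == 0) {
        lab[j] = lab[cur];
        pq.push(Node(-height[j], j));
      }
    }
  }
  return lab;
}
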