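#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[ra < rb ? rb : ra] = (ra < rb ? ra : rb);
}

// Label foreground voxels of a 3D logical array into connected components
// using the full 26-neighbourhood. Returns an integer array of the same
// dimensions: 0 = background, components numbered 1..k in decreasing voxel
// count (label 1 is always the largest component).
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;

  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  // Scan: union each foreground voxel with already-visited neighbours
  // (half of the 26-neighbourhood, lexicographically earlier).
  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        R_xlen_t idx = (R_xlen_t)i + (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        if (!mask[idx]) continue;
        for (int dk = -1; dk <= 0; ++dk) {
          int kk = k + dk;
          if (kk < 0) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = j + dj;
            if (jj < 0 || jj >= d2) continue;
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di;
              if (ii < 0 || ii >= d1) continue;
              // only strictly-earlier voxels in scan order
              if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
              R_xlen_t nidx = (R_xlen_t)ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
              if (mask[nidx]) uf_union(parent, (int)idx, (int)nidx);
            }
          }
        }
      }
    }
  }

  // Provisional labels from union-find roots.
  IntegerVector out(n, 0);
  out.attr("dim") = dims;
  std::vector<int> root_label((size_t)n, 0);
  std::vector<R_xlen_t> counts;  // per provisional label voxel count
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = uf_find(parent, (int)i);
    if (root_label[r] == 0) {
      root_label[r] = ++next;
      counts.push_back(0);
    }
    out[i] = root_label[r];
    counts[root_label[r] - 1]++;
  }

  // Renumber so that label 1 is the largest component.
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return counts[a] > counts[b]; });
  std::vector<int> remap(next);
  for (int i = 0; i < next; ++i) remap[order[i]] = i + 1;
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] > 0) out[i] = remap[out[i] - 1];

  out.attr("n_components") = next;
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void dt1d(const double *f, double *d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform of a 3D logical array: for every
// foreground voxel, the distance (in voxel units) to the nearest background
// voxel centre; 0 on background. Separable squared-distance passes along
// each axis.
// [[Rcpp::export(name = ".edt_3d")]]
NumericVector edt_3d(LogicalVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const double INF = 1e18;

  NumericVector out(n);
  out.attr("dim") = dims;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  int maxd = std::max(d1, std::max(d2, d3));
  std::vector<double> f(maxd), d(maxd);
  std::vector<int> v(maxd);
  std::vector<double> z(maxd + 1);

  // pass along axis 1 (fastest-varying)
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
      for (int i = 0; i < d1; ++i) f[i] = out[base + i];
      dt1d(f.data(), d.data(), d1, v, z);
      for (int i = 0; i < d1; ++i) out[base + i] = d[i];
    }
  // pass along axis 2
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)d1 * d2 * k;
      for (int j = 0; j < d2; ++j) f[j] = out[base + (R_xlen_t)d1 * j];
      dt1d(f.data(), d.data(), d2, v, z);
      for (int j = 0; j < d2; ++j) out[base + (R_xlen_t)d1 * j] = d[j];
    }
  // pass along axis 3
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)d1 * j;
      R_xlen_t stride = (R_xlen_t)d1 * d2;
      for (int k = 0; k < d3; ++k) f[k] = out[base + stride * k];
      dt1d(f.data(), d.data(), d3, v, z);
      for (int k = 0; k < d3; ++k) out[base + stride * k] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}
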