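// Voxelization, periodic Euclidean distance transform, and watershed pore
// detection for fiber networks in a cubic periodic box.
//
// The EDT is the exact squared-distance transform computed separably with
// the lower-envelope (parabola) algorithm; periodicity is handled by
// running each 1-D pass on a periodically tripled row and keeping the
// middle copy, which covers every minimal image.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <numeric>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
IntegerVector voxelize_cpp(NumericMatrix centers, NumericVector radii,
                           double box, double h, int n, bool partial = false) {
  IntegerVector occ((size_t)n * n * n);
  // partial containment marks any voxel the sphere touches (margin half a
  // voxel diagonal); center containment is unbiased in expectation
  const double pad = partial ? h * std::sqrt(3.0) / 2.0 : 0.0;
  for (int p = 0; p < centers.nrow(); ++p) {
    double r = radii[p] + pad;
    double cx = centers(p,0), cy = centers(p,1), cz = centers(p,2);
    int i0 = (int)std::floor((cx - r) / h), i1 = (int)std::floor((cx + r) / h);
    int j0 = (int)std::floor((cy - r) / h), j1 = (int)std::floor((cy + r) / h);
    int k0 = (int)std::floor((cz - r) / h), k1 = (int)std::floor((cz + r) / h);
    double r2 = r * r;
    for (int k = k0; k <= k1; ++k) {
      double dz = (k + 0.5) * h - cz;
      int kw = ((k % n) + n) % n;
      for (int j = j0; j <= j1; ++j) {
        double dy = (j + 0.5) * h - cy;
        int jw = ((j % n) + n) % n;
        double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = (i + 0.5) * h - cx;
          if (dx * dx + dyz <= r2) {
            int iw = ((i % n) + n) % n;
            occ[iw + (size_t)n * (jw + (size_t)n * kw)] = 1;
          }
        }
      }
    }
  }
  return occ;
}

// 1-D squared distance transform (lower envelope of parabolas); sites with
// f = INF contribute nothing
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  if (k < 0) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// one periodic pass along a given stride; 'line' has length len, values are
// current squared distances; tripled to emulate periodic images
static void pass_periodic(std::vector<double>& grid, int nx, int ny, int nz,
                          int axis) {
  int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> f(3 * (size_t)len), d(3 * (size_t)len);
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
  };
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      for (int q = 0; q < len; ++q) {
        double val;
        if (axis == 0) val = grid[idx(q, a, b)];
        else if (axis == 1) val = grid[idx(a, q, b)];
        else val = grid[idx(a, b, q)];
        f[q] = f[q + len] = f[q + 2 * (size_t)len] = val;
      }
      dt1d(f, d, 3 * len);
      for (int q = 0; q < len; ++q) {
        double val = d[q + len];
        if (axis == 0) grid[idx(q, a, b)] = val;
        else if (axis == 1) grid[idx(a, q, b)] = val;
        else grid[idx(a, b, q)] = val;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector edt_periodic_cpp(IntegerVector occ, int nx, int ny, int nz,
                               double h) {
  size_t total = (size_t)nx * ny * nz;
  if ((size_t)occ.size() != total) stop("occupancy size mismatch");
  bool any_occ = false;
  std::vector<double> g(total);
  for (size_t q = 0; q < total; ++q) {
    g[q] = occ[q] ? 0.0 : INF;
    if (occ[q]) any_occ = true;
  }
  if (!any_occ) stop("empty grid: distance transform undefined");
  pass_periodic(g, nx, ny, nz, 0);
  pass_periodic(g, nx, ny, nz, 1);
  pass_periodic(g, nx, ny, nz, 2);
  NumericVector out(total);
  for (size_t q = 0; q < total; ++q) out[q] = h * std::sqrt(g[q]);
  return out;
}

struct DSU {
  std::vector<int> parent;
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

// Watershed by immersion on the negated EDT with persistence-style merging:
// empty voxels are processed in order of decreasing EDT; a voxel with no
// processed neighbor founds a basin at a local maximum of the EDT; when
// basins meet, any basin whose peak rises less than merge_depth above the
// meeting level is absorbed (suppresses spurious shallow maxima).
// Returns the surviving basin peaks: voxel indices (0-based), EDT values,
// and per-basin voxel counts.
// [[Rcpp::export]]
List watershed_pores_cpp(NumericVector edt, int nx, int ny, int nz,
                         double merge_depth, bool periodic = true) {
  size_t total = (size_t)nx * ny * nz;
  if ((size_t)edt.size() != total) stop("edt size mismatch");
  std::vector<int> order;
  order.reserve(total);
  for (size_t q = 0; q < total; ++q)
    if (edt[q] > 0) order.push_back((int)q);
  if (order.empty())
    return List::create(_["index"] = IntegerVector(0),
                        _["value"] = NumericVector(0),
                        _["size"] = IntegerVector(0));
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return edt[a] > edt[b];
  });

  DSU dsu;
  dsu.parent.assign(total, -1);
  std::vector<double> peak(total, 0.0);
  std::vector<int> peak_idx(total, -1);
  std::vector<int> roots_buf;

  for (int v : order) {
    int vx = v % nx, vy = (v / nx) % ny, vz = v / (nx * ny);
    roots_buf.clear();
    for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
    for (int ox = -1; ox <= 1; ++ox) {
      if (!ox && !oy && !oz) continue;
      int x = vx + ox, y = vy + oy, z = vz + oz;
      if (periodic) {
        x = (x + nx) % nx; y = (y + ny) % ny; z = (z + nz) % nz;
      } else if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
        continue;
      int u = x + nx * (y + ny * z);
      if (dsu.parent[u] < 0) continue; // not processed yet
      int r = dsu.find(u);
      if (std::find(roots_buf.begin(), roots_buf.end(), r) == roots_buf.end())
        roots_buf.push_back(r);
    }
    if (roots_buf.empty()) {
      dsu.parent[v] = v;
      peak[v] = edt[v];
      peak_idx[v] = v;
      continue;
    }
    // attach to the basin with the highest peak
    int best = roots_buf[0];
    for (int r : roots_buf) if (peak[r] > peak[best]) best = r;
    dsu.parent[v] = best;
    for (int r : roots_buf) {
      if (r == best) continue;
      if (peak[r] - edt[v] <= merge_depth) { // shallow basin: absorb
        dsu.parent[r] = best;
      }
    }
  }

  // collect surviving roots and basin sizes
  std::vector<int> root_of(total, -1);
  std::vector<int> counts(total, 0);
  for (int v : order) {
    int r = dsu.find(v);
    root_of[v] = r;
    counts[r]++;
  }
  std::vector<int> pores;
  for (int v : order) if (root_of[v] == v) pores.push_back(v);
  IntegerVector idx(pores.size()), sz(pores.size());
  NumericVector val(pores.size());
  for (size_t q = 0; q < pores.size(); ++q) {
    idx[q] = peak_idx[pores[q]];
    val[q] = peak[pores[q]];
    sz[q] = counts[pores[q]];
  }
  return List::create(_["index"] = idx, _["value"] = val, _["size"] = sz);
}
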