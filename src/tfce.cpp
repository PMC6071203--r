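#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// union-find with path halving + union by size
static inline int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Threshold-free cluster enhancement of the positive part of a 3-D map.
// stat: full-grid values (column-major x,y,z); mask: same length.
// Midpoint rule over n_steps thresholds from 0 to max(stat in mask):
//   out[v] = sum_h extent(v,h)^E * h^H * dh
// where extent(v,h) is the size of v's connected supra-threshold cluster.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       LogicalVector mask, double E, double H,
                       int n_steps, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  if (stat.size() != nvox || mask.size() != nvox)
    stop("stat/mask length does not match grid dims");
  NumericVector out(nvox);

  // candidate voxels: in-mask, positive, finite
  std::vector<int> cand;
  cand.reserve(nvox);
  double hmax = 0.0;
  bool any_mask = false;
  for (int v = 0; v < nvox; ++v) {
    if (mask[v]) {
      any_mask = true;
      double s = stat[v];
      if (R_finite(s) && s > 0.0) {
        cand.push_back(v);
        if (s > hmax) hmax = s;
      }
    }
  }
  if (!any_mask) stop("empty mask");
  if (cand.empty() || hmax <= 0.0) return out;

  // sort candidates by value descending
  std::sort(cand.begin(), cand.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  // neighbourhood offsets
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int d = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (d == 0) continue;
        bool use = (connectivity == 26) ||
                   (connectivity == 18 && d <= 2) ||
                   (connectivity == 6 && d == 1);
        if (use) nb.push_back({dx, dy, dz});
      }

  std::vector<int> parent(nvox, -1), csize(nvox, 0);
  std::vector<int> active;
  active.reserve(cand.size());
  const double dh = hmax / n_steps;
  size_t ptr = 0;

  for (int s = n_steps; s >= 1; --s) {
    const double h = (s - 0.5) * dh;
    // activate voxels with stat >= h, merging with active neighbours
    while (ptr < cand.size() && stat[cand[ptr]] >= h) {
      int v = cand[ptr++];
      parent[v] = v;
      csize[v] = 1;
      active.push_back(v);
      int z = v / (nx * ny), rem = v % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (auto& o : nb) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (parent[w] < 0) continue;  // not active yet
        int rv = uf_find(parent, v), rw = uf_find(parent, w);
        if (rv != rw) {
          if (csize[rv] < csize[rw]) std::swap(rv, rw);
          parent[rw] = rv;
          csize[rv] += csize[rw];
        }
      }
    }
    // accumulate increment for every active voxel
    const double hh = std::pow(h, H) * dh;
    for (int v : active)
      out[v] += std::pow((double)csize[uf_find(parent, v)], E) * hh;
  }
  return out;
}
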