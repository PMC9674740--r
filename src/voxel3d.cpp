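#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Column-major 3D index helpers. Arrays arrive as flat vectors with dims
// d = (nrow, ncol, nslice) = (y, x, z) in the package's convention; the
// kernels below are agnostic to axis meaning.

static inline int idx3(int i, int j, int k, const int *d) {
  return i + d[0] * (j + d[1] * k);
}

static void neighbor_offsets(int connectivity, std::vector<int> &di,
                             std::vector<int> &dj, std::vector<int> &dk) {
  di.clear(); dj.clear(); dk.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// Label connected components of a binary mask. Returns integer labels
// (0 = background); labels are assigned in scan order, not by size.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const R_xlen_t n = mask.size();
  std::vector<int> di, dj, dk;
  neighbor_offsets(connectivity, di, dj, dk);
  const int m = (int)di.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int p = idx3(i, j, k, d);
        if (!mask[p] || lab[p]) continue;
        ++next;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          int q = stack.back(); stack.pop_back();
          int qi = q % d[0];
          int qj = (q / d[0]) % d[1];
          int qk = q / (d[0] * d[1]);
          for (int t = 0; t < m; ++t) {
            int ni = qi + di[t], nj = qj + dj[t], nk = qk + dk[t];
            if (ni < 0 || nj < 0 || nk < 0 ||
                ni >= d[0] || nj >= d[1] || nk >= d[2]) continue;
            int np = idx3(ni, nj, nk, d);
            if (mask[np] && !lab[np]) {
              lab[np] = next;
              stack.push_back(np);
            }
          }
        }
      }
  return lab;
}

static void blur_axis(std::vector<double> &v, std::vector<double> &tmp,
                      const int *d, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    kern[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += kern[t + r];
  }
  for (double &w : kern) w /= s;
  int len = d[axis];
  int stride = 1;
  for (int a = 0; a < axis; ++a) stride *= d[a];
  // iterate over all lines along `axis`
  int nlines = (int)(v.size() / len);
  std::vector<double> line(len);
  // enumerate line start offsets
  for (int k = 0; k < d[2]; ++k)
    for (int j = 0; j < d[1]; ++j)
      for (int i = 0; i < d[0]; ++i) {
        int coord[3] = {i, j, k};
        if (coord[axis] != 0) continue;
        int base = idx3(i, j, k, d);
        for (int t = 0; t < len; ++t) line[t] = v[base + t * stride];
        for (int t = 0; t < len; ++t) {
          double acc = 0.0;
          for (int u = -r; u <= r; ++u) {
            int p = t + u;
            if (p < 0) p = -p - 1;              // reflect
            if (p >= len) p = 2 * len - p - 1;
            acc += kern[u + r] * line[p];
          }
          tmp[base + t * stride] = acc;
        }
      }
  (void)nlines;
  v.swap(tmp);
}

// Separable anisotropic Gaussian blur with reflective boundaries.
// sigma is per-axis in voxel units, order matching dims.
// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector img, IntegerVector dims,
                         NumericVector sigma) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  std::vector<double> v(img.begin(), img.end());
  std::vector<double> tmp(v.size());
  for (int a = 0; a < 3; ++a) blur_axis(v, tmp, d, a, sigma[a]);
  return NumericVector(v.begin(), v.end());
}

// Chebyshev (cube) dilation by integer radius: separable max filter.
// [[Rcpp::export]]
LogicalVector cpp_dilate3d(LogicalVector mask, IntegerVector dims,
                           int radius) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  std::vector<char> v(mask.begin(), mask.end());
  std::vector<char> tmp(v.size());
  for (int axis = 0; axis < 3; ++axis) {
    int len = d[axis];
    int stride = 1;
    for (int a = 0; a < axis; ++a) stride *= d[a];
    for (int k = 0; k < d[2]; ++k)
      for (int j = 0; j < d[1]; ++j)
        for (int i = 0; i < d[0]; ++i) {
          int coord[3] = {i, j, k};
          if (coord[axis] != 0) continue;
          int base = idx3(i, j, k, d);
          for (int t = 0; t < len; ++t) {
            char hit = 0;
            int lo = std::max(0, t - radius), hi = std::min(len - 1, t + radius);
            for (int u = lo; u <= hi && !hit; ++u)
              hit = v[base + u * stride];
            tmp[base + t * stride] = hit;
          }
        }
    v.swap(tmp);
  }
  return LogicalVector(v.begin(), v.end());
}

// Stochastic blob growth (Eden-type aggregation) from a seed voxel inside
// an `allowed` region, using R's RNG so results are governed by set.seed().
// irregularity in [0,1]: 0 favours compact growth (tournament pick of the
// frontier voxel with most filled 6-neighbours), 1 is uniform frontier pick.
// Returns 1-based voxel indices in growth order; may be shorter than
// `target` if the blob runs out of room.
// [[Rcpp::export]]
IntegerVector cpp_grow_blob(LogicalVector allowed, IntegerVector dims,
                            int seed_idx0, int target, double irregularity) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const R_xlen_t n = allowed.size();
  std::vector<int> di6, dj6, dk6;
  neighbor_offsets(6, di6, dj6, dk6);
  std::vector<char> in_blob(n, 0), in_frontier(n, 0);
  std::vector<int> blob, frontier;
  blob.reserve(target);
  if (seed_idx0 < 0 || seed_idx0 >= n || !allowed[seed_idx0])
    return IntegerVector(0);
  auto push_neighbors = [&](int q) {
    int qi = q % d[0], qj = (q / d[0]) % d[1], qk = q / (d[0] * d[1]);
    for (size_t t = 0; t < di6.size(); ++t) {
      int ni = qi + di6[t], nj = qj + dj6[t], nk = qk + dk6[t];
      if (ni < 0 || nj < 0 || nk < 0 ||
          ni >= d[0] || nj >= d[1] || nk >= d[2]) continue;
      int np = idx3(ni, nj, nk, d);
      if (allowed[np] && !in_blob[np] && !in_frontier[np]) {
        in_frontier[np] = 1;
        frontier.push_back(np);
      }
    }
  };
  auto filled6 = [&](int q) {
    int qi = q % d[0], qj = (q / d[0]) % d[1], qk = q / (d[0] * d[1]);
    int c = 0;
    for (size_t t = 0; t < di6.size(); ++t) {
      int ni = qi + di6[t], nj = qj + dj6[t], nk = qk + dk6[t];
      if (ni < 0 || nj < 0 || nk < 0 ||
          ni >= d[0] || nj >= d[1] || nk >= d[2]) continue;
      if (in_blob[idx3(ni, nj, nk, d)]) ++c;
    }
    return c;
  };
  in_blob[seed_idx0] = 1;
  blob.push_back(seed_idx0);
  push_neighbors(seed_idx0);
  // Growth bias. Candidates are accepted with probability
  // (filled6/6)^4 * directional term: the compactness exponent keeps the
  // surface smooth at the scale of a voxel or two (detail below the
  // imaging resolution would be unrecoverable by construction), while
  // `irregularity` controls a random directional drift that elongates
  // and bends the blob at scales the imaging can resolve.
  const double gamma = 4.0;
  // random drift direction for this blob
  double ux = norm_rand(), uy = norm_rand(), uz = norm_rand();
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  if (un < 1e-12) { ux = 1; uy = 0; uz = 0; un = 1; }
  ux /= un; uy /= un; uz /= un;
  const int si = seed_idx0 % d[0];
  const int sj = (seed_idx0 / d[0]) % d[1];
  const int sk = seed_idx0 / (d[0] * d[1]);
  auto dir_weight = [&](int q) {
    if (irregularity <= 0) return 1.0;
    double vx = (q % d[0]) - si;
    double vy = ((q / d[0]) % d[1]) - sj;
    double vz = (q / (d[0] * d[1])) - sk;
    double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (vn < 1e-12) return 1.0;
    double proj = (vx * ux + vy * uy + vz * uz) / vn;  // cos angle
    return std::exp(2.0 * irregularity * (proj - 1.0));
  };
  while ((int)blob.size() < target && !frontier.empty()) {
    int pick = -1;
    for (int tries = 0; tries < 60; ++tries) {
      int a = (int)std::floor(unif_rand() * frontier.size());
      if (a >= (int)frontier.size()) a = (int)frontier.size() - 1;
      double w = std::pow(filled6(frontier[a]) / 6.0, gamma) *
                 dir_weight(frontier[a]);
      if (unif_rand() < w) { pick = a; break; }
    }
    if (pick < 0) {
      // fall back to the best-supported candidate
      int best = 0, bestn = -1;
      for (size_t t = 0; t < frontier.size(); ++t) {
        int nf = filled6(frontier[t]);
        if (nf > bestn) { bestn = nf; best = (int)t; }
      }
      pick = best;
    }
    int q = frontier[pick];
    frontier[pick] = frontier.back();
    frontier.pop_back();
    in_frontier[q] = 0;
    in_blob[q] = 1;
    blob.push_back(q);
    push_neighbors(q);
  }
  IntegerVector out(blob.size());
  for (size_t t = 0; t < blob.size(); ++t) out[t] = blob[t] + 1;
  return out;
}
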