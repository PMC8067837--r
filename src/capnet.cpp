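// 3D image primitives used by the pipeline:
//  - separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
//    with anisotropic voxel spacing and the grid border treated as background
//  - distance-ordered homotopic thinning using the Malandain-Bertrand (26,6)
//    simple-point characterization, preserving curve endpoints
//  - 3x3x3 binary majority (median) filter with symmetric edge reflection
//
// Arrays are passed as flat vectors in R column-major order, dim = (n1,n2,n3).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 1D squared distance transform over a sampled line with spacing w.
// f: input (squared) values, d: output, v/z: work buffers of size n and n+1.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;            // parabola at +inf never lowest
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + (double)q * q * w2) - (f[v[k]] + (double)v[k] * v[k] * w2)) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q * w2) - (f[v[k]] + (double)v[k] * v[k] * w2)) /
          (2.0 * w2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq * w2 + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing, bool border_background) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double w1 = spacing[0], w2_ = spacing[1], w3 = spacing[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);

  // squared distances; background voxels seed with 0
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest-varying)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, n1, w1 * w1);
      for (int i = 0; i < n1; ++i) g[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) f[j] = g[base + (R_xlen_t)j * n1];
      dt1d(f, d, v, z, n2, w2_ * w2_);
      for (int j = 0; j < n2; ++j) g[base + (R_xlen_t)j * n1] = d[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; ++k) f[k] = g[base + (R_xlen_t)k * n1 * n2];
      dt1d(f, d, v, z, n3, w3 * w3);
      for (int k = 0; k < n3; ++k) g[base + (R_xlen_t)k * n1 * n2] = d[k];
    }

  R_xlen_t idx = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++idx) {
        double dist = std::sqrt(g[idx]);
        if (border_background && mask[idx]) {
          double b1 = std::min(i + 1, n1 - i) * w1;
          double b2 = std::min(j + 1, n2 - j) * w2_;
          double b3 = std::min(k + 1, n3 - k) * w3;
          double b = std::min(b1, std::min(b2, b3));
          if (b < dist) dist = b;
        }
        out[idx] = mask[idx] ? dist : 0.0;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test in the (26,6) digital topology.
// nb[27]: 3x3x3 neighbourhood values (center at index 13), out-of-grid = 0.

static inline int cube_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of 26-connected components of foreground in N26 (center excluded)
static int count_fg_components(const int* nb) {
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int t = 0; t < 27; ++t) {
        if (t == 13 || seen[t] || !nb[t]) continue;
        int tx = t % 3, ty = (t / 3) % 3, tz = t / 9;
        if (std::abs(tx - cx) <= 1 && std::abs(ty - cy) <= 1 &&
            std::abs(tz - cz) <= 1) {
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  return ncomp;
}

// number of 6-connected components of background in N18 that touch a
// 6-neighbour of the center
static int count_bg_components(const int* nb) {
  // N18 membership: Chebyshev distance 1 and city-block distance <= 2
  bool in18[27];
  for (int t = 0; t < 27; ++t) {
    int tx = t % 3 - 1, ty = (t / 3) % 3 - 1, tz = t / 9 - 1;
    int l1 = std::abs(tx) + std::abs(ty) + std::abs(tz);
    in18[t] = (t != 13) && l1 <= 2;
  }
  static const int face[6] = {cube_index(-1, 0, 0), cube_index(1, 0, 0),
                              cube_index(0, -1, 0), cube_index(0, 1, 0),
                              cube_index(0, 0, -1), cube_index(0, 0, 1)};
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int fi = 0; fi < 6; ++fi) {
    int s = face[fi];
    if (nb[s] || seen[s]) continue;
    ++ncomp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int t = 0; t < 27; ++t) {
        if (!in18[t] || seen[t] || nb[t]) continue;
        int tx = t % 3, ty = (t / 3) % 3, tz = t / 9;
        int dd = std::abs(tx - cx) + std::abs(ty - cy) + std::abs(tz - cz);
        if (dd == 1) {
          seen[t] = true;
          stack[top++] = t;
        }
      }
    }
  }
  return ncomp;
}

static inline bool is_simple(const int* nb) {
  return count_fg_components(nb) == 1 && count_bg_components(nb) == 1;
}

// fill the 27-cell neighbourhood of voxel (i,j,k); outside the grid = 0
static void fill_nb(const std::vector<char>& img, int n1, int n2, int n3,
                    int i, int j, int k, int* nb) {
  int t = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++t) {
        int x = i + dx, y = j + dy, z = k + dz;
        nb[t] = (x >= 0 && x < n1 && y >= 0 && y < n2 && z >= 0 && z < n3)
                    ? img[(R_xlen_t)z * n1 * n2 + (R_xlen_t)y * n1 + x]
                    : 0;
      }
}

static inline int n26_count(const int* nb) {
  int c = 0;
  for (int t = 0; t < 27; ++t)
    if (t != 13 && nb[t]) ++c;
  return c;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim,
                         NumericVector priority) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<char> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;

  typedef std::pair<double, R_xlen_t> QE; // (priority, linear index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;

  int nb[27];
  // seed with all foreground voxels having a background 26-neighbour
  R_xlen_t idx = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++idx) {
        if (!img[idx]) continue;
        fill_nb(img, n1, n2, n3, i, j, k, nb);
        if (n26_count(nb) < 26) q.push(QE(priority[idx], idx));
      }

  while (!q.empty()) {
    R_xlen_t c = q.top().second;
    q.pop();
    if (!img[c]) continue;
    int i = (int)(c % n1), j = (int)((c / n1) % n2), k = (int)(c / ((R_xlen_t)n1 * n2));
    fill_nb(img, n1, n2, n3, i, j, k, nb);
    int cnt = n26_count(nb);
    if (cnt <= 1) continue;            // endpoint or isolated voxel: keep
    if (!is_simple(nb)) continue;      // removal would change topology
    img[c] = 0;
    // deletion exposes the neighbours: re-queue foreground ones
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int x = i + dx, y = j + dy, z = k + dz;
          if (x < 0 || x >= n1 || y < 0 || y >= n2 || z < 0 || z >= n3) continue;
          R_xlen_t t = (R_xlen_t)z * n1 * n2 + (R_xlen_t)y * n1 + x;
          if (img[t]) q.push(QE(priority[t], t));
        }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_majority3d(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  LogicalVector out(n);

  // symmetric reflection: -1 -> 0, n -> n-1
  auto refl = [](int x, int nn) {
    if (x < 0) return -x - 1;
    if (x >= nn) return 2 * nn - x - 1;
    return x;
  };

  R_xlen_t idx = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++idx) {
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          int z = refl(k + dz, n3);
          for (int dy = -1; dy <= 1; ++dy) {
            int y = refl(j + dy, n2);
            for (int dx = -1; dx <= 1; ++dx) {
              int x = refl(i + dx, n1);
              if (mask[(R_xlen_t)z * n1 * n2 + (R_xlen_t)y * n1 + x]) ++cnt;
            }
          }
        }
        out[idx] = cnt >= 14; // majority of the 27-voxel neighbourhood
      }
  return out;
}
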