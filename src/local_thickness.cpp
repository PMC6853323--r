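#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e20;

// 1-D squared distance transform (lower-envelope / parabola method).
// f: input squared distances, d: output, n: length.
static void dt1d(const double* f, double* d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance transform (voxel units) of a 3D
// array: distance from every voxel to the nearest zero voxel.
// dims = (n1, n2, n3), column-major as in R.
static std::vector<double> edt3d(const LogicalVector& phase,
                                 int n1, int n2, int n3) {
  size_t N = (size_t)n1 * n2 * n3;
  std::vector<double> d(N);
  for (size_t i = 0; i < N; i++) d[i] = phase[i] ? INF : 0.0;

  std::vector<double> f(std::max(n1, std::max(n2, n3)));
  std::vector<double> g(f.size());

  // axis 1 (fastest-varying)
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      size_t off = (size_t)k * n1 * n2 + (size_t)j * n1;
      for (int i = 0; i < n1; i++) f[i] = d[off + i];
      dt1d(f.data(), g.data(), n1);
      for (int i = 0; i < n1; i++) d[off + i] = g[i];
    }
  // axis 2
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      size_t off = (size_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; j++) f[j] = d[off + (size_t)j * n1];
      dt1d(f.data(), g.data(), n2);
      for (int j = 0; j < n2; j++) d[off + (size_t)j * n1] = g[j];
    }
  // axis 3
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      size_t off = (size_t)j * n1 + i;
      for (int k = 0; k < n3; k++) f[k] = d[off + (size_t)k * n1 * n2];
      dt1d(f.data(), g.data(), n3);
      for (int k = 0; k < n3; k++) d[off + (size_t)k * n1 * n2] = g[k];
    }
  return d;
}

// Local thickness (largest inscribed sphere) of the TRUE phase of a 3D
// logical array, in voxel units.  For every phase voxel c the maximal
// admissible sphere radius is R(c) = sqrt(d2(c)) - 1/2 with d2 the
// squared center-to-center distance to the nearest complement voxel;
// a voxel v is covered by the sphere at c when |v - c|^2 <= R(c)^2.
// The result at v is 2 * max(R(c)) over covering centers; complement
// voxels get 0.  Spheres may protrude through the volume faces (the
// volume border is not treated as complement).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector phase, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  size_t N = (size_t)n1 * n2 * n3;
  NumericVector out(N);

  bool any_phase = false, any_comp = false;
  for (size_t i = 0; i < N; i++) {
    if (phase[i]) any_phase = true; else any_comp = true;
  }
  if (!any_phase) return out;
  if (!any_comp) {
    // no complement voxel anywhere: cap at the volume diagonal
    double cap = 2.0 * (std::sqrt((double)n1 * n1 + (double)n2 * n2 +
                                  (double)n3 * n3) - 0.5);
    for (size_t i = 0; i < N; i++) out[i] = cap;
    return out;
  }

  std::vector<double> d2 = edt3d(phase, n1, n2, n3);

  struct Center { double R; int i, j, k; };
  std::vector<Center> centers;
  centers.reserve(N / 2);
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        size_t idx = (size_t)k * n1 * n2 + (size_t)j * n1 + i;
        if (phase[idx]) {
          Center c;
          c.R = std::sqrt(d2[idx]) - 0.5;
          c.i = i; c.j = j; c.k = k;
          centers.push_back(c);
        }
      }
  std::sort(centers.begin(), centers.end(),
            [](const Center& a, const Center& b) { return a.R > b.R; });

  for (const Center& c : centers) {
    double R2 = c.R * c.R;
    double diam = 2.0 * c.R;
    int rb = (int)std::floor(c.R);
    int i0 = std::max(0, c.i - rb), i1 = std::min(n1 - 1, c.i + rb);
    int j0 = std::max(0, c.j - rb), j1 = std::min(n2 - 1, c.j + rb);
    int k0 = std::max(0, c.k - rb), k1 = std::min(n3 - 1, c.k + rb);
    for (int k = k0; k <= k1; k++) {
      double dk = (double)(k - c.k) * (k - c.k);
      for (int j = j0; j <= j1; j++) {
        double dj = (double)(j - c.j) * (j - c.j);
        if (dk + dj > R2) continue;
        size_t off = (size_t)k * n1 * n2 + (size_t)j * n1;
        for (int i = i0; i <= i1; i++) {
          double dd = dk + dj + (double)(i - c.i) * (i - c.i);
          if (dd <= R2 && out[off + i] < diam) out[off + i] = diam;
        }
      }
    }
  }
  return out;
}
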