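#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Index helper for column-major (n1 fastest) 3D arrays.
static inline R_xlen_t idx3(int i, int j, int k, int n1, int n2) {
  return (R_xlen_t)i + (R_xlen_t)n1 * ((R_xlen_t)j + (R_xlen_t)n2 * (R_xlen_t)k);
}

// Separable 1D correlation along each axis in turn, replicate (clamp)
// padding at the edges. Kernels are centred, odd length; an empty kernel
// (length 0) skips that axis. Kernels are assumed symmetric so correlation
// equals convolution.
// [[Rcpp::export]]
NumericVector cpp_sep_conv3(NumericVector x, IntegerVector dims, List kernels) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (x.size() != n) stop("cpp_sep_conv3: length/dims mismatch");
  std::vector<double> a(x.begin(), x.end()), b(n);

  for (int ax = 0; ax < 3; ++ax) {
    NumericVector k = kernels[ax];
    const int kl = k.size();
    if (kl == 0) continue;
    if (kl % 2 == 0) stop("cpp_sep_conv3: kernel length must be odd");
    const int h = (kl - 1) / 2;
    const int na = (ax == 0) ? n1 : (ax == 1) ? n2 : n3;
    for (int kk = 0; kk < n3; ++kk) {
      for (int jj = 0; jj < n2; ++jj) {
        for (int ii = 0; ii < n1; ++ii) {
          double s = 0.0;
          for (int t = -h; t <= h; ++t) {
            int i = ii, j = jj, l = kk;
            int *p = (ax == 0) ? &i : (ax == 1) ? &j : &l;
            int q = *p + t;
            if (q < 0) q = 0;
            if (q >= na) q = na - 1;
            *p = q;
            s += k[t + h] * a[idx3(i, j, l, n1, n2)];
          }
          b[idx3(ii, jj, kk, n1, n2)] = s;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Accumulate soft-profile tube segments into a volume. Each row of `tubes`
// is (p1, p2, p3, u1, u2, u3, radius, amplitude, halflen) with p the segment
// centre in 0-based voxel coordinates and u a unit direction. Intensity
// contribution is amplitude * exp(-d^2 / (2 radius^2)) where d is the
// perpendicular distance to the (finite) segment, truncated at 3 radii.
// [[Rcpp::export]]
NumericVector cpp_stamp_tubes(IntegerVector dims, NumericMatrix tubes) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);

  for (int t = 0; t < tubes.nrow(); ++t) {
    const double p1 = tubes(t, 0), p2 = tubes(t, 1), p3 = tubes(t, 2);
    const double u1 = tubes(t, 3), u2 = tubes(t, 4), u3 = tubes(t, 5);
    const double r = tubes(t, 6), amp = tubes(t, 7), hl = tubes(t, 8);
    const double cut = 3.0 * r, cut2 = cut * cut;
    const double inv2r2 = 1.0 / (2.0 * r * r);
    // bounding box of the dilated segment
    const double e1a = p1 - hl * u1, e1b = p1 + hl * u1;
    const double e2a = p2 - hl * u2, e2b = p2 + hl * u2;
    const double e3a = p3 - hl * u3, e3b = p3 + hl * u3;
    int lo1 = (int)std::floor(std::min(e1a, e1b) - cut), hi1 = (int)std::ceil(std::max(e1a, e1b) + cut);
    int lo2 = (int)std::floor(std::min(e2a, e2b) - cut), hi2 = (int)std::ceil(std::max(e2a, e2b) + cut);
    int lo3 = (int)std::floor(std::min(e3a, e3b) - cut), hi3 = (int)std::ceil(std::max(e3a, e3b) + cut);
    lo1 = std::max(lo1, 0); hi1 = std::min(hi1, n1 - 1);
    lo2 = std::max(lo2, 0); hi2 = std::min(hi2, n2 - 1);
    lo3 = std::max(lo3, 0); hi3 = std::min(hi3, n3 - 1);
    for (int k = lo3; k <= hi3; ++k) {
      for (int j = lo2; j <= hi2; ++j) {
        for (int i = lo1; i <= hi1; ++i) {
          const double w1 = i - p1, w2 = j - p2, w3 = k - p3;
          double s = w1 * u1 + w2 * u2 + w3 * u3;
          if (s > hl) s = hl;
          if (s < -hl) s = -hl;
          const double d1 = w1 - s * u1, d2 = w2 - s * u2, d3 = w3 - s * u3;
          const double d2sum = d1 * d1 + d2 * d2 + d3 * d3;
          if (d2sum < cut2)
            out[idx3(i, j, k, n1, n2)] += amp * std::exp(-d2sum * inv2r2);
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) used by the
// separable 3D EDT below.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) to the nearest nonzero voxel of a
// binary feature mask. A large finite sentinel stands in for infinity so
// the parabola intersections stay NaN-free; callers must pass a nonempty
// mask (enforced in R).
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double BIG = 1e12;  // far beyond any realisable squared distance
  std::vector<double> a(n);
  for (R_xlen_t i = 0; i < n; ++i) a[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> f(std::max(n1, std::max(n2, n3))), d(f.size());
  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) f[i] = a[idx3(i, j, k, n1, n2)];
      dt1d(f, d, n1);
      for (int i = 0; i < n1; ++i) a[idx3(i, j, k, n1, n2)] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j) f[j] = a[idx3(i, j, k, n1, n2)];
      dt1d(f, d, n2);
      for (int j = 0; j < n2; ++j) a[idx3(i, j, k, n1, n2)] = d[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      for (int k = 0; k < n3; ++k) f[k] = a[idx3(i, j, k, n1, n2)];
      dt1d(f, d, n3);
      for (int k = 0; k < n3; ++k) a[idx3(i, j, k, n1, n2)] = d[k];
    }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}

// Largest 6-connected component of a binary mask.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  std::vector<int> label(n, 0);
  int nlab = 0;
  R_xlen_t best_size = 0;
  int best_lab = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++nlab;
    R_xlen_t sz = 0;
    label[s] = nlab;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      ++sz;
      int i = (int)(cur % n1);
      int j = (int)((cur / n1) % n2);
      int k = (int)(cur / ((R_xlen_t)n1 * n2));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
        R_xlen_t t = idx3(ii, jj, kk, n1, n2);
        if (mask[t] && !label[t]) {
          label[t] = nlab;
          q.push(t);
        }
      }
    }
    if (sz > best_size) {
      best_size = sz;
      best_lab = nlab;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (label[i] == best_lab) && best_lab > 0;
  out.attr("dim") = dims;
  return out;
}
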