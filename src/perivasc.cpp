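#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Large finite sentinel standing in for "no mask pixel in this scan line".
// Any true squared distance is bounded by nr^2 + nc^2 << BIG, and doubles are
// exact integers up to 2^53, so envelope intersections stay exact.
static const double BIG = 1e15;

// One-dimensional squared distance transform of sampled function f
// (Felzenszwalb & Huttenlocher lower envelope of parabolas; exact).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance transform: for each pixel, squared distance
// (pixel units) to the nearest TRUE pixel. An empty mask yields values >= BIG;
// callers must guard that case.
// [[Rcpp::export(name = ".edt_squared")]]
NumericMatrix edt_squared(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass 1: down each column
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : BIG;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // pass 2: along each row of the column result
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

// Flood-fill labelling of TRUE pixels with 8-connectivity (diagonal neighbours
// connect). Labels run 1..n in first-encounter (column-major) order.
// [[Rcpp::export(name = ".label_components_8")]]
IntegerMatrix label_components_8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc); // zero-initialised
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di, qj = pj + dj;
            if ((di == 0 && dj == 0) || qi < 0 || qi >= nr || qj < 0 || qj >= nc)
              continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
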