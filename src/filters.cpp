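#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Separable image filters used by the masking and detection stages.
// All filters use reflective boundary handling unless noted.

static inline int reflect_idx(int i, int n) {
  // reflect-101: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical pass)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d)
        acc += k[d + r] * img(reflect_idx(i + d, nr), j);
      tmp(i, j) = acc;
    }
  }
  // along columns (horizontal pass)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d)
        acc += k[d + r] * tmp(i, reflect_idx(j + d, nc));
      out(i, j) = acc;
    }
  }
  return out;
}

// Windowed mean over a (2r+1)^2 square, edge-aware (mean over the pixels
// actually inside the image). Computed with summed-area tables.
// [[Rcpp::export]]
NumericMatrix box_mean_cpp(NumericMatrix img, int r) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  // integral image, (nr+1) x (nc+1)
  std::vector<double> I((size_t)(nr + 1) * (nc + 1), 0.0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      I[(size_t)(i + 1) * (nc + 1) + (j + 1)] =
        img(i, j) + I[(size_t)i * (nc + 1) + (j + 1)] +
        I[(size_t)(i + 1) * (nc + 1) + j] - I[(size_t)i * (nc + 1) + j];
  for (int i = 0; i < nr; ++i) {
    int i0 = std::max(0, i - r), i1 = std::min(nr - 1, i + r);
    for (int j = 0; j < nc; ++j) {
      int j0 = std::max(0, j - r), j1 = std::min(nc - 1, j + r);
      double s = I[(size_t)(i1 + 1) * (nc + 1) + (j1 + 1)] -
                 I[(size_t)i0 * (nc + 1) + (j1 + 1)] -
                 I[(size_t)(i1 + 1) * (nc + 1) + j0] +
                 I[(size_t)i0 * (nc + 1) + j0];
      out(i, j) = s / ((double)(i1 - i0 + 1) * (j1 - j0 + 1));
    }
  }
  return out;
}

// Square-window maximum filter, separable two-pass, edge-clamped window.
// [[Rcpp::export]]
NumericMatrix max_filter_cpp(NumericMatrix img, int r) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = img(i, j);
      for (int d = std::max(0, i - r); d <= std::min(nr - 1, i + r); ++d)
        if (img(d, j) > m) m = img(d, j);
      tmp(i, j) = m;
    }
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double m = tmp(i, j);
      for (int d = std::max(0, j - r); d <= std::min(nc - 1, j + r); ++d)
        if (tmp(i, d) > m) m = tmp(i, d);
      out(i, j) = m;
    }
  return out;
}

// 8-connected component labelling of a logical mask (BFS).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int cur = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++cur;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = cur;
      while (!stack.empty()) {
        auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = cur;
              stack.push_back({ni, nj});
            }
          }
      }
    }
  return lab;
}
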