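#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Linear index helpers for an array of dim (n1, n2, n3), 0-based,
// column-major as in R: idx = i + j*n1 + k*n1*n2.

// Connected component of `mask` containing `seed` (1-based triple),
// under 6- or 26-connectivity. Plain BFS with an explicit stack; volumes
// here are a few million voxels at most, so int indices suffice.
// [[Rcpp::export]]
LogicalVector flood_fill3d(const LogicalVector& mask, const IntegerVector& dim,
                           const IntegerVector& seed, const int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");
  std::vector<int> d1, d2, d3;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && (std::abs(a) + std::abs(b) + std::abs(c)) != 1)
          continue;
        d1.push_back(a); d2.push_back(b); d3.push_back(c);
      }
  LogicalVector out(mask.size(), false);
  const int si = seed[0] - 1, sj = seed[1] - 1, sk = seed[2] - 1;
  const int s = si + sj * n1 + sk * n1 * n2;
  if (!mask[s]) return out;
  std::vector<int> stack;
  stack.push_back(s);
  out[s] = true;
  while (!stack.empty()) {
    const int cur = stack.back();
    stack.pop_back();
    const int i = cur % n1;
    const int j = (cur / n1) % n2;
    const int k = cur / (n1 * n2);
    for (size_t m = 0; m < d1.size(); ++m) {
      const int ii = i + d1[m], jj = j + d2[m], kk = k + d3[m];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      const int nb = ii + jj * n1 + kk * n1 * n2;
      if (mask[nb] && !out[nb]) {
        out[nb] = true;
        stack.push_back(nb);
      }
    }
  }
  return out;
}

// 3x3x3 modal filter on an integer label volume (labels 0..n_levels-1).
// Border neighbourhoods are clipped. Ties keep the centre voxel's label when
// it is among the modal labels, otherwise take the smallest modal label —
// a fixed rule so the cleanup is deterministic.
// [[Rcpp::export]]
IntegerVector majority_filter3d(const IntegerVector& labels,
                                const IntegerVector& dim,
                                const int n_levels) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  IntegerVector out(labels.size());
  std::vector<int> counts(n_levels);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        std::fill(counts.begin(), counts.end(), 0);
        for (int kk = std::max(0, k - 1); kk <= std::min(n3 - 1, k + 1); ++kk)
          for (int jj = std::max(0, j - 1); jj <= std::min(n2 - 1, j + 1); ++jj)
            for (int ii = std::max(0, i - 1); ii <= std::min(n1 - 1, i + 1); ++ii)
              ++counts[labels[ii + jj * n1 + kk * n1 * n2]];
        const int cur = i + j * n1 + k * n1 * n2;
        const int centre = labels[cur];
        int best = 0;
        for (int l = 1; l < n_levels; ++l)
          if (counts[l] > counts[best]) best = l;
        if (counts[centre] == counts[best]) best = centre;
        out[cur] = best;
      }
  return out;
}
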