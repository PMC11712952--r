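// 3D median filter with a one-voxel span (3x3x3 neighborhood, shrunken at
// edges). NA values are ignored in the neighborhood; an NA center with no
// finite neighbors stays NA.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector x, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(x.size());
  std::vector<double> buf;
  buf.reserve(27);
  auto idx = [&](int i, int j, int k) {
    return i + n1 * (j + (R_xlen_t)n2 * k);
  };
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) {
        buf.clear();
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = k + dk;
          if (kk < 0 || kk >= n3) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = j + dj;
            if (jj < 0 || jj >= n2) continue;
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di;
              if (ii < 0 || ii >= n1) continue;
              double v = x[idx(ii, jj, kk)];
              if (!ISNAN(v)) buf.push_back(v);
            }
          }
        }
        R_xlen_t c = idx(i, j, k);
        if (buf.empty()) {
          out[c] = NA_REAL;
        } else {
          size_t m = buf.size() / 2;
          std::nth_element(buf.begin(), buf.begin() + m, buf.end());
          double med = buf[m];
          if (buf.size() % 2 == 0) {
            double lo = *std::max_element(buf.begin(), buf.begin() + m);
            med = (med + lo) / 2.0;
          }
          out[c] = med;
        }
      }
    }
  }
  return out;
}
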