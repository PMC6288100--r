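#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact order-statistic median filter with edge-replicated borders.
// The window is (2*radius+1)^2, always an odd pixel count, so the median is a
// single sample value and no averaging (hence no floating-point rounding
// beyond the input values themselves) occurs.
static inline void sort2(double &a, double &b) {
  if (b < a) { double t = a; a = b; b = t; }
}

// median of 9 by a fixed comparison network (Paeth), no branches beyond swaps
static inline double median9(double p0, double p1, double p2,
                             double p3, double p4, double p5,
                             double p6, double p7, double p8) {
  sort2(p1, p2); sort2(p4, p5); sort2(p7, p8);
  sort2(p0, p1); sort2(p3, p4); sort2(p6, p7);
  sort2(p1, p2); sort2(p4, p5); sort2(p7, p8);
  sort2(p0, p3); sort2(p5, p8); sort2(p4, p7);
  sort2(p3, p6); sort2(p1, p4); sort2(p2, p5);
  sort2(p4, p7); sort2(p4, p2); sort2(p6, p4);
  sort2(p4, p2);
  return p4;
}

// 3x3 case: column-pointer walk with replicated borders
static void median_filter3(const NumericMatrix &img, NumericMatrix &out) {
  const int H = img.nrow(), W = img.ncol();
  for (int j = 0; j < W; ++j) {
    const double *cl = &img(0, j > 0 ? j - 1 : 0);
    const double *cm = &img(0, j);
    const double *cr = &img(0, j < W - 1 ? j + 1 : j);
    for (int i = 0; i < H; ++i) {
      const int iu = i > 0 ? i - 1 : 0;
      const int id = i < H - 1 ? i + 1 : i;
      out(i, j) = median9(cl[iu], cl[i], cl[id],
                          cm[iu], cm[i], cm[id],
                          cr[iu], cr[i], cr[id]);
    }
  }
}

// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  const int k = 2 * radius + 1, n = k * k;
  NumericMatrix out(H, W);
  if (radius == 1) {
    median_filter3(img, out);
    return out;
  }
  std::vector<double> buf(n);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int m = 0;
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= W) jj = W - 1;
        for (int di = -radius; di <= radius; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= H) ii = H - 1;
          buf[m++] = img(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}
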