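#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// reflect index into [0, n-1] (symmetric padding without edge repetition,
// falling back to clamping for very small images)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Classical adaptive median filter.  For each pixel the window grows from
// 3x3 to maxWindow; Stage A passes when the window median lies strictly
// between the window min and max, Stage B then keeps the pixel unless it is
// itself a window extreme (in which case the median is output).  If the
// largest window still has a degenerate median, the median of that window is
// output.
// [[Rcpp::export]]
NumericMatrix amf_cpp(NumericMatrix image, int maxWindow) {
  const int nr = image.nrow(), nc = image.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)maxWindow * maxWindow);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double px = image(i, j);
      double med = px;
      bool decided = false;
      for (int w = 3; w <= maxWindow; w += 2) {
        const int h = w / 2;
        buf.clear();
        for (int dj = -h; dj <= h; ++dj) {
          const int cj = reflect(j + dj, nc);
          for (int di = -h; di <= h; ++di)
            buf.push_back(image(reflect(i + di, nr), cj));
        }
        std::sort(buf.begin(), buf.end());
        const double mn = buf.front(), mx = buf.back();
        med = buf[buf.size() / 2];  // odd count: exact middle element
        if (med > mn && med < mx) {
          // Stage B: replace only pixels that are window extremes
          out(i, j) = (px > mn && px < mx) ? px : med;
          decided = true;
          break;
        }
      }
      if (!decided) out(i, j) = med;  // degenerate at the largest window
    }
  }
  return out;
}
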