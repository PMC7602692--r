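#include <Rcpp.h>
using namespace Rcpp;

// Local maxima of a series with plateau handling, plus widths at a fraction
// of each peak's height. A plateau (run of equal values) higher than both
// neighbouring samples counts as one peak at its midpoint. No height or
// prominence threshold is applied. The width of a peak is the length, in
// samples, of the maximal contiguous interval containing it on which the
// series stays at or above rel_height * peak magnitude.
// [[Rcpp::export(name = ".peak_scan")]]
List peak_scan(NumericVector x, double rel_height) {
  int n = x.size();
  std::vector<int> idx;   // 0-based peak positions
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1]) {
      int j = i;
      while (j < n - 1 && x[j + 1] == x[j]) j++;
      if (j < n - 1 && x[j + 1] < x[j]) {
        idx.push_back((i + j) / 2);  // plateau midpoint
        i = j + 1;
      } else {
        i = (j > i) ? j : i + 1;
      }
    } else {
      i++;
    }
  }
  int p = idx.size();
  IntegerVector out_idx(p);
  NumericVector out_mag(p), out_wid(p);
  for (int k = 0; k < p; k++) {
    int ip = idx[k];
    double thr = rel_height * x[ip];
    int a = ip, b = ip;
    while (a > 0 && x[a - 1] >= thr) a--;
    while (b < n - 1 && x[b + 1] >= thr) b++;
    out_idx[k] = ip + 1;          // 1-based for R
    out_mag[k] = x[ip];
    out_wid[k] = (double)(b - a); // samples; caller divides by fs
  }
  return List::create(_["indices"] = out_idx, _["magnitudes"] = out_mag,
                      _["width_samples"] = out_wid);
}
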