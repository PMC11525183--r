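#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Per-replicate counts of inter-adenoma spacings smaller than x for n
// adenoma start positions on a circle of circumference y.
//
// method 0 ("placement"): draw n uniform positions, sort, count adjacent
// gaps (including the wrap-around gap) below x.
// method 1 ("gaps"): draw the spacing vector directly as y * E_i / sum(E)
// with E_i iid Exp(1) -- the Dirichlet representation of circular spacings,
// distributionally identical to method 0 but O(n) per replicate.
// [[Rcpp::export]]
IntegerVector cpp_spacing_collisions(int n, double x, double y, int reps,
                                     int method) {
  IntegerVector out(reps);
  if (n < 2 || x <= 0.0) return out;  // fewer than two adenomas never collide
  std::vector<double> buf(n);
  for (int r = 0; r < reps; ++r) {
    int count = 0;
    if (method == 0) {
      for (int i = 0; i < n; ++i) buf[i] = unif_rand() * y;
      std::sort(buf.begin(), buf.end());
      for (int i = 1; i < n; ++i) {
        if (buf[i] - buf[i - 1] < x) ++count;
      }
      if (y - (buf[n - 1] - buf[0]) < x) ++count;
    } else {
      double s = 0.0;
      for (int i = 0; i < n; ++i) {
        // inverse-CDF exponential: one uniform per draw
        buf[i] = -std::log(unif_rand());
        s += buf[i];
      }
      const double thr = x * s / y;
      for (int i = 0; i < n; ++i) {
        if (buf[i] < thr) ++count;
      }
    }
    out[r] = count;
  }
  return out;
}
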