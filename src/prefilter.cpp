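#include <Rcpp.h>
using namespace Rcpp;

// Sliding 60-codon window sums of an upper-bound score matrix over a
// translated frame, with an exact branch-and-bound early exit: a window is
// dropped as soon as its running sum plus the best possible remainder falls
// below min_bits. Returns 1-based indices of windows whose full bound-sum
// reaches min_bits (a sound superset of windows any class profile can pass).
// [[Rcpp::export(name = ".prefilter_windows_cpp")]]
IntegerVector prefilter_windows_cpp(IntegerVector idx, NumericMatrix bound,
                                    double min_bits) {
  const int np = idx.size();
  const int W = bound.ncol();
  const int nw = np - W + 1;
  if (nw < 1) return IntegerVector(0);
  const int nr = bound.nrow();
  std::vector<double> suffix(W + 1, 0.0);
  for (int p = W - 1; p >= 0; --p) {
    double m = bound(0, p);
    for (int a = 1; a < nr; ++a) m = std::max(m, bound(a, p));
    suffix[p] = suffix[p + 1] + m;
  }
  std::vector<int> out;
  const double *B = REAL(bound);
  const int *ix = INTEGER(idx);
  for (int w = 0; w < nw; ++w) {
    double s = 0.0;
    bool ok = true;
    const int *wx = ix + w;
    for (int p = 0; p < W; ++p) {
      s += B[p * nr + (wx[p] - 1)];
      if (s + suffix[p + 1] < min_bits) { ok = false; break; }
    }
    if (ok && s >= min_bits) out.push_back(w + 1);
  }
  return wrap(out);
}
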