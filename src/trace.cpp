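#include <Rcpp.h>
using namespace Rcpp;

// Cumulative similarity trace: start at 1, add the per-position
// increment, clamp to [0, 1].  The clamp writes literal 0.0 / 1.0, and
// values within 1e-9 of a bound are snapped to it (all score paths built
// from 3-decimal matrix entries are exact multiples of 0.001, so a value
// that close to a bound is that bound up to accumulation error); this
// keeps the score == 0 and score == 1 tests used by segment detection
// well defined in floating point.
// [[Rcpp::export]]
NumericVector trace_accumulate(NumericVector increments) {
  const double snap = 1e-9;
  int n = increments.size();
  NumericVector out(n);
  double s = 1.0;
  for (int i = 0; i < n; ++i) {
    s += increments[i];
    if (s >= 1.0 - snap) s = 1.0;
    if (s <= snap) s = 0.0;
    out[i] = s;
  }
  return out;
}
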