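#include <Rcpp.h>
using namespace Rcpp;

// One rule's weight update: shift `delta` toward the input whose value moves
// the rule output in the error-reducing direction, clamp to [0,1],
// renormalize to sum 1.  Equal inputs are a no-op (output is
// weight-invariant).  Must stay in lockstep with train_step() in R/network.R.
static inline void update_rule(double &w1, double &w2, double v1, double v2,
                               double delta, bool err_positive) {
  if (v1 == v2) return;
  bool toward_first = err_positive ? (v1 > v2) : (v1 < v2);
  if (toward_first) {
    w1 += delta;
    w2 -= delta;
  } else {
    w1 -= delta;
    w2 += delta;
  }
  if (w1 < 0) w1 = 0; else if (w1 > 1) w1 = 1;
  if (w2 < 0) w2 = 0; else if (w2 > 1) w2 = 1;
  double s = w1 + w2;
  w1 /= s;
  w2 /= s;
}

// Replay the per-row SF/TR cycle of profile training over a normalized
// input matrix (columns: heart rate, ETCO2, respiratory rate, blood
// pressure) for the fixed two-level topology: rule 1 and rule 2 each pair
// two inputs (1-based column indices in pair1/pair2), rule 3 combines the
// intermediates into the output.  Returns final weights and the facts left
// by the last training row's forward pass.
// [[Rcpp::export]]
List gdes_train_loop_cpp(NumericMatrix inputs, IntegerVector pair1,
                         IntegerVector pair2, NumericVector w0, double target,
                         double velocity) {
  if (inputs.ncol() != 4) stop("inputs must have 4 columns");
  if (w0.size() != 6) stop("w0 must hold 6 weights");
  int a1 = pair1[0] - 1, b1 = pair1[1] - 1;
  int a2 = pair2[0] - 1, b2 = pair2[1] - 1;
  double w11 = w0[0], w12 = w0[1], w21 = w0[2], w22 = w0[3], w31 = w0[4],
         w32 = w0[5];
  int n = inputs.nrow();
  double f1 = NA_REAL, f2 = NA_REAL, out = NA_REAL;

  for (int i = 0; i < n; ++i) {
    double x1 = inputs(i, a1), y1 = inputs(i, b1);
    double x2 = inputs(i, a2), y2 = inputs(i, b2);
    f1 = w11 * x1 + w12 * y1;
    f2 = w21 * x2 + w22 * y2;
    out = w31 * f1 + w32 * f2;
    double e = target - out;
    if (e == 0) continue;
    // shares: each rule's contribution (downstream weight product; 1 for
    // the final rule) normalized over the three rules
    double csum = w31 + w32 + 1.0;
    double ae = std::fabs(e);
    bool pos = e > 0;
    double d1 = velocity * (w31 / csum) * ae;
    double d2 = velocity * (w32 / csum) * ae;
    double d3 = velocity * (1.0 / csum) * ae;
    update_rule(w11, w12, x1, y1, d1, pos);
    update_rule(w21, w22, x2, y2, d2, pos);
    update_rule(w31, w32, f1, f2, d3, pos);
  }

  // facts as left by the final row under the updated weights
  if (n > 0) {
    f1 = w11 * inputs(n - 1, a1) + w12 * inputs(n - 1, b1);
    f2 = w21 * inputs(n - 1, a2) + w22 * inputs(n - 1, b2);
    out = w31 * f1 + w32 * f2;
  }
  return List::create(
      _["weights"] = NumericVector::create(w11, w12, w21, w22, w31, w32),
      _["intermediates"] = NumericVector::create(f1, f2), _["output"] = out);
}
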