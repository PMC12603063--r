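#include <Rcpp.h>
using namespace Rcpp;

// Forward Rescorla-Wagner recursion over one session.
// alpha is ordered (pos_ingroup, neg_ingroup, pos_outgroup, neg_outgroup);
// a zero prediction error routes to the positive-valence cell (no update
// happens either way, the convention only fixes determinism).
// [[Rcpp::export]]
List rw_forward(IntegerVector is_ingroup, NumericVector outcome,
                NumericVector alpha, double beta,
                double v0_in, double v0_out) {
  int n = outcome.size();
  NumericVector V(n), delta(n), pred(n);
  double vin = v0_in, vout = v0_out;
  for (int t = 0; t < n; ++t) {
    bool ing = is_ingroup[t] == 1;
    double v = ing ? vin : vout;
    V[t] = v;
    pred[t] = beta * v;
    double d = outcome[t] - v;
    delta[t] = d;
    double a = (d >= 0.0) ? (ing ? alpha[0] : alpha[2])
                          : (ing ? alpha[1] : alpha[3]);
    v += a * d;
    if (ing) vin = v; else vout = v;
  }
  return List::create(_["V"] = V, _["delta"] = delta, _["predicted"] = pred);
}

// Running gamma-discounted sums of prediction errors split by valence.
// delta must be aligned to absolute trial time with 0 at trials where the
// group is inactive: the existing sum is still discounted on those trials.
// [[Rcpp::export]]
List discount_sums(NumericVector delta, double gamma) {
  int n = delta.size();
  NumericVector spos(n), sneg(n), sall(n);
  double p = 0.0, q = 0.0, s = 0.0;
  for (int t = 0; t < n; ++t) {
    double d = delta[t];
    p = gamma * p + (d > 0.0 ? d : 0.0);
    q = gamma * q + (d < 0.0 ? d : 0.0);
    s = gamma * s + d;
    spos[t] = p; sneg[t] = q; sall[t] = s;
  }
  return List::create(_["S_pos"] = spos, _["S_neg"] = sneg, _["S_all"] = sall);
}
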