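#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of an observed choice/outcome sequence under a
// Rescorla-Wagner + softmax model with two options. Values reset to q0
// wherever new_block is true. Vectors must contain only non-missed trials,
// in experienced order. Valence gating: outcomes equal to reward_value use
// alpha_gain, anything else alpha_loss (pass alpha_gain == alpha_loss for
// the one-rate model).
// [[Rcpp::export]]
double rw_loglik_cpp(LogicalVector chosen_good,
                     NumericVector outcome,
                     LogicalVector new_block,
                     double alpha_gain,
                     double alpha_loss,
                     double beta,
                     double q0,
                     double reward_value) {
  const int n = chosen_good.size();
  double q_good = q0, q_bad = q0;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (new_block[i]) { q_good = q0; q_bad = q0; }
    const bool good = chosen_good[i];
    const double qc = good ? q_good : q_bad;
    const double qu = good ? q_bad : q_good;
    const double d = beta * (qc - qu);
    // log(1 / (1 + exp(-d))), overflow-safe
    ll += -R::log1pexp(-d);
    const double r = outcome[i];
    const double a = (r == reward_value) ? alpha_gain : alpha_loss;
    const double qn = qc + a * (r - qc);
    if (good) q_good = qn; else q_bad = qn;
  }
  return ll;
}
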