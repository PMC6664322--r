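#include <Rcpp.h>
using namespace Rcpp;

// Session log-likelihood of the hybrid model-free/model-based learner.
// Parameter order: beta1, beta2, alpha1, alpha2, lam, persev, w.
// state2 coded 0 = B, 1 = C; action 0's common state is B, action 1's is C.
// Invalid trials contribute nothing and trigger no update; perseveration is
// keyed to the last valid stage-1 choice.
// [[Rcpp::export]]
double cpp_session_loglik(NumericVector par,
                          IntegerVector choice1,
                          IntegerVector state2,
                          IntegerVector choice2,
                          NumericVector reward,
                          LogicalVector valid,
                          double common_prob,
                          double q_init,
                          double prob_floor) {
  const double beta1 = par[0], beta2 = par[1];
  const double alpha1 = par[2], alpha2 = par[3];
  const double lam = par[4], persev = par[5], w = par[6];
  const int n = choice1.size();

  double qmf[2] = {q_init, q_init};
  double q2[2][2] = {{q_init, q_init}, {q_init, q_init}};  // [state][action]
  int prev = -1;
  double ll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (!valid[t]) continue;
    const int a1 = choice1[t], s = state2[t], a2 = choice2[t];

    // model-based stage-1 values from the true transition matrix
    const double bestB = std::max(q2[0][0], q2[0][1]);
    const double bestC = std::max(q2[1][0], q2[1][1]);
    const double qmb0 = common_prob * bestB + (1.0 - common_prob) * bestC;
    const double qmb1 = (1.0 - common_prob) * bestB + common_prob * bestC;

    double net0 = beta1 * (w * qmb0 + (1.0 - w) * qmf[0]);
    double net1 = beta1 * (w * qmb1 + (1.0 - w) * qmf[1]);
    if (prev == 0) net0 += persev;
    if (prev == 1) net1 += persev;
    const double m1 = std::max(net0, net1);
    const double e0 = std::exp(net0 - m1), e1 = std::exp(net1 - m1);
    const double p1 = (a1 == 0 ? e0 : e1) / (e0 + e1);

    const double v0 = beta2 * q2[s][0], v1 = beta2 * q2[s][1];
    const double m2 = std::max(v0, v1);
    const double f0 = std::exp(v0 - m2), f1 = std::exp(v1 - m2);
    const double p2 = (a2 == 0 ? f0 : f1) / (f0 + f1);

    ll += std::log(std::max(p1, prob_floor)) +
          std::log(std::max(p2, prob_floor));

    // SARSA(lambda)-style updates
    const double q2sa = q2[s][a2];
    const double delta1 = q2sa - qmf[a1];
    qmf[a1] += alpha1 * delta1;
    const double delta2 = reward[t] - q2sa;
    q2[s][a2] = q2sa + alpha2 * delta2;
    qmf[a1] += alpha1 * lam * delta2;

    prev = a1;
  }
  return ll;
}
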