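#include <Rcpp.h>
using namespace Rcpp;

// Deterministic replay of the latent learning recursion against recorded
// choices and rewards, shared by all twelve model variants. Latents reset
// at every block boundary (new stimuli per block): Q to 50, S to S0, the
// previous-trial outcome PE to 0.
//
// par slots (natural space):
//  0 alpha (base learning rate / alpha_Q)   5 k_attention
//  1 alpha_pos                              6 k (utility curvature)
//  2 alpha_neg                              7 alpha_S
//  3 alpha_risky                            8 beta
//  4 alpha_safe                             9 omega
//                                          10 S0
// util_family: 0 identity, 1 exponential (concave/convex by sign of k),
//              2 sign-preserving power (s-shaped / inverse-s by k)
// rate_rule:   0 fixed, 1 valence, 2 variance, 3 attention
// risk_gate:   0 none, 1 stimulus-PE, 2 prediction, 3 previous outcome PE

// [[Rcpp::export]]
List replay_session_cpp(IntegerVector block, IntegerVector first,
                        IntegerVector second, IntegerVector choice,
                        NumericVector reward, int util_family, int rate_rule,
                        bool pe_scaling, int risk_gate, NumericVector par,
                        bool want_trace) {
  const int n = block.size();
  const double q0 = 50.0, u_scale = 50.0, u_shift = 50.0;
  const double s_floor = 1e-3;  // keeps the scaled-PE divisor positive
  const double alpha = par[0], alpha_pos = par[1], alpha_neg = par[2],
               alpha_risky = par[3], alpha_safe = par[4], k_att = par[5],
               k_util = par[6], alpha_s = par[7], beta = par[8],
               omega = par[9], s0 = par[10];

  double Q[4], S[4];
  double prev_out_pe = 0.0, loglik = 0.0;
  int cur_block = NA_INTEGER;

  NumericVector p_chosen(n), p_first(n);
  NumericMatrix Qtr, Str;
  NumericVector gate_tr, delta_tr;
  if (want_trace) {
    Qtr = NumericMatrix(n, 4);
    Str = NumericMatrix(n, 4);
    gate_tr = NumericVector(n);
    delta_tr = NumericVector(n);
  }

  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != cur_block) {
      cur_block = block[t];
      for (int i = 0; i < 4; ++i) { Q[i] = q0; S[i] = s0; }
      prev_out_pe = 0.0;
    }
    const int f = first[t] - 1, s = second[t] - 1, c = choice[t] - 1;
    if (c != f && c != s) stop("recorded choice outside the shown pair");

    // gating signal and action activations for the shown pair
    double gate = 0.0;
    if (risk_gate == 1) {
      gate = 0.5 * (Q[f] + Q[s]) - 0.25 * (Q[0] + Q[1] + Q[2] + Q[3]);
    } else if (risk_gate == 2) {
      gate = 0.5 * (Q[f] + Q[s]);
    } else if (risk_gate == 3) {
      gate = prev_out_pe;
    }
    double a1 = Q[f], a2 = Q[s];
    if (risk_gate > 0) {
      const double g = std::tanh(omega * gate);
      a1 += g * S[f];
      a2 += g * S[s];
    }
    const double z = beta * (a1 - a2);
    const double pf = (z >= 0) ? 1.0 / (1.0 + std::exp(-z))
                               : std::exp(z) / (1.0 + std::exp(z));
    const double pc = (c == f) ? pf : 1.0 - pf;
    loglik += std::log(pc);

    if (want_trace) {
      for (int i = 0; i < 4; ++i) { Qtr(t, i) = Q[i]; Str(t, i) = S[i]; }
      gate_tr[t] = gate;
    }
    p_first[t] = pf;
    p_chosen[t] = pc;

    // outcome: utility transform, prediction error, delta-rule updates
    double U = reward[t];
    if (util_family == 1) {
      const double zz = (U - u_shift) / u_scale;
      U = u_shift + u_scale * (1.0 - std::exp(-k_util * zz)) / k_util;
    } else if (util_family == 2) {
      const double zz = (U - u_shift) / u_scale;
      const double sgn = (zz > 0) - (zz < 0);
      U = u_shift + u_scale * sgn * std::pow(std::fabs(zz), k_util);
    }
    const double delta = U - Q[c];
    const double delta_use = pe_scaling ? delta / S[c] : delta;

    double a_eff = alpha;
    if (rate_rule == 1) {
      a_eff = (delta >= 0) ? alpha_pos : alpha_neg;
    } else if (rate_rule == 2) {
      a_eff = (c == 0 || c == 2) ? alpha_risky : alpha_safe;
    } else if (rate_rule == 3) {
      a_eff = alpha * std::pow(std::fabs(delta), k_att);
    }
    if (delta_use != 0.0) Q[c] += a_eff * delta_use;

    if (risk_gate > 0) {
      S[c] += alpha_s * (std::fabs(delta) - S[c]);
    } else if (pe_scaling) {
      S[c] += alpha_s * (std::fabs(delta_use) - 1.0);
      if (S[c] < s_floor) S[c] = s_floor;
    }
    prev_out_pe = delta;
    if (want_trace) delta_tr[t] = delta;
  }

  if (want_trace) {
    return List::create(_["loglik"] = loglik, _["p_chosen"] = p_chosen,
                        _["p_first"] = p_first, _["Q"] = Qtr, _["S"] = Str,
                        _["gate"] = gate_tr, _["delta_out"] = delta_tr);
  }
  return List::create(_["loglik"] = loglik, _["p_chosen"] = p_chosen,
                      _["p_first"] = p_first);
}
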