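#include <Rcpp.h>
using namespace Rcpp;

double wfpt_lpdf_choice(double t, int choice, double v, double a, double w);

// Hybrid model-based / model-free learner: SARSA(lambda) caching at stage 1,
// shared second-stage values, decay of non-selected values toward q_init, and
// the variant-specific transition-learning rule.  One forward sweep over a
// session emits the pre-choice covariates the decision layer consumes.
//
// Data encoding per subject (equal-length vectors over trials):
//   s1: stage-1 state (1-based; always 1 in the original variant)
//   c1: stage-1 choice 1/2, 0 = missing
//   s2: stage-2 state 2/3
//   c2: stage-2 choice 1/2, 0 = missing or not applicable (newer variant)
//   rew: reward, already rescaled to the common scale
//   m1, m2: missed-deadline flags
// variant: 0 = original (probabilistic transitions, two stage-2 choices),
//          1 = newer (two stage-1 pairs, deterministic transitions, one
//              forced stage-2 option)

struct Sweep {
  std::vector<double> dq_mf, dq_mb, rep, dq2;
};

static void rl_sweep(const IntegerVector& s1, const IntegerVector& c1,
                     const IntegerVector& s2, const IntegerVector& c2,
                     const NumericVector& rew, const IntegerVector& m1,
                     const IntegerVector& m2, int variant, double q_init,
                     double alpha, double lam, Sweep& out) {
  int n = s1.size();
  int nS1 = (variant == 0) ? 1 : 2;
  int nA2 = (variant == 0) ? 2 : 1;
  double q1[2][2], q2[2][2], p2[2][2];
  for (int s = 0; s < 2; s++)
    for (int a = 0; a < 2; a++) { q1[s][a] = q_init; q2[s][a] = q_init; }
  // transition estimate: p2[s][a] = p(next state = 2 | stage-1 state s, action a)
  long cnt_a1s2 = 0, cnt_a2s3 = 0, cnt_a1s3 = 0, cnt_a2s2 = 0;
  bool pair_known[2] = {false, false};
  if (variant == 0) { p2[0][0] = 0.3; p2[0][1] = 0.7; } // tie -> "opposite" assignment
  else { p2[0][0] = p2[0][1] = p2[1][0] = p2[1][1] = 0.5; }
  bool last_ok[2] = {false, false};
  int last_choice[2] = {0, 0};

  out.dq_mf.resize(n); out.dq_mb.resize(n); out.rep.resize(n); out.dq2.resize(n);

  for (int t = 0; t < n; t++) {
    int s1i = s1[t] - 1;
    int s2i = s2[t] - 2;
    // pre-choice covariates
    out.dq_mf[t] = q1[s1i][0] - q1[s1i][1];
    double max2[2];
    for (int s = 0; s < 2; s++) {
      max2[s] = q2[s][0];
      if (nA2 == 2 && q2[s][1] > max2[s]) max2[s] = q2[s][1];
    }
    double qmb[2];
    for (int a = 0; a < 2; a++)
      qmb[a] = p2[s1i][a] * max2[0] + (1.0 - p2[s1i][a]) * max2[1];
    out.dq_mb[t] = qmb[0] - qmb[1];
    out.rep[t] = last_ok[s1i] ? (last_choice[s1i] == 1 ? 1.0 : -1.0) : 0.0;
    bool have_c1 = (m1[t] == 0) && (c1[t] > 0);
    out.dq2[t] = (variant == 0 && have_c1 && s2i >= 0)
                     ? q2[s2i][0] - q2[s2i][1] : NA_REAL;

    // learning updates (chosen cells marked; everything else decays)
    bool chosen1[2][2] = {{false, false}, {false, false}};
    bool chosen2[2][2] = {{false, false}, {false, false}};
    bool have_full = have_c1 && s2i >= 0 &&
        (variant == 1 || ((m2[t] == 0) && (c2[t] > 0)));
    if (have_full) {
      int c2i = (variant == 0) ? c2[t] - 1 : 0;
      double q22 = q2[s2i][c2i];
      double q11 = q1[s1i][c1[t] - 1];
      double qprime = q11 + alpha * (q22 - q11);
      q1[s1i][c1[t] - 1] = qprime + lam * alpha * (rew[t] - q22);
      q2[s2i][c2i] = q22 + alpha * (rew[t] - q22);
      chosen1[s1i][c1[t] - 1] = true;
      chosen2[s2i][c2i] = true;
    }
    if (have_c1 && s2i >= 0) {
      if (variant == 0) {
        if (c1[t] == 1 && s2[t] == 2) cnt_a1s2++;
        if (c1[t] == 2 && s2[t] == 3) cnt_a2s3++;
        if (c1[t] == 1 && s2[t] == 3) cnt_a1s3++;
        if (c1[t] == 2 && s2[t] == 2) cnt_a2s2++;
        if (cnt_a1s2 + cnt_a2s3 > cnt_a1s3 + cnt_a2s2) {
          p2[0][0] = 0.7; p2[0][1] = 0.3;
        } else {
          p2[0][0] = 0.3; p2[0][1] = 0.7;
        }
      } else if (!pair_known[s1i]) {
        double p = (s2[t] == 2) ? 1.0 : 0.0;
        p2[s1i][c1[t] - 1] = p;
        p2[s1i][2 - c1[t]] = 1.0 - p;
        pair_known[s1i] = true;
      }
    }
    for (int s = 0; s < nS1; s++)
      for (int a = 0; a < 2; a++)
        if (!chosen1[s][a]) q1[s][a] += alpha * (q_init - q1[s][a]);
    for (int s = 0; s < 2; s++)
      for (int a = 0; a < nA2; a++)
        if (!chosen2[s][a]) q2[s][a] += alpha * (q_init - q2[s][a]);

    // perseveration bookkeeping: +/-1 only if the previous trial of this
    // stage-1 state had an observed choice and no missed deadline
    bool ok = have_c1 && (variant == 1 || m2[t] == 0);
    last_ok[s1i] = ok;
    if (c1[t] > 0) last_choice[s1i] = c1[t];
  }
}

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

//' @keywords internal
// [[Rcpp::export(name = ".rl_sweep_cpp")]]
NumericMatrix rl_sweep_cpp(List d, double alpha, double lam,
                           int variant, double q_init) {
  Sweep sw;
  rl_sweep(d["s1"], d["c1"], d["s2"], d["c2"], d["rew"], d["m1"], d["m2"],
           variant, q_init, alpha, lam, sw);
  int n = sw.dq_mf.size();
  NumericMatrix out(n, 4);
  colnames(out) = CharacterVector::create("dq_mf", "dq_mb", "rep", "dq2");
  for (int t = 0; t < n; t++) {
    out(t, 0) = sw.dq_mf[t]; out(t, 1) = sw.dq_mb[t];
    out(t, 2) = sw.rep[t];   out(t, 3) = sw.dq2[t];
  }
  return out;
}

// ---- stage-1 choice-only (softmax) likelihood ------------------------------
// theta = (alpha_u, lam_u, b_mb, b_mf, b_rep, b2); alpha/lam on the
// unconstrained scale, mapped through the logistic inside.

static double ll_stage1(const List& d, const NumericVector& theta,
                        int variant, double q_init, double rt_floor) {
  double alpha = logistic(theta[0]), lam = logistic(theta[1]);
  double b_mb = theta[2], b_mf = theta[3], b_rep = theta[4], b2 = theta[5];
  Sweep sw;
  IntegerVector s1 = d["s1"], c1 = d["c1"], s2 = d["s2"], c2 = d["c2"],
                m1 = d["m1"], m2 = d["m2"];
  NumericVector rew = d["rew"], rt1 = d["rt1"], rt2 = d["rt2"];
  rl_sweep(s1, c1, s2, c2, rew, m1, m2, variant, q_init, alpha, lam, sw);
  double ll = 0.0;
  int n = s1.size();
  for (int t = 0; t < n; t++) {
    if (m1[t] == 0 && c1[t] > 0 &&
        R_finite(rt1[t]) && rt1[t] >= rt_floor) {
      double x = b_mb * sw.dq_mb[t] + b_mf * sw.dq_mf[t] + b_rep * sw.rep[t];
      double p1 = logistic(x);
      double p = (c1[t] == 1) ? p1 : 1.0 - p1;
      ll += std::log(std::max(p, 1e-300));
    }
    if (variant == 0 && m2[t] == 0 && c2[t] > 0 && R_finite(sw.dq2[t]) &&
        R_finite(rt2[t]) && rt2[t] >= rt_floor) {
      double p1 = logistic(b2 * sw.dq2[t]);
      double p = (c2[t] == 1) ? p1 : 1.0 - p1;
      ll += std::log(std::max(p, 1e-300));
    }
  }
  return ll;
}

// ---- drift-diffusion likelihood of one session -----------------------------
// Trial regressors per the conflict-modulated decision layer.  model codes:
//   0 between-system (conflict value/action/interaction terms)
//   1 within-system  (|dq| of the other system on drift; both |dq| on boundary)
//   2 reduced between (squared value conflict, no action conflict)
//   3 reduced within  (squared within-system terms)
// theta layout (full 17-slot vector; unused slots ignored):
//   0 v_mb_base 1 v_mb_c1 2 v_mb_c2 3 v_mb_c3
//   4 v_mf_base 5 v_mf_c1 6 v_mf_c2 7 v_mf_c3
//   8 v_rep 9 a1_base 10 a_c1 11 a_c2 12 a_c3 13 s_rep 14 v2_base 15 a2 16 tau
// between: c1 = conflict_value, c2 = conflict_action, c3 = interaction
// within (drift): v_mb uses c1 * |dq_mf|, v_mf uses c1 * |dq_mb|
// within (boundary): a_c1 * |dq_mb| + a_c2 * |dq_mf|
// reduced between: c1 = (dq_mb - dq_mf)^2 on both drift strengths and boundary
// reduced within: squared analogues of the within terms

static double ll_ddm(const List& d, const Sweep& sw, const NumericVector& th,
                     int model, int variant, double rt_floor) {
  IntegerVector c1 = d["c1"], c2 = d["c2"], m1 = d["m1"], m2 = d["m2"],
                s2 = d["s2"];
  NumericVector rt1 = d["rt1"], rt2 = d["rt2"];
  double tau = th[16];
  if (tau < 0.0 || th[9] < 0.0 || (variant == 0 && th[15] <= 0.0))
    return R_NegInf;
  double ll = 0.0;
  int n = c1.size();
  for (int t = 0; t < n; t++) {
    bool v1ok = (m1[t] == 0) && (c1[t] > 0) && R_finite(rt1[t]) &&
                rt1[t] >= rt_floor;
    bool v2ok = (variant == 1) || ((m2[t] == 0) && (c2[t] > 0) &&
                R_finite(rt2[t]) && rt2[t] >= rt_floor);
    if (!(v1ok && v2ok)) continue;   // whole trial left out of the likelihood
    double dqmf = sw.dq_mf[t], dqmb = sw.dq_mb[t], rep = sw.rep[t];
    double vmb, vmf, a1;
    if (model == 0 || model == 2) {
      double cv, ca;
      if (model == 0) {
        cv = std::fabs(dqmb - dqmf);
        ca = (dqmb * dqmf < 0.0) ? 1.0 : 0.0;
      } else {
        cv = (dqmb - dqmf) * (dqmb - dqmf);
        ca = 0.0;
      }
      vmb = th[0] + th[1] * cv + th[2] * ca + th[3] * cv * ca;
      vmf = th[4] + th[5] * cv + th[6] * ca + th[7] * cv * ca;
      a1 = th[9] + th[10] * cv + th[11] * ca + th[12] * cv * ca;
    } else {
      double wmf = std::fabs(dqmf), wmb = std::fabs(dqmb);
      if (model == 3) { wmf *= wmf; wmb *= wmb; }
      vmb = th[0] + th[1] * wmf;   // other system's within-conflict
      vmf = th[4] + th[5] * wmb;
      a1 = th[9] + th[10] * wmb + th[11] * wmf;
    }
    if (!(a1 > 0.0)) return R_NegInf;
    double v1 = vmf * dqmf + vmb * dqmb + th[8] * rep;
    double w1 = logistic(th[13] * rep);
    double t1 = rt1[t] - tau;
    if (!(t1 > 0.0)) return R_NegInf;
    ll += wfpt_lpdf_choice(t1, c1[t], v1, a1, w1);
    if (variant == 0) {
      double t2 = rt2[t] - tau;
      if (!(t2 > 0.0)) return R_NegInf;
      double v2 = th[14] * sw.dq2[t];
      ll += wfpt_lpdf_choice(t2, c2[t], v2, th[15], 0.5);
    }
    if (!R_finite(ll)) return R_NegInf;
  }
  return ll;
}

//' @keywords internal
// [[Rcpp::export(name = ".ll_stage1_all_cpp")]]
NumericVector ll_stage1_all_cpp(List subjects, NumericMatrix theta,
                                int variant, double q_init, double rt_floor) {
  int J = subjects.size();
  NumericVector out(J);
  for (int j = 0; j < J; j++) {
    List d = subjects[j];
    NumericVector th = theta(_, j);
    out[j] = ll_stage1(d, th, variant, q_init, rt_floor);
  }
  return out;
}

//' @keywords internal
// [[Rcpp::export(name = ".ll_ddm_all_cpp")]]
NumericVector ll_ddm_all_cpp(List subjects, NumericMatrix theta, int model,
                             int variant, double rt_floor) {
  int J = subjects.size();
  NumericVector out(J);
  for (int j = 0; j < J; j++) {
    List d = subjects[j];
    NumericVector th = theta(_, j);
    Sweep sw;
    NumericVector dq_mf = d["dq_mf"], dq_mb = d["dq_mb"], rep = d["rep"],
                  dq2 = d["dq2"];
    sw.dq_mf.assign(dq_mf.begin(), dq_mf.end());
    sw.dq_mb.assign(dq_mb.begin(), dq_mb.end());
    sw.rep.assign(rep.begin(), rep.end());
    sw.dq2.assign(dq2.begin(), dq2.end());
    out[j] = ll_ddm(d, sw, th, model, variant, rt_floor);
  }
  return out;
}

// Reduced single-pass models: alpha and lambda are sampled, so the RL sweep is
// rerun inside the likelihood.  theta = (alpha_u, lam_u, <17-slot ddm vector>).
//' @keywords internal
// [[Rcpp::export(name = ".ll_reduced_all_cpp")]]
NumericVector ll_reduced_all_cpp(List subjects, NumericMatrix theta, int model,
                                 int variant, double q_init, double rt_floor) {
  int J = subjects.size();
  NumericVector out(J);
  for (int j = 0; j < J; j++) {
    List d = subjects[j];
    NumericVector th = theta(_, j);
    double alpha = logistic(th[0]), lam = logistic(th[1]);
    Sweep sw;
    rl_sweep(d["s1"], d["c1"], d["s2"], d["c2"], d["rew"], d["m1"], d["m2"],
             variant, q_init, alpha, lam, sw);
    NumericVector ddm_th(17);
    for (int k = 0; k < 17; k++) ddm_th[k] = th[k + 2];
    out[j] = ll_ddm(d, sw, ddm_th, model, variant, rt_floor);
  }
  return out;
}
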