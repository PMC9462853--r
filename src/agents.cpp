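#include <Rcpp.h>
using namespace Rcpp;

// Port coding throughout: 1 = left, 2 = right.
// common_dest_left is the outcome port (1/2) reached by the common
// transition from the left choice port; the right choice port's common
// destination is the other outcome port (the map is a bijection).

static inline int other_port(int p) { return p == 1 ? 2 : 1; }

// Per-trial latent value trajectories of the mixture-of-agents model,
// given an observed session. Values returned are the PRE-choice values:
// row t holds the values used to score the choice on trial t; updates
// from trial t's outcome land in row t+1.
//
// form: 0 = compact (single learning rate), 1 = split (value/reward rates).
// session_start: 1 where a new session begins (values re-initialised).
// [[Rcpp::export]]
NumericMatrix agent_trajectories_cpp(IntegerVector choice,
                                     IntegerVector outcome,
                                     NumericVector reward,
                                     IntegerVector common,
                                     IntegerVector session_start,
                                     int common_dest_left,
                                     double p_common,
                                     int form,
                                     double alpha_plan,
                                     double alpha_value,
                                     double alpha_reward,
                                     double ev_baseline,
                                     double alpha_persev) {
  int n = choice.size();
  NumericMatrix out(n, 8);
  colnames(out) = CharacterVector::create(
      "V_left", "V_right", "Q_plan_left", "Q_plan_right",
      "Q_np_left", "Q_np_right", "Q_persev_left", "Q_persev_right");

  double V[3], Qnp[3], Qp[3]; // 1-indexed
  int cdl = common_dest_left, cdr = other_port(common_dest_left);

  for (int t = 0; t < n; ++t) {
    if (session_start[t]) {
      V[1] = 0.5; V[2] = 0.5;
      Qnp[1] = 0.0; Qnp[2] = 0.0;
      Qp[1] = 0.0; Qp[2] = 0.0;
    }
    out(t, 0) = V[1];
    out(t, 1) = V[2];
    out(t, 2) = p_common * V[cdl] + (1.0 - p_common) * V[cdr];
    out(t, 3) = p_common * V[cdr] + (1.0 - p_common) * V[cdl];
    out(t, 4) = Qnp[1];
    out(t, 5) = Qnp[2];
    out(t, 6) = Qp[1];
    out(t, 7) = Qp[2];

    int c = choice[t], o = outcome[t];
    double r = reward[t];

    // novelty preference: uncommon-stay / common-switch
    Qnp[c] = common[t] ? 0.0 : 1.0;
    Qnp[other_port(c)] = 1.0 - Qnp[c];

    // perseveration: exponential trace of past choices
    Qp[c] = (1.0 - alpha_persev) * Qp[c] + alpha_persev;
    Qp[other_port(c)] = (1.0 - alpha_persev) * Qp[other_port(c)];

    // outcome values: symmetric update, visited port toward the reward,
    // unvisited port away from it
    int u = other_port(o);
    if (form == 0) {
      double Vo = V[o], Vu = V[u];
      V[o] = (1.0 - alpha_plan) * Vo + alpha_plan * r;
      V[u] = (1.0 - alpha_plan) * Vu - alpha_plan * r;
    } else {
      double Vo = V[o], Vu = V[u];
      double decay = (1.0 - alpha_value - alpha_reward) * ev_baseline;
      V[o] = alpha_value * Vo + alpha_reward * r + decay;
      V[u] = alpha_value * Vu - alpha_reward * r + decay;
    }
  }
  return out;
}

// Generative simulation of one session: two-step task environment plus
// the mixture-of-agents policy, with optional scheduled "inactivation"
// impairments. Consumes R's RNG (seed with set.seed() from R). A fixed
// number of uniform draws is consumed per trial so that trial tables are
// reproducible across impairment variants sharing a seed.
//
// schedule: per-trial condition, 0 none / 1 outcome / 2 choice / 3 both.
// impair_target: 0 none, 1 beta_plan, 2 alpha_value, 3 alpha_reward.
// beta_trigger / alpha_trigger: length-3 logicals saying which scheduled
// types (outcome, choice, both) trigger the impairment. beta_plan is
// impaired on the trial FOLLOWING a triggering trial; alpha impairments
// apply to the triggering trial's own value update.
// [[Rcpp::export]]
List simulate_session_cpp(int n_trials,
                          double beta_plan, double beta_np,
                          double beta_persev, double beta_bias,
                          int form,
                          double alpha_plan, double alpha_value,
                          double alpha_reward, double ev_baseline,
                          double alpha_persev,
                          double p_common, double p_high, double p_low,
                          int min_block_length, double block_hazard,
                          int common_dest_left,
                          int init_high_port,
                          IntegerVector schedule,
                          int impair_target, double multiplier,
                          LogicalVector beta_trigger,
                          LogicalVector alpha_trigger) {
  IntegerVector choice(n_trials), outcome(n_trials), common(n_trials),
      reward(n_trials), block_high(n_trials);

  double V[3] = {0, 0.5, 0.5}, Qnp[3] = {0, 0, 0}, Qp[3] = {0, 0, 0};
  int cdl = common_dest_left, cdr = other_port(common_dest_left);
  int high = init_high_port;
  int tib = 0; // completed trials in the current block

  for (int t = 0; t < n_trials; ++t) {
    double u_haz = R::unif_rand();
    double u_choice = R::unif_rand();
    double u_trans = R::unif_rand();
    double u_rew = R::unif_rand();

    // block dynamics: hazard applies once the minimum length is reached
    if (tib >= min_block_length && u_haz < block_hazard) {
      high = other_port(high);
      tib = 0;
    }
    tib += 1;
    block_high[t] = high;

    // effective planning weight (impaired on trials following a trigger)
    double bp = beta_plan;
    if (impair_target == 1 && t > 0 && schedule[t - 1] > 0 &&
        beta_trigger[schedule[t - 1] - 1])
      bp = beta_plan * multiplier;

    double Qplan_l = p_common * V[cdl] + (1.0 - p_common) * V[cdr];
    double Qplan_r = p_common * V[cdr] + (1.0 - p_common) * V[cdl];
    double Ql = bp * Qplan_l + beta_np * Qnp[1] + beta_persev * Qp[1] +
                beta_bias * 1.0;
    double Qr = bp * Qplan_r + beta_np * Qnp[2] + beta_persev * Qp[2] +
                beta_bias * (-1.0);
    double m = Ql > Qr ? Ql : Qr;
    double pl = std::exp(Ql - m) / (std::exp(Ql - m) + std::exp(Qr - m));

    int c = (u_choice < pl) ? 1 : 2;
    int is_common = (u_trans < p_common) ? 1 : 0;
    int cd = (c == 1) ? cdl : cdr;
    int o = is_common ? cd : other_port(cd);
    double p_r = (o == high) ? p_high : p_low;
    int r = (u_rew < p_r) ? 1 : 0;

    choice[t] = c; common[t] = is_common; outcome[t] = o; reward[t] = r;

    // agent updates
    Qnp[c] = is_common ? 0.0 : 1.0;
    Qnp[other_port(c)] = 1.0 - Qnp[c];
    Qp[c] = (1.0 - alpha_persev) * Qp[c] + alpha_persev;
    Qp[other_port(c)] = (1.0 - alpha_persev) * Qp[other_port(c)];

    double av = alpha_value, ar = alpha_reward, ap = alpha_plan;
    if (schedule[t] > 0 && alpha_trigger[schedule[t] - 1]) {
      if (impair_target == 2) av = alpha_value * multiplier;
      if (impair_target == 3) ar = alpha_reward * multiplier;
    }
    int uo = other_port(o);
    if (form == 0) {
      double Vo = V[o], Vu = V[uo];
      V[o] = (1.0 - ap) * Vo + ap * r;
      V[uo] = (1.0 - ap) * Vu - ap * r;
    } else {
      double Vo = V[o], Vu = V[uo];
      double decay = (1.0 - av - ar) * ev_baseline;
      V[o] = av * Vo + ar * r + decay;
      V[uo] = av * Vu - ar * r + decay;
    }
  }

  return List::create(_["choice"] = choice, _["common"] = common,
                      _["outcome"] = outcome, _["reward"] = reward,
                      _["block_high"] = block_high);
}
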