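# Shared small fixtures: a typical well-trained "rat" and convenience
# simulators. All randomness is seeded at the call site.

typical_params <- function(...) {
  args <- utils::modifyList(
    list(beta_plan = 1.5, beta_np = 0.2, beta_persev = 0.8,
         beta_bias = 0.1, alpha_plan = 0.35, alpha_persev = 0.6),
    list(...))
  do.call(agent_params, args)
}

sim_rat <- function(params, n_trials, session_length = 1000, seed = 1,
                    schedule_spec = NULL, impairment = impairment_spec("none"),
                    config = task_config()) {
  set.seed(seed)
  simulate_rat(params, n_trials, session_length, config,
               schedule_spec = schedule_spec, impairment = impairment)
}

# small spike fixture: planner rat, design and counts with given gains
sim_spikes <- function(n_trials = 300, seed = 3, gains = NULL,
                       n_units = 4, baseline_hz = 10) {
  p <- typical_params(alpha_plan = 0.5)
  tr <- sim_rat(p, n_trials, session_length = ceiling(n_trials / 2),
                seed = seed)
  vals <- agent_values(tr, p)
  des <- build_neural_design(tr, vals)
  st <- generate_spikes(des, spike_gen_spec(baseline_hz, gains),
                        n_units = n_units)
  list(params = p, trials = tr, values = vals, design = des, spikes = st)
}
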