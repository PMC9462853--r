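#' Mixture-of-agents parameters
#'
#' Parameters of the mixture-of-agents model of two-step behavior. Four
#' agents contribute weighted values to a softmax policy: model-based
#' planning (`beta_plan`), novelty preference (`beta_np`), perseveration
#' (`beta_persev`) and a fixed side bias (`beta_bias`). The planning
#' agent's outcome-value learning rule comes in two forms: the compact
#' form with a single learning rate `alpha_plan`, and the split form with
#' separate retention (`alpha_value`) and reward (`alpha_reward`) rates
#' plus decay toward the task's random-policy expected reward
#' (`expected_value_baseline`). The split form separates the contribution
#' of stored value from that of immediate reward, which is what lets
#' synthetic inactivation experiments impair one without the other.
#'
#' @param beta_plan,beta_np,beta_persev,beta_bias Agent weights.
#' @param alpha_plan Compact-form learning rate in \[0, 1\].
#' @param alpha_persev Perseveration trace decay rate in \[0, 1\].
#' @param alpha_value,alpha_reward Split-form rates; both nonnegative with
#'   `alpha_value + alpha_reward <= 1`.
#' @param expected_value_baseline Expected reward of a random-choice
#'   policy, the split-form decay target (default 0.5).
#' @param form `"compact"` or `"split"`.
#' @return A list of class `agent_params`.
#' @examples
#' p <- agent_params(beta_plan = 1.5, alpha_plan = 0.35)
#' @export
agent_params <- function(beta_plan = 0, beta_np = 0, beta_persev = 0,
                         beta_bias = 0, alpha_plan = 0.5,
                         alpha_persev = 0.5, alpha_value = NA_real_,
                         alpha_reward = NA_real_,
                         expected_value_baseline = 0.5,
                         form = c("compact", "split")) {
  form <- match.arg(form)
  for (b in list(beta_plan, beta_np, beta_persev, beta_bias)) {
    if (!is.numeric(b) || !is.finite(b)) abort("agent weights must be finite")
  }
  if (!is_probability(alpha_persev)) abort("alpha_persev must lie in [0, 1]")
  if (!is_probability(expected_value_baseline)) {
    abort("expected_value_baseline must lie in [0, 1]")
  }
  if (form == "compact") {
    if (!is_probability(alpha_plan)) abort("alpha_plan must lie in [0, 1]")
  } else {
    if (is.na(alpha_value) || is.na(alpha_reward)) {
      abort("split form requires alpha_value and alpha_reward")
    }
    if (alpha_value < 0 || alpha_reward < 0 ||
        alpha_value + alpha_reward > 1 + 1e-12) {
      abort("split form requires alpha_value, alpha_reward >= 0 and alpha_value + alpha_reward <= 1")
    }
  }
  structure(
    list(beta_plan = beta_plan, beta_np = beta_np,
         beta_persev = beta_persev, beta_bias = beta_bias,
         alpha_plan = alpha_plan, alpha_persev = alpha_persev,
         alpha_value = alpha_value, alpha_reward = alpha_reward,
         expected_value_baseline = expected_value_baseline, form = form),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params> form =", x$form, "\n")
  nm <- setdiff(names(x), "form")
  vals <- unlist(x[nm])
  print(round(vals, 4))
  invisible(x)
}

#' Planning values of the two choice ports
#'
#' Combines learned outcome-port values with the transition model:
#' `Q_plan(c) = sum_o V(o) P(o | c)`, the expected probability that each
#' choice ultimately yields reward.
#'
#' @param V Named numeric vector of outcome-port values
#'   (`c(left = , right = )`).
#' @param transition_matrix 2 x 2 matrix `P(o | c)` with rows = choice
#'   ports and columns = outcome ports, both ordered (left, right); rows
#'   must sum to 1.
#' @return Named numeric vector of choice values.
#' @export
compute_choice_values <- function(V, transition_matrix) {
  if (length(V) != ncol(transition_matrix)) {
    abort("V must have one entry per outcome port")
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-8)) {
    abort("transition_matrix rows must sum to 1")
  }
  q <- drop(transition_matrix %*% as.numeric(V))
  names(q) <- rownames(transition_matrix) %||% PORTS
  q
}

#' Transition matrix implied by a task configuration
#'
#' @param config A [task_config()].
#' @return 2 x 2 matrix `P(o | c)`, rows = choices, columns = outcomes.
#' @export
transition_matrix <- function(config = task_config()) {
  m <- matrix(0, 2, 2, dimnames = list(choice = PORTS, outcome = PORTS))
  for (c in PORTS) {
    dest <- unname(config$transition_map[[c]])
    m[c, dest] <- config$p_common
    m[c, other_port(dest)] <- 1 - config$p_common
  }
  m
}

#' Outcome-value learning rules
#'
#' `update_outcome_values_compact()` applies the single-rate rule: the
#' visited port moves toward the reward, `(1 - a) V + a r`, and the
#' unvisited port moves symmetrically away, `(1 - a) V - a r`.
#' `update_outcome_values_split()` applies the two-rate generalization
#' `a_value V +/- a_reward r + (1 - a_value - a_reward) E[V]`, which
#' reduces to the compact rule when `a_value = 1 - a` and `a_reward = a`.
#' Values are not clipped and may leave \[0, 1\].
#'
#' @param V Named numeric vector of outcome-port values.
#' @param outcome_port Visited outcome port.
#' @param reward Reward on the trial, 0 or 1.
#' @param alpha_plan,alpha_value,alpha_reward Learning rates.
#' @param expected_value_baseline Decay target of the split rule.
#' @return Updated value vector.
#' @export
update_outcome_values_compact <- function(V, outcome_port, reward,
                                          alpha_plan) {
  if (!is_probability(alpha_plan)) abort("alpha_plan must lie in [0, 1]")
  if (!reward %in% c(0, 1)) abort("reward must be 0 or 1")
  visited <- names(V) == outcome_port
  out <- (1 - alpha_plan) * V + alpha_plan * reward * ifelse(visited, 1, -1)
  out
}

#' @rdname update_outcome_values_compact
#' @export
update_outcome_values_split <- function(V, outcome_port, reward,
                                        alpha_value, alpha_reward,
                                        expected_value_baseline = 0.5) {
  if (alpha_value < 0 || alpha_reward < 0 ||
      alpha_value + alpha_reward > 1 + 1e-12) {
    abort("require alpha_value, alpha_reward >= 0 and sum <= 1")
  }
  visited <- names(V) == outcome_port
  alpha_value * V + alpha_reward * reward * ifelse(visited, 1, -1) +
    (1 - alpha_value - alpha_reward) * expected_value_baseline
}

#' Novelty-preference update
#'
#' Implements the uncommon-stay/common-switch pattern: after a common
#' transition the chosen port's novelty value is 0 (and the other port's
#' 1); after an uncommon transition it is 1. Entries are always a
#' permutation of (0, 1) after the first trial.
#'
#' @param Q_np Named numeric vector of novelty values per choice port.
#' @param choice Chosen port.
#' @param transition `"common"` or `"uncommon"`.
#' @return Updated novelty values.
#' @export
update_novelty <- function(Q_np, choice, transition) {
  if (!transition %in% c("common", "uncommon")) {
    abort("transition must be 'common' or 'uncommon'")
  }
  chosen <- names(Q_np) == choice
  Q_np[chosen] <- if (transition == "common") 0 else 1
  Q_np[!chosen] <- 1 - Q_np[chosen]
  Q_np
}

#' Perseveration update
#'
#' Exponentially decaying trace of past choices: the chosen port's value
#' moves toward 1, the unchosen port's decays toward 0.
#'
#' @param Q_persev Named numeric vector of perseveration values.
#' @param choice Chosen port.
#' @param alpha_persev Decay rate in \[0, 1\].
#' @return Updated perseveration values.
#' @export
update_perseveration <- function(Q_persev, choice, alpha_persev) {
  if (!is_probability(alpha_persev)) abort("alpha_persev must lie in [0, 1]")
  chosen <- names(Q_persev) == choice
  (1 - alpha_persev) * Q_persev + alpha_persev * ifelse(chosen, 1, 0)
}

#' Agent state at the start of a session
#'
#' Outcome values start at 0.5 for both ports; novelty and perseveration
#' values start at 0, so the first trial is driven by planning (from the
#' flat value prior) and bias alone. The bias values are fixed at +1
#' (left) and -1 (right).
#'
#' @param config A [task_config()]; the transition model is set to the
#'   rat's true transition map.
#' @return A list of class `agent_state`.
#' @export
agent_state <- function(config = task_config()) {
  structure(
    list(V = c(left = 0.5, right = 0.5),
         Q_np = c(left = 0, right = 0),
         Q_persev = c(left = 0, right = 0),
         Q_bias = c(left = 1, right = -1),
         transition_matrix = transition_matrix(config)),
    class = "agent_state"
  )
}

#' Mixture policy choice probabilities
#'
#' Combines the agents' values with their weights,
#' `Q_total(c) = sum_A beta_A Q_A(c)`, and maps the totals through a
#' softmax. The softmax is computed in the log domain with
#' max-subtraction, so probabilities are exact up to floating point and
#' do not overflow for `|Q_total| <= 700`.
#'
#' @param state An [agent_state()].
#' @param params An [agent_params()].
#' @return A list with `Q_total` and `pi`, both named by choice port.
#' @export
choice_probability <- function(state, params) {
  q_plan <- compute_choice_values(state$V, state$transition_matrix)
  q_total <- params$beta_plan * q_plan + params$beta_np * state$Q_np +
    params$beta_persev * state$Q_persev + params$beta_bias * state$Q_bias
  if (any(!is.finite(q_total))) abort("non-finite Q_total")
  p_left <- softmax2(q_total[["left"]], q_total[["right"]])
  list(Q_total = q_total, pi = c(left = p_left, right = 1 - p_left))
}

#' Per-trial latent value trajectories
#'
#' Runs the mixture-of-agents model over an observed trial table and
#' returns, per trial, the pre-choice values of every agent (the values
#' that scored that trial's choice; learning from the trial's outcome
#' applies to the next row). Values reset at each session start.
#'
#' @param trials A trial tibble (see [read_trials()] for columns), ordered
#'   within sessions.
#' @param params An [agent_params()].
#' @param config A [task_config()].
#' @return A tibble with columns `V_left, V_right, Q_plan_left,
#'   Q_plan_right, Q_np_left, Q_np_right, Q_persev_left, Q_persev_right`
#'   plus the scored choice probability `p_choice`.
#' @export
agent_values <- function(trials, params, config = task_config()) {
  check_trials(trials)
  n <- nrow(trials)
  if (n == 0) {
    return(tibble::tibble(V_left = double(), V_right = double(),
                          Q_plan_left = double(), Q_plan_right = double(),
                          Q_np_left = double(), Q_np_right = double(),
                          Q_persev_left = double(),
                          Q_persev_right = double(), p_choice = double()))
  }
  traj <- agent_trajectories_cpp(
    choice = port_to_int(trials$choice),
    outcome = port_to_int(trials$outcome_port),
    reward = as.numeric(trials$reward),
    common = as.integer(trials$transition == "common"),
    session_start = session_starts(trials$session_id),
    common_dest_left = port_to_int(unname(config$transition_map[["left"]])),
    p_common = config$p_common,
    form = if (params$form == "split") 1L else 0L,
    alpha_plan = params$alpha_plan %||% 0.5,
    alpha_value = if (is.na(params$alpha_value)) 0 else params$alpha_value,
    alpha_reward = if (is.na(params$alpha_reward)) 0 else params$alpha_reward,
    ev_baseline = params$expected_value_baseline,
    alpha_persev = params$alpha_persev
  )
  out <- tibble::as_tibble(traj)
  q_left <- params$beta_plan * out$Q_plan_left +
    params$beta_np * out$Q_np_left +
    params$beta_persev * out$Q_persev_left + params$beta_bias
  q_right <- params$beta_plan * out$Q_plan_right +
    params$beta_np * out$Q_np_right +
    params$beta_persev * out$Q_persev_right - params$beta_bias
  p_left <- softmax2(q_left, q_right)
  out$p_choice <- ifelse(trials$choice == "left", p_left, 1 - p_left)
  out
}

#' Session negative log-likelihood of the mixture model
#'
#' Scores each trial's observed choice under the mixture policy with the
#' pre-trial agent state, applying all latent updates in trial order.
#' Latent values reset at each session boundary, so the result is
#' invariant to the order in which sessions are concatenated.
#'
#' @inheritParams agent_values
#' @return The scalar negative log-likelihood; 0 for an empty table.
#' @export
session_negloglik <- function(params, trials, config = task_config()) {
  if (nrow(trials) == 0) return(0)
  vals <- agent_values(trials, params, config)
  -sum(log(vals$p_choice))
}

#' Read and write agent parameters
#'
#' Parameters are stored as a flat `key: value` text document with the
#' canonical names (`beta_plan`, `beta_np`, `beta_persev`, `beta_bias`,
#' `alpha_plan`, `alpha_value`, `alpha_reward`, `alpha_persev`,
#' `expected_value_baseline`, `form`).
#'
#' @param params An [agent_params()].
#' @param path File path.
#' @return `read_agent_params()` returns an [agent_params()];
#'   `write_agent_params()` returns `path` invisibly.
#' @export
write_agent_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_agent_params
#' @export
read_agent_params <- function(path) {
  x <- yaml::read_yaml(path)
  x <- lapply(x, function(v) if (is.null(v)) NA_real_ else v)
  do.call(agent_params, x)
}
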