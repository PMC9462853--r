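#' Two-step task configuration
#'
#' Bundles the generative constants of the two-step task environment: the
#' common-transition probability linking choice ports to outcome ports, the
#' block reward probabilities, and the block-reversal dynamics (a minimum
#' block length followed by a constant per-trial reversal hazard).
#'
#' @param p_common Probability that a choice leads to its common outcome
#'   port (default 0.8).
#' @param p_high,p_low Reward probabilities at the currently good and bad
#'   outcome ports (defaults 0.8 and 0.2).
#' @param min_block_length Minimum number of trials per reward block
#'   (default 10).
#' @param block_hazard Per-trial probability of a block reversal once the
#'   minimum length has been reached (default 0.02).
#' @param transition_map Named character vector giving the common outcome
#'   port for each choice port; must be a bijection. The default maps left
#'   to left. Counterbalanced (crossed) rats use
#'   `c(left = "right", right = "left")`.
#' @return A list of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$p_common
#' @export
task_config <- function(p_common = 0.8, p_high = 0.8, p_low = 0.2,
                        min_block_length = 10, block_hazard = 0.02,
                        transition_map = c(left = "left", right = "right")) {
  transition_map <- unlist(transition_map)
  for (p in list(p_common, p_high, p_low, block_hazard)) {
    if (!is_probability(p)) abort("task probabilities must lie in [0, 1]")
  }
  if (p_high <= p_low) abort("p_high must exceed p_low")
  if (!is.numeric(min_block_length) || min_block_length < 1) {
    abort("min_block_length must be >= 1")
  }
  if (!setequal(names(transition_map), PORTS) ||
      !setequal(unname(transition_map), PORTS)) {
    abort("transition_map must be a bijection on {left, right}")
  }
  structure(
    list(p_common = p_common, p_high = p_high, p_low = p_low,
         min_block_length = as.integer(min_block_length),
         block_hazard = block_hazard,
         transition_map = transition_map[PORTS]),
    class = "task_config"
  )
}

#' Reward block state
#'
#' @param high_port Outcome port currently rewarded at the high rate.
#' @param trials_in_block Number of completed trials in the current block.
#' @return A list of class `block_state`.
#' @export
block_state <- function(high_port = "left", trials_in_block = 0L) {
  if (!high_port %in% PORTS) abort("high_port must be 'left' or 'right'")
  if (trials_in_block < 0) abort("trials_in_block must be nonnegative")
  structure(list(high_port = high_port,
                 trials_in_block = as.integer(trials_in_block)),
            class = "block_state")
}

#' Advance the reward block by one trial
#'
#' Called once per trial. While `trials_in_block` is below the configured
#' minimum the high port never changes and the counter increments. Once the
#' minimum is reached the high port reverses with probability
#' `block_hazard`; on a reversal the counter resets to zero so every block
#' lasts at least `min_block_length` trials.
#'
#' @param state A [block_state()].
#' @param config A [task_config()].
#' @return The updated `block_state`.
#' @export
advance_block <- function(state, config = task_config()) {
  stopifnot(inherits(state, "block_state"), inherits(config, "task_config"))
  u <- runif(1)
  if (state$trials_in_block >= config$min_block_length &&
      u < config$block_hazard) {
    block_state(other_port(state$high_port), 0L)
  } else {
    block_state(state$high_port, state$trials_in_block + 1L)
  }
}

#' Sample the choice-to-outcome transition
#'
#' @param choice `"left"` or `"right"`.
#' @param config A [task_config()].
#' @return A list with `outcome_port` and `transition`
#'   (`"common"`/`"uncommon"`).
#' @export
sample_transition <- function(choice, config = task_config()) {
  if (!choice %in% PORTS) abort("choice must be 'left' or 'right'")
  common_dest <- unname(config$transition_map[[choice]])
  if (runif(1) < config$p_common) {
    list(outcome_port = common_dest, transition = "common")
  } else {
    list(outcome_port = other_port(common_dest), transition = "uncommon")
  }
}

#' Sample the trial reward
#'
#' @param outcome_port The outcome port the rat visited.
#' @param block A [block_state()].
#' @param config A [task_config()].
#' @return Integer reward, 0 or 1.
#' @export
sample_reward <- function(outcome_port, block, config = task_config()) {
  if (!outcome_port %in% PORTS) abort("outcome_port must be a port label")
  p <- if (outcome_port == block$high_port) config$p_high else config$p_low
  as.integer(runif(1) < p)
}

#' Label a transition under a task configuration
#'
#' @inheritParams sample_transition
#' @param outcome_port Observed outcome port.
#' @return `"common"` or `"uncommon"`.
#' @export
transition_label <- function(choice, outcome_port, config = task_config()) {
  ifelse(unname(config$transition_map[choice]) == outcome_port,
         "common", "uncommon")
}

#' Read and write trial tables
#'
#' Trial tables are delimited text with one row per trial and columns
#' `session_id, trial_index, choice, transition, outcome_port, reward,
#' inactivation, block_high_port, excluded`. Trial indices are 0-based and
#' port labels lower case. A `rat` column is carried when present.
#'
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns
#'   `path` invisibly.
#' @export
read_trials <- function(path) {
  cols <- readr::cols(
    session_id = readr::col_integer(),
    trial_index = readr::col_integer(),
    choice = readr::col_character(),
    transition = readr::col_character(),
    outcome_port = readr::col_character(),
    reward = readr::col_integer(),
    inactivation = readr::col_character(),
    block_high_port = readr::col_character(),
    excluded = readr::col_logical(),
    .default = readr::col_guess()
  )
  trials <- readr::read_csv(path, col_types = cols, progress = FALSE)
  check_trials(trials)
  trials
}

#' @param trials A trial tibble.
#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}
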