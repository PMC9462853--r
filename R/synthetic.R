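EVENTS <- c("trial_start", "choice_port", "bottom_center", "outcome_port")

#' Inactivation schedule specification
#'
#' Scheduling of optogenetic-style inactivation in simulated sessions:
#' each of the three inactivation types (`outcome`, `choice`, `both`
#' periods) is scheduled independently on a fraction of even-numbered
#' trials; no trial carries two types.
#'
#' @param fraction_per_type Probability that an eligible trial receives
#'   each inactivation type (default 0.07; scalar or named vector over
#'   `outcome`, `choice`, `both`). The summed fraction must not exceed
#'   0.5.
#' @param even_trials_only Restrict scheduling to even-numbered trials
#'   (1-based within session; default TRUE).
#' @param max_duration_s Maximum inactivation duration in seconds
#'   (metadata only in simulation; default 15).
#' @return A list of class `inactivation_schedule_spec`.
#' @export
inactivation_schedule_spec <- function(fraction_per_type = 0.07,
                                       even_trials_only = TRUE,
                                       max_duration_s = 15) {
  types <- c("outcome", "choice", "both")
  if (length(fraction_per_type) == 1) {
    fraction_per_type <- stats::setNames(rep(fraction_per_type, 3), types)
  }
  if (!setequal(names(fraction_per_type), types)) {
    abort("fraction_per_type must cover outcome, choice, both")
  }
  fraction_per_type <- fraction_per_type[types]
  if (any(fraction_per_type < 0) || sum(fraction_per_type) > 0.5) {
    abort("scheduled fractions must be nonnegative and sum to at most 0.5")
  }
  structure(list(fraction_per_type = fraction_per_type,
                 even_trials_only = even_trials_only,
                 max_duration_s = max_duration_s),
            class = "inactivation_schedule_spec")
}

#' Impairment specification for synthetic inactivation datasets
#'
#' Which model parameter is impaired by scheduled inactivation, by how
#' much, and which scheduled types trigger it. Learning-rate targets
#' (`alpha_value`, `alpha_reward`) are impaired on the scheduled trial's
#' own value update and are triggered by outcome-period and both-period
#' inactivation; the decision-weight target (`beta_plan`) is impaired on
#' the choice of the trial following a scheduled trial and is triggered
#' by all three types.
#'
#' @param target `"none"`, `"beta_plan"`, `"alpha_value"` or
#'   `"alpha_reward"`.
#' @param multiplier Factor applied to the impaired parameter
#'   (default 0.3).
#' @param applies_to Scheduled types that trigger the impairment;
#'   defaults depend on `target` as above.
#' @return A list of class `impairment_spec`.
#' @export
impairment_spec <- function(target = c("none", "beta_plan", "alpha_value",
                                       "alpha_reward"),
                            multiplier = 0.3, applies_to = NULL) {
  target <- match.arg(target)
  if (multiplier < 0 || multiplier > 1) {
    abort("multiplier must lie in [0, 1]")
  }
  if (is.null(applies_to)) {
    applies_to <- switch(target,
      none = character(0),
      beta_plan = c("outcome", "choice", "both"),
      alpha_value = c("outcome", "both"),
      alpha_reward = c("outcome", "both"))
  }
  if (!all(applies_to %in% c("outcome", "choice", "both"))) {
    abort("applies_to must be a subset of outcome, choice, both")
  }
  structure(list(target = target, multiplier = multiplier,
                 applies_to = applies_to),
            class = "impairment_spec")
}

#' Draw an inactivation schedule
#'
#' Assigns each eligible (even-numbered, 1-based) trial independently to
#' one of the three inactivation types with the specified per-type
#' probability, or to `none`. Odd-numbered trials are always `none`.
#'
#' @param n_trials Number of trials.
#' @param spec An [inactivation_schedule_spec()].
#' @return Character vector of length `n_trials` over
#'   `none/outcome/choice/both`.
#' @export
make_schedule <- function(n_trials, spec = inactivation_schedule_spec()) {
  if (n_trials < 0) abort("n_trials must be nonnegative")
  tags <- rep("none", n_trials)
  if (n_trials == 0) return(tags)
  eligible <- if (spec$even_trials_only) {
    seq_len(n_trials) %% 2 == 0
  } else rep(TRUE, n_trials)
  u <- runif(n_trials)
  f <- spec$fraction_per_type
  cuts <- cumsum(f)
  tags[eligible & u < cuts[1]] <- "outcome"
  tags[eligible & u >= cuts[1] & u < cuts[2]] <- "choice"
  tags[eligible & u >= cuts[2] & u < cuts[3]] <- "both"
  tags
}

IMPAIR_CODES <- c(none = 0L, beta_plan = 1L, alpha_value = 2L,
                  alpha_reward = 3L)
SCHED_CODES <- c(none = 0L, outcome = 1L, choice = 2L, both = 3L)

#' Simulate one rat on the two-step task
#'
#' Generates behavior from the mixture-of-agents model interacting with
#' the task environment, session by session, with an optional
#' inactivation schedule and parameter impairment. Each session starts a
#' fresh agent state and a uniformly drawn high port. Uses the current R
#' random stream (`set.seed()` for reproducibility); a fixed number of
#' draws is consumed per trial, so cohorts generated from the same seed
#' share trial-by-trial randomness across impairment variants.
#'
#' @param params An [agent_params()] (split form required for
#'   learning-rate impairments).
#' @param n_trials Total trials.
#' @param session_length Trials per session (default 1000).
#' @param config A [task_config()].
#' @param schedule_spec An [inactivation_schedule_spec()], or NULL for no
#'   scheduling.
#' @param impairment An [impairment_spec()].
#' @param rat Optional rat identifier added as a column.
#' @return A trial tibble (see [read_trials()] for columns).
#' @export
simulate_rat <- function(params, n_trials, session_length = 1000,
                         config = task_config(),
                         schedule_spec = inactivation_schedule_spec(),
                         impairment = impairment_spec("none"),
                         rat = NULL) {
  stopifnot(inherits(params, "agent_params"),
            inherits(impairment, "impairment_spec"))
  if (impairment$target %in% c("alpha_value", "alpha_reward") &&
      params$form != "split") {
    abort("learning-rate impairments require split-form parameters (see translate_params())")
  }
  n_sessions <- ceiling(n_trials / session_length)
  sizes <- rep(session_length, n_sessions)
  if (n_sessions > 0) {
    sizes[n_sessions] <- n_trials - session_length * (n_sessions - 1)
  }
  alpha_trig <- c("outcome", "choice", "both") %in%
    (if (impairment$target %in% c("alpha_value", "alpha_reward"))
       impairment$applies_to else character(0))
  beta_trig <- c("outcome", "choice", "both") %in%
    (if (impairment$target == "beta_plan") impairment$applies_to
     else character(0))

  out <- purrr::map_dfr(seq_len(n_sessions), function(s) {
    ns <- sizes[s]
    tags <- if (is.null(schedule_spec)) rep("none", ns) else {
      make_schedule(ns, schedule_spec)
    }
    init_high <- sample.int(2, 1)
    sim <- simulate_session_cpp(
      n_trials = ns,
      beta_plan = params$beta_plan, beta_np = params$beta_np,
      beta_persev = params$beta_persev, beta_bias = params$beta_bias,
      form = if (params$form == "split") 1L else 0L,
      alpha_plan = if (is.na(params$alpha_plan)) 0.5 else params$alpha_plan,
      alpha_value = if (is.na(params$alpha_value)) 0 else params$alpha_value,
      alpha_reward = if (is.na(params$alpha_reward)) 0 else
        params$alpha_reward,
      ev_baseline = params$expected_value_baseline,
      alpha_persev = params$alpha_persev,
      p_common = config$p_common, p_high = config$p_high,
      p_low = config$p_low,
      min_block_length = config$min_block_length,
      block_hazard = config$block_hazard,
      common_dest_left = port_to_int(unname(config$transition_map["left"])),
      init_high_port = init_high,
      schedule = unname(SCHED_CODES[tags]),
      impair_target = unname(IMPAIR_CODES[impairment$target]),
      multiplier = impairment$multiplier,
      beta_trigger = beta_trig, alpha_trigger = alpha_trig)
    tibble::tibble(
      session_id = s,
      trial_index = seq_len(ns) - 1L,
      choice = int_to_port(sim$choice),
      transition = ifelse(sim$common == 1, "common", "uncommon"),
      outcome_port = int_to_port(sim$outcome),
      reward = as.integer(sim$reward),
      inactivation = tags,
      block_high_port = int_to_port(sim$block_high),
      excluded = FALSE)
  })
  if (n_sessions == 0) {
    out <- tibble::tibble(
      session_id = integer(), trial_index = integer(),
      choice = character(), transition = character(),
      outcome_port = character(), reward = integer(),
      inactivation = character(), block_high_port = character(),
      excluded = logical())
  }
  if (!is.null(rat)) out <- dplyr::mutate(out, rat = rat, .before = 1)
  attr(out, "task_config") <- config
  attr(out, "impairment") <- impairment
  out
}

#' Default parameters for a synthetic cohort
#'
#' Draws per-rat mixture-of-agents parameters around values typical of
#' well-trained rats on this task: strong model-based planning, modest
#' novelty preference of either sign, clear perseveration, small side
#' bias, and moderate learning rates. Uses the current R random stream.
#'
#' @param n_rats Number of rats (default 9, the size of an optogenetics
#'   cohort).
#' @return A named list of compact-form [agent_params()].
#' @export
cohort_params <- function(n_rats = 9) {
  params <- purrr::map(seq_len(n_rats), function(i) {
    agent_params(
      beta_plan = rnorm(1, 1.5, 0.25),
      beta_np = rnorm(1, 0.2, 0.15),
      beta_persev = rnorm(1, 0.8, 0.2),
      beta_bias = rnorm(1, 0, 0.15),
      alpha_plan = min(0.9, max(0.1, rnorm(1, 0.55, 0.08))),
      alpha_persev = min(0.9, max(0.1, rnorm(1, 0.6, 0.1))))
  })
  names(params) <- paste0("rat", seq_len(n_rats))
  params
}

#' Simulate a cohort of rats, optionally with scheduled impairments
#'
#' Simulates each rat's full dataset under a shared task configuration
#' and inactivation schedule specification. The four canonical dataset
#' variants are obtained by varying `impairment`: none (control; fit
#' parameters used on trials of all types), impaired outcome values
#' (`alpha_value` x 0.3 on outcome/both-scheduled trials), impaired
#' reward processing (`alpha_reward` x 0.3 on those trials), and
#' impaired decision-making (`beta_plan` x 0.3 on trials following
#' inhibition).
#'
#' @param params_per_rat Named list of [agent_params()], one per rat
#'   (split form for learning-rate impairments; see
#'   [translate_params()]).
#' @param n_trials_per_rat Trials per rat (default 100000).
#' @param session_length Trials per session (default 1000).
#' @inheritParams simulate_rat
#' @return A trial tibble with a `rat` column.
#' @export
simulate_cohort <- function(params_per_rat, n_trials_per_rat = 100000,
                            session_length = 1000,
                            config = task_config(),
                            schedule_spec = inactivation_schedule_spec(),
                            impairment = impairment_spec("none")) {
  if (is.null(names(params_per_rat))) {
    names(params_per_rat) <- paste0("rat", seq_along(params_per_rat))
  }
  out <- purrr::imap_dfr(params_per_rat, function(p, rat) {
    simulate_rat(p, n_trials_per_rat, session_length, config,
                 schedule_spec, impairment, rat = rat)
  })
  attr(out, "task_config") <- config
  attr(out, "impairment") <- impairment
  attr(out, "schedule_spec") <- schedule_spec
  out
}

#' Synthetic spike-count generation specification
#'
#' Planted log-linear dependence of Poisson spike counts on the encoding
#' design: counts for a unit in an event bin are Poisson with rate
#' `exp(log(baseline_hz * bin_width) + sum gain * regressor)`, with the
#' gains specified per regressor, event and (optionally) bin.
#'
#' @param baseline_hz Baseline firing rate in spikes/s (default 10).
#' @param gains Tibble with columns `regressor`, `event`, `gain` and
#'   optionally `bin` (NA or absent = all bins of the event). Empty
#'   (default) means no planted coding.
#' @param window,bin_width Peri-event binning (defaults match
#'   [align_and_bin()]).
#' @param events Event set (default: the four port-entry events).
#' @return A list of class `spike_gen_spec`.
#' @export
spike_gen_spec <- function(baseline_hz = 10, gains = NULL,
                           window = c(-0.5, 0.5), bin_width = 0.2,
                           events = EVENTS) {
  if (baseline_hz <= 0) abort("baseline_hz must be positive")
  if (is.null(gains)) {
    gains <- tibble::tibble(regressor = character(), event = character(),
                            bin = integer(), gain = double())
  }
  if (!"bin" %in% names(gains)) gains$bin <- NA_integer_
  if (!all(gains$regressor %in% REGRESSORS)) {
    abort("unknown regressor in gains")
  }
  if (!all(gains$event %in% events)) abort("unknown event in gains")
  if (any(abs(gains$gain) > 5)) abort("|gain| > 5 risks rate overflow")
  structure(list(baseline_hz = baseline_hz, gains = gains,
                 window = window, bin_width = bin_width, events = events),
            class = "spike_gen_spec")
}

#' Generate synthetic spike counts with planted regressor coding
#'
#' Draws per-unit, per-trial-pair, per-event-bin Poisson counts whose
#' log rate is the baseline plus the planted gains times the (z-scored)
#' design columns. With all gains zero the counts are exchangeable
#' Poisson and carry no coding.
#'
#' @param design A [build_neural_design()] result.
#' @param spec A [spike_gen_spec()].
#' @param n_units Number of units (default 12).
#' @return A binned spike-count tibble shaped like [align_and_bin()]
#'   output (`unit_id`, `session_id`, `trial_index`, `event`, `bin`,
#'   `bin_start`, `count`).
#' @export
generate_spikes <- function(design, spec = spike_gen_spec(),
                            n_units = 12) {
  stopifnot(inherits(design, "neural_design"),
            inherits(spec, "spike_gen_spec"))
  n_bins <- as.integer(round((spec$window[2] - spec$window[1]) /
                               spec$bin_width))
  bins <- tibble::tibble(
    event = rep(spec$events, each = n_bins),
    bin = rep(seq_len(n_bins), length(spec$events)),
    bin_start = rep(spec$window[1] +
                      spec$bin_width * (seq_len(n_bins) - 1),
                    length(spec$events)))
  n_pairs <- nrow(design$X)
  base_log <- log(spec$baseline_hz * spec$bin_width)

  cells <- tidyr::crossing(unit_id = paste0("unit", sprintf("%02d",
                                                            seq_len(n_units))),
                           bins)
  out <- purrr::pmap_dfr(cells, function(unit_id, event, bin, bin_start) {
    g <- spec$gains[spec$gains$event == event &
                      (is.na(spec$gains$bin) | spec$gains$bin == bin), ]
    eta <- rep(base_log, n_pairs)
    if (nrow(g) > 0) {
      for (j in seq_len(nrow(g))) {
        eta <- eta + g$gain[j] * design$X[, g$regressor[j]]
      }
    }
    tibble::tibble(unit_id = unit_id, session_id = design$session_id,
                   trial_index = design$trial_index, event = event,
                   bin = bin, bin_start = bin_start,
                   count = rpois(n_pairs, exp(pmin(eta, 10))))
  })
  out
}
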