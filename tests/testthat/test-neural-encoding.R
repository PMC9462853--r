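test_that("peri-event binning counts spikes in half-open 200 ms bins", {
  # homogeneous 10 Hz Poisson train: mean count per 200 ms bin ~ 2
  set.seed(31)
  dur <- 2000
  spikes <- tibble::tibble(unit_id = "u1",
                           spike_time_s = sort(runif(10 * dur, 0, dur)))
  events <- tibble::tibble(trial_index = 0:399, event = "outcome_port",
                           time_s = seq(2, by = 5, length.out = 400))
  st <- align_and_bin(spikes, events)
  expect_equal(nrow(st), 400 * 5)
  expect_lt(abs(mean(st$count) - 2), 3 * sqrt(2 / nrow(st)))

  # a unit with no spikes near any event gives all-zero counts
  st0 <- align_and_bin(tibble::tibble(unit_id = "u1",
                                      spike_time_s = -1e6), events)
  expect_equal(nrow(st0), 400 * 5)
  expect_true(all(st0$count == 0))

  # a spike exactly at the event time lands in the first post-event bin
  sp <- tibble::tibble(unit_id = "u1", spike_time_s = 10)
  ev <- tibble::tibble(trial_index = 0L, event = "choice_port",
                       time_s = 10)
  stp <- align_and_bin(sp, ev, window = c(0, 1))
  expect_equal(stp$count[stp$bin == 1], 1)
  expect_equal(sum(stp$count), 1)
  # and a spike exactly at the window's right edge is excluded
  ste <- align_and_bin(sp, ev, window = c(9, 10))
  expect_equal(sum(ste$count), 0)
})

test_that("artifact flagging uses the scaled-MAD rule", {
  base <- tidyr::crossing(unit_id = "u1", session_id = 1L,
                          trial_index = 0:39, event = "outcome_port",
                          bin = 1:2)
  set.seed(32)
  base$count <- rpois(nrow(base), 1)
  burst <- dplyr::mutate(base, count = ifelse(trial_index == 7,
                                              50L, count))
  fl <- flag_artifact_trials(burst)
  expect_true(fl$excluded[fl$trial_index == 7])
  expect_equal(sum(fl$excluded), 1)
  # constant counts: MAD is zero, nothing flagged
  const <- dplyr::mutate(base, count = 2L)
  expect_true(all(!flag_artifact_trials(const)$excluded))
  # infinite threshold: empty mask
  expect_true(all(!flag_artifact_trials(burst, threshold = Inf)$excluded))
})

test_that("the encoding design has the stated structure", {
  fx <- sim_spikes(n_trials = 200, seed = 33)
  des <- fx$design
  expect_equal(colnames(des$X),
               c("choice", "outcome", "reward", "choice_x_outcome",
                 "choice_x_reward", "outcome_x_reward", "next_choice",
                 "outcome_value", "choice_value_diff", "chosen_value"))
  # z-scoring
  expect_true(all(abs(colMeans(des$X)) < 1e-10))
  expect_true(all(abs(apply(des$X, 2, sd) - 1) < 1e-10))
  # transition column is the product of choice and outcome pre-scaling
  raw <- sweep(sweep(des$X, 2, des$scaling$scale, "*"), 2,
               des$scaling$center, "+")
  expect_equal(raw[, "choice_x_outcome"],
               raw[, "choice"] * raw[, "outcome"])
  # binary columns take exactly two values pre-scaling
  for (cc in colnames(raw)[1:7]) {
    expect_length(unique(round(raw[, cc], 9)), 2)
  }
  # pairs never cross session boundaries
  expect_true(all(des$trial_index <
                    max(fx$trials$trial_index)))
  # value regressors match a step-through of the agent trajectories
  tr5 <- fx$trials[1:6, ]
  v5 <- agent_values(tr5, fx$params)
  d5 <- build_neural_design(tr5, v5)
  raw5 <- sweep(sweep(d5$X, 2, d5$scaling$scale, "*"), 2,
                d5$scaling$center, "+")
  expect_equal(raw5[, "choice_value_diff"],
               v5$Q_plan_left[2:6] - v5$Q_plan_right[2:6])
  expect_equal(raw5[, "outcome_value"],
               ifelse(tr5$outcome_port[1:5] == "left",
                      v5$V_left[1:5], v5$V_right[1:5]))
  # a constant column is rejected
  tr_const <- dplyr::mutate(fx$trials, choice = "left",
                            outcome_port = "left")
  expect_error(build_neural_design(tr_const,
                                   agent_values(tr_const, fx$params)),
               "constant")
})

test_that("the Poisson path fit recovers planted coefficients", {
  # 1,000 trials: coefficient SE is ~0.022, so 0.1 sits at ~4.5 SE
  fx <- sim_spikes(n_trials = 1000, seed = 34, n_units = 1)
  des <- fx$design
  errs <- c()
  set.seed(35)
  for (i in 1:10) {
    eta <- log(2) + 0.5 * des$X[, "reward"]
    y <- rpois(nrow(des$X), exp(eta))
    fit <- fit_spike_glm(y, des)
    expect_equal(fit$lambda, 0)
    expect_true(fit$converged)
    errs <- c(errs, fit$coefficients[["reward"]] - 0.5)
    # unregularized fit equals maximum likelihood (glm oracle)
    if (i == 1) {
      ref <- stats::glm(y ~ des$X, family = stats::poisson())
      expect_equal(unname(fit$coefficients),
                   unname(coef(ref)), tolerance = 1e-6)
    }
  }
  expect_true(all(abs(errs) < 0.1))
  # all-zero coefficients come back near zero
  set.seed(36)
  y0 <- rpois(nrow(des$X), 2)
  fit0 <- fit_spike_glm(y0, des)
  expect_true(all(abs(fit0$coefficients[-1]) < 0.1))
})

test_that("pooled-SSE CPD equals brute-force drop-one refits", {
  fx <- sim_spikes(n_trials = 140, seed = 37,
                   gains = tibble::tibble(regressor = "outcome_value",
                                          event = "outcome_port",
                                          gain = 0.5))
  st <- dplyr::filter(fx$spikes,
                      event %in% c("choice_port", "outcome_port"),
                      bin <= 3)
  cpd <- compute_cpd(st, fx$design, scope = "unit_bin")
  for (cell in list(
    list(u = "unit01", e = "outcome_port", b = 2, r = "outcome_value"),
    list(u = "unit02", e = "choice_port", b = 1, r = "choice"),
    list(u = "unit03", e = "outcome_port", b = 3, r = "reward"))) {
    mine <- cpd$cpd[cpd$unit_id == cell$u & cpd$event == cell$e &
                      cpd$bin == cell$b & cpd$regressor == cell$r]
    ref <- oracle_cpd_cell(st, fx$design, cell$u, cell$e, cell$b, cell$r)
    expect_equal(mine, ref, tolerance = 1e-6)
  }
  # unit-event pooling: sum SSEs over bins, then take the ratio
  ue <- compute_cpd(st, fx$design, scope = "unit_event")
  by_hand <- cpd |>
    dplyr::group_by(.data$unit_id, .data$event, .data$regressor) |>
    dplyr::summarise(cpd = (sum(sse_reduced) - sum(sse_full)) /
                       sum(sse_reduced), .groups = "drop")
  merged <- dplyr::left_join(
    ue, by_hand, by = c("unit_id", "event", "regressor"))
  expect_equal(merged$cpd.x, merged$cpd.y, tolerance = 1e-12)
  # population CPD lies between the min and max unit CPD per cell
  pop <- compute_cpd(st, fx$design, scope = "population_bin")
  rng <- cpd |>
    dplyr::group_by(.data$event, .data$bin, .data$regressor) |>
    dplyr::summarise(lo = min(cpd), hi = max(cpd), .groups = "drop")
  m2 <- dplyr::left_join(pop, rng, by = c("event", "bin", "regressor"))
  expect_true(all(m2$cpd >= m2$lo - 1e-12 & m2$cpd <= m2$hi + 1e-12))
  # planted regressor dominates; CPDs are nonnegative up to the
  # count-scale SSE approximation
  top <- ue |>
    dplyr::filter(.data$event == "outcome_port") |>
    dplyr::group_by(.data$regressor) |>
    dplyr::summarise(m = mean(cpd), .groups = "drop")
  expect_equal(top$regressor[which.max(top$m)], "outcome_value")
  expect_true(all(cpd$cpd > -0.05))
})

test_that("a zero circular shift reproduces the observed CPD", {
  fx <- sim_spikes(n_trials = 120, seed = 38, n_units = 2)
  st <- dplyr::filter(fx$spikes, event == "outcome_port")
  prep <- twostepr:::prep_encoding(st, fx$design)
  base <- twostepr:::sse_by_unit(prep)
  shifted <- twostepr:::sse_by_unit(
    prep, shifts = list(`1` = 0L, `2` = 0L))
  expect_identical(base, shifted)
})

test_that("sign-rank and fraction summaries match hand computation", {
  set.seed(39)
  cells <- tidyr::crossing(unit_id = paste0("u", 1:10),
                           event = "outcome_port",
                           regressor = c("outcome_value",
                                         "choice_value_diff"))
  cells$cpd <- runif(nrow(cells), 0, 0.2)
  cells$p_value <- rep(c(0.005, 0.5), 10)
  class(cells) <- c("cpd_result", class(cells))
  s <- summarize_coding(
    cells, pairs = list(c("outcome_value", "choice_value_diff")))
  a <- cells$cpd[cells$regressor == "outcome_value"]
  b <- cells$cpd[cells$regressor == "choice_value_diff"]
  expect_equal(s$comparisons$signed_rank_V, oracle_signed_rank_V(a, b))
  expect_equal(s$comparisons$mean_ratio, mean(a) / mean(b))
  fr <- s$fractions
  expect_equal(
    fr$frac_significant[fr$regressor == "outcome_value"],
    mean(cells$p_value[cells$regressor == "outcome_value"] < 0.01))
})
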