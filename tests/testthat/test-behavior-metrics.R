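make_trials <- function(choice, transition, reward, session = NULL) {
  n <- length(choice)
  tibble::tibble(
    session_id = session %||% rep(1L, n),
    trial_index = unlist(lapply(split(seq_len(n), session %||% rep(1L, n)),
                                seq_along), use.names = FALSE) - 1L,
    choice = choice, transition = transition,
    outcome_port = choice, reward = reward,
    inactivation = rep("none", n))
}

test_that("history design uses signed one-of-four coding with zero padding", {
  tr <- make_trials(c("left", "right", "left"),
                    c("common", "uncommon", "common"),
                    c(1L, 0L, 1L))
  d <- encode_history_design(tr, 3)
  # trial 2 sees (left, common, reward) at lag 1
  expect_equal(unname(d$X[2, "CR_1"]), 1)
  expect_equal(sum(abs(d$X[2, setdiff(colnames(d$X), "CR_1")])), 0)
  # trial 3 sees (right, uncommon, omission) at lag 1 and the first
  # trial's (left, common, reward) at lag 2
  expect_equal(unname(d$X[3, "UO_1"]), -1)
  expect_equal(unname(d$X[3, "CR_2"]), 1)
  expect_equal(unname(d$X[3, "UO_2"]), 0)
  # exactly one nonzero entry per available (trial, lag), value in {-1, +1}
  for (t in 2:3) {
    for (tau in 1:(t - 1)) {
      cols <- grepl(paste0("_", tau, "$"), colnames(d$X))
      expect_equal(sum(d$X[t, cols] != 0), 1)
      expect_true(all(d$X[t, cols] %in% c(-1, 0, 1)))
    }
  }
  # missing lags (start of data / other session) are zero
  expect_equal(sum(abs(d$X[1, ])), 0)
  tr2 <- make_trials(rep("left", 4), rep("common", 4), rep(1L, 4),
                     session = c(1L, 1L, 2L, 2L))
  d2 <- encode_history_design(tr2, 3)
  expect_equal(sum(abs(d2$X[3, ])), 0)  # first trial of session 2
  expect_equal(unname(d2$X[4, "CR_1"]), 1)
  expect_equal(sum(abs(d2$X[4, ])), 1)  # lag 2 would cross the boundary
  expect_error(encode_history_design(tr, 0), "n_lags")
})

test_that("maximum-likelihood history fit matches a generic logistic oracle", {
  p <- typical_params()
  tr <- sim_rat(p, 500, 250, seed = 21)
  d <- encode_history_design(tr, 3)
  fit <- fit_history_logistic(d, prior_sd = Inf)
  ref <- stats::glm(d$y ~ d$X, family = stats::binomial())
  w <- tidy(fit)
  expect_equal(w$estimate,
               unname(coef(ref)[paste0("d$X", w$predictor, "_", w$lag)]),
               tolerance = 1e-5)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-5)
})

test_that("history weights reflect the generating strategy", {
  # pure stay agent: repeats its previous choice regardless of outcome
  stay <- typical_params(beta_plan = 0, beta_np = 0, beta_persev = 4,
                         beta_bias = 0, alpha_persev = 1)
  tr <- sim_rat(stay, 10000, 1000, seed = 22)
  w <- tidy(fit_history_logistic(tr))
  lag1 <- w$estimate[w$lag == 1]
  expect_true(all(lag1 > 0.5))
  expect_lt(max(lag1) - min(lag1), 0.35)

  # planner: CR > UR and UO > CO at lag 1
  plan <- typical_params(beta_np = 0, beta_persev = 0, beta_bias = 0)
  trp <- sim_rat(plan, 10000, 1000, seed = 23)
  wp <- tidy(fit_history_logistic(trp))
  g <- function(pred, lag) wp$estimate[wp$predictor == pred & wp$lag == lag]
  expect_gt(g("CR", 1), g("UR", 1))
  expect_gt(g("UO", 1), g("CO", 1))

  # uniform-random choices: all weights near zero. The uncommon-
  # transition predictors are nonzero on only ~20% of trials, so their
  # standard errors shrink slowly; 3 x 10^5 trials put 0.05 at > 4 SE
  # for every weight.
  trr <- sim_rat(agent_params(), 300000, 1000, seed = 24)
  wr <- tidy(fit_history_logistic(trr))
  expect_true(all(abs(wr$estimate) < 0.05))
})

test_that("behavioral indices are the stated combinations and are linear", {
  flat <- tidyr::crossing(predictor = c("CR", "CO", "UR", "UO"),
                          lag = 1:3) |>
    dplyr::mutate(estimate = 0.25)
  idx <- compute_indices(flat)
  expect_equal(idx$planning_index, 0)
  expect_equal(idx$model_free_index, 0)
  expect_equal(idx$stay_index, 12 * 0.25)

  w <- tibble::tibble(
    predictor = rep(c("CR", "UO", "UR", "CO"), each = 3),
    lag = rep(1:3, 4),
    estimate = c(1, 0, 0, 0.5, 0, 0, -0.5, 0, 0, -1, 0, 0))
  idx2 <- compute_indices(w)
  expect_equal(idx2$planning_index, 3)
  expect_equal(idx2$model_free_index, 1)
  # alternate form of the transition-dependence index equals the
  # model-free index algebraically
  expect_equal(compute_indices(w, csus_form = "alternate")$csus_index,
               idx2$model_free_index)
  # linearity
  w2 <- dplyr::mutate(w, estimate = rev(estimate) + 0.3)
  both <- dplyr::mutate(w, estimate = estimate + w2$estimate)
  for (col in c("planning_index", "model_free_index", "stay_index",
                "csus_index")) {
    expect_equal(compute_indices(both)[[col]],
                 compute_indices(w)[[col]] + compute_indices(w2)[[col]])
  }
  # per-lag identity: planning(tau) + model_free(tau) = 2 (CR - CO)(tau)
  lp <- compute_indices(w)$lagged_planning[[1]]
  for (tau in 1:3) {
    mf_tau <- with(w, sum(estimate[predictor %in% c("CR", "UR") &
                                     lag == tau]) -
                     sum(estimate[predictor %in% c("UO", "CO") &
                                    lag == tau]))
    cr_co <- with(w, sum(estimate[predictor == "CR" & lag == tau]) -
                    sum(estimate[predictor == "CO" & lag == tau]))
    expect_equal(lp$planning[lp$lag == tau] + mf_tau, 2 * cr_co)
  }
})

test_that("conditions without trials sit exactly at the control weights", {
  p <- typical_params()
  tr <- sim_rat(p, 400, 200, seed = 25)  # no schedule: all control
  expect_warning(fit <- fit_inactivation_history(tr), "no trials")
  wide <- tidyr::pivot_wider(tidy(fit), names_from = "condition",
                             values_from = "estimate")
  for (cc in c("out", "ch", "both")) {
    expect_equal(wide[[cc]], wide$cntrl, tolerance = 1e-5)
  }
  expect_setequal(fit$empty_conditions, c("out", "ch", "both"))
})

test_that("condition-split weights respond to scheduled impairments", {
  pars <- typical_params(alpha_plan = 0.55)
  ps <- translate_params(pars)
  sched <- inactivation_schedule_spec()
  ctrl <- sim_rat(ps, 20000, 1000, seed = 26, schedule_spec = sched)
  impaired <- sim_rat(ps, 20000, 1000, seed = 26, schedule_spec = sched,
                      impairment = impairment_spec("alpha_value"))
  lp <- function(tr) {
    f <- fit_inactivation_history(tr)
    idx <- compute_indices(tidy(f))
    lagged <- tidyr::unnest(idx[, c("condition", "lagged_planning")],
                            "lagged_planning")
    lagged
  }
  lc <- lp(ctrl); li <- lp(impaired)
  get <- function(d, cc, tau) d$planning[d$condition == cc & d$lag == tau]
  # impaired outcome values: lag-1 planning on affected conditions is
  # spared, lag-2 is reduced relative to the same rat's control trials
  drop2 <- (get(lc, "out", 2) - get(lc, "cntrl", 2)) -
    (get(li, "out", 2) - get(li, "cntrl", 2))
  expect_gt(drop2, 0.2)
  drop1 <- abs(get(li, "out", 1) - get(li, "cntrl", 1))
  expect_lt(drop1, drop2)
})

test_that("planning contrasts and t statistics match hand-computed oracles", {
  # four synthetic rats with known weights: condition out halves the
  # lag-2 and lag-3 planning weights
  mk <- function(scale2) {
    tidyr::crossing(condition = c("cntrl", "out"),
                    predictor = c("CR", "CO", "UR", "UO"), lag = 1:3) |>
      dplyr::mutate(estimate = dplyr::case_when(
        predictor == "CR" & lag == 1 ~ 1,
        predictor == "CR" & condition == "cntrl" ~ 0.5,
        predictor == "CR" & condition == "out" ~ 0.5 * scale2,
        TRUE ~ 0))
  }
  fits <- purrr::map(c(0.4, 0.5, 0.6, 0.7), mk)
  names(fits) <- paste0("r", 1:4)
  pc <- planning_contrast(fits)
  # relative change oracle: PI_cntrl = 2, PI_out = 1 + s per rat
  rel <- pc$per_rat$relative_change[pc$per_rat$condition == "out"]
  expect_equal(sort(rel), sort((c(0.4, 0.5, 0.6, 0.7) - 1) / 2))
  t_one <- pc$tests$statistic[pc$tests$test == "one_sample_vs_zero"]
  expect_equal(t_one, oracle_t_one(rel))
  # identical weights: zero change everywhere
  same <- purrr::map(c(1, 1), mk)
  names(same) <- c("a", "b")
  pc0 <- planning_contrast(same)
  expect_true(all(abs(pc0$per_rat$relative_change) < 1e-12))
  expect_true(all(abs(pc0$lag_tests$estimate) < 1e-12))
  # two-sample test against a sham cohort, textbook Welch statistic
  sham <- purrr::map(c(0.95, 1.0, 1.05, 1.0), mk)
  names(sham) <- paste0("s", 1:4)
  pcs <- planning_contrast(fits, sham = sham)
  t2 <- pcs$tests$statistic[pcs$tests$test == "two_sample_vs_sham"]
  rel_sham <- (c(0.95, 1.0, 1.05, 1.0) - 1) / 2
  expect_equal(t2, oracle_t_two(rel, rel_sham))
})

test_that("performance curve has the expected form for simple policies", {
  # uniform-random agent: 0.5 at all lags
  tr <- sim_rat(agent_params(), 40000, 2000, seed = 27)
  pc <- performance_curve(tr)
  expect_true(all(abs(pc$p_correct - 0.5) < 0.08))
  # an oracle agent choosing correctly every trial scores 1 everywhere
  cfg <- task_config()
  oracle_tr <- tr |>
    dplyr::mutate(choice = ifelse(block_high_port == "left",
                                  "left", "right"))
  pco <- performance_curve(oracle_tr, cfg)
  expect_true(all(pco$p_correct == 1))
  # a fitted-scale planner improves with trials since the reversal
  trp <- sim_rat(typical_params(), 40000, 2000, seed = 28)
  pcp <- performance_curve(trp, max_lag = 10)
  early <- mean(pcp$p_correct[pcp$trials_since_reversal <= 1])
  late <- mean(pcp$p_correct[pcp$trials_since_reversal >= 6])
  expect_gt(late, early + 0.1)
  expect_gt(late, 0.6)
})
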