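test_that("an empty dataset returns the prior mode", {
  fit <- fit_map(tibble::tibble(), n_restarts = 1)
  expect_equal(fit$params$beta_plan, 0)
  expect_equal(fit$params$beta_np, 0)
  expect_equal(fit$params$beta_persev, 0)
  expect_equal(fit$params$beta_bias, 0)
  expect_equal(fit$params$alpha_plan, 0.5)
  expect_equal(fit$params$alpha_persev, 0.5)
  expect_true(fit$converged)
})

test_that("MAP fitting recovers generating parameters on one simulated rat", {
  gen <- typical_params()
  tr <- sim_rat(gen, 20000, 1000, seed = 11)
  fit <- fit_map(tr, n_restarts = 3, seed = 2)
  expect_true(fit$converged)
  # posterior at the optimum is at least as good as at the prior mode
  prior_mode <- agent_params(alpha_plan = 0.5, alpha_persev = 0.5)
  nlp_mode <- session_negloglik(prior_mode, tr)
  expect_lte(fit$neg_log_posterior, nlp_mode)
  # learning rates and bias on the natural scale
  expect_lt(abs(fit$params$alpha_plan - gen$alpha_plan), 0.15)
  expect_lt(abs(fit$params$alpha_persev - gen$alpha_persev), 0.15)
  expect_lt(abs(fit$params$beta_bias - gen$beta_bias), 0.15)
  # agent weights compared on the standardized (common) scale
  fitted_std <- standardize_weights(fit, mode = "multiply")
  gen_std <- standardize_weights(gen, tr, mode = "multiply")
  expect_true(all(abs(fitted_std$standardized -
                        gen_std$standardized) < 0.15))
})

test_that("uniform-random choices yield near-zero standardized weights", {
  tr <- sim_rat(agent_params(), 20000, 1000, seed = 12)
  fit <- fit_map(tr, n_restarts = 3, seed = 3)
  # on the common (conventional standardized) scale every agent's
  # influence is negligible
  std <- standardize_weights(fit, mode = "multiply")
  expect_true(all(abs(std$standardized) < 0.1))
  # and the fitted model barely beats a fair coin on these data
  expect_gt(session_negloglik(fit$params, tr),
            nrow(tr) * log(2) - 30)
})

test_that("weight standardization follows the stated rule in both modes", {
  p <- typical_params()
  tr <- sim_rat(p, 2000, 1000, seed = 13)
  div <- standardize_weights(p, tr, mode = "divide")
  mul <- standardize_weights(p, tr, mode = "multiply")
  expect_equal(div$standardized, div$beta / div$sd_Q)
  expect_equal(mul$standardized, mul$beta * mul$sd_Q)
  # bias is never standardized
  expect_false("bias" %in% div$agent)
  # an agent with constant values has an undefined standardized weight:
  # with alpha_persev = 0 the perseveration values never leave zero
  p0 <- typical_params(alpha_persev = 0)
  tr0 <- sim_rat(p0, 500, 500, seed = 14)
  expect_warning(std0 <- standardize_weights(p0, tr0), "zero value spread")
  expect_true(is.na(std0$standardized[std0$agent == "persev"]))
})

test_that("fitting is invariant to session order", {
  gen <- typical_params()
  tr <- sim_rat(gen, 3000, 500, seed = 15)
  rev_tr <- tr[order(-tr$session_id, tr$trial_index), ]
  f1 <- fit_map(tr, n_restarts = 2, seed = 4)
  f2 <- fit_map(rev_tr, n_restarts = 2, seed = 4)
  expect_equal(f1$neg_log_posterior, f2$neg_log_posterior,
               tolerance = 1e-6)
  expect_equal(f1$params$beta_plan, f2$params$beta_plan,
               tolerance = 1e-3)
})

test_that("fit results serialize with priors, seed and diagnostics", {
  tr <- sim_rat(typical_params(), 600, 300, seed = 17)
  fit <- fit_map(tr, n_restarts = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fit_result(fit, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$params$beta_plan, fit$params$beta_plan,
               tolerance = 1e-6)
  expect_equal(back$priors$beta_prior_sd, 0.5)
  expect_equal(back$seed, 9)
  expect_length(back$restarts$value, 2)
})

test_that("the split translation for synthetic runs swaps the rate roles", {
  p <- typical_params(alpha_plan = 0.35)
  ps <- translate_params(p)
  expect_identical(ps$form, "split")
  expect_equal(ps$alpha_value, 0.35)
  expect_equal(ps$alpha_reward, 0.65)
  expect_error(translate_params(ps), "compact")
})

test_that("cross-validated likelihood separates useful from useless agents", {
  gen <- typical_params(beta_np = 0, beta_bias = 0)
  tr <- sim_rat(gen, 4800, 800, seed = 16)
  cv <- crossval_compare(
    tr,
    variants = list(full = c("plan", "persev", "bias"),
                    no_plan = c("persev", "bias"),
                    no_bias = c("plan", "persev")),
    n_restarts = 2, seed = 5)
  ll <- function(v) cv$cv_loglik[cv$variant == v]
  # dropping the planner on planner data costs held-out likelihood
  expect_lt(ll("no_plan"), ll("full") - 10)
  # dropping an agent whose generating weight is ~0 changes little
  expect_lt(abs(ll("no_bias") - ll("full")), 2)
  expect_error(crossval_compare(sim_rat(gen, 100, 100, seed = 1),
                                variants = list(a = "plan")),
               "2 sessions")
})
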