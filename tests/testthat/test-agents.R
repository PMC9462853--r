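test_that("planning values combine outcome values with the transition model", {
  tm <- transition_matrix(task_config())
  expect_equal(unname(compute_choice_values(c(left = 0.5, right = 0.5), tm)),
               c(0.5, 0.5))
  expect_equal(unname(compute_choice_values(c(left = 1, right = 0), tm)),
               c(0.8, 0.2))
  # column sums of the symmetric matrix are 1, so Q sums equal V sums
  set.seed(1)
  for (i in 1:20) {
    V <- c(left = rnorm(1), right = rnorm(1))
    expect_equal(sum(compute_choice_values(V, tm)), sum(V))
  }
  expect_error(compute_choice_values(c(0.5, 0.5, 0.5), tm), "outcome port")
})

test_that("compact outcome-value rule moves ports symmetrically", {
  V <- c(left = 0.5, right = 0.5)
  expect_equal(
    unname(update_outcome_values_compact(V, "left", 1, 0.2)),
    c(0.6, 0.2))
  expect_equal(update_outcome_values_compact(V, "left", 1, 0), V)
  # omission shrinks both entries by (1 - alpha)
  V2 <- c(left = 0.7, right = 0.3)
  expect_equal(unname(update_outcome_values_compact(V2, "right", 0, 0.3)),
               unname(0.7 * V2))
  expect_error(update_outcome_values_compact(V, "left", 1, 1.5), "alpha")
})

test_that("split outcome-value rule generalizes the compact rule", {
  V <- c(left = 0.6, right = 0.2)
  expect_equal(
    unname(update_outcome_values_split(V, "left", 1, 0.5, 0.3, 0.5)),
    c(0.7, -0.1))
  # full decay to baseline
  expect_equal(
    unname(update_outcome_values_split(V, "left", 1, 0, 0, 0.5)),
    c(0.5, 0.5))
  # algebraic identity with the compact rule at (1 - a, a)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1)
    V <- c(left = runif(1), right = runif(1))
    r <- sample(0:1, 1)
    o <- sample(c("left", "right"), 1)
    expect_equal(update_outcome_values_split(V, o, r, 1 - a, a, runif(1)),
                 update_outcome_values_compact(V, o, r, a))
  }
  expect_error(update_outcome_values_split(V, "left", 1, 0.8, 0.5, 0.5),
               "sum")
})

test_that("novelty values implement uncommon-stay/common-switch", {
  q <- c(left = 0, right = 0)
  expect_equal(unname(update_novelty(q, "left", "common")), c(0, 1))
  expect_equal(unname(update_novelty(q, "left", "uncommon")), c(1, 0))
  # entries are a permutation of (0, 1) after any update
  set.seed(3)
  for (i in 1:20) {
    q <- update_novelty(q, sample(c("left", "right"), 1),
                        sample(c("common", "uncommon"), 1))
    expect_setequal(unname(q), c(0, 1))
  }
})

test_that("perseveration trace decays geometrically toward the chosen port", {
  q <- c(left = 0, right = 0)
  expect_equal(unname(update_perseveration(q, "left", 1)), c(1, 0))
  # n consecutive left choices give 1 - (1 - a)^n on the left
  a <- 0.3
  q <- c(left = 0, right = 0)
  for (n in 1:6) {
    q <- update_perseveration(q, "left", a)
    expect_equal(q[["left"]], 1 - (1 - a)^n)
    expect_equal(q[["right"]], 0)
  }
  set.seed(4)
  q <- c(left = 0.4, right = 0.7)
  for (i in 1:30) {
    q <- update_perseveration(q, sample(c("left", "right"), 1), runif(1))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("mixture policy is a softmax over weighted agent values", {
  st <- agent_state()
  expect_equal(unname(choice_probability(st, agent_params())$pi),
               c(0.5, 0.5))
  # only bias active: pi(left) = 1 / (1 + exp(-2 b))
  for (b in c(-1, 0.3, 2)) {
    p <- choice_probability(st, agent_params(beta_bias = b))$pi
    expect_equal(p[["left"]], 1 / (1 + exp(-2 * b)))
  }
  # large planning weight saturates toward the better option
  st$V <- c(left = 1, right = 0)
  p <- choice_probability(st, agent_params(beta_plan = 600))$pi
  expect_gt(p[["left"]], 1 - 1e-10)
  expect_true(all(is.finite(choice_probability(
    st, agent_params(beta_plan = 600))$Q_total)))
})

test_that("session likelihood matches an inline step-through oracle", {
  p <- typical_params()
  tr <- sim_rat(p, 20, 20, seed = 5)
  expect_equal(session_negloglik(p, tr), oracle_negloglik(p, tr))
  # multi-session, crossed transition map
  cfg <- task_config(transition_map = c(left = "right", right = "left"))
  tr2 <- sim_rat(typical_params(beta_np = -0.3), 60, 20, seed = 6,
                 config = cfg)
  expect_equal(session_negloglik(typical_params(beta_np = -0.3), tr2, cfg),
               oracle_negloglik(typical_params(beta_np = -0.3), tr2, cfg))
  # uniform policy gives n log 2
  expect_equal(session_negloglik(agent_params(), tr), 20 * log(2))
  expect_identical(session_negloglik(p, tr[0, ]), 0)
})

test_that("true planner parameters beat a flat planner on planner data", {
  p <- typical_params()
  tr <- sim_rat(p, 5000, 1000, seed = 7)
  p0 <- typical_params(beta_plan = 0)
  expect_lt(session_negloglik(p, tr), session_negloglik(p0, tr))
})

test_that("split form reproduces compact trajectories and session order is irrelevant", {
  to_split <- function(pc, ev) {
    agent_params(beta_plan = pc$beta_plan, beta_np = pc$beta_np,
                 beta_persev = pc$beta_persev, beta_bias = pc$beta_bias,
                 alpha_persev = pc$alpha_persev,
                 alpha_value = 1 - pc$alpha_plan,
                 alpha_reward = pc$alpha_plan,
                 expected_value_baseline = ev, form = "split")
  }
  # dyadic learning rate: the embedding is exact in floating point
  pc <- typical_params(alpha_plan = 0.25)
  tr <- sim_rat(pc, 400, 100, seed = 8)
  expect_identical(agent_values(tr, to_split(pc, 0.37)),
                   agent_values(tr, pc))
  # non-dyadic rate: equal up to floating point
  pc2 <- typical_params(alpha_plan = 0.35)
  expect_equal(agent_values(tr, to_split(pc2, 0.8)),
               agent_values(tr, pc2))
  # reversing session order leaves the total likelihood unchanged
  rev_tr <- tr[order(-tr$session_id, tr$trial_index), ]
  expect_equal(session_negloglik(pc, rev_tr), session_negloglik(pc, tr))
})

test_that("agent parameters validate and round-trip through text", {
  expect_error(agent_params(alpha_plan = 1.2), "alpha_plan")
  expect_error(agent_params(alpha_value = 0.7, alpha_reward = 0.5,
                            form = "split"), "split")
  p <- typical_params()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_agent_params(p, path)
  expect_equal(read_agent_params(path), p)
})
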