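# Independent oracles used to cross-check the package implementation.
# These deliberately re-derive the arithmetic inline (no calls into the
# package's update/likelihood code paths).

# Step-through negative log-likelihood of the mixture model, pure R,
# inline arithmetic.
oracle_negloglik <- function(params, trials, config = task_config()) {
  stopifnot(params$form == "compact")
  cdl <- unname(config$transition_map[["left"]])
  cdr <- setdiff(c("left", "right"), cdl)
  total <- 0
  for (s in unique(trials$session_id)) {
    tt <- trials[trials$session_id == s, ]
    V <- c(left = 0.5, right = 0.5)
    qnp <- c(left = 0, right = 0)
    qp <- c(left = 0, right = 0)
    for (i in seq_len(nrow(tt))) {
      qplan <- c(
        left = config$p_common * V[[cdl]] + (1 - config$p_common) * V[[cdr]],
        right = config$p_common * V[[cdr]] + (1 - config$p_common) * V[[cdl]])
      qtot <- params$beta_plan * qplan + params$beta_np * qnp +
        params$beta_persev * qp +
        params$beta_bias * c(left = 1, right = -1)
      pl <- 1 / (1 + exp(qtot[["right"]] - qtot[["left"]]))
      p <- if (tt$choice[i] == "left") pl else 1 - pl
      total <- total - log(p)

      ch <- tt$choice[i]; oth <- setdiff(c("left", "right"), ch)
      qnp[[ch]] <- if (tt$transition[i] == "common") 0 else 1
      qnp[[oth]] <- 1 - qnp[[ch]]
      qp[[ch]] <- (1 - params$alpha_persev) * qp[[ch]] + params$alpha_persev
      qp[[oth]] <- (1 - params$alpha_persev) * qp[[oth]]
      o <- tt$outcome_port[i]; ou <- setdiff(c("left", "right"), o)
      r <- tt$reward[i]; a <- params$alpha_plan
      vo <- V[[o]]; vu <- V[[ou]]
      V[[o]] <- (1 - a) * vo + a * r
      V[[ou]] <- (1 - a) * vu - a * r
    }
  }
  total
}

# Brute-force CPD for one unit/event/bin/regressor cell via stats::glm
# Poisson refits on the count scale.
oracle_cpd_cell <- function(spike_table, design, uid, ev, b, reg) {
  key <- paste0(spike_table$session_id, "#", spike_table$trial_index)
  dkey <- paste0(design$session_id, "#", design$trial_index)
  sel <- spike_table$unit_id == uid & spike_table$event == ev &
    spike_table$bin == b
  y <- spike_table$count[sel][match(dkey, key[sel])]
  Xf <- as.data.frame(design$X)
  gf <- stats::glm(y ~ ., data = Xf, family = stats::poisson())
  gr <- stats::glm(y ~ ., data = Xf[, setdiff(colnames(Xf), reg)],
                   family = stats::poisson())
  ssef <- sum((y - stats::fitted(gf))^2)
  sser <- sum((y - stats::fitted(gr))^2)
  (sser - ssef) / sser
}

# Textbook t statistics.
oracle_t_one <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
oracle_t_paired <- function(x, y) oracle_t_one(x - y)
oracle_t_two <- function(x, y) {
  (mean(x) - mean(y)) /
    sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
}

# Wilcoxon signed-rank V: sum of ranks of |d| over positive differences.
oracle_signed_rank_V <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  sum(r[d > 0])
}
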