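#' Priors for maximum-a-posteriori model fitting
#'
#' Weakly informative priors: Normal(0, 0.5) on every agent weight and
#' Beta(3, 3) on every learning rate.
#'
#' @param beta_prior_mean,beta_prior_sd Normal prior on the weights.
#' @param alpha_prior_a,alpha_prior_b Beta prior shape parameters on the
#'   learning rates.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(beta_prior_mean = 0, beta_prior_sd = 0.5,
                       alpha_prior_a = 3, alpha_prior_b = 3) {
  if (beta_prior_sd <= 0) abort("beta_prior_sd must be positive")
  if (alpha_prior_a <= 0 || alpha_prior_b <= 0) {
    abort("beta-distribution shapes must be positive")
  }
  structure(list(beta_prior_mean = beta_prior_mean,
                 beta_prior_sd = beta_prior_sd,
                 alpha_prior_a = alpha_prior_a,
                 alpha_prior_b = alpha_prior_b),
            class = "prior_spec")
}

AGENT_NAMES <- c("plan", "np", "persev", "bias")

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# negative log prior (natural-space density, no transform Jacobian, so
# the optimum matches box-constrained natural-space MAP)
neg_log_prior <- function(betas, alphas, priors) {
  nlp <- sum((betas - priors$beta_prior_mean)^2 /
               (2 * priors$beta_prior_sd^2))
  if (length(alphas) > 0) {
    nlp <- nlp - sum((priors$alpha_prior_a - 1) * log(alphas) +
                       (priors$alpha_prior_b - 1) * log1p(-alphas))
  }
  nlp
}

# parameter vector layout for a given agent subset (compact form)
par_layout <- function(agents) {
  betas <- paste0("beta_", agents)
  alphas <- character(0)
  if ("plan" %in% agents) alphas <- c(alphas, "alpha_plan")
  if ("persev" %in% agents) alphas <- c(alphas, "alpha_persev")
  list(betas = betas, alphas = alphas, n = length(betas) + length(alphas))
}

theta_to_params <- function(theta, layout) {
  betas <- c(beta_plan = 0, beta_np = 0, beta_persev = 0, beta_bias = 0)
  betas[layout$betas] <- theta[seq_along(layout$betas)]
  alphas <- c(alpha_plan = 0.5, alpha_persev = 0.5)
  if (length(layout$alphas) > 0) {
    alphas[layout$alphas] <-
      inv_logit(theta[length(layout$betas) + seq_along(layout$alphas)])
  }
  agent_params(beta_plan = betas[["beta_plan"]], beta_np = betas[["beta_np"]],
               beta_persev = betas[["beta_persev"]],
               beta_bias = betas[["beta_bias"]],
               alpha_plan = alphas[["alpha_plan"]],
               alpha_persev = alphas[["alpha_persev"]])
}

#' Fit the mixture-of-agents model by maximum a posteriori
#'
#' Minimizes the session negative log-likelihood plus the negative log
#' prior over the weights of the requested agents and the learning rates
#' they use (compact form). Optimization is box-constrained quasi-Newton
#' on a transformed space (logit for rates, identity for weights) with
#' seeded multi-start; the best restart is returned. Latent values reset
#' at session boundaries, so the fit does not depend on session order.
#'
#' @param trials A trial tibble covering one rat (all sessions pooled).
#' @param agents Character subset of `c("plan", "np", "persev", "bias")`.
#' @param priors A [prior_spec()].
#' @param config A [task_config()].
#' @param n_restarts Number of seeded optimizer restarts (first restart
#'   starts at the prior mode).
#' @param seed Integer seed for the restart draws.
#' @return An object of class `agent_fit` with elements `params`,
#'   `normalized_betas` (see [standardize_weights()]),
#'   `neg_log_posterior`, `converged`, `n_trials`, `gradient_norm` and a
#'   per-restart diagnostic tibble.
#' @export
fit_map <- function(trials, agents = AGENT_NAMES, priors = prior_spec(),
                    config = task_config(), n_restarts = 8, seed = 1) {
  agents <- match.arg(agents, AGENT_NAMES, several.ok = TRUE)
  layout <- par_layout(agents)

  if (nrow(trials) == 0) {
    params <- theta_to_params(rep(0, layout$n), layout)
    fit <- structure(
      list(params = params, agents = agents, priors = priors,
           config = config,
           neg_log_posterior = neg_log_prior(
             rep(0, length(layout$betas)),
             rep(0.5, length(layout$alphas)), priors),
           converged = TRUE, n_trials = 0L, gradient_norm = 0,
           seed = seed, restarts = tibble::tibble(), trials = trials),
      class = "agent_fit")
    fit$normalized_betas <- tibble::tibble(
      agent = setdiff(agents, "bias"), beta = 0, sd_Q = NA_real_,
      standardized = NA_real_, mode = "divide")
    return(fit)
  }
  check_trials(trials)

  objective <- function(theta) {
    params <- theta_to_params(theta, layout)
    nb <- length(layout$betas)
    betas <- theta[seq_len(nb)]
    alphas <- unlist(params[layout$alphas])
    session_negloglik(params, trials, config) +
      neg_log_prior(betas, alphas, priors)
  }

  starts <- matrix(0, n_restarts, layout$n)
  set.seed(seed)
  if (n_restarts > 1) {
    for (i in 2:n_restarts) {
      sb <- rnorm(length(layout$betas), priors$beta_prior_mean,
                  priors$beta_prior_sd)
      sa <- logit(rbeta(length(layout$alphas), priors$alpha_prior_a,
                        priors$alpha_prior_b))
      starts[i, ] <- c(sb, sa)
    }
  }

  runs <- purrr::map(seq_len(n_restarts), function(i) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble::tibble(restart = i, value = res$value,
                   convergence = res$convergence,
                   theta = list(res$par))
  })
  runs <- dplyr::bind_rows(purrr::compact(runs))
  if (nrow(runs) == 0) abort("all optimizer restarts failed")
  best <- runs[which.min(runs$value), ]
  theta_hat <- best$theta[[1]]
  params <- theta_to_params(theta_hat, layout)

  # numeric gradient at the optimum (central differences)
  h <- 1e-5
  g <- vapply(seq_len(layout$n), function(j) {
    e <- rep(0, layout$n); e[j] <- h
    (objective(theta_hat + e) - objective(theta_hat - e)) / (2 * h)
  }, numeric(1))
  gnorm <- max(abs(g)) / max(1, nrow(trials))
  converged <- best$convergence == 0 && gnorm < 1e-3
  if (!converged) {
    warn("fit_map did not converge on any restart; inspect $restarts")
  }

  fit <- structure(
    list(params = params, agents = agents, priors = priors, config = config,
         neg_log_posterior = best$value, converged = converged,
         n_trials = nrow(trials), gradient_norm = gnorm, seed = seed,
         restarts = dplyr::select(runs, -"theta"), trials = trials),
    class = "agent_fit")
  fit$normalized_betas <- standardize_weights(fit)
  fit
}

#' @export
print.agent_fit <- function(x, ...) {
  cat("<agent_fit> agents:", paste(x$agents, collapse = ", "),
      "| n_trials:", x$n_trials,
      "| -log posterior:", round(x$neg_log_posterior, 2),
      "| converged:", x$converged, "\n")
  print(x$params)
  invisible(x)
}

#' Standardized agent weights
#'
#' Brings the agent weights onto a common scale using the spread of each
#' agent's values across the fitted trials. The default `"divide"` mode
#' reports `beta_A / SD(Q_A)`; the `"multiply"` mode reports
#' `beta_A * SD(Q_A)`, the conventional standardized-coefficient
#' direction. The bias agent's values are the constants (+1, -1), so its
#' weight is never standardized. Values with zero spread yield an
#' undefined (NA) standardized weight.
#'
#' @param fit An `agent_fit`, or an [agent_params()] if `trials` is given.
#' @param trials Trial tibble used to compute the value trajectories when
#'   `fit` is a bare parameter set.
#' @param mode `"divide"` (default) or `"multiply"`.
#' @param config A [task_config()].
#' @return A tibble with columns `agent`, `beta`, `sd_Q`, `standardized`,
#'   `mode`.
#' @export
standardize_weights <- function(fit, trials = NULL,
                                mode = c("divide", "multiply"),
                                config = task_config()) {
  mode <- match.arg(mode)
  if (inherits(fit, "agent_fit")) {
    params <- fit$params
    trials <- trials %||% fit$trials
    config <- fit$config
    agents <- setdiff(fit$agents, "bias")
  } else {
    params <- fit
    if (is.null(trials)) abort("trials required when fit is a parameter set")
    agents <- setdiff(AGENT_NAMES, "bias")
  }
  vals <- agent_values(trials, params, config)
  sds <- c(
    plan = sd(c(vals$Q_plan_left, vals$Q_plan_right)),
    np = sd(c(vals$Q_np_left, vals$Q_np_right)),
    persev = sd(c(vals$Q_persev_left, vals$Q_persev_right)))
  betas <- c(plan = params$beta_plan, np = params$beta_np,
             persev = params$beta_persev)
  out <- tibble::tibble(
    agent = agents,
    beta = unname(betas[agents]),
    sd_Q = unname(sds[agents]))
  out$standardized <- ifelse(
    out$sd_Q > 0,
    if (mode == "divide") out$beta / out$sd_Q else out$beta * out$sd_Q,
    NA_real_)
  out$mode <- mode
  if (any(!is.na(out$beta) & is.na(out$standardized))) {
    warn("agent(s) with zero value spread: standardized weight undefined")
  }
  out
}

#' Translate compact-form parameters for synthetic-inactivation runs
#'
#' Maps a compact-form fit onto the split learning rule by setting
#' `alpha_value` to the fitted `alpha_plan` and `alpha_reward` to
#' `1 - alpha_plan`, the translation used to build synthetic inactivation
#' datasets. Note this is not the algebraic identity embedding of the
#' compact rule (that is `alpha_value = 1 - alpha`,
#' `alpha_reward = alpha`); it deliberately re-interprets the fitted rate
#' as the value-retention rate.
#'
#' @param params A compact-form [agent_params()].
#' @return A split-form [agent_params()].
#' @export
translate_params <- function(params) {
  if (params$form != "compact") abort("expected compact-form parameters")
  agent_params(beta_plan = params$beta_plan, beta_np = params$beta_np,
               beta_persev = params$beta_persev,
               beta_bias = params$beta_bias,
               alpha_plan = params$alpha_plan,
               alpha_persev = params$alpha_persev,
               alpha_value = params$alpha_plan,
               alpha_reward = 1 - params$alpha_plan,
               expected_value_baseline = params$expected_value_baseline,
               form = "split")
}

#' Serialize a model fit as a structured text document
#'
#' Writes the fitted parameters together with the prior specification,
#' the restart seed, convergence diagnostics and the per-restart
#' objective values, as YAML.
#'
#' @param fit An `agent_fit` from [fit_map()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "agent_fit"))
  yaml::write_yaml(list(
    params = unclass(fit$params),
    priors = unclass(fit$priors),
    agents = fit$agents,
    seed = fit$seed,
    n_trials = fit$n_trials,
    neg_log_posterior = fit$neg_log_posterior,
    converged = fit$converged,
    gradient_norm = fit$gradient_norm,
    normalized_betas = as.list(fit$normalized_betas),
    restarts = as.list(fit$restarts)), path)
  invisible(path)
}

#' Cross-validated comparison of agent subsets
#'
#' Fits each model variant on training sessions and evaluates the
#' held-out log-likelihood, with leave-one-session-out folding by
#' default. Latent values reset per session, so held-out sessions are
#' scored independently of the training data.
#'
#' @param trials Trial tibble with at least two sessions.
#' @param variants Named list of agent subsets, e.g.
#'   `list(full = c("plan","np","persev","bias"), no_plan = c("np","persev","bias"))`.
#' @param priors A [prior_spec()].
#' @param config A [task_config()].
#' @param folds Number of session-grouped folds; `NULL` (default) gives
#'   leave-one-session-out.
#' @param n_restarts Optimizer restarts per fold fit.
#' @param seed Integer seed.
#' @return A tibble with one row per variant: `variant`, `cv_loglik`
#'   (summed held-out log-likelihood), `n_folds`.
#' @export
crossval_compare <- function(trials, variants, priors = prior_spec(),
                             config = task_config(), folds = NULL,
                             n_restarts = 4, seed = 1) {
  check_trials(trials)
  sessions <- unique(trials$session_id)
  if (length(sessions) < 2) {
    abort("session-wise cross-validation needs at least 2 sessions")
  }
  if (is.null(folds)) folds <- length(sessions)
  folds <- min(folds, length(sessions))
  fold_of <- rep_len(seq_len(folds), length(sessions))
  if (is.null(names(variants))) {
    names(variants) <- vapply(variants, paste, "", collapse = "+")
  }
  res <- purrr::imap(variants, function(agents, vname) {
    ll <- 0
    for (k in seq_len(folds)) {
      held <- sessions[fold_of == k]
      train <- dplyr::filter(trials, !.data$session_id %in% held)
      test <- dplyr::filter(trials, .data$session_id %in% held)
      fit <- fit_map(train, agents = agents, priors = priors,
                     config = config, n_restarts = n_restarts,
                     seed = seed + k)
      ll <- ll - session_negloglik(fit$params, test, config)
    }
    tibble::tibble(variant = vname, cv_loglik = ll, n_folds = folds)
  })
  dplyr::bind_rows(res)
}
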