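#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a mixture-of-agents fit
#'
#' @param x An `agent_fit` from [fit_map()].
#' @param ... Unused.
#' @return One row per fitted parameter with `term`, `estimate`, and
#'   (for agent weights) the standardized estimate.
#' @export
tidy.agent_fit <- function(x, ...) {
  layout <- par_layout(x$agents)
  terms <- c(layout$betas, layout$alphas)
  est <- unlist(x$params[terms])
  out <- tibble::tibble(term = terms, estimate = unname(est))
  nb <- x$normalized_betas
  out$standardized <- nb$standardized[match(sub("^beta_", "", out$term),
                                            nb$agent)]
  out
}

#' @rdname tidy.agent_fit
#' @export
glance.agent_fit <- function(x, ...) {
  tibble::tibble(neg_log_posterior = x$neg_log_posterior,
                 n_trials = x$n_trials, converged = x$converged,
                 gradient_norm = x$gradient_norm,
                 n_restarts = nrow(x$restarts))
}

#' Tidy a trial-history regression fit
#'
#' @param x A `history_fit` or `inactivation_fit`.
#' @param ... Unused.
#' @return The long weights tibble (`predictor`, `lag`, `estimate`,
#'   plus `condition` for inactivation fits).
#' @export
tidy.history_fit <- function(x, ...) x$weights

#' @rdname tidy.history_fit
#' @export
glance.history_fit <- function(x, ...) {
  tibble::tibble(n_trials = x$n_trials, n_lags = x$n_lags,
                 prior_sd = x$prior_sd,
                 neg_log_posterior = x$neg_log_posterior,
                 converged = x$converged)
}

#' @rdname tidy.history_fit
#' @export
tidy.inactivation_fit <- function(x, ...) x$weights

#' @rdname tidy.history_fit
#' @export
glance.inactivation_fit <- function(x, ...) {
  tibble::tibble(n_lags = x$n_lags, prior_sd = x$prior_sd,
                 converged = x$converged,
                 neg_log_posterior = x$neg_log_posterior,
                 empty_conditions = length(x$empty_conditions))
}

#' Tidy a spike encoding model
#'
#' @param x A `spike_glm` from [fit_spike_glm()].
#' @param ... Unused.
#' @return One row per coefficient with `term` and `estimate`.
#' @export
tidy.spike_glm <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.spike_glm
#' @export
glance.spike_glm <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, converged = x$converged)
}

#' Tidy planning-index contrasts
#'
#' @param x A `planning_contrast`.
#' @param ... Unused.
#' @return The across-rat test table (empty tibble when fewer than two
#'   rats were supplied).
#' @export
tidy.planning_contrast <- function(x, ...) {
  x$tests %||% tibble::tibble()
}

#' @rdname tidy.planning_contrast
#' @export
glance.planning_contrast <- function(x, ...) {
  tibble::tibble(n_rats = length(unique(x$per_rat$rat)),
                 n_conditions = length(unique(x$per_rat$condition)),
                 n_unstable = sum(x$per_rat$unstable))
}
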