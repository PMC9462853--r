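#' Trial-history regression design
#'
#' Builds the signed one-of-four lagged predictor blocks used by the
#' trial-history logistic regression. Each past trial is classified by
#' its transition and reward as common-reward (CR), common-omission (CO),
#' uncommon-reward (UR) or uncommon-omission (UO); the predictor for that
#' block at lag `tau` is +1 if the lagged choice was left, -1 if right,
#' and 0 for the other blocks. Lags that would cross a session boundary
#' (or precede the data) are zero-padded, keeping all trials in the
#' design.
#'
#' @param trials Trial tibble, ordered within sessions.
#' @param n_lags Number of past trials used (default 3).
#' @return A list of class `history_design` with the predictor matrix
#'   `X` (columns `CR_1 ... UO_n_lags`), response `y` (1 = left), the
#'   per-trial previous-trial inactivation `condition`
#'   (`cntrl`/`out`/`ch`/`both`) and `session_id`.
#' @export
encode_history_design <- function(trials, n_lags = 3) {
  if (n_lags < 1) abort("n_lags must be >= 1")
  check_trials(trials)
  n <- nrow(trials)
  signed <- ifelse(trials$choice == "left", 1, -1)
  type <- dplyr::case_when(
    trials$transition == "common" & trials$reward == 1 ~ "CR",
    trials$transition == "common" & trials$reward == 0 ~ "CO",
    trials$transition == "uncommon" & trials$reward == 1 ~ "UR",
    TRUE ~ "UO")
  blocks <- c("CR", "CO", "UR", "UO")
  X <- matrix(0, n, 4 * n_lags,
              dimnames = list(NULL, paste0(rep(blocks, each = n_lags), "_",
                                           rep(seq_len(n_lags), 4))))
  same_session <- function(lag) {
    idx <- seq_len(n) - lag
    ok <- idx >= 1
    ok[ok] <- trials$session_id[idx[ok]] == trials$session_id[ok]
    ok
  }
  for (tau in seq_len(n_lags)) {
    ok <- same_session(tau)
    src <- which(ok) - tau
    for (b in blocks) {
      col <- paste0(b, "_", tau)
      vals <- rep(0, n)
      vals[ok] <- ifelse(type[src] == b, signed[src], 0)
      X[, col] <- vals
    }
  }

  inact <- trials$inactivation %||% rep("none", n)
  prev <- c("none", inact[-n])
  prev[session_starts(trials$session_id) == 1] <- "none"
  condition <- dplyr::recode(prev, none = "cntrl", outcome = "out",
                             choice = "ch", both = "both")

  structure(list(X = X, y = as.integer(trials$choice == "left"),
                 condition = condition, session_id = trials$session_id,
                 n_lags = n_lags),
            class = "history_design")
}

# penalized logistic negative log posterior and gradient; D = precision
# diagonal (0 entries unpenalized)
logistic_nlp <- function(beta, X, y, D) {
  eta <- drop(X %*% beta)
  # log(1 + exp(eta)) computed stably
  ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
  -ll + sum(D * beta^2) / 2
}

logistic_grad <- function(beta, X, y, D) {
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  -drop(crossprod(X, y - p)) + D * beta
}

# Newton-with-step-halving solver for the penalized logistic objective
newton_logistic <- function(X, y, D, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  f <- logistic_nlp(beta, X, y, D)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + D + 1e-12
    g <- logistic_grad(beta, X, y, D)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step)) break
    frac <- 1
    repeat {
      f_new <- logistic_nlp(beta + frac * step, X, y, D)
      if (is.finite(f_new) && f_new <= f + 1e-12) break
      frac <- frac / 2
      if (frac < 1e-10) break
    }
    beta <- beta + frac * step
    if (abs(f - f_new) < tol * (abs(f_new) + 0.1)) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  list(beta = beta, value = f, converged = converged)
}

#' Fit the trial-history logistic regression
#'
#' Maximum-a-posteriori logistic regression of choice on the four signed
#' lagged outcome-type blocks, under independent Normal(0, `prior_sd`)
#' priors on the weights. `prior_sd = Inf` gives the maximum-likelihood
#' fit; complete separation is then reported as a warning. An intercept
#' (capturing side bias) is included by default and shares the weight
#' prior.
#'
#' @param design A `history_design` (or a trial tibble, which is encoded
#'   with `n_lags`).
#' @param prior_sd Prior standard deviation on the weights (default 1).
#' @param n_lags Used only when `design` is a trial tibble.
#' @param intercept Include an intercept column (default TRUE).
#' @return An object of class `history_fit` with a long `weights` tibble
#'   (`predictor`, `lag`, `estimate`), the `intercept` estimate, and fit
#'   metadata.
#' @export
fit_history_logistic <- function(design, prior_sd = 1, n_lags = 3,
                                 intercept = TRUE) {
  if (!inherits(design, "history_design")) {
    design <- encode_history_design(design, n_lags = n_lags)
  }
  X <- design$X
  y <- design$y
  if (nrow(X) < 10 * ncol(X)) {
    warn("fewer than 10 trials per history weight; estimates may be noisy")
  }
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  D <- rep(if (is.finite(prior_sd)) 1 / prior_sd^2 else 0, ncol(X))
  fit <- newton_logistic(X, y, D)
  if (!is.finite(prior_sd) &&
      (!fit$converged || any(abs(fit$beta) > 15))) {
    warn("possible complete separation in maximum-likelihood history fit")
  }
  beta <- fit$beta
  names(beta) <- colnames(X)
  wnames <- colnames(design$X)
  weights <- tibble::tibble(
    predictor = sub("_\\d+$", "", wnames),
    lag = as.integer(sub("^.*_", "", wnames)),
    estimate = unname(beta[wnames]))
  structure(
    list(weights = weights,
         intercept = if (intercept) unname(beta["(Intercept)"]) else 0,
         prior_sd = prior_sd, n_lags = design$n_lags,
         n_trials = nrow(design$X), neg_log_posterior = fit$value,
         converged = fit$converged),
    class = "history_fit")
}

#' @export
print.history_fit <- function(x, ...) {
  cat("<history_fit> n_trials:", x$n_trials, "| lags:", x$n_lags,
      "| prior_sd:", x$prior_sd, "\n")
  print(tidyr::pivot_wider(x$weights, names_from = "lag",
                           values_from = "estimate", names_prefix = "lag"))
  invisible(x)
}

sum_by <- function(weights, predictor) {
  sum(weights$estimate[weights$predictor == predictor])
}

#' Behavioral indices from trial-history weights
#'
#' Linear combinations of the fitted history weights diagnostic of
#' different strategies. The planning index sums
#' `(CR - UR) + (UO - CO)` across lags: planners treat an uncommon
#' transition from one choice as evidence about the other choice. The
#' model-free index sums `(CR + UR) - (UO + CO)`: model-free learners
#' repeat rewarded choices regardless of transition. The stay index sums
#' all weights. The common-stay/uncommon-switch index defaults to the
#' conventional transition-dependence contrast
#' `(CR + CO) - (UR + UO)`; `csus_form = "alternate"` instead gives the
#' reward-symmetric combination `(CR - CO) + (UR - UO)`, kept for
#' comparability with formulations that write the index that way even
#' though it algebraically equals the model-free index.
#'
#' @param weights A `history_fit`, or a tibble with columns `predictor`
#'   (`CR`/`CO`/`UR`/`UO`), `lag`, `estimate`, and optionally
#'   `condition`.
#' @param csus_form `"conventional"` (default) or `"alternate"`.
#' @return A one-row tibble (or one row per condition) with
#'   `planning_index`, `model_free_index`, `stay_index`, `csus_index`
#'   and a `lagged_planning` list-column of the per-lag planning
#'   contributions.
#' @export
compute_indices <- function(weights, csus_form = c("conventional",
                                                   "alternate")) {
  csus_form <- match.arg(csus_form)
  if (inherits(weights, "history_fit")) weights <- weights$weights
  if (!all(c("predictor", "lag", "estimate") %in% names(weights))) {
    abort("weights must have columns predictor, lag, estimate")
  }
  one <- function(w) {
    cr <- sum_by(w, "CR"); co <- sum_by(w, "CO")
    ur <- sum_by(w, "UR"); uo <- sum_by(w, "UO")
    lp <- w |>
      dplyr::group_by(.data$lag) |>
      dplyr::summarise(
        planning = sum(.data$estimate[.data$predictor == "CR"]) -
          sum(.data$estimate[.data$predictor == "UR"]) +
          sum(.data$estimate[.data$predictor == "UO"]) -
          sum(.data$estimate[.data$predictor == "CO"]),
        .groups = "drop")
    tibble::tibble(
      planning_index = (cr - ur) + (uo - co),
      model_free_index = (cr + ur) - (uo + co),
      stay_index = cr + co + ur + uo,
      csus_index = if (csus_form == "conventional") {
        (cr + co) - (ur + uo)
      } else {
        (cr - co) + (ur - uo)
      },
      lagged_planning = list(lp))
  }
  if ("condition" %in% names(weights)) {
    weights |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(weights)
  }
}

CONDITIONS <- c("cntrl", "out", "ch", "both")

#' Inactivation-conditioned trial-history regression
#'
#' Fits the trial-history logistic regression with a separate set of
#' weights for trials whose previous trial carried each inactivation
#' type (`out`, `ch`, `both`) and for control trials (`cntrl`). All four
#' weight sets are estimated in one joint MAP problem: control weights
#' have Normal(0, `prior_sd`) priors, and each inactivation-condition
#' weight has a prior centered on the corresponding control weight,
#' Normal(`beta_cntrl`, `prior_sd`), so the priors cannot induce
#' spurious control-versus-inactivation differences. A condition with no
#' trials comes back exactly at its prior center (the control weights)
#' and is flagged.
#'
#' @param trials Trial tibble with an `inactivation` column
#'   (`none`/`outcome`/`choice`/`both`).
#' @param n_lags Number of history lags (default 3).
#' @param prior_sd Prior standard deviation (default 1).
#' @param intercept Include a per-condition intercept sharing the same
#'   prior structure (default TRUE).
#' @return An object of class `inactivation_fit` with a long `weights`
#'   tibble (`condition`, `predictor`, `lag`, `estimate`), per-condition
#'   trial counts, and the conditions that had no trials.
#' @export
fit_inactivation_history <- function(trials, n_lags = 3, prior_sd = 1,
                                     intercept = TRUE) {
  design <- encode_history_design(trials, n_lags = n_lags)
  X0 <- design$X
  if (intercept) X0 <- cbind(`(Intercept)` = 1, X0)
  y <- design$y
  p <- ncol(X0)
  cond <- factor(design$condition, levels = CONDITIONS)
  n_by_cond <- table(cond)
  rows <- lapply(CONDITIONS, function(cc) which(cond == cc))
  names(rows) <- CONDITIONS
  prec <- 1 / prior_sd^2

  # theta = (beta_cntrl, beta_out, beta_ch, beta_both), each length p
  unpack <- function(theta) matrix(theta, nrow = p,
                                   dimnames = list(colnames(X0), CONDITIONS))
  objective <- function(theta) {
    B <- unpack(theta)
    nll <- 0
    for (cc in CONDITIONS) {
      idx <- rows[[cc]]
      if (length(idx) == 0) next
      eta <- drop(X0[idx, , drop = FALSE] %*% B[, cc])
      nll <- nll - sum(y[idx] * eta -
                         ifelse(eta > 30, eta,
                                log1p(exp(pmin(eta, 30)))))
    }
    prior <- prec * sum(B[, "cntrl"]^2) / 2
    for (cc in CONDITIONS[-1]) {
      prior <- prior + prec * sum((B[, cc] - B[, "cntrl"])^2) / 2
    }
    nll + prior
  }
  gradient <- function(theta) {
    B <- unpack(theta)
    G <- matrix(0, p, 4, dimnames = dimnames(B))
    for (cc in CONDITIONS) {
      idx <- rows[[cc]]
      if (length(idx) == 0) next
      Xc <- X0[idx, , drop = FALSE]
      pr <- 1 / (1 + exp(-drop(Xc %*% B[, cc])))
      G[, cc] <- G[, cc] - drop(crossprod(Xc, y[idx] - pr))
    }
    G[, "cntrl"] <- G[, "cntrl"] + prec * B[, "cntrl"]
    for (cc in CONDITIONS[-1]) {
      d <- prec * (B[, cc] - B[, "cntrl"])
      G[, cc] <- G[, cc] + d
      G[, "cntrl"] <- G[, "cntrl"] - d
    }
    as.numeric(G)
  }

  res <- optim(rep(0, 4 * p), objective, gradient, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  B <- unpack(res$par)
  wnames <- colnames(design$X)
  weights <- purrr::map_dfr(CONDITIONS, function(cc) {
    tibble::tibble(condition = cc,
                   predictor = sub("_\\d+$", "", wnames),
                   lag = as.integer(sub("^.*_", "", wnames)),
                   estimate = unname(B[wnames, cc]))
  })
  empty <- CONDITIONS[n_by_cond == 0]
  if (length(empty) > 0) {
    warn(paste0("condition(s) with no trials returned at the control ",
                "weights: ", paste(empty, collapse = ", ")))
  }
  structure(
    list(weights = weights,
         intercepts = if (intercept) B["(Intercept)", ] else NULL,
         n_by_condition = tibble::tibble(
           condition = CONDITIONS, n = as.integer(n_by_cond)),
         empty_conditions = empty, prior_sd = prior_sd,
         n_lags = n_lags, converged = res$convergence == 0,
         neg_log_posterior = res$value),
    class = "inactivation_fit")
}

#' @export
print.inactivation_fit <- function(x, ...) {
  cat("<inactivation_fit> lags:", x$n_lags, "| trials per condition:\n")
  print(x$n_by_condition)
  invisible(x)
}


# t.test wrapper that reports NA on degenerate (constant) data instead
# of erroring; identical weight sets across rats are a legitimate input
safe_t <- function(...) {
  tryCatch(t.test(...), error = function(e) {
    list(statistic = NA_real_, parameter = NA_real_, p.value = NA_real_)
  })
}

#' Planning-index contrasts across inactivation conditions and rats
#'
#' Computes, per rat and inactivation condition, the planning index, its
#' per-lag contributions, and the relative change versus control
#' `(PI_i - PI_cntrl) / PI_cntrl`; then tests across rats: one-sample
#' t-tests of the relative change against 0 per condition, paired
#' t-tests between conditions, per-lag paired t-tests of the lagged
#' planning contributions versus control, and (when a sham cohort is
#' supplied) two-sample t-tests against the sham relative changes.
#' Rats whose control planning index is near zero are flagged, since
#' their relative change is unstable.
#'
#' @param fits Named list (one element per rat) of
#'   [fit_inactivation_history()] results, or a tibble of weights with
#'   columns `rat`, `condition`, `predictor`, `lag`, `estimate`.
#' @param sham Optional same-shaped object for a sham (no-opsin) cohort.
#' @param zero_tol Control planning indices with absolute value below
#'   this are flagged as unstable (default 0.1).
#' @return A list of class `planning_contrast` with tibbles `per_rat`
#'   (indices and relative changes), `lagged` (per-lag planning by
#'   condition), `tests` (condition-level tests) and `lag_tests`.
#' @export
planning_contrast <- function(fits, sham = NULL, zero_tol = 0.1) {
  weights <- contrast_weights(fits)
  per_rat <- weights |>
    dplyr::group_by(.data$rat, .data$condition) |>
    dplyr::group_modify(function(w, key) {
      lp <- compute_indices(w)$lagged_planning[[1]]
      tibble::tibble(planning_index = sum(lp$planning),
                     lagged = list(lp))
    }) |>
    dplyr::ungroup()
  ctrl <- per_rat |>
    dplyr::filter(.data$condition == "cntrl") |>
    dplyr::select("rat", pi_cntrl = "planning_index")
  per_rat <- per_rat |>
    dplyr::left_join(ctrl, by = "rat") |>
    dplyr::mutate(
      relative_change = (.data$planning_index - .data$pi_cntrl) /
        .data$pi_cntrl,
      unstable = abs(.data$pi_cntrl) < zero_tol)
  if (any(per_rat$unstable)) {
    warn("near-zero control planning index for some rats; relative changes flagged unstable")
  }

  lagged <- per_rat |>
    dplyr::select("rat", "condition", "lagged") |>
    tidyr::unnest("lagged")

  inact <- setdiff(unique(per_rat$condition), "cntrl")
  n_rats <- length(unique(per_rat$rat))

  tests <- NULL
  lag_tests <- NULL
  if (n_rats >= 2) {
    rc <- function(cc) {
      per_rat$relative_change[per_rat$condition == cc][
        order(per_rat$rat[per_rat$condition == cc])]
    }
    tests <- purrr::map_dfr(inact, function(cc) {
      tt <- safe_t(rc(cc))
      tibble::tibble(test = "one_sample_vs_zero", condition = cc,
                     comparison = NA_character_,
                     estimate = mean(rc(cc)), statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value)
    })
    if (length(inact) >= 2) {
      pairs <- utils::combn(inact, 2, simplify = FALSE)
      tests <- dplyr::bind_rows(tests, purrr::map_dfr(pairs, function(pr) {
        tt <- safe_t(rc(pr[1]), rc(pr[2]), paired = TRUE)
        tibble::tibble(test = "paired_between_conditions",
                       condition = pr[1], comparison = pr[2],
                       estimate = mean(rc(pr[1]) - rc(pr[2])),
                       statistic = unname(tt$statistic),
                       df = unname(tt$parameter), p_value = tt$p.value)
      }))
    }
    if (!is.null(sham)) {
      sham_pr <- planning_contrast(sham, zero_tol = zero_tol)$per_rat
      tests <- dplyr::bind_rows(tests, purrr::map_dfr(inact, function(cc) {
        a <- rc(cc)
        b <- sham_pr$relative_change[sham_pr$condition == cc]
        tt <- safe_t(a, b)
        tibble::tibble(test = "two_sample_vs_sham", condition = cc,
                       comparison = "sham",
                       estimate = mean(a) - mean(b),
                       statistic = unname(tt$statistic),
                       df = unname(tt$parameter), p_value = tt$p.value)
      }))
    }
    wide <- lagged |>
      tidyr::pivot_wider(names_from = "condition",
                         values_from = "planning")
    lag_tests <- purrr::map_dfr(inact, function(cc) {
      wide |>
        dplyr::group_by(.data$lag) |>
        dplyr::group_modify(function(d, key) {
          tt <- safe_t(d[[cc]], d$cntrl, paired = TRUE)
          tibble::tibble(condition = cc,
                         estimate = mean(d[[cc]] - d$cntrl),
                         statistic = unname(tt$statistic),
                         df = unname(tt$parameter), p_value = tt$p.value)
        }) |>
        dplyr::ungroup()
    })
  }

  structure(list(per_rat = dplyr::select(per_rat, -"lagged"),
                 lagged = lagged, tests = tests, lag_tests = lag_tests),
            class = "planning_contrast")
}

contrast_weights <- function(fits) {
  if (inherits(fits, "data.frame")) {
    needed <- c("rat", "condition", "predictor", "lag", "estimate")
    if (!all(needed %in% names(fits))) {
      abort("weights tibble must have columns rat, condition, predictor, lag, estimate")
    }
    return(fits)
  }
  if (is.null(names(fits))) names(fits) <- as.character(seq_along(fits))
  purrr::imap_dfr(fits, function(f, rat) {
    w <- if (inherits(f, "inactivation_fit")) f$weights else f
    dplyr::mutate(w, rat = rat, .before = 1)
  })
}

#' @export
print.planning_contrast <- function(x, ...) {
  cat("<planning_contrast>\n")
  print(x$per_rat)
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}

#' Choice accuracy as a function of trials since a block reversal
#'
#' A trial is scored correct when the rat selected the choice port whose
#' common transition leads to the currently high-probability outcome
#' port. Trials are grouped by the number of trials elapsed since the
#' last reward-probability reversal within the session; trials before a
#' session's first observed reversal are excluded (the preceding
#' reversal time is unknown).
#'
#' @param trials Trial tibble with a `block_high_port` column.
#' @param config A [task_config()] supplying the transition map.
#' @param max_lag Largest lag reported (default 20).
#' @return A tibble with `trials_since_reversal`, `p_correct`, `n`.
#' @export
performance_curve <- function(trials, config = task_config(),
                              max_lag = 20) {
  check_trials(trials)
  if (!"block_high_port" %in% names(trials)) {
    abort("performance_curve needs a block_high_port column")
  }
  correct_choice <- ifelse(
    unname(config$transition_map["left"]) == trials$block_high_port,
    "left", "right")
  trials |>
    dplyr::mutate(correct = .data$choice == correct_choice) |>
    dplyr::group_by(.data$session_id) |>
    dplyr::mutate(
      flip = dplyr::row_number() > 1 &
        .data$block_high_port != dplyr::lag(.data$block_high_port,
                                            default = "none"),
      flip_number = cumsum(.data$flip)) |>
    dplyr::group_by(.data$session_id, .data$flip_number) |>
    dplyr::mutate(trials_since_reversal = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$flip_number > 0,
                  .data$trials_since_reversal <= max_lag) |>
    dplyr::group_by(.data$trials_since_reversal) |>
    dplyr::summarise(p_correct = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop")
}
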