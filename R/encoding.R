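REGRESSORS <- c("choice", "outcome", "reward", "choice_x_outcome",
                "choice_x_reward", "outcome_x_reward", "next_choice",
                "outcome_value", "choice_value_diff", "chosen_value")

#' Bin spike times around port-entry events
#'
#' Counts spikes in half-open `[t0, t0 + bin_width)` bins taken relative
#' to each trial's port-entry events. The default window spans the five
#' 200 ms bins of a 1 s window centered on the event. Trials missing an
#' event time simply contribute no rows for that event.
#'
#' @param spikes Tibble with columns `unit_id`, `spike_time_s` and
#'   optionally `unit_kind` (`single`/`multi`).
#' @param events Tibble with columns `trial_index`, `event`, `time_s` and
#'   optionally `session_id`.
#' @param window Length-2 numeric, window around each event in seconds
#'   (default `c(-0.5, 0.5)`); must span a whole number of bins.
#' @param bin_width Bin width in seconds (default 0.2).
#' @return A tibble with `unit_id` (+ `unit_kind`, `session_id` when
#'   available), `trial_index`, `event`, `bin` (1-based), `bin_start`
#'   (seconds relative to the event) and `count`.
#' @export
align_and_bin <- function(spikes, events, window = c(-0.5, 0.5),
                          bin_width = 0.2) {
  stopifnot(all(c("unit_id", "spike_time_s") %in% names(spikes)),
            all(c("trial_index", "event", "time_s") %in% names(events)))
  n_bins <- (window[2] - window[1]) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    abort("window must span a whole number of bins")
  }
  n_bins <- as.integer(round(n_bins))
  breaks <- window[1] + bin_width * (0:n_bins)

  units <- split(spikes$spike_time_s, spikes$unit_id)
  kinds <- if ("unit_kind" %in% names(spikes)) {
    tapply(spikes$unit_kind, spikes$unit_id, function(k) k[1])
  } else NULL

  out <- purrr::imap_dfr(units, function(s, uid) {
    s <- sort(s)
    counts <- matrix(0L, nrow(events), n_bins)
    for (i in seq_len(nrow(events))) {
      t0 <- events$time_s[i]
      i1 <- findInterval(t0 + breaks[1] - 1e-9, s) + 1L
      i2 <- findInterval(t0 + breaks[n_bins + 1] + 1e-9, s)
      if (i2 < i1) next
      b <- findInterval(s[i1:i2] - t0, breaks)
      b <- b[b >= 1 & b <= n_bins]
      if (length(b) > 0) counts[i, ] <- tabulate(b, n_bins)
    }
    tibble::tibble(
      unit_id = uid,
      events[rep(seq_len(nrow(events)), each = n_bins),
             intersect(c("session_id", "trial_index", "event"),
                       names(events))],
      bin = rep(seq_len(n_bins), nrow(events)),
      bin_start = rep(breaks[seq_len(n_bins)], nrow(events)),
      count = as.integer(t(counts)))
  })
  if (!is.null(kinds)) {
    out$unit_kind <- unname(kinds[out$unit_id])
  }
  out
}

#' Flag artifact trials by robust spike-count deviation
#'
#' Flags, per unit, trials whose total spike count deviates from the
#' unit's median by more than `threshold` median absolute deviations
#' (MAD scaled by 1.4826 for normal consistency). Units with zero MAD
#' (constant counts) produce no flags.
#'
#' @param spike_table Binned counts from [align_and_bin()] or
#'   [generate_spikes()].
#' @param threshold Robust z threshold (default 3).
#' @return A tibble `unit_id`, `session_id`, `trial_index`,
#'   `total_count`, `excluded`.
#' @export
flag_artifact_trials <- function(spike_table, threshold = 3) {
  if (!"session_id" %in% names(spike_table)) spike_table$session_id <- 1L
  totals <- spike_table |>
    dplyr::group_by(.data$unit_id, .data$session_id, .data$trial_index) |>
    dplyr::summarise(total_count = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$unit_id)
  if (any(dplyr::summarise(totals, n = dplyr::n())$n < 20)) {
    warn("fewer than 20 trials for some units; artifact statistics are weak")
  }
  totals |>
    dplyr::mutate(
      mad_ = 1.4826 * median(abs(.data$total_count -
                                   median(.data$total_count))),
      excluded = .data$mad_ > 0 &
        abs(.data$total_count - median(.data$total_count)) / .data$mad_ >
          threshold) |>
    dplyr::ungroup() |>
    dplyr::select("unit_id", "session_id", "trial_index", "total_count",
                  "excluded")
}

#' Encoding-model design matrix over adjacent-trial pairs
#'
#' Builds the ten-regressor design used by the spike-count encoding
#' model. Rows are pairs of adjacent trials within a session, indexed by
#' the earlier trial. Seven regressors are binary (+/-1 before scaling):
#' the earlier trial's choice port, outcome port, reward, the three
#' pairwise interactions (choice x outcome is the transition), and the
#' later trial's choice port. Three are continuous model-derived value
#' signals: the value of the visited outcome port on the earlier trial
#' (`V(o_t)`, taken before that trial's value update), the later trial's
#' choice-value difference `Q(left) - Q(right)`, and the later trial's
#' chosen value `Q(chosen)`. All ten columns are z-scored.
#'
#' @param trials Trial tibble.
#' @param values Matching latent trajectories from [agent_values()]
#'   computed with the rat's fitted parameters.
#' @return An object of class `neural_design`: z-scored matrix `X`
#'   (`n_pairs` x 10), the earlier-trial index `trial_index`,
#'   `session_id`, and the per-column centers/scales.
#' @export
build_neural_design <- function(trials, values) {
  check_trials(trials)
  if (nrow(values) != nrow(trials)) {
    abort("values must have one row per trial (see agent_values())")
  }
  n <- nrow(trials)
  if (n < 2) abort("need at least two trials")
  t1 <- seq_len(n - 1)
  t2 <- t1 + 1
  keep <- trials$session_id[t1] == trials$session_id[t2]
  t1 <- t1[keep]; t2 <- t2[keep]

  pm <- function(x) ifelse(x, 1, -1)
  choice <- pm(trials$choice[t1] == "left")
  outcome <- pm(trials$outcome_port[t1] == "left")
  reward <- pm(trials$reward[t1] == 1)
  v_out <- ifelse(trials$outcome_port[t1] == "left",
                  values$V_left[t1], values$V_right[t1])
  qdiff <- values$Q_plan_left[t2] - values$Q_plan_right[t2]
  qchosen <- ifelse(trials$choice[t2] == "left",
                    values$Q_plan_left[t2], values$Q_plan_right[t2])

  X <- cbind(choice = choice, outcome = outcome, reward = reward,
             choice_x_outcome = choice * outcome,
             choice_x_reward = choice * reward,
             outcome_x_reward = outcome * reward,
             next_choice = pm(trials$choice[t2] == "left"),
             outcome_value = v_out,
             choice_value_diff = qdiff,
             chosen_value = qchosen)
  centers <- colMeans(X)
  scales <- apply(X, 2, sd)
  if (any(scales < 1e-12)) {
    abort(paste0("constant design column(s): ",
                 paste(colnames(X)[scales < 1e-12], collapse = ", ")))
  }
  Xz <- scale(X, center = centers, scale = scales)
  attr(Xz, "scaled:center") <- NULL
  attr(Xz, "scaled:scale") <- NULL
  structure(
    list(X = Xz, trial_index = trials$trial_index[t1],
         session_id = trials$session_id[t1],
         scaling = tibble::tibble(regressor = colnames(X),
                                  center = centers, scale = scales)),
    class = "neural_design")
}

#' @export
print.neural_design <- function(x, ...) {
  cat("<neural_design>", nrow(x$X), "adjacent-trial pairs x",
      ncol(x$X), "regressors\n")
  invisible(x)
}

#' Poisson encoding model with L1 regularization path
#'
#' Fits the spike-count regression for one unit-bin response with a
#' Poisson noise model, both unregularized and along an L1 path
#' (`lambda = 1e-10 ... 1e-1`), and returns the fit at the weakest
#' regularization whose weights are identifiable: the fit converged, all
#' coefficients are finite, and the design restricted to the active
#' coefficients has condition number below `cond_max`.
#'
#' @param counts Integer response vector aligned with the design rows.
#' @param design A [build_neural_design()] result (or a bare matrix).
#' @param lambda_grid Penalties tried, in addition to 0 (default
#'   `10^(-10:-1)`).
#' @param cond_max Condition-number bound for identifiability
#'   (default 1e6).
#' @return A list of class `spike_glm`: `coefficients` (intercept plus
#'   one weight per regressor), `lambda` (selected penalty),
#'   `converged`, and the per-penalty diagnostics tibble `path`.
#' @export
fit_spike_glm <- function(counts, design, lambda_grid = 10^seq(-10, -1),
                          cond_max = 1e6) {
  X <- if (inherits(design, "neural_design")) design$X else design
  if (length(counts) != nrow(X)) abort("counts must match design rows")
  lambda_grid <- sort(lambda_grid)

  identifiable <- function(coefs, converged) {
    if (!converged || any(!is.finite(coefs))) return(FALSE)
    active <- which(abs(coefs[-1]) > 1e-12)
    if (length(active) == 0) return(TRUE)
    Xa <- cbind(1, X[, active, drop = FALSE])
    kappa(crossprod(Xa), exact = TRUE)^0.5 < cond_max
  }

  fit0 <- poisson_irls_cpp(cbind(1, X), counts)
  path <- tibble::tibble(
    lambda = 0, converged = fit0$converged,
    identifiable = identifiable(drop(fit0$coefficients), fit0$converged),
    coefficients = list(stats::setNames(drop(fit0$coefficients),
                                        c("(Intercept)", colnames(X)))))

  gl <- tryCatch(
    glmnet::glmnet(X, counts, family = "poisson", alpha = 1,
                   lambda = rev(lambda_grid), standardize = FALSE,
                   thresh = 1e-10),
    error = function(e) NULL)
  if (!is.null(gl)) {
    for (lam in lambda_grid) {
      cf <- drop(as.matrix(coef(gl, s = lam, exact = FALSE)))
      names(cf) <- c("(Intercept)", colnames(X))
      path <- dplyr::bind_rows(path, tibble::tibble(
        lambda = lam, converged = TRUE,
        identifiable = identifiable(cf, TRUE),
        coefficients = list(cf)))
    }
  }
  path <- dplyr::arrange(path, .data$lambda)
  sel <- which(path$identifiable)[1]
  if (is.na(sel)) {
    warn("no penalty yielded identifiable weights; returning strongest fit")
    sel <- nrow(path)
  }
  structure(
    list(coefficients = path$coefficients[[sel]],
         lambda = path$lambda[sel], converged = path$converged[sel],
         path = dplyr::select(path, -"coefficients")),
    class = "spike_glm")
}

#' @export
print.spike_glm <- function(x, ...) {
  cat("<spike_glm> lambda =", x$lambda, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# Internal: per-unit response matrices and designs, honouring artifact
# exclusions. Trials are keyed jointly by (session_id, trial_index)
# since trial indices restart per session. Returns one entry per unit
# with design rows matched to the unit's usable pairs.
prep_encoding <- function(spike_table, design, exclusions = NULL) {
  if (!"session_id" %in% names(spike_table)) spike_table$session_id <- 1L
  keys <- spike_table |>
    dplyr::distinct(.data$event, .data$bin) |>
    dplyr::arrange(.data$event, .data$bin)
  units <- unique(spike_table$unit_id)
  wide <- spike_table |>
    dplyr::mutate(.trial = paste0(.data$session_id, "#",
                                  .data$trial_index)) |>
    dplyr::select("unit_id", ".trial", "event", "bin", "count") |>
    tidyr::pivot_wider(names_from = c("event", "bin"),
                       values_from = "count", names_sep = "|")
  col_of <- paste(keys$event, keys$bin, sep = "|")
  design_key <- paste0(design$session_id, "#", design$trial_index)

  purrr::map(units, function(uid) {
    w <- dplyr::filter(wide, .data$unit_id == uid)
    bad <- if (!is.null(exclusions)) {
      ex <- exclusions[exclusions$unit_id == uid & exclusions$excluded, ]
      paste0(ex$session_id, "#", ex$trial_index)
    } else character(0)
    row_of <- match(design_key, w$.trial)
    keep <- !is.na(row_of) & !design_key %in% bad
    Y <- as.matrix(w[row_of[keep], col_of])
    storage.mode(Y) <- "double"
    list(unit_id = uid, X = design$X[keep, , drop = FALSE], Y = Y,
         session_id = design$session_id[keep],
         col_meta = keys)
  })
}

# SSE matrices (full + drop-one) for every unit, optionally with the
# responses circularly shifted within session (shifts named by session)
sse_by_unit <- function(prep, shifts = NULL) {
  drop_cols <- as.list(seq_len(length(REGRESSORS)))
  purrr::map(prep, function(u) {
    Y <- u$Y
    if (!is.null(shifts)) {
      for (s in unique(u$session_id)) {
        idx <- which(u$session_id == s)
        k <- shifts[[as.character(s)]] %% length(idx)
        if (length(idx) > 1 && k > 0) {
          Y[idx, ] <- Y[idx[c((k + 1):length(idx), 1:k)], , drop = FALSE]
        }
      }
    }
    cpd_sse_cpp(cbind(1, u$X), Y, drop_cols)$sse
  })
}

# pool SSE matrices into a CPD tibble at the requested scope
pool_cpd <- function(sse_list, prep, scope) {
  meta <- prep[[1]]$col_meta
  rows <- purrr::imap_dfr(sse_list, function(s, i) {
    tibble::tibble(
      unit_id = prep[[i]]$unit_id,
      event = rep(meta$event, each = length(REGRESSORS)),
      bin = rep(meta$bin, each = length(REGRESSORS)),
      regressor = rep(REGRESSORS, nrow(meta)),
      sse_full = rep(s[1, ], each = length(REGRESSORS)),
      sse_reduced = as.numeric(s[-1, ]))
  })
  grouped <- switch(scope,
    unit_bin = dplyr::group_by(rows, .data$unit_id, .data$event,
                               .data$bin, .data$regressor),
    unit_event = dplyr::group_by(rows, .data$unit_id, .data$event,
                                 .data$regressor),
    unit_total = dplyr::group_by(rows, .data$unit_id, .data$regressor),
    population_bin = dplyr::group_by(rows, .data$event, .data$bin,
                                     .data$regressor),
    abort("unknown scope"))
  grouped |>
    dplyr::summarise(sse_reduced = sum(.data$sse_reduced),
                     sse_full = sum(.data$sse_full), .groups = "drop") |>
    dplyr::mutate(cpd = ifelse(
      .data$sse_reduced > 0,
      (.data$sse_reduced - .data$sse_full) / .data$sse_reduced,
      NA_real_))
}

#' Coefficients of partial determination for spike encoding
#'
#' For every unit, event and time bin, fits the full ten-regressor
#' Poisson model and each drop-one-regressor reduced model on identical
#' rows, and reports the coefficient of partial determination
#' `CPD = (SSE_reduced - SSE_full) / SSE_reduced`, with the sum-squared
#' error computed on the count scale. SSEs are pooled before the ratio:
#' over the bins of an event window (`scope = "unit_event"`, the five
#' bins of the 1 s window), over all bins (`"unit_total"`), over units
#' (`"population_bin"`), or not at all (`"unit_bin"`). Cells with zero
#' reduced-model SSE return `NA`.
#'
#' @param spike_table Binned counts (see [align_and_bin()] /
#'   [generate_spikes()]).
#' @param design A [build_neural_design()] result.
#' @param scope One of `"unit_bin"`, `"unit_event"`, `"unit_total"`,
#'   `"population_bin"`.
#' @param exclusions Optional [flag_artifact_trials()] output; flagged
#'   unit-trials are dropped for that unit.
#' @return A tibble of class `cpd_result` keyed by the scope's grouping
#'   columns, with `sse_reduced`, `sse_full` and `cpd`.
#' @export
compute_cpd <- function(spike_table, design,
                        scope = c("unit_event", "unit_bin", "unit_total",
                                  "population_bin"),
                        exclusions = NULL) {
  scope <- match.arg(scope)
  prep <- prep_encoding(spike_table, design, exclusions)
  out <- pool_cpd(sse_by_unit(prep), prep, scope)
  class(out) <- c("cpd_result", class(out))
  attr(out, "scope") <- scope
  out
}

#' Circular-permutation inference for CPDs
#'
#' Builds surrogate datasets by circularly shifting each session's trial
#' labels (one uniform shift in `1 .. n_session - 1` per session per
#' surrogate, applied identically to every unit), recomputes the pooled
#' CPDs, and reports per cell the permutation percentile p-value
#' `(1 + #{null >= observed}) / (n_perm + 1)`, the null mean and 99th
#' percentile, and the null-mean-subtracted CPD (the quantity comparable
#' to zero). Circular shifts preserve within-session autocorrelation
#' while breaking trial-specific alignment.
#'
#' @inheritParams compute_cpd
#' @param n_perm Number of surrogates (default 500; fewer than 100 gives
#'   poor p-value resolution and a warning).
#' @return A `cpd_result` tibble with added `null_mean`, `null_q99`,
#'   `cpd_null_subtracted`, `p_value`.
#' @export
permutation_inference <- function(spike_table, design, n_perm = 500,
                                  scope = c("unit_event", "unit_bin",
                                            "unit_total",
                                            "population_bin"),
                                  exclusions = NULL) {
  scope <- match.arg(scope)
  if (n_perm < 100) warn("n_perm < 100: permutation p-values are coarse")
  prep <- prep_encoding(spike_table, design, exclusions)
  obs <- pool_cpd(sse_by_unit(prep), prep, scope)

  sessions <- unique(design$session_id)
  n_by_session <- table(design$session_id)
  null_mat <- matrix(NA_real_, n_perm, nrow(obs))
  for (b in seq_len(n_perm)) {
    shifts <- lapply(sessions, function(s) {
      ns <- n_by_session[[as.character(s)]]
      if (ns > 1) sample.int(ns - 1, 1) else 0L
    })
    names(shifts) <- as.character(sessions)
    perm <- pool_cpd(sse_by_unit(prep, shifts), prep, scope)
    null_mat[b, ] <- perm$cpd
  }
  obs$null_mean <- colMeans(null_mat)
  obs$null_q99 <- apply(null_mat, 2, quantile, probs = 0.99, na.rm = TRUE)
  obs$cpd_null_subtracted <- obs$cpd - obs$null_mean
  obs$p_value <- vapply(seq_len(nrow(obs)), function(j) {
    (1 + sum(null_mat[, j] >= obs$cpd[j], na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1))
  class(obs) <- c("cpd_result", class(obs))
  attr(obs, "scope") <- scope
  attr(obs, "n_perm") <- n_perm
  obs
}

#' Population summaries of regressor coding
#'
#' From unit-event CPDs with permutation p-values: the fraction of units
#' significant per regressor and event at `alpha`, paired Wilcoxon
#' signed-rank comparisons of per-unit CPDs between named regressor
#' pairs, and their mean and median CPD ratios.
#'
#' @param cpd_result A `"unit_event"`-scope [permutation_inference()]
#'   result.
#' @param pairs List of length-2 character vectors of regressor names to
#'   compare (default: outcome value vs the two choice-value regressors).
#' @param alpha Significance level on the permutation p-values
#'   (default 0.01).
#' @return A list with tibbles `fractions` (per regressor and event) and
#'   `comparisons` (per pair and event).
#' @export
summarize_coding <- function(cpd_result,
                             pairs = list(
                               c("outcome_value", "choice_value_diff"),
                               c("outcome_value", "chosen_value")),
                             alpha = 0.01) {
  if (!"p_value" %in% names(cpd_result)) {
    abort("summarize_coding needs permutation_inference() output")
  }
  fractions <- cpd_result |>
    dplyr::group_by(.data$regressor, .data$event) |>
    dplyr::summarise(n_units = dplyr::n(),
                     n_significant = sum(.data$p_value < alpha),
                     frac_significant = mean(.data$p_value < alpha),
                     mean_cpd = mean(.data$cpd, na.rm = TRUE),
                     median_cpd = median(.data$cpd, na.rm = TRUE),
                     .groups = "drop")
  comparisons <- purrr::map_dfr(pairs, function(pr) {
    cpd_result |>
      dplyr::select("unit_id", "event", "regressor", "cpd") |>
      dplyr::filter(.data$regressor %in% pr) |>
      tidyr::pivot_wider(names_from = "regressor", values_from = "cpd") |>
      dplyr::group_by(.data$event) |>
      dplyr::group_modify(function(d, key) {
        a <- d[[pr[1]]]; b <- d[[pr[2]]]
        wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
        tibble::tibble(regressor_a = pr[1], regressor_b = pr[2],
                       mean_ratio = mean(a) / mean(b),
                       median_ratio = median(a) / median(b),
                       signed_rank_V = unname(wt$statistic),
                       p_value = wt$p.value)
      }) |>
      dplyr::ungroup()
  })
  list(fractions = fractions, comparisons = comparisons)
}
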