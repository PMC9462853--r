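#' Run configuration for the analysis pipeline
#'
#' A validated, serializable bundle of every setting the pipeline stages
#' need. All defaults equal the task's stated constants (3 history lags,
#' 200 ms bins, artifact threshold 3, impairment multiplier 0.3, 7%
#' scheduling on even trials). Every stage derives its own seed from the
#' top-level `seed`, so a configuration fully determines the outputs.
#'
#' @param seed Top-level integer seed.
#' @param n_rats,n_trials_per_rat,session_length Cohort dimensions.
#' @param task,priors,schedule,impairment,fit,behavior,encoding Named
#'   lists overriding the corresponding component defaults (see
#'   [task_config()], [prior_spec()], [inactivation_schedule_spec()],
#'   [impairment_spec()]).
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_rats = 3, n_trials_per_rat = 5000,
                       session_length = 1000, task = list(),
                       priors = list(), schedule = list(),
                       impairment = list(), fit = list(),
                       behavior = list(), encoding = list()) {
  cfg <- list(
    seed = as.integer(seed), n_rats = as.integer(n_rats),
    n_trials_per_rat = as.integer(n_trials_per_rat),
    session_length = as.integer(session_length),
    task = utils::modifyList(
      list(p_common = 0.8, p_high = 0.8, p_low = 0.2,
           min_block_length = 10, block_hazard = 0.02,
           transition_map = c(left = "left", right = "right")), task),
    priors = utils::modifyList(
      list(beta_prior_mean = 0, beta_prior_sd = 0.5, alpha_prior_a = 3,
           alpha_prior_b = 3), priors),
    schedule = utils::modifyList(
      list(fraction_per_type = 0.07, even_trials_only = TRUE,
           max_duration_s = 15), schedule),
    impairment = utils::modifyList(
      list(target = "none", multiplier = 0.3), impairment),
    fit = utils::modifyList(list(n_restarts = 4), fit),
    behavior = utils::modifyList(list(n_lags = 3, prior_sd = 1), behavior),
    encoding = utils::modifyList(
      list(simulate_spikes = FALSE, n_units = 12, baseline_hz = 10,
           n_perm = 200, window = c(-0.5, 0.5), bin_width = 0.2,
           artifact_threshold = 3, gains = list()), encoding))
  # stored as a named list so the YAML serialization keeps the names
  cfg$task$transition_map <- as.list(unlist(cfg$task$transition_map))
  cfg$encoding$window <- as.numeric(unlist(cfg$encoding$window))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1,
            cfg$n_rats >= 1, cfg$n_trials_per_rat >= 0,
            cfg$session_length >= 1)
  # constructors do the detailed checking
  do.call(task_config, cfg$task)
  do.call(prior_spec, cfg$priors)
  do.call(inactivation_schedule_spec, cfg$schedule)
  do.call(impairment_spec, cfg$impairment)
  if (cfg$encoding$n_perm < 1) abort("encoding$n_perm must be >= 1")
  invisible(cfg)
}

#' @rdname run_config
#' @param path File path for the YAML serialization.
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$task$transition_map <- unlist(raw$task$transition_map)
  raw$encoding$window <- unlist(raw$encoding$window)
  cfg <- do.call(run_config, raw[intersect(names(raw),
                                           names(formals(run_config)))])
  cfg
}

derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483647)
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

manifest_path <- function(dir, stage) {
  file.path(dir, paste0("manifest_", stage, ".json"))
}

write_manifest <- function(dir, stage, cfg, files, t0) {
  files <- files[file.exists(files)]
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- sub(paste0(dir, "/"), "", files, fixed = TRUE)
  manifest <- list(stage = stage, seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   elapsed_s = round(as.numeric(Sys.time()) - t0, 2),
                   files = hashes)
  jsonlite::write_json(manifest, manifest_path(dir, stage),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line <- jsonlite::toJSON(
    c(manifest[c("stage", "seed", "config_hash", "elapsed_s")],
      list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    auto_unbox = TRUE)
  cat(log_line, "\n", file = file.path(dir, "run_log.jsonl"),
      append = TRUE, sep = "")
  invisible(manifest)
}

require_stage <- function(dir, stage) {
  p <- manifest_path(dir, stage)
  if (!file.exists(p)) {
    abort(paste0("missing upstream stage '", stage, "': run_", stage,
                 "() has not been run in ", dir))
  }
  jsonlite::read_json(p)
}

stage_is_current <- function(dir, stage, cfg) {
  p <- manifest_path(dir, stage)
  if (!file.exists(p)) return(FALSE)
  m <- jsonlite::read_json(p)
  if (!identical(m$config_hash, config_hash(cfg))) return(FALSE)
  all(vapply(names(m$files), function(f) {
    fp <- file.path(dir, f)
    file.exists(fp) && identical(unname(tools::md5sum(fp)), m$files[[f]])
  }, logical(1)))
}

cfg_task <- function(cfg) do.call(task_config, cfg$task)

#' Pipeline stages
#'
#' Each stage reads its upstream outputs through their manifests, writes
#' result tables plus a JSON manifest with content hashes, and appends a
#' line to the run log. Re-running a stage whose configuration and
#' outputs are unchanged is a no-op; changed outputs require
#' `overwrite = TRUE`. `run_simulate()` generates the behavioral cohort
#' (translated to the split learning rule whenever an impairment is
#' configured, so control and impaired datasets share a generative
#' form), and optionally synthetic spikes for the first rat.
#' `run_fit()` fits the mixture-of-agents model per rat.
#' `run_behavior()` produces history weights, behavioral indices and the
#' reversal performance curve per rat. `run_inactivation()` fits the
#' condition-split history regression and the across-rat planning
#' contrasts. `run_encode()` builds the encoding design from the fitted
#' parameters and computes CPDs with circular-permutation inference.
#' `run_report()` writes a plain-text summary of whatever stages have
#' run.
#'
#' @param cfg A [run_config()].
#' @param dir Output directory (created if needed).
#' @param overwrite Allow replacing outputs produced under a different
#'   configuration.
#' @return Invisibly, the stage manifest.
#' @export
run_simulate <- function(cfg, dir, overwrite = FALSE) {
  t0 <- as.numeric(Sys.time())
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (stage_is_current(dir, "simulate", cfg)) {
    message("simulate: outputs up to date, skipping")
    return(invisible(jsonlite::read_json(manifest_path(dir, "simulate"))))
  }
  if (file.exists(file.path(dir, "trials.csv")) && !overwrite) {
    abort("trials.csv exists and was produced under a different configuration; use overwrite = TRUE")
  }
  task <- cfg_task(cfg)
  impair <- do.call(impairment_spec, cfg$impairment)
  sched <- do.call(inactivation_schedule_spec, cfg$schedule)

  set.seed(derive_seed(cfg$seed, 1))
  params <- cohort_params(cfg$n_rats)
  gen_params <- if (impair$target != "none") {
    purrr::map(params, translate_params)
  } else params
  trials <- simulate_cohort(gen_params, cfg$n_trials_per_rat,
                            cfg$session_length, task, sched, impair)
  files <- file.path(dir, "trials.csv")
  write_trials(trials, files)
  pdir <- file.path(dir, "params")
  dir.create(pdir, showWarnings = FALSE)
  for (r in names(params)) {
    f <- file.path(pdir, paste0(r, ".yaml"))
    write_agent_params(params[[r]], f)
    files <- c(files, f)
  }
  if (isTRUE(cfg$encoding$simulate_spikes) && cfg$n_trials_per_rat > 1) {
    set.seed(derive_seed(cfg$seed, 2))
    r1 <- names(params)[1]
    tr1 <- dplyr::filter(trials, .data$rat == r1)
    vals <- agent_values(tr1, gen_params[[r1]], task)
    design <- build_neural_design(tr1, vals)
    gains <- if (length(cfg$encoding$gains) > 0) {
      tibble::as_tibble(cfg$encoding$gains)
    } else NULL
    spec <- spike_gen_spec(cfg$encoding$baseline_hz, gains,
                           cfg$encoding$window, cfg$encoding$bin_width)
    spikes <- generate_spikes(design, spec, cfg$encoding$n_units)
    f <- file.path(dir, "spikes.csv")
    readr::write_csv(spikes, f, progress = FALSE)
    files <- c(files, f)
  }
  invisible(write_manifest(dir, "simulate", cfg, files, t0))
}

#' @rdname run_simulate
#' @export
run_fit <- function(cfg, dir, overwrite = FALSE) {
  t0 <- as.numeric(Sys.time())
  require_stage(dir, "simulate")
  if (stage_is_current(dir, "fit", cfg) && !overwrite) {
    message("fit: outputs up to date, skipping")
    return(invisible(jsonlite::read_json(manifest_path(dir, "fit"))))
  }
  task <- cfg_task(cfg)
  priors <- do.call(prior_spec, cfg$priors)
  trials <- read_trials(file.path(dir, "trials.csv"))
  rats <- unique(trials$rat)
  fdir <- file.path(dir, "fit_params")
  dir.create(fdir, showWarnings = FALSE)
  files <- character(0)
  rows <- purrr::imap_dfr(stats::setNames(rats, rats), function(r, nm) {
    fit <- fit_map(dplyr::filter(trials, .data$rat == r),
                   priors = priors, config = task,
                   n_restarts = cfg$fit$n_restarts,
                   seed = derive_seed(cfg$seed, 10 + match(r, rats)))
    f <- file.path(fdir, paste0(r, ".yaml"))
    write_agent_params(fit$params, f)
    files <<- c(files, f)
    dplyr::mutate(tidy(fit), rat = r, converged = fit$converged,
                  .before = 1)
  })
  f <- file.path(dir, "fits.csv")
  readr::write_csv(rows, f, progress = FALSE)
  invisible(write_manifest(dir, "fit", cfg, c(f, files), t0))
}

#' @rdname run_simulate
#' @export
run_behavior <- function(cfg, dir, overwrite = FALSE) {
  t0 <- as.numeric(Sys.time())
  require_stage(dir, "simulate")
  if (stage_is_current(dir, "behavior", cfg) && !overwrite) {
    message("behavior: outputs up to date, skipping")
    return(invisible(jsonlite::read_json(manifest_path(dir, "behavior"))))
  }
  task <- cfg_task(cfg)
  trials <- read_trials(file.path(dir, "trials.csv"))
  rats <- unique(trials$rat)
  weights <- purrr::map_dfr(rats, function(r) {
    fit <- fit_history_logistic(dplyr::filter(trials, .data$rat == r),
                                prior_sd = cfg$behavior$prior_sd,
                                n_lags = cfg$behavior$n_lags)
    dplyr::mutate(tidy(fit), rat = r, .before = 1)
  })
  indices <- weights |>
    dplyr::group_by(.data$rat) |>
    dplyr::group_modify(~ compute_indices(.x)) |>
    dplyr::ungroup()
  lagged <- indices |>
    dplyr::select("rat", "lagged_planning") |>
    tidyr::unnest("lagged_planning")
  curve <- purrr::map_dfr(rats, function(r) {
    dplyr::mutate(performance_curve(dplyr::filter(trials, .data$rat == r),
                                    task), rat = r, .before = 1)
  })
  files <- file.path(dir, c("behavior_weights.csv",
                            "behavior_indices.csv",
                            "behavior_lagged_planning.csv",
                            "performance_curve.csv"))
  readr::write_csv(weights, files[1], progress = FALSE)
  readr::write_csv(dplyr::select(indices, -"lagged_planning"), files[2],
                   progress = FALSE)
  readr::write_csv(lagged, files[3], progress = FALSE)
  readr::write_csv(curve, files[4], progress = FALSE)
  invisible(write_manifest(dir, "behavior", cfg, files, t0))
}

#' @rdname run_simulate
#' @export
run_inactivation <- function(cfg, dir, overwrite = FALSE) {
  t0 <- as.numeric(Sys.time())
  require_stage(dir, "simulate")
  if (stage_is_current(dir, "inactivation", cfg) && !overwrite) {
    message("inactivation: outputs up to date, skipping")
    return(invisible(jsonlite::read_json(manifest_path(dir,
                                                       "inactivation"))))
  }
  trials <- read_trials(file.path(dir, "trials.csv"))
  rats <- unique(trials$rat)
  fits <- purrr::map(stats::setNames(rats, rats), function(r) {
    fit_inactivation_history(dplyr::filter(trials, .data$rat == r),
                             n_lags = cfg$behavior$n_lags,
                             prior_sd = cfg$behavior$prior_sd)
  })
  weights <- purrr::imap_dfr(fits, function(f, r) {
    dplyr::mutate(tidy(f), rat = r, .before = 1)
  })
  contrast <- planning_contrast(fits)
  files <- file.path(dir, c("inactivation_weights.csv",
                            "planning_per_rat.csv",
                            "planning_lagged.csv",
                            "planning_tests.csv",
                            "planning_lag_tests.csv"))
  readr::write_csv(weights, files[1], progress = FALSE)
  readr::write_csv(contrast$per_rat, files[2], progress = FALSE)
  readr::write_csv(contrast$lagged, files[3], progress = FALSE)
  readr::write_csv(contrast$tests %||% tibble::tibble(), files[4],
                   progress = FALSE)
  readr::write_csv(contrast$lag_tests %||% tibble::tibble(), files[5],
                   progress = FALSE)
  invisible(write_manifest(dir, "inactivation", cfg, files, t0))
}

#' @rdname run_simulate
#' @export
run_encode <- function(cfg, dir, overwrite = FALSE) {
  t0 <- as.numeric(Sys.time())
  require_stage(dir, "simulate")
  require_stage(dir, "fit")
  if (stage_is_current(dir, "encode", cfg) && !overwrite) {
    message("encode: outputs up to date, skipping")
    return(invisible(jsonlite::read_json(manifest_path(dir, "encode"))))
  }
  spikes_path <- file.path(dir, "spikes.csv")
  if (!file.exists(spikes_path)) {
    abort("missing spikes.csv: enable encoding$simulate_spikes in run_simulate() or supply spike data")
  }
  task <- cfg_task(cfg)
  trials <- read_trials(file.path(dir, "trials.csv"))
  r1 <- unique(trials$rat)[1]
  tr1 <- dplyr::filter(trials, .data$rat == r1)
  fitted <- read_agent_params(file.path(dir, "fit_params",
                                        paste0(r1, ".yaml")))
  spikes <- readr::read_csv(spikes_path, show_col_types = FALSE,
                            progress = FALSE)
  vals <- agent_values(tr1, fitted, task)
  design <- build_neural_design(tr1, vals)
  excl <- flag_artifact_trials(spikes, cfg$encoding$artifact_threshold)
  set.seed(derive_seed(cfg$seed, 3))
  unit_event <- permutation_inference(spikes, design,
                                      n_perm = cfg$encoding$n_perm,
                                      scope = "unit_event",
                                      exclusions = excl)
  set.seed(derive_seed(cfg$seed, 4))
  pop <- permutation_inference(spikes, design,
                               n_perm = cfg$encoding$n_perm,
                               scope = "population_bin",
                               exclusions = excl)
  summ <- summarize_coding(unit_event)
  files <- file.path(dir, c("cpd_unit_event.csv", "cpd_population.csv",
                            "coding_fractions.csv",
                            "coding_comparisons.csv"))
  readr::write_csv(unit_event, files[1], progress = FALSE)
  readr::write_csv(pop, files[2], progress = FALSE)
  readr::write_csv(summ$fractions, files[3], progress = FALSE)
  readr::write_csv(summ$comparisons, files[4], progress = FALSE)
  invisible(write_manifest(dir, "encode", cfg, files, t0))
}

#' @rdname run_simulate
#' @export
run_report <- function(cfg, dir, overwrite = FALSE) {
  t0 <- as.numeric(Sys.time())
  require_stage(dir, "simulate")
  lines <- c("two-step pipeline report",
             paste("config hash:", config_hash(cfg)), "")
  for (stage in c("fit", "behavior", "inactivation", "encode")) {
    p <- manifest_path(dir, stage)
    if (!file.exists(p)) next
    m <- jsonlite::read_json(p)
    lines <- c(lines, paste0("stage ", stage, ": ",
                             length(m$files), " file(s), ",
                             m$elapsed_s, " s"))
  }
  if (file.exists(file.path(dir, "behavior_indices.csv"))) {
    idx <- readr::read_csv(file.path(dir, "behavior_indices.csv"),
                           show_col_types = FALSE, progress = FALSE)
    lines <- c(lines, "", "behavioral indices:",
               utils::capture.output(print(as.data.frame(idx))))
  }
  if (file.exists(file.path(dir, "planning_tests.csv"))) {
    tst <- readr::read_csv(file.path(dir, "planning_tests.csv"),
                           show_col_types = FALSE, progress = FALSE)
    if (nrow(tst) > 0) {
      lines <- c(lines, "", "planning-index tests:",
                 utils::capture.output(print(as.data.frame(tst))))
    }
  }
  f <- file.path(dir, "report.txt")
  writeLines(lines, f)
  invisible(write_manifest(dir, "report", cfg, f, t0))
}
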