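# End-to-end orchestration: simulate -> extract -> classify -> behaviour ->
# report, file-based (CSV/JSON) with a single config seed from which every
# stage derives its own RNG seed. Reruns with the same config are
# byte-identical.

#' Pipeline run configuration
#'
#' Builds a validated configuration for the file-based pipeline. The same
#' structure can be read from a YAML file with [read_run_config()]. A seed
#' is mandatory: each stage seeds the RNG from it deterministically.
#'
#' @param seed integer master seed (required).
#' @param out_dir directory for all stage outputs.
#' @param n_sessions,trials_per_session simulated experiment size.
#' @param sim list of [sim_config()] overrides (e.g. `list(whisk_freq = 10)`).
#' @param policy list of [behavior_policy()] overrides.
#' @param dist_threshold,band_hz feature-extraction parameters.
#' @param k_folds,n_null classifier CV folds and shuffle-chance iterations.
#' @param n_shuffles behavioural shuffle iterations.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed, out_dir,
                       n_sessions = 4, trials_per_session = 190,
                       sim = list(), policy = list(),
                       dist_threshold = 0.5, band_hz = c(4, 30),
                       k_folds = 10, n_null = 50, n_shuffles = 10000) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (missing(out_dir) || is.null(out_dir)) stop("out_dir is required")
  sim$n_trials <- trials_per_session
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              n_sessions = as.integer(n_sessions),
              trials_per_session = as.integer(trials_per_session),
              sim = sim, policy = policy,
              dist_threshold = dist_threshold, band_hz = band_hz,
              k_folds = as.integer(k_folds), n_null = as.integer(n_null),
              n_shuffles = as.integer(n_shuffles))
  cfg$sim_config <- do.call(sim_config, cfg$sim)
  cfg$policy_obj <- do.call(behavior_policy, cfg$policy)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the [run_config()] arguments as key/value pairs
#' (`seed`, `out_dir`, `n_sessions`, `trials_per_session`, nested `sim` and
#' `policy` blocks, `dist_threshold`, `band_hz`, `k_folds`, `n_null`,
#' `n_shuffles`).
#'
#' @param path YAML file path.
#' @param out_dir optional override of the configured output directory.
#' @return `run_config` object.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(run_config, raw)
}

config_hash <- function(config) {
  core <- unclass(config)
  core$out_dir <- NULL
  core$sim_config <- NULL
  core$policy_obj <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(core), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

read_stage_csv <- function(path, required) {
  if (!file.exists(path)) stop("missing pipeline input: ", path)
  d <- as.data.frame(data.table::fread(path))
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("file ", basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "))
  d
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Pipeline stage: simulate
#'
#' Generates the synthetic experiment and writes `trials.csv` and
#' `frames.csv` to the output directory.
#'
#' @param config a [run_config()].
#' @return invisibly, the paths written.
#' @export
run_simulate <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(stage_seed(config$seed, 1L))
  t0 <- proc.time()[3]
  exp <- generate_experiment(config$n_sessions, config$sim_config,
                             config$policy_obj, frames = TRUE)
  paths <- file.path(config$out_dir, c("trials.csv", "frames.csv"))
  data.table::fwrite(exp$trials, paths[1])
  data.table::fwrite(exp$frames, paths[2])
  stage_log("simulate", "%d sessions, %d trials, %d frames (%.1fs)",
            config$n_sessions, nrow(exp$trials), nrow(exp$frames),
            proc.time()[3] - t0)
  invisible(paths)
}

#' Pipeline stage: extract features
#'
#' Reads `trials.csv`/`frames.csv`, builds the predictor table and writes
#' `predictors.csv` (plus `episodes.csv` with all touch episodes).
#'
#' @param config a [run_config()].
#' @return invisibly, the predictor-table path.
#' @export
run_extract <- function(config) {
  t0 <- proc.time()[3]
  trials <- read_stage_csv(file.path(config$out_dir, "trials.csv"),
                           c("session_id", "trial_idx", "pole_location",
                             "choice", "correct"))
  frames <- read_stage_csv(file.path(config$out_dir, "frames.csv"),
                           c("session_id", "trial_idx", "t_ms", "angle_deg",
                             "kappa_per_mm", "pole_dist", "quality"))
  pt <- build_predictor_table(trials, frames,
                              dist_threshold = config$dist_threshold,
                              band_hz = config$band_hz)
  path <- file.path(config$out_dir, "predictors.csv")
  data.table::fwrite(as.data.frame(pt), path)
  eps <- attr(pt, "episodes")
  ep_rows <- do.call(rbind, lapply(seq_along(eps), function(i) {
    e <- eps[[i]]
    if (nrow(e) == 0) return(NULL)
    cbind(session_id = pt$session_id[i], trial_idx = pt$trial_idx[i], e)
  }))
  if (is.null(ep_rows))
    ep_rows <- data.frame(session_id = integer(), trial_idx = integer(),
                          start_ms = integer(), end_ms = integer(),
                          direction = character(), is_first = logical())
  data.table::fwrite(ep_rows, file.path(config$out_dir, "episodes.csv"))
  stage_log("extract", "%d trials, %d episodes, %d unusable (%.1fs)",
            nrow(pt), sum(vapply(eps, nrow, integer(1))),
            sum(!pt$usable), proc.time()[3] - t0)
  invisible(path)
}

# One classifier's CV metrics + 50-iteration shuffle chance for both metrics
# (performance and choice consistency), sharing one CV per iteration.
classify_one <- function(x, y, choices, k_folds, n_null) {
  cv <- crossval_predict(x, y, k_folds)
  perf <- classifier_performance(cv$predicted, y)
  cons <- choice_consistency(cv$predicted, choices)
  np <- numeric(n_null); nc <- numeric(n_null)
  for (i in seq_len(n_null)) {
    yp <- sample(y)
    cvn <- crossval_predict(x, yp, k_folds)
    np[i] <- classifier_performance(cvn$predicted, yp)
    nc[i] <- choice_consistency(cvn$predicted, choices)
  }
  sp <- null_summary(np); sc <- null_summary(nc)
  list(performance = perf, consistency = cons,
       performance_chance = list(mean = sp$mean, ci = sp$ci),
       consistency_chance = list(mean = sc$mean, ci = sc$ci))
}

#' Pipeline stage: classify
#'
#' Fits the four cross-validated MAP classifiers of pole location (PAT,
#' touch type, touch type + dkappa95, previous choice type), with shuffle
#' chance for performance and choice consistency, and writes
#' `classify.json`.
#'
#' @param config a [run_config()].
#' @return invisibly, the JSON path.
#' @export
run_classify <- function(config) {
  t0 <- proc.time()[3]
  d <- read_stage_csv(file.path(config$out_dir, "predictors.csv"),
                      c("pole_location", "choice", "correct", "pat",
                        "touch_type", "dkappa95", "prev_choice_type",
                        "usable"))
  d$pat <- factor(d$pat, levels = c(0, 1))
  d$touch_type <- factor(d$touch_type,
                         levels = c("none", "protraction", "retraction"))
  d$prev_choice_type <- factor(d$prev_choice_type,
                               levels = CHOICE_TYPE_LEVELS)
  d <- d[d$usable, , drop = FALSE]
  y <- as_location(d$pole_location)
  choices <- as_choice(d$choice)
  set.seed(stage_seed(config$seed, 2L))
  out <- list(
    pat = classify_one(d[, "pat", drop = FALSE], y, choices,
                       config$k_folds, config$n_null),
    touch_type = classify_one(d[, "touch_type", drop = FALSE], y, choices,
                              config$k_folds, config$n_null),
    dkappa95_touch_type = classify_one(d[, c("touch_type", "dkappa95")], y,
                                       choices, config$k_folds,
                                       config$n_null))
  dh <- d[!is.na(d$prev_choice_type), , drop = FALSE]
  out$previous_choice <- classify_one(
    dh[, "prev_choice_type", drop = FALSE], as_location(dh$pole_location),
    as_choice(dh$choice), config$k_folds, config$n_null)
  out$n_trials <- nrow(d)
  out$n_first_trials_excluded <- nrow(d) - nrow(dh)
  path <- file.path(config$out_dir, "classify.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  stage_log("classify", "4 classifiers on %d trials (%.1fs)", nrow(d),
            proc.time()[3] - t0)
  invisible(path)
}

#' Pipeline stage: behavioural analysis
#'
#' Computes task performance (10,000-shuffle chance), perseveration on all /
#' correct / error trials, perseveration on error trials by previous
#' outcome, the sensory-vs-history dissociation, touch-sequence statistics
#' and the choice-bias test, and writes `behavior.json`.
#'
#' @param config a [run_config()].
#' @return invisibly, the JSON path.
#' @export
run_behavior <- function(config) {
  t0 <- proc.time()[3]
  trials <- read_stage_csv(file.path(config$out_dir, "trials.csv"),
                           c("session_id", "trial_idx", "pole_location",
                             "choice", "correct"))
  d <- read_stage_csv(file.path(config$out_dir, "predictors.csv"),
                      c("pole_location", "choice", "correct", "touch_type",
                        "dkappa95", "prev_choice_type", "usable"))
  d$touch_type <- factor(d$touch_type,
                         levels = c("none", "protraction", "retraction"))
  d$prev_choice_type <- factor(d$prev_choice_type,
                               levels = CHOICE_TYPE_LEVELS)
  eps <- read_stage_csv(file.path(config$out_dir, "episodes.csv"),
                        c("session_id", "trial_idx", "direction"))
  set.seed(stage_seed(config$seed, 3L))
  ts <- task_performance(trials, n_shuffles = config$n_shuffles)
  cor_mask <- as.logical(trials$correct)
  pers <- list(
    all = perseveration(trials$choice, NULL, config$n_shuffles),
    correct = perseveration(trials$choice, cor_mask, config$n_shuffles),
    error = perseveration(trials$choice, !cor_mask, config$n_shuffles))
  ppo <- perseveration_by_previous_outcome(trials)
  diss <- dissociation_analysis(d, config$k_folds, config$n_null)
  ep_list <- split(eps, list(eps$session_id, eps$trial_idx), drop = TRUE)
  no_touch <- sum(d$touch_type == "none")
  tss <- touch_sequence_stats(c(ep_list, rep(list(eps[0, ]), no_touch)))
  bias <- choice_bias_test(trials$choice)
  out <- list(
    performance = list(value = ts$performance,
                       per_location = as.list(ts$per_location),
                       chance_mean = ts$chance_mean,
                       chance_ci = ts$chance_ci,
                       above_chance = ts$above_chance,
                       n_trials = ts$n_trials),
    perseveration = lapply(pers, function(p)
      list(prob = p$prob, chance_mean = p$chance_mean, chance_ci = p$chance_ci,
           n = p$n)),
    perseveration_by_previous_outcome = ppo,
    dissociation = list(accuracy = diss$accuracy,
                        null = lapply(diss$null, lapply, function(v)
                          list(mean = v$mean, ci = v$ci)),
                        n_correct = diss$n_correct,
                        n_error = diss$n_error),
    touch_sequence = tss,
    choice_bias = list(statistic = unname(bias$statistic),
                       p_value = bias$p.value))
  path <- file.path(config$out_dir, "behavior.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  stage_log("behavior", "%d trials analysed (%.1fs)", nrow(trials),
            proc.time()[3] - t0)
  invisible(path)
}

#' Pipeline stage: report
#'
#' Collects the classify and behaviour outputs into a single machine-
#' readable `report.json` (stamped with the config hash and seed) and a
#' human-readable `report.txt` mirroring the classifier-comparison and
#' correct/error-dissociation structure of the analysis.
#'
#' @param config a [run_config()].
#' @return invisibly, the report JSON path.
#' @export
run_report <- function(config) {
  cls <- jsonlite::read_json(file.path(config$out_dir, "classify.json"))
  beh <- jsonlite::read_json(file.path(config$out_dir, "behavior.json"))
  report <- list(schema_version = "1.0",
                 seed = config$seed,
                 config_hash = config_hash(config),
                 classifiers = cls[c("pat", "touch_type",
                                     "dkappa95_touch_type",
                                     "previous_choice")],
                 behavior = beh)
  jpath <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, jpath, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  txt <- c(
    "Whisker-guided pole localization: analysis report",
    sprintf("seed %d  config %s", config$seed, report$config_hash),
    "",
    sprintf("Mouse task performance: %.3f (chance %.3f [%.3f, %.3f])",
            beh$performance$value, beh$performance$chance_mean,
            beh$performance$chance_ci[[1]], beh$performance$chance_ci[[2]]),
    "",
    "Pole-location classifiers (performance | choice consistency):",
    vapply(c("pat", "touch_type", "dkappa95_touch_type", "previous_choice"),
           function(k) sprintf("  %-20s %.3f | %.3f", k,
                               cls[[k]]$performance, cls[[k]]$consistency),
           character(1)),
    "",
    "Perseveration (all | correct | error):",
    sprintf("  %.3f | %.3f | %.3f",
            beh$perseveration$all$prob, beh$perseveration$correct$prob,
            beh$perseveration$error$prob),
    "",
    "Choice prediction by trial outcome (accuracy):",
    sprintf("  sensory:  correct %.3f | error %.3f",
            beh$dissociation$accuracy$sensory$correct,
            beh$dissociation$accuracy$sensory$error),
    sprintf("  history:  correct %.3f | error %.3f",
            beh$dissociation$accuracy$history$correct,
            beh$dissociation$accuracy$history$error))
  writeLines(unlist(txt), file.path(config$out_dir, "report.txt"))
  stage_log("report", "written to %s", config$out_dir)
  invisible(jpath)
}

#' Run the full pipeline
#'
#' simulate -> extract -> classify -> behaviour -> report.
#'
#' @param config a [run_config()].
#' @return invisibly, the report JSON path.
#' @export
run_all <- function(config) {
  run_simulate(config)
  run_extract(config)
  run_classify(config)
  run_behavior(config)
  run_report(config)
}
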