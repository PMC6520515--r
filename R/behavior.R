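# Session-level behavioural statistics: task performance against a
# shuffle-based chance interval, learning/asymptote criteria, perseveration,
# the correct/error double dissociation, touch-sequence descriptives and a
# choice-bias test.

#' Task performance with shuffle-based chance interval
#'
#' Performance is the proportion of trials on which the mouse's choice was
#' correct. Chance is estimated by shuffling the pole-location sequence with
#' respect to the choice sequence `n_shuffles` times and recomputing the
#' proportion correct; the 95% interval is the 2.5/97.5 percentile of that
#' null.
#'
#' @param trials trial table with columns pole_location, choice (and
#'   session metadata).
#' @param n_shuffles shuffle iterations (default 10,000).
#' @param mapping location -> correct-choice bijection.
#' @return object of class `session_summary`: performance, per-location
#'   performance, chance_mean, chance_ci, above_chance, n_trials.
#' @export
task_performance <- function(trials, n_shuffles = 10000,
                             mapping = stats::setNames(CHOICE_LEVELS,
                                                       LOCATION_LEVELS)) {
  stopifnot(nrow(trials) >= 1)
  loc <- as.character(trials$pole_location)
  cho <- as.character(trials$choice)
  correct <- unname(mapping[loc]) == cho
  perf <- mean(correct)
  per_loc <- vapply(LOCATION_LEVELS, function(l) {
    i <- loc == l
    if (any(i)) mean(correct[i]) else NA_real_
  }, numeric(1))
  n <- length(loc)
  null <- vapply(seq_len(n_shuffles), function(i)
    mean(unname(mapping[loc[sample.int(n)]]) == cho), numeric(1))
  ns <- null_summary(null)
  structure(list(performance = perf, per_location = per_loc,
                 chance_mean = ns$mean, chance_ci = ns$ci,
                 above_chance = perf > ns$ci[2], n_trials = n),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf(
    "Session: %d trials, performance %.3f (chance %.3f [%.3f, %.3f])%s\n",
    x$n_trials, x$performance, x$chance_mean, x$chance_ci[1], x$chance_ci[2],
    if (x$above_chance) ", above chance" else ""))
  invisible(x)
}

#' Detect task learning across sessions
#'
#' A mouse has learned when performance is above the shuffle chance interval
#' on three consecutive sessions; the first index of such a window is
#' returned.
#'
#' @param summaries list of [task_performance()] results in session order.
#' @return 1-based session index, or `NA` if no window qualifies.
#' @export
learning_detector <- function(summaries) {
  stopifnot(length(summaries) >= 3)
  flags <- vapply(summaries, function(s) isTRUE(s$above_chance), logical(1))
  for (i in seq_len(length(flags) - 2))
    if (all(flags[i:(i + 2)])) return(i)
  NA_integer_
}

#' Asymptotic performance
#'
#' Mean performance over the latest window of `window` consecutive
#' above-chance sessions (as close as possible to the end of training).
#'
#' @param summaries list of session summaries in order.
#' @param window window length (default 8 sessions).
#' @return mean proportion correct over that window.
#' @export
asymptotic_performance <- function(summaries, window = 8) {
  stopifnot(length(summaries) >= window)
  flags <- vapply(summaries, function(s) isTRUE(s$above_chance), logical(1))
  perf <- vapply(summaries, function(s) s$performance, numeric(1))
  starts <- which(vapply(seq_len(length(flags) - window + 1), function(i)
    all(flags[i:(i + window - 1)]), logical(1)))
  if (length(starts) == 0)
    stop("no window of ", window, " consecutive above-chance sessions")
  i <- max(starts)
  mean(perf[i:(i + window - 1)])
}

#' Probability of perseveration
#'
#' Proportion of selected trials (t >= 2) on which the choice equals the
#' previous trial's choice. Chance is computed by permuting the full choice
#' sequence and recomputing the statistic on the same subset positions.
#'
#' @param choices choice sequence.
#' @param subset_mask logical mask over trials selecting current-trial
#'   membership (e.g. all, correct-only, error-only); default all trials.
#' @param n_shuffles shuffle iterations.
#' @return list: prob, chance_mean, chance_ci, n (selected trial count).
#' @export
perseveration <- function(choices, subset_mask = NULL, n_shuffles = 10000) {
  cho <- as.character(choices)
  n <- length(cho)
  stopifnot(n >= 2)
  if (is.null(subset_mask)) subset_mask <- rep(TRUE, n)
  stopifnot(length(subset_mask) == n)
  sel <- which(subset_mask & seq_len(n) >= 2)
  if (length(sel) == 0) stop("empty subset")
  stat <- function(x) mean(x[sel] == x[sel - 1])
  null <- vapply(seq_len(n_shuffles), function(i) stat(cho[sample.int(n)]),
                 numeric(1))
  ns <- null_summary(null)
  list(prob = stat(cho), chance_mean = ns$mean, chance_ci = ns$ci,
       n = length(sel))
}

#' Perseveration on error trials by previous-trial outcome
#'
#' Among current error trials, the probability of repeating the previous
#' choice, split by whether the previous trial was correct or an error.
#'
#' @param trials trial table with choice and correct columns (single
#'   ordered sequence).
#' @return list: prev_correct, prev_error (probabilities, `NA` when the
#'   stratum is empty), n_prev_correct, n_prev_error.
#' @export
perseveration_by_previous_outcome <- function(trials) {
  stopifnot(nrow(trials) >= 2)
  cho <- as.character(trials$choice)
  cor <- as.logical(trials$correct)
  t <- 2:length(cho)
  err_now <- !cor[t]
  persev <- cho[t] == cho[t - 1]
  prev_cor <- cor[t - 1]
  p_c <- if (any(err_now & prev_cor))
    mean(persev[err_now & prev_cor]) else NA_real_
  p_e <- if (any(err_now & !prev_cor))
    mean(persev[err_now & !prev_cor]) else NA_real_
  list(prev_correct = p_c, prev_error = p_e,
       n_prev_correct = sum(err_now & prev_cor),
       n_prev_error = sum(err_now & !prev_cor))
}

#' Correct/error double dissociation of sensory vs history classifiers
#'
#' Predicts mouse choice twice under one shared cross-validation partition:
#' once from sensory predictors (touch type + dkappa95) and once from the
#' previous trial's choice type. Accuracy is then evaluated separately on
#' correct and error trials, each against a shuffle null computed on the
#' same subset positions.
#'
#' @param predictors a [build_predictor_table()] data.frame (rows with
#'   undefined previous choice or unusable features are dropped).
#' @param k_folds CV folds.
#' @param n_null shuffle iterations for the per-subset chance levels.
#' @return object of class `dissociation`: per-classifier, per-subset
#'   accuracies, null summaries, subset sizes.
#' @export
dissociation_analysis <- function(predictors, k_folds = 10, n_null = 50) {
  keep <- !is.na(predictors$prev_choice_type) & predictors$usable
  d <- predictors[keep, , drop = FALSE]
  y <- as_choice(d$choice)
  correct <- as.logical(d$correct)
  if (!any(correct) || all(correct))
    stop("both correct and error subsets must be nonempty")
  if (min(sum(correct), sum(!correct)) < k_folds)
    warning("a correctness subset is smaller than the fold count; ",
            "subset metrics may be unstable (n = ",
            min(sum(correct), sum(!correct)), ")")
  x_sens <- d[, c("touch_type", "dkappa95")]
  x_hist <- d[, "prev_choice_type", drop = FALSE]
  T_ <- nrow(d)
  folds <- NULL
  for (r in 1:100) {
    cand <- sample(rep(seq_len(k_folds), length.out = T_))
    bad <- any(vapply(seq_len(k_folds), function(f)
      any(table(y[cand != f]) == 0), logical(1)))
    if (!bad) { folds <- cand; break }
  }
  if (is.null(folds)) stop("could not allocate folds with all classes")
  cv_s <- crossval_predict(x_sens, y, k_folds, folds = folds)
  cv_h <- crossval_predict(x_hist, y, k_folds, folds = folds)
  subset_acc <- function(pred, labels, mask)
    mean(as.character(pred[mask]) == as.character(labels[mask]))
  acc <- list(
    sensory = list(correct = subset_acc(cv_s$predicted, y, correct),
                   error = subset_acc(cv_s$predicted, y, !correct)),
    history = list(correct = subset_acc(cv_h$predicted, y, correct),
                   error = subset_acc(cv_h$predicted, y, !correct)))
  nulls <- list(sensory = list(correct = numeric(n_null),
                               error = numeric(n_null)),
                history = list(correct = numeric(n_null),
                               error = numeric(n_null)))
  for (i in seq_len(n_null)) {
    yp <- sample(y)
    ns <- crossval_predict(x_sens, yp, k_folds, folds = folds)
    nh <- crossval_predict(x_hist, yp, k_folds, folds = folds)
    nulls$sensory$correct[i] <- subset_acc(ns$predicted, yp, correct)
    nulls$sensory$error[i] <- subset_acc(ns$predicted, yp, !correct)
    nulls$history$correct[i] <- subset_acc(nh$predicted, yp, correct)
    nulls$history$error[i] <- subset_acc(nh$predicted, yp, !correct)
  }
  nulls <- lapply(nulls, lapply, function(v)
    structure(null_summary(v), class = "null_dist"))
  structure(list(accuracy = acc, null = nulls,
                 n_correct = sum(correct), n_error = sum(!correct),
                 folds = folds),
            class = "dissociation")
}

#' @export
print.dissociation <- function(x, ...) {
  cat("Choice prediction by trial outcome (accuracy):\n")
  cat(sprintf("  sensory (touch type + dkappa95): correct %.3f | error %.3f\n",
              x$accuracy$sensory$correct, x$accuracy$sensory$error))
  cat(sprintf("  previous choice type:            correct %.3f | error %.3f\n",
              x$accuracy$history$correct, x$accuracy$history$error))
  cat(sprintf("  subsets: %d correct, %d error trials\n",
              x$n_correct, x$n_error))
  invisible(x)
}

#' Touch-sequence descriptive statistics
#'
#' @param episodes list of per-trial episode tables (with directions).
#' @return list: frac_le3 (fraction of trials with at most three touches),
#'   frac_second_matches_first and frac_third_matches_second (direction
#'   agreement among trials with enough touches; `NA` when no such trial).
#' @export
touch_sequence_stats <- function(episodes) {
  n_touch <- vapply(episodes, nrow, integer(1))
  dir_at <- function(ep, j) ep$direction[j]
  m2 <- which(n_touch >= 2)
  m3 <- which(n_touch >= 3)
  list(
    frac_le3 = mean(n_touch <= 3),
    frac_second_matches_first = if (length(m2))
      mean(vapply(episodes[m2], function(e)
        dir_at(e, 2) == dir_at(e, 1), logical(1))) else NA_real_,
    frac_third_matches_second = if (length(m3))
      mean(vapply(episodes[m3], function(e)
        dir_at(e, 3) == dir_at(e, 2), logical(1))) else NA_real_)
}

#' Chi-squared test of equal choice frequencies
#'
#' Goodness-of-fit of the observed choice counts against the uniform
#' three-category null (standard library test; a response bias shows as a
#' small p-value).
#'
#' @param choices choice labels.
#' @return `htest` object from [stats::chisq.test()].
#' @export
choice_bias_test <- function(choices) {
  cho <- as_choice(choices)
  if (length(cho) < 3) stop("need at least 3 choices")
  stats::chisq.test(table(cho))
}
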