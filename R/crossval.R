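# Cross-validated prediction, evaluation metrics, and shuffle-based chance
# distributions for the MAP classifier.

#' Cross-validated MAP classification
#'
#' Randomly partitions trials into `k_folds` folds (sizes differing by at
#' most one), fits the classifier on each training complement and predicts
#' the held-out fold; predictions are concatenated in the original trial
#' order. A partition whose training split misses a class is resampled (up
#' to `max_retries`).
#'
#' @param x predictor data.frame.
#' @param y class labels.
#' @param k_folds number of folds (k = T gives leave-one-out).
#' @param folds optional integer fold assignment (length T, values in
#'   1..k_folds) to reuse a fixed partition.
#' @param max_retries resampling attempts for degenerate partitions.
#' @param ... forwarded to [nb_map()].
#' @return object of class `nb_cv`: `predicted` (factor, original order),
#'   `posterior` (matrix), `folds`, `y`.
#' @export
crossval_predict <- function(x, y, k_folds = 10, folds = NULL,
                             max_retries = 100, ...) {
  y <- if (is.factor(y)) y else factor(y)
  T_ <- nrow(x)
  stopifnot(T_ >= k_folds, T_ == length(y))
  if (any(table(y) == 0)) stop("a class is absent from y")
  if (is.null(folds)) {
    for (r in seq_len(max_retries)) {
      cand <- sample(rep(seq_len(k_folds), length.out = T_))
      bad <- any(vapply(seq_len(k_folds), function(f)
        any(table(y[cand != f]) == 0), logical(1)))
      if (!bad) { folds <- cand; break }
    }
    if (is.null(folds))
      stop("could not find a fold partition with all classes in every ",
           "training split")
  } else {
    stopifnot(length(folds) == T_, all(folds %in% seq_len(k_folds)))
  }
  predicted <- factor(rep(NA_character_, T_), levels = levels(y))
  posterior <- matrix(NA_real_, T_, length(levels(y)),
                      dimnames = list(NULL, levels(y)))
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- nb_map(x[!test, , drop = FALSE], y[!test], ...)
    posterior[test, ] <- predict(fit, x[test, , drop = FALSE],
                                 type = "posterior")
    predicted[test] <- predict(fit, x[test, , drop = FALSE])
  }
  structure(list(predicted = predicted, posterior = posterior,
                 folds = folds, y = y),
            class = "nb_cv")
}

#' @export
print.nb_cv <- function(x, ...) {
  cat("Cross-validated MAP classification:",
      length(x$predicted), "trials,",
      length(unique(x$folds)), "folds\n")
  cat("  accuracy vs labels:",
      sprintf("%.3f", classifier_performance(x$predicted, x$y)), "\n")
  invisible(x)
}

#' Cross-validated prediction of mouse choice
#'
#' Same machinery as [crossval_predict()] with the mouse's choices as the
#' class labels.
#'
#' @param x predictor data.frame.
#' @param choices mouse choice labels.
#' @inheritParams crossval_predict
#' @return `nb_cv` object.
#' @export
predict_mouse_choice <- function(x, choices, k_folds = 10, folds = NULL,
                                 ...) {
  crossval_predict(x, droplevels(as_choice(choices)), k_folds = k_folds,
                   folds = folds, ...)
}

#' Classifier performance (proportion correct)
#'
#' @param predicted,true equal-length label vectors.
#' @return fraction of matching entries, in \[0, 1\].
#' @export
classifier_performance <- function(predicted, true) {
  if (length(predicted) == 0) stop("empty input")
  if (length(predicted) != length(true)) stop("length mismatch")
  mean(as.character(predicted) == as.character(true))
}

#' Classifier-mouse choice consistency
#'
#' Fraction of trials on which the classifier's implied choice (predicted
#' pole location mapped through the location-to-correct-choice bijection)
#' equals the mouse's choice.
#'
#' @param predicted_locations predicted pole locations.
#' @param mouse_choices observed choices.
#' @param mapping named bijection location -> choice.
#' @return proportion in \[0, 1\].
#' @export
choice_consistency <- function(predicted_locations, mouse_choices,
                               mapping = stats::setNames(CHOICE_LEVELS,
                                                         LOCATION_LEVELS)) {
  if (length(predicted_locations) == 0) stop("empty input")
  if (length(predicted_locations) != length(mouse_choices))
    stop("length mismatch")
  stopifnot(setequal(names(mapping), LOCATION_LEVELS),
            !any(duplicated(unname(mapping))))
  implied <- unname(mapping[as.character(predicted_locations)])
  mean(implied == as.character(mouse_choices))
}

#' Shuffle-based chance distribution for a cross-validated metric
#'
#' Permutes the class labels, reruns the full cross-validation, and records
#' the metric, yielding the classifier's chance level and its 95% percentile
#' interval.
#'
#' @param x predictor data.frame.
#' @param y labels to permute.
#' @param statistic function(predicted, y_shuffled) -> scalar; closures may
#'   capture unshuffled quantities (e.g. mouse choices for consistency).
#' @param iters number of shuffle iterations.
#' @param k_folds folds per iteration.
#' @param ... forwarded to [crossval_predict()].
#' @return object of class `null_dist`: `values`, `mean`, `ci` (2.5/97.5
#'   percentiles).
#' @export
shuffle_chance <- function(x, y, statistic = classifier_performance,
                           iters = 50, k_folds = 10, ...) {
  stopifnot(iters >= 2)
  y <- if (is.factor(y)) y else factor(y)
  values <- vapply(seq_len(iters), function(i) {
    yp <- sample(y)
    cv <- crossval_predict(x, yp, k_folds = k_folds, ...)
    statistic(cv$predicted, yp)
  }, numeric(1))
  structure(null_summary(values), class = "null_dist")
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf(
    "Shuffle null (%d iterations): mean %.3f, 95%% interval [%.3f, %.3f]\n",
    length(x$values), x$mean, x$ci[1], x$ci[2]))
  invisible(x)
}
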