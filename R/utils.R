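# Shared constants and small numerical utilities.

#' Canonical factor levels
#'
#' Pole locations and mouse choices share one label set: each choice is named
#' after the pole location for which it is the correct response (lick-left,
#' lick-right and no-lick map to the three locations). The fixed order also
#' defines deterministic tie-breaking in the classifier.
#'
#' @format Character vectors of length 3 (locations/choices) and 6
#'   (previous-trial choice types: choice crossed with correctness).
#' @name levels-constants
NULL

#' @rdname levels-constants
#' @export
LOCATION_LEVELS <- c("posterior", "middle", "anterior")

#' @rdname levels-constants
#' @export
CHOICE_LEVELS <- c("posterior", "middle", "anterior")

#' @rdname levels-constants
#' @export
CHOICE_TYPE_LEVELS <- as.vector(outer(CHOICE_LEVELS, c("correct", "error"),
                                      paste, sep = "_"))

as_location <- function(x) factor(as.character(x), levels = LOCATION_LEVELS)
as_choice <- function(x) factor(as.character(x), levels = CHOICE_LEVELS)

#' Choice-type label (choice crossed with correctness)
#'
#' Builds the six-valued categorical label combining a trial's choice and
#' whether it was correct, used as the previous-trial history predictor.
#'
#' @param choice character/factor vector of choices.
#' @param correct logical/0-1 vector.
#' @return factor with the six `CHOICE_TYPE_LEVELS` levels.
#' @export
choice_type <- function(choice, correct) {
  stopifnot(length(choice) == length(correct))
  lab <- paste(as.character(choice),
               ifelse(as.logical(correct), "correct", "error"), sep = "_")
  lab[is.na(choice) | is.na(correct)] <- NA
  factor(lab, levels = CHOICE_TYPE_LEVELS)
}

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal of a real series (the series plus i
#' times its Hilbert transform), computed by zeroing negative frequencies.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), length(x) > 2, all(is.finite(x)))
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Zero-phase band-pass of a mean-removed series (2nd-order Butterworth,
# forward-backward). fs in Hz; band = c(low, high) in Hz.
bandpass <- function(x, band, fs = 1000) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x - mean(x))
}

# Percentile interval (2.5/97.5) of a shuffle distribution, plus mean.
null_summary <- function(values) {
  list(values = values,
       mean = mean(values),
       ci = stats::quantile(values, c(0.025, 0.975), names = FALSE, type = 7))
}

# Derive a bounded stage seed from a base seed and an offset.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}
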