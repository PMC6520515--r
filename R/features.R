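# Mechanosensory feature extraction from tracked whisker frame series:
# gap filling, touch-episode segmentation, whisking phase/amplitude via the
# analytic signal, touch-type classification, and the dkappa95 bending
# statistic.

# A per-trial frame series is a data.frame with columns t_ms (0-based, unit
# step), angle_deg, kappa_per_mm, pole_dist and quality ("ok"/"dropped").
check_frame_series <- function(series) {
  need <- c("t_ms", "angle_deg", "kappa_per_mm", "pole_dist", "quality")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("frame series is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(series) > 1 && any(diff(series$t_ms) != 1))
    stop("t_ms must be strictly increasing with unit step")
  invisible(series)
}

#' Interpolate isolated dropped frames
#'
#' Single dropped frames flanked by ok frames get angle and curvature
#' linearly interpolated from their neighbours and are reflagged ok. Runs of
#' two or more dropped frames are left untouched.
#'
#' @param series per-trial frame series data.frame.
#' @return the series with isolated gaps filled.
#' @export
fill_isolated_gaps <- function(series) {
  check_frame_series(series)
  ok <- series$quality == "ok"
  n <- nrow(series)
  if (n < 3) return(series)
  i <- which(!ok)
  i <- i[i > 1 & i < n]
  i <- i[ok[i - 1] & ok[i + 1]]
  if (length(i)) {
    series$angle_deg[i] <- (series$angle_deg[i - 1] +
                              series$angle_deg[i + 1]) / 2
    series$kappa_per_mm[i] <- (series$kappa_per_mm[i - 1] +
                                 series$kappa_per_mm[i + 1]) / 2
    series$quality[i] <- "ok"
  }
  series
}

#' Detect touch episodes from the whisker-pole distance
#'
#' A touch episode is a maximal contiguous run of frames whose whisker-pole
#' minimum distance is below `dist_threshold`. Dropped frames inside a
#' candidate run cannot be resolved: the run is split at them and a warning
#' is issued.
#'
#' @param series per-trial frame series data.frame.
#' @param dist_threshold positive distance threshold (same units as
#'   `pole_dist`).
#' @return data.frame with columns start_ms, end_ms (inclusive), direction
#'   (`NA`, set by [classify_touch_type()]) and is_first; zero rows if no
#'   touch.
#' @export
detect_touch_episodes <- function(series, dist_threshold) {
  check_frame_series(series)
  stopifnot(dist_threshold > 0)
  cand <- series$pole_dist < dist_threshold
  ok <- series$quality == "ok"
  if (any(cand & !ok))
    warning("dropped frame(s) inside candidate touch run; run split there")
  r <- rle(cand & ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  ep <- data.frame(start_ms = series$t_ms[starts[keep]],
                   end_ms = series$t_ms[ends[keep]],
                   direction = rep(NA_character_, sum(keep)),
                   is_first = rep(FALSE, sum(keep)),
                   stringsAsFactors = FALSE)
  if (nrow(ep)) ep$is_first[1] <- TRUE
  ep
}

#' Whisking phase from the analytic signal
#'
#' Band-passes the mean-removed whisker angle (zero-phase Butterworth) and
#' returns the phase of its analytic signal. Convention: phase in (-pi, 0) =
#' protraction (angle rising), elsewhere retraction; exact 0 and ±pi break
#' to retraction.
#'
#' @param angle numeric whisker-angle series (deg) at 1 kHz, gap-filled.
#' @param band_hz c(low, high) pass band in Hz.
#' @param fs sampling rate, Hz.
#' @return numeric phase per frame in (-pi, pi].
#' @export
whisking_phase <- function(angle, band_hz = c(4, 30), fs = 1000) {
  stopifnot(band_hz[1] > 0, band_hz[2] > band_hz[1], band_hz[2] < fs / 2)
  if (length(angle) < 3 * fs / band_hz[1])
    stop("series shorter than 3 cycles of the low band edge")
  Arg(analytic_signal(bandpass(angle, band_hz, fs)))
}

#' Whisking amplitude envelope
#'
#' Magnitude of the analytic signal of the band-passed whisker angle; for a
#' noiseless sinusoid of amplitude A the envelope is ~A away from the series
#' edges.
#'
#' @inheritParams whisking_phase
#' @return numeric amplitude per frame (deg).
#' @export
whisking_amplitude <- function(angle, band_hz = c(4, 30), fs = 1000) {
  stopifnot(band_hz[1] > 0, band_hz[2] > band_hz[1], band_hz[2] < fs / 2)
  if (length(angle) < 3 * fs / band_hz[1])
    stop("series shorter than 3 cycles of the low band edge")
  Mod(analytic_signal(bandpass(angle, band_hz, fs)))
}

phase_is_protraction <- function(phase) phase > -pi & phase < 0

#' Classify touch direction from whisking phase
#'
#' Labels each episode protraction or retraction from the whisking phase at
#' its start frame (first ok frame of the episode if the start frame is
#' dropped). The trial-level touch type is the direction of the first
#' episode, or "none" without episodes.
#'
#' @param episodes data.frame from [detect_touch_episodes()].
#' @param phase per-frame phase from [whisking_phase()].
#' @param series the frame series the phase was computed on (for t_ms and
#'   quality alignment).
#' @return list with `episodes` (directions filled) and `touch_type`
#'   (factor: none/protraction/retraction).
#' @export
classify_touch_type <- function(episodes, phase, series) {
  check_frame_series(series)
  tt <- "none"
  if (nrow(episodes)) {
    for (j in seq_len(nrow(episodes))) {
      idx <- which(series$t_ms >= episodes$start_ms[j] &
                     series$t_ms <= episodes$end_ms[j])
      okidx <- idx[series$quality[idx] == "ok"]
      use <- if (length(okidx)) okidx[1] else idx[1]
      episodes$direction[j] <- if (phase_is_protraction(phase[use]))
        "protraction" else "retraction"
    }
    tt <- episodes$direction[episodes$is_first][1]
  }
  list(episodes = episodes,
       touch_type = factor(tt, levels = c("none", "protraction",
                                          "retraction")))
}

#' dkappa95: peak bending change during the first touch
#'
#' Noise-robust scalar index of the largest curvature change during the
#' first touch episode. The baseline is the median curvature over the 6 ok
#' frames immediately before touch onset; per-frame dkappa is curvature
#' minus baseline; the statistic is whichever of the 5th and 95th
#' percentiles of dkappa (linear interpolation between order statistics) has
#' the greater absolute value, ties going to the 95th. Zero by definition
#' when the trial has no touch; `NA` (trial unusable) when all six baseline
#' frames are dropped.
#'
#' @param series per-trial frame series data.frame.
#' @param first_episode one-row data.frame (start_ms, end_ms) or `NULL` for
#'   a no-touch trial.
#' @return scalar curvature change (mm^-1), or `NA_real_` if unusable.
#' @export
delta_kappa_95 <- function(series, first_episode) {
  if (is.null(first_episode) || (is.data.frame(first_episode) &&
                                 nrow(first_episode) == 0))
    return(0)
  check_frame_series(series)
  s <- first_episode$start_ms[1]
  e <- first_episode$end_ms[1]
  stopifnot(s <= e, s >= series$t_ms[1], e <= series$t_ms[nrow(series)])
  base_idx <- which(series$t_ms >= s - 6 & series$t_ms <= s - 1 &
                      series$quality == "ok")
  if (length(base_idx) == 0) return(NA_real_)
  baseline <- stats::median(series$kappa_per_mm[base_idx])
  ep_idx <- which(series$t_ms >= s & series$t_ms <= e &
                    series$quality == "ok")
  if (length(ep_idx) == 0) return(NA_real_)
  dk <- series$kappa_per_mm[ep_idx] - baseline
  q <- stats::quantile(dk, c(0.05, 0.95), names = FALSE, type = 7)
  if (abs(q[2]) >= abs(q[1])) q[2] else q[1]
}

#' Extract all per-trial predictors from one frame series
#'
#' Runs gap filling, touch detection, phase estimation, direction
#' classification and dkappa95 for a single trial.
#'
#' @param series per-trial frame series data.frame.
#' @param dist_threshold touch distance threshold.
#' @param band_hz pass band for the whisking phase.
#' @return list: pat (0/1), touch_type (factor), dkappa95 (scalar or NA),
#'   episodes (directions filled), usable (logical).
#' @export
extract_trial_features <- function(series, dist_threshold = 0.5,
                                   band_hz = c(4, 30)) {
  series <- fill_isolated_gaps(series)
  ep <- detect_touch_episodes(series, dist_threshold)
  if (nrow(ep) == 0) {
    return(list(pat = 0L,
                touch_type = factor("none", levels = c("none", "protraction",
                                                       "retraction")),
                dkappa95 = 0, episodes = ep, usable = TRUE))
  }
  ph <- whisking_phase(series$angle_deg, band_hz)
  cl <- classify_touch_type(ep, ph, series)
  dk <- delta_kappa_95(series, cl$episodes[cl$episodes$is_first, ])
  list(pat = 1L, touch_type = cl$touch_type, dkappa95 = dk,
       episodes = cl$episodes, usable = !is.na(dk))
}

#' Build the trial-by-predictor table
#'
#' Combines the trial table and per-trial features into one row per trial:
#' PAT, touch type, dkappa95 and the previous trial's choice type (choice
#' crossed with correctness; `NA` on the first trial of each session), plus
#' the label vectors (pole location and mouse choice).
#'
#' @param trials trial table (session_id, trial_idx, pole_location, choice,
#'   correct).
#' @param frames long-format frame series for the same trials, or `NULL` if
#'   `features` is supplied.
#' @param features optional precomputed list of [extract_trial_features()]
#'   results in trial order.
#' @param dist_threshold,band_hz forwarded to [extract_trial_features()].
#' @return data.frame (class `predictor_table`) with predictor and label
#'   columns and an `episodes` attribute (per-trial episode tables).
#' @export
build_predictor_table <- function(trials, frames = NULL, features = NULL,
                                  dist_threshold = 0.5, band_hz = c(4, 30)) {
  need <- c("session_id", "trial_idx", "pole_location", "choice", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "))
  ord <- order(trials$session_id, trials$trial_idx)
  trials <- trials[ord, , drop = FALSE]
  n <- nrow(trials)
  if (is.null(features)) {
    if (is.null(frames)) stop("supply either frames or features")
    key_t <- paste(trials$session_id, trials$trial_idx)
    key_f <- paste(frames$session_id, frames$trial_idx)
    idx <- split(seq_len(nrow(frames)), factor(key_f, levels = key_t))
    if (any(lengths(idx) == 0))
      stop("frame series missing for some trials in the trial table")
    features <- lapply(idx, function(i)
      extract_trial_features(frames[i, , drop = FALSE], dist_threshold,
                             band_hz))
  }
  if (length(features) != n)
    stop("mismatched trial counts between trial table and features")
  pat <- vapply(features, function(f) f$pat, integer(1))
  tt <- vapply(features, function(f) as.character(f$touch_type),
               character(1))
  dk <- vapply(features, function(f) as.numeric(f$dkappa95), numeric(1))
  usable <- vapply(features, function(f) isTRUE(f$usable), logical(1))
  dk[pat == 0L] <- 0
  prev <- as.integer(choice_type(trials$choice, trials$correct))
  prev <- c(NA_integer_, prev[-n])
  first_of_session <- c(TRUE, diff(trials$session_id) != 0)
  prev[first_of_session] <- NA
  out <- data.frame(
    session_id = trials$session_id, trial_idx = trials$trial_idx,
    pole_location = as_location(trials$pole_location),
    choice = as_choice(trials$choice),
    correct = as.integer(trials$correct),
    pat = factor(pat, levels = c(0, 1)),
    touch_type = factor(tt, levels = c("none", "protraction", "retraction")),
    dkappa95 = dk,
    prev_choice_type = factor(CHOICE_TYPE_LEVELS[prev],
                              levels = CHOICE_TYPE_LEVELS),
    usable = usable)
  attr(out, "episodes") <- lapply(features, `[[`, "episodes")
  class(out) <- c("predictor_table", "data.frame")
  out
}
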