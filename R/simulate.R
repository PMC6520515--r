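# Synthetic-session generator: trial sequences, whisking kinematics, contact
# traces and a behavioural policy mixing sensory-guided and perseverative
# choices. Every stochastic function consumes the global RNG; callers seed.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic session generator.
#' Defaults emulate the task's reported structure: three pole locations
#' presented pseudorandomly with runs capped at three; touch probabilities
#' 0.87/0.93/0.46 for posterior/middle/anterior; posterior poles contacted
#' mostly during retraction and middle/anterior mostly during protraction;
#' per-(location, direction) Gaussian peak bending change (dkappa, mm^-1),
#' positive for protraction touches and negative for retraction touches.
#'
#' @param n_trials trials per session.
#' @param location_probs probabilities of posterior/middle/anterior poles
#'   (must sum to 1).
#' @param max_run maximum run length of identical pole locations.
#' @param trial_duration trial length in ms (frame rate is fixed at 1 kHz).
#' @param pole_onset time of pole presentation in ms.
#' @param whisk_freq whisking frequency, Hz.
#' @param amp_pre,amp_post whisking amplitude (deg) before/after pole onset;
#'   `amp_post > amp_pre >= 0`.
#' @param amp_ramp_ms duration of the linear amplitude ramp after pole onset.
#' @param setpoint whisking set point, deg (0 deg = anterior-posterior axis,
#'   nose to tail; protraction = increasing angle).
#' @param touch_prob named probabilities of at least one touch per location.
#' @param touch_dir_probs 2-column matrix (rows = locations) of
#'   P(protraction), P(retraction) for the first touch given touch.
#' @param dkappa_params data.frame with columns location, direction, mean, sd
#'   (mm^-1) for the peak curvature change of each touch.
#' @param touch_count_probs probabilities of 1, 2, ... touches given touch.
#' @param dir_persist probability that touch k+1 repeats the direction of
#'   touch k; recycled (defaults give high first/second and second/third
#'   direction agreement).
#' @param touch_dur_ms touch episode duration (ms, odd so the ramp peak sits
#'   on a frame).
#' @param baseline_dist,touch_dist whisker-pole minimum distance (mm) outside
#'   and inside touch episodes.
#' @param kappa_baseline intrinsic whisker curvature near the base, mm^-1.
#' @param noise_sd_angle,noise_sd_kappa white measurement noise SDs (deg,
#'   mm^-1).
#' @param drop_prob per-frame probability of a dropped (untracked) frame.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_trials = 179,
                       location_probs = c(1, 1, 1) / 3,
                       max_run = 3,
                       trial_duration = 2000,
                       pole_onset = 500,
                       whisk_freq = 12,
                       amp_pre = 2,
                       amp_post = 15,
                       amp_ramp_ms = 100,
                       setpoint = 100,
                       touch_prob = c(posterior = 0.87, middle = 0.93,
                                      anterior = 0.46),
                       touch_dir_probs = rbind(posterior = c(0.25, 0.75),
                                               middle = c(0.85, 0.15),
                                               anterior = c(0.80, 0.20)),
                       dkappa_params = default_dkappa_params(),
                       touch_count_probs = c(0.44, 0.25, 0.15, 0.16),
                       dir_persist = c(0.94, 0.98),
                       touch_dur_ms = 21,
                       baseline_dist = 2,
                       touch_dist = 0.1,
                       kappa_baseline = 0.03,
                       noise_sd_angle = 0.5,
                       noise_sd_kappa = 0.001,
                       drop_prob = 0) {
  cfg <- list(n_trials = as.integer(n_trials),
              location_probs = location_probs, max_run = max_run,
              frame_rate = 1000L,
              trial_duration = trial_duration, pole_onset = pole_onset,
              whisk_freq = whisk_freq, amp_pre = amp_pre,
              amp_post = amp_post, amp_ramp_ms = amp_ramp_ms,
              setpoint = setpoint, touch_prob = touch_prob,
              touch_dir_probs = touch_dir_probs,
              dkappa_params = dkappa_params,
              touch_count_probs = touch_count_probs,
              dir_persist = dir_persist, touch_dur_ms = touch_dur_ms,
              baseline_dist = baseline_dist, touch_dist = touch_dist,
              kappa_baseline = kappa_baseline,
              noise_sd_angle = noise_sd_angle,
              noise_sd_kappa = noise_sd_kappa, drop_prob = drop_prob)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_dkappa_params <- function() {
  data.frame(
    location  = rep(LOCATION_LEVELS, each = 2),
    direction = rep(c("protraction", "retraction"), 3),
    mean = c(0.012, -0.030, 0.030, -0.010, 0.005, -0.005),
    sd   = rep(0.003, 6),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_trials >= 1,
              length(location_probs) == 3,
              abs(sum(location_probs) - 1) < 1e-8,
              all(location_probs >= 0), all(location_probs <= 1),
              max_run >= 1,
              amp_post > amp_pre, amp_pre >= 0,
              trial_duration > pole_onset, pole_onset > 0,
              trial_duration %% 1 == 0,
              all(touch_prob >= 0), all(touch_prob <= 1),
              setequal(names(touch_prob), LOCATION_LEVELS),
              all(abs(rowSums(touch_dir_probs) - 1) < 1e-8),
              abs(sum(touch_count_probs) - 1) < 1e-8,
              touch_dur_ms %% 2 == 1,
              touch_dist < baseline_dist,
              noise_sd_angle >= 0, noise_sd_kappa >= 0,
              drop_prob >= 0, drop_prob < 1)
    half_ms <- 1000 / (2 * whisk_freq)
    if (touch_dur_ms > 0.8 * half_ms)
      stop("touch_dur_ms too long for the whisking half-cycle at whisk_freq")
  })
  invisible(cfg)
}

#' Behavioural policy mixing sensory and perseverative choices
#'
#' @param p_perseverate probability of copying the previous choice (lambda).
#' @param sensory_noise probability of a uniformly random choice on a
#'   sensory-guided trial (epsilon).
#' @param mapping named character vector, bijection pole location -> correct
#'   choice; default identity (choices are labelled by the location for which
#'   they are correct).
#' @return object of class `behavior_policy`.
#' @export
behavior_policy <- function(p_perseverate = 0.3, sensory_noise = 0.15,
                            mapping = stats::setNames(CHOICE_LEVELS,
                                                      LOCATION_LEVELS)) {
  stopifnot(p_perseverate >= 0, p_perseverate <= 1,
            sensory_noise >= 0, sensory_noise <= 1,
            setequal(names(mapping), LOCATION_LEVELS),
            setequal(unname(mapping), CHOICE_LEVELS))
  structure(list(p_perseverate = p_perseverate,
                 sensory_noise = sensory_noise, mapping = mapping),
            class = "behavior_policy")
}

#' Pseudorandom pole-location sequence with a run cap
#'
#' Samples locations i.i.d. from `location_probs`, resampling any draw that
#' would create a run of `max_run + 1` identical locations (the constrained
#' randomization used for trial sequencing).
#'
#' @param n_trials sequence length.
#' @param location_probs 3-vector of location probabilities.
#' @param max_run maximum run length.
#' @return factor of length `n_trials` with levels `LOCATION_LEVELS`.
#' @export
generate_pole_sequence <- function(n_trials, location_probs = c(1, 1, 1) / 3,
                                   max_run = 3) {
  stopifnot(n_trials >= 1, length(location_probs) == 3,
            abs(sum(location_probs) - 1) < 1e-8, all(location_probs >= 0),
            max_run >= 1)
  if (n_trials > max_run && sum(location_probs > 0) < 2)
    stop("run constraint unsatisfiable: only one location has ",
         "nonzero probability but max_run < n_trials")
  out <- character(n_trials)
  run_loc <- ""; run_len <- 0L
  for (i in seq_len(n_trials)) {
    for (try in seq_len(10000L)) {
      loc <- sample(LOCATION_LEVELS, 1L, prob = location_probs)
      if (!(loc == run_loc && run_len >= max_run)) break
      if (try == 10000L) stop("run constraint unsatisfiable")
    }
    if (loc == run_loc) run_len <- run_len + 1L else {
      run_loc <- loc; run_len <- 1L
    }
    out[i] <- loc
  }
  as_location(out)
}

#' Synthetic whisking angle trace
#'
#' Generates a 1 kHz whisker-angle series: a sinusoid around the set point
#' whose amplitude is `amp_pre` before pole onset and ramps linearly to
#' `amp_post` over `amp_ramp_ms` after onset, plus white noise. The random
#' initial whisk phase is attached as attribute `"phase0"` (the contact
#' generator uses it to place touches in the correct whisk half-cycle).
#'
#' @param config a [sim_config()].
#' @return numeric vector of `trial_duration` samples (degrees), with
#'   attribute `phase0`.
#' @export
synth_whisking_trace <- function(config) {
  n <- config$trial_duration
  t <- seq_len(n) - 1
  phase0 <- stats::runif(1, -pi, pi)
  amp <- ifelse(t < config$pole_onset, config$amp_pre,
                pmin(config$amp_pre +
                       (config$amp_post - config$amp_pre) *
                       (t - config$pole_onset) / config$amp_ramp_ms,
                     config$amp_post))
  theta <- config$setpoint +
    amp * cos(2 * pi * config$whisk_freq * t / 1000 + phase0)
  if (config$noise_sd_angle > 0)
    theta <- theta + stats::rnorm(n, 0, config$noise_sd_angle)
  attr(theta, "phase0") <- phase0
  theta
}

# dkappa ramp over an episode of length L: half-cosine rise over the first
# 40%, plateau at 1 over the central 20%, half-cosine fall over the last 40%.
# The plateau guarantees the episode's 95th-percentile curvature change
# equals the drawn peak exactly in noiseless data.
dkappa_ramp <- function(L) {
  x <- (seq_len(L) - 1) / (L - 1)
  y <- numeric(L)
  r <- x < 0.4
  f <- x > 0.6
  y[r] <- (1 - cos(pi * x[r] / 0.4)) / 2
  y[!r & !f] <- 1
  y[f] <- (1 - cos(pi * (1 - x[f]) / 0.4)) / 2
  y
}

#' Synthetic contact traces for one trial
#'
#' Given a whisking trace and the trial's pole location, draws whether the
#' trial has touches, how many, their directions (first per the location's
#' direction probabilities, later touches repeating the previous direction
#' with probability `dir_persist`), and places each touch in the matching
#' half (protraction = rising angle) of successive whisk cycles after pole
#' onset. Inside a touch the pole distance drops to `touch_dist` and the
#' curvature follows a rise/plateau/fall ramp to a Gaussian peak whose sign
#' follows the touch direction.
#'
#' @param angle series from [synth_whisking_trace()] (needs `phase0`).
#' @param pole_location one of `LOCATION_LEVELS`.
#' @param config a [sim_config()].
#' @return list with `pole_dist`, `kappa` (numeric series), `quality`
#'   (character, "ok"/"dropped"), `touches` (data.frame start_ms, end_ms,
#'   direction, peak), `first_touch_dir` ("protraction", "retraction" or
#'   "none").
#' @export
synth_contact <- function(angle, pole_location, config) {
  loc <- match.arg(as.character(pole_location), LOCATION_LEVELS)
  n <- length(angle)
  phase0 <- attr(angle, "phase0")
  stopifnot(!is.null(phase0))
  dist <- rep(config$baseline_dist, n)
  kappa <- rep(config$kappa_baseline, n)
  touches <- data.frame(start_ms = integer(), end_ms = integer(),
                        direction = character(), peak = numeric(),
                        stringsAsFactors = FALSE)
  if (stats::runif(1) < config$touch_prob[[loc]]) {
    n_touch <- sample.int(length(config$touch_count_probs), 1L,
                          prob = config$touch_count_probs)
    dirs <- character(n_touch)
    dirs[1] <- if (stats::runif(1) < config$touch_dir_probs[loc, 1])
      "protraction" else "retraction"
    if (n_touch > 1) {
      pp <- rep_len(config$dir_persist, n_touch - 1)
      for (k in 2:n_touch) {
        dirs[k] <- if (stats::runif(1) < pp[k - 1]) dirs[k - 1] else
          setdiff(c("protraction", "retraction"), dirs[k - 1])
      }
    }
    # cycle position u: angle ~ cos(2*pi*u); rising (protraction) half is
    # frac(u) in (0.5, 1), falling (retraction) half is (0, 0.5)
    t <- seq_len(n) - 1
    u <- config$whisk_freq * t / 1000 + phase0 / (2 * pi)
    t_min <- config$pole_onset + config$amp_ramp_ms + 20
    k0 <- ceiling(u[t_min + 1])
    cyc <- floor(u)
    frac <- u - cyc
    L <- config$touch_dur_ms
    placed <- 0L
    k <- k0
    while (placed < n_touch) {
      dir <- dirs[placed + 1L]
      half <- if (dir == "protraction") frac > 0.5 else frac <= 0.5 & frac > 0
      idx <- which(cyc == k & half)
      k <- k + 1L
      if (length(idx) < L) {
        if (length(idx) == 0 && k > max(cyc)) break  # out of room
        next
      }
      mid <- idx[ceiling(length(idx) / 2)]
      s <- mid - (L - 1L) %/% 2L
      e <- s + L - 1L
      if (s < 1L || e > n) next
      prm <- config$dkappa_params[config$dkappa_params$location == loc &
                                    config$dkappa_params$direction == dir, ]
      repeat {
        peak <- stats::rnorm(1, prm$mean, prm$sd)
        if ((dir == "protraction" && peak > 0) ||
            (dir == "retraction" && peak < 0)) break
      }
      dist[s:e] <- config$touch_dist
      kappa[s:e] <- kappa[s:e] + peak * dkappa_ramp(L)
      touches <- rbind(touches,
                       data.frame(start_ms = s - 1L, end_ms = e - 1L,
                                  direction = dir, peak = peak,
                                  stringsAsFactors = FALSE))
      placed <- placed + 1L
    }
  }
  if (config$noise_sd_kappa > 0)
    kappa <- kappa + stats::rnorm(n, 0, config$noise_sd_kappa)
  quality <- rep("ok", n)
  if (config$drop_prob > 0)
    quality[stats::runif(n) < config$drop_prob] <- "dropped"
  list(pole_dist = dist, kappa = kappa, quality = quality,
       touches = touches,
       first_touch_dir = if (nrow(touches)) touches$direction[1] else "none")
}

#' Draw one choice from the behavioural policy
#'
#' With probability `p_perseverate` the previous choice is copied; otherwise
#' the trial is sensory-guided: with probability `1 - sensory_noise` the
#' correct choice for the pole location, else a uniformly random choice. The
#' first trial (no previous choice) is forced onto the sensory branch.
#'
#' @param pole_location current trial's location.
#' @param previous_choice previous trial's choice, or `NULL`/`NA`.
#' @param policy a [behavior_policy()].
#' @return character choice label.
#' @export
generate_choice <- function(pole_location, previous_choice, policy) {
  loc <- as.character(pole_location)
  has_prev <- !is.null(previous_choice) && !is.na(previous_choice)
  if (has_prev && stats::runif(1) < policy$p_perseverate)
    return(as.character(previous_choice))
  if (stats::runif(1) < policy$sensory_noise)
    return(sample(CHOICE_LEVELS, 1L))
  unname(policy$mapping[[loc]])
}

#' Generate one synthetic session
#'
#' Composes the pole sequence, behavioural policy and (optionally) per-trial
#' frame series into a complete session. Fully reproducible from the RNG
#' state (`set.seed()` before calling).
#'
#' @param config a [sim_config()].
#' @param policy a [behavior_policy()].
#' @param session_id integer session identifier.
#' @param frames if `FALSE`, skip frame-series synthesis (trial table only;
#'   used for behaviour-only simulations).
#' @return list with `trials` (data.frame: session_id, trial_idx,
#'   pole_location, choice, correct, true_touch, true_first_touch_dir) and
#'   `frames` (long data.frame: session_id, trial_idx, t_ms, angle_deg,
#'   kappa_per_mm, pole_dist, quality; `NULL` when `frames = FALSE`), plus
#'   `truth` (per-trial list of ground-truth touch tables).
#' @export
generate_session <- function(config, policy = behavior_policy(),
                             session_id = 1L, frames = TRUE) {
  n <- config$n_trials
  locs <- generate_pole_sequence(n, config$location_probs, config$max_run)
  choices <- character(n)
  prev <- NA_character_
  for (i in seq_len(n)) {
    choices[i] <- generate_choice(locs[i], prev, policy)
    prev <- choices[i]
  }
  correct <- as.integer(choices == unname(policy$mapping[as.character(locs)]))
  trials <- data.frame(session_id = as.integer(session_id),
                       trial_idx = seq_len(n),
                       pole_location = as.character(locs),
                       choice = choices, correct = correct,
                       true_touch = NA_integer_,
                       true_first_touch_dir = NA_character_,
                       stringsAsFactors = FALSE)
  frames_df <- NULL
  truth <- vector("list", n)
  if (frames) {
    per_trial <- vector("list", n)
    for (i in seq_len(n)) {
      ang <- synth_whisking_trace(config)
      ct <- synth_contact(ang, locs[i], config)
      trials$true_touch[i] <- as.integer(nrow(ct$touches) > 0)
      trials$true_first_touch_dir[i] <- ct$first_touch_dir
      truth[[i]] <- ct$touches
      per_trial[[i]] <- data.frame(
        session_id = as.integer(session_id), trial_idx = i,
        t_ms = seq_len(config$trial_duration) - 1L,
        angle_deg = as.numeric(ang), kappa_per_mm = ct$kappa,
        pole_dist = ct$pole_dist, quality = ct$quality,
        stringsAsFactors = FALSE)
    }
    frames_df <- do.call(rbind, per_trial)
  }
  list(trials = trials, frames = frames_df, truth = truth)
}

#' Generate a multi-session experiment
#'
#' @param n_sessions number of sessions.
#' @param config,policy as in [generate_session()].
#' @param frames generate frame series?
#' @return list with pooled `trials`, `frames` and per-trial `truth`.
#' @export
generate_experiment <- function(n_sessions, config,
                                policy = behavior_policy(), frames = TRUE) {
  out <- lapply(seq_len(n_sessions), function(s)
    generate_session(config, policy, session_id = s, frames = frames))
  list(trials = do.call(rbind, lapply(out, `[[`, "trials")),
       frames = if (frames) do.call(rbind, lapply(out, `[[`, "frames")),
       truth = do.call(c, lapply(out, `[[`, "truth")))
}
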