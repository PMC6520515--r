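# Feature extraction: gap filling, touch-episode segmentation, whisking
# phase/amplitude, touch-type classification and dkappa95.

test_that("isolated dropped frames are interpolated, runs are left alone", {
  s <- make_series(3, kappa = c(1, 99, 3), angle = c(10, 99, 30),
                   quality = c("ok", "dropped", "ok"))
  f <- fill_isolated_gaps(s)
  expect_equal(f$kappa_per_mm[2], 2)
  expect_equal(f$angle_deg[2], 20)
  expect_equal(f$quality[2], "ok")

  s2 <- make_series(10)
  expect_identical(fill_isolated_gaps(s2), s2)

  s3 <- make_series(4, quality = c("ok", "dropped", "dropped", "ok"))
  f3 <- fill_isolated_gaps(s3)
  expect_equal(f3$quality, c("ok", "dropped", "dropped", "ok"))
})

test_that("touch episodes are maximal sub-threshold runs in time order", {
  s <- make_series(300)
  expect_equal(nrow(detect_touch_episodes(s, 0.5)), 0)

  s$pole_dist[101:121] <- 0.1
  s$pole_dist[201:206] <- 0.1
  ep <- detect_touch_episodes(s, 0.5)
  expect_equal(ep$start_ms, c(100, 200))
  expect_equal(ep$end_ms, c(120, 205))
  expect_equal(ep$is_first, c(TRUE, FALSE))

  # dropped frame inside a candidate run splits it, with a warning
  s$quality[110] <- "dropped"
  expect_warning(ep2 <- detect_touch_episodes(s, 0.5), "dropped")
  expect_equal(ep2$start_ms, c(100, 110, 200))
  expect_equal(ep2$end_ms, c(108, 120, 205))

  # invariant to monotone rescaling that preserves the crossing set
  s4 <- make_series(300); s4$pole_dist[101:121] <- 0.1
  ref <- detect_touch_episodes(s4, 0.5)
  s4b <- s4; s4b$pole_dist <- s4$pole_dist^2 * 10
  expect_equal(detect_touch_episodes(s4b, 0.5^2 * 10), ref)
})

test_that("whisking phase follows the analytic-signal conventions", {
  t <- 0:2999
  ang <- 90 + 10 * cos(2 * pi * 10 * t / 1000)
  ph <- whisking_phase(ang, c(4, 30))
  mid <- 500:2500
  # unwrapped phase advances 2*pi per 100 ms cycle
  dph <- diff(ph[mid]); dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
  expect_equal(mean(dph) * 100, 2 * pi, tolerance = 1e-3)
  # rising zero crossing of the angle has phase -pi/2
  rising0 <- which(diff(sign(ang - 90)) > 0 & seq_along(ang)[-1] %in% mid)
  expect_true(all(abs(ph[rising0 + 1] + pi / 2) < 0.1))
  expect_error(whisking_phase(ang[1:100], c(4, 30)), "3 cycles")
})

test_that("phase halves agree with finite-difference angular velocity", {
  set.seed(8)
  cfg <- sim_config(noise_sd_angle = 0.5)
  th <- synth_whisking_trace(cfg)
  ph <- whisking_phase(as.numeric(th))
  amp <- whisking_amplitude(as.numeric(th))
  sm <- stats::filter(as.numeric(th), rep(1 / 9, 9))  # denoise for velocity
  vel <- c(NA, diff(sm))
  use <- which(!is.na(vel) & abs(vel) > 0.1 & amp > 2)
  use <- use[use > cfg$pole_onset + 200 & use < cfg$trial_duration - 100]
  agree <- (vel[use] > 0) == (ph[use] > -pi & ph[use] < 0)
  expect_gt(mean(agree), 0.99)
})

test_that("whisking amplitude recovers the envelope", {
  t <- 0:1999
  ang <- 100 + 15 * cos(2 * pi * 10 * t / 1000 + 0.7)
  env <- whisking_amplitude(ang, c(4, 30))
  core <- 200:1800
  expect_true(all(abs(env[core] - 15) / 15 < 0.05))

  flat <- whisking_amplitude(rep(100, 2000) + 0, c(4, 30))
  expect_true(all(abs(flat) < 1e-6))

  set.seed(9)
  cfg <- quiet_config(amp_pre = 2, amp_post = 15)
  th <- as.numeric(synth_whisking_trace(cfg))
  env2 <- whisking_amplitude(th)
  post <- (cfg$pole_onset + cfg$amp_ramp_ms):(cfg$pole_onset + cfg$amp_ramp_ms + 200)
  pre <- (cfg$pole_onset - 220):(cfg$pole_onset - 20)
  expect_gt(mean(env2[post]), mean(env2[pre]))
  # envelope recovers the configured post-onset amplitude within 10%
  expect_lt(abs(mean(env2[post]) - cfg$amp_post) / cfg$amp_post, 0.1)
})

test_that("touch type comes from the phase at episode start", {
  s <- make_series(2000)
  ph <- rep(0.5, 2000)           # retraction half
  cl <- classify_touch_type(detect_touch_episodes(s, 0.5), ph, s)
  expect_equal(as.character(cl$touch_type), "none")

  t <- 0:1999
  s$angle_deg <- 100 + 10 * cos(2 * pi * 10 * t / 1000)
  ph <- whisking_phase(s$angle_deg)
  # rising segment of cycle 6: angle minimum near t = 550, rising until 600
  s$pole_dist[561:581] <- 0.1
  ep <- detect_touch_episodes(s, 0.5)
  cl <- classify_touch_type(ep, ph, s)
  expect_equal(as.character(cl$touch_type), "protraction")
  expect_equal(cl$episodes$direction[1], "protraction")

  # dropped start frame: direction read from first ok frame of the episode
  s$quality[561] <- "dropped"
  cl2 <- classify_touch_type(ep, ph, s)   # same episode, start now dropped
  expect_equal(as.character(cl2$touch_type), "protraction")
})

test_that("dkappa95 matches its definition on hand-built data", {
  # no touch: zero by definition
  expect_equal(delta_kappa_95(make_series(50), NULL), 0)
  expect_equal(delta_kappa_95(make_series(50), data.frame()[0, ]), 0)

  # constant curvature equal to baseline: zero
  s <- make_series(60, kappa = 0.002)
  s$pole_dist[31:40] <- 0.1
  expect_equal(delta_kappa_95(s, data.frame(start_ms = 30, end_ms = 39)), 0)

  # worked example: episode dkappa {-0.004, 0.001, 0.010, 0.030, 0.015,
  # -0.002} over a 0.002 baseline; 95th percentile (interpolated) wins
  dk <- c(-0.004, 0.001, 0.010, 0.030, 0.015, -0.002)
  s2 <- make_series(30, kappa = 0.002)
  s2$kappa_per_mm[21:26] <- 0.002 + dk
  ep <- data.frame(start_ms = 20, end_ms = 25)
  got <- delta_kappa_95(s2, ep)
  expect_equal(got, oracle_percentile(dk, 0.95), tolerance = 1e-15)
  expect_equal(got, 0.02625, tolerance = 1e-12)

  # invariant to adding a constant to the whole curvature series
  s3 <- s2; s3$kappa_per_mm <- s3$kappa_per_mm + 5
  expect_equal(delta_kappa_95(s3, ep), got, tolerance = 1e-12)

  # all six baseline frames dropped: trial unusable
  s4 <- s2; s4$quality[15:20] <- "dropped"
  expect_true(is.na(delta_kappa_95(s4, ep)))
})

test_that("predictor table enforces the pat/touch/dkappa invariant chain", {
  set.seed(10)
  cfg <- sim_config(n_trials = 60)
  s <- generate_session(cfg, behavior_policy(), frames = TRUE)
  pt <- build_predictor_table(s$trials, s$frames)
  no_touch <- pt$pat == "0"
  expect_true(all(pt$touch_type[no_touch] == "none"))
  expect_true(all(pt$dkappa95[no_touch] == 0))
  expect_true(all(pt$touch_type[!no_touch] != "none"))
  # previous-choice predictor undefined exactly on the session's first trial
  expect_equal(which(is.na(pt$prev_choice_type)), 1L)
  expect_equal(nrow(pt), 60)

  # fully perseverative mouse: previous-choice column constant in its
  # choice component after the first transition
  set.seed(11)
  s1 <- generate_session(sim_config(n_trials = 40),
                         behavior_policy(1, 0), frames = FALSE)
  feats <- replicate(40, list(pat = 0L,
                              touch_type = factor("none",
                                                  c("none", "protraction",
                                                    "retraction")),
                              dkappa95 = 0, episodes = NULL, usable = TRUE),
                     simplify = FALSE)
  pt1 <- build_predictor_table(s1$trials, features = feats)
  prev_choice <- sub("_(correct|error)$", "",
                     as.character(pt1$prev_choice_type[-1]))
  expect_equal(length(unique(prev_choice)), 1L)

  expect_error(build_predictor_table(s1$trials, features = feats[1:10]),
               "mismatch")
  expect_error(build_predictor_table(s1$trials[, 1:3], features = feats),
               "missing column")
})
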