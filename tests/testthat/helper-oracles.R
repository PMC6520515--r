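# Independent oracles and small fixture builders shared across tests.
# Oracles are written from first principles (linear-domain arithmetic,
# manual interpolation) so they stay independent of the package internals
# they check.

# Percentile with linear interpolation between order statistics
# (h = (n-1)p + 1 convention), written without stats::quantile.
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# dkappa95 recomputed from scratch: median-of-6-pre-frames baseline,
# 5th/95th percentile of baseline-subtracted curvature over the episode,
# larger absolute value wins, ties to the 95th.
oracle_dk95 <- function(kappa, t_ms, quality, start_ms, end_ms) {
  pre <- which(t_ms >= start_ms - 6 & t_ms < start_ms & quality == "ok")
  base <- median(kappa[pre])
  ep <- which(t_ms >= start_ms & t_ms <= end_ms & quality == "ok")
  dk <- kappa[ep] - base
  q5 <- oracle_percentile(dk, 0.05)
  q95 <- oracle_percentile(dk, 0.95)
  if (abs(q95) >= abs(q5)) q95 else q5
}

# Brute-force MAP posterior enumeration for all-categorical predictors:
# linear-domain product of training relative frequencies with a floor for
# zero/unseen categories, argmax with ties to the earlier class level.
oracle_nb_predict <- function(train_x, train_y, test_x, floor = 1e-9) {
  classes <- levels(train_y)
  priors <- sapply(classes, function(k) mean(train_y == k))
  preds <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    post <- numeric(length(classes))
    for (ki in seq_along(classes)) {
      k <- classes[ki]
      p <- priors[ki]
      for (j in seq_along(test_x)) {
        nk <- sum(train_y == k)
        pj <- sum(train_x[train_y == k, j] == test_x[i, j]) / nk
        if (pj < floor) pj <- floor
        p <- p * pj
      }
      post[ki] <- p
    }
    # ties (including exact rational ties computed with different
    # roundings) go to the earlier class in level order
    preds[i] <- classes[which(post >= max(post) * (1 - 1e-9))[1]]
  }
  factor(preds, levels = classes)
}

# Moments of a normal truncated to the sign of its mean (the generator
# resamples wrong-signed bending peaks).
oracle_truncated_moments <- function(mu, sigma) {
  pos <- mu > 0
  m <- abs(mu)
  a <- -m / sigma
  lam <- dnorm(a) / (1 - pnorm(a))
  mean_t <- m + sigma * lam
  var_t <- sigma^2 * (1 + a * lam - lam^2)
  list(mean = if (pos) mean_t else -mean_t, sd = sqrt(var_t))
}

# Frame-series builder for hand-constructed trials.
make_series <- function(n, angle = 0, kappa = 0, dist = 2,
                        quality = "ok") {
  data.frame(t_ms = seq_len(n) - 1L,
             angle_deg = rep_len(angle, n),
             kappa_per_mm = rep_len(kappa, n),
             pole_dist = rep_len(dist, n),
             quality = rep_len(quality, n),
             stringsAsFactors = FALSE)
}

# Noise-free simulation config scaled down for unit tests.
quiet_config <- function(...) {
  sim_config(noise_sd_angle = 0, noise_sd_kappa = 0, ...)
}

# Fake session summary for learning/asymptote tests.
fake_summary <- function(performance, above_chance) {
  structure(list(performance = performance, per_location = rep(NA_real_, 3),
                 chance_mean = 1 / 3, chance_ci = c(0.25, 0.42),
                 above_chance = above_chance, n_trials = 100L),
            class = "session_summary")
}
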