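# MAP naive-Bayes classifier: fitting, prediction, cross-validation,
# metrics and shuffle-based chance.

test_that("fitted priors and conditionals equal hand-computed frequencies", {
  y <- factor(c("A", "A", "A", "B", "B", "B"))
  x <- data.frame(touch = factor(c("p", "p", "n", "n", "n", "p")))
  fit <- nb_map(x, y)
  expect_equal(unname(fit$priors), c(0.5, 0.5))
  tab <- fit$conditionals$touch$table
  expect_equal(tab["p", "A"], 2 / 3)
  expect_equal(tab["n", "A"], 1 / 3)
  expect_equal(tab["p", "B"], 1 / 3)
  expect_equal(tab["n", "B"], 2 / 3)

  # a predictor identical to the class gives identity-like tables
  fit2 <- nb_map(data.frame(lab = y), y)
  expect_equal(fit2$conditionals$lab$table["A", "A"], 1)
  expect_equal(fit2$conditionals$lab$table["B", "A"], 0)

  expect_error(nb_map(x, factor(c("A", "A", "A", "A", "A", "A"),
                                levels = c("A", "B"))), "absent")
})

test_that("posteriors follow Bayes' rule on a worked two-class example", {
  # priors (.5, .5); P(x=1|y1) = .9, P(x=1|y2) = .2; observe x = 1
  # posterior = (.45, .10)/.55 = (0.8181..., 0.1818...)
  x <- data.frame(v = factor(c(rep(1, 9), 0, rep(1, 2), rep(0, 8)),
                             levels = c(0, 1)))
  y <- factor(rep(c("y1", "y2"), each = 10))
  fit <- nb_map(x, y)
  post <- predict(fit, data.frame(v = factor(1, levels = c(0, 1))),
                  type = "posterior")
  expect_equal(as.numeric(post), c(9 / 11, 2 / 11), tolerance = 1e-12)
  # posterior rows always normalise to one
  expect_equal(rowSums(post), 1, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("uniform conditionals reduce prediction to the prior argmax", {
  set.seed(20)
  y <- factor(rep(c("a", "b", "c"), times = c(6, 10, 4)))
  x <- data.frame(u = factor(rep(c("l", "r"), 10)))
  fit <- nb_map(x, y)
  fit$conditionals$u$table[] <- 0.5
  pred <- predict(fit, x)
  expect_true(all(pred == "b"))
})

test_that("predictions agree with brute-force posterior enumeration", {
  set.seed(21)
  for (rep in 1:60) {
    R <- sample(1:3, 1)
    L <- sample(2:3, 1)
    T_ <- sample(5:30, 1)
    y <- factor(sample(LOCATION_LEVELS[1:sample(2:3, 1)], T_, replace = TRUE))
    if (any(table(y) == 0)) next
    x <- as.data.frame(lapply(seq_len(R), function(j)
      factor(sample(letters[1:L], T_, replace = TRUE),
             levels = letters[1:L])))
    names(x) <- paste0("x", seq_len(R))
    fit <- nb_map(x, y)
    expect_identical(predict(fit, x), oracle_nb_predict(x, y, x))
    # unseen-level handling: a test row with a level absent from training
    x_new <- x[1, , drop = FALSE]
    expect_identical(predict(fit, x_new), oracle_nb_predict(x, y, x_new))
  }
})

test_that("MAP fit agrees with an independent naive-Bayes implementation", {
  skip_if_not_installed("e1071")
  set.seed(22)
  n <- 300
  y <- factor(sample(c("p", "m", "a"), n, replace = TRUE,
                     prob = c(.4, .35, .25)))
  x <- data.frame(
    tt = factor(sample(c("none", "pro", "ret"), n, TRUE,
                       prob = c(.3, .4, .3))),
    dk = rnorm(n, as.numeric(y) / 50, 0.01))
  fit <- nb_map(x, y)
  ref <- e1071::naiveBayes(x, y)
  expect_equal(unname(fit$priors), as.numeric(ref$apriori / n))
  expect_equal(unclass(fit$conditionals$tt$table),
               unclass(t(ref$tables$tt)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.numeric(fit$conditionals$dk$mean),
               as.numeric(ref$tables$dk[, 1]), tolerance = 1e-12)
  agree <- mean(predict(fit, x) == predict(ref, x))
  expect_gt(agree, 0.98)
})

test_that("zero within-class variance triggers the variance floor", {
  y <- factor(rep(c("A", "B"), each = 5))
  x <- data.frame(v = c(rep(1, 5), rnorm(5)))
  expect_message(fit <- nb_map(x, y), "variance floor")
  expect_gte(min(fit$conditionals$v$sd), 1e-6)
})

test_that("cross-validation predicts every trial once, deterministically", {
  set.seed(23)
  n <- 60
  y <- factor(sample(LOCATION_LEVELS, n, replace = TRUE))
  x <- data.frame(v = factor(as.character(y)))  # perfectly separable
  cv <- crossval_predict(x, y, k_folds = 10)
  expect_equal(classifier_performance(cv$predicted, y), 1)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_true(all(abs(table(cv$folds) - 6) <= 1))
  expect_false(anyNA(cv$predicted))
  expect_equal(rowSums(cv$posterior), rep(1, n), tolerance = 1e-9)

  # leave-one-out limit
  cv_loo <- crossval_predict(x, y, k_folds = n)
  expect_equal(classifier_performance(cv_loo$predicted, y), 1)

  set.seed(99); a <- crossval_predict(x, y, 10)
  set.seed(99); b <- crossval_predict(x, y, 10)
  expect_identical(a, b)
})

test_that("performance and consistency metrics count agreements", {
  p <- factor(c("posterior", "middle", "anterior", "middle"))
  t <- factor(c("posterior", "middle", "middle", "anterior"))
  expect_equal(classifier_performance(p, p), 1)
  expect_equal(classifier_performance(p, rev(p)), 0)
  expect_equal(classifier_performance(p, t), 0.5)
  expect_error(classifier_performance(factor(), factor()), "empty")

  # hand-counted consistency through the location -> choice mapping
  pred_loc <- c("posterior", "posterior", "middle", "anterior", "middle",
                "anterior")
  mouse <- c("posterior", "middle", "middle", "anterior", "anterior",
             "posterior")
  expect_equal(choice_consistency(pred_loc, mouse), 3 / 6)

  # permutation invariance under consistent reordering
  set.seed(24)
  i <- sample(6)
  expect_equal(choice_consistency(pred_loc[i], mouse[i]), 3 / 6)
})

test_that("shuffle chance sits at symmetry level and flags real signal", {
  set.seed(25)
  n <- 300
  y <- factor(rep(LOCATION_LEVELS, each = n / 3))
  x_noise <- data.frame(u = factor(sample(c("l", "r"), n, TRUE)))
  null <- shuffle_chance(x_noise, y, iters = 30)
  expect_lt(abs(null$mean - 1 / 3), 0.05)
  expect_lte(null$ci[1], null$ci[2])
  expect_length(null$values, 30)

  # informative predictor: observed metric above the null's upper bound
  x_sig <- data.frame(v = factor(as.character(y)))
  cv <- crossval_predict(x_sig, y, 10)
  obs <- classifier_performance(cv$predicted, y)
  null_sig <- shuffle_chance(x_sig, y, iters = 30)
  expect_gt(obs, null_sig$ci[2])

  set.seed(77); a <- shuffle_chance(x_noise, y, iters = 10)
  set.seed(77); b <- shuffle_chance(x_noise, y, iters = 10)
  expect_identical(a, b)
})

test_that("mouse-choice prediction mirrors the label structure", {
  # fully perseverative synthetic mouse: previous choice predicts perfectly
  set.seed(26)
  s <- generate_session(sim_config(n_trials = 120), behavior_policy(1, 0),
                        frames = FALSE)
  prev <- factor(c(NA, s$trials$choice[-120]), levels = CHOICE_LEVELS)
  keep <- !is.na(prev)
  cv <- predict_mouse_choice(data.frame(prev = prev[keep]),
                             s$trials$choice[keep], k_folds = 10)
  expect_equal(classifier_performance(cv$predicted,
                                      s$trials$choice[keep]), 1)

  # i.i.d. uniform choices: previous choice carries no information
  set.seed(27)
  ch <- factor(sample(CHOICE_LEVELS, 1500, replace = TRUE),
               levels = CHOICE_LEVELS)
  prev <- ch[-1500]; cur <- ch[-1]
  cv0 <- predict_mouse_choice(data.frame(prev = prev), cur, k_folds = 10)
  expect_lt(abs(classifier_performance(cv0$predicted, cur) - 1 / 3), 0.05)
})

test_that("Gaussian conditionals recover class parameters at n = 1000", {
  set.seed(28)
  mus <- c(posterior = 0.012, middle = 0.030, anterior = 0.005)
  sd0 <- 0.003
  n <- 1000
  y <- factor(rep(LOCATION_LEVELS, each = n), levels = LOCATION_LEVELS)
  x <- data.frame(dk = rnorm(3 * n, rep(mus, each = n), sd0))
  fit <- nb_map(x, y)
  se_mean <- sd0 / sqrt(n)
  se_sd <- sd0 / sqrt(2 * n)
  for (k in LOCATION_LEVELS) {
    expect_lt(abs(fit$conditionals$dk$mean[[k]] - mus[[k]]), 3 * se_mean)
    expect_lt(abs(fit$conditionals$dk$sd[[k]] - sd0), 3 * se_sd)
  }
})
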