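test_that("lick statistics summarise medians, no-lick rate and CDF", {
  out <- lick_stats(toy_trials(rep(1, 20)))
  expect_equal(out$median_lick_time, 1)
  expect_equal(out$no_lick_rate, 0)
  expect_equal(max(out$cdf[[1]]$F), 1)

  out2 <- lick_stats(toy_trials(c(rep(1.2, 10), rep(NA, 10))))
  expect_equal(out2$no_lick_rate, 0.5)

  # perturbation comparisons keep only licks after the stimulation onset
  out3 <- lick_stats(toy_trials(c(0.3, 0.5, 1.0, 1.4)), after_onset = 0.6)
  expect_equal(out3$n, 2L)
  expect_equal(out3$median_lick_time, 1.2)

  empty <- lick_stats(toy_trials(numeric(0)))
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$median_lick_time))
})

test_that("hierarchical bootstrap has correct degenerate and Gaussian behaviour", {
  # one animal, one session, constant statistic: zero-width CI
  d <- tibble::tibble(animal = "a", session = "s", y = rep(3, 20))
  hb <- hierarchical_bootstrap(d, function(df) mean(df$y), iters = 50)
  expect_equal(hb$mean, 3)
  expect_equal(hb$ci_low, hb$ci_high)
  expect_lte(hb$ci_low, hb$ci_high)

  # mean of 100 iid N(0,1): CI width ~ 2 * 1.96 / 10
  set.seed(42)
  d2 <- tibble::tibble(animal = "a", session = "s", y = rnorm(100))
  hb2 <- hierarchical_bootstrap(d2, function(df) mean(df$y), iters = 500)
  expect_lt(abs((hb2$ci_high - hb2$ci_low) - 2 * 1.96 / 10),
            0.3 * 2 * 1.96 / 10)

  expect_error(
    hierarchical_bootstrap(tibble::tibble(animal = character(0),
                                          session = character(0)),
                           function(df) 0),
    "animal")
})

test_that("trial-order permutation leaves the bootstrap distribution invariant", {
  set.seed(1)
  d <- tibble::tibble(animal = "a", session = "s", y = rnorm(60))
  set.seed(99)
  hb1 <- hierarchical_bootstrap(d, function(df) mean(df$y), iters = 400)
  set.seed(99)
  hb2 <- hierarchical_bootstrap(d[sample.int(60), ],
                                function(df) mean(df$y), iters = 400)
  # exchangeable rows: the two bootstrap distributions agree in law
  s1 <- attr(hb1, "samples")
  s2 <- attr(hb2, "samples")
  expect_lt(abs(mean(s1) - mean(s2)), 4 * sd(s1) / sqrt(length(s1)))
  expect_lt(abs(sd(s1) - sd(s2)) / sd(s1), 0.25)
})

test_that("history regression finds no structure in i.i.d. lick times", {
  bh <- make_behavior(
    behavior_gen_config(n_trials = 2200, bT = c(0, 0), bTR = c(0, 0),
                        b0 = 1.3), seed = 7)
  set.seed(1)
  fit <- fit_history_regression(bh$session$trials)
  expect_lte(fit$mad_explained, 0.05)
  expect_equal(nrow(fit$cv_table), 42L)
})

test_that("history regression explains a noiseless AR(1) exactly", {
  y <- numeric(300)
  y[1] <- 1.5
  for (i in 2:300) y[i] <- 0.4 + 0.7 * y[i - 1]
  tr <- toy_trials(y, delay = 0)    # all rewarded, T regressor carries it all
  set.seed(2)
  fit <- fit_history_regression(tr)
  expect_gt(fit$mad_explained, 0.999)
})

test_that("history regression recovers planted coefficients within the bootstrap CI", {
  bh <- make_behavior(behavior_gen_config(n_trials = 600), seed = 1001)
  set.seed(3)
  fit <- fit_history_regression(bh$session$trials, max_lag = 2,
                                families = list(c("T", "TR")))
  est <- tidy(fit)
  bT <- est$estimate[est$term == "T_1"]
  bTR <- est$estimate[est$term == "TR_1"]
  expect_gt(bT, 0)
  expect_lt(bTR, 0)
  # nonparametric bootstrap of the refit coefficients
  dat <- fit$design[fit$design$usable &
                      complete.cases(fit$design[c("T_1", "TR_1")]), ]
  bs <- replicate(400, {
    idx <- sample.int(nrow(dat), nrow(dat), replace = TRUE)
    coef(lm(y ~ T_1 + TR_1, data = dat[idx, ]))[c("T_1", "TR_1")]
  })
  ci <- apply(bs, 1, quantile, c(0.025, 0.975))
  expect_gte(0.3, ci[1, "T_1"])
  expect_lte(0.3, ci[2, "T_1"])
  expect_gte(-0.2, ci[1, "TR_1"])
  expect_lte(-0.2, ci[2, "TR_1"])
})

test_that("lagged regressors carry over no-lick and no-cue trials", {
  licks <- c(1.0, NA, 1.4, 1.6)
  d <- build_history_design(fill_trial_defaults(toy_trials(licks)),
                            max_lag = 2, na_action = "carry")
  # trial 3 follows the no-lick trial 2: lag-1 is trial 1's lick
  expect_equal(d$T_1[3], 1.0)
  expect_equal(d$T_1[4], 1.4)
  expect_equal(d$T_2[4], 1.0)
  d2 <- build_history_design(fill_trial_defaults(toy_trials(licks)),
                             max_lag = 1, na_action = "drop")
  expect_true(is.na(d2$T_1[3]))
})

test_that("hazard of exponential lick times is flat", {
  set.seed(11)
  lt <- rexp(10000, rate = 1)
  hc <- hazard_rate(lt, t_max = 6)
  # memoryless: h = lambda * binwidth over the first 80% of the mass
  t80 <- hc$t[which(hc$F >= 0.8)[1]]
  sel <- hc$t < t80
  # flat on average; individual 20-ms bins carry Monte-Carlo noise
  expect_lt(mean(abs(hc$h[sel] / (1 * 0.02) - 1)), 0.10)
  expect_lt(max(abs(hc$h[sel] / (1 * 0.02) - 1)), 0.30)
})

test_that("hazard matches the uniform closed form and degenerate cases", {
  set.seed(12)
  lt <- runif(50000)
  hc <- hazard_rate(lt, t_max = 1.2)
  sel <- hc$t > 0.05 & hc$t < 0.8
  expected <- 0.02 / (1 - (hc$t[sel] - 0.01))   # binwidth / (1 - t_binstart)
  expect_lt(max(abs(hc$h_raw[sel] / expected - 1)), 0.15)

  # all licks at exactly 1.0 s: zero hazard before
  hc2 <- hazard_rate(rep(1.0, 100), t_max = 2)
  expect_true(all(hc2$h_raw[hc2$t < 0.95] == 0))

  expect_error(hazard_rate(rep(NA_real_, 10)), "censored")
})

test_that("the discrete hazard reconstructs the survivor function", {
  set.seed(13)
  lt <- c(rinvgauss(4000, 1.3, 12), rep(NA, 400))
  hc <- hazard_rate(lt)
  surv <- cumprod(1 - ifelse(is.na(hc$h_raw), 0, hc$h_raw))
  expect_equal(surv, 1 - hc$F, tolerance = 1e-12)
})

test_that("sigmoid hazard shift recovers a constructed translation", {
  set.seed(14)
  lt <- rinvgauss(20000, 1.3, 12)
  h1 <- hazard_rate(lt)
  h2 <- hazard_rate(lt + 0.30)
  out <- hazard_shift(h1, h1)
  expect_equal(out$shift, 0, tolerance = 1e-6)
  out2 <- hazard_shift(h1, h2)
  expect_equal(out2$shift, 0.30, tolerance = 0.021)  # within one 20-ms bin
})

test_that("hierarchical bootstrap p-values are super-uniform under the null", {
  set.seed(15)
  n_rep <- 150
  rejections <- vapply(seq_len(n_rep), function(i) {
    d <- tibble::tibble(animal = rep(c("a", "b", "c"), each = 20),
                        session = rep(rep(c("s1", "s2"), each = 10), 3),
                        y = rnorm(60))
    hb <- hierarchical_bootstrap(d, function(df) mean(df$y), iters = 200,
                                 null_value = 0, alternative = "greater")
    hb$p_value <= 0.05
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(rejections), 0.05 + 2 * mc_se)
})
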