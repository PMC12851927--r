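test_that("a single ramping unit yields the trivial ramp mode", {
  n <- 40
  set.seed(51)
  licks <- runif(n, 1.2, 1.5)
  trials <- fill_trial_defaults(toy_trials(licks))
  spikes <- deterministic_spikes(trials, "u1", function(t) 5 + 15 * t,
                                 t_max = 1.6)
  ses <- toy_session(licks, spikes = spikes)
  ws <- capture_warnings(ms <- define_modes(ses))
  expect_true(all(grepl("degenerate", ws)))   # middle/cue/execution collapse
  expect_equal(unname(ms$vectors[, "ramp"]), 1)
  expect_true(anyNA(ms$vectors[, "middle"]))
})

test_that("mode vectors are unit norm with the stated orthogonalization", {
  fx <- fix_mixed()
  ms <- define_modes(fx$session)
  V <- ms$vectors
  expect_equal(unname(colSums(V^2)), rep(1, 4), tolerance = 1e-12)
  expect_lt(abs(sum(V[, "middle"] * V[, "ramp"])), 1e-10)
  expect_lt(abs(sum(V[, "cue"] * V[, "ramp"])), 1e-10)
  expect_lt(abs(sum(V[, "cue"] * V[, "middle"])), 1e-10)
  expect_lt(abs(sum(V[, "execution"] * V[, "ramp"])), 1e-10)
})

test_that("mode definition is equivariant to unit reordering", {
  fx <- fix_mixed()
  wm <- mode_window_means(fx$session)
  set.seed(52)
  perm <- sample.int(nrow(wm))
  m1 <- define_modes(wm)
  m2 <- define_modes(wm[perm, ])
  expect_equal(unname(m2$vectors), unname(m1$vectors[perm, ]))
})

test_that("trial-history mode recovers the planted tonic coefficients", {
  fx <- fix_history()
  ses <- fx$session
  set.seed(53)
  fit <- fit_history_regression(ses$trials, max_lag = 2,
                                families = list(c("T", "TR")))
  thm <- define_trial_history_mode(ses, predict(fit))
  truth <- fx$ground_truth$units$history_coef
  expect_gt(cor(thm$loadings, truth), 0.8)
  expect_equal(sum(thm$vector^2), 1, tolerance = 1e-12)

  # destroying the trial labels destroys the loadings
  set.seed(54)
  shuffled <- predict(fit)
  shuffled$predicted_lick_time <- sample(shuffled$predicted_lick_time)
  thm0 <- define_trial_history_mode(ses, shuffled)
  expect_lt(abs(cor(thm0$loadings, truth)), 0.3)
})

test_that("projection is the inner product, linear, and zero on silence", {
  d <- c(3, 2, 4)
  vals <- array(0, dim = c(2, 3, 5))
  for (b in 1:5) vals[1, , b] <- d * b     # trial 1: amplitude b along d
  tensor <- structure(vals, class = "binned_tensor", bin_size = 0.05,
                      alignment = "cue", window = c(0, 0.25),
                      smoothing = NA_real_, trial_index = 1:2,
                      unit_id = c("a", "b", "c"))
  mode <- d / sqrt(sum(d^2))
  pr <- project_mode(tensor, mode)
  amp <- sqrt(sum(d^2))
  expect_equal(pr$value[pr$trial == 1], amp * (1:5))
  expect_equal(pr$value[pr$trial == 2], rep(0, 5))
  # linearity: project(2A) = 2 project(A)
  tensor2 <- tensor
  tensor2[] <- 2 * vals
  pr2 <- project_mode(tensor2, mode)
  expect_equal(pr2$value, 2 * pr$value)
})

test_that("variance explained recovers planted orthogonal pattern shares", {
  set.seed(55)
  u <- 12
  p1 <- rnorm(u); p1 <- p1 / sqrt(sum(p1^2))
  p2 <- rnorm(u); p2 <- p2 - sum(p2 * p1) * p1; p2 <- p2 / sqrt(sum(p2^2))
  n_bins <- 24
  tt <- seq(0.05, 1.2, length.out = n_bins)
  share1 <- 0.7; share2 <- 0.3
  base <- matrix(0, u, 4)
  act <- sqrt(share1) * outer(p1, tt) + sqrt(share2) * outer(p2, rev(tt))
  vals <- array(0, dim = c(12, u, n_bins + 4))
  for (trial in 1:12) vals[trial, , ] <- cbind(base, act)
  tensor <- structure(vals, class = "binned_tensor", bin_size = 0.05,
                      alignment = "cue", window = c(-0.2, 1.2),
                      smoothing = NA_real_, trial_index = 1:12,
                      unit_id = paste0("u", 1:u))
  ms <- list(vectors = cbind(ramp = p1, middle = p2))
  ve <- variance_explained(tensor, ms, groups = list(all = 1:12),
                           span = c(0, 1.2))
  got1 <- ve$proportion[ve$mode == "ramp"]
  got2 <- ve$proportion[ve$mode == "middle"]
  expect_equal(got1 / (got1 + got2), share1, tolerance = 0.05)
  expect_lte(got1 + got2, 1 + 1e-12)
})

test_that("mode proportions obey Bessel's inequality on real data", {
  fx <- fix_mixed()
  ms <- define_modes(fx$session)
  b <- bin_spikes(fx$session, 0.05, "cue", c(-0.4, 1.6), smoothing = 0.2)
  tr <- group_trials_by_lick_time(fx$session$trials)
  groups <- split(tr$trial, tr$lick_group)
  groups <- groups[lengths(groups) >= 10]
  ve <- variance_explained(b, ms, groups)
  # cue, middle and ramp are mutually orthonormal; execution is only
  # orthogonal to ramp, so the bound applies to the first three
  ve3 <- ve[ve$mode %in% c("cue", "middle", "ramp"), ]
  tot <- tapply(ve3$proportion, ve3$group, sum)
  expect_true(all(tot <= 1 + 1e-9))
  # the pure-ramp generator concentrates power in the ramp mode
  ramp_share <- ve$proportion[ve$mode == "ramp"]
  expect_true(all(ramp_share > 0.5))
})

test_that("mode angles come with a calibrated shuffle null", {
  expect_equal(mode_angle(c(1, 0, 0), c(1, 0, 0), 50)$cosine, 1)
  fx <- fix_mixed()
  ms <- define_modes(fx$session)
  out <- mode_angle(ms$vectors[, "middle"], ms$vectors[, "ramp"], 100)
  expect_equal(out$cosine, 0, tolerance = 1e-10)
  # random high-dimensional vectors are rarely significantly aligned
  set.seed(56)
  sig <- vapply(1:60, function(i) {
    mode_angle(rnorm(100), rnorm(100), 100)$significant
  }, logical(1))
  expect_lt(mean(sig), 0.2)
  expect_error(mode_angle(rep(0, 5), rnorm(5)), "zero")
})

test_that("population correlation peak traces track temporal scaling", {
  fx <- fix_ramp()
  ses <- fx$session
  idx <- ses$trials$trial[!is.na(ses$trials$first_lick_time) &
                            !ses$trials$perturbed]
  # self comparison: peak trace on the diagonal
  pc <- population_correlation_analysis(ses, idx, idx, window = c(0, 1.2))
  expect_true(all(pc$peak_trace$ref_time == pc$peak_trace$comp_time,
                  na.rm = TRUE))
  # constructed x1.25 slowdown: peak trace slope ~ 0.8
  A <- bin_spikes(ses, 0.2, "cue", c(0, 1.2), trials = idx)
  Am <- apply(A, c(2, 3), mean)
  tt <- tensor_times(A) + 0.1
  Bm <- t(apply(Am, 1, function(v) approx(tt, v, xout = tt / 1.25,
                                          rule = 2)$y))
  C <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) C[i, j] <- cor(Am[, i], Bm[, j])
  keep <- apply(C, 2, max) > 0.8
  pk <- apply(C, 2, which.max)
  slope <- unname(coef(lm(pk[keep] ~ seq_len(6)[keep]))[2])
  expect_equal(slope, 0.8, tolerance = 0.2)
})

test_that("count-matched controls sit nearest the median lick time", {
  tr <- fill_trial_defaults(toy_trials(seq(0.8, 2.0, by = 0.1)))
  picked <- match_control_trials(tr, 3)
  med <- median(tr$first_lick_time)
  d <- abs(tr$first_lick_time[tr$trial %in% picked] - med)
  expect_true(all(d <= sort(abs(tr$first_lick_time - med))[3]))
})

test_that("pseudo-sessions enforce inclusion rules and disjoint trial sets", {
  fx <- fix_mixed()
  ps <- assemble_pseudo_session(list(fx$session, fx$session), n_define = 40)
  expect_gt(nrow(ps$units), 0)
  expect_equal(dim(ps$group_activity)[2], 6L)
  # pooled ramp-mode projection orders lick-time groups by unfolding speed
  ms <- define_modes(ps$window_means)
  late <- ps$times >= 0.5 & ps$times <= 0.9
  proj <- vapply(seq_len(6), function(g) {
    mean(ms$vectors[, "ramp"] %*% ps$group_activity[, g, late])
  }, numeric(1))
  expect_lt(cor(seq_len(6), proj), 0)   # slower trials ramp later -> lower
  # a session failing the per-range trial counts is excluded
  small <- fx$session
  small$trials <- small$trials[1:40, ]
  expect_error(assemble_pseudo_session(list(small), n_define = 30),
               "inclusion")
})

test_that("2-D vector fields detect flow reversal and respect exclusions", {
  set.seed(57)
  mk <- function(rev) {
    purrr::map(1:150, function(tr) {
      t <- seq(0, 1, by = 0.05)
      y <- 2 * t + cumsum(rnorm(length(t), 0, 0.02))
      x <- 3 + cumsum(rnorm(length(t), 0, 0.1))
      tibble::tibble(trial = tr, time = t, x = x,
                     y = if (rev) 2 - y else y)
    }) |> purrr::list_rbind()
  }
  ctrl <- mk(FALSE)
  vf <- vector_field_2d(ctrl, mk(TRUE), stim_onset = 0,
                        stim_window = c(0.1, 1))
  ang <- vf$angles[!vf$angles$excluded, ]
  expect_gt(nrow(ang), 3)
  expect_gt(mean(abs(ang$angle_diff)), 3)       # close to pi
  # identical fields: angle differences near zero
  vf0 <- vector_field_2d(ctrl, ctrl, stim_onset = 0, stim_window = c(0.1, 1))
  ang0 <- vf0$angles[!vf0$angles$excluded, ]
  expect_lt(mean(abs(ang0$angle_diff)), 0.2)
  # sparse bins (30 points or fewer) are omitted
  few <- ctrl[ctrl$trial <= 2, ]
  vf_few <- vector_field_2d(few, few, stim_onset = 0, stim_window = c(0.1, 1))
  expect_equal(nrow(vf_few$control_field), 0L)
})
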