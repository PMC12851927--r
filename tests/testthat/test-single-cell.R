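test_that("temporal warping rescales and preserves spike counts", {
  expect_equal(warp_spike_times(0.7, 1.4), 0.5)
  s <- c(0.1, 0.5, 1.0)
  expect_equal(warp_spike_times(s, 1), s)             # identity at target
  expect_equal(warp_spike_times(1.4, 1.4), 1)         # lick maps to target
  expect_length(warp_spike_times(s, 2.2), 3L)
  expect_error(warp_spike_times(s, 0), "positive")
  expect_error(warp_spike_times(s, NA), "positive")
})

test_that("across-trial variance vanishes for identical trials", {
  trials <- fill_trial_defaults(toy_trials(rep(1.3, 30)))
  # spike rate chosen so no spike lands exactly on a window edge (edge
  # assignment would otherwise flip with floating-point session-clock jitter)
  spikes <- deterministic_spikes(trials, "u1",
                                 function(t) rep(17.3, length(t)))
  ses <- toy_session(rep(1.3, 30), spikes = spikes)
  out <- across_trial_variance(ses, "u1", n_boot = 50)
  expect_equal(out$var_orig, 0)
  expect_equal(out$var_warped, 0)
})

test_that("warping reduces variance for scalable but not absolute-time units", {
  fx <- fix_mixed()
  gt <- fx$ground_truth$units
  gt_s <- gt[gt$scalable & gt$history_coef == 0, ]
  scal <- gt_s$unit_id[order(-gt_s$gain)][1:2]   # strongest planted ramps
  absu <- gt$unit_id[!gt$scalable & gt$history_coef == 0][1:2]
  for (u in scal) {
    out <- across_trial_variance(fx$session, u, n_boot = 300)
    expect_lt(out$var_warped, out$var_orig)
    expect_true(out$significant_reduction)
  }
  for (u in absu) {
    out <- across_trial_variance(fx$session, u, n_boot = 300)
    expect_false(out$significant_reduction)
  }
})

test_that("ramp characterization identifies a linear ramp", {
  n <- 60
  set.seed(41)
  licks <- runif(n, 1.3, 1.45)
  trials <- fill_trial_defaults(toy_trials(licks))
  spikes <- poisson_spikes(trials, "u1", function(t) 5 + 20 * t)
  ses <- toy_session(licks, spikes = spikes)
  set.seed(42)
  fit <- characterize_ramp(ses, "u1")
  expect_equal(fit$order, 1)
  expect_true(fit$monotonic)
  expect_gt(fit$peak_time, 1.0)        # fitted maximum at the lick end
})

test_that("ramp characterization identifies a mid-delay bump", {
  n <- 60
  set.seed(43)
  licks <- runif(n, 1.3, 1.45)
  trials <- fill_trial_defaults(toy_trials(licks))
  bump <- function(t) 5 + 30 * exp(-(t - 0.6)^2 / (2 * 0.15^2))
  spikes <- poisson_spikes(trials, "u1", bump)
  ses <- toy_session(licks, spikes = spikes)
  set.seed(44)
  fit <- characterize_ramp(ses, "u1")
  expect_false(fit$monotonic)
  # the 200-ms causal boxcar delays the PSTH peak by about half its width
  expect_gt(fit$peak_time, 0.6)
  expect_lt(fit$peak_time, 0.8)

  expect_error(characterize_ramp(ses, "u1", min_trials = 100), "skipped")
})

test_that("pre-lick and photostimulation modulation tests detect planted effects", {
  fx <- fix_ramp()
  gt <- fx$ground_truth_units
  alm <- gt$unit_id[gt$area == "ALM" & gt$gain > 15][1]
  out <- modulation_tests(fx$session, alm)
  expect_lt(out$prelick_p, 0.01)
  expect_equal(out$prelick_direction, "increase")
  expect_equal(out$photostim_direction, "inhibited")
  expect_lt(out$photostim_p, 0.01)
  # striatal units keep firing during the ALM stimulus (paused, not silenced)
  str_u <- gt$unit_id[gt$area == "STR"]
  b_stim <- bin_spikes(fx$session, 0.1, "cue", c(0.65, 1.15),
                       trials = fx$pert_pause, units = str_u)
  b_ctrl <- bin_spikes(fx$session, 0.1, "cue", c(0.65, 1.15),
                       trials = fx$test_ctrl, units = str_u)
  expect_gt(mean(b_stim), 0.5 * mean(b_ctrl))
})

test_that("partial rank correlation matches the residual-rank oracle", {
  oracle <- function(R, P, U) {
    rr <- rank(R); rp <- rank(P); ru <- rank(U)
    res_r <- resid(lm(rr ~ ru))
    res_p <- resid(lm(rp ~ ru))
    cor(res_r, res_p)
  }
  set.seed(45)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    R <- rnorm(n); P <- rnorm(n); U <- 0.5 * P + rnorm(n)
    got <- partial_rank_correlation(R, P, U, n_shuffle = 2)
    expect_equal(got$rho, oracle(R, P, U), tolerance = 1e-10)
  }
})

test_that("partial rank correlation handles identities and degenerate input", {
  set.seed(46)
  P <- rnorm(40); U <- rnorm(40)
  # R = P with U independent: partial correlation approaches 1
  got <- partial_rank_correlation(P, P, U, n_shuffle = 10)
  expect_gt(got$rho, 0.95)
  # symmetry under exchanging R and P
  R <- rnorm(40)
  a <- partial_rank_correlation(R, P, U, n_shuffle = 2)$rho
  b <- partial_rank_correlation(P, R, U, n_shuffle = 2)$rho
  expect_equal(a, b, tolerance = 1e-12)
  expect_true(abs(a) <= 1)
  expect_error(partial_rank_correlation(rep(1, 40), P, U), "constant")
  expect_error(partial_rank_correlation(R[1:10], P[1:10], U[1:10]), "20")
})

test_that("shuffle and session nulls flag a genuine history signal", {
  set.seed(47)
  n <- 80
  P <- rnorm(n)
  R <- 0.8 * P + 0.3 * rnorm(n)
  U <- rnorm(n)
  out <- partial_rank_correlation(R, P, U, n_shuffle = 300,
                                  P_pool = list(rnorm(n), rnorm(n)))
  expect_true(out$shuffle_significant)
  expect_true(out$session_significant)
})
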