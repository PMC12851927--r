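test_that("uncoupled units relax to their input with the membrane time constant", {
  cfg <- network_config(matrix(0, 2, 2), areas = c("ALM", "STR"),
                        rest_h = c(0, 0), dt = 1e-4)
  cfg$I_base <- c(0, 0)
  traj <- integrate_dynamics(cfg, 0.1, I_ext = function(t) c(4, 2))
  expected <- 4 * (1 - exp(-traj$times / 0.01))
  expect_lt(max(abs(traj$r[, 1] - expected)) / 4, 0.01)
})

test_that("an eigenvalue-1 loop integrates input linearly along its mode", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)      # symmetric loop, eigenvalues +-1
  cfg <- network_config(W, areas = c("ALM", "STR"), rest_h = c(5, 5),
                        target_unit = "u1")
  cfg <- calibrate_baseline(cfg)
  inp <- c(0.05, 0.05)                  # along the integrating eigenvector
  traj <- integrate_dynamics(cfg, 1.5, I_ext = function(t) inp)
  late <- traj$times > 0.2              # past the fast transient
  fit <- lm(traj$r[late, 1] ~ traj$times[late])
  # slope = projection on the mode / tau = 0.05 / 0.01
  expect_equal(unname(coef(fit)[2]), 0.05 / 0.01, tolerance = 0.01)
  expect_gt(summary(fit)$r.squared, 0.999)
})

test_that("strong negative current rectifies a driven unit to zero", {
  W <- matrix(0, 2, 2)
  W[2, 1] <- 1
  cfg <- network_config(W, areas = c("ALM", "STR"), rest_h = c(5, 5),
                        target_unit = "u2")
  cfg <- calibrate_baseline(cfg)
  traj <- integrate_dynamics(cfg, 0.5, I_stim = function(t) c(0, -10))
  expect_true(all(traj$r[traj$times > 0.05, 2] == 0))
  expect_true(all(traj$r >= 0))
})

test_that("baseline calibration solves the fixed point and flags instability", {
  cfg <- network_config(matrix(0, 2, 2), areas = c("ALM", "STR"),
                        rest_h = c(5, 5), target_unit = "u1")
  cfg <- calibrate_baseline(cfg, target_rate = 5)
  expect_equal(unname(cfg$I_base), c(5, 5))
  bad <- network_config(matrix(1.2, 1, 1), areas = "ALM", rest_h = 5,
                        target_unit = "u1")
  expect_error(calibrate_baseline(bad), "eigenvalue")
})

test_that("the calibrated striatal integrator rests at 5 spikes/s", {
  cfg <- fix_specialized_str()
  traj <- simulate_variant_trial(cfg, step_amp = 0, t_pre = 0, t_max = 2)
  tgt <- traj$r[nrow(traj$r), cfg$target_unit]
  expect_equal(unname(tgt), 5, tolerance = 0.01)
  # and rates stay nonnegative throughout a perturbed trial
  stim <- simulate_variant_trial(cfg, stim = stim_protocol("alm_silencing"))
  expect_true(all(stim$r >= 0))
})

test_that("variant constraint checks verify the stated eigenstructure", {
  red <- build_variant("redundant", tune = FALSE)
  ev <- eigen(red$W, only.values = TRUE)$values
  expect_equal(sum(abs(Mod(ev) - 1) < 1e-9), 2L)

  dis <- build_variant("distributed", tune = FALSE)
  W_cut <- dis$W
  W_cut["a1", "s1"] <- 0
  W_cut["s1", "a1"] <- 0                # sever the interareal loop
  expect_lt(max(Re(eigen(W_cut, only.values = TRUE)$values)), 1)

  leaky <- build_variant("ALM_leaky", tune = FALSE)
  expect_lt(max(Re(eigen(leaky$W, only.values = TRUE)$values)), 1)
})

test_that("perturbed stable architectures return to their fixed point", {
  # uncoupled units: return within 10 membrane time constants
  cfg <- calibrate_baseline(network_config(matrix(0, 2, 2),
                                           areas = c("ALM", "STR"),
                                           rest_h = c(5, 5),
                                           target_unit = "u1"))
  traj <- integrate_dynamics(cfg, 10 * cfg$tau, h0 = cfg$rest_h + c(1, -1))
  expect_lt(max(abs(traj$r[nrow(traj$r), ] - cfg$rest_h) / cfg$rest_h), 0.01)
  # the leaky loop relaxes on its slow-mode timescale tau / (1 - lambda)
  leaky <- build_variant("ALM_leaky", tune = FALSE)
  lam <- max(Re(eigen(leaky$W, only.values = TRUE)$values))
  t_slow <- leaky$tau / (1 - lam)
  traj2 <- integrate_dynamics(leaky, 6 * t_slow,
                              h0 = leaky$rest_h + c(1, 0, 0, 0))
  expect_lt(max(abs(traj2$r[nrow(traj2$r), ] - leaky$rest_h) /
                  leaky$rest_h), 0.01)
})

test_that("feedforward chains show graded, input-controlled speed", {
  cfg <- build_variant("feedforward_ALM", tune = FALSE)
  t_weak <- crossing_time(
    simulate_variant_trial(cfg, step_amp = 2.05, t_pre = 0.2, t_max = 3.5),
    cfg$target_unit, 10, after = 0.6)
  t_strong <- crossing_time(
    simulate_variant_trial(cfg, step_amp = 2.3, t_pre = 0.2, t_max = 3.5),
    cfg$target_unit, 10, after = 0.6)
  expect_false(is.na(t_weak))
  expect_lt(t_strong, t_weak)
})

test_that("halving the integration step leaves trajectories unchanged", {
  cfg <- fix_specialized_str()
  t1 <- simulate_variant_trial(cfg, t_pre = 0.1, t_max = 1)
  cfg2 <- cfg
  cfg2$dt <- cfg$dt / 2
  t2 <- simulate_variant_trial(cfg2, t_pre = 0.1, t_max = 1)
  r1 <- t1$r[nrow(t1$r), ]
  r2 <- t2$r[nrow(t2$r), ]
  expect_lt(max(abs(r1 - r2) / pmax(r1, 1)), 0.001)
})

test_that("the striatal-integrator variant shows pause and rewind signatures", {
  cfg <- fix_specialized_str()
  sil <- run_perturbation_experiment(cfg, "alm_silencing", t_max = 3.2)
  d1 <- run_perturbation_experiment(cfg, "d1_inhibition", t_max = 3.2)
  expect_equal(classify_silencing_response(sil)$label, "parallel_resume")
  expect_equal(classify_d1_response(d1)$label, "gradual_decay_no_jump")
  # striatal ramp holds its level through ALM silencing (the pause itself)
  str_stim <- sil$ramp[sil$ramp$area == "STR" & sil$ramp$condition == "stim", ]
  at <- function(tt) str_stim$ramp[which.min(abs(str_stim$time - tt))]
  expect_equal(at(1.15), at(0.6), tolerance = 0.05)
})
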