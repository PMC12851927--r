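# Shared fixtures, generated once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, fn(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Hand-built trial table: licks[i] gives the first-lick time of trial i (NA
# for no lick), everything else takes defaults.
toy_trials <- function(licks, delay = 1, cue = TRUE, perturbed = FALSE) {
  n <- length(licks)
  tibble::tibble(
    trial = seq_len(n),
    cue_present = rep_len(cue, n),
    delay_duration = rep_len(delay, n),
    first_lick_time = licks,
    rewarded = !is.na(licks) & licks >= rep_len(delay, n),
    perturbed = rep_len(perturbed, n))
}

toy_session <- function(licks, spikes = NULL, units = NULL, ...) {
  trials <- fill_trial_defaults(toy_trials(licks, ...))
  if (is.null(units)) {
    units <- tibble::tibble(unit_id = "u1", area = "ALM", mean_rate = 5,
                            spike_width = 0.6,
                            post_spike_suppression = NA_real_,
                            long_isi_fraction = 0.2)
  }
  if (is.null(spikes)) {
    spikes <- tibble::tibble(unit_id = character(0), time_s = numeric(0))
  }
  new_session(trials, units, spikes)
}

# Deterministic spike train for one unit: spike when the cumulative
# intensity crosses an integer (time-rescaling inverse), per trial.
deterministic_spikes <- function(trials, unit_id, intensity_fn, t_max = 1.2) {
  grid <- seq(0, t_max, by = 0.001)
  lam <- intensity_fn(grid)
  cum <- cumsum(lam) * 0.001
  st <- grid[findInterval(seq_len(floor(max(cum))), cum) + 1L]
  tibble::tibble(
    unit_id = unit_id,
    time_s = as.vector(outer(st, trials$cue_onset, `+`)))
}

# Poisson spike train for one unit with a given intensity profile.
poisson_spikes <- function(trials, unit_id, intensity_fn, t_max = 1.6) {
  grid <- seq(0.0005, t_max, by = 0.001)
  lam <- intensity_fn(grid)
  purrr::map(seq_len(nrow(trials)), function(i) {
    n <- rpois(length(grid), lam * 0.001)
    tibble::tibble(unit_id = unit_id,
                   time_s = trials$cue_onset[i] + rep(grid, n) +
                     runif(sum(n), 0, 0.001))
  }) |> purrr::list_rbind()
}

# Mixed population session (history + scalable + absolute units).
fix_mixed <- function() fixture("mixed", function() {
  bh <- make_behavior(behavior_gen_config(n_trials = 320), seed = 11)
  make_spikes(bh, neural_gen_config(n_units = c(ALM = 12, STR = 12)),
              seed = 12)
})

# Larger history-coding population for trial-history-mode recovery.
fix_history <- function() fixture("history", function() {
  bh <- make_behavior(behavior_gen_config(n_trials = 220), seed = 21)
  make_spikes(bh, neural_gen_config(n_units = c(ALM = 25, STR = 25)),
              seed = 22)
})

# Pure temporally scalable ramping population with planted pause and rewind
# perturbations; the decoding test bed.
fix_ramp <- function() fixture("ramp", function() {
  bh <- make_behavior(behavior_gen_config(n_trials = 500), seed = 31)
  tr <- bh$session$trials
  set.seed(32)
  eligible <- which(!is.na(tr$first_lick_time) & tr$first_lick_time > 0.9)
  pert_pause <- sort(sample(eligible, 35))
  bh <- add_perturbation(bh, pert_pause, "silencing")
  rest <- setdiff(which(!is.na(bh$session$trials$first_lick_time) &
                          bh$session$trials$first_lick_time > 0.9 &
                          !bh$session$trials$perturbed), pert_pause)
  pert_rew <- sort(sample(rest, 35))
  bh <- add_perturbation(bh, pert_rew, "rewind", rewind_rate = 1)
  sp <- make_spikes(bh, neural_gen_config(n_units = c(ALM = 15, STR = 15),
                                          scalable_fraction = 1,
                                          history_fraction = 0,
                                          rewind_rate = 1), seed = 33)
  tr <- sp$session$trials
  unpert <- tr$trial[!tr$perturbed]
  set.seed(34)
  test_ctrl <- sort(sample(intersect(unpert,
                                     tr$trial[!is.na(tr$first_lick_time)]),
                           100))
  list(session = sp$session, ground_truth_units = sp$ground_truth$units,
       behavior_gt = bh$ground_truth,
       pert_pause = pert_pause, pert_rew = pert_rew,
       test_ctrl = test_ctrl, train = setdiff(unpert, test_ctrl))
})

fix_ramp_decoder <- function() fixture("ramp_decoder", function() {
  fx <- fix_ramp()
  fit_decoder(fx$session, fx$train)
})

fix_specialized_str <- function() fixture("specialized_str", function() {
  build_variant("specialized_STR")
})
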