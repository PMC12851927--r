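test_that("session bundles round-trip losslessly, including no-lick trials", {
  ses <- toy_session(c(1.2, NA, 0.9),
                     spikes = tibble::tibble(
                       unit_id = c("u1", "u1", "u2"),
                       time_s = c(1.0, 2.5, 3.1)),
                     units = tibble::tibble(
                       unit_id = c("u1", "u2"), area = c("ALM", "STR"),
                       mean_rate = c(4, 2), spike_width = c(0.6, 0.45),
                       post_spike_suppression = c(NA, 30),
                       long_isi_fraction = c(0.2, 0.05)))
  path <- withr::local_tempdir()
  save_session(ses, path)
  back <- load_session(path)
  expect_equal(back$trials, ses$trials)
  expect_equal(back$units, ses$units)
  expect_equal(back$spikes, ses$spikes)
  expect_true(is.na(back$trials$first_lick_time[2]))

  # absent lick is an empty field in the delimited text
  raw <- readLines(file.path(path, "trials.csv"))
  expect_false(grepl("NA", raw[3]))
})

test_that("bundle loading reports missing files and malformed rows", {
  ses <- toy_session(c(1.2, 1.0))
  path <- withr::local_tempdir()
  save_session(ses, path)
  file.remove(file.path(path, "manifest.yaml"))
  expect_error(load_session(path), "manifest not found")

  save_session(ses, path)
  file.remove(file.path(path, "spikes.csv"))
  expect_error(load_session(path), "spikes.csv")

  save_session(ses, path)
  writeLines(c("unit_id,time_s", "u1,1.0", "u1,not_a_number"),
             file.path(path, "spikes.csv"))
  expect_error(load_session(path), "row 2")
})

test_that("binned rates convert counts to spikes/s in half-open bins", {
  # one spike per 50-ms bin -> 20 spikes/s everywhere
  ses <- toy_session(1.0,
                     spikes = tibble::tibble(
                       unit_id = "u1",
                       time_s = 0.025 + seq(0, 0.95, by = 0.05)))
  ses$trials$cue_onset <- 0
  b <- bin_spikes(ses, 0.05, "cue", c(0, 1))
  expect_equal(as.vector(b[1, 1, ]), rep(20, 20))
})

test_that("binning conserves total spike count and never leaks the future", {
  set.seed(1)
  st <- sort(runif(200, 0, 3))
  ses <- toy_session(1.0, spikes = tibble::tibble(unit_id = "u1", time_s = st))
  on <- ses$trials$cue_onset[1]
  b <- bin_spikes(ses, 0.05, "cue", c(-1, 2))
  inside <- sum(st >= on - 1 & st < on + 2)
  expect_equal(sum(b) * 0.05, inside)

  # single spike at 0.5 s, 1-ms bins, 200-ms causal boxcar: support [0.5, 0.7)
  ses2 <- toy_session(1.0, spikes = tibble::tibble(unit_id = "u1",
                                                   time_s = 0.5))
  ses2$trials$cue_onset <- 0
  bs <- bin_spikes(ses2, 0.001, "cue", c(0, 1), smoothing = 0.2)
  tt <- tensor_times(bs)
  nz <- tt[bs[1, 1, ] > 0]
  expect_true(min(nz) >= 0.5)
  expect_true(max(nz) < 0.7)

  # causal boxcar leaves a constant-rate train unchanged
  ses3 <- toy_session(1.0,
                      spikes = tibble::tibble(
                        unit_id = "u1", time_s = seq(0.005, 2, by = 0.01)))
  ses3$trials$cue_onset <- 0
  raw <- bin_spikes(ses3, 0.05, "cue", c(0.5, 1.5))
  smo <- bin_spikes(ses3, 0.05, "cue", c(0.5, 1.5), smoothing = 0.2)
  expect_equal(as.vector(smo), as.vector(raw), tolerance = 1e-10)
})

test_that("binning rejects empty unit sets and out-of-span windows", {
  ses <- toy_session(c(1.2, 1.0))
  expect_error(bin_spikes(ses, 0.05, "cue", c(0, 1), units = character(0)),
               "no units")
  expect_error(bin_spikes(ses, 0.05, "cue", c(-100, 1)), "outside")
})

test_that("engagement window follows the run-based start and stop rules", {
  # all trials licked: full range from the 5th trial to the last
  tr <- toy_trials(rep(1.2, 150))
  expect_equal(unname(select_engaged_trials(fill_trial_defaults(tr))),
               c(5, 150))

  # licks from trial 1, a no-lick run at 100-102, licks resume after:
  # engaged range ends 20 trials before the run
  licks <- rep(1.2, 150)
  licks[100:102] <- NA
  tr <- fill_trial_defaults(toy_trials(licks))
  expect_equal(unname(select_engaged_trials(tr)), c(5, 79))

  # fewer than 5 licked trials: no engaged range
  tr <- fill_trial_defaults(toy_trials(c(1, 1, NA, 1, NA, 1)))
  expect_length(select_engaged_trials(tr), 0)

  # a perturbed no-lick run does not end engagement
  licks2 <- rep(1.2, 150)
  licks2[100:102] <- NA
  tr2 <- fill_trial_defaults(toy_trials(licks2))
  tr2$perturbed[100:102] <- TRUE
  expect_equal(unname(select_engaged_trials(tr2)), c(5, 150))
})

test_that("engagement window ignores trials outside the returned range", {
  licks <- rep(1.2, 150)
  licks[100:102] <- NA
  tr <- fill_trial_defaults(toy_trials(licks))
  rng <- select_engaged_trials(tr)
  tr2 <- tr
  tr2$first_lick_time[140:150] <- 1.9   # lick values beyond the range change
  tr2$first_lick_time[1:2] <- 0.5
  tr2$rewarded[120:130] <- FALSE
  expect_equal(select_engaged_trials(tr2), rng)
})

test_that("unit classification applies the waveform rules as a partition", {
  units <- tibble::tibble(
    unit_id = paste0("u", 1:6),
    area = c("ALM", "ALM", "STR", "STR", "STR", "STR"),
    mean_rate = c(3, 0.3, 2, 1, 1, 0.05),
    spike_width = c(0.6, 0.6, 0.45, 0.3, 0.3, 0.5),
    post_spike_suppression = c(NA, NA, 30, 10, 10, 20),
    long_isi_fraction = c(0.2, 0.2, 0.2, 0.05, 0.5, 0.1))
  out <- suppressWarnings(classify_units(units))
  expect_equal(out$class,
               c("ALM_pyramidal", "ALM_other", "SPN", "FSI", "TAN",
                 "unclassified"))
  # partition: exactly one class each
  expect_true(all(!is.na(out$class)))
  expect_warning(
    classify_units(tibble::tibble(
      unit_id = "x", area = "ALM", mean_rate = 2, spike_width = NA,
      post_spike_suppression = NA, long_isi_fraction = NA)),
    "unclassified")
})

test_that("lick-time grouping uses half-open ranges and skips no-licks", {
  tr <- fill_trial_defaults(toy_trials(c(1.10, NA, 2.5, 0.9, 1.999)))
  out <- group_trials_by_lick_time(tr)
  expect_equal(out$lick_group,
               c("[1.10,1.25)", NA, NA, "[0.80,1.10)", "[1.70,2.00)"))
  expect_error(
    group_trials_by_lick_time(tr, tibble::tibble(lo = c(0, 0.5),
                                                 hi = c(1, 1.5))),
    "non-overlapping")
})
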