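#' Behaviour generator configuration
#'
#' Defines the study conditions emulated by the synthetic behaviour
#' generator: block-switched unsignalled delays, trial-history-dependent
#' lick times with inverse-Gaussian dispersion, exponential inter-trial
#' intervals with an offset and cap, and randomly interleaved no-cue probe
#' trials.
#'
#' The defaults are the task's stated conditions: delays alternating between
#' 1 s and 3 s in blocks of 30-70 trials, ITI = 1 s + Exp(mean 3 s) capped
#' at 7 s, ~10% no-cue trials, and lick-time dispersion matched to the
#' inverse-Gaussian shape `lambda = 12` of the empirical lick-time
#' distribution. The default history coefficients (positive dependence on
#' previous lick times, negative interaction with previous reward) give a
#' stationary mean lick time near 1.3 s.
#'
#' @param n_trials Number of trials.
#' @param delay_levels Delay durations in seconds, cycled across blocks.
#' @param block_length_range Min/max block length in trials.
#' @param b0 Regression intercept (s).
#' @param bT Coefficients on previous lick times, one per lag.
#' @param bTR Coefficients on previous lick time x reward interactions.
#' @param lambda_gen Inverse-Gaussian shape of the lick-time noise.
#' @param iti_offset,iti_mean,iti_max ITI = offset + Exp(mean), capped.
#' @param p_no_cue Probability of a no-cue probe trial.
#' @param min_lick Lower clip for realized lick times (s).
#' @return A `behavior_gen_config` list.
#' @export
behavior_gen_config <- function(n_trials = 400L,
                                delay_levels = c(1, 3),
                                block_length_range = c(30L, 70L),
                                b0 = 1.17, bT = c(0.3, 0), bTR = c(-0.2, 0),
                                lambda_gen = 12,
                                iti_offset = 1, iti_mean = 3, iti_max = 7,
                                p_no_cue = 0.10, min_lick = 0.2) {
  stopifnot(lambda_gen > 0, p_no_cue >= 0, p_no_cue < 1,
            length(bT) == length(bTR))
  structure(list(n_trials = as.integer(n_trials),
                 delay_levels = delay_levels,
                 block_length_range = block_length_range,
                 b0 = b0, bT = bT, bTR = bTR, lambda_gen = lambda_gen,
                 iti_offset = iti_offset, iti_mean = iti_mean,
                 iti_max = iti_max, p_no_cue = p_no_cue,
                 min_lick = min_lick),
            class = "behavior_gen_config")
}

#' Generate a synthetic behaviour session
#'
#' Sequentially simulates lick times with the generative model
#' `mu_n = b0 + sum_k bT_k LT_(n-k) + sum_k bTR_k LT_(n-k) R_(n-k)`,
#' where the lagged values come from the most recent licked trials, and the
#' realized lick time is drawn from IG(mean `mu_n`, shape `lambda_gen`)
#' clipped below at `min_lick`. A trial is rewarded iff its lick falls at or
#' after the current delay. No-cue probe trials produce no lick and no
#' reward. Delay blocks alternate through `delay_levels` with lengths drawn
#' uniformly from `block_length_range`.
#'
#' @param config A [behavior_gen_config()].
#' @param seed Optional integer seed (sessions are bit-reproducible given a
#'   seed).
#' @param animal_id,session_id Identifiers for the session.
#' @return List with `session` (a `cbg_session` without units or spikes) and
#'   `ground_truth` (tibble: per-trial `mu`, `z` standardized predicted lick
#'   time, plus the generator coefficients as attributes).
#' @export
make_behavior <- function(config = behavior_gen_config(), seed = NULL,
                          animal_id = "synth", session_id = "s1") {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  n_lag <- length(config$bT)

  # delay blocks
  delays <- numeric(0)
  lev <- 0L
  while (length(delays) < n) {
    len <- sample(seq(config$block_length_range[1],
                      config$block_length_range[2]), 1)
    delays <- c(delays,
                rep(config$delay_levels[lev %% length(config$delay_levels) + 1],
                    len))
    lev <- lev + 1L
  }
  delays <- delays[seq_len(n)]

  cue <- runif(n) >= config$p_no_cue
  iti <- pmin(config$iti_offset + rexp(n, 1 / config$iti_mean),
              config$iti_max)

  lt <- rep(NA_real_, n)
  rew <- logical(n)
  mu <- rep(NA_real_, n)
  n_clipped <- 0L
  hist_lt <- rep(config$b0 / (1 - sum(config$bT) - sum(config$bTR)), n_lag)
  hist_r <- rep(1, n_lag)     # warm start at the rewarded stationary point
  for (i in seq_len(n)) {
    m <- config$b0 + sum(config$bT * hist_lt) +
      sum(config$bTR * hist_lt * hist_r)
    if (m <= config$min_lick) {
      m <- config$min_lick
      n_clipped <- n_clipped + 1L
    }
    mu[i] <- m
    if (cue[i]) {
      lt[i] <- max(rinvgauss(1, m, config$lambda_gen), config$min_lick)
      rew[i] <- lt[i] >= delays[i]
      hist_lt <- c(lt[i], hist_lt)[seq_len(n_lag)]
      hist_r <- c(as.numeric(rew[i]), hist_r)[seq_len(n_lag)]
    }
  }
  if (n_clipped > 0) {
    warn(paste0(n_clipped, " trial(s) had nonpositive predicted lick time; ",
                "clipped."))
  }
  trials <- tibble::tibble(
    trial = seq_len(n), cue_present = cue, cue_intensity = 0,
    delay_duration = delays, first_lick_time = lt, rewarded = rew,
    iti_duration = iti)
  session <- new_session(trials, units = tibble::tibble(
    unit_id = character(0), area = character(0), mean_rate = numeric(0),
    spike_width = numeric(0), post_spike_suppression = numeric(0),
    long_isi_fraction = numeric(0)),
    spikes = tibble::tibble(unit_id = character(0), time_s = numeric(0)),
    animal_id = animal_id, session_id = session_id, condition = "switching")
  gt <- tibble::tibble(trial = seq_len(n), mu = mu,
                       z = as.numeric(scale(mu)),
                       intended_lick_time = lt)
  attr(gt, "coefficients") <- list(b0 = config$b0, bT = config$bT,
                                   bTR = config$bTR,
                                   lambda = config$lambda_gen)
  list(session = session, ground_truth = gt)
}

#' Apply a synthetic perturbation to a behaviour session
#'
#' Marks the given trials as perturbed and shifts their lick times according
#' to the behavioural-level effect of the perturbation on an internal timer
#' running at unit speed: `"silencing"` (ALM-style) pauses the timer during
#' the stimulus (with the final `ramp_down` at linearly recovering speed),
#' `"rewind"` (striatal D1-style) makes it decay at `rewind_rate` and resume
#' from the decayed level; a timer stuck at zero for more than 0.32 s
#' continuously yields a no-lick trial. Trials whose lick would occur before
#' the perturbation onset are unaffected.
#'
#' @param behavior Output of [make_behavior()] (list with `session` and
#'   `ground_truth`), or a bare `cbg_session`.
#' @param trials Integer indices of trials to perturb.
#' @param kind `"silencing"` or `"rewind"`.
#' @param onset,duration,ramp_down Stimulus timing in seconds.
#' @param rewind_rate Decay rate of the timer during a rewind (s of timer
#'   content per s; default 2).
#' @param power Nominal light power (mW), recorded in the trial table.
#' @return Same structure as the input with updated trials; the ground truth
#'   gains `effective_shift` per trial.
#' @export
add_perturbation <- function(behavior, trials,
                             kind = c("silencing", "rewind"),
                             onset = 0.6, duration = 0.6, ramp_down = 0.3,
                             rewind_rate = 2, power = 1.5) {
  kind <- match.arg(kind)
  session <- if (inherits(behavior, "cbg_session")) behavior
             else behavior$session
  tr <- session$trials
  manip <- if (kind == "silencing") {
    timer_manipulation("pause", onset = onset, duration = duration,
                       ramp_down = ramp_down, c = 0)
  } else {
    timer_manipulation("rewind", onset = onset, duration = duration,
                       ramp_down = ramp_down, r_decay = -rewind_rate)
  }
  shift <- rep(0, nrow(tr))
  for (i in trials) {
    lt0 <- tr$first_lick_time[i]
    if (is.na(lt0) || lt0 <= onset) next
    cfg <- timer_config(theta = lt0, mu = 1.3, lambda = 12, dt = 0.001,
                        t_max = max(10, lt0 + duration + 5))
    new_lt <- simulate_trial(1, manip, cfg)
    shift[i] <- if (is.na(new_lt)) NA_real_ else new_lt - lt0
    tr$first_lick_time[i] <- new_lt
    if (is.na(new_lt)) tr$rewarded[i] <- FALSE
  }
  tr$perturbed[trials] <- TRUE
  tr$pert_target[trials] <- if (kind == "silencing") "ALM" else "VLS-D1"
  tr$pert_laterality[trials] <- "bilateral"
  tr$pert_onset[trials] <- onset
  tr$pert_duration[trials] <- duration
  tr$pert_ramp_down[trials] <- ramp_down
  tr$pert_power[trials] <- power
  session$trials <- tr
  if (inherits(behavior, "cbg_session")) return(session)
  behavior$session <- session
  gt <- behavior$ground_truth
  prev <- if ("effective_shift" %in% names(gt)) gt$effective_shift
          else rep(0, nrow(tr))
  prev[trials] <- shift[trials]
  gt$effective_shift <- prev
  prev_kind <- if ("pert_kind" %in% names(gt)) gt$pert_kind
               else rep(NA_character_, nrow(tr))
  prev_kind[trials] <- kind
  gt$pert_kind <- prev_kind
  behavior$ground_truth <- gt
  behavior
}
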