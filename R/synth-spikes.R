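#' Neural generator configuration
#'
#' Parameters of the synthetic spike generator. Units are inhomogeneous
#' Poisson at 1-ms resolution with three ingredients matching the
#' phenomenology the analyses assume: (i) a monotone ramp between cue and
#' lick, temporally *scalable* (unfolding in proportional time `t / LT`) for
#' a configurable fraction of units and in absolute time for the rest;
#' (ii) a tonic trial-history signal `h_i * z_n` present throughout the ITI
#' and the trial, where `z_n` is the standardized history-predicted lick
#' time; (iii) perturbation responses at the rate level — silencing
#' multiplies rates by ~0 during the stimulus and pauses the ramp phase
#' (post-offset activity resumes at the pre-offset ramp level, offset in
#' time); rewind makes the ramp phase decay during the stimulus and resume
#' from the decayed level.
#'
#' @param n_units Units per area (named vector, e.g. `c(ALM = 25, STR = 25)`).
#' @param baseline_rate Mean baseline rate, spikes/s.
#' @param ramp_gain Mean peak ramp amplitude above baseline, spikes/s.
#' @param scalable_fraction Fraction of units whose ramp scales with lick
#'   time.
#' @param history_fraction Fraction of units carrying the tonic history
#'   signal.
#' @param history_gain Scale of the tonic history coefficients `h_i`
#'   (spikes/s per SD of predicted lick time).
#' @param silencing_factor Rate multiplier during a silencing stimulus.
#' @param rewind_rate Ramp-phase decay rate during a rewind stimulus.
#' @return A `neural_gen_config` list.
#' @export
neural_gen_config <- function(n_units = c(ALM = 25, STR = 25),
                              baseline_rate = 5, ramp_gain = 20,
                              scalable_fraction = 0.6,
                              history_fraction = 0.4, history_gain = 2,
                              silencing_factor = 0.02, rewind_rate = 2) {
  structure(list(n_units = n_units, baseline_rate = baseline_rate,
                 ramp_gain = ramp_gain,
                 scalable_fraction = scalable_fraction,
                 history_fraction = history_fraction,
                 history_gain = history_gain,
                 silencing_factor = silencing_factor,
                 rewind_rate = rewind_rate),
            class = "neural_gen_config")
}

# ramp phase u(t) on a 1-ms grid given the trial's perturbation descriptors:
# unit speed, paused or decaying during the stimulus, clamped at zero.
ramp_phase <- function(t_grid, trial_row, config) {
  if (!isTRUE(trial_row$perturbed)) return(pmax(t_grid, 0))
  on <- trial_row$pert_onset
  dur <- trial_row$pert_duration
  ramp <- trial_row$pert_ramp_down
  t_full <- on + dur - ramp
  speed0 <- if (identical(trial_row$pert_target, "ALM")) 0
            else -config$rewind_rate
  dt <- diff(t_grid[1:2])
  speed <- rep(1, length(t_grid))
  inwin <- t_grid >= on & t_grid < on + dur
  frac <- pmax((t_grid - t_full) / ramp, 0)
  speed[inwin] <- (speed0 + (1 - speed0) * frac)[inwin]
  u <- cumsum(c(0, speed[-length(speed)]) * dt) + t_grid[1]
  u[t_grid < 0] <- t_grid[t_grid < 0]
  pos <- t_grid >= 0
  u0 <- u[pos]
  u[pos] <- u0 - pmin(0, cummin(u0))   # reflect at zero; resume from decayed level
  u
}

#' Generate synthetic spike trains for a behaviour session
#'
#' Draws per-unit ground-truth parameters (baseline, ramp gain, scalable
#' flag, tonic history coefficient), builds the per-trial rate profile
#' described in [neural_gen_config()], and samples Poisson spikes at 1-ms
#' resolution over each trial window (1.5 s before the cue to 1 s after the
#' lick, or 5 s after cue for no-lick trials). Unit metadata (spike width,
#' post-spike suppression, long-ISI fraction) are assigned so that
#' [classify_units()] labels ALM units pyramidal and striatal units SPN.
#'
#' @param behavior Output of [make_behavior()] (list) or a `cbg_session`.
#' @param config A [neural_gen_config()].
#' @param seed Optional integer seed.
#' @return List with `session` (a full `cbg_session`) and `ground_truth`
#'   (list of `units` and `trials` tibbles).
#' @export
make_spikes <- function(behavior, config = neural_gen_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  session <- if (inherits(behavior, "cbg_session")) behavior
             else behavior$session
  gt_trials <- if (inherits(behavior, "cbg_session")) {
    mu <- dplyr::coalesce(session$trials$first_lick_time, 1.3)
    tibble::tibble(trial = session$trials$trial, mu = mu,
                   z = as.numeric(scale(mu)),
                   intended_lick_time = session$trials$first_lick_time)
  } else behavior$ground_truth

  areas <- rep(names(config$n_units), config$n_units)
  n_u <- length(areas)
  units_gt <- tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(n_u)),
    area = areas,
    baseline = config$baseline_rate * runif(n_u, 0.5, 1.5),
    gain = config$ramp_gain * runif(n_u, 0.5, 1.5),
    scalable = runif(n_u) < config$scalable_fraction,
    history_coef = ifelse(runif(n_u) < config$history_fraction,
                          config$history_gain * sample(c(-1, 1), n_u,
                                                       replace = TRUE) *
                            runif(n_u, 0.5, 1.5),
                          0))

  tr <- session$trials
  dt <- 0.001
  spike_unit <- vector("list", nrow(tr))
  spike_time <- vector("list", nrow(tr))
  z <- gt_trials$z
  z[is.na(z)] <- 0
  for (i in seq_len(nrow(tr))) {
    lt <- tr$first_lick_time[i]
    lt_ref <- gt_trials$intended_lick_time[i]
    if (is.na(lt_ref)) lt_ref <- 1.3
    t_hi <- if (is.na(lt)) 5 else min(lt + 1, 6)
    t_grid <- seq(-1.5, t_hi, by = dt)
    u <- ramp_phase(t_grid, tr[i, ], config)
    ramp_scal <- smoothstep(u / lt_ref)
    ramp_abs <- smoothstep(u / 1)
    if (is.na(lt)) {             # no lick: freeze the ramp where it got stuck
      ramp_scal <- pmin(ramp_scal, 1)
    }
    stim_mask <- if (isTRUE(tr$perturbed[i]) &&
                     identical(tr$pert_target[i], "ALM")) {
      t_grid >= tr$pert_onset[i] & t_grid < tr$pert_onset[i] +
        tr$pert_duration[i]
    } else rep(FALSE, length(t_grid))

    # rate matrix: units x time
    ramp_mat <- outer(units_gt$gain * units_gt$scalable, ramp_scal) +
      outer(units_gt$gain * !units_gt$scalable, ramp_abs)
    ramp_mat[, t_grid < 0] <- 0
    rate <- units_gt$baseline + units_gt$history_coef * z[i] + ramp_mat
    if (any(stim_mask)) {
      alm <- units_gt$area == "ALM"
      rate[alm, stim_mask] <- rate[alm, stim_mask] * config$silencing_factor
    }
    rate <- pmax(rate, 0)
    counts <- matrix(rpois(length(rate), rate * dt), nrow = n_u)
    hit <- which(counts > 0, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      times <- t_grid[hit[, 2]] + runif(nrow(hit)) * dt +
        tr$cue_onset[i]
      reps <- counts[hit]
      spike_unit[[i]] <- rep(units_gt$unit_id[hit[, 1]], reps)
      spike_time[[i]] <- rep(times, reps)
    }
  }
  spikes <- tibble::tibble(unit_id = unlist(spike_unit) %||% character(0),
                           time_s = unlist(spike_time) %||% numeric(0)) |>
    dplyr::arrange(.data$unit_id, .data$time_s)

  total_time <- sum(tr$iti_duration) +
    sum(pmin(dplyr::coalesce(tr$first_lick_time, 5), 5) + 1.5)
  units <- tibble::tibble(
    unit_id = units_gt$unit_id, area = units_gt$area,
    mean_rate = as.numeric(table(factor(spikes$unit_id,
                                        levels = units_gt$unit_id))) /
      total_time,
    spike_width = ifelse(units_gt$area == "ALM", 0.6, 0.45),
    post_spike_suppression = ifelse(units_gt$area == "ALM", NA_real_, 30),
    long_isi_fraction = 0.2)

  out_session <- new_session(tr, units, spikes,
                             animal_id = session$animal_id,
                             session_id = session$session_id,
                             condition = session$condition)
  list(session = out_session,
       ground_truth = list(units = units_gt, trials = gt_trials))
}
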