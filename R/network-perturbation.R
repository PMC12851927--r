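#' Perturbation protocol for network simulations
#'
#' Optogenetic-style negative currents: ALM silencing injects `amplitude`
#' (default -10) into every ALM unit; D1-SPN inhibition injects the
#' variant-specific amplitude into the configured striatal target units.
#' Transient protocols start 0.6 s after the cue and last 0.6 s including a
#' 0.3-s linear ramp-down of the current; the prolonged protocol keeps the
#' current on for the rest of the trial with no ramp.
#'
#' @param target `"alm_silencing"` or `"d1_inhibition"`.
#' @param onset Seconds after cue (default 0.6).
#' @param duration Total stimulus duration (default 0.6).
#' @param ramp_down Final linearly decaying portion (default 0.3).
#' @param amplitude Current amplitude; `NULL` uses -10 for ALM silencing and
#'   the variant default for D1 inhibition.
#' @param prolonged If `TRUE`, current stays on from `onset` to the end of
#'   the trial, without a ramp.
#' @return A `stim_protocol` list.
#' @export
stim_protocol <- function(target = c("alm_silencing", "d1_inhibition"),
                          onset = 0.6, duration = 0.6, ramp_down = 0.3,
                          amplitude = NULL, prolonged = FALSE) {
  target <- match.arg(target)
  stopifnot(duration > 0, ramp_down >= 0, ramp_down <= duration)
  structure(list(target = target, onset = onset, duration = duration,
                 ramp_down = ramp_down, amplitude = amplitude,
                 prolonged = prolonged),
            class = "stim_protocol")
}

stim_current_fn <- function(config, protocol) {
  if (is.null(protocol)) return(NULL)
  n <- length(config$units)
  vec <- rep(0, n)
  if (protocol$target == "alm_silencing") {
    vec[config$areas == "ALM"] <- protocol$amplitude %||% -10
  } else {
    vec[config$units %in% config$d1_units] <-
      protocol$amplitude %||% config$d1_amp
  }
  on <- protocol$onset
  off <- on + protocol$duration
  t_full <- off - protocol$ramp_down
  function(t) {
    if (t < on) return(rep(0, n))
    if (protocol$prolonged) return(vec)
    if (t >= off) return(rep(0, n))
    if (t < t_full) return(vec)
    vec * (1 - (t - t_full) / protocol$ramp_down)
  }
}

#' Simulate one trial of a built variant
#'
#' Integrates the network from its rest state with the variant's external
#' input (step or ramp from the cue at t = 0, plus the cue-like transient
#' for feedforward variants) and an optional perturbation protocol.
#'
#' @param config A calibrated `network_config` from [build_variant()].
#' @param stim Optional [stim_protocol()].
#' @param step_amp Step amplitude (defaults to the tuned `config$step_amp`).
#' @param t_pre Pre-cue time simulated (s).
#' @param t_max Post-cue time simulated (s).
#' @return A `network_trajectory`.
#' @export
simulate_variant_trial <- function(config, stim = NULL,
                                   step_amp = config$step_amp,
                                   t_pre = 0.5, t_max = 3.5) {
  n <- length(config$units)
  ramp_input <- identical(config$input_kind %||% "step", "ramp")
  step_vec <- config$step_vec
  cue_vec <- config$cue_vec
  cue_amp <- config$cue_amp
  cue_dur <- config$cue_duration
  cue_ramp <- config$cue_ramp
  I_ext <- function(t) {
    out <- if (t < 0) rep(0, n)
           else if (ramp_input) step_vec * step_amp * t
           else step_vec * step_amp
    if (!is.null(cue_vec) && t >= 0 && t < cue_dur) {
      s <- if (t < cue_dur - cue_ramp) 1
           else 1 - (t - (cue_dur - cue_ramp)) / cue_ramp
      out <- out + cue_vec * cue_amp * s
    }
    out
  }
  integrate_dynamics(config, duration = t_pre + t_max,
                     I_ext = I_ext, I_stim = stim_current_fn(config, stim),
                     t0 = -t_pre)
}

# area ramp mode from a control trajectory: mean rate 0.2-0.5 s before the
# (model) lick minus mean rate 0-1 s before the cue, unit-normalized per area
area_ramp_modes <- function(config, control_traj, lick_time) {
  t <- control_traj$times
  pre_lick <- t >= lick_time - 0.5 & t < lick_time - 0.2
  pre_cue <- t >= -1 & t < 0
  if (!any(pre_cue)) pre_cue <- t < 0
  w <- colMeans(control_traj$r[pre_lick, , drop = FALSE]) -
    colMeans(control_traj$r[pre_cue, , drop = FALSE])
  modes <- list()
  for (ar in unique(config$areas)) {
    v <- w * (config$areas == ar)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) abort(paste0("degenerate ramp mode in area ", ar))
    modes[[ar]] <- v / nv
  }
  modes
}

# normalized ramp-mode activity: 0 at the target neuron's baseline,
# 1 at the time the target neuron reaches 10 spikes/s in the control trial
normalize_ramp <- function(proj, proj_at_baseline, proj_at_10) {
  (proj - proj_at_baseline) / (proj_at_10 - proj_at_baseline)
}

#' Run a perturbation experiment on a model variant
#'
#' Simulates a control trial and a perturbed trial, defines the per-area
#' ramp modes from the control activity (same window rule as for recorded
#' populations), normalizes the ramp-mode projection so 0 is the target
#' neuron's baseline and 1 the level at which the target neuron reaches 10
#' spikes/s, and reads out the model lick time as the moment normalized
#' target-area ramp activity reaches 1.
#'
#' @param config A calibrated `network_config` from [build_variant()].
#' @param protocol A [stim_protocol()] (or one of the strings
#'   `"alm_silencing"`, `"d1_inhibition"`).
#' @param input_levels Optional vector of step amplitudes; default the tuned
#'   amplitude only.
#' @param t_max Post-cue simulation span (s).
#' @return A `network_experiment`: list with `ramp` (tibble: time, area,
#'   condition, input level, normalized ramp activity), `lick_times`
#'   (tibble), `trajectories` (list of `network_trajectory`), `modes`,
#'   `config`, `protocol`.
#' @export
run_perturbation_experiment <- function(config, protocol,
                                        input_levels = NULL, t_max = 3.5) {
  if (is.character(protocol)) protocol <- stim_protocol(protocol)
  input_levels <- input_levels %||% config$step_amp
  target_area <- config$areas[config$units == config$target_unit]
  out_ramp <- list()
  out_lick <- list()
  trajs <- list()
  for (amp in input_levels) {
    ctrl <- simulate_variant_trial(config, stim = NULL, step_amp = amp,
                                   t_pre = 1.2, t_max = t_max)
    stim <- simulate_variant_trial(config, stim = protocol, step_amp = amp,
                                   t_pre = 1.2, t_max = t_max)
    t10 <- crossing_time(ctrl, config$target_unit, 10)
    if (is.na(t10)) abort("control trial never reaches 10 spikes/s.")
    modes <- area_ramp_modes(config, ctrl, t10)
    base_rate <- config$rest_h[config$units == config$target_unit]
    for (cond in c("control", "stim")) {
      tr <- if (cond == "control") ctrl else stim
      for (ar in names(modes)) {
        proj <- drop(tr$r %*% modes[[ar]])
        p0 <- mean(proj[tr$times < 0])
        p10 <- drop(ctrl$r[which(ctrl$times >= t10)[1], , drop = FALSE] %*%
                      modes[[ar]])
        val <- normalize_ramp(proj, p0, p10)
        out_ramp[[length(out_ramp) + 1L]] <- tibble::tibble(
          time = tr$times, area = ar, condition = cond, input = amp,
          ramp = val)
        if (ar == target_area) {
          idx <- which(tr$times >= 0 & val >= 1)
          out_lick[[length(out_lick) + 1L]] <- tibble::tibble(
            condition = cond, input = amp,
            lick_time = if (length(idx) == 0) NA_real_ else tr$times[idx[1]])
        }
      }
    }
    trajs[[as.character(amp)]] <- list(control = ctrl, stim = stim,
                                       modes = modes, t10 = t10)
  }
  structure(list(ramp = purrr::list_rbind(out_ramp),
                 lick_times = purrr::list_rbind(out_lick),
                 trajectories = trajs, config = config, protocol = protocol),
            class = "network_experiment")
}

ramp_of <- function(exp, area, cond, input = NULL) {
  d <- exp$ramp
  input <- input %||% d$input[1]
  d <- d[d$area == area & d$condition == cond & d$input == input, ]
  d
}

#' Classify the ALM-silencing response of a model
#'
#' Automated signature classifier for the target-area ramp under transient
#' ALM silencing. Signatures:
#' * `"parallel_resume"` — the ramp resumes after the stimulus from its
#'   pre-stimulus level at the control slope, and the model lick is delayed
#'   by roughly the effective silencing duration (the pause signature).
#' * `"reconverge"` — the perturbed ramp catches up with the control
#'   trajectory (lick shift near 0).
#' * `"reset"` — the ramp restarts near baseline after the stimulus.
#'
#' @param experiment A `network_experiment` run with an ALM-silencing
#'   protocol.
#' @return List with `label` and the decision `metrics`.
#' @export
classify_silencing_response <- function(experiment) {
  cfg <- experiment$config
  target_area <- cfg$areas[cfg$units == cfg$target_unit]
  p <- experiment$protocol
  off <- p$onset + p$duration
  ctrl <- ramp_of(experiment, target_area, "control")
  stim <- ramp_of(experiment, target_area, "stim")
  lk <- experiment$lick_times
  shift <- lk$lick_time[lk$condition == "stim"][1] -
    lk$lick_time[lk$condition == "control"][1]
  at <- function(d, t) approx(d$time, d$ramp, xout = t, rule = 2)$y
  lvl_onset <- at(ctrl, p$onset)
  lvl_resume <- at(stim, off + 0.1)
  slope <- function(d, t1, t2) (at(d, t2) - at(d, t1)) / (t2 - t1)
  slope_ratio <- slope(stim, off + 0.1, off + 0.4) /
    slope(ctrl, p$onset - 0.3, p$onset)
  level_ratio <- lvl_resume / lvl_onset
  metrics <- tibble::tibble(shift = shift, level_ratio = level_ratio,
                            slope_ratio = slope_ratio)
  label <- if (!is.na(shift) && abs(shift) < 0.1) "reconverge"
    else if (level_ratio < 0.3) "reset"
    else if (level_ratio > 0.6 && level_ratio < 1.4 &&
             slope_ratio > 0.7 && slope_ratio < 1.3 &&
             !is.na(shift) && shift > 0.25 && shift < 0.9) "parallel_resume"
    else "other"
  list(label = label, metrics = metrics)
}

#' Classify the D1-inhibition response of a model
#'
#' Distinguishes the rewind signature — the striatal ramp decays
#' *gradually* during the stimulus and resumes from the decayed level with
#' no jump back toward control — from a follower's jump recovery, in which
#' the deficit closes almost immediately after stimulus offset.
#'
#' @param experiment A `network_experiment` run with a D1-inhibition
#'   protocol.
#' @return List with `label` (`"gradual_decay_no_jump"`, `"jump_recovery"`
#'   or `"other"`) and the decision `metrics`.
#' @export
classify_d1_response <- function(experiment) {
  p <- experiment$protocol
  ctrl <- ramp_of(experiment, "STR", "control")
  stim <- ramp_of(experiment, "STR", "stim")
  at <- function(d, t) approx(d$time, d$ramp, xout = t, rule = 2)$y
  t_full <- p$onset + p$duration - p$ramp_down
  off <- p$onset + p$duration
  d_full <- at(ctrl, t_full) - at(stim, t_full)     # deficit at full strength end
  d_post <- at(ctrl, off + 0.1) - at(stim, off + 0.1)
  # gradual: deficit 50 ms after onset is a small fraction of d_full
  d_early <- at(ctrl, p$onset + 0.05) - at(stim, p$onset + 0.05)
  frac_early <- d_early / d_full
  frac_post <- d_post / d_full
  metrics <- tibble::tibble(deficit = d_full, frac_early = frac_early,
                            frac_post = frac_post)
  label <- if (d_full <= 0) "other"
    else if (frac_post < 0.3) "jump_recovery"
    else if (frac_early < 0.5 && frac_post > 0.6) "gradual_decay_no_jump"
    else "other"
  list(label = label, metrics = metrics)
}

#' @method autoplot network_experiment
#' @export
autoplot.network_experiment <- function(object, ...) {
  ggplot2::ggplot(object$ramp,
                  ggplot2::aes(x = .data$time, y = .data$ramp,
                               colour = .data$condition,
                               linetype = .data$area,
                               group = interaction(.data$condition,
                                                   .data$area,
                                                   .data$input))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::labs(x = "time from cue (s)", y = "normalized ramp-mode activity") +
    ggplot2::theme_classic()
}
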