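#' Threshold-linear rate network configuration
#'
#' Dynamics of a small population-rate network:
#' `tau dh_i/dt = -h_i + sum_j W_ij r_j + I_base_i + I_ext_i(t) + I_stim_i(t)`
#' with `r = f(h) = max(h, 0)`. Temporal integration arises from the
#' eigenstructure of `W`: an eigenvalue of exactly 1 makes the network a
#' continuous (line) attractor along the corresponding mode, an eigenvalue
#' below 1 a leaky integrator, and chains of sub-unity recurrent modules
#' with feedforward links amplify input without any single perfect
#' integrator.
#'
#' @param W Square connectivity matrix (post x pre), with unit names as
#'   dimnames.
#' @param areas Character vector assigning each unit to `"ALM"` or `"STR"`.
#' @param tau Membrane time constant in seconds (default 0.01).
#' @param dt Integration step in seconds (default 1e-4); must satisfy
#'   `dt <= tau / 10`.
#' @param rest_h Desired fixed-point membrane currents (the lower attractor);
#'   used by [calibrate_baseline()].
#' @param I_base Baseline currents; usually filled in by
#'   [calibrate_baseline()].
#' @param target_unit Name of the readout neuron whose baseline and 10
#'   spikes/s crossing anchor the ramp-mode normalization.
#' @param step_vec Input weight vector of the step (desired-lick-time)
#'   input.
#' @param step_amp Default step amplitude.
#' @param cue_vec Optional input axis of the transient cue-like input
#'   (feedforward variants), orthogonal to the amplified direction.
#' @param cue_amp,cue_duration,cue_ramp Cue transient parameters (s).
#' @param d1_units,d1_amp Units targeted by D1-SPN inhibition and the
#'   default (negative) current amplitude.
#' @param variant Variant id string.
#' @return A `network_config` list.
#' @export
network_config <- function(W, areas, tau = 0.01, dt = 1e-4,
                           rest_h = NULL, I_base = NULL,
                           target_unit = NULL,
                           step_vec = NULL, step_amp = 0,
                           cue_vec = NULL, cue_amp = 0,
                           cue_duration = 0.6, cue_ramp = 0.45,
                           d1_units = NULL, d1_amp = -0.1,
                           variant = "custom") {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) abort("W must be square.")
  stopifnot(tau > 0)
  n <- nrow(W)
  nm <- rownames(W) %||% paste0("u", seq_len(n))
  dimnames(W) <- list(nm, nm)
  structure(list(W = W, areas = areas, tau = tau, dt = dt,
                 rest_h = rest_h %||% rep(0, n),
                 I_base = I_base, target_unit = target_unit %||% nm[1],
                 step_vec = step_vec %||% rep(0, n), step_amp = step_amp,
                 cue_vec = cue_vec, cue_amp = cue_amp,
                 cue_duration = cue_duration, cue_ramp = cue_ramp,
                 d1_units = d1_units, d1_amp = d1_amp,
                 units = nm, variant = variant),
            class = "network_config")
}

#' Forward-Euler integration of the network dynamics
#'
#' @param config A [network_config()] with `I_base` set (see
#'   [calibrate_baseline()]).
#' @param duration Simulated time in seconds, starting at `t0`.
#' @param I_ext,I_stim Optional functions of time returning the external /
#'   perturbation current vector (length = number of units).
#' @param h0 Initial membrane currents (defaults to the calibrated rest
#'   state).
#' @param t0 Start time (default 0).
#' @return A `network_trajectory`: list with `times`, matrices `h` and `r`
#'   (time x units), and the config. Integration aborts with an error naming
#'   the first diverging unit if any |h| exceeds 1e6.
#' @export
integrate_dynamics <- function(config, duration, I_ext = NULL, I_stim = NULL,
                               h0 = NULL, t0 = 0) {
  if (config$dt > config$tau / 10) {
    abort("dt must be <= tau / 10 for stable forward Euler.")
  }
  if (is.null(config$I_base)) {
    abort("config has no I_base; run calibrate_baseline() first.")
  }
  n <- length(config$units)
  n_steps <- ceiling(duration / config$dt)
  times <- t0 + (seq_len(n_steps + 1L) - 1L) * config$dt
  H <- matrix(0, n_steps + 1L, n, dimnames = list(NULL, config$units))
  h <- h0 %||% config$rest_h
  H[1L, ] <- h
  W <- config$W
  a <- config$dt / config$tau
  # total input per step, precomputed (a function is evaluated on the grid;
  # a matrix of n_steps (+1) x units rows is used as is)
  as_input_mat <- function(inp) {
    if (is.null(inp)) return(NULL)
    if (is.matrix(inp)) return(inp)
    t(vapply(times[seq_len(n_steps)], inp, numeric(n)))
  }
  Imat <- matrix(config$I_base, n_steps, n, byrow = TRUE)
  ext <- as_input_mat(I_ext)
  if (!is.null(ext)) Imat <- Imat + ext[seq_len(n_steps), , drop = FALSE]
  stm <- as_input_mat(I_stim)
  if (!is.null(stm)) Imat <- Imat + stm[seq_len(n_steps), , drop = FALSE]
  for (s in seq_len(n_steps)) {
    h <- h + a * (-h + drop(W %*% pmax(h, 0)) + Imat[s, ])
    if (any(abs(h) > 1e6)) {
      abort(paste0("dynamics diverged at unit ",
                   config$units[which.max(abs(h))], " (t = ",
                   round(times[s], 4), " s)."))
    }
    H[s + 1L, ] <- h
  }
  structure(list(times = times, h = H, r = pmax(H, 0), config = config),
            class = "network_trajectory")
}

#' @method tidy network_trajectory
#' @export
tidy.network_trajectory <- function(x, ...) {
  n <- length(x$config$units)
  tibble::tibble(
    time = rep(x$times, times = n),
    unit = rep(x$config$units, each = length(x$times)),
    area = rep(x$config$areas, each = length(x$times)),
    rate = as.vector(x$r))
}

#' Calibrate baseline currents for the lower attractor
#'
#' Solves `I_base = h* - W f(h*)` so that the no-input steady state sits at
#' the configured rest profile, scaled so the target neuron fires at
#' `target_rate` (default 5 spikes/s), and verifies the stability of the
#' active linearization: every eigenvalue of `W` restricted to the active
#' (above-threshold) units must have real part at most 1 (an eigenvalue of
#' exactly 1 is the marginal, line-attractor direction).
#'
#' @param config A [network_config()].
#' @param target_rate Desired rate of the target neuron at rest (spikes/s).
#' @return The config with `I_base` and `rest_h` filled in.
#' @export
calibrate_baseline <- function(config, target_rate = 5) {
  rest <- config$rest_h
  tgt <- which(config$units == config$target_unit)
  if (rest[tgt] > 0) rest <- rest * (target_rate / rest[tgt])
  active <- rest > 1e-12
  if (any(active)) {
    Wa <- config$W[active, active, drop = FALSE]
    ev <- Re(eigen(Wa, only.values = TRUE)$values)
    if (any(ev > 1 + 1e-8)) {
      abort(paste0("no stable low-rate fixed point: leading active ",
                   "eigenvalue ", round(max(ev), 6), " exceeds 1."))
    }
  }
  config$I_base <- rest - drop(config$W %*% pmax(rest, 0))
  config$rest_h <- rest
  config
}
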