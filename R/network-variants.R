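#' Integrator model zoo
#'
#' Ids of the implemented cortico-striatal integrator architectures. The six
#' positive-feedback variants use two neurons per area (`a1`, `a2` in ALM;
#' `s1`, `s2` in striatum; the readout target is the first striatal neuron,
#' except in the leaky variant where it is the second); the two feedforward
#' variants chain three two-neuron recurrent modules. Exact connectivity
#' values are synthesized from the architectural constraints each variant
#' must satisfy (eigenstructure, area wiring, a stable 5 spikes/s lower
#' fixed point) and are recorded in the built config.
#'
#' * `externally_driven` — no internal integration (all eigenvalues 0); ALM
#'   follows a ramping external input whose slope sets the lick time.
#' * `distributed` — integration lives only in the interareal loop
#'   (`a1 <-> s1`, loop gain 1); cutting the long-range connections
#'   abolishes slow dynamics.
#' * `redundant` — two identical, weakly coupled eigenvalue-1 integrators,
#'   one per area; eigenvalues are exactly {1, 1, 0, 0}.
#' * `specialized_ALM` — ALM integrates (self-weight 1), striatum follows.
#' * `ALM_leaky` — a leaky cortico-striatal loop (leading eigenvalue
#'   sqrt(0.95) < 1).
#' * `specialized_STR` — the striatum integrates; ALM provides the drive
#'   through a baseline-zero relay carrying the above-baseline cortical
#'   rate, and otherwise follows the striatal ramp.
#' * `feedforward_ALM`, `feedforward_STR` — chains of sub-unity recurrent
#'   modules with feedforward links and global inhibitory baseline; the step
#'   input enters the first module's ALM (or striatal) neuron and a
#'   cue-like transient (600 ms, 450-ms linear ramp-down) enters along an
#'   axis orthogonal to the amplified direction.
#'
#' @return Character vector of variant ids.
#' @export
network_variants <- function() {
  c("externally_driven", "distributed", "redundant", "specialized_ALM",
    "ALM_leaky", "specialized_STR", "feedforward_ALM", "feedforward_STR")
}

# D1-SPN inhibition current amplitude per positive-feedback variant,
# chosen to keep the perturbation effect on the striatal ramp comparable.
d1_amplitudes <- c(externally_driven = -0.3, distributed = -0.1,
                   redundant = -0.1, specialized_ALM = -0.2,
                   ALM_leaky = -0.02, specialized_STR = -0.03,
                   feedforward_ALM = -0.05, feedforward_STR = -0.05)

build_variant_raw <- function(variant) {
  four <- function() {
    W <- matrix(0, 4, 4, dimnames = list(c("a1", "a2", "s1", "s2"),
                                         c("a1", "a2", "s1", "s2")))
    W
  }
  areas4 <- c("ALM", "ALM", "STR", "STR")
  rest5 <- rep(5, 4)
  amp <- unname(d1_amplitudes[variant])
  switch(
    variant,
    externally_driven = {
      W <- four()
      W["a2", "a1"] <- 0.8; W["s1", "a1"] <- 0.8; W["s2", "s1"] <- 0.8
      cfg <- network_config(W, areas4, rest_h = rest5, target_unit = "s1",
                            step_vec = c(1, 0, 0, 0), step_amp = 4.8,
                            d1_units = "s1", d1_amp = amp, variant = variant)
      cfg$input_kind <- "ramp"          # input slope scales with desired lick time
      cfg
    },
    distributed = {
      W <- four()
      W["a1", "s1"] <- 1; W["s1", "a1"] <- 1
      W["a2", "a1"] <- 0.8; W["s2", "s1"] <- 0.8
      network_config(W, areas4, rest_h = rest5, target_unit = "s1",
                     step_vec = c(1, 0, 0, 0), step_amp = 0.0769,
                     d1_units = "s1", d1_amp = amp, variant = variant)
    },
    redundant = {
      W <- four()
      W["a1", "a1"] <- 1; W["s1", "s1"] <- 1
      W["a2", "a1"] <- 0.4; W["a2", "s1"] <- 0.4; W["s2", "s1"] <- 0.8
      network_config(W, areas4, rest_h = rest5, target_unit = "s1",
                     step_vec = c(1, 0, 1, 0), step_amp = 0.0385,
                     d1_units = "s1", d1_amp = amp, variant = variant)
    },
    specialized_ALM = {
      W <- four()
      W["a1", "a1"] <- 1
      W["a2", "a1"] <- 0.8; W["s1", "a1"] <- 0.8; W["s2", "s1"] <- 0.8
      network_config(W, areas4, rest_h = rest5, target_unit = "s1",
                     step_vec = c(1, 0, 0, 0), step_amp = 0.048,
                     d1_units = "s1", d1_amp = amp, variant = variant)
    },
    ALM_leaky = {
      W <- four()
      W["a1", "s1"] <- 0.95 / 0.8; W["s1", "a1"] <- 0.8
      W["a2", "a1"] <- 0.8; W["s2", "s1"] <- 0.8
      network_config(W, areas4, rest_h = rest5, target_unit = "s2",
                     step_vec = c(1, 0, 0, 0), step_amp = 0.35,
                     d1_units = "s1", d1_amp = amp, variant = variant)
    },
    specialized_STR = {
      W <- four()
      W["s2", "a1"] <- 1               # baseline-zero relay of cortical drive
      W["s1", "s1"] <- 1; W["s1", "s2"] <- 0.5
      W["a2", "s1"] <- 0.8
      network_config(W, areas4, rest_h = c(5, 5, 5, 0), target_unit = "s1",
                     step_vec = c(1, 0, 0, 0), step_amp = 0.0769,
                     d1_units = "s1", d1_amp = amp, variant = variant)
    },
    feedforward_ALM = ,
    feedforward_STR = {
      nm <- c("a1", "s1", "a2", "s2", "a3", "s3")
      W <- matrix(0, 6, 6, dimnames = list(nm, nm))
      # slow recurrent modules (eigenvalue 0.95 < 1) with near-marginal
      # interstage links: each stage roughly reproduces its input, so the
      # crossing time of the last module is a smooth, monotone function of
      # the step amplitude (graded speed control)
      w_rec <- 0.95; w_ff <- 0.1
      for (m in 1:3) {
        a <- paste0("a", m); s <- paste0("s", m)
        W[a, s] <- w_rec; W[s, a] <- w_rec
        if (m < 3) {
          W[paste0("a", m + 1), a] <- w_ff
          W[paste0("s", m + 1), s] <- w_ff
        }
      }
      step_vec <- rep(0, 6)
      step_vec[if (variant == "feedforward_STR") 2 else 1] <- 1
      cue_vec <- c(1, -1, 0, 0, 0, 0) / sqrt(2)  # orthogonal to (1,1) module axis
      cfg <- network_config(W, rep(c("ALM", "STR"), 3),
                            rest_h = rep(0, 6), target_unit = "a3",
                            step_vec = step_vec, step_amp = 2.05,
                            cue_vec = cue_vec, cue_amp = 0.5,
                            d1_units = c("s2", "s3"), d1_amp = amp,
                            variant = variant)
      cfg$I_base_override <- rep(-0.5, 6)   # global inhibition
      cfg
    },
    abort(paste0("unknown variant: ", variant))
  )
}

check_variant_constraints <- function(config) {
  ev <- eigen(config$W, only.values = TRUE)$values
  lead <- max(Re(ev))
  v <- config$variant
  ok <- switch(
    v,
    externally_driven = abs(lead) < 1e-9,
    distributed = abs(lead - 1) < 1e-9,
    redundant = sum(abs(Mod(ev) - 1) < 1e-9) == 2,
    specialized_ALM = abs(lead - 1) < 1e-9,
    ALM_leaky = lead < 1 - 1e-9,
    specialized_STR = abs(lead - 1) < 1e-9,
    feedforward_ALM = ,
    feedforward_STR = lead < 1 - 1e-9,
    TRUE)
  if (!ok) {
    abort(paste0("variant ", v, " failed its eigenstructure check ",
                 "(leading eigenvalue ", round(lead, 6), ")."))
  }
  invisible(config)
}

#' Build a named integrator variant
#'
#' Constructs the connectivity, rest state and input routing of one of the
#' architectures in [network_variants()], calibrates the baseline currents
#' for the 5 spikes/s lower attractor (global inhibition for the
#' feedforward chains), verifies the variant's eigenstructure at build time,
#' and optionally tunes the step-input amplitude so the control lick time
#' (target neuron crossing 10 spikes/s) lands at `target_lick_time`.
#'
#' @param variant One of [network_variants()].
#' @param target_lick_time Desired control lick time in seconds (default
#'   1.3).
#' @param tune Numerically tune the step amplitude? (default TRUE; when
#'   FALSE the stored analytic approximation is used).
#' @return A calibrated `network_config`.
#' @export
build_variant <- function(variant = network_variants(),
                          target_lick_time = 1.3, tune = TRUE) {
  variant <- match.arg(variant)
  cfg <- build_variant_raw(variant)
  check_variant_constraints(cfg)
  cfg <- calibrate_baseline(cfg, target_rate = 5)
  if (!is.null(cfg$I_base_override)) cfg$I_base <- cfg$I_base_override
  if (tune) cfg <- tune_step_input(cfg, target_lick_time)
  cfg
}

#' Tune the step input to a target lick time
#'
#' Adjusts the step amplitude by root finding so that the target neuron's
#' rate crosses 10 spikes/s at `target_lick_time` in an unperturbed trial
#' (the speed of the dynamics is a monotone function of the input strength).
#'
#' @param config A calibrated `network_config`.
#' @param target_lick_time Seconds after cue.
#' @return The config with `step_amp` updated.
#' @export
tune_step_input <- function(config, target_lick_time = 1.3) {
  # ignore crossings during the cue transient (cue-evoked bump, not the ramp)
  min_t <- if (!is.null(config$cue_vec)) config$cue_duration else 0
  t10 <- function(amp) {
    tr <- simulate_variant_trial(config, stim = NULL, step_amp = amp,
                                 t_pre = 0.1,
                                 t_max = 3 * target_lick_time)
    crossing_time(tr, config$target_unit, 10, after = min_t)
  }
  f <- function(amp) {
    ct <- t10(amp)
    if (is.na(ct)) return(10)          # too weak: never crosses
    ct - target_lick_time
  }
  lo <- config$step_amp / 10
  hi <- config$step_amp * 10
  root <- tryCatch(uniroot(f, c(lo, hi), tol = 1e-5)$root,
                   error = function(e) NA_real_)
  if (is.na(root)) {
    abort(paste0("could not tune step input for variant ", config$variant))
  }
  config$step_amp <- root
  config
}

#' First time a unit's rate crosses a level
#'
#' @param traj A `network_trajectory`.
#' @param unit Unit name.
#' @param level Rate threshold (spikes/s).
#' @param after Ignore crossings before this time (s).
#' @return Crossing time in seconds, or `NA`.
#' @export
crossing_time <- function(traj, unit, level, after = 0) {
  r <- traj$r[, unit]
  idx <- which(traj$times >= after & r >= level)
  if (length(idx) == 0) return(NA_real_)
  traj$times[idx[1]]
}
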