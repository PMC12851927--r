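#' Timer (accumulator) model configuration
#'
#' The timer represents elapsed time as the integral `T(t)` of a constant
#' inflow rate `r`; a lick is triggered when `T(t)` reaches the threshold
#' `theta`. `r` varies across trials (constant within a trial): a target
#' first-passage time `t*` is drawn from an inverse Gaussian IG(mu, lambda)
#' matched to the empirical lick-time distribution, and `r = theta / t*`, so
#' the unmanipulated lick time reproduces `t*` exactly.
#'
#' @param theta Threshold (default 1).
#' @param mu,lambda Inverse-Gaussian mean (s) and shape of the target
#'   lick-time distribution (defaults 1.3 and 12).
#' @param n_trials Number of simulated trials (default 10,000).
#' @param dt Integration step in seconds (default 0.001; steps coarser than
#'   0.01 s are refused as an accuracy guard).
#' @param t_max Simulation horizon in seconds (default 5; trials that have
#'   not licked by then are no-lick).
#' @return A `timer_config` list.
#' @export
timer_config <- function(theta = 1, mu = 1.3, lambda = 12,
                         n_trials = 10000L, dt = 0.001, t_max = 5) {
  stopifnot(theta > 0, mu > 0, lambda > 0, dt > 0, t_max > 0)
  if (dt > 0.01) abort("dt coarser than 10 ms is refused (accuracy guard).")
  structure(list(theta = theta, mu = mu, lambda = lambda,
                 n_trials = as.integer(n_trials), dt = dt, t_max = t_max),
            class = "timer_config")
}

#' Timer manipulation descriptor
#'
#' Two transient perturbations of the running timer, both lasting
#' `duration` seconds with the final `ramp_down` seconds at linearly
#' decaying strength (matching the optogenetic light profile):
#'
#' * **pause / slowdown** — the inflow rate is multiplied by the speed
#'   coefficient `c` (`c = 0` full pause, `0 < c < 1` slowdown); during the
#'   ramp the effective rate interpolates linearly from `c * r` back to `r`.
#' * **rewind** — the inflow is replaced by a negative rate `r_decay`, so the
#'   accumulated state itself decreases; during the ramp the effective rate
#'   interpolates from `r_decay` back to `r`. The state is clamped at zero,
#'   and if it dwells at zero continuously for more than
#'   `zero_dwell_nolick` seconds the timer is fixed at zero for the rest of
#'   the trial (a no-lick outcome).
#'
#' @param kind `"none"`, `"pause"` or `"rewind"`.
#' @param onset Manipulation onset, seconds after cue (default 0.6).
#' @param duration Total duration in seconds (default 0.6).
#' @param ramp_down Final portion with linearly decaying strength (default
#'   0.3).
#' @param c Speed coefficient for pause/slowdown (default 0.5).
#' @param r_decay Negative rewind rate; `NULL` (default) uses `-2 * r` per
#'   trial, which empties a typical trial's accumulated state well within
#'   the full-strength phase.
#' @param zero_dwell_nolick Continuous zero-dwell beyond which the trial
#'   becomes no-lick (default 0.32 s).
#' @return A `timer_manipulation` list.
#' @export
timer_manipulation <- function(kind = c("none", "pause", "rewind"),
                               onset = 0.6, duration = 0.6, ramp_down = 0.3,
                               c = 0.5, r_decay = NULL,
                               zero_dwell_nolick = 0.32) {
  kind <- match.arg(kind)
  stopifnot(duration > 0, ramp_down >= 0, ramp_down <= duration, c >= 0)
  if (!is.null(r_decay) && r_decay > 0) {
    abort("`r_decay` must be <= 0 for a rewind.")
  }
  structure(list(kind = kind, onset = onset, duration = duration,
                 ramp_down = ramp_down, c = c, r_decay = r_decay,
                 zero_dwell_nolick = zero_dwell_nolick),
            class = "timer_manipulation")
}

#' Draw per-trial inflow rates
#'
#' Draws target lick times `t* ~ IG(mu, lambda)` and sets `r = theta / t*`,
#' so the unmanipulated lick time equals `t*` exactly (up to the integration
#' step).
#'
#' @param config A [timer_config()].
#' @param n Number of trials (defaults to `config$n_trials`).
#' @return A tibble with columns `target_time` (s) and `r`.
#' @export
draw_rates <- function(config, n = config$n_trials) {
  t_star <- rinvgauss(n, config$mu, config$lambda)
  tibble::tibble(target_time = t_star, r = config$theta / t_star)
}

# effective inflow at time t for one trial (scalar reference semantics)
effective_rate <- function(t, r, manip) {
  if (manip$kind == "none") return(r)
  t0 <- manip$onset
  t_full <- t0 + manip$duration - manip$ramp_down
  t_off <- t0 + manip$duration
  strength_rate <- if (manip$kind == "pause") manip$c * r
                   else (manip$r_decay %||% (-2 * r))
  if (t < t0 || t >= t_off) return(r)
  if (t < t_full) return(strength_rate)
  frac <- (t - t_full) / manip$ramp_down     # 0 -> 1 across the ramp
  strength_rate + (r - strength_rate) * frac
}

#' Simulate a single timer trial
#'
#' Forward integration of `dT = r_eff dt` with the manipulation semantics of
#' [timer_manipulation()]. This is the scalar reference implementation; use
#' [simulate_timer_experiment()] for large trial counts.
#'
#' @param r Inflow rate for this trial (> 0).
#' @param manipulation A [timer_manipulation()].
#' @param config A [timer_config()].
#' @return The lick time in seconds, or `NA` for a no-lick outcome.
#' @export
simulate_trial <- function(r, manipulation = timer_manipulation("none"),
                           config = timer_config()) {
  stopifnot(r > 0)
  dt <- config$dt
  T_acc <- 0
  dwell <- 0
  t <- 0
  while (t < config$t_max) {
    r_eff <- effective_rate(t, r, manipulation)
    T_acc <- T_acc + r_eff * dt
    if (T_acc <= 0) {
      T_acc <- 0
      dwell <- dwell + dt
      if (dwell > manipulation$zero_dwell_nolick) return(NA_real_)
    } else {
      dwell <- 0
    }
    t <- t + dt
    if (T_acc >= config$theta) return(t)
  }
  NA_real_
}

#' Simulate many timer trials under one manipulation
#'
#' Vectorized counterpart of [simulate_trial()]: integrates the time grid
#' once with all trials as vectors, then closes the remaining first passage
#' analytically after the manipulation window. Semantics are identical to
#' the scalar path (cross-checked in the test suite).
#'
#' @param r Vector of per-trial inflow rates.
#' @param manipulation A [timer_manipulation()].
#' @param config A [timer_config()].
#' @return Vector of lick times (s), `NA` for no-lick outcomes.
#' @export
simulate_timer_trials <- function(r, manipulation, config) {
  n <- length(r)
  dt <- config$dt
  theta <- config$theta
  if (manipulation$kind == "none") {
    lick <- theta / r
    lick[lick > config$t_max] <- NA_real_
    return(lick)
  }
  t_off <- manipulation$onset + manipulation$duration
  n_steps <- ceiling(t_off / dt)
  T_acc <- numeric(n)
  dwell <- numeric(n)
  lick <- rep(NA_real_, n)
  dead <- logical(n)       # no-lick by zero dwell
  done <- logical(n)
  t0 <- manipulation$onset
  t_full <- t0 + manipulation$duration - manipulation$ramp_down
  base_strength <- if (manipulation$kind == "pause") manipulation$c * r
                   else rep(manipulation$r_decay %||% NA_real_, n)
  if (manipulation$kind == "rewind" && is.null(manipulation$r_decay)) {
    base_strength <- -2 * r
  }
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    if (t < t0 || t >= t_off) {
      r_eff <- r
    } else if (t < t_full) {
      r_eff <- base_strength
    } else {
      frac <- (t - t_full) / manipulation$ramp_down
      r_eff <- base_strength + (r - base_strength) * frac
    }
    act <- !done & !dead
    T_acc[act] <- T_acc[act] + r_eff[act] * dt
    clamp <- act & T_acc <= 0
    T_acc[clamp] <- 0
    dwell[clamp] <- dwell[clamp] + dt
    dwell[act & !clamp] <- 0
    dead[clamp & dwell > manipulation$zero_dwell_nolick] <- TRUE
    hit <- act & !dead & T_acc >= theta
    lick[hit] <- t + dt
    done[hit] <- TRUE
  }
  # past the manipulation: constant rate r, closed-form remaining passage
  open <- !done & !dead
  rest <- t_off + (theta - T_acc[open]) / r[open]
  rest[rest > config$t_max] <- NA_real_
  lick[open] <- rest
  lick
}

#' Simulate a timer experiment across manipulation conditions
#'
#' Draws one shared set of per-trial rates and simulates every condition on
#' the same trials (paired design), returning lick times, hazard curves,
#' sigmoid hazard shifts against control, and no-lick rates, plus example
#' internal `T(t)` trajectories.
#'
#' @param config A [timer_config()].
#' @param manipulations Named list of [timer_manipulation()] objects; a
#'   `"control"` (no manipulation) condition is always added.
#' @param n_example_trajectories Number of per-condition example `T(t)`
#'   traces to record (default 5).
#' @return A `timer_experiment` list with elements `lick_times` (tibble:
#'   condition, trial, target_time, lick_time), `hazard` (named list of
#'   [hazard_rate()] curves), `shifts` (tibble of [hazard_shift()] rows vs
#'   control), `no_lick_rate` (tibble) and `trajectories` (tibble: condition,
#'   trial, t, T).
#' @export
simulate_timer_experiment <- function(config = timer_config(),
                                      manipulations = list(),
                                      n_example_trajectories = 5L) {
  rates <- draw_rates(config)
  conds <- c(list(control = timer_manipulation("none")), manipulations)
  lick <- purrr::imap(conds, function(m, nm) {
    tibble::tibble(condition = nm, trial = seq_len(nrow(rates)),
                   target_time = rates$target_time,
                   lick_time = simulate_timer_trials(rates$r, m, config))
  }) |> purrr::list_rbind()

  hazard <- purrr::map(setNames(names(conds), names(conds)), function(nm) {
    hazard_rate(lick$lick_time[lick$condition == nm], t_max = config$t_max)
  })
  # shift quantification is restricted, in both the control and manipulated
  # distributions, to trials whose lick falls after the manipulation onset
  # (the same restriction applied when comparing photostimulated behaviour)
  shifts <- purrr::map(setdiff(names(conds), "control"), function(nm) {
    on <- conds[[nm]]$onset
    restrict <- function(cond) {
      lt <- lick$lick_time[lick$condition == cond]
      lt[is.na(lt) | lt > on]
    }
    h_ctrl <- hazard_rate(restrict("control"), t_max = config$t_max)
    h_cond <- hazard_rate(restrict(nm), t_max = config$t_max)
    dplyr::mutate(hazard_shift(h_ctrl, h_cond), condition = nm, .before = 1)
  }) |> purrr::list_rbind()
  no_lick <- lick |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(no_lick_rate = mean(is.na(.data$lick_time)))

  traj <- purrr::imap(conds, function(m, nm) {
    idx <- head(order(rates$target_time), n_example_trajectories)
    purrr::map(idx, function(i) {
      tt <- seq(0, config$t_max, by = max(config$dt, 0.005))
      T_path <- timer_trajectory(rates$r[i], m, config, tt)
      tibble::tibble(condition = nm, trial = i, t = tt, T = T_path)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  structure(list(lick_times = lick, hazard = hazard, shifts = shifts,
                 no_lick_rate = no_lick, trajectories = traj,
                 config = config, rates = rates),
            class = "timer_experiment")
}

# dense T(t) path for one trial (for plotting); stops accumulating at lick
timer_trajectory <- function(r, manip, config, times) {
  dt <- config$dt
  grid <- seq(0, max(times), by = dt)
  T_acc <- numeric(length(grid))
  dwell <- 0
  dead <- FALSE
  for (s in seq_along(grid)[-1]) {
    if (dead) { T_acc[s] <- 0; next }
    r_eff <- effective_rate(grid[s - 1], r, manip)
    v <- T_acc[s - 1] + r_eff * dt
    if (v <= 0) {
      v <- 0
      dwell <- dwell + dt
      if (dwell > manip$zero_dwell_nolick) dead <- TRUE
    } else dwell <- 0
    T_acc[s] <- v
    if (v >= config$theta) {
      T_acc[s:length(grid)] <- v
      break
    }
  }
  approx(grid, T_acc, xout = times, rule = 2)$y
}

#' @export
print.timer_experiment <- function(x, ...) {
  cat("<timer_experiment> ", nrow(x$rates), " trials x ",
      length(x$hazard), " conditions\n", sep = "")
  print(x$no_lick_rate)
  if (nrow(x$shifts) > 0) print(x$shifts)
  invisible(x)
}

#' @method autoplot timer_experiment
#' @export
autoplot.timer_experiment <- function(object, what = c("hazard", "cdf", "T"),
                                      ...) {
  what <- match.arg(what)
  if (what == "T") {
    return(ggplot2::ggplot(object$trajectories,
                           ggplot2::aes(x = .data$t, y = .data$T,
                                        group = interaction(.data$condition,
                                                            .data$trial),
                                        colour = .data$condition)) +
             ggplot2::geom_line() + ggplot2::theme_classic() +
             ggplot2::labs(x = "time from cue (s)", y = "timer state T"))
  }
  dat <- purrr::imap(object$hazard, function(h, nm) {
    dplyr::mutate(tibble::as_tibble(h), condition = nm)
  }) |> purrr::list_rbind()
  y <- if (what == "hazard") "h" else "F"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t, y = .data[[y]],
                                    colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::theme_classic() +
    ggplot2::labs(x = "time from cue (s)",
                  y = if (what == "hazard") "hazard (prob. per bin)"
                      else "cumulative fraction licked")
}
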