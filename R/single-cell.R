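#' Temporally warp post-cue spike times
#'
#' Linearly rescales spike times after the cue by the trial's lick time:
#' `t_warped = t * lick_target / lick_time`, so a spike at the lick maps
#' exactly to `lick_target`. Warping a trial whose lick time equals the
#' target is the identity, and spike counts are preserved.
#'
#' @param spike_times Post-cue spike times of one trial, seconds from cue.
#' @param lick_time The trial's first-lick time (s); must be positive.
#' @param lick_target Target warp time (default 1 s).
#' @return Warped spike times.
#' @export
warp_spike_times <- function(spike_times, lick_time, lick_target = 1) {
  if (is.na(lick_time) || lick_time <= 0) {
    abort("`lick_time` must be positive to warp.")
  }
  spike_times * lick_target / lick_time
}

unit_trial_spikes <- function(session, unit_id, trial_rows) {
  st <- session$spikes$time_s[session$spikes$unit_id == unit_id]
  lapply(seq_len(nrow(trial_rows)), function(i) {
    on <- trial_rows$cue_onset[i]
    st[st >= on - 1.5 & st < on + 6] - on
  })
}

#' Across-trial variance, original vs warped
#'
#' Computes the across-trial variance of one unit's firing in five 200-ms
#' windows after the cue (averaged over windows), for the original spike
#' times and for lick-time-warped spike times. For a unit whose activity
#' pattern scales with lick time, warping aligns the pattern across trials
#' and reduces the variance; for an absolute-time unit it does not.
#' Significance of the reduction is assessed by a trial-resampling bootstrap
#' of `var_orig - var_warped` (significant if the 95% CI excludes 0).
#'
#' @param session A `cbg_session`.
#' @param unit_id Unit to analyse.
#' @param trials Optional trial indices (default: all licked cue trials).
#' @param lick_target Target warp time (s); `NULL` (default) uses the median
#'   lick time of the analysed trials, so that warped and original windows
#'   span the same counting duration on average and the comparison is not
#'   confounded by Poisson noise scaling with window duration.
#' @param n_boot Bootstrap iterations (default 1000).
#' @return One-row tibble: `var_orig`, `var_warped`, `reduction`, `ci_low`,
#'   `ci_high`, `significant_reduction`.
#' @export
across_trial_variance <- function(session, unit_id, trials = NULL,
                                  lick_target = NULL, n_boot = 1000L) {
  tr <- session$trials
  if (!is.null(trials)) tr <- tr[tr$trial %in% trials, , drop = FALSE]
  tr <- tr[tr$cue_present & !is.na(tr$first_lick_time), , drop = FALSE]
  if (nrow(tr) < 2) abort("need at least 2 licked trials.")
  lick_target <- lick_target %||% median(tr$first_lick_time)
  spk <- unit_trial_spikes(session, unit_id, tr)
  windows <- cbind(seq(0, 0.8, by = 0.2), seq(0.2, 1, by = 0.2))
  rate_mat <- function(warp) {
    t(vapply(seq_along(spk), function(i) {
      s <- spk[[i]]
      s <- s[s >= 0]
      # rates use the elapsed original time spanned by each window, so that
      # warping rescales the clock along with the spike times (a warped
      # window of 0.2 warped-seconds spans 0.2 * LT / LT_target real seconds)
      dur <- 0.2
      if (warp) {
        s <- warp_spike_times(s, tr$first_lick_time[i], lick_target)
        dur <- 0.2 * tr$first_lick_time[i] / lick_target
      }
      vapply(seq_len(nrow(windows)), function(w) {
        sum(s >= windows[w, 1] & s < windows[w, 2]) / dur
      }, numeric(1))
    }, numeric(nrow(windows))))
  }
  ro <- rate_mat(FALSE)
  rw <- rate_mat(TRUE)
  avg_var <- function(m, idx) mean(apply(m[idx, , drop = FALSE], 2, var))
  n <- nrow(ro)
  v_o <- avg_var(ro, seq_len(n))
  v_w <- avg_var(rw, seq_len(n))
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    avg_var(ro, idx) - avg_var(rw, idx)
  }, numeric(1))
  ci <- quantile(boot, c(0.025, 0.975))
  tibble::tibble(unit_id = unit_id, var_orig = v_o, var_warped = v_w,
                 reduction = v_o - v_w,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 significant_reduction = ci[1] > 0)
}

#' Characterize a unit's ramping profile
#'
#' Polynomial model selection for the cue-to-lick firing profile of one
#' unit, using trials with lick times inside `lick_range` (at least
#' `min_trials`). On each of `n_reps` repeats the trials are split in
#' half at random; polynomial fits of order 1-8 to the training-half PSTH
#' (10-ms lattice, 200-ms causal boxcar) are scored by mean squared error
#' against the test-half PSTH, and the winning order is recorded. The final
#' order is the most frequent winner (ties broken toward the smallest
#' order). The final fit on the full PSTH determines monotonicity (the
#' fitted derivative keeps one sign from cue to lick) and the peak firing
#' time.
#'
#' @param session A `cbg_session`.
#' @param unit_id Unit to analyse.
#' @param lick_range Lick-time window defining the trial group (default
#'   1.25-1.5 s).
#' @param min_trials Minimum qualifying trials (default 50).
#' @param n_reps Number of split-half repeats (default 10).
#' @param orders Candidate polynomial orders (default 1:8).
#' @return A `ramp_fit`: one-row tibble with `order`, `monotonic`,
#'   `peak_time`, `n_trials`, plus the fitted curve as attribute `curve`
#'   (tibble `t`, `rate`).
#' @export
characterize_ramp <- function(session, unit_id, lick_range = c(1.25, 1.5),
                              min_trials = 50, n_reps = 10, orders = 1:8) {
  tr <- session$trials
  tr <- tr[tr$cue_present & !is.na(tr$first_lick_time) &
             tr$first_lick_time >= lick_range[1] &
             tr$first_lick_time <= lick_range[2], , drop = FALSE]
  if (nrow(tr) < min_trials) {
    abort(paste0("unit skipped: only ", nrow(tr), " qualifying trials (< ",
                 min_trials, ")."))
  }
  spk <- unit_trial_spikes(session, unit_id, tr)
  t_end <- min(tr$first_lick_time)
  bs <- 0.01
  grid <- seq(0, t_end - bs, by = bs)
  psth <- function(idx) {
    counts <- rowSums(vapply(idx, function(i) {
      s <- spk[[i]]
      tabulate(pmin(floor(s[s >= 0 & s < t_end] / bs) + 1L, length(grid)),
               nbins = length(grid))
    }, numeric(length(grid))))
    causal_boxcar(counts / (length(idx) * bs), 0.2, bs)
  }
  n <- nrow(tr)
  best_orders <- vapply(seq_len(n_reps), function(rep) {
    half <- sample.int(n, floor(n / 2))
    y_tr <- psth(half)
    y_te <- psth(setdiff(seq_len(n), half))
    mse <- vapply(orders, function(k) {
      fit <- lm(y_tr ~ poly(grid, k, raw = TRUE))
      mean((y_te - predict(fit))^2)
    }, numeric(1))
    orders[which.min(mse)]
  }, numeric(1))
  tab <- table(best_orders)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  final_order <- min(winners)          # parsimony tie-break
  y_all <- psth(seq_len(n))
  fit <- lm(y_all ~ poly(grid, final_order, raw = TRUE))
  curve <- predict(fit)
  dcurve <- diff(curve)
  monotonic <- all(dcurve >= -1e-9) || all(dcurve <= 1e-9)
  out <- tibble::tibble(unit_id = unit_id, order = final_order,
                        monotonic = monotonic,
                        peak_time = grid[which.max(curve)],
                        n_trials = n)
  attr(out, "curve") <- tibble::tibble(t = grid, rate = curve)
  class(out) <- c("ramp_fit", class(out))
  out
}

#' Pre-lick and photostimulation modulation tests
#'
#' Two unit-level tests: (i) pre-lick modulation — the per-trial firing rate
#' 0.2-0.5 s before the lick is compared with the rate 0-1 s before the cue
#' by a two-sided paired signed-rank test; (ii) photostimulation effect —
#' the rate 50-250 ms after the stimulation onset is compared between
#' control and stimulated trials by a two-sided rank-sum test, after
#' excluding trials that licked before the onset, and only for units firing
#' above 1 spikes/s in that window with at least 10 trials per condition.
#'
#' @param session A `cbg_session`.
#' @param unit_id Unit to analyse.
#' @param stim_onset Photostimulation onset (s after cue); `NULL` skips the
#'   photostim test.
#' @return One-row tibble with `prelick_p`, `prelick_direction`,
#'   `photostim_p`, `photostim_direction` (`"inhibited"`, `"excited"` or
#'   `NA`) and `photostim_reason` (why the test was skipped, if it was).
#' @export
modulation_tests <- function(session, unit_id, stim_onset = 0.6) {
  tr <- session$trials
  licked <- tr[tr$cue_present & !is.na(tr$first_lick_time), , drop = FALSE]
  spk <- unit_trial_spikes(session, unit_id, licked)
  rate_in <- function(i, lo, hi) {
    sum(spk[[i]] >= lo & spk[[i]] < hi) / (hi - lo)
  }
  pre_lick <- vapply(seq_len(nrow(licked)), function(i) {
    lt <- licked$first_lick_time[i]
    rate_in(i, lt - 0.5, lt - 0.2)
  }, numeric(1))
  baseline <- vapply(seq_len(nrow(licked)), function(i) {
    rate_in(i, -1, 0)
  }, numeric(1))
  pl <- tryCatch(wilcox.test(pre_lick, baseline, paired = TRUE,
                             exact = FALSE),
                 error = function(e) NULL)
  prelick_p <- if (is.null(pl)) NA_real_ else pl$p.value
  prelick_dir <- if (median(pre_lick - baseline) > 0) "increase"
                 else if (median(pre_lick - baseline) < 0) "decrease"
                 else NA_character_

  ps_p <- NA_real_
  ps_dir <- NA_character_
  ps_reason <- NA_character_
  if (!is.null(stim_onset)) {
    keep <- tr[tr$cue_present &
                 (is.na(tr$first_lick_time) |
                    tr$first_lick_time > stim_onset), , drop = FALSE]
    spk2 <- unit_trial_spikes(session, unit_id, keep)
    win_rate <- vapply(seq_len(nrow(keep)), function(i) {
      sum(spk2[[i]] >= stim_onset + 0.05 & spk2[[i]] < stim_onset + 0.25) /
        0.2
    }, numeric(1))
    is_stim <- keep$perturbed
    if (sum(is_stim) < 10 || sum(!is_stim) < 10) {
      ps_reason <- "fewer than 10 trials per condition"
    } else if (mean(win_rate) <= 1) {
      ps_reason <- "rate at or below 1 spikes/s in test window"
    } else {
      ps <- wilcox.test(win_rate[is_stim], win_rate[!is_stim],
                        exact = FALSE)
      ps_p <- ps$p.value
      d <- median(win_rate[is_stim]) - median(win_rate[!is_stim])
      if (d == 0) d <- mean(win_rate[is_stim]) - mean(win_rate[!is_stim])
      ps_dir <- if (d < 0) "inhibited" else "excited"
    }
  }
  tibble::tibble(unit_id = unit_id, prelick_p = prelick_p,
                 prelick_direction = prelick_dir,
                 photostim_p = ps_p, photostim_direction = ps_dir,
                 photostim_reason = ps_reason)
}

#' Partial rank correlation with shuffle nulls
#'
#' Spearman-based partial correlation between a unit's spike rate `R` and
#' the previous trial's lick time `P`, removing the effect of the upcoming
#' lick time `U`:
#' `rho_RP.U = (rho_RP - rho_RU * rho_PU) / sqrt((1 - rho_RU^2) (1 - rho_PU^2))`.
#' Two null distributions are available: a trial-order shuffle of the
#' history variable `P` (destroys trial history), and a session permutation
#' in which `P` is replaced by a same-length history vector from a different
#' session (guards against nonsense correlations between slowly drifting
#' variables). The observed value is significant when it falls outside the
#' central 95% of the null.
#'
#' Following the source analyses, callers should restrict the trials to
#' those after rewarded trials before calling.
#'
#' @param R Spike rates per trial.
#' @param P Previous-trial lick times.
#' @param U Upcoming (current-trial) lick times.
#' @param n_shuffle Null iterations (default 1000).
#' @param P_pool Optional list of history vectors from other sessions for
#'   the session-permutation null.
#' @return One-row tibble with `rho`, shuffle-null band, session-null band
#'   (if available) and significance flags.
#' @export
partial_rank_correlation <- function(R, P, U, n_shuffle = 1000L,
                                     P_pool = NULL) {
  if (length(R) < 20) abort("need at least 20 trials.")
  if (sd(R) == 0 || sd(P) == 0 || sd(U) == 0) {
    abort("partial correlation undefined for a constant input vector.")
  }
  prho <- function(R, P, U) {
    rp <- cor(R, P, method = "spearman")
    ru <- cor(R, U, method = "spearman")
    pu <- cor(P, U, method = "spearman")
    (rp - ru * pu) / (sqrt(1 - ru^2) * sqrt(1 - pu^2))
  }
  rho <- prho(R, P, U)
  shuf <- vapply(seq_len(n_shuffle), function(i) {
    prho(R, sample(P), U)
  }, numeric(1))
  band <- quantile(shuf, c(0.025, 0.975))
  sess_lo <- NA_real_
  sess_hi <- NA_real_
  sess_sig <- NA
  if (!is.null(P_pool) && length(P_pool) > 0) {
    perm <- vapply(seq_len(n_shuffle), function(i) {
      p <- P_pool[[sample.int(length(P_pool), 1)]]
      if (length(p) >= length(R)) {
        p <- p[seq_len(length(R))]
      } else {
        p <- p[1 + (seq_len(length(R)) - 1) %% length(p)]
      }
      prho(R, p, U)
    }, numeric(1))
    sb <- quantile(perm, c(0.025, 0.975))
    sess_lo <- unname(sb[1]); sess_hi <- unname(sb[2])
    sess_sig <- rho < sess_lo || rho > sess_hi
  }
  tibble::tibble(rho = rho,
                 shuffle_lo = unname(band[1]), shuffle_hi = unname(band[2]),
                 shuffle_significant = rho < band[1] || rho > band[2],
                 session_lo = sess_lo, session_hi = sess_hi,
                 session_significant = sess_sig)
}
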