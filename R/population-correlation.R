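#' Count-matched control trials
#'
#' Subselects `n` unperturbed trials whose lick times are closest to the
#' median lick time of the unperturbed condition — the control used when
#' comparing population activity against a perturbed trial group of size
#' `n`.
#'
#' @param trials Trial tibble or `cbg_session`.
#' @param n Number of trials to select.
#' @return Integer vector of trial indices.
#' @export
match_control_trials <- function(trials, n) {
  if (inherits(trials, "cbg_session")) trials <- trials$trials
  pool <- trials[!trials$perturbed & trials$cue_present &
                   !is.na(trials$first_lick_time), , drop = FALSE]
  if (nrow(pool) < n) abort("not enough unperturbed trials to match.")
  med <- median(pool$first_lick_time)
  pool$trial[order(abs(pool$first_lick_time - med))][seq_len(n)]
}

#' Population activity correlation between trial groups
#'
#' Builds the trial-averaged population activity matrix (units x time bins,
#' 200-ms bins by default) for a reference trial group and a comparison
#' group, computes the pairwise Pearson correlation between all column
#' pairs, and extracts the peak trace: for each comparison time bin, the
#' reference time with the maximum correlation, reported only where that
#' maximum exceeds `threshold` (0.8). Columns with zero variance yield
#' missing correlations (never 0). When activity patterns unfold at
#' different speeds in the two groups, the peak trace deviates from the
#' diagonal with slope equal to the inverse time-scaling factor.
#'
#' @param session A `cbg_session`.
#' @param ref_trials,comp_trials Trial index vectors.
#' @param window Cue-aligned analysis window (default `c(0, 1.4)`).
#' @param bin_size Bin width in seconds (default 0.2).
#' @param threshold Minimum correlation for the peak trace (default 0.8).
#' @return List with `correlation` (matrix, rows = reference bins, columns
#'   = comparison bins), `peak_trace` (tibble: `comp_time`, `ref_time`,
#'   `max_corr`; `ref_time` is `NA` below threshold) and the bin times.
#' @export
population_correlation_analysis <- function(session, ref_trials, comp_trials,
                                            window = c(0, 1.4),
                                            bin_size = 0.2,
                                            threshold = 0.8) {
  if (nrow(session$units) < 2) abort("need at least 2 units.")
  mean_mat <- function(idx) {
    b <- bin_spikes(session, bin_size, "cue", window, trials = idx)
    apply(b, c(2, 3), mean)      # units x bins
  }
  A <- mean_mat(ref_trials)
  B <- mean_mat(comp_trials)
  nb <- ncol(A)
  C <- matrix(NA_real_, nb, nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      if (sd(A[, i]) > 0 && sd(B[, j]) > 0) C[i, j] <- cor(A[, i], B[, j])
    }
  }
  times <- window[1] + (seq_len(nb) - 0.5) * bin_size
  peak <- purrr::map(seq_len(nb), function(j) {
    col <- C[, j]
    if (all(is.na(col))) {
      return(tibble::tibble(comp_time = times[j], ref_time = NA_real_,
                            max_corr = NA_real_))
    }
    i <- which.max(col)
    tibble::tibble(comp_time = times[j],
                   ref_time = if (col[i] > threshold) times[i] else NA_real_,
                   max_corr = col[i])
  }) |> purrr::list_rbind()
  list(correlation = C, peak_trace = peak, times = times)
}

#' Assemble a pseudo-session across recordings
#'
#' Pools units recorded in different sessions into one pseudo-population.
#' For each unit, `n_define` unperturbed control trials (first lick within
#' 1-3 s of the cue) are drawn at random to define the modes, and the
#' remaining trials are used for projection; the two sets are strictly
#' disjoint. Units are included only if they have more than `min_per_range`
#' trials within every one of the six lick-time ranges.
#'
#' @param sessions List of `cbg_session` objects.
#' @param n_define Number of mode-definition trials per unit (default 50).
#' @param ranges Lick-time ranges (default [default_lick_ranges()]).
#' @param min_per_range Minimum trials per range (default 10; inclusion
#'   requires strictly more).
#' @param window Cue-aligned window for the pooled activity (default
#'   `c(-0.2, 2)`).
#' @param bin_size Bin width (default 0.05).
#' @param smoothing Causal boxcar width (default 0.2).
#' @return A `pseudo_session`: list with `window_means` (mode-definition
#'   window statistics per included unit), `group_activity` (units x groups
#'   x bins array of projection-trial mean rates), `times`, `units`
#'   (tibble with session of origin) and `excluded` (tibble of exclusion
#'   reasons).
#' @export
assemble_pseudo_session <- function(sessions, n_define = 50,
                                    ranges = default_lick_ranges(),
                                    min_per_range = 10,
                                    window = c(-0.2, 2), bin_size = 0.05,
                                    smoothing = 0.2) {
  wm_rows <- list()
  act_rows <- list()
  unit_rows <- list()
  excluded <- list()
  for (si in seq_along(sessions)) {
    ses <- sessions[[si]]
    tr <- group_trials_by_lick_time(ses$trials, ranges)
    counts <- table(factor(tr$lick_group, levels = ranges$label))
    eligible <- tr$trial[!tr$perturbed & tr$cue_present &
                           !is.na(tr$first_lick_time) &
                           tr$first_lick_time >= 1 &
                           tr$first_lick_time <= 3]
    if (any(counts <= min_per_range)) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        session = ses$session_id, unit_id = ses$units$unit_id,
        reason = "fewer than required trials in some lick-time range")
      next
    }
    if (length(eligible) <= n_define) {
      excluded[[length(excluded) + 1L]] <- tibble::tibble(
        session = ses$session_id, unit_id = ses$units$unit_id,
        reason = "not enough eligible mode-definition trials")
      next
    }
    def_trials <- sort(sample(eligible, n_define))
    proj_trials <- setdiff(tr$trial, def_trials)
    stopifnot(length(intersect(def_trials, proj_trials)) == 0)
    wm <- mode_window_means(ses, def_trials)
    b <- bin_spikes(ses, bin_size, "cue", window, smoothing = smoothing,
                    trials = proj_trials)
    grp <- tr$lick_group[match(attr(b, "trial_index"), tr$trial)]
    act <- array(NA_real_, dim = c(nrow(wm), nrow(ranges), dim(b)[3]))
    for (g in seq_len(nrow(ranges))) {
      rows <- which(grp == ranges$label[g])
      if (length(rows) > 0) {
        act[, g, ] <- apply(b[rows, , , drop = FALSE], c(2, 3), mean)
      }
    }
    wm_rows[[length(wm_rows) + 1L]] <- wm
    act_rows[[length(act_rows) + 1L]] <- act
    unit_rows[[length(unit_rows) + 1L]] <- tibble::tibble(
      session = ses$session_id, unit_id = wm$unit_id)
    times <- tensor_times(b)
  }
  if (length(wm_rows) == 0) abort("no session passed pseudo-session inclusion.")
  structure(
    list(window_means = purrr::list_rbind(wm_rows),
         group_activity = do.call(abind3, act_rows),
         times = times, groups = ranges$label,
         units = purrr::list_rbind(unit_rows),
         excluded = if (length(excluded)) purrr::list_rbind(excluded)
                    else tibble::tibble()),
    class = "pseudo_session")
}

# bind arrays along the first (unit) dimension
abind3 <- function(...) {
  args <- list(...)
  d <- dim(args[[1]])
  out <- array(NA_real_, dim = c(sum(vapply(args, function(a) dim(a)[1],
                                            numeric(1))), d[2], d[3]))
  at <- 1L
  for (a in args) {
    out[at:(at + dim(a)[1] - 1L), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
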