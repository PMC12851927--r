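#' Fit a kNN time-to-lick decoder
#'
#' Stacks every (trial, 50-ms bin) population activity vector between 1 s
#' before the cue and the first lick of the training trials, labels each
#' with the remaining time to lick `T_to_lick`, and fits a PCA retaining
#' the top components explaining `pc_variance` of the variance. Distances
#' between states are computed in that PC space. With the default
#' `metric = "pc"`, distance is Euclidean in the retained PC space — the
#' Mahalanobis distance with respect to the noise covariance when the
#' trial-to-trial noise is approximately isotropic (as for independent
#' Poisson spiking). `metric = "whitened"` instead scales every component
#' by its training standard deviation (Mahalanobis with respect to the
#' total covariance); this down-weights the high-variance signal
#' directions relative to retained near-noise components and degrades
#' decoding when the noise is isotropic, so it is not the default.
#'
#' Sessions must pass quality control: at least `min_trials` trials and
#' `min_units` simultaneously recorded units.
#'
#' @param session A `cbg_session`.
#' @param train_trials Trial indices of the training set (licked trials
#'   only are used).
#' @param k Number of neighbours (default 30; values 20-50 behave
#'   similarly).
#' @param pc_variance Retained variance proportion (default 0.90).
#' @param bin_size Bin width (default 0.05 s).
#' @param smoothing Optional causal boxcar width (s) applied to the rate
#'   bins before stacking (default 0.2; `NULL` for raw 50-ms counts).
#' @param metric `"pc"` (default) or `"whitened"`; see Details.
#' @param min_trials,min_units QC thresholds (defaults 300 and 5).
#' @return A `knn_decoder` with the projected training cloud and labels.
#' @export
fit_decoder <- function(session, train_trials, k = 30, pc_variance = 0.90,
                        bin_size = 0.05, smoothing = 0.2,
                        metric = c("pc", "whitened"),
                        min_trials = 300, min_units = 5) {
  metric <- match.arg(metric)
  stopifnot(k >= 1, pc_variance > 0, pc_variance <= 1)
  if (nrow(session$trials) < min_trials || nrow(session$units) < min_units) {
    abort(paste0("session fails decoder QC (needs >= ", min_trials,
                 " trials and >= ", min_units, " units)."),
          class = "cbg_qc_error")
  }
  stacked <- stack_states(session, train_trials, bin_size, smoothing)
  if (nrow(stacked$X) <= k) abort("fewer training points than k.")
  pca <- stats::prcomp(stacked$X, center = TRUE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  n_pc <- which(cum >= pc_variance)[1]
  scale_by <- if (metric == "whitened") pca$sdev[seq_len(n_pc)]
              else rep(1, n_pc)
  scores <- sweep(pca$x[, seq_len(n_pc), drop = FALSE], 2, scale_by, "/")
  structure(list(scores = scores, labels = stacked$t_to_lick,
                 rotation = pca$rotation[, seq_len(n_pc), drop = FALSE],
                 center = pca$center, sdev = scale_by, metric = metric,
                 k = k, n_pc = n_pc, bin_size = bin_size,
                 smoothing = smoothing,
                 unit_id = stacked$unit_id, train_trials = train_trials),
            class = "knn_decoder")
}

stack_states <- function(session, trials, bin_size, smoothing = NULL) {
  tr <- session$trials
  tr <- tr[tr$trial %in% trials & tr$cue_present &
             !is.na(tr$first_lick_time), , drop = FALSE]
  if (nrow(tr) == 0) abort("no licked trials to stack.")
  b <- bin_spikes(session, bin_size, "cue",
                  c(-1, max(tr$first_lick_time)), smoothing = smoothing,
                  trials = tr$trial)
  times <- tensor_times(b)
  rows <- list()
  labs <- list()
  meta <- list()
  for (i in seq_len(dim(b)[1])) {
    lt <- tr$first_lick_time[i]
    keep <- which(times + bin_size <= lt)
    rows[[i]] <- matrix(b[i, , keep], nrow = dim(b)[2])
    labs[[i]] <- lt - times[keep]
    meta[[i]] <- tibble::tibble(trial = tr$trial[i], time = times[keep])
  }
  list(X = t(do.call(cbind, rows)), t_to_lick = unlist(labs),
       meta = purrr::list_rbind(meta), unit_id = attr(b, "unit_id"))
}

#' @export
print.knn_decoder <- function(x, ...) {
  cat("<knn_decoder> ", nrow(x$scores), " training states, ",
      x$n_pc, " PCs, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Decode remaining time-to-lick
#'
#' Projects test activity states into the decoder's whitened PC space and
#' averages the `T_to_lick` labels of the k nearest training states.
#' Distance ties are broken by training-point order, so the result is
#' deterministic.
#'
#' @param decoder A `knn_decoder`.
#' @param session The session (same unit set as training).
#' @param trials Test trial indices.
#' @param until_lick If `TRUE` (default) decode only bins before each
#'   trial's lick; otherwise decode the full window up to `t_max`.
#' @param t_max Window end when `until_lick = FALSE`.
#' @return Tibble: `trial`, `time`, `t_to_lick_hat` and `decoded_lick_time`
#'   (= `time` + decoded remaining time).
#' @export
decode <- function(decoder, session, trials, until_lick = TRUE, t_max = 2) {
  tr <- session$trials
  tr <- tr[tr$trial %in% trials, , drop = FALSE]
  if (nrow(decoder$scores) < decoder$k) abort("fewer training points than k.")
  end <- if (until_lick) {
    tr <- tr[!is.na(tr$first_lick_time), , drop = FALSE]
    max(tr$first_lick_time)
  } else t_max
  b <- bin_spikes(session, decoder$bin_size, "cue", c(-1, end),
                  smoothing = decoder$smoothing, trials = tr$trial)
  if (!identical(attr(b, "unit_id"), decoder$unit_id)) {
    abort("unit set differs from the decoder's training units.")
  }
  times <- tensor_times(b)
  out <- list()
  for (i in seq_len(dim(b)[1])) {
    lt <- tr$first_lick_time[i]
    keep <- if (until_lick) which(times + decoder$bin_size <= lt)
            else seq_along(times)
    if (length(keep) == 0) next
    X <- t(matrix(b[i, , keep], nrow = dim(b)[2]))
    pred <- knn_predict(decoder, X)
    out[[length(out) + 1L]] <- tibble::tibble(
      trial = tr$trial[i], time = times[keep], t_to_lick_hat = pred,
      decoded_lick_time = times[keep] + pred)
  }
  purrr::list_rbind(out)
}

knn_predict <- function(decoder, X) {
  Xc <- sweep(X, 2, decoder$center)
  S <- sweep(Xc %*% decoder$rotation, 2, decoder$sdev, "/")
  tr_sq <- rowSums(decoder$scores^2)
  vapply(seq_len(nrow(S)), function(i) {
    d2 <- tr_sq - 2 * drop(decoder$scores %*% S[i, ]) + sum(S[i, ]^2)
    nn <- order(d2)[seq_len(decoder$k)]      # ties broken by training order
    mean(decoder$labels[nn])
  }, numeric(1))
}

#' Session decodability
#'
#' Pearson correlation between the decoded lick time read out at
#' `at_time` (0.6 s after the cue, the perturbation onset time; decoded
#' lick time = 0.6 s + decoded remaining time) and the actual lick time on
#' held-out unperturbed trials. Sessions with decodability at or below 0.35
#' are excluded from perturbation analyses downstream.
#'
#' @param decoder A `knn_decoder`.
#' @param session The session.
#' @param test_trials Held-out unperturbed trial indices.
#' @param at_time Readout time (default 0.6 s).
#' @param min_trials Minimum held-out licked trials (default 10).
#' @return One-row tibble: `r`, `n`, `pass` (r > 0.35).
#' @export
session_decodability <- function(decoder, session, test_trials,
                                 at_time = 0.6, min_trials = 10) {
  tr <- session$trials
  tr <- tr[tr$trial %in% test_trials & !is.na(tr$first_lick_time) &
             tr$first_lick_time > at_time, , drop = FALSE]
  if (nrow(tr) < min_trials) {
    return(tibble::tibble(r = NA_real_, n = nrow(tr), pass = NA))
  }
  dec <- decode(decoder, session, tr$trial)
  at_bin <- dec[abs(dec$time - at_time) < decoder$bin_size / 2, ]
  m <- dplyr::inner_join(at_bin, tr[, c("trial", "first_lick_time")],
                         by = "trial")
  r <- cor(m$decoded_lick_time, m$first_lick_time)
  tibble::tibble(r = r, n = nrow(m), pass = r > 0.35)
}

#' Match perturbed and unperturbed trials by decoded state
#'
#' For each perturbed trial, finds the unperturbed trial with the closest
#' decoded lick time at the perturbation onset (0.6 s after the cue), then
#' compares the mean decoded `T_to_lick` trajectories of the two matched
#' groups aligned on the stimulation onset: divergence during the stimulus,
#' the persistent offset after stimulus offset, and the time for the
#' difference to recover to its pre-perturbation level.
#'
#' @param decoder A `knn_decoder`.
#' @param session The session.
#' @param perturbed_trials,control_pool Trial index vectors.
#' @param onset,duration Stimulus timing (s).
#' @param t_max Decode window end for perturbed trials (s after cue).
#' @return List with `pairs` (tibble of matches), `trajectories` (tibble of
#'   paired group means and differences over time) and `summary` (one-row
#'   tibble): `divergence_stim` and `offset_post` are the paired trajectory
#'   differences during the stimulus and just after its offset;
#'   `delta_decoded_lick` is the control-corrected within-trial change of
#'   the decoded lick time across the stimulus (the calibrated estimate of
#'   the perturbation-induced shift); `recovery_time` is the time after
#'   offset for the paired difference to return to its pre-stimulus level.
#' @export
match_and_compare <- function(decoder, session, perturbed_trials,
                              control_pool, onset = 0.6, duration = 0.6,
                              t_max = 3) {
  if (length(perturbed_trials) == 0 || length(control_pool) == 0) {
    abort("empty trial pools.")
  }
  dec_p <- decode(decoder, session, perturbed_trials, until_lick = TRUE,
                  t_max = t_max)
  dec_c <- decode(decoder, session, control_pool, until_lick = TRUE,
                  t_max = t_max)
  # match on the last fully pre-onset bin (states from bins overlapping the
  # stimulus would already be contaminated by the perturbation)
  at <- function(d) {
    pre_bins <- d[d$time + decoder$bin_size <= onset, , drop = FALSE]
    pre_bins |>
      dplyr::group_by(.data$trial) |>
      dplyr::slice_max(.data$time, n = 1) |>
      dplyr::ungroup()
  }
  ap <- at(dec_p); ac <- at(dec_c)
  if (nrow(ap) == 0 || nrow(ac) == 0) abort("no pre-onset states to match.")
  pairs <- purrr::map(seq_len(nrow(ap)), function(i) {
    j <- which.min(abs(ac$decoded_lick_time - ap$decoded_lick_time[i]))
    tibble::tibble(perturbed = ap$trial[i], control = ac$trial[j],
                   decoded_at_onset_p = ap$decoded_lick_time[i],
                   decoded_at_onset_c = ac$decoded_lick_time[j])
  }) |> purrr::list_rbind()
  # paired trajectory differences: a pair contributes at a time point only
  # while both of its trials are still unlicked, avoiding attrition bias
  paired <- dplyr::inner_join(
    dplyr::inner_join(pairs[, c("perturbed", "control")],
                      dec_p, by = c(perturbed = "trial")),
    dec_c, by = c("control" = "trial", "time" = "time"),
    suffix = c("_p", "_c"))
  traj <- paired |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(perturbed = mean(.data$t_to_lick_hat_p),
                     control = mean(.data$t_to_lick_hat_c),
                     diff = mean(.data$t_to_lick_hat_p -
                                   .data$t_to_lick_hat_c),
                     n_pairs = dplyr::n(), .groups = "drop")
  off <- onset + duration
  # causal smoothing carries stimulus-period activity into the first bins
  # after the offset; post-stimulus readouts start once it has cleared
  clear <- off + (decoder$smoothing %||% 0)
  pre <- mean(traj$diff[traj$time >= onset - 0.3 & traj$time < onset],
              na.rm = TRUE)
  div <- mean(traj$diff[traj$time >= onset & traj$time < off], na.rm = TRUE)
  post <- mean(traj$diff[traj$time >= clear & traj$time < clear + 0.3],
               na.rm = TRUE)
  rec_idx <- which(traj$time >= clear & abs(traj$diff - pre) < 0.05)
  recovery <- if (length(rec_idx) == 0) NA_real_
              else traj$time[rec_idx[1]] - off
  # within-trial change of the decoded lick time from the last pre-onset bin
  # to the first post-offset bin; the matched-control change corrects for
  # decoder drift. Free of the attrition/selection bias of pooled or paired
  # group means, this calibrates the perturbation-induced shift directly.
  within_change <- function(d, ids) {
    d <- d[d$trial %in% ids, , drop = FALSE]
    d |>
      dplyr::group_by(.data$trial) |>
      dplyr::summarise(
        pre = .data$decoded_lick_time[
          max(which(.data$time + decoder$bin_size <= onset))],
        post = if (any(.data$time >= clear))
          .data$decoded_lick_time[which(.data$time >= clear)[1]]
        else NA_real_,
        .groups = "drop") |>
      dplyr::summarise(m = mean(.data$post - .data$pre, na.rm = TRUE)) |>
      dplyr::pull(.data$m)
  }
  delta <- within_change(dec_p, pairs$perturbed) -
    within_change(dec_c, pairs$control)
  list(pairs = pairs, trajectories = traj,
       summary = tibble::tibble(divergence_stim = div - pre,
                                offset_post = post - pre,
                                delta_decoded_lick = delta,
                                recovery_time = recovery))
}
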