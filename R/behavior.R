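#' Summary statistics of lick behaviour
#'
#' Computes the median first-lick time, the no-lick rate (fraction of cue
#' trials without a lick within `horizon` seconds), the empirical cumulative
#' lick-time distribution, and — when perturbation descriptors are present —
#' the post-stimulation lick rate (probability of licking within 0.6 s after
#' the perturbation offset in no-cue trials).
#'
#' For perturbation comparisons, pass `after_onset` to include only trials
#' whose first lick occurred after the perturbation onset time (applied to
#' control and stimulated trials alike), so the comparison is restricted to
#' trials in which the manipulation could have acted.
#'
#' @param trials Trial tibble or `cbg_session`.
#' @param after_onset Optional time (s after cue): keep only trials licking
#'   after it (no-lick trials are kept).
#' @param horizon No-lick horizon in seconds (default 5).
#' @return One-row tibble with `n`, `median_lick_time`, `no_lick_rate`,
#'   `post_stim_lick_rate` and a list-column `cdf` holding the empirical CDF
#'   as a tibble `(t, F)`. When no trial qualifies, `n` is 0 and all
#'   statistics are `NA`.
#' @export
lick_stats <- function(trials, after_onset = NULL, horizon = 5) {
  if (inherits(trials, "cbg_session")) trials <- trials$trials
  assert_trials(trials)
  cue <- trials[trials$cue_present, , drop = FALSE]
  if (!is.null(after_onset)) {
    cue <- cue[is.na(cue$first_lick_time) |
                 cue$first_lick_time > after_onset, , drop = FALSE]
  }
  if (nrow(cue) == 0) {
    return(tibble::tibble(n = 0L, median_lick_time = NA_real_,
                          no_lick_rate = NA_real_,
                          post_stim_lick_rate = NA_real_,
                          cdf = list(tibble::tibble(t = numeric(0),
                                                    F = numeric(0)))))
  }
  lt <- cue$first_lick_time
  licked <- !is.na(lt) & lt <= horizon
  no_cue <- trials[!trials$cue_present & trials$perturbed, , drop = FALSE]
  post_stim <- if (nrow(no_cue) > 0) {
    off <- no_cue$pert_onset + no_cue$pert_duration
    mean(!is.na(no_cue$first_lick_time) &
           no_cue$first_lick_time > off &
           no_cue$first_lick_time <= off + 0.6)
  } else NA_real_
  srt <- sort(lt[licked])
  tibble::tibble(
    n = nrow(cue),
    median_lick_time = if (any(licked)) median(lt[licked]) else NA_real_,
    no_lick_rate = mean(!licked),
    post_stim_lick_rate = post_stim,
    cdf = list(tibble::tibble(t = srt, F = seq_along(srt) / nrow(cue)))
  )
}

#' Hierarchical bootstrap
#'
#' Nested resampling that propagates animal-, session- and trial-level
#' variability into confidence intervals and p-values: animals are drawn
#' with replacement, then sessions within each drawn animal, then rows
#' (trials) within each drawn session; the statistic is recomputed on each
#' resampled dataset. Repeated `iters` times (1,000 by default).
#'
#' @param data Tibble with columns `animal` and `session` (plus whatever the
#'   statistic needs), one row per trial-level record.
#' @param statistic_fn Function mapping such a tibble to a scalar.
#' @param iters Number of bootstrap iterations.
#' @param null_value Optional null value of the statistic for a p-value.
#' @param alternative Direction of the alternative relative to
#'   `null_value`: the one-sided p is the fraction of iterations violating
#'   that direction; `"two.sided"` doubles the smaller tail.
#' @return An `hboot` object: tibble row with `mean`, `ci_low`, `ci_high`
#'   (2.5/97.5 percentiles), `p_value`, `iters`, and the samples as an
#'   attribute.
#' @export
hierarchical_bootstrap <- function(data, statistic_fn, iters = 1000L,
                                   null_value = NULL,
                                   alternative = c("greater", "less",
                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  if (!all(c("animal", "session") %in% names(data))) {
    abort("`data` must have `animal` and `session` columns.")
  }
  animals <- unique(as.character(data$animal))
  if (length(animals) == 0) abort("level `animal` has zero members.")
  key <- paste(data$animal, data$session, sep = "\r")
  rows_by_key <- split(seq_len(nrow(data)), key)
  keys_by_animal <- lapply(
    setNames(animals, animals),
    function(a) unique(key[as.character(data$animal) == a]))
  if (any(lengths(keys_by_animal) == 0)) {
    abort("level `session` has zero members for some animal.")
  }
  samples <- vapply(seq_len(iters), function(i) {
    draw_animals <- sample(animals, length(animals), replace = TRUE)
    rows <- unlist(lapply(draw_animals, function(a) {
      keys <- keys_by_animal[[a]]
      draw_sessions <- sample(keys, length(keys), replace = TRUE)
      unlist(lapply(draw_sessions, function(k) {
        idx <- rows_by_key[[k]]
        idx[sample.int(length(idx), length(idx), replace = TRUE)]
      }), use.names = FALSE)
    }), use.names = FALSE)
    statistic_fn(data[rows, , drop = FALSE])
  }, numeric(1))

  p <- NA_real_
  if (!is.null(null_value)) {
    p_greater <- mean(samples <= null_value)   # violations of "greater"
    p_less <- mean(samples >= null_value)
    p <- switch(alternative,
                greater = p_greater, less = p_less,
                two.sided = min(1, 2 * min(p_greater, p_less)))
  }
  out <- tibble::tibble(mean = mean(samples),
                        ci_low = unname(quantile(samples, 0.025)),
                        ci_high = unname(quantile(samples, 0.975)),
                        p_value = p, iters = iters)
  structure(out, class = c("hboot", class(out)), samples = samples)
}

#' @method tidy hboot
#' @export
tidy.hboot <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}
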