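#' Select the engaged block of trials
#'
#' Task engagement is bounded by two behavioural landmarks: the block starts
#' at the first occurrence of five consecutive cue trials with licks, and it
#' ends before the last occurrence of three consecutive no-lick,
#' unperturbed cue trials, additionally discarding the 20 cue trials
#' immediately preceding that no-lick run (disengagement builds up before
#' licking stops outright). Runs are counted over the subsequence of cue
#' trials; no-cue probe trials neither extend nor break a run.
#'
#' @param session A `cbg_session`, or a trial tibble.
#' @return Integer vector `c(first, last)` of trial indices bounding the
#'   engaged range (inclusive), or `integer(0)` when the criteria are unmet.
#' @export
select_engaged_trials <- function(session) {
  trials <- if (inherits(session, "cbg_session")) session$trials else session
  assert_trials(trials)
  cue <- trials[trials$cue_present, , drop = FALSE]
  if (nrow(cue) < 5) return(integer(0))
  licked <- !is.na(cue$first_lick_time)

  run5 <- which(stats::filter(as.numeric(licked), rep(1, 5), sides = 1) == 5)
  if (length(run5) == 0) return(integer(0))
  a <- cue$trial[run5[1]]

  nolick_run <- !licked & !cue$perturbed
  run3 <- which(stats::filter(as.numeric(nolick_run), rep(1, 3), sides = 1) == 3)
  if (length(run3) == 0) {
    b <- trials$trial[nrow(trials)]
  } else {
    run_start_pos <- max(run3) - 2L     # position (in cue subsequence) of run start
    keep_pos <- run_start_pos - 21L     # drop the 20 cue trials before the run
    if (keep_pos < 1) return(integer(0))
    b <- cue$trial[keep_pos]
  }
  if (b < a) return(integer(0))
  c(first = a, last = b)
}

#' Classify units from waveform and firing statistics
#'
#' Rule-based cell-type assignment. ALM units with mean rate above 0.5
#' spikes/s and spike width of at least 0.5 ms are putative pyramidal
#' neurons; other ALM units are kept but labelled `ALM_other`. Striatal
#' units are analysed only above 0.1 spikes/s; among those, spike width of
#' at least 0.4 ms with post-spike suppression of at most 40 ms marks a
#' striatal projection neuron (SPN), width below 0.4 ms with under 10%
#' long interspike intervals marks a fast-spiking interneuron (FSI), and the
#' remainder are putative tonically active neurons (TAN). Units with missing
#' features are `unclassified` (with a warning).
#'
#' The paper-level analyses never define what counts as a "long" ISI; the
#' fraction is expected to be precomputed against a configurable threshold
#' (2 s default in the synthetic generator).
#'
#' @param units Unit metadata tibble (see [new_session()]), or a
#'   `cbg_session`.
#' @return The unit tibble with a `class` column, one of `ALM_pyramidal`,
#'   `ALM_other`, `SPN`, `FSI`, `TAN`, `unclassified`.
#' @export
classify_units <- function(units) {
  if (inherits(units, "cbg_session")) units <- units$units
  units <- tibble::as_tibble(units)
  classify_one <- function(area, rate, width, supp, isi) {
    if (is.na(area) || is.na(rate)) return("unclassified")
    if (area == "ALM") {
      if (is.na(width)) return("unclassified")
      if (rate > 0.5 && width >= 0.5) return("ALM_pyramidal")
      return("ALM_other")
    }
    # striatal subregions
    if (rate <= 0.1) return("unclassified")
    if (!is.na(width) && !is.na(supp) && width >= 0.4 && supp <= 40) {
      return("SPN")
    }
    if (!is.na(width) && width < 0.4) {
      if (is.na(isi)) return("unclassified")
      if (isi < 0.10) return("FSI")
      return("TAN")
    }
    if (is.na(width)) return("unclassified")
    "TAN"
  }
  cls <- purrr::pmap_chr(
    list(units$area, units$mean_rate, units$spike_width,
         units$post_spike_suppression, units$long_isi_fraction),
    classify_one
  )
  if (any(cls == "unclassified")) {
    warn(paste0(sum(cls == "unclassified"),
                " unit(s) unclassified (missing features or below rate floor)."))
  }
  units$class <- cls
  units
}

#' Default lick-time ranges
#'
#' The six half-open lick-time ranges used to group trials for population
#' analyses.
#'
#' @return Tibble with columns `lo`, `hi` (seconds) and `label`.
#' @export
default_lick_ranges <- function() {
  lo <- c(0.80, 1.10, 1.25, 1.40, 1.55, 1.70)
  hi <- c(1.10, 1.25, 1.40, 1.55, 1.70, 2.00)
  tibble::tibble(lo = lo, hi = hi,
                 label = sprintf("[%.2f,%.2f)", lo, hi))
}

#' Group trials by first-lick time
#'
#' Assigns each licked trial to at most one half-open range `[lo, hi)`;
#' no-lick trials and licks outside every range are left ungrouped (`NA`).
#'
#' @param trials Trial tibble or `cbg_session`.
#' @param ranges Tibble with columns `lo`, `hi` and optionally `label`;
#'   defaults to [default_lick_ranges()]. Ranges must not overlap.
#' @return The trial tibble with a `lick_group` character column.
#' @export
group_trials_by_lick_time <- function(trials, ranges = default_lick_ranges()) {
  if (inherits(trials, "cbg_session")) trials <- trials$trials
  assert_trials(trials)
  ranges <- dplyr::arrange(tibble::as_tibble(ranges), .data$lo)
  if (!"label" %in% names(ranges)) {
    ranges$label <- sprintf("[%.2f,%.2f)", ranges$lo, ranges$hi)
  }
  if (any(ranges$hi <= ranges$lo) ||
      (nrow(ranges) > 1 && any(ranges$lo[-1] < ranges$hi[-nrow(ranges)]))) {
    abort("lick-time ranges must be non-overlapping with hi > lo.")
  }
  lt <- trials$first_lick_time
  idx <- rep(NA_integer_, length(lt))
  for (r in seq_len(nrow(ranges))) {
    hit <- !is.na(lt) & lt >= ranges$lo[r] & lt < ranges$hi[r]
    idx[hit] <- r
  }
  trials$lick_group <- ranges$label[idx]
  trials
}
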