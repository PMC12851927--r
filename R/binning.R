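#' Bin spike trains into a trials x units x bins rate tensor
#'
#' Counts spikes in half-open bins `[t, t + bin_size)` aligned to the cue or
#' to the first lick of each trial and converts counts to rates (spikes/s).
#' Optional causal boxcar smoothing averages each bin with the preceding bins
#' spanning the filter width, so no future activity leaks backwards in time.
#'
#' @param session A `cbg_session`.
#' @param bin_size Bin size in seconds (e.g. 0.001 for PSTHs, 0.05 for
#'   decoding, 0.2 for population correlation matrices).
#' @param alignment `"cue"` or `"lick"`. Lick alignment silently drops trials
#'   without a first lick.
#' @param window Length-2 numeric, `(start, end)` seconds relative to the
#'   alignment event.
#' @param smoothing `NULL` for none, or the width in seconds of a causal
#'   boxcar filter (the standard PSTH smoothing is 0.2 s).
#' @param trials Optional integer vector of trial indices to include.
#' @param units Optional character vector of unit ids to include.
#' @return A 3-d array (trials x units x bins) of class `binned_tensor`,
#'   with attributes `bin_size`, `alignment`, `window`, `smoothing`,
#'   `trial_index` and `unit_id`. Bin start times (relative to the alignment
#'   event) are available through [tensor_times()].
#' @export
bin_spikes <- function(session, bin_size, alignment = c("cue", "lick"),
                       window, smoothing = NULL,
                       trials = NULL, units = NULL) {
  stopifnot(inherits(session, "cbg_session"))
  alignment <- match.arg(alignment)
  if (length(window) != 2 || window[2] <= window[1]) {
    abort("`window` must be (start, end) with end > start.")
  }
  tr <- session$trials
  if (!is.null(trials)) tr <- tr[tr$trial %in% trials, , drop = FALSE]
  if (alignment == "lick") tr <- tr[!is.na(tr$first_lick_time), , drop = FALSE]
  unit_ids <- if (is.null(units)) session$units$unit_id else units
  if (length(unit_ids) == 0) abort("no units to bin.")

  align_time <- tr$cue_onset +
    if (alignment == "lick") tr$first_lick_time else 0
  span_hi <- max(c(session$spikes$time_s, session$trials$cue_onset + 10, 0))
  if (nrow(tr) > 0 &&
      (min(align_time) + window[1] < -1e-9 ||
       max(align_time) + window[2] > span_hi + 1e-9)) {
    abort("window extends outside the recorded span of the session.")
  }

  n_bins <- as.integer(round((window[2] - window[1]) / bin_size))
  vals <- array(0, dim = c(nrow(tr), length(unit_ids), n_bins))
  spk <- split(session$spikes$time_s, session$spikes$unit_id)
  for (u in seq_along(unit_ids)) {
    st <- spk[[unit_ids[u]]]
    if (is.null(st) || length(st) == 0) next
    for (i in seq_len(nrow(tr))) {
      lo <- align_time[i] + window[1]
      sel <- st[st >= lo & st < align_time[i] + window[2]]
      if (length(sel) == 0) next
      b <- pmin(floor((sel - lo) / bin_size) + 1L, n_bins)
      vals[i, u, ] <- tabulate(b, nbins = n_bins) / bin_size
    }
  }
  if (!is.null(smoothing)) {
    for (u in seq_along(unit_ids)) {
      vals[, u, ] <- causal_boxcar(
        matrix(vals[, u, ], nrow = nrow(tr)), smoothing, bin_size)
    }
  }
  structure(vals, class = "binned_tensor",
            bin_size = bin_size, alignment = alignment, window = window,
            smoothing = smoothing %||% NA_real_,
            trial_index = tr$trial, unit_id = unit_ids)
}

#' Bin start times of a binned tensor
#'
#' @param x A `binned_tensor`.
#' @param center If `TRUE`, return bin centers instead of bin starts.
#' @return Numeric vector of times in seconds relative to the alignment event.
#' @export
tensor_times <- function(x, center = FALSE) {
  w <- attr(x, "window")
  bs <- attr(x, "bin_size")
  w[1] + (seq_len(dim(x)[3]) - 1L) * bs + if (center) bs / 2 else 0
}

#' @export
print.binned_tensor <- function(x, ...) {
  d <- dim(x)
  cat("<binned_tensor> ", d[1], " trials x ", d[2], " units x ", d[3],
      " bins (", attr(x, "alignment"), "-aligned, ",
      attr(x, "bin_size") * 1000, "-ms bins)\n", sep = "")
  invisible(x)
}

#' Tidy a binned tensor into long format
#'
#' @param x A `binned_tensor`.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `unit_id`, `time` (bin start,
#'   seconds relative to the alignment event) and `rate` (spikes/s).
#' @method tidy binned_tensor
#' @export
tidy.binned_tensor <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    trial = rep(attr(x, "trial_index"), times = d[2] * d[3]),
    unit_id = rep(rep(attr(x, "unit_id"), each = d[1]), times = d[3]),
    time = rep(tensor_times(x), each = d[1] * d[2]),
    rate = as.vector(x)
  )
}
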