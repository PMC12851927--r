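#' Per-unit mean rates in the mode-defining windows
#'
#' Mean firing rate of every unit in the five windows used for targeted
#' dimensionality reduction: baseline (0-1 s before cue), cue (0-0.3 s after
#' cue), middle (0.5-0.8 s before lick), ramp (0.2-0.5 s before lick) and
#' execution (0-0.3 s after lick), averaged across the given trials (licked
#' cue trials only for the lick-anchored windows).
#'
#' @param session A `cbg_session`.
#' @param trials Optional trial indices.
#' @return Tibble: `unit_id`, `baseline`, `cue`, `middle`, `ramp`,
#'   `execution` (spikes/s).
#' @export
mode_window_means <- function(session, trials = NULL) {
  tr <- session$trials
  if (!is.null(trials)) tr <- tr[tr$trial %in% trials, , drop = FALSE]
  tr <- tr[tr$cue_present & !is.na(tr$first_lick_time), , drop = FALSE]
  if (nrow(tr) == 0) abort("no licked cue trials to define windows on.")
  lt <- tr$first_lick_time
  windows <- list(baseline = cbind(-1, 0), cue = cbind(0, 0.3),
                  middle = cbind(lt - 0.8, lt - 0.5),
                  ramp = cbind(lt - 0.5, lt - 0.2),
                  execution = cbind(lt, lt + 0.3))
  spk <- split(session$spikes$time_s, session$spikes$unit_id)
  purrr::map(session$units$unit_id, function(u) {
    st <- spk[[u]] %||% numeric(0)
    means <- vapply(windows, function(w) {
      lo <- tr$cue_onset + w[, 1]
      hi <- tr$cue_onset + w[, 2]
      counts <- vapply(seq_along(lo), function(i) {
        sum(st >= lo[i] & st < hi[i])
      }, numeric(1))
      mean(counts / (hi - lo))
    }, numeric(1))
    tibble::tibble(unit_id = u, !!!as.list(means))
  }) |> purrr::list_rbind()
}

gram_schmidt <- function(v, against) {
  for (u in against) v <- v - sum(v * u) * u
  v
}

normalize_vec <- function(v, what) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) abort(paste0("zero difference vector for ", what, " mode."))
  v / nv
}

#' Define task-activity modes (targeted dimensionality reduction)
#'
#' Each mode is the unit-norm population direction separating the mean
#' activity in its window from the baseline (pre-cue) activity:
#' `w = r_window - r_baseline`, normalized. Orthogonalization by
#' Gram-Schmidt follows the fixed order: the middle mode is orthogonalized
#' to the ramp mode, the cue mode to both, and the execution mode to the
#' ramp mode; the ramp mode itself is left raw. (The trial-history mode,
#' defined by [define_trial_history_mode()], is never orthogonalized.)
#'
#' @param session A `cbg_session`, or a precomputed [mode_window_means()]
#'   tibble.
#' @param trials Optional trial indices (mode-definition trials).
#' @return A `mode_set`: list with `vectors` (units x modes matrix, columns
#'   `cue`, `middle`, `ramp`, `execution`), `unit_id`, and the
#'   orthogonalization record.
#' @export
define_modes <- function(session, trials = NULL) {
  wm <- if (inherits(session, "cbg_session")) {
    mode_window_means(session, trials)
  } else session
  raw <- function(col) wm[[col]] - wm$baseline
  ramp <- normalize_vec(raw("ramp"), "ramp")
  # a mode annihilated by orthogonalization (e.g. with a single unit the
  # ramp direction spans the space) becomes NA with a warning
  orth <- function(v, against, what) {
    v <- gram_schmidt(v, Filter(function(u) !anyNA(u), against))
    if (sqrt(sum(v^2)) < 1e-12) {
      warn(paste0(what, " mode is degenerate after orthogonalization."))
      return(rep(NA_real_, length(v)))
    }
    v / sqrt(sum(v^2))
  }
  middle <- orth(raw("middle"), list(ramp), "middle")
  cue <- orth(raw("cue"), list(ramp, middle), "cue")
  execution <- orth(raw("execution"), list(ramp), "execution")
  vectors <- cbind(cue = cue, middle = middle, ramp = ramp,
                   execution = execution)
  rownames(vectors) <- wm$unit_id
  structure(list(vectors = vectors, unit_id = wm$unit_id,
                 orthogonalized = list(middle = "ramp",
                                       cue = c("ramp", "middle"),
                                       execution = "ramp")),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set> ", nrow(x$vectors), " units x ",
      paste(colnames(x$vectors), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Define the trial-history mode
#'
#' One loading per neuron: the Spearman rank correlation between the
#' neuron's firing rate during the inter-trial interval (0-1 s before the
#' cue) and the regression-predicted lick time of the upcoming trial,
#' assembled into a unit vector. Neurons with constant ITI activity get a
#' loading of 0 (with a warning). The trial-history mode is not
#' orthogonalized to any other mode.
#'
#' @param session A `cbg_session`.
#' @param predicted_lick_times Tibble from [predict.history_fit()] (columns
#'   `trial`, `predicted_lick_time`), or a numeric vector aligned with
#'   `trials`.
#' @param trials Optional trial indices.
#' @return List with `vector` (unit-norm loadings), `loadings` (raw
#'   Spearman correlations) and `unit_id`.
#' @export
define_trial_history_mode <- function(session, predicted_lick_times,
                                      trials = NULL) {
  tr <- session$trials
  if (!is.null(trials)) tr <- tr[tr$trial %in% trials, , drop = FALSE]
  if (is.data.frame(predicted_lick_times)) {
    pred <- predicted_lick_times$predicted_lick_time[
      match(tr$trial, predicted_lick_times$trial)]
  } else {
    pred <- predicted_lick_times
  }
  ok <- !is.na(pred)
  tr <- tr[ok, , drop = FALSE]
  pred <- pred[ok]
  iti <- bin_spikes(session, bin_size = 1, alignment = "cue",
                    window = c(-1, 0), trials = tr$trial)
  rates <- matrix(iti[, , 1], nrow = dim(iti)[1])   # trials x units
  n_const <- 0L
  load <- vapply(seq_len(ncol(rates)), function(u) {
    if (sd(rates[, u]) == 0) {
      n_const <<- n_const + 1L
      return(0)
    }
    cor(rates[, u], pred, method = "spearman")
  }, numeric(1))
  if (n_const > 0) {
    warn(paste0(n_const, " unit(s) with constant ITI activity; loading 0."))
  }
  list(vector = normalize_vec(load, "trial-history"), loadings = load,
       unit_id = attr(iti, "unit_id"))
}

#' Project binned activity onto a mode
#'
#' Per-trial, per-bin dot product of the population activity with a mode
#' vector. `normalization = "control_sd"` divides by the standard deviation
#' of the projection across the given control trials (all bins pooled)
#' without subtracting the mean, so 0 still corresponds to zero spiking.
#'
#' @param binned A `binned_tensor` over the same unit set as the mode.
#' @param mode Numeric mode vector (units).
#' @param normalization `"raw"` or `"control_sd"`.
#' @param control_trials Trial indices defining the normalization SD
#'   (defaults to all trials in the tensor).
#' @return Tibble: `trial`, `time`, `value`.
#' @export
project_mode <- function(binned, mode,
                         normalization = c("raw", "control_sd"),
                         control_trials = NULL) {
  normalization <- match.arg(normalization)
  d <- dim(binned)
  if (length(mode) != d[2]) abort("mode dimensionality mismatch.")
  proj <- apply(binned, c(1, 3), function(v) sum(v * mode))
  if (normalization == "control_sd") {
    ctrl <- if (is.null(control_trials)) seq_len(d[1])
            else which(attr(binned, "trial_index") %in% control_trials)
    s <- sd(proj[ctrl, ])
    if (s == 0) abort("zero variance among control trials.")
    proj <- proj / s
  }
  tibble::tibble(
    trial = rep(attr(binned, "trial_index"), times = d[3]),
    time = rep(tensor_times(binned), each = d[1]),
    value = as.vector(proj))
}

#' Fraction of spiking activity explained by modes
#'
#' For each trial group, the trial-averaged, causally smoothed activity is
#' baseline-subtracted (0-0.2 s before the cue), and the squared projection
#' onto each mode is summed over the analysis span and divided by the total
#' squared activity across neurons. Mutually orthogonal modes explain at
#' most a total of 1 (Bessel). The trial-history mode is evaluated without
#' baseline subtraction.
#'
#' @param binned Cue-aligned `binned_tensor` whose window includes 0.2 s of
#'   pre-cue baseline.
#' @param mode_set A [define_modes()] `mode_set`.
#' @param groups Named list of trial-index vectors (e.g. lick-time groups,
#'   each with at least `min_trials` trials).
#' @param span Analysis span `(start, end)` in seconds from cue (default
#'   0.2 s from cue to the group's minimum lick is approximated by the
#'   tensor window end).
#' @param history_mode Optional trial-history mode vector (evaluated
#'   without baseline subtraction).
#' @param min_trials Minimum trials per group (default 10).
#' @return Tibble: `group`, `mode`, `proportion`.
#' @export
variance_explained <- function(binned, mode_set, groups, span = NULL,
                               history_mode = NULL, min_trials = 10) {
  times <- tensor_times(binned)
  if (is.null(span)) span <- c(0.2, max(times))
  base_bins <- times >= -0.2 & times < 0
  span_bins <- times >= span[1] & times <= span[2]
  if (!any(base_bins)) abort("tensor window lacks the pre-cue baseline.")
  out <- list()
  for (g in names(groups)) {
    rows <- which(attr(binned, "trial_index") %in% groups[[g]])
    if (length(rows) < min_trials) {
      abort(paste0("group ", g, " has fewer than ", min_trials, " trials."))
    }
    avg <- apply(binned[rows, , , drop = FALSE], c(2, 3), mean)  # units x bins
    base <- rowMeans(avg[, base_bins, drop = FALSE])
    centered <- avg - base
    tot <- sum(centered[, span_bins]^2)
    if (tot == 0) abort("zero total activity power.")
    for (m in colnames(mode_set$vectors)) {
      pr <- drop(mode_set$vectors[, m] %*% centered[, span_bins])
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g, mode = m, proportion = sum(pr^2) / tot)
    }
    if (!is.null(history_mode)) {
      pr <- drop(history_mode %*% avg[, span_bins])
      tot_raw <- sum(avg[, span_bins]^2)
      out[[length(out) + 1L]] <- tibble::tibble(
        group = g, mode = "trial_history",
        proportion = sum(pr^2) / tot_raw)
    }
  }
  purrr::list_rbind(out)
}

#' Angle between two population modes
#'
#' Cosine similarity with a shuffle-based significance test: the entries of
#' one vector are permuted `n_shuffles` times to build the chance
#' distribution of cosines at this dimensionality (cosines concentrate near
#' 0 as the number of neurons grows, so the raw value is not interpretable
#' without this reference).
#'
#' @param mode_a,mode_b Numeric vectors of equal length.
#' @param n_shuffles Permutations (default 1000).
#' @return One-row tibble: `cosine`, null band, `significant`.
#' @export
mode_angle <- function(mode_a, mode_b, n_shuffles = 1000L) {
  if (length(mode_a) != length(mode_b)) abort("dimension mismatch.")
  na <- sqrt(sum(mode_a^2)); nb <- sqrt(sum(mode_b^2))
  if (na < 1e-12 || nb < 1e-12) abort("zero vector.")
  cosine <- sum(mode_a * mode_b) / (na * nb)
  null <- vapply(seq_len(n_shuffles), function(i) {
    v <- sample(mode_b)
    sum(mode_a * v) / (na * nb)
  }, numeric(1))
  band <- quantile(null, c(0.025, 0.975))
  tibble::tibble(cosine = cosine,
                 null_lo = unname(band[1]), null_hi = unname(band[2]),
                 significant = cosine < band[1] || cosine > band[2])
}
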