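#' Construct a recording session
#'
#' A session bundles the behavioural trial table, the spike table, and the
#' unit metadata table of one recording. All within-trial times are seconds
#' relative to the cue onset of that trial; the spike table and the
#' `cue_onset` column of the trial table are on the session clock.
#'
#' @param trials Tibble with one row per trial and columns `trial` (1-based
#'   ordinal), `cue_onset` (s, session clock), `cue_present` (logical),
#'   `cue_intensity` (dB offset from the standard cue, 0 default),
#'   `delay_duration` (s), `first_lick_time` (s from cue onset, `NA` when the
#'   animal never licked), `rewarded` (logical), `iti_duration` (s), and the
#'   flattened perturbation descriptor columns `perturbed` (logical),
#'   `pert_target`, `pert_laterality`, `pert_onset`, `pert_duration`,
#'   `pert_ramp_down`, `pert_power`.
#' @param units Tibble with columns `unit_id`, `area` (e.g. "ALM", "STR"),
#'   `mean_rate` (spikes/s), `spike_width` (ms), `post_spike_suppression`
#'   (ms), `long_isi_fraction` (proportion of ISIs longer than the long-ISI
#'   threshold).
#' @param spikes Tibble with columns `unit_id` and `time_s` (session clock),
#'   sorted within unit.
#' @param animal_id,session_id Identifiers.
#' @param condition Delay schedule: `"switching"`, `"random"` or `"constant"`.
#' @return An object of class `cbg_session`.
#' @export
new_session <- function(trials, units, spikes,
                        animal_id = "animal", session_id = "session",
                        condition = c("switching", "random", "constant")) {
  condition <- match.arg(condition)
  trials <- fill_trial_defaults(tibble::as_tibble(trials))
  assert_trials(trials)
  units <- tibble::as_tibble(units)
  spikes <- tibble::as_tibble(spikes)
  if (nrow(spikes) > 0 && !all(c("unit_id", "time_s") %in% names(spikes))) {
    abort("`spikes` must have columns unit_id and time_s.")
  }
  if (is.unsorted(trials$cue_onset)) {
    abort("trials must be ordered by cue onset.")
  }
  bad_reward <- trials$rewarded &
    (is.na(trials$first_lick_time) |
       trials$first_lick_time < trials$delay_duration)
  if (any(bad_reward, na.rm = TRUE)) {
    abort("rewarded trials must have a first lick at or after the delay.")
  }
  spikes <- dplyr::arrange(spikes, .data$unit_id, .data$time_s)
  structure(
    list(animal_id = animal_id, session_id = session_id,
         condition = condition,
         trials = trials, units = units, spikes = spikes),
    class = "cbg_session"
  )
}

#' Fill default columns of a trial table
#'
#' Completes a partial trial tibble with the default values of the optional
#' columns (cue flags, ITI, perturbation descriptors) and, when absent,
#' assigns session-clock cue onsets spaced by ITI + response epoch.
#'
#' @param trials Tibble with at least `first_lick_time` and
#'   `delay_duration` columns.
#' @return The completed tibble.
#' @export
fill_trial_defaults <- function(trials) {
  n <- nrow(trials)
  defaults <- list(
    cue_present = TRUE, cue_intensity = 0, rewarded = FALSE,
    iti_duration = 3, perturbed = FALSE,
    pert_target = NA_character_, pert_laterality = NA_character_,
    pert_onset = NA_real_, pert_duration = NA_real_,
    pert_ramp_down = NA_real_, pert_power = NA_real_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(trials)) trials[[nm]] <- rep(defaults[[nm]], n)
  }
  if (!"trial" %in% names(trials)) trials$trial <- seq_len(n)
  if (!"cue_onset" %in% names(trials)) {
    span <- trials$iti_duration +
      pmin(dplyr::coalesce(trials$first_lick_time, 5), 5) + 1.5
    trials$cue_onset <- cumsum(span) - span[1] + trials$iti_duration[1] + 1.5
  }
  trials
}

#' @export
print.cbg_session <- function(x, ...) {
  cat("<cbg_session> ", x$animal_id, "/", x$session_id,
      " (", x$condition, ")\n", sep = "")
  cat("  trials: ", nrow(x$trials),
      "  units: ", nrow(x$units),
      "  spikes: ", nrow(x$spikes), "\n", sep = "")
  invisible(x)
}

trial_col_types <- function() {
  readr::cols(
    trial = readr::col_integer(),
    cue_onset = readr::col_double(),
    cue_present = readr::col_logical(),
    cue_intensity = readr::col_double(),
    delay_duration = readr::col_double(),
    first_lick_time = readr::col_double(),
    rewarded = readr::col_logical(),
    iti_duration = readr::col_double(),
    perturbed = readr::col_logical(),
    pert_target = readr::col_character(),
    pert_laterality = readr::col_character(),
    pert_onset = readr::col_double(),
    pert_duration = readr::col_double(),
    pert_ramp_down = readr::col_double(),
    pert_power = readr::col_double()
  )
}

#' Save / load a session bundle
#'
#' A bundle is a directory holding `trials.csv`, `spikes.csv`, `units.csv`
#' and a `manifest.yaml` with the session identifiers. The round trip is
#' lossless; an absent first lick is written as an empty field.
#'
#' @param session A `cbg_session`.
#' @param path Directory to write to (created if needed) / read from.
#' @return `save_session` returns `path` invisibly; `load_session` returns a
#'   `cbg_session`.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "cbg_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(session$trials, file.path(path, "trials.csv"), na = "")
  readr::write_csv(session$spikes, file.path(path, "spikes.csv"), na = "")
  readr::write_csv(session$units, file.path(path, "units.csv"), na = "")
  yaml::write_yaml(
    list(animal_id = session$animal_id, session_id = session$session_id,
         condition = session$condition,
         n_trials = nrow(session$trials), n_units = nrow(session$units)),
    file.path(path, "manifest.yaml")
  )
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  manifest_path <- file.path(path, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    abort(paste0("manifest not found: ", manifest_path))
  }
  manifest <- yaml::read_yaml(manifest_path)
  read_table <- function(file, col_types) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) abort(paste0("bundle table missing: ", file))
    tb <- suppressWarnings(readr::read_csv(fp, col_types = col_types,
                                           na = c("", "NA"),
                                           progress = FALSE))
    probs <- readr::problems(tb)
    if (nrow(probs) > 0) {
      abort(paste0("malformed row ", probs$row[1] - 1L, " in ", file, ": ",
                   probs$expected[1]))   # problems() rows count the header
    }
    tb
  }
  trials <- read_table("trials.csv", trial_col_types())
  spikes <- read_table("spikes.csv",
                       readr::cols(unit_id = readr::col_character(),
                                   time_s = readr::col_double()))
  units <- read_table("units.csv",
                      readr::cols(unit_id = readr::col_character(),
                                  area = readr::col_character(),
                                  .default = readr::col_double()))
  new_session(trials, units, spikes,
              animal_id = manifest$animal_id,
              session_id = manifest$session_id,
              condition = manifest$condition)
}
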