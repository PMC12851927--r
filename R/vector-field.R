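#' Two-dimensional vector field of population dynamics
#'
#' Characterizes how activity evolves in the plane spanned by the middle
#' mode (X) and the ramp mode (Y). Each consecutive pair of 50-ms time
#' points within a trial contributes a displacement vector anchored at the
#' current state; vectors are averaged within spatial bins of `bin` (0.5 in
#' normalized units) along both axes, keeping only bins with more than
#' `min_points` data points. The control field uses all cue-to-lick time
#' points of control trials; the stimulation field pools the time points
#' 100-400 ms after the inhibition onset in perturbed trials. For every
#' spatial bin where both fields exist the angular difference is reported,
#' except bins whose control vector lies within pi/6 of the through-origin
#' radial direction of that bin (where rewinding toward zero and collapsing
#' toward zero are indistinguishable).
#'
#' @param control Tibble of control-trial states: columns `trial`, `time`,
#'   `x`, `y` (projections in 50-ms bins, cue-to-lick span, control-SD
#'   normalized without mean subtraction).
#' @param stim Tibble of the same shape for perturbed trials.
#' @param stim_onset Inhibition onset (s after cue, default 0.6).
#' @param stim_window Window after onset pooled for the stim field (default
#'   `c(0.1, 0.4)`).
#' @param bin Spatial bin width (default 0.5).
#' @param min_points Minimum data points per spatial bin; bins with this
#'   many or fewer are omitted (default 30).
#' @param radial_exclusion Half-angle (rad) of the radial exclusion cone
#'   (default `pi/6`).
#' @return List with `control_field`, `stim_field` (tibbles: bin centers
#'   `x`, `y`, mean displacement `dx`, `dy`, `n`) and `angles` (tibble with
#'   per-bin angular difference in radians and the exclusion flag).
#' @export
vector_field_2d <- function(control, stim, stim_onset = 0.6,
                            stim_window = c(0.1, 0.4), bin = 0.5,
                            min_points = 30, radial_exclusion = pi / 6) {
  steps <- function(d) {
    d |>
      dplyr::arrange(.data$trial, .data$time) |>
      dplyr::group_by(.data$trial) |>
      dplyr::mutate(dx = dplyr::lead(.data$x) - .data$x,
                    dy = dplyr::lead(.data$y) - .data$y) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$dx))
  }
  field <- function(d) {
    d |>
      dplyr::mutate(bx = floor(.data$x / bin) * bin + bin / 2,
                    by = floor(.data$y / bin) * bin + bin / 2) |>
      dplyr::group_by(.data$bx, .data$by) |>
      dplyr::summarise(dx = mean(.data$dx), dy = mean(.data$dy),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::filter(.data$n > min_points) |>
      dplyr::rename(x = "bx", y = "by")
  }
  ctrl_field <- field(steps(control))
  stim_steps <- steps(stim) |>
    dplyr::filter(.data$time >= stim_onset + stim_window[1],
                  .data$time < stim_onset + stim_window[2])
  stim_field <- field(stim_steps)
  if (nrow(ctrl_field) == 0 || nrow(stim_field) == 0) {
    return(list(control_field = ctrl_field, stim_field = stim_field,
                angles = tibble::tibble()))
  }
  joined <- dplyr::inner_join(ctrl_field, stim_field,
                              by = c("x", "y"), suffix = c("_ctrl", "_stim"))
  ang <- function(dx, dy) atan2(dy, dx)
  wrap <- function(a) atan2(sin(a), cos(a))
  joined <- joined |>
    dplyr::mutate(
      theta_ctrl = ang(.data$dx_ctrl, .data$dy_ctrl),
      theta_stim = ang(.data$dx_stim, .data$dy_stim),
      angle_diff = wrap(.data$theta_stim - .data$theta_ctrl),
      radial = atan2(.data$y, .data$x),
      excluded = pmin(abs(wrap(.data$theta_ctrl - .data$radial)),
                      abs(wrap(.data$theta_ctrl - .data$radial - pi))) <
        radial_exclusion)
  list(control_field = ctrl_field, stim_field = stim_field,
       angles = joined[, c("x", "y", "angle_diff", "excluded")])
}

#' Plot a 2-D vector field
#'
#' @param field A field tibble from [vector_field_2d()].
#' @param scale Arrow scaling factor.
#' @return A ggplot object.
#' @export
plot_vector_field <- function(field, scale = 1) {
  ggplot2::ggplot(field, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x + scale * .data$dx,
                   yend = .data$y + scale * .data$dy),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "cm"))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "middle mode (norm.)", y = "ramp mode (norm.)") +
    ggplot2::theme_classic()
}
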