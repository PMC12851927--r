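#' Hazard rate of lick times
#'
#' The hazard `h(t) = f(t) / (1 - F(t))` is the instantaneous probability of
#' a first lick at time `t` given that no lick has occurred yet — the
#' moment-by-moment drive to lick. Lick times are binned (20-ms bins by
#' default), `f` is the binned probability mass, `F` its cumulative sum, and
#' the survivor in the denominator is evaluated at the bin start so the
#' discrete survival identity `1 - F = cumprod(1 - h_raw)` holds exactly.
#' The hazard is then smoothed with a centred boxcar over 5 bins.
#'
#' No-lick trials enter as right-censored beyond `t_max`: they contribute to
#' the at-risk denominator but never to `f`.
#'
#' @param lick_times Numeric vector of first-lick times (s); `NA` marks a
#'   no-lick (censored) trial.
#' @param t_max Censoring horizon in seconds (default 5, the no-lick horizon).
#' @param bin_size Bin width in seconds (default 0.02).
#' @param smooth_bins Width of the centred boxcar in bins (default 5).
#' @return A `hazard_curve`: tibble with columns `t` (bin centers), `h`
#'   (smoothed hazard, probability per bin), `h_raw`, `f` and `F`, plus
#'   attributes `bin_size`, `n` and `n_censored`.
#' @export
hazard_rate <- function(lick_times, t_max = 5, bin_size = 0.02,
                        smooth_bins = 5L) {
  if (all(is.na(lick_times))) {
    abort("hazard undefined: all trials are censored (no licks).")
  }
  if (any(lick_times < 0, na.rm = TRUE)) abort("lick times must be >= 0.")
  n <- length(lick_times)
  lt <- lick_times[!is.na(lick_times) & lick_times < t_max]
  edges <- seq(0, t_max, by = bin_size)
  n_bins <- length(edges) - 1L
  counts <- tabulate(pmin(floor(lt / bin_size) + 1L, n_bins), nbins = n_bins)
  f <- counts / n
  Fc <- cumsum(f)
  surv_start <- 1 - c(0, Fc[-n_bins])       # survivor at bin start
  h_raw <- ifelse(surv_start > 0, f / surv_start, NA_real_)
  h <- centered_boxcar(ifelse(is.na(h_raw), 0, h_raw), smooth_bins)
  h[is.na(h_raw)] <- NA_real_
  out <- tibble::tibble(t = edges[-length(edges)] + bin_size / 2,
                        h = h, h_raw = h_raw, f = f, F = Fc)
  structure(out, class = c("hazard_curve", class(out)),
            bin_size = bin_size, n = n,
            n_censored = sum(is.na(lick_times) | lick_times >= t_max))
}

#' Evaluate a hazard curve at given times
#'
#' @param curve A `hazard_curve`.
#' @param t Times in seconds.
#' @param raw Use the unsmoothed hazard?
#' @return Hazard (probability per bin) at the bins containing `t`.
#' @export
hazard_at <- function(curve, t, raw = FALSE) {
  bs <- attr(curve, "bin_size")
  idx <- pmin(pmax(floor(t / bs) + 1L, 1L), nrow(curve))
  if (raw) curve$h_raw[idx] else curve$h[idx]
}

sigmoid4 <- function(t, A, K, B, M) A + K / (1 + exp(-B * (t - M)))

fit_hazard_sigmoid <- function(curve) {
  bs <- attr(curve, "bin_size")
  t80_idx <- which(curve$F >= 0.80)
  if (length(t80_idx) == 0) t80_idx <- nrow(curve)
  keep <- seq_len(min(t80_idx))
  t <- curve$t[keep]
  h <- curve$h[keep]
  ok <- !is.na(h)
  t <- t[ok]; h <- h[ok]
  half <- min(h, na.rm = TRUE) + diff(range(h, na.rm = TRUE)) / 2
  m0 <- t[which(h >= half)[1]]
  fallback <- list(mid = m0, method = "halfmax_interp")
  if (length(t) < 6) return(fallback)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      h ~ sigmoid4(t, A, K, B, M),
      start = list(A = max(min(h), 1e-6), K = diff(range(h)) + 1e-6,
                   B = 5 / diff(range(t)), M = m0),
      lower = c(A = 0, K = 0, B = 0.01, M = min(t) - 1),
      upper = c(A = Inf, K = Inf, B = Inf, M = max(t) + 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  M <- coef(fit)[["M"]]
  if (M < min(t) - 0.5 || M > max(t) + 0.5) return(fallback)
  list(mid = M, method = "sigmoid", fit = fit)
}

#' Temporal shift between two hazard curves
#'
#' Each hazard is fitted with a four-parameter sigmoid (free baseline,
#' amplitude, slope, midpoint) over the rising phase, restricted to times
#' before the cumulative lick distribution reaches 80% (beyond which the
#' shrinking at-risk denominator makes the hazard noisy). The shift is the
#' difference between the two 50%-rise points (curve_b minus curve_a):
#' positive values mean `curve_b` rises later. If the sigmoid fit does not
#' converge, the half-maximum crossing by interpolation is used and flagged.
#'
#' @param curve_a,curve_b `hazard_curve` objects from comparable trial sets
#'   (e.g. control and perturbed).
#' @return A tibble with `shift` (s), the two midpoints `mid_a`, `mid_b`,
#'   and the fit `method` used for each curve.
#' @export
hazard_shift <- function(curve_a, curve_b) {
  fa <- fit_hazard_sigmoid(curve_a)
  fb <- fit_hazard_sigmoid(curve_b)
  tibble::tibble(shift = fb$mid - fa$mid,
                 mid_a = fa$mid, mid_b = fb$mid,
                 method = paste(fa$method, fb$method, sep = "/"))
}

#' @method autoplot hazard_curve
#' @export
autoplot.hazard_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t, y = .data$h)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from cue (s)", y = "hazard (prob. per bin)") +
    ggplot2::theme_classic()
}
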