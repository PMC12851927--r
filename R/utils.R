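#' Inverse-Gaussian random variates
#'
#' Draws from the inverse-Gaussian (Wald) distribution IG(mu, lambda) with mean
#' `mu` and shape `lambda`, via the Michael-Schucany-Haas transformation.
#' This is the first-passage-time distribution of a drift-diffusion process to
#' a fixed threshold, and the distribution used both to dispersion-match the
#' timer simulator's per-trial rates and to generate synthetic lick times.
#'
#' @param n Number of draws.
#' @param mu Mean, must be positive.
#' @param lambda Shape parameter, must be positive. Variance is `mu^3 / lambda`.
#' @return Numeric vector of positive draws.
#' @examples
#' x <- rinvgauss(1000, mu = 1.3, lambda = 12)
#' mean(x)
#' @export
rinvgauss <- function(n, mu, lambda) {
  stopifnot(mu > 0, lambda > 0)
  y <- rchisq(n, df = 1)
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Causal boxcar smoothing
#'
#' Replaces each bin by the mean of itself and the preceding bins spanning
#' `width` seconds. No future bins contribute (no leakage of post-event
#' activity into earlier times). At the start of the window the available
#' partial history is used (shrinking window), so a constant signal is left
#' unchanged everywhere.
#'
#' @param x Numeric vector (one bin per element) or matrix (bins in columns).
#' @param width Filter width in seconds.
#' @param bin_size Bin size in seconds.
#' @return Smoothed object of the same shape.
#' @export
causal_boxcar <- function(x, width, bin_size) {
  k <- max(1L, as.integer(round(width / bin_size)))
  if (is.matrix(x)) {
    return(t(apply(x, 1L, causal_boxcar, width = width, bin_size = bin_size)))
  }
  cs <- cumsum(x)
  n <- length(x)
  idx <- seq_len(n)
  lo <- pmax(idx - k, 0L)
  (cs - c(0, cs)[lo + 1L]) / (idx - lo)
}

#' Centred boxcar smoothing
#'
#' Symmetric moving average over `k` bins with shrinking windows at the edges.
#' Used for hazard-rate smoothing (5 bins of 20 ms).
#'
#' @param x Numeric vector.
#' @param k Odd number of bins.
#' @return Smoothed vector, same length.
#' @export
centered_boxcar <- function(x, k = 5L) {
  stopifnot(k %% 2 == 1)
  half <- (k - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Smoothstep ramp template
#'
#' Monotone ramp on [0, 1] used by the synthetic spike generator: 0 at the cue,
#' 1 at the (intended) lick, smooth in between (3u^2 - 2u^3). Clamped outside
#' [0, 1].
#'
#' @param u Normalized time, cue = 0, lick = 1.
#' @return Template values in [0, 1].
#' @export
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  3 * u^2 - 2 * u^3
}

# shared input checks ---------------------------------------------------------

assert_trials <- function(trials) {
  if (!is.data.frame(trials)) {
    abort("`trials` must be a data frame of trial records.")
  }
  needed <- c("trial", "cue_present", "delay_duration", "first_lick_time",
              "rewarded")
  missing <- setdiff(needed, names(trials))
  if (length(missing) > 0) {
    abort(paste0("`trials` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(trials)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
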