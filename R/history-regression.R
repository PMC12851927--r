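#' Build the lagged trial-history design
#'
#' For each licked cue trial, assembles the previous lick times `T_k`, the
#' previous reward outcomes `R_k`, and their interactions `TR_k = T_k * R_k`
#' at lags `k = 1..max_lag`. Trials following no-lick or no-cue trials are
#' handled by `na_action`: `"carry"` (default) takes the k-th most recent
#' trial *with a lick* as the lag-k regressor, keeping the design matrix
#' complete; `"drop"` requires the k immediately preceding trials to have
#' licks and drops the row otherwise.
#'
#' @param trials Trial tibble or `cbg_session`.
#' @param max_lag Maximum lag.
#' @param na_action `"carry"` or `"drop"`.
#' @return Tibble with `trial`, response `y` (first-lick time) and columns
#'   `T_1..`, `R_1..`, `TR_1..`.
#' @export
build_history_design <- function(trials, max_lag = 6,
                                 na_action = c("carry", "drop")) {
  if (inherits(trials, "cbg_session")) trials <- trials$trials
  assert_trials(trials)
  na_action <- match.arg(na_action)
  n <- nrow(trials)
  licked <- !is.na(trials$first_lick_time)
  out <- tibble::tibble(trial = trials$trial, y = trials$first_lick_time,
                        usable = licked & trials$cue_present)
  lick_idx <- which(licked)
  for (k in seq_len(max_lag)) {
    Tk <- rep(NA_real_, n)
    Rk <- rep(NA_real_, n)
    if (na_action == "carry") {
      # k-th most recent licked trial strictly before each trial
      pos <- findInterval(seq_len(n) - 1L, lick_idx)   # licked trials before i
      src <- ifelse(pos - k + 1L >= 1L, lick_idx[pmax(pos - k + 1L, 1L)],
                    NA_integer_)
      ok <- !is.na(src)
      Tk[ok] <- trials$first_lick_time[src[ok]]
      Rk[ok] <- as.numeric(trials$rewarded[src[ok]])
    } else {
      src <- seq_len(n) - k
      ok <- src >= 1L & licked[pmax(src, 1L)]
      Tk[ok] <- trials$first_lick_time[src[ok]]
      Rk[ok] <- as.numeric(trials$rewarded[src[ok]])
    }
    out[[paste0("T_", k)]] <- Tk
    out[[paste0("R_", k)]] <- Rk
    out[[paste0("TR_", k)]] <- Tk * Rk
  }
  out
}

history_terms <- function(family, lag) {
  unlist(lapply(seq_len(lag), function(k) {
    paste0(intersect(c("T", "R", "TR"), family), "_", k)
  }))
}

#' Default regressor-family grid
#'
#' The seven non-empty subsets of previous lick time (`T`), previous outcome
#' (`R`) and their interaction (`TR`); crossed with maximum lags 1-6 this
#' gives the 42 candidate models of the trial-history regression.
#'
#' @return List of character vectors.
#' @export
history_families <- function() {
  list("T", "R", "TR", c("T", "R"), c("T", "TR"), c("R", "TR"),
       c("T", "R", "TR"))
}

mad_explained <- function(y, pred, pred_null) {
  r1 <- median(abs(y - pred))
  r2 <- median(abs(y - pred_null))
  if (r2 == 0) return(ifelse(r1 == 0, 0, -Inf))
  1 - r1 / r2
}

#' Trial-history regression of lick time
#'
#' Regresses each trial's first-lick time on the recent behavioural history.
#' Candidate models are every regressor family crossed with maximum lags
#' `1..max_lag` (the default grid has 7 families x 6 lags = 42 models);
#' models are scored by five-fold cross-validated MAD explained
#' (`1 - R1/R2`, where `R1` is the median absolute residual of the model on
#' held-out trials and `R2` that of the intercept-only null), and the best
#' model is refit on all trials.
#'
#' @param trials Trial tibble or `cbg_session`.
#' @param max_lag Maximum lag of the grid (default 6).
#' @param folds Number of cross-validation folds (default 5).
#' @param families List of regressor families (subsets of
#'   `c("T","R","TR")`); default [history_families()].
#' @param na_action Passed to [build_history_design()].
#' @param min_trials Minimum number of usable trials (default 50).
#' @return A `history_fit`: list with `model` (the refit `lm`), `family`,
#'   `lag`, `cv_table` (tibble of all 42 models with mean CV score),
#'   `mad_explained` (full data), `design`, `n`. Supports [tidy()],
#'   [glance()] and [predict()].
#' @export
fit_history_regression <- function(trials, max_lag = 6, folds = 5,
                                   families = history_families(),
                                   na_action = c("carry", "drop"),
                                   min_trials = 50) {
  na_action <- match.arg(na_action)
  design <- build_history_design(trials, max_lag = max_lag,
                                 na_action = na_action)
  all_terms <- history_terms(c("T", "R", "TR"), max_lag)
  rows <- design$usable & complete.cases(design[all_terms])
  dat <- design[rows, , drop = FALSE]
  if (nrow(dat) < min_trials) {
    abort(paste0("insufficient usable trials (", nrow(dat), " < ",
                 min_trials, ")."))
  }
  fold_id <- rep_len(sample.int(folds), nrow(dat))

  grid <- tidyr::expand_grid(
    family = purrr::map_chr(families, paste, collapse = "+"),
    lag = seq_len(max_lag))
  fam_lookup <- setNames(families, purrr::map_chr(families, paste,
                                                  collapse = "+"))
  grid$cv_score <- purrr::map2_dbl(grid$family, grid$lag, function(fam, lag) {
    terms <- history_terms(fam_lookup[[fam]], lag)
    fml <- stats::reformulate(terms, response = "y")
    mean(vapply(seq_len(folds), function(f) {
      tr <- dat[fold_id != f, , drop = FALSE]
      te <- dat[fold_id == f, , drop = FALSE]
      fit <- lm(fml, data = tr)
      mad_explained(te$y, predict(fit, te), mean(tr$y))
    }, numeric(1)))
  })
  best <- grid[which.max(grid$cv_score), ]
  best_terms <- history_terms(fam_lookup[[best$family]], best$lag)
  model <- lm(stats::reformulate(best_terms, response = "y"), data = dat)
  structure(
    list(model = model, family = fam_lookup[[best$family]], lag = best$lag,
         cv_table = grid,
         mad_explained = mad_explained(dat$y, predict(model),
                                       mean(dat$y)),
         cv_score = best$cv_score,
         design = design, n = nrow(dat), max_lag = max_lag,
         na_action = na_action),
    class = "history_fit")
}

#' @export
print.history_fit <- function(x, ...) {
  cat("<history_fit> family {", paste(x$family, collapse = ", "),
      "} x ", x$lag, " lag(s); n = ", x$n, "\n", sep = "")
  cat("  CV MAD explained: ", round(x$cv_score, 4),
      "; full-data MAD explained: ", round(x$mad_explained, 4), "\n",
      sep = "")
  invisible(x)
}

#' @method tidy history_fit
#' @export
tidy.history_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @method glance history_fit
#' @export
glance.history_fit <- function(x, ...) {
  tibble::tibble(family = paste(x$family, collapse = "+"), lag = x$lag,
                 cv_mad_explained = x$cv_score,
                 mad_explained = x$mad_explained, n = x$n)
}

#' Predict lick times from trial history
#'
#' Applies the selected (or a refit lag-1..2) history regression to new
#' trials, returning the regression-predicted lick time per trial — the
#' scalar summary of recent history used, e.g., to define the
#' trial-history population mode.
#'
#' @param object A `history_fit`.
#' @param newdata Optional trial tibble or `cbg_session` (defaults to the
#'   trials the model was fit on).
#' @param ... Unused.
#' @return Tibble with `trial` and `predicted_lick_time` (`NA` where the
#'   lagged design is incomplete).
#' @export
predict.history_fit <- function(object, newdata = NULL, ...) {
  design <- if (is.null(newdata)) object$design
            else build_history_design(newdata, max_lag = object$max_lag,
                                      na_action = object$na_action)
  terms <- history_terms(object$family, object$lag)
  pred <- rep(NA_real_, nrow(design))
  ok <- complete.cases(design[terms])
  pred[ok] <- predict(object$model, design[ok, , drop = FALSE])
  tibble::tibble(trial = design$trial, predicted_lick_time = pred)
}
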