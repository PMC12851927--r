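test_that("decoder QC rejects pathological sessions", {
  ses <- toy_session(rep(1.2, 10))
  expect_error(fit_decoder(ses, 1:10), class = "cbg_qc_error")
  # relaxing QC still guards against fewer training points than k
  expect_error(fit_decoder(ses, 1:10, min_trials = 1, min_units = 1, k = 500),
               "training points")
})

test_that("kNN decoding transfers labels exactly in degenerate geometries", {
  fx <- fix_ramp()
  dec <- fix_ramp_decoder()
  # a test point placed on k identical training states inherits their label
  dec2 <- dec
  dec2$scores <- matrix(0, 40, dec$n_pc)
  dec2$labels <- rep(0.8, 40)
  X0 <- matrix(dec$center, nrow = 1)   # projects to the origin
  expect_equal(unname(cbgtimer:::knn_predict(dec2, X0)), 0.8)
  # k = 1 with a unique nearest neighbour: exact transfer
  dec3 <- dec
  dec3$k <- 1L
  i <- 57
  Xi <- matrix(dec$center, nrow = 1) +
    dec$scores[i, , drop = FALSE] %*% t(dec$rotation)
  expect_equal(unname(cbgtimer:::knn_predict(dec3, Xi)), dec$labels[i])
})

test_that("decoded values stay inside the convex hull of training labels", {
  fx <- fix_ramp()
  dec <- fix_ramp_decoder()
  d <- decode(dec, fx$session, fx$test_ctrl[1:30])
  expect_true(all(d$t_to_lick_hat >= min(dec$labels)))
  expect_true(all(d$t_to_lick_hat <= max(dec$labels)))
})

test_that("a planted ramping population is decodable; shuffled labels are not", {
  fx <- fix_ramp()
  dec <- fix_ramp_decoder()
  qc <- session_decodability(dec, fx$session, fx$test_ctrl)
  expect_gt(qc$r, 0.8)
  expect_true(qc$pass)
  # destroying the lick-time pairing destroys the correlation
  d <- decode(dec, fx$session, fx$test_ctrl)
  at <- d[abs(d$time - 0.6) < 0.025, ]
  lt <- fx$session$trials$first_lick_time[match(at$trial,
                                                fx$session$trials$trial)]
  set.seed(61)
  r_shuf <- abs(cor(at$decoded_lick_time, sample(lt)))
  expect_lt(r_shuf, 0.15)
  # too few held-out trials yields an explicit undefined result
  qc2 <- session_decodability(dec, fx$session, fx$test_ctrl[1:5])
  expect_true(is.na(qc2$r))
})

test_that("matched-pair comparison recovers planted pause and rewind shifts", {
  fx <- fix_ramp()
  dec <- fix_ramp_decoder()
  ses <- fx$session
  mc_p <- match_and_compare(dec, ses, fx$pert_pause, fx$test_ctrl)
  mc_r <- match_and_compare(dec, ses, fx$pert_rew, fx$test_ctrl)
  gt_p <- mean(fx$behavior_gt$effective_shift[fx$pert_pause], na.rm = TRUE)
  gt_r <- mean(fx$behavior_gt$effective_shift[fx$pert_rew], na.rm = TRUE)
  expect_equal(mc_p$summary$delta_decoded_lick, gt_p, tolerance = 0.35)
  expect_equal(mc_r$summary$delta_decoded_lick, gt_r, tolerance = 0.35)
  # rewind pushes the decoded time back further than the pause
  expect_gt(mc_r$summary$delta_decoded_lick, mc_p$summary$delta_decoded_lick)
  expect_gt(mc_r$summary$offset_post, mc_p$summary$offset_post)
  # matching is a function: one control per perturbed trial
  expect_equal(nrow(mc_p$pairs), length(fx$pert_pause))
  # sham perturbation: no systematic shift (bootstrap CI covers zero)
  sham <- fx$test_ctrl[seq(1, 99, by = 2)]
  mc_0 <- match_and_compare(dec, ses, sham, setdiff(fx$test_ctrl, sham))
  expect_lt(abs(mc_0$summary$offset_post), 0.2)
  set.seed(62)
  d_sham <- decode(dec, ses, sham)
  d_pool <- decode(dec, ses, setdiff(fx$test_ctrl, sham))
  chg <- function(d) {
    d |>
      dplyr::group_by(trial) |>
      dplyr::summarise(
        pre = decoded_lick_time[max(which(time + dec$bin_size <= 0.6))],
        post = if (any(time >= 1.4))
          decoded_lick_time[which(time >= 1.4)[1]] else NA_real_,
        .groups = "drop") |>
      dplyr::mutate(change = post - pre) |>
      dplyr::pull(change)
  }
  c1 <- chg(d_sham); c2 <- chg(d_pool)
  boot <- replicate(400, mean(sample(c1, length(c1), TRUE), na.rm = TRUE) -
                      mean(sample(c2, length(c2), TRUE), na.rm = TRUE))
  qs <- quantile(boot, c(0.025, 0.975))
  expect_true(qs[1] <= 0 && 0 <= qs[2])
  expect_error(match_and_compare(dec, ses, integer(0), fx$test_ctrl),
               "empty")
})

test_that("conclusions are stable across the plausible k range", {
  fx <- fix_ramp()
  deltas <- vapply(c(20, 50), function(k) {
    dec <- fit_decoder(fx$session, fx$train, k = k)
    mc_p <- match_and_compare(dec, fx$session, fx$pert_pause, fx$test_ctrl)
    mc_r <- match_and_compare(dec, fx$session, fx$pert_rew, fx$test_ctrl)
    c(mc_p$summary$delta_decoded_lick, mc_r$summary$delta_decoded_lick)
  }, numeric(2))
  expect_true(all(deltas > 0))                 # both shifts positive at all k
  expect_true(all(deltas[2, ] > deltas[1, ]))  # rewind > pause at all k
})
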