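test_that("reaction time is onset minus stimulus onset, absent when undefined", {
  ev <- tibble::tibble(
    valid = TRUE, n_reactions = 1L, onset_s = 5.42, peak_s = 5.8,
    return_s = 6.1, peak_elevation_m = 0.3, premature = FALSE
  )
  expect_equal(reaction_time(ev, stimulus_onset_s = 5.0), 0.42)
  expect_error(reaction_time(ev, 5.0, is_x = TRUE), class = "cpt_usage_error")

  omission <- ev
  omission$onset_s <- NA_real_
  expect_true(is.na(reaction_time(omission, 5.0)))

  early <- ev
  early$premature <- TRUE
  expect_true(is.na(reaction_time(early, 5.0)))
})

test_that("completion time is return minus onset, absent without a return", {
  ev <- tibble::tibble(
    valid = TRUE, n_reactions = 1L, onset_s = 0.4, peak_s = 0.8,
    return_s = 1.1, peak_elevation_m = 0.3, premature = FALSE
  )
  expect_equal(completion_time(ev), 0.7)
  partial <- ev
  partial$return_s <- NA_real_
  expect_true(is.na(completion_time(partial)))
  none <- ev
  none$onset_s <- NA_real_
  expect_true(is.na(completion_time(none)))
})

test_that("path length sums consecutive tracked distances", {
  # hand-summed consecutive distances: |0.1| + |0.1| + |-0.1| = 0.3
  w <- make_window(0:3 / 30, c(0, 0.1, 0.2, 0.1))
  expect_equal(path_length(w), 0.3)

  still <- make_window(0:5 / 30, rep(0.8, 6))
  expect_equal(path_length(still), 0)

  expect_equal(path_length(make_window(0, 0.8)), 0)
  expect_true(is.na(path_length(make_window(0:2 / 30, rep(0.8, 3), tracked = FALSE))))
})

test_that("path length is additive over splits sharing the boundary sample", {
  withr::local_seed(8)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    w <- tibble::tibble(
      t_s = seq(0, by = 1 / 30, length.out = n),
      x_m = cumsum(rnorm(n, sd = 0.02)),
      y_m = cumsum(rnorm(n, sd = 0.02)),
      z_m = cumsum(rnorm(n, sd = 0.02)),
      tracked = TRUE
    )
    k <- sample(2:(n - 1), 1)
    expect_equal(
      path_length(w),
      path_length(w[1:k, ]) + path_length(w[k:n, ]),
      tolerance = 1e-12
    )
  }
})

test_that("commission index is the X path over the larger neighbour path", {
  # neighbours with path lengths 4 and 5; X window with path 2
  mk <- function(total, n = 9) {
    step <- total / (n - 1)
    make_window(seq(0, by = 1 / 30, length.out = n),
      y = cumsum(c(0, rep(step, n - 1)))
    )
  }
  expect_equal(commission_index(mk(2), mk(4), mk(5)), 0.4)

  still <- make_window(0:8 / 30, rep(0, 9))
  expect_equal(commission_index(still, mk(4), mk(5)), 0)

  # both neighbours effectively motionless: not computable
  expect_true(is.na(commission_index(mk(2), still, still)))

  # final X-stimulus: previous neighbour only
  expect_equal(commission_index(mk(2), mk(4), NULL), 0.5)

  expect_error(commission_index(mk(2), mk(4), mk(5), is_x = FALSE),
    class = "cpt_usage_error"
  )
})

test_that("commission index is scale invariant and monotone in X amplitude", {
  t <- seq(0, 2, by = 1 / 30)
  neighbour <- make_window(t, 0.8 + mj_bump(t, 0.5))

  idx_for_amp <- function(amp, scale = 1) {
    x_win <- make_window(t, scale * (0.8 + mj_bump(t, 0.5, amp = amp)))
    nb <- neighbour
    nb$y_m <- nb$y_m * scale
    nb$x_m <- nb$x_m * scale
    nb$z_m <- nb$z_m * scale
    commission_index(x_win, nb, nb)
  }

  amps <- seq(0, 0.35, by = 0.05)
  idx <- vapply(amps, idx_for_amp, numeric(1))
  expect_true(all(diff(idx) >= -1e-12))

  for (s in c(0.5, 2, 10)) {
    expect_equal(
      vapply(amps, idx_for_amp, numeric(1), scale = s), idx,
      tolerance = 1e-9
    )
  }
})

test_that("trial classification follows the documented precedence", {
  p <- class_params()
  ev <- function(valid = TRUE, n = 1L, onset = 0.5, ret = 1.2, prem = FALSE) {
    list(valid = valid, n_reactions = n, onset_s = onset, return_s = ret, premature = prem)
  }
  # X trials cut on the index
  expect_equal(classify_trial(TRUE, index = 0.02, params = p), "correct_inhibition")
  expect_equal(classify_trial(TRUE, index = 0.3, params = p), "inhibited_commission")
  expect_equal(classify_trial(TRUE, index = 0.7, params = p), "commission")
  expect_equal(classify_trial(TRUE, index = NA_real_, params = p), "invalid_trial")

  # non-X precedence
  expect_equal(classify_trial(FALSE, ev(), params = p), "full_reaction")
  expect_equal(classify_trial(FALSE, ev(ret = NA_real_), params = p), "partial_omission")
  expect_equal(classify_trial(FALSE, ev(n = 0L, onset = NA_real_, ret = NA_real_), params = p), "omission")
  expect_equal(classify_trial(FALSE, ev(n = 2L), params = p), "multiple_reaction")
  expect_equal(classify_trial(FALSE, ev(n = 2L, prem = TRUE), params = p), "premature_reaction")
  expect_equal(classify_trial(FALSE, ev(valid = FALSE), valid = FALSE, params = p), "invalid_trial")
})

test_that("participant summaries take medians over valid observations only", {
  res <- tibble::tibble(
    index = 0:5,
    letter = c("A", "B", "C", "D", "X", "X"),
    is_x = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    onset_s = c(2, 5, 8, 11, 14, 17),
    rt_s = c(0.3, 0.5, 0.4, 0.8, NA, NA),
    ct_s = c(0.7, 0.8, 0.75, NA, NA, NA),
    displacement_m = c(1, 1, 1, 1, 0, 0),
    commission_index = c(NA, NA, NA, NA, 0, 0),
    n_reactions = c(1L, 1L, 1L, 1L, 0L, 0L),
    premature = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    event_class = factor(
      c(
        "full_reaction", "full_reaction", "full_reaction",
        "premature_reaction", "correct_inhibition", "correct_inhibition"
      ),
      levels = kinectcpt:::event_classes
    )
  )
  s <- summarize_participant(res)
  # premature trial excluded: odd count median of {0.3, 0.5, 0.4}
  expect_equal(s$median_rt_s, 0.4)
  expect_equal(s$n_rt_obs, 3L)
  # even count median = mean of the central pair is exercised with 2 CTs? 3 here
  expect_equal(s$median_ct_s, 0.75)
  expect_equal(s$median_commission_index, 0)
  expect_equal(s$n_ci_obs, 2L)
  expect_equal(s$n_full_reaction, 3L)
  expect_equal(s$n_premature_reaction, 1L)

  # even-count median: mean of central pair
  res2 <- res[1:2, ]
  s2 <- summarize_participant(res2)
  expect_equal(s2$median_rt_s, 0.4)

  # zero RT observations warn and give an NA median
  res3 <- res[5:6, ]
  expect_warning(s3 <- summarize_participant(res3), class = "cpt_no_rt_warning")
  expect_true(is.na(s3$median_rt_s))
  expect_equal(s3$n_rt_obs, 0L)
})

test_that("heavily untracked windows are invalid and excluded from medians", {
  sched <- cpt_schedule("revised-60", seed = 15)
  sim <- simulate_participant(sched, trait_profile(30, 30, 30), quiet_cfg(seed = 15))
  df <- tibble::as_tibble(sim$trajectory)
  # blank out ~1 s inside one non-X trial window
  j <- which(!sched$is_x)[6]
  i0 <- which(df$t_s >= sched$onset_s[j] + 0.2)[1]
  df$tracked[i0:(i0 + 30)] <- FALSE
  res <- score_session(as_trajectory(df), sched)
  expect_equal(as.character(res$event_class[j]), "invalid_trial")
  s <- summarize_participant(res)
  expect_equal(s$n_rt_obs, 47L)
  expect_equal(s$n_invalid_trial, 1L)
})

test_that("scored sessions agree with window-level operations", {
  sched <- cpt_schedule("revised-60", seed = 21)
  sim <- simulate_participant(sched, trait_profile(50, 50, 50), sim_config(seed = 21))
  res <- score_session(sim$trajectory, sched)
  trials <- segment_trials(sim$trajectory, sched)
  # displacement from the generic path_length on segmented windows
  d <- vapply(trials$samples, path_length, numeric(1))
  expect_equal(res$displacement_m, d, tolerance = 1e-12)
})
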