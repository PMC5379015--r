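test_that("the simulator is deterministic given a seed", {
  sched <- cpt_schedule("revised-60", seed = 4)
  tr <- trait_profile(60, 40, 70)
  cfg <- sim_config(seed = 4)
  a <- simulate_participant(sched, tr, cfg, seed = 99)
  b <- simulate_participant(sched, tr, cfg, seed = 99)
  expect_identical(tibble::as_tibble(a$trajectory), tibble::as_tibble(b$trajectory))
  expect_identical(a$swan, b$swan)
  c <- simulate_participant(sched, tr, cfg, seed = 100)
  expect_false(identical(a$trajectory$y_m, c$trajectory$y_m))
})

test_that("the omission branch produces a statistically flat segment", {
  sched <- cpt_schedule("revised-60", seed = 4)
  cfg <- sim_config(
    seed = 4, omission_base = 1, omission_slope_inattention = 0,
    commission_amp_base_m = 0, commission_amp_slope_impulsivity_m = 0,
    commission_amp_sd_m = 0,
    noise_sd_m = 0.001
  )
  sim <- simulate_participant(sched, trait_profile(50, 50, 50), cfg, seed = 7)
  expect_true(all(sim$truth$branch[!sim$truth$is_x] == "omission"))
  expect_lt(max(abs(sim$trajectory$y_m - 0.8)), 4 * 0.001 * 3) # AR(1) jitter only
})

test_that("noise-free programmed reaction times are recovered within a sample", {
  sched <- cpt_schedule("revised-60", seed = 5)
  cfg <- quiet_cfg(seed = 5)
  for (s in 1:5) {
    sim <- simulate_participant(sched, trait_profile(50, 50, 50), cfg, seed = s)
    res <- score_session(sim$trajectory, sched)
    cmp <- dplyr::inner_join(
      sim$truth[!sim$truth$is_x, c("index", "rt_true_s")],
      tibble::as_tibble(res)[, c("index", "rt_s")],
      by = "index"
    )
    expect_lte(max(abs(cmp$rt_s - cmp$rt_true_s)), 1 / 30 + 1e-9)
  }
})

test_that("zero commission amplitude scores a near-zero commission index", {
  sched <- cpt_schedule("revised-60", seed = 6)
  cfg <- quiet_cfg(
    seed = 6, commission_amp_base_m = 0,
    commission_amp_slope_impulsivity_m = 0, commission_amp_sd_m = 0
  )
  sim <- simulate_participant(sched, trait_profile(50, 50, 50), cfg)
  res <- score_session(sim$trajectory, sched)
  expect_true(all(res$commission_index[res$is_x] < 1e-9))
  expect_true(all(res$event_class[res$is_x] == "correct_inhibition"))
})

test_that("zero traits with zero noise give all-zero SWAN items", {
  sched <- cpt_schedule("revised-60", seed = 4)
  cfg <- quiet_cfg(seed = 4, swan_noise_sd = 0)
  sim <- simulate_participant(sched, trait_profile(0, 0, 0), cfg)
  expect_true(all(unlist(sim$swan) == 0))
})

test_that("simulate_trial emits a scoreable single-trial segment", {
  sched <- cpt_schedule("revised-60", seed = 8)
  stim <- sched[2, ]
  out <- simulate_trial(stim, trait_profile(50, 50, 50), quiet_cfg(), seed = 3)
  expect_true(all(out$segment$t_s >= stim$onset_s))
  expect_true(all(out$segment$t_s < stim$onset_s + stim$isi_after_s))
  if (out$truth$branch == "reaction") {
    ev <- detect_reaction(out$segment, baseline_y = 0.8, stimulus_onset_s = stim$onset_s)
    expect_lte(abs((ev$onset_s - stim$onset_s) - out$truth$rt), 1 / 30 + 1e-9)
  }
})

test_that("cohorts have the requested size and log true traits", {
  sched <- cpt_schedule("revised-60", seed = 2)
  co <- simulate_cohort(8, sched, cfg = sim_config(seed = 2), seed = 2)
  expect_equal(nrow(co), 8L)
  expect_true(all(co$inattention >= 0 & co$inattention <= 100))
  expect_true(all(c("median_rt_s", "median_commission_index", "item_01") %in% names(co)))

  one <- simulate_cohort(1, sched, cfg = sim_config(seed = 2), seed = 5)
  expect_equal(nrow(one), 1L)

  # deterministic
  co2 <- simulate_cohort(8, sched, cfg = sim_config(seed = 2), seed = 2)
  expect_identical(co, co2)
})

test_that("the pipeline is loss-free end to end through files", {
  sched <- cpt_schedule("revised-60", seed = 13)
  cfg <- quiet_cfg(seed = 13)
  sim <- simulate_participant(sched, trait_profile(50, 50, 50), cfg)

  traj_f <- withr::local_tempfile(fileext = ".csv")
  sched_f <- withr::local_tempfile(fileext = ".json")
  write_trajectory(sim$trajectory, traj_f)
  write_schedule(sched, sched_f)

  res <- score_session(read_trajectory(traj_f), read_schedule(sched_f))
  expect_equal(nrow(res), 60L)
  expect_false(any(is.na(res$event_class)))
  expect_false(any(res$event_class == "invalid_trial"))
  s <- summarize_participant(res)
  expect_equal(s$n_rt_obs, 48L)
  expect_equal(s$n_ci_obs, 12L)
})

test_that("mean omission count is non-decreasing in the inattention trait", {
  sched <- cpt_schedule("revised-60", seed = 3)
  cfg <- sim_config(seed = 3)
  grid <- c(0, 50, 100)
  reps <- 12
  means <- ses <- numeric(length(grid))
  withr::local_seed(17)
  for (g in seq_along(grid)) {
    counts <- numeric(reps)
    for (r in seq_len(reps)) {
      sim <- simulate_participant(
        sched, trait_profile(grid[g], 50, 50), cfg,
        seed = sample.int(2^30, 1)
      )
      counts[r] <- sum(sim$truth$branch == "omission")
    }
    means[g] <- mean(counts)
    ses[g] <- sd(counts) / sqrt(reps)
  }
  # Monte-Carlo monotonicity within 2 SE
  for (g in 2:length(grid)) {
    expect_gte(means[g] - means[g - 1], -2 * sqrt(ses[g]^2 + ses[g - 1]^2))
  }
})
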