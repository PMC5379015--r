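# Latent-trait participant and cohort simulator: minimum-jerk hand
# kinematics on a ~30 Hz grid plus SWAN item scores, so that scoring and
# psychometrics can be exercised end to end and parameter recovery is
# checkable against the programmed generative law.

#' Latent trait profile of a simulated participant
#'
#' Traits live on the 0-100 web scale of the SWAN instrument: higher
#' inattention drives more omissions, higher impulsivity drives faster
#' reaction times and larger X-trial excursions, higher hyperactivity
#' also shortens reaction times.
#'
#' @param inattention,hyperactivity,impulsivity Values in [0, 100].
#' @return A one-row tibble of class `cpt_traits`.
#' @export
trait_profile <- function(inattention = 50, hyperactivity = 50, impulsivity = 50) {
  vals <- c(inattention, hyperactivity, impulsivity)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    cpt_abort("traits must lie in [0, 100].", "cpt_invalid_traits")
  }
  structure(
    tibble::tibble(
      inattention = inattention,
      hyperactivity = hyperactivity,
      impulsivity = impulsivity
    ),
    class = c("cpt_traits", tbl_classes)
  )
}

#' Simulator configuration
#'
#' Generative model of one session. Reaction times follow a shifted
#' lognormal, `rt = rt_shift_s + exp(rt_mu0 + b_imp * impulsivity +
#' b_hyp * hyperactivity + rt_sigma * Z)`: the canonical positive-skew
#' RT family, with negative trait slopes so more impulsive and more
#' hyperactive profiles respond faster. Omission probability grows
#' linearly in inattention; the X-trial excursion amplitude grows
#' linearly in impulsivity. Hand raises are minimum-jerk
#' rise-hold-return bumps of `raise_height_m`; sensor jitter is AR(1)
#' noise (temporally correlated, as skeletal tracking jitter is).
#'
#' @param rt_mu0 Log-scale location of the RT lognormal at zero traits.
#' @param rt_shift_s Irreducible RT shift (s).
#' @param rt_sigma Log-scale RT spread.
#' @param rt_slope_impulsivity,rt_slope_hyperactivity Log-scale change
#'   per trait unit (negative = faster).
#' @param omission_base,omission_slope_inattention Omission probability
#'   intercept and per-unit slope (clamped to [0, 1]).
#' @param commission_amp_base_m,commission_amp_slope_impulsivity_m,commission_amp_sd_m
#'   X-trial excursion amplitude model (m): base + slope * impulsivity +
#'   Gaussian jitter, clamped at 0.
#' @param premature_prob Probability a non-X reaction starts up to
#'   `premature_max_lead_s` before the stimulus.
#' @param multiple_prob Probability of a second raise in a non-X window.
#' @param premature_max_lead_s Largest premature lead (s).
#' @param raise_height_m,raise_duration_s,hold_s,return_duration_s
#'   Minimum-jerk raise kinematics.
#' @param noise_sd_m Marginal sd of AR(1) sensor jitter (m).
#' @param noise_ar AR(1) coefficient of the jitter.
#' @param rate_hz Sampling rate of the synthetic stream.
#' @param tail_s Recording continued past the final stimulus (s).
#' @param rest_pos Rest position of the hand (m, camera frame).
#' @param swan_noise_sd SD of the iid Gaussian item noise around the
#'   factor's trait in the SWAN generator.
#' @param seed Integer seed used by [simulate_participant()] and
#'   [simulate_cohort()].
#' @return A list of class `cpt_sim_config`.
#' @export
sim_config <- function(rt_mu0 = log(0.45), rt_shift_s = 0.15, rt_sigma = 0.35,
                       rt_slope_impulsivity = -0.004,
                       rt_slope_hyperactivity = -0.002,
                       omission_base = 0.01,
                       omission_slope_inattention = 0.0015,
                       commission_amp_base_m = 0.01,
                       commission_amp_slope_impulsivity_m = 0.0025,
                       commission_amp_sd_m = 0.02,
                       premature_prob = 0.02,
                       multiple_prob = 0.05,
                       premature_max_lead_s = 0.3,
                       raise_height_m = 0.30, raise_duration_s = 0.35,
                       hold_s = 0.10, return_duration_s = 0.40,
                       noise_sd_m = 0.001, noise_ar = 0.9,
                       rate_hz = 30, tail_s = 3,
                       rest_pos = c(x = 0.10, y = 0.80, z = 1.60),
                       swan_noise_sd = 8,
                       seed = 1L) {
  stopifnot(
    rate_hz > 0, noise_sd_m >= 0, noise_ar >= 0, noise_ar < 1,
    raise_height_m > 0, raise_duration_s > 0, return_duration_s > 0,
    hold_s >= 0, tail_s >= 0, swan_noise_sd >= 0,
    premature_prob >= 0, premature_prob <= 1,
    multiple_prob >= 0, multiple_prob <= 1
  )
  structure(
    list(
      rt_mu0 = rt_mu0, rt_shift_s = rt_shift_s, rt_sigma = rt_sigma,
      rt_slope_impulsivity = rt_slope_impulsivity,
      rt_slope_hyperactivity = rt_slope_hyperactivity,
      omission_base = omission_base,
      omission_slope_inattention = omission_slope_inattention,
      commission_amp_base_m = commission_amp_base_m,
      commission_amp_slope_impulsivity_m = commission_amp_slope_impulsivity_m,
      commission_amp_sd_m = commission_amp_sd_m,
      premature_prob = premature_prob, multiple_prob = multiple_prob,
      premature_max_lead_s = premature_max_lead_s,
      raise_height_m = raise_height_m, raise_duration_s = raise_duration_s,
      hold_s = hold_s, return_duration_s = return_duration_s,
      noise_sd_m = noise_sd_m, noise_ar = noise_ar,
      rate_hz = rate_hz, tail_s = tail_s, rest_pos = rest_pos,
      swan_noise_sd = swan_noise_sd, seed = as.integer(seed)
    ),
    class = "cpt_sim_config"
  )
}

# minimum-jerk position profile on [0, 1]
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# elevation of a rise-hold-return bump evaluated at times t
bump_profile <- function(t, start, amp, rise_d, hold_d, return_d) {
  e <- numeric(length(t))
  u <- t - start
  up <- u >= 0 & u < rise_d
  e[up] <- amp * min_jerk(u[up] / rise_d)
  hold <- u >= rise_d & u < rise_d + hold_d
  e[hold] <- amp
  down <- u >= rise_d + hold_d & u < rise_d + hold_d + return_d
  e[down] <- amp * (1 - min_jerk((u[down] - rise_d - hold_d) / return_d))
  e
}

# draw the per-trial ground truth (branch, RT, amplitude) for one trial
draw_trial_truth <- function(stimulus_is_x, traits, cfg) {
  rt <- cfg$rt_shift_s + exp(
    cfg$rt_mu0 +
      cfg$rt_slope_impulsivity * traits$impulsivity +
      cfg$rt_slope_hyperactivity * traits$hyperactivity +
      cfg$rt_sigma * stats::rnorm(1)
  )
  if (stimulus_is_x) {
    amp <- max(0, cfg$commission_amp_base_m +
      cfg$commission_amp_slope_impulsivity_m * traits$impulsivity +
      stats::rnorm(1, sd = cfg$commission_amp_sd_m))
    list(branch = "x_excursion", rt = rt, amp = amp, lead = 0, second = NA_real_)
  } else {
    p_om <- min(1, max(0, cfg$omission_base +
      cfg$omission_slope_inattention * traits$inattention))
    if (stats::runif(1) < p_om) {
      return(list(branch = "omission", rt = NA_real_, amp = 0, lead = 0, second = NA_real_))
    }
    lead <- if (stats::runif(1) < cfg$premature_prob) {
      stats::runif(1, 0.05, cfg$premature_max_lead_s)
    } else {
      0
    }
    second <- if (stats::runif(1) < cfg$multiple_prob) {
      stats::runif(1, 0.1, 0.4)
    } else {
      NA_real_
    }
    list(
      branch = if (lead > 0) "premature" else "reaction",
      rt = rt, amp = cfg$raise_height_m, lead = lead, second = second
    )
  }
}

#' Simulate one trial's trajectory segment
#'
#' Generates the hand trajectory of a single stimulus presentation on
#' its own window `[onset, onset + isi)`. Non-X trials produce a
#' minimum-jerk raise at a sampled reaction time (or nothing, on the
#' omission branch); X trials produce an excursion whose amplitude comes
#' from the impulsivity-linked commission model and may be ~0.
#'
#' @param stimulus One row of a `cpt_schedule` (needs `is_x`, `onset_s`,
#'   `isi_after_s`).
#' @param traits A [trait_profile()].
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed for a deterministic draw.
#' @return A list with `segment` (a tibble of samples) and `truth`
#'   (branch, programmed RT, amplitude).
#' @export
simulate_trial <- function(stimulus, traits, cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) local_cpt_seed(seed)
  isi <- stimulus$isi_after_s
  if (is.na(isi)) isi <- min(5, cfg$tail_s + 2)
  t <- seq(stimulus$onset_s, stimulus$onset_s + isi - 1e-9, by = 1 / cfg$rate_hz)
  truth <- draw_trial_truth(stimulus$is_x, traits, cfg)
  e <- trial_elevation(t, stimulus$onset_s, truth, cfg)
  seg <- tibble::tibble(
    t_s = t,
    x_m = cfg$rest_pos[["x"]] + noise_series(length(t), cfg),
    y_m = cfg$rest_pos[["y"]] + e + noise_series(length(t), cfg),
    z_m = cfg$rest_pos[["z"]] + noise_series(length(t), cfg),
    tracked = TRUE
  )
  list(segment = seg, truth = tibble::as_tibble(truth))
}

# add one bump to the elevation vector, touching only its support
add_bump <- function(e, t, rate_hz, start, amp, rise_d, hold_d, return_d) {
  total <- rise_d + hold_d + return_d
  i0 <- max(1L, as.integer(ceiling(start * rate_hz - 1e-9)) + 1L)
  i1 <- min(length(t), as.integer(floor((start + total) * rate_hz + 1e-9)) + 1L)
  if (i0 > i1) {
    return(e)
  }
  idx <- i0:i1
  e[idx] <- e[idx] + bump_profile(t[idx], start, amp, rise_d, hold_d, return_d)
  e
}

# fast path over a uniform grid starting at t = 0
trial_elevation_add <- function(e, t, onset_s, truth, cfg) {
  if (truth$branch == "omission" || truth$amp <= 0) {
    return(e)
  }
  start <- onset_s + if (truth$branch == "premature") -truth$lead else truth$rt
  e <- add_bump(
    e, t, cfg$rate_hz, start, truth$amp,
    cfg$raise_duration_s, cfg$hold_s, cfg$return_duration_s
  )
  if (!is.na(truth$second)) {
    start2 <- start + cfg$raise_duration_s + cfg$hold_s + cfg$return_duration_s +
      truth$second
    e <- add_bump(
      e, t, cfg$rate_hz, start2, truth$amp,
      cfg$raise_duration_s, cfg$hold_s, cfg$return_duration_s
    )
  }
  e
}

trial_elevation <- function(t, onset_s, truth, cfg) {
  e <- numeric(length(t))
  if (truth$branch == "omission" || truth$amp <= 0) {
    return(e)
  }
  start <- onset_s + if (truth$branch == "premature") -truth$lead else truth$rt
  e <- e + bump_profile(
    t, start, truth$amp,
    cfg$raise_duration_s, cfg$hold_s, cfg$return_duration_s
  )
  if (!is.na(truth$second)) {
    start2 <- start + cfg$raise_duration_s + cfg$hold_s + cfg$return_duration_s +
      truth$second
    e <- e + bump_profile(
      t, start2, truth$amp,
      cfg$raise_duration_s, cfg$hold_s, cfg$return_duration_s
    )
  }
  e
}

noise_series <- function(n, cfg) {
  if (cfg$noise_sd_m <= 0 || n == 0L) {
    return(numeric(n))
  }
  innov_sd <- cfg$noise_sd_m * sqrt(1 - cfg$noise_ar^2)
  as.numeric(stats::filter(
    stats::rnorm(n, sd = innov_sd), cfg$noise_ar,
    method = "recursive",
    init = stats::rnorm(1, sd = cfg$noise_sd_m)
  ))
}

#' Simulate a full participant session
#'
#' Builds the complete trajectory stream of one session — a uniform-rate
#' sample grid from t = 0 (before the first stimulus, covering the
#' schedule lead-in) to `tail_s` past the final stimulus — by summing
#' per-trial minimum-jerk bumps on the grid, then adds AR(1) sensor
#' jitter. SWAN items are generated as the item's factor trait plus iid
#' Gaussian noise, clamped to [0, 100].
#'
#' @param schedule A `cpt_schedule`.
#' @param traits A [trait_profile()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to `cfg$seed`. The same
#'   `(schedule, traits, cfg, seed)` always yields an identical session.
#' @return A list of class `cpt_participant`: `trajectory`
#'   (`cpt_trajectory`), `swan` (one-row tibble `item_01`..`item_18`),
#'   `truth` (per-trial generative ground truth), `traits`.
#' @export
simulate_participant <- function(schedule, traits, cfg = sim_config(),
                                 seed = cfg$seed) {
  local_cpt_seed(seed)
  n <- nrow(schedule)
  t_end <- schedule$onset_s[n] + cfg$tail_s
  t <- seq(0, t_end, by = 1 / cfg$rate_hz)
  e <- numeric(length(t))

  branch <- character(n)
  rt_true <- amp_true <- lead_true <- second_true <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    truth <- draw_trial_truth(schedule$is_x[i], traits, cfg)
    branch[i] <- truth$branch
    rt_true[i] <- truth$rt
    amp_true[i] <- truth$amp
    lead_true[i] <- truth$lead
    second_true[i] <- truth$second
    e <- trial_elevation_add(e, t, schedule$onset_s[i], truth, cfg)
  }
  truths <- tibble::new_tibble(
    list(
      index = schedule$index, is_x = schedule$is_x, branch = branch,
      rt_true_s = rt_true, amp_true_m = amp_true,
      lead_s = lead_true, second_gap_s = second_true
    ),
    nrow = n
  )

  traj <- as_trajectory(
    tibble::new_tibble(
      list(
        t_s = t,
        x_m = cfg$rest_pos[["x"]] + noise_series(length(t), cfg),
        y_m = cfg$rest_pos[["y"]] + e + noise_series(length(t), cfg),
        z_m = cfg$rest_pos[["z"]] + noise_series(length(t), cfg),
        tracked = rep(TRUE, length(t))
      ),
      nrow = length(t)
    ),
    rate_hz = cfg$rate_hz
  )

  swan <- simulate_swan(traits, cfg)

  structure(
    list(
      trajectory = traj,
      swan = swan,
      truth = truths,
      traits = traits
    ),
    class = "cpt_participant"
  )
}

simulate_swan <- function(traits, cfg) {
  means <- c(
    rep(traits$inattention, 9),
    rep(traits$hyperactivity, 6),
    rep(traits$impulsivity, 3)
  )
  items <- pmin(100, pmax(0, means + stats::rnorm(18, sd = cfg$swan_noise_sd)))
  tibble::new_tibble(
    as.list(stats::setNames(items, sprintf("item_%02d", 1:18))),
    nrow = 1L
  )
}

#' Trait distribution for cohort simulation
#'
#' Independent truncated-normal draws per trait, on the 0-100 scale.
#'
#' @param mean,sd Length-3 vectors (inattention, hyperactivity,
#'   impulsivity).
#' @return A list of class `cpt_trait_distribution`.
#' @export
trait_distribution <- function(mean = c(50, 50, 50), sd = c(20, 20, 20)) {
  stopifnot(length(mean) == 3L, length(sd) == 3L, all(sd >= 0))
  structure(list(mean = mean, sd = sd), class = "cpt_trait_distribution")
}

#' Simulate and score a cohort
#'
#' Draws `n` independent participants from a trait distribution,
#' simulates each session, and (by default) scores it immediately so the
#' cohort fits in memory as one tidy row per participant. True trait
#' draws are always logged for parameter-recovery checks.
#'
#' @param n Number of participants.
#' @param schedule A `cpt_schedule` shared by the cohort.
#' @param trait_dist A [trait_distribution()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @param score Score each session with [score_session()] and bind the
#'   participant summary columns (default `TRUE`).
#' @param keep_streams Retain each trajectory in a `stream` list-column
#'   (default `FALSE`; a 200-participant cohort of raw streams is large).
#' @param onset,classify Scoring parameters, used when `score = TRUE`.
#' @return A tibble with one row per participant: `participant_id`, the
#'   true traits, the 18 SWAN items, and (when scoring) the
#'   [summarize_participant()] columns.
#' @export
simulate_cohort <- function(n, schedule = cpt_schedule("revised-60", seed = cfg$seed),
                            trait_dist = trait_distribution(),
                            cfg = sim_config(), seed = cfg$seed,
                            score = TRUE, keep_streams = FALSE,
                            onset = onset_params(), classify = class_params()) {
  if (!is_scalar_number(n) || n < 1) {
    cpt_abort("`n` must be a positive count.", "cpt_invalid_design")
  }
  n <- as.integer(n)
  local_cpt_seed(seed)
  part_seeds <- sample.int(.Machine$integer.max - 1L, n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- trait_profile(
      draw_trait(trait_dist$mean[1], trait_dist$sd[1]),
      draw_trait(trait_dist$mean[2], trait_dist$sd[2]),
      draw_trait(trait_dist$mean[3], trait_dist$sd[3])
    )
    sim <- simulate_participant(schedule, tr, cfg, seed = part_seeds[i])
    cols <- c(
      list(participant_id = sprintf("P%03d", i)),
      as.list(unclass(tr)[c("inattention", "hyperactivity", "impulsivity")]),
      as.list(sim$swan)
    )
    if (score) {
      res <- score_session(sim$trajectory, schedule, onset = onset, classify = classify)
      cols <- c(cols, as.list(summarize_participant(res)))
    }
    if (keep_streams) {
      cols$stream <- list(sim$trajectory)
    }
    rows[[i]] <- tibble::new_tibble(cols, nrow = 1L)
  }
  dplyr::bind_rows(rows)
}

draw_trait <- function(mean, sd) {
  min(100, max(0, stats::rnorm(1, mean, sd)))
}
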