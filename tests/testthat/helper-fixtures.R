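# Constructed-trajectory builders used across tests. Independent of the
# simulator: plain closed-form minimum-jerk bumps.

mj_pos <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# rise-hold-return elevation bump
mj_bump <- function(t, start, amp = 0.3, rise = 0.35, hold = 0.1, ret = 0.4) {
  up <- amp * mj_pos((t - start) / rise)
  down <- amp * mj_pos((t - start - rise - hold) / ret)
  up - down
}

make_window <- function(t, y, x = 0.1, z = 1.6, tracked = TRUE) {
  tibble::tibble(
    t_s = t,
    x_m = rep_len(x, length(t)),
    y_m = y,
    z_m = rep_len(z, length(t)),
    tracked = rep_len(tracked, length(t))
  )
}

# a full single-trial stream: rest at baseline, one optional bump
make_trial_stream <- function(t0 = 0, t1 = 4, rate = 30, baseline = 0.8,
                              bump_start = NULL, amp = 0.3, ...) {
  t <- seq(t0, t1, by = 1 / rate)
  y <- rep(baseline, length(t))
  if (!is.null(bump_start)) {
    y <- y + mj_bump(t, bump_start, amp = amp, ...)
  }
  as_trajectory(make_window(t, y), rate_hz = rate)
}

quiet_cfg <- function(...) {
  sim_config(
    noise_sd_m = 0, premature_prob = 0, multiple_prob = 0,
    omission_base = 0, omission_slope_inattention = 0, ...
  )
}
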