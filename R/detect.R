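#' Onset-detection thresholds
#'
#' Tunable parameters of the movement-onset detector. The hand is deemed
#' to start rising at the last sample before the first frame of a
#' sustained vertical-velocity crossing (`v_min` exceeded for `k`
#' consecutive frames) whose elevation subsequently clears the rise
#' threshold. Distinct rise episodes are counted with an elevation
#' Schmitt trigger: an episode arms when elevation exceeds
#' `rise_min_m` above baseline and releases when it falls back below
#' `rest_band_m`, so jitter around a single threshold cannot double
#' count.
#'
#' @param v_min Sustained vertical-velocity threshold (m/s). Default
#'   0.15 m/s, an order of magnitude above 30 Hz skeletal jitter but far
#'   below the ~1.6 m/s peak of a 0.3 m hand raise.
#' @param k Frames the velocity must stay above `v_min` (default 3, i.e.
#'   100 ms at 30 Hz).
#' @param v_release_frac A velocity run is considered new only if
#'   preceded by a frame at or below `v_release_frac * v_min` (default
#'   0.4), merging runs that dip briefly.
#' @param rise_min_m Elevation above baseline that qualifies an episode
#'   as a raise (m).
#' @param rest_band_m Elevation below which the hand is back in the rest
#'   band (m); the return time is the first sample re-entering it.
#' @return A list of class `cpt_onset_params`.
#' @export
onset_params <- function(v_min = 0.15, k = 3L, v_release_frac = 0.4,
                         rise_min_m = 0.05, rest_band_m = 0.05) {
  stopifnot(v_min > 0, k >= 1L, v_release_frac >= 0, v_release_frac <= 1,
            rise_min_m > 0, rest_band_m > 0, rest_band_m <= rise_min_m)
  structure(
    list(
      v_min = v_min, k = as.integer(k), v_release_frac = v_release_frac,
      rise_min_m = rise_min_m, rest_band_m = rest_band_m
    ),
    class = "cpt_onset_params"
  )
}

#' Detect the hand-raise event in a trial window
#'
#' Runs the movement-onset detector over one trial's samples (pre-onset
#' baseline buffer plus in-window samples). Only tracked samples are
#' used. The returned event describes the first rise episode: when the
#' hand started to rise, when it peaked, when it re-entered the rest
#' band, how high it rose, how many distinct rise episodes occurred in
#' the window, and whether the first episode began before the stimulus
#' appeared (a premature reaction).
#'
#' @param samples Data frame of samples (`t_s`, `y_m`, `tracked`),
#'   typically `buffer` and `samples` of one `segment_trials()` row
#'   combined.
#' @param baseline_y Rest-position hand height for this trial (m).
#' @param stimulus_onset_s Stimulus onset (s); episodes starting earlier
#'   are flagged premature.
#' @param params An [onset_params()] list.
#' @return One-row tibble: `valid`, `n_reactions`, `onset_s`, `peak_s`,
#'   `return_s`, `peak_elevation_m`, `premature`. `valid` is `FALSE`
#'   (the invalid-trial signal) when fewer than two tracked samples are
#'   available.
#' @examples
#' t <- seq(0, 2, by = 1 / 30)
#' y <- 0.8 + pmax(0, pmin(1, (t - 0.9) / 0.3)) * 0.3 * (t < 1.5)
#' win <- tibble::tibble(t_s = t, y_m = y, tracked = TRUE)
#' detect_reaction(win, baseline_y = 0.8, stimulus_onset_s = 0.5)
#' @export
detect_reaction <- function(samples, baseline_y, stimulus_onset_s,
                            params = onset_params()) {
  keep <- samples$tracked & is.finite(samples$y_m)
  t <- samples$t_s[keep]
  e <- samples$y_m[keep] - baseline_y
  res <- detect_episodes_cpp(
    t, e,
    params$v_min, params$k, params$v_release_frac * params$v_min,
    params$rise_min_m, params$rest_band_m, stimulus_onset_s
  )
  tibble::tibble(
    valid = res$valid,
    n_reactions = as.integer(res$n_reactions),
    onset_s = res$onset_s,
    peak_s = res$peak_s,
    return_s = res$return_s,
    peak_elevation_m = res$peak_elevation_m,
    premature = res$premature
  )
}
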