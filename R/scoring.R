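# Per-trial measures, event classification and participant summaries.

#' Classification thresholds
#'
#' @param c_lo Commission-index cut below which an X trial counts as a
#'   correct inhibition (default 0.1: displacement within jitter range of
#'   a tenth of a neighbouring reaction).
#' @param c_hi Commission-index cut at or above which an X trial counts
#'   as a full commission (default 0.5); indices in `[c_lo, c_hi)` are
#'   inhibited commissions, movements begun and aborted.
#' @param d_min_m Smallest neighbour displacement (m) accepted as a
#'   commission-index denominator; below it the index is not computable.
#' @param max_untracked_s Untracked time per window above which the trial
#'   is invalid (default 0.5 s): inhibition cannot be certified from
#'   missing data.
#' @return A list of class `cpt_class_params`.
#' @export
class_params <- function(c_lo = 0.1, c_hi = 0.5, d_min_m = 0.01,
                         max_untracked_s = 0.5) {
  stopifnot(c_lo >= 0, c_hi > c_lo, d_min_m > 0, max_untracked_s > 0)
  structure(
    list(c_lo = c_lo, c_hi = c_hi, d_min_m = d_min_m,
         max_untracked_s = max_untracked_s),
    class = "cpt_class_params"
  )
}

#' Hand-path length of a trial window
#'
#' Sum of Euclidean distances between consecutive tracked samples, in
#' metres. Untracked samples are skipped, so the path connects the
#' tracked subsequence. Windows with no tracked samples return `NA`
#' (the invalid-trial signal); a single tracked sample gives 0.
#'
#' @param samples Data frame with `x_m`, `y_m`, `z_m`, `tracked`.
#' @return Path length in metres.
#' @examples
#' w <- tibble::tibble(
#'   t_s = 0:3 / 30, x_m = 0, y_m = c(0, 0.1, 0.2, 0.1), z_m = 0,
#'   tracked = TRUE
#' )
#' path_length(w) # 0.4
#' @export
path_length <- function(samples) {
  keep <- samples$tracked
  if (!any(keep)) {
    return(NA_real_)
  }
  x <- samples$x_m[keep]
  y <- samples$y_m[keep]
  z <- samples$z_m[keep]
  if (length(x) < 2L) {
    return(0)
  }
  sum(sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2))
}

#' Commission index of an X trial
#'
#' The continuous inhibition-failure measure: the ratio of the hand-path
#' length during the X-stimulus window to the maximum path length over
#' the neighbouring (previous and posterior) trial windows. A perfectly
#' inhibited X trial between two executed reactions scores near 0; a
#' full-sized reaction to the X scores near 1 or above. When the X is
#' the final stimulus only the previous neighbour is used; when both
#' neighbours are effectively motionless (denominator below `d_min`)
#' the index is not computable and `NA` is returned.
#'
#' @param x_window Samples of the X trial window.
#' @param prev_window Samples of the preceding trial window.
#' @param next_window Samples of the following trial window, or `NULL`
#'   when the X-stimulus is last.
#' @param is_x Flag of the centre trial; supplying a non-X trial is a
#'   usage error.
#' @param d_min Denominator floor in metres.
#' @return The index (>= 0) or `NA` when not computable.
#' @export
commission_index <- function(x_window, prev_window, next_window = NULL,
                             is_x = TRUE, d_min = 0.01) {
  if (!isTRUE(is_x)) {
    cpt_abort("commission_index() applies to X trials only.", "cpt_usage_error")
  }
  num <- path_length(x_window)
  d_prev <- path_length(prev_window)
  d_next <- if (is.null(next_window)) NA_real_ else path_length(next_window)
  commission_index_num(num, d_prev, d_next, d_min)
}

commission_index_num <- function(num, d_prev, d_next, d_min) {
  denom <- max(c(d_prev, d_next), na.rm = TRUE)
  if (!is.finite(num) || !is.finite(denom) || denom < d_min) {
    return(NA_real_)
  }
  num / denom
}

#' Reaction and completion times from a detected event
#'
#' The reaction time (RT) of a non-X trial is the time from stimulus
#' appearance to movement onset; it is absent for omissions and for
#' premature episodes (which began before the stimulus). The completion
#' time (CT) is the time from movement onset to the hand's return to the
#' rest band; it is absent when the hand never returned (partial
#' omission) or never rose.
#'
#' @param event One-row event tibble from [detect_reaction()].
#' @param stimulus_onset_s Onset of the stimulus (s).
#' @param is_x Whether the trial is an X trial; RT is defined for non-X
#'   trials only and requesting it for an X trial is a usage error.
#' @return A duration in seconds, or `NA` when undefined.
#' @export
reaction_time <- function(event, stimulus_onset_s, is_x = FALSE) {
  if (isTRUE(is_x)) {
    cpt_abort("reaction_time() applies to non-X trials only.", "cpt_usage_error")
  }
  if (!isTRUE(event$valid) || is.na(event$onset_s) || isTRUE(event$premature)) {
    return(NA_real_)
  }
  event$onset_s - stimulus_onset_s
}

#' @rdname reaction_time
#' @export
completion_time <- function(event) {
  if (!isTRUE(event$valid) || is.na(event$onset_s) || is.na(event$return_s)) {
    return(NA_real_)
  }
  event$return_s - event$onset_s
}

#' Classify a scored trial
#'
#' Assigns one event class per trial. Non-X trials, in precedence order:
#' `invalid_trial` (tracking failure), `premature_reaction` (first rise
#' episode began before the stimulus), `multiple_reaction` (two or more
#' rise episodes), `full_reaction` (onset and return), `partial_omission`
#' (onset, no return), `omission` (no onset). X trials are cut on the
#' continuous commission index: `commission` at or above `c_hi`,
#' `inhibited_commission` in `[c_lo, c_hi)`, `correct_inhibition` below
#' `c_lo`, and `invalid_trial` when the index is not computable.
#'
#' @param is_x X-trial flag.
#' @param event One-row event tibble from [detect_reaction()] (may be
#'   `NULL` for X trials).
#' @param index Commission index of an X trial (`NA` if not computable).
#' @param valid Whether tracking sufficed for scoring.
#' @param params A [class_params()] list.
#' @return A single event-class string.
#' @export
classify_trial <- function(is_x, event = NULL, index = NA_real_,
                           valid = TRUE, params = class_params()) {
  if (!isTRUE(valid)) {
    return("invalid_trial")
  }
  if (isTRUE(is_x)) {
    if (!is.finite(index)) {
      return("invalid_trial")
    }
    if (index >= params$c_hi) {
      return("commission")
    }
    if (index >= params$c_lo) {
      return("inhibited_commission")
    }
    return("correct_inhibition")
  }
  if (!isTRUE(event$valid)) {
    return("invalid_trial")
  }
  if (isTRUE(event$premature)) {
    return("premature_reaction")
  }
  if (event$n_reactions >= 2L) {
    return("multiple_reaction")
  }
  if (!is.na(event$onset_s) && !is.na(event$return_s)) {
    return("full_reaction")
  }
  if (!is.na(event$onset_s)) {
    return("partial_omission")
  }
  "omission"
}

event_classes <- c(
  "full_reaction", "omission", "partial_omission", "multiple_reaction",
  "premature_reaction", "commission", "inhibited_commission",
  "correct_inhibition", "invalid_trial"
)

#' Score a full session
#'
#' The main scoring verb: segments the stream against the schedule,
#' detects the hand-raise event in every trial window, and derives the
#' per-trial measures — reaction time and completion time for non-X
#' trials, hand-path displacement for every trial, the commission index
#' for X trials, and the event class.
#'
#' @param stream A `cpt_trajectory` covering the schedule.
#' @param schedule A `cpt_schedule`.
#' @param onset An [onset_params()] list.
#' @param classify A [class_params()] list.
#' @param buffer_s Pre-onset baseline buffer (s), as in
#'   [segment_trials()].
#' @return A tibble of class `cpt_session`, one row per stimulus:
#'   `index`, `letter`, `is_x`, `onset_s`, `rt_s`, `ct_s`,
#'   `displacement_m`, `commission_index`, `n_reactions`, `premature`,
#'   `event_class`.
#' @examples
#' sched <- cpt_schedule("revised-60", seed = 3)
#' sim <- simulate_participant(sched, trait_profile(50, 50, 50),
#'   sim_config(seed = 3)
#' )
#' results <- score_session(sim$trajectory, sched)
#' summarize_participant(results)
#' @export
score_session <- function(stream, schedule, onset = onset_params(),
                          classify = class_params(), buffer_s = 0.25) {
  if (nrow(stream) == 0L) {
    cpt_abort("trajectory stream has no samples.", "cpt_empty_stream")
  }
  onsets <- schedule$onset_s
  n <- length(onsets)
  t <- stream$t_s
  eps <- 1e-9

  min_isi <- min(attr(schedule, "isi_set_s") %||% schedule$isi_after_s, na.rm = TRUE)
  window_end <- c(onsets[-1L], onsets[n] + min_isi)
  max_t <- t[length(t)]
  uncovered <- schedule$index[window_end > max_t + eps]
  if (length(uncovered) > 0L) {
    cpt_abort(
      paste0(
        "stream ends at ", format(max_t), " s and does not cover stimuli ",
        paste(range(uncovered), collapse = "-")
      ),
      "cpt_coverage_error", uncovered = uncovered
    )
  }

  first_in <- findInterval(onsets - eps, t) + 1L
  last_in <- c(first_in[-1L] - 1L, length(t))
  buf_first <- findInterval(onsets - buffer_s - eps, t) + 1L
  global_baseline <- session_baseline(stream)

  tr <- stream$tracked
  x <- stream$x_m; y <- stream$y_m; z <- stream$z_m

  v_release <- onset$v_release_frac * onset$v_min

  rt_s <- ct_s <- displacement_m <- rep(NA_real_, n)
  n_reactions <- integer(n)
  premature <- logical(n)
  valid <- logical(n)
  onset_time <- return_time <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    rng <- if (first_in[i] <= last_in[i]) first_in[i]:last_in[i] else integer(0)
    brg <- if (buf_first[i] <= first_in[i] - 1L) buf_first[i]:(first_in[i] - 1L) else integer(0)

    # untracked time: inter-sample intervals with an untracked endpoint
    if (length(rng) >= 2L) {
      dt <- diff(t[rng])
      pair_ok <- tr[rng][-1L] & tr[rng][-length(rng)]
      untracked_s <- sum(dt[!pair_ok])
    } else {
      untracked_s <- 0
    }

    # displacement over tracked subsequence within the window
    wk <- rng[tr[rng]]
    displacement_m[i] <- if (length(wk) == 0L) {
      NA_real_
    } else if (length(wk) < 2L) {
      0
    } else {
      sum(sqrt(diff(x[wk])^2 + diff(y[wk])^2 + diff(z[wk])^2))
    }

    # baseline from tracked buffer samples, else session fallback
    bk <- brg[tr[brg]]
    base_y <- if (length(bk) > 0L) stats::median(y[bk]) else global_baseline[["y"]]

    det_idx <- c(brg, rng)
    det_idx <- det_idx[tr[det_idx]]
    if (length(det_idx) >= 2L && is.finite(base_y) &&
        untracked_s <= classify$max_untracked_s) {
      res <- detect_episodes_cpp(
        t[det_idx], y[det_idx] - base_y,
        onset$v_min, onset$k, v_release,
        onset$rise_min_m, onset$rest_band_m, onsets[i]
      )
      valid[i] <- TRUE
      n_reactions[i] <- res$n_reactions
      premature[i] <- res$premature
      onset_time[i] <- res$onset_s
      return_time[i] <- res$return_s
      if (!schedule$is_x[i] && !is.na(res$onset_s) && !res$premature) {
        rt_s[i] <- res$onset_s - onsets[i]
      }
      if (!schedule$is_x[i] && !is.na(res$onset_s) && !is.na(res$return_s)) {
        ct_s[i] <- res$return_s - res$onset_s
      }
    } else {
      valid[i] <- FALSE
    }
  }

  ci <- rep(NA_real_, n)
  for (i in which(schedule$is_x)) {
    d_prev <- if (i > 1L) displacement_m[i - 1L] else NA_real_
    d_next <- if (i < n) displacement_m[i + 1L] else NA_real_
    ci[i] <- commission_index_num(displacement_m[i], d_prev, d_next, classify$d_min_m)
  }

  event_class <- character(n)
  for (i in seq_len(n)) {
    ev <- list(
      valid = valid[i], n_reactions = n_reactions[i],
      onset_s = onset_time[i], return_s = return_time[i],
      premature = premature[i]
    )
    event_class[i] <- classify_trial(
      is_x = schedule$is_x[i], event = ev, index = ci[i],
      valid = valid[i], params = classify
    )
  }

  out <- tibble::new_tibble(
    list(
      index = schedule$index,
      letter = schedule$letter,
      is_x = schedule$is_x,
      onset_s = onsets,
      rt_s = rt_s,
      ct_s = ct_s,
      displacement_m = displacement_m,
      commission_index = ci,
      n_reactions = n_reactions,
      premature = premature,
      event_class = factor(event_class, levels = event_classes)
    ),
    nrow = n
  )
  structure(out, class = c("cpt_session", tbl_classes))
}

#' Summarise a participant's session
#'
#' Characterises a participant by the medians of the per-trial measures:
#' median reaction time and median completion time over the non-X trials
#' that yielded them, and the median commission index over the X trials
#' where it was computable. On a fully compliant revised-60 session this
#' uses 48 RTs, 48 CTs and 12 commission indices. Medians over an even
#' count are the mean of the central pair. Premature and invalid trials
#' contribute to no median. Event-class counts are reported as `n_*`
#' columns.
#'
#' @param results A `cpt_session` tibble from [score_session()].
#' @return A one-row tibble of class `cpt_summary`: `median_rt_s`,
#'   `median_ct_s`, `median_commission_index`, `n_rt_obs`, `n_ct_obs`,
#'   `n_ci_obs`, `n_trials`, and one `n_<event_class>` column per class.
#'   A warning is raised when no valid RT observation exists.
#' @export
summarize_participant <- function(results) {
  contributes <- !results$is_x &
    !(results$event_class %in% c("invalid_trial", "premature_reaction"))
  rts <- results$rt_s[contributes & !is.na(results$rt_s)]
  cts <- results$ct_s[contributes & !is.na(results$ct_s)]
  cis <- results$commission_index[results$is_x &
    results$event_class != "invalid_trial" &
    !is.na(results$commission_index)]

  if (length(rts) == 0L) {
    rlang::warn("no valid reaction-time observations in this session",
      class = "cpt_no_rt_warning"
    )
  }

  counts <- tabulate(
    factor(as.character(results$event_class), levels = event_classes),
    nbins = length(event_classes)
  )
  count_cols <- stats::setNames(
    as.list(as.integer(counts)),
    paste0("n_", event_classes)
  )

  out <- tibble::new_tibble(
    c(
      list(
        median_rt_s = median_or_na(rts),
        median_ct_s = median_or_na(cts),
        median_commission_index = median_or_na(cis),
        n_rt_obs = length(rts),
        n_ct_obs = length(cts),
        n_ci_obs = length(cis),
        n_trials = nrow(results)
      ),
      count_cols
    ),
    nrow = 1L
  )
  structure(out, class = c("cpt_summary", tbl_classes))
}
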