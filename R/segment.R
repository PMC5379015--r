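# Trial segmentation: one half-open window [onset, next onset) per
# stimulus; the final window runs to the end of the stream.

#' Segment a trajectory stream into per-stimulus trial windows
#'
#' Cuts the session into one window per stimulus using the half-open
#' convention `[onset, next onset)`; the last window extends to the end
#' of the stream. Each window carries a rest-position baseline: the
#' componentwise median over the tracked samples of the `buffer_s`
#' seconds preceding the stimulus onset, falling back to the
#' session-global 10th-percentile hand height (and median lateral/depth
#' position) when no pre-onset samples are available.
#'
#' @param stream A `cpt_trajectory` covering the schedule's time span.
#' @param schedule A `cpt_schedule`.
#' @param buffer_s Length of the pre-onset baseline buffer (seconds).
#' @return A tibble of class `cpt_trials` with one row per stimulus:
#'   the stimulus columns, `window_end_s`, baseline position columns
#'   `baseline_x_m`/`baseline_y_m`/`baseline_z_m`, `n_samples`, and
#'   list-columns `samples` (in-window samples) and `buffer` (pre-onset
#'   baseline samples, which overlap the previous trial's tail).
#' @details A coverage error (class `cpt_coverage_error`) is raised when
#'   the stream ends before the schedule does; its message lists the
#'   uncovered stimulus indices. A non-final stimulus is covered when the
#'   stream reaches the next onset; the final stimulus is covered when
#'   the stream extends at least the design's shortest ISI past its
#'   onset.
#' @export
segment_trials <- function(stream, schedule, buffer_s = 0.25) {
  if (nrow(stream) == 0L) {
    cpt_abort("trajectory stream has no samples.", "cpt_empty_stream")
  }
  onsets <- schedule$onset_s
  n <- length(onsets)
  max_t <- stream$t_s[nrow(stream)]
  eps <- 1e-9

  min_isi <- min(attr(schedule, "isi_set_s") %||% schedule$isi_after_s, na.rm = TRUE)
  window_end <- c(onsets[-1L], onsets[n] + min_isi)
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

  t <- stream$t_s
  first_in <- findInterval(onsets - eps, t) + 1L   # first sample with t >= onset
  last_in <- c(first_in[-1L] - 1L, length(t))      # last sample before next onset
  buf_first <- findInterval(onsets - buffer_s - eps, t) + 1L

  global_baseline <- session_baseline(stream)

  rows <- lapply(seq_len(n), function(i) {
    samp_idx <- if (first_in[i] <= last_in[i]) first_in[i]:last_in[i] else integer(0)
    buf_idx <- if (buf_first[i] <= first_in[i] - 1L) buf_first[i]:(first_in[i] - 1L) else integer(0)
    samples <- tibble::as_tibble(stream)[samp_idx, ]
    buffer <- tibble::as_tibble(stream)[buf_idx, ]
    base <- trial_baseline(buffer, global_baseline)
    tibble::tibble(
      index = schedule$index[i],
      letter = schedule$letter[i],
      is_x = schedule$is_x[i],
      onset_s = onsets[i],
      window_end_s = if (i < n) onsets[i + 1L] else max_t,
      baseline_x_m = base[["x"]], baseline_y_m = base[["y"]], baseline_z_m = base[["z"]],
      n_samples = length(samp_idx),
      samples = list(samples),
      buffer = list(buffer)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cpt_trials", tbl_classes))
}

session_baseline <- function(stream) {
  tr <- stream$tracked
  if (!any(tr)) {
    return(c(x = NA_real_, y = NA_real_, z = NA_real_))
  }
  c(
    x = stats::median(stream$x_m[tr]),
    y = unname(stats::quantile(stream$y_m[tr], 0.1)),
    z = stats::median(stream$z_m[tr])
  )
}

trial_baseline <- function(buffer, global_baseline) {
  tr <- buffer$tracked
  if (nrow(buffer) == 0L || !any(tr)) {
    return(global_baseline)
  }
  c(
    x = stats::median(buffer$x_m[tr]),
    y = stats::median(buffer$y_m[tr]),
    z = stats::median(buffer$z_m[tr])
  )
}
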