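# ggplot2 views of the result types.

#' Plot a hand trajectory
#'
#' Hand height over session time, with stimulus onsets marked when a
#' schedule is supplied (X-stimuli dashed).
#'
#' @param object A `cpt_trajectory`.
#' @param schedule Optional `cpt_schedule` for onset markers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpt_trajectory <- function(object, schedule = NULL, ...) {
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$t_s, y = .data$y_m)
  ) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "Session time (s)", y = "Hand height (m)")
  if (!is.null(schedule)) {
    p <- p + ggplot2::geom_vline(
      data = tibble::as_tibble(schedule),
      ggplot2::aes(xintercept = .data$onset_s, linetype = .data$is_x),
      colour = "steelblue", alpha = 0.5
    ) +
      ggplot2::scale_linetype_manual(
        values = c(`FALSE` = "solid", `TRUE` = "dashed"),
        labels = c(`FALSE` = "non-X", `TRUE` = "X"), name = "Stimulus"
      )
  }
  p
}

#' Plot a scored session
#'
#' One point per stimulus: reaction time for non-X trials and commission
#' index for X trials (on a secondary panel), coloured by event class —
#' the per-trial audit view of a session.
#'
#' @param object A `cpt_session` from [score_session()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpt_session <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$measure <- ifelse(df$is_x, "Commission index (X trials)", "Reaction time (s)")
  df$value <- ifelse(df$is_x, df$commission_index, df$rt_s)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$index, y = .data$value,
    colour = .data$event_class
  )) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Stimulus index", y = NULL, colour = "Event")
}

#' Plot a correlation report
#'
#' Predictor-by-factor tile map of the correlation coefficients, with
#' `r (P=...)` labels.
#'
#' @param object A `cpt_correlation` from [correlate_traits()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cpt_correlation <- function(object, ...) {
  df <- object$table
  df$label <- ifelse(
    is.na(df$r), "NA",
    paste0(fmt_trim(df$r), "\n(P=", fmt_trim(df$p), ")")
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$factor, y = .data$predictor, fill = .data$r
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = "SWAN factor", y = "Predictor", fill = "r")
}

#' @rdname autoplot.cpt_trajectory
#' @param x A `cpt_trajectory`.
#' @export
plot_trajectory <- function(x, schedule = NULL, ...) {
  autoplot.cpt_trajectory(x, schedule = schedule, ...)
}

#' @rdname autoplot.cpt_session
#' @param x A `cpt_session`.
#' @export
plot_session <- function(x, ...) {
  autoplot.cpt_session(x, ...)
}

#' @rdname autoplot.cpt_correlation
#' @param x A `cpt_correlation`.
#' @export
plot_correlation <- function(x, ...) {
  autoplot.cpt_correlation(x, ...)
}
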