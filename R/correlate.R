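# Predictor-by-factor correlation report: the validity analysis relating
# CPT summary measures to SWAN factor scores.

#' Correlate CPT predictors with SWAN factors
#'
#' Computes the correlation of each per-participant CPT predictor
#' (median reaction time, median commission index, optionally median
#' completion time) with each SWAN factor (inattention, hyperactivity,
#' impulsivity), with a two-sided p-value from the t transform on
#' `n - 2` degrees of freedom. Missing predictors are handled
#' pairwise-complete, and the `n` actually used is reported per cell;
#' cells with fewer than 3 complete pairs are marked not computable
#' (`NA`).
#'
#' @param summaries Data frame with one row per participant holding the
#'   predictor columns (and optionally `participant_id`).
#' @param swan Data frame with one row per participant holding the
#'   factor columns (as produced by [score_swan()]). When both inputs
#'   have `participant_id` they are joined on it; otherwise they are
#'   matched by row order.
#' @param predictors Predictor column names in `summaries`.
#' @param factors Factor column names in `swan`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param adjust P-value adjustment across cells: `"none"` (default,
#'   matching raw-P reporting) or any [stats::p.adjust()] method such as
#'   `"holm"`.
#' @return An object of class `cpt_correlation`: a list with `table`
#'   (tibble of `predictor`, `factor`, `r`, `p`, `n`), `method`,
#'   `adjust` and `n_participants`. Use [tidy()] / [glance()] /
#'   [render_report()] on it.
#' @examples
#' cohort <- simulate_cohort(12, cpt_schedule("revised-60", seed = 2),
#'   cfg = sim_config(seed = 2)
#' )
#' swan <- score_swan(cohort)
#' correlate_traits(cohort, swan)
#' @export
correlate_traits <- function(summaries, swan,
                             predictors = c("median_rt_s", "median_commission_index"),
                             factors = c("inattention", "hyperactivity", "impulsivity"),
                             method = c("pearson", "spearman"),
                             adjust = "none") {
  method <- match.arg(method)
  missing_pred <- setdiff(predictors, names(summaries))
  if (length(missing_pred) > 0L) {
    cpt_abort(
      paste0("predictor columns not found: ", paste(missing_pred, collapse = ", ")),
      "cpt_usage_error"
    )
  }
  missing_fac <- setdiff(factors, names(swan))
  if (length(missing_fac) > 0L) {
    cpt_abort(
      paste0("factor columns not found: ", paste(missing_fac, collapse = ", ")),
      "cpt_usage_error"
    )
  }

  if ("participant_id" %in% names(summaries) && "participant_id" %in% names(swan)) {
    merged <- dplyr::inner_join(
      summaries[unique(c("participant_id", predictors))],
      swan[unique(c("participant_id", factors))],
      by = "participant_id",
      suffix = c("", ".swan")
    )
  } else {
    if (nrow(summaries) != nrow(swan)) {
      cpt_abort(
        "without participant_id, summaries and swan must have equal row counts.",
        "cpt_usage_error"
      )
    }
    merged <- dplyr::bind_cols(
      summaries[predictors],
      swan[setdiff(factors, predictors)]
    )
  }

  grid <- tidyr::expand_grid(predictor = predictors, factor = factors)
  cells <- purrr::pmap(grid, function(predictor, factor) {
    x <- merged[[predictor]]
    y <- merged[[factor]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3L) {
      return(tibble::tibble(
        predictor = predictor, factor = factor,
        r = NA_real_, p = NA_real_, n = n
      ))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = method, exact = FALSE)
    )
    tibble::tibble(
      predictor = predictor, factor = factor,
      r = unname(ct$estimate), p = ct$p.value, n = n
    )
  })
  table <- dplyr::bind_rows(cells)
  if (adjust != "none") {
    table$p <- stats::p.adjust(table$p, method = adjust)
  }
  structure(
    list(
      table = table, method = method, adjust = adjust,
      n_participants = nrow(merged)
    ),
    class = "cpt_correlation"
  )
}

#' @export
tidy.cpt_correlation <- function(x, ...) {
  x$table
}

#' @export
glance.cpt_correlation <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    adjust = x$adjust,
    n_participants = x$n_participants,
    n_cells = nrow(x$table),
    n_computable = sum(!is.na(x$table$r))
  )
}

#' @export
print.cpt_correlation <- function(x, ...) {
  cat(
    "CPT predictor vs SWAN factor correlations (", x$method,
    if (x$adjust != "none") paste0(", ", x$adjust, "-adjusted") else "",
    ", n = ", x$n_participants, ")\n\n",
    sep = ""
  )
  cat(render_report(x, format = "markdown"), sep = "\n")
  invisible(x)
}
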