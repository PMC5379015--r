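# SWAN scale scoring: 18 items on the 0-100 web scale, three factors.

swan_item_names <- sprintf("item_%02d", 1:18)

swan_factor_map <- list(
  inattention = 1:9,
  hyperactivity = 10:15,
  impulsivity = 16:18
)

#' Score the SWAN scale
#'
#' The SWAN rating scale has 18 items, each scored 0-100 in the web
#' format. Items 1-9 form the inattention factor, items 10-15 the
#' hyperactivity factor, and items 16-18 the impulsivity factor. Factor
#' scores are item means, which keeps them on the same 0-100 scale as
#' the items (sums differ only by a constant factor and leave
#' correlations unchanged).
#'
#' @param data Either a numeric vector of exactly 18 item scores, or a
#'   data frame with columns `item_01`..`item_18` (plus any id columns,
#'   which are carried through).
#' @return A tibble with the input columns plus `inattention`,
#'   `hyperactivity` and `impulsivity` factor scores.
#' @examples
#' score_swan(rep(50, 18))
#' @export
score_swan <- function(data) {
  if (is.numeric(data)) {
    if (length(data) != 18L) {
      cpt_abort(
        paste0("SWAN requires exactly 18 item scores, got ", length(data)),
        "cpt_swan_error"
      )
    }
    data <- tibble::as_tibble(as.list(stats::setNames(data, swan_item_names)))
  }
  missing_cols <- setdiff(swan_item_names, names(data))
  if (length(missing_cols) > 0L) {
    cpt_abort(
      paste0("missing SWAN items: ", paste(missing_cols, collapse = ", ")),
      "cpt_swan_error"
    )
  }
  items <- as.matrix(data[swan_item_names])
  bad <- which(!is.finite(items) | items < 0 | items > 100, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    cpt_abort(
      paste0(
        "SWAN item out of [0, 100]: ", swan_item_names[bad[1L, "col"]],
        " (row ", bad[1L, "row"], ")"
      ),
      "cpt_swan_error"
    )
  }
  out <- tibble::as_tibble(data)
  for (f in names(swan_factor_map)) {
    out[[f]] <- rowMeans(items[, swan_factor_map[[f]], drop = FALSE])
  }
  out
}

#' SWAN factor composition
#'
#' @return A named list mapping each factor to its 1-based item indices
#'   (inattention 1-9, hyperactivity 10-15, impulsivity 16-18).
#' @export
swan_factors <- function() {
  swan_factor_map
}

#' Read a SWAN item-score table
#'
#' Expects a CSV with `participant_id` and `item_01`..`item_18`; returns
#' the table with factor scores appended.
#'
#' @param path CSV file path.
#' @return A tibble as from [score_swan()].
#' @export
read_swan <- function(path) {
  if (!file.exists(path)) {
    cpt_abort(paste0("SWAN file not found: ", path), "cpt_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  score_swan(df)
}
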