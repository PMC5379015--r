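# Rendering the correlation report.

fmt_trim <- function(x, digits = 2) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  sub("^(-?)0\\.", "\\1.", out)
}

predictor_labels <- c(
  median_rt_s = "RT",
  median_commission_index = "Commission",
  median_ct_s = "CT"
)

#' Render a correlation report
#'
#' Serialises a `cpt_correlation` as a markdown table (predictors in
#' rows, the three SWAN factors in columns, cells formatted
#' `r (P=...)`), as a tidy CSV, or as JSON. CSV and JSON round-trip the
#' full-precision cell values; the markdown view rounds to two decimals
#' in the conventional leading-zero-free style. Not-computable cells
#' render as `NA`.
#'
#' @param report A `cpt_correlation` from [correlate_traits()].
#' @param format `"markdown"`, `"csv"` or `"json"`.
#' @param path Optional file to write; the rendered text is returned
#'   either way.
#' @return A character vector of lines (markdown) or a single string
#'   (csv, json), invisibly when `path` is given.
#' @export
render_report <- function(report, format = c("markdown", "csv", "json"),
                          path = NULL) {
  format <- match.arg(format)
  tbl <- report$table
  out <- switch(format,
    markdown = {
      factors <- unique(tbl$factor)
      header <- paste0(
        "| Explanatory variables | ",
        paste(tools::toTitleCase(factors), collapse = " | "), " |"
      )
      rule <- paste0("|", paste(rep("---", length(factors) + 1L), collapse = "|"), "|")
      rows <- vapply(unique(tbl$predictor), function(p) {
        cells <- vapply(factors, function(f) {
          row <- tbl[tbl$predictor == p & tbl$factor == f, ]
          if (nrow(row) == 0L || is.na(row$r)) {
            "NA"
          } else {
            paste0(fmt_trim(row$r), " (P=", fmt_trim(row$p), ")")
          }
        }, character(1))
        label <- predictor_labels[p]
        if (is.na(label)) label <- p
        paste0("| ", label, " | ", paste(cells, collapse = " | "), " |")
      }, character(1))
      c(header, rule, rows)
    },
    csv = readr::format_csv(tbl),
    json = as.character(jsonlite::toJSON(
      list(
        method = report$method, adjust = report$adjust,
        n_participants = report$n_participants, cells = tbl
      ),
      dataframe = "rows", auto_unbox = TRUE, digits = I(10), pretty = TRUE,
      na = "null"
    ))
  )
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read back a CSV correlation report
#'
#' @param path CSV written by `render_report(..., format = "csv")`.
#' @param method,adjust Metadata to restore on the object.
#' @return A `cpt_correlation`.
#' @export
read_report_csv <- function(path, method = "pearson", adjust = "none") {
  tbl <- readr::read_csv(path,
    col_types = readr::cols(
      predictor = readr::col_character(), factor = readr::col_character(),
      r = readr::col_double(), p = readr::col_double(),
      n = readr::col_integer()
    ),
    progress = FALSE
  )
  structure(
    list(
      table = tbl, method = method, adjust = adjust,
      n_participants = max(tbl$n, 0L)
    ),
    class = "cpt_correlation"
  )
}
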