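#' Generate a CPT stimulus schedule
#'
#' Builds the ordered letter sequence of a continuous performance test:
#' which stimuli are the forbidden X, when each appears, and the
#' inter-stimulus interval (ISI) after it. Two presets are provided:
#' `"revised-60"`, the 3-minute design with 60 stimuli of which 12 are X
#' and ISIs drawn from {2, 3, 5} s, and `"legacy-360"`, the original
#' 15-minute design with 360 stimuli and ISIs from {1, 2, 4} s. Custom
#' designs are specified by overriding `n_stimuli`, `n_x` and `isi_set_s`.
#'
#' ISIs are drawn independently from `isi_set_s` (uniformly unless
#' `isi_weights` is given). X positions are drawn uniformly at random but
#' never at the first position, so that every X trial has a preceding
#' trial for the commission-index denominator. Non-X letters are drawn
#' uniformly from `alphabet` (A-Z without X by default).
#'
#' @param design `"revised-60"`, `"legacy-360"`, or `"custom"`.
#' @param seed Integer seed; the schedule is a deterministic function of
#'   `(design parameters, seed)`.
#' @param n_stimuli,n_x,isi_set_s Total stimulus count, X-stimulus count
#'   and allowed ISI set (seconds). Defaults come from the preset; all
#'   three must be given for `design = "custom"`.
#' @param isi_weights Optional sampling weights over `isi_set_s`.
#' @param first_onset_s Onset of the first stimulus (seconds from session
#'   start). The default 2 s leaves a lead-in so a rest-position baseline
#'   and premature movements can be measured before the first trial.
#' @param alphabet Candidate letters for non-X stimuli.
#'
#' @return A tibble of class `cpt_schedule` with one row per stimulus and
#'   columns `index` (0-based), `letter`, `is_x`, `onset_s`,
#'   `isi_after_s` (`NA` for the last stimulus). Design metadata is
#'   stored in attributes `design_name`, `isi_set_s`, `seed`,
#'   `first_onset_s`.
#' @examples
#' sched <- cpt_schedule("revised-60", seed = 7)
#' sum(sched$is_x)
#' @export
cpt_schedule <- function(design = c("revised-60", "legacy-360", "custom"),
                         seed = 1L,
                         n_stimuli = NULL, n_x = NULL, isi_set_s = NULL,
                         isi_weights = NULL,
                         first_onset_s = 2,
                         alphabet = setdiff(LETTERS, "X")) {
  design <- match.arg(design)
  preset <- switch(design,
    "revised-60" = list(n = 60L, x = 12L, isi = c(2, 3, 5)),
    "legacy-360" = list(n = 360L, x = 72L, isi = c(1, 2, 4)),
    "custom"     = list(n = NULL, x = NULL, isi = NULL)
  )
  n_stimuli <- as.integer(n_stimuli %||% preset$n)
  n_x <- as.integer(n_x %||% preset$x)
  isi_set_s <- isi_set_s %||% preset$isi
  if (is.null(n_stimuli) || is.na(n_stimuli) || n_stimuli < 1L) {
    cpt_abort("`n_stimuli` must be a positive integer.", "cpt_invalid_design")
  }
  if (is.na(n_x) || n_x < 0L || n_x > n_stimuli) {
    cpt_abort("`n_x` must lie in [0, n_stimuli].", "cpt_invalid_design")
  }
  if (n_x >= 1L && n_x > n_stimuli - 1L) {
    cpt_abort(
      "`n_x` must leave at least one non-X stimulus: X never occupies the first position.",
      "cpt_invalid_design"
    )
  }
  if (length(isi_set_s) == 0L || any(!is.finite(isi_set_s)) || any(isi_set_s <= 0)) {
    cpt_abort("`isi_set_s` must be a non-empty set of positive durations.", "cpt_invalid_design")
  }
  if (!is.null(isi_weights) && (length(isi_weights) != length(isi_set_s) || any(isi_weights < 0))) {
    cpt_abort("`isi_weights` must be non-negative and match `isi_set_s`.", "cpt_invalid_design")
  }
  if (!is_scalar_number(first_onset_s) || first_onset_s < 0) {
    cpt_abort("`first_onset_s` must be a non-negative number.", "cpt_invalid_design")
  }

  local_cpt_seed(seed)

  is_x <- rep(FALSE, n_stimuli)
  if (n_x > 0L) {
    pos <- sample(2:n_stimuli, n_x)
    is_x[pos] <- TRUE
  }
  letter <- character(n_stimuli)
  letter[!is_x] <- sample(alphabet, sum(!is_x), replace = TRUE)
  letter[is_x] <- "X"

  isi <- if (n_stimuli > 1L) {
    isi_set_s[sample.int(length(isi_set_s), n_stimuli - 1L,
      replace = TRUE, prob = isi_weights
    )]
  } else {
    numeric(0)
  }
  onset_s <- first_onset_s + cumsum(c(0, isi))

  out <- tibble::tibble(
    index = 0:(n_stimuli - 1L),
    letter = letter,
    is_x = is_x,
    onset_s = onset_s,
    isi_after_s = c(isi, NA_real_)
  )
  new_cpt_schedule(out,
    design_name = design, isi_set_s = sort(unique(isi_set_s)),
    seed = as.integer(seed), first_onset_s = first_onset_s
  )
}

new_cpt_schedule <- function(df, design_name, isi_set_s, seed, first_onset_s) {
  structure(
    df,
    design_name = design_name,
    isi_set_s = isi_set_s,
    seed = seed,
    first_onset_s = first_onset_s,
    class = c("cpt_schedule", tbl_classes)
  )
}

#' Validate a stimulus schedule
#'
#' Checks a schedule against its declared design: letter/flag
#' consistency, strictly increasing onsets, ISI membership in the design
#' set, agreement between onset differences and stored ISIs, and the
#' preset composition rules (60 stimuli with 12 X for `revised-60`;
#' 360 stimuli for `legacy-360`).
#'
#' @param schedule A `cpt_schedule` (or compatible data frame with the
#'   same columns).
#' @return A tibble with columns `rule` and `message`, one row per
#'   violated invariant; zero rows iff the schedule is valid.
#' @examples
#' nrow(validate_schedule(cpt_schedule("revised-60", seed = 1)))
#' @export
validate_schedule <- function(schedule) {
  problems <- list()
  note <- function(rule, message) {
    problems[[length(problems) + 1L]] <<- tibble::tibble(rule = rule, message = message)
  }

  required <- c("index", "letter", "is_x", "onset_s")
  missing_cols <- setdiff(required, names(schedule))
  if (length(missing_cols) > 0L) {
    note("columns", paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
    return(dplyr::bind_rows(problems))
  }

  bad_flag <- which(schedule$is_x != (schedule$letter == "X"))
  if (length(bad_flag) > 0L) {
    note("x_flag", paste0(
      "is_x inconsistent with letter at index ",
      paste(schedule$index[bad_flag], collapse = ", ")
    ))
  }
  if (nrow(schedule) > 1L && any(diff(schedule$onset_s) <= 0)) {
    first_bad <- which(diff(schedule$onset_s) <= 0)[1L]
    note("onset_order", paste0(
      "onsets not strictly increasing at index ", schedule$index[first_bad + 1L]
    ))
  }

  isi_set <- attr(schedule, "isi_set_s")
  if (!is.null(isi_set) && "isi_after_s" %in% names(schedule)) {
    isi <- schedule$isi_after_s[-nrow(schedule)]
    off <- which(!vapply(isi, function(d) any(abs(d - isi_set) < 1e-9), logical(1)))
    if (length(off) > 0L) {
      note("isi_membership", paste0(
        "isi_after_s outside the design ISI set at index ",
        paste(schedule$index[off], collapse = ", ")
      ))
    }
    if (nrow(schedule) > 1L) {
      mism <- which(abs(diff(schedule$onset_s) - isi) > 1e-9)
      if (length(mism) > 0L) {
        note("isi_onset_agreement", paste0(
          "onset differences disagree with isi_after_s at index ",
          paste(schedule$index[mism], collapse = ", ")
        ))
      }
    }
  }

  design <- attr(schedule, "design_name") %||% "custom"
  n <- nrow(schedule)
  n_x <- sum(schedule$is_x)
  if (design == "revised-60") {
    if (n != 60L) note("preset_total", paste0("revised-60 requires 60 stimuli, found ", n))
    if (n_x != 12L) note("preset_x_count", paste0("revised-60 requires 12 X-stimuli, found ", n_x))
  } else if (design == "legacy-360") {
    if (n != 360L) note("preset_total", paste0("legacy-360 requires 360 stimuli, found ", n))
  }

  if (length(problems) == 0L) {
    tibble::tibble(rule = character(), message = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Read and write schedule files
#'
#' Schedules are stored as JSON with fields `design_name`, `seed`,
#' `isi_set_s`, `first_onset_s` and a `stimuli` array. Writing the same
#' schedule twice produces byte-identical files.
#'
#' @param schedule A `cpt_schedule`.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `cpt_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stimuli <- as.data.frame(schedule[, c("index", "letter", "is_x", "onset_s", "isi_after_s")])
  payload <- list(
    design_name = attr(schedule, "design_name") %||% "custom",
    seed = attr(schedule, "seed") %||% NA_integer_,
    isi_set_s = attr(schedule, "isi_set_s"),
    first_onset_s = attr(schedule, "first_onset_s") %||% schedule$onset_s[1L],
    stimuli = stimuli
  )
  json <- jsonlite::toJSON(payload,
    dataframe = "rows", auto_unbox = TRUE, digits = I(10),
    pretty = TRUE, na = "null"
  )
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) {
    cpt_abort(paste0("schedule file not found: ", path), "cpt_io_error")
  }
  payload <- jsonlite::fromJSON(path)
  stimuli <- tibble::as_tibble(payload$stimuli)
  stimuli$isi_after_s <- as.numeric(stimuli$isi_after_s)
  sched <- new_cpt_schedule(
    stimuli,
    design_name = payload$design_name,
    isi_set_s = as.numeric(payload$isi_set_s),
    seed = as.integer(payload$seed),
    first_onset_s = as.numeric(payload$first_onset_s)
  )
  issues <- validate_schedule(sched)
  if (nrow(issues) > 0L) {
    cpt_abort(
      paste0(
        "schedule file violates invariants: ",
        paste(issues$message, collapse = "; ")
      ),
      "cpt_format_error"
    )
  }
  sched
}
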