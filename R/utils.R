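# internal helpers shared across modules

tbl_classes <- c("tbl_df", "tbl", "data.frame")

cpt_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "cpt_error"), ...)
}

# Deterministic RNG scope: fixes the generator kind so the same seed gives
# the same draws regardless of the caller's RNG settings.
local_cpt_seed <- function(seed, .local_envir = parent.frame()) {
  withr::local_seed(
    as.integer(seed),
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection",
    .local_envir = .local_envir
  )
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# median that returns NA (with zero count) on empty input, never warns
median_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NA_real_ else stats::median(x)
}
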