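# Brute-force movement-onset oracle, independent of the package's
# detector: plain per-sample scans over the stated definition.
#
# A rise episode: elevation crosses rise_min (hi) coming from below the
# rest band (lo), ends when it falls back below lo. Each episode must be
# initiated by a sustained velocity run: k consecutive frame velocities
# above v_min, beginning where the velocity first exceeds v_min after
# having been at or below v_release. The onset is the last sample before
# the run, extended back through contiguous frames above v_release.
oracle_detect <- function(t, e, v_min = 0.15, k = 3L, v_release = 0.4 * 0.15,
                          hi = 0.05, lo = 0.05, stim_onset = 0) {
  m <- length(t)
  if (m < 2L) {
    return(list(valid = FALSE, n_reactions = 0L, onset_s = NA_real_,
                return_s = NA_real_, premature = FALSE))
  }
  v <- c(0, diff(e) / diff(t))

  # run starts via exhaustive forward scan of the velocity hysteresis
  armed <- logical(m)
  state <- FALSE
  for (j in 2:m) {
    state <- if (state) v[j] > v_release else v[j] > v_min
    armed[j] <- state
  }
  run_starts <- integer(0)
  for (j in 2:m) {
    if (armed[j] && !(j > 2 && armed[j - 1])) run_starts <- c(run_starts, j)
  }
  cands <- integer(0)
  for (j in run_starts) {
    if (j + k - 1L <= m && all(v[j:(j + k - 1L)] > v_min)) cands <- c(cands, j)
  }

  n_ep <- 0L
  onset_s <- return_s <- NA_real_
  j <- 1L
  last_end <- 0L
  while (j <= m) {
    if (e[j] >= hi) {
      cc <- cands[cands <= j & cands > last_end]
      qualified <- length(cc) > 0L
      # end of this high excursion
      ret <- NA_integer_
      jj <- j
      while (jj <= m && e[jj] >= lo) jj <- jj + 1L
      if (jj <= m) ret <- jj
      if (qualified) {
        c0 <- max(cc)
        while (c0 - 1L >= 2L && v[c0 - 1L] > v_release) c0 <- c0 - 1L
        n_ep <- n_ep + 1L
        if (n_ep == 1L) {
          onset_s <- t[c0 - 1L]
          if (!is.na(ret)) return_s <- t[ret]
        }
        last_end <- if (!is.na(ret)) ret else m
      }
      j <- if (!is.na(ret)) ret + 1L else m + 1L
    } else {
      j <- j + 1L
    }
  }
  list(
    valid = TRUE, n_reactions = n_ep, onset_s = onset_s,
    return_s = return_s,
    premature = n_ep > 0L && onset_s < stim_onset
  )
}
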