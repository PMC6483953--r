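# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with naive loops so they share no code with the package.

# Naive per-sample SCR scan: central-difference derivative computed inline,
# peaks at + -> - crossings, backward search for - -> + troughs (or near-flat
# bends when no strict trough exists), minimal-value / latest tie-break.
oracle_detect <- function(values, rate_hz, window_s = 4, eps = 0.001,
                          amp_floor = 1e-4) {
  n <- length(values)
  dt <- 1 / rate_hz
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- if (i == 1) (values[2] - values[1]) / dt
    else if (i == n) (values[n] - values[n - 1]) / dt
    else (values[i + 1] - values[i - 1]) / (2 * dt)
  }
  win <- round(window_s * rate_hz)
  out <- NULL
  for (i in 2:n) {
    if (!(d[i - 1] > 0 && d[i] <= 0)) next       # peak at sample i
    lo <- max(1, i - win)
    troughs <- integer(0)
    bends <- integer(0)
    for (j in lo:(i - 1)) {
      if (j >= 2 && d[j - 1] < 0 && d[j] >= 0) troughs <- c(troughs, j)
      if (abs(d[j]) < eps) bends <- c(bends, j)
    }
    cand <- if (length(troughs) > 0) troughs else bends
    if (length(cand) == 0) next
    vmin <- min(values[cand])
    tr <- max(cand[values[cand] <= vmin + 1e-12])
    amp <- values[i] - values[tr]
    if (amp <= amp_floor) next
    out <- rbind(out, c((tr - 1) * dt, (i - 1) * dt, amp))
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 3)
  data.frame(trough_time_s = out[, 1], peak_time_s = out[, 2],
             amplitude_uS = out[, 3])
}

# Direct scan of a presence/absence sequence for the habituation count.
oracle_habituation <- function(present) {
  n <- length(present)
  for (t in seq_len(n - 1)) {
    if (!present[t] && !present[t + 1]) return(t - 1L)
  }
  n
}

# Closed form for a deterministic step observer on a 5-dB staircase
# starting at a multiple of 5: lowest grid level at/above the threshold.
oracle_step_threshold <- function(true_threshold, step = 5) {
  step * ceiling(true_threshold / step)
}

# Build an scr_events-shaped data frame by hand for scoring tests.
events_df <- function(trough, peak, amp) {
  data.frame(trough_time_s = trough, peak_time_s = peak, amplitude_uS = amp)
}
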