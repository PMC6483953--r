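# Trial-level SCR scoring: attribute detected events to stimulus trials,
# apply amplitude/latency criteria, and derive trials-to-habituation,
# responder status, block magnitudes, and baseline skin-conductance level.

#' Scoring criteria for a qualifying SCR
#'
#' A detected event counts as an event-related SCR when its amplitude is at
#' least `min_amplitude_uS` and its response time falls within
#' `[window_min_s, window_max_s]` after stimulus onset (both ends inclusive).
#'
#' @param min_amplitude_uS minimum amplitude in microsiemens (default 0.03).
#' @param window_min_s,window_max_s response window after onset in seconds
#'   (defaults 1 and 4).
#' @return A list of class `scoring_criteria`.
#' @export
scoring_criteria <- function(min_amplitude_uS = 0.03, window_min_s = 1,
                             window_max_s = 4) {
  if (!(min_amplitude_uS > 0)) stop_param("`min_amplitude_uS` must be positive")
  if (!(window_min_s > 0 && window_min_s < window_max_s)) {
    stop_param("need 0 < window_min_s < window_max_s")
  }
  structure(list(min_amplitude_uS = min_amplitude_uS,
                 window_min_s = window_min_s, window_max_s = window_max_s),
            class = "scoring_criteria")
}

#' Score each stimulus trial for a qualifying SCR
#'
#' For trial k an event qualifies when its response time lies in
#' `[onset_k + window_min_s, onset_k + window_max_s]` (inclusive) and its
#' amplitude reaches `min_amplitude_uS`. The response time is the event's
#' trough time by default — the onset of the conductance rise — or the peak
#' time with `event_time = "peak"`. When several events qualify for a trial,
#' the largest-amplitude one is recorded, so magnitude analyses get a single
#' value per trial.
#'
#' @param events an [detect_scr_events()] result (time-sorted).
#' @param schedule the [make_schedule()] the trace was generated/recorded
#'   under; onsets must be far enough apart that response windows do not
#'   overlap.
#' @param criteria a [scoring_criteria()].
#' @param event_time which event time is matched against the response
#'   window: `"trough"` (response onset, default) or `"peak"`.
#' @return A data frame with one row per trial: `trial` (1-based),
#'   `scr_present` (logical) and `amplitude_uS` (0 when absent).
#' @export
score_trials <- function(events, schedule, criteria = scoring_criteria(),
                         event_time = c("trough", "peak")) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(criteria, "scoring_criteria"))
  event_time <- match.arg(event_time)
  onsets <- schedule$onsets_s
  if (any(diff(onsets) < criteria$window_max_s)) {
    stop_param("response windows overlap: onsets closer than %g s",
               criteria$window_max_s)
  }
  ev_t <- if (event_time == "trough") events$trough_time_s else events$peak_time_s
  present <- logical(schedule$n_trials)
  amp <- numeric(schedule$n_trials)
  for (k in seq_len(schedule$n_trials)) {
    in_win <- ev_t >= onsets[k] + criteria$window_min_s &
      ev_t <= onsets[k] + criteria$window_max_s &
      events$amplitude_uS >= criteria$min_amplitude_uS
    if (any(in_win)) {
      present[k] <- TRUE
      amp[k] <- max(events$amplitude_uS[in_win])
    }
  }
  data.frame(trial = seq_len(schedule$n_trials), scr_present = present,
             amplitude_uS = amp)
}

#' Trials to habituation
#'
#' Habituation is complete at the first pair of consecutive trials with no
#' qualifying SCR. If trials t and t+1 are the first such pair, the
#' participant habituated after t - 1 responded trials and `t - 1` is
#' returned (a participant responding on trials 1-4 and silent from trial 5
#' scores 4). When no two consecutive absent trials occur in the block, the
#' result is censored at the number of trials.
#'
#' @param scores a [score_trials()] data frame ordered by trial.
#' @return A list of class `habituation_result` with `trials_to_habituation`
#'   and `censored`.
#' @export
trials_to_habituation <- function(scores) {
  p <- scores$scr_present
  n <- length(p)
  if (n == 0L) stop_param("empty trial-score list")
  if (n >= 2L) {
    pair <- which(!p[-n] & !p[-1])
    if (length(pair) > 0L) {
      return(structure(list(trials_to_habituation = pair[1] - 1L,
                            censored = FALSE),
                       class = "habituation_result"))
    }
  }
  structure(list(trials_to_habituation = n, censored = TRUE),
            class = "habituation_result")
}

#' @export
print.habituation_result <- function(x, ...) {
  cat(sprintf("<habituation_result> %d trials%s\n", x$trials_to_habituation,
              if (x$censored) " (censored: never habituated)" else ""))
  invisible(x)
}

#' Classify a participant as responder or non-responder
#'
#' A non-responder shows no qualifying SCR at the start of a stimulus block.
#' Under the default `"both_absent"` rule a participant is a non-responder
#' when, in any condition, *neither* of the first two trials contains a
#' qualifying SCR. The stricter `"any_absent"` rule flags a participant who
#' misses *at least one* of the first two trials in any condition.
#'
#' @param scores_per_condition a list of [score_trials()] data frames, one
#'   per stimulus condition (each with >= 2 trials).
#' @param rule `"both_absent"` (default) or `"any_absent"`.
#' @return `TRUE` if the participant is a responder, `FALSE` otherwise.
#' @export
classify_responder <- function(scores_per_condition,
                               rule = c("both_absent", "any_absent")) {
  rule <- match.arg(rule)
  if (is.data.frame(scores_per_condition)) {
    scores_per_condition <- list(scores_per_condition)
  }
  non <- vapply(scores_per_condition, function(sc) {
    if (nrow(sc) < 2L) stop_param("each condition needs at least 2 trials")
    first2 <- sc$scr_present[1:2]
    if (rule == "both_absent") !any(first2) else !all(first2)
  }, logical(1))
  !any(non)
}

#' Mean SCR magnitude per block of trials
#'
#' Splits the trial sequence into consecutive blocks of `block_size` trials
#' and averages the SCR amplitude per block. By convention, magnitude
#' averages include zeros for trials without a qualifying SCR
#' (`include_zeros = TRUE`); setting it to `FALSE` averages amplitudes over
#' responded trials only (NaN for a block with none).
#'
#' @param scores a [score_trials()] data frame; the number of trials must be
#'   divisible by `block_size`.
#' @param block_size trials per block (default 5, giving 3 blocks of a
#'   15-trial run).
#' @param include_zeros include absent trials as zeros? Default `TRUE`.
#' @return Numeric vector of block means, in block order.
#' @export
block_means <- function(scores, block_size = 5, include_zeros = TRUE) {
  n <- nrow(scores)
  if (n %% block_size != 0) {
    stop_param("%d trials are not divisible into blocks of %d", n, block_size)
  }
  blk <- rep(seq_len(n / block_size), each = block_size)
  if (include_zeros) {
    as.numeric(tapply(scores$amplitude_uS, blk, mean))
  } else {
    amp <- ifelse(scores$scr_present, scores$amplitude_uS, NA_real_)
    as.numeric(tapply(amp, blk, mean, na.rm = TRUE))
  }
}

#' Baseline skin-conductance level
#'
#' The tonic skin-conductance level (SCL) over a rest baseline: the
#' arithmetic mean of all samples in the final `last_s` seconds of a
#' `total_baseline_s` baseline period (defaults: last 5 min of 10 min). No
#' filtering is applied — averaging is itself a low-pass operation.
#'
#' @param trace an [eda_trace()] covering at least `total_baseline_s`.
#' @param total_baseline_s length of the baseline period in seconds.
#' @param last_s how much of the end of the baseline to average.
#' @return Mean conductance in microsiemens.
#' @export
baseline_scl <- function(trace, total_baseline_s = 600, last_s = 300) {
  stopifnot(inherits(trace, "eda_trace"))
  if (!(last_s > 0 && last_s <= total_baseline_s)) {
    stop_param("need 0 < last_s <= total_baseline_s")
  }
  tt <- trace_times(trace)
  t_end <- trace$start_s + total_baseline_s
  if (max(tt) + 1 / trace$rate_hz < t_end) {
    stop_param("trace (%.1f s) shorter than the %g s baseline period",
               max(tt) - trace$start_s, total_baseline_s)
  }
  sel <- tt >= t_end - last_s & tt < t_end
  mean(trace$values_uS[sel])
}
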