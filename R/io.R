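# Plain-text interchange formats: traces, schedules, events, cohorts.
# Everything is comma-separated with a header so files open anywhere.

#' Read and write skin-conductance traces
#'
#' Traces travel as two-column delimited text: `time_s`, `eda_uS`, with
#' uniform sampling. The sampling rate is recovered from the median time
#' step on read.
#'
#' @param trace an [eda_trace()].
#' @param path file path.
#' @return `read_eda_trace()` returns an [eda_trace()];
#'   `write_eda_trace()` returns `path` invisibly.
#' @export
write_eda_trace <- function(trace, path) {
  stopifnot(inherits(trace, "eda_trace"))
  utils::write.csv(data.frame(time_s = trace_times(trace),
                              eda_uS = trace$values_uS),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eda_trace
#' @export
read_eda_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "eda_uS") %in% names(df))) {
    stop_param("expected columns `time_s`, `eda_uS` in %s", path)
  }
  dt <- stats::median(diff(df$time_s))
  eda_trace(df$eda_uS, rate_hz = 1 / dt, start_s = df$time_s[1])
}

#' Read and write stimulus schedules
#'
#' Schedules travel as delimited text with columns `trial`, `onset_s`,
#' `duration_s`.
#'
#' @param schedule a [make_schedule()] result.
#' @param path file path.
#' @return `read_schedule()` returns a `stimulus_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  utils::write.csv(data.frame(trial = seq_len(schedule$n_trials),
                              onset_s = schedule$onsets_s,
                              duration_s = schedule$duration_s),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("trial", "onset_s", "duration_s") %in% names(df))) {
    stop_param("expected columns `trial`, `onset_s`, `duration_s` in %s", path)
  }
  df <- df[order(df$onset_s), ]
  structure(list(onsets_s = df$onset_s, duration_s = df$duration_s[1],
                 n_trials = nrow(df)),
            class = "stimulus_schedule")
}

#' Write detected SCR events as delimited text
#'
#' @param events a [detect_scr_events()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scr_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("trough_time_s", "peak_time_s",
                                             "amplitude_uS")],
                   path, row.names = FALSE)
  invisible(path)
}
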