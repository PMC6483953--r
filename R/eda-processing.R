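# Skin-conductance preprocessing and event-related SCR detection:
# low-pass Butterworth filtering, first derivative, and peak/trough pairing
# by derivative sign changes with a backward trough search.

#' Uniformly sampled skin-conductance trace
#'
#' @param values_uS numeric vector of conductance samples in microsiemens.
#' @param rate_hz sampling rate in samples/second.
#' @param start_s time of the first sample in seconds.
#' @return An object of class `eda_trace`.
#' @export
eda_trace <- function(values_uS, rate_hz, start_s = 0) {
  if (!is.numeric(values_uS) || length(values_uS) < 2L) {
    stop_param("`values_uS` must be a numeric vector of length >= 2")
  }
  if (!all(is.finite(values_uS))) stop_param("trace values must be finite")
  if (!(rate_hz > 0)) stop_param("`rate_hz` must be positive")
  structure(
    list(values_uS = as.numeric(values_uS), rate_hz = rate_hz,
         start_s = start_s),
    class = "eda_trace"
  )
}

#' @export
print.eda_trace <- function(x, ...) {
  cat(sprintf("<eda_trace> %d samples @ %g Hz (%.1f s), %.2f..%.2f uS\n",
              length(x$values_uS), x$rate_hz,
              length(x$values_uS) / x$rate_hz,
              min(x$values_uS), max(x$values_uS)))
  invisible(x)
}

# time stamps of an eda_trace
trace_times <- function(trace) {
  trace$start_s + (seq_along(trace$values_uS) - 1L) / trace$rate_hz
}

#' Low-pass Butterworth filter for skin-conductance traces
#'
#' Applies an order-`order` Butterworth low-pass at `cutoff_hz`, by default
#' forward-backward (zero-phase, via [signal::filtfilt()]) so that detected
#' event times are not shifted by filter delay. Zero-phase filtering applies
#' the magnitude response twice: the gain at the cutoff is 0.5 rather than
#' the single-pass 1/sqrt(2). A single forward pass ([signal::filter()],
#' which does delay features) is available with `zero_phase = FALSE`.
#'
#' @param trace an [eda_trace()].
#' @param cutoff_hz cutoff frequency in Hz (default 10, the conventional
#'   pre-detection smoothing for electrodermal recordings).
#' @param order filter order (default 4).
#' @param zero_phase forward-backward filtering? Default `TRUE`.
#' @return A filtered [eda_trace()] of the same length, rate and start time.
#' @export
lowpass_butterworth <- function(trace, cutoff_hz = 10, order = 4,
                                zero_phase = TRUE) {
  stopifnot(inherits(trace, "eda_trace"))
  nyquist <- trace$rate_hz / 2
  if (!(cutoff_hz > 0) || cutoff_hz >= nyquist) {
    stop_param("`cutoff_hz` (%g) must lie in (0, Nyquist = %g)",
               cutoff_hz, nyquist)
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  x <- trace$values_uS
  n <- length(x)
  # odd-reflection padding and mean removal suppress the start-up transient
  # (ringing at the trace edges) that would otherwise masquerade as events
  npad <- min(n - 1L, ceiling(3 * trace$rate_hz / cutoff_hz))
  left <- 2 * x[1] - x[(npad + 1L):2]
  right <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(left, x, right)
  mu <- mean(xp)
  yp <- if (zero_phase) {
    signal::filtfilt(bf, xp - mu)
  } else {
    as.numeric(signal::filter(bf, xp - mu))
  }
  y <- yp[(npad + 1L):(npad + n)] + mu
  eda_trace(y, trace$rate_hz, trace$start_s)
}

#' First derivative of a trace (microsiemens per second)
#'
#' Central differences on interior samples, one-sided differences at the two
#' ends; exact for affine signals on the interior.
#'
#' @param trace an [eda_trace()] with at least 3 samples.
#' @return Numeric vector of the same length as the trace.
#' @export
first_derivative <- function(trace) {
  stopifnot(inherits(trace, "eda_trace"))
  x <- trace$values_uS
  n <- length(x)
  if (n < 3L) stop_param("need at least 3 samples for a derivative")
  dt <- 1 / trace$rate_hz
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' Detect SCR peak/trough pairs by first-derivative sign changes
#'
#' A peak is a sample where the first derivative crosses from positive to
#' negative. For each peak the algorithm searches backward over
#' `backward_window_s` for troughs — derivative sign changes from negative to
#' positive — or "bends", near-flat samples where `|derivative| < bend_eps`
#' (used only when no strict sign change exists in the window). Among the
#' candidates the one with minimal conductance is taken (ties broken toward
#' the latest, i.e. the onset closest to the rise), and the event amplitude
#' is peak minus trough. Peaks with no candidate trough in the window, or a
#' non-positive amplitude, are dropped.
#'
#' The trace should already be low-pass filtered ([lowpass_butterworth()]);
#' detection runs on the samples it is given.
#'
#' @param trace a filtered [eda_trace()].
#' @param backward_window_s how far back to search for the trough (s).
#' @param bend_eps flat-derivative tolerance in microsiemens/second for the
#'   bend rule.
#' @param amp_floor_uS numerical floor below which a peak/trough excursion is
#'   treated as floating-point ripple, not an event (default 1e-4, two
#'   orders of magnitude under any scoreable SCR).
#' @return A data frame of class `scr_events` with columns `trough_time_s`,
#'   `peak_time_s`, `amplitude_uS`, sorted by peak time; zero rows for flat
#'   or monotone signals.
#' @export
detect_scr_events <- function(trace, backward_window_s = 4.0,
                              bend_eps = 0.001, amp_floor_uS = 1e-4) {
  stopifnot(inherits(trace, "eda_trace"))
  x <- trace$values_uS
  d <- first_derivative(trace)
  tt <- trace_times(trace)
  n <- length(x)
  win <- round(backward_window_s * trace$rate_hz)

  s <- sign(d)
  # sign-change indices: first sample of the new sign regime
  peaks <- which(s[-n] > 0 & s[-1] <= 0) + 1L
  troughs <- which(s[-n] < 0 & s[-1] >= 0) + 1L
  bends <- which(abs(d) < bend_eps)

  out <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    lo <- max(1L, p - win)
    cand <- troughs[troughs >= lo & troughs < p]
    if (length(cand) == 0L) {
      cand <- bends[bends >= lo & bends < p]
    }
    if (length(cand) == 0L) next
    v <- x[cand]
    best <- cand[v <= min(v) + 1e-12]
    tr <- best[length(best)]            # latest among minimal-value candidates
    amp <- x[p] - x[tr]
    if (amp <= amp_floor_uS) next
    out[[i]] <- c(tt[tr], tt[p], amp)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- matrix(numeric(0), ncol = 3)
  }
  ev <- data.frame(trough_time_s = out[, 1], peak_time_s = out[, 2],
                   amplitude_uS = out[, 3])
  ev <- ev[order(ev$peak_time_s), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("scr_events", "data.frame")
  ev
}
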