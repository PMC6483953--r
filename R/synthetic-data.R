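# Synthetic-data generators: stimulus schedules, skin-conductance traces with
# known ground-truth SCRs, psychometric observers, and two-group cohorts.
# Everything is deterministic given a seed so downstream stages can be tested
# end-to-end without real recordings.

#' Build a jittered auditory stimulus schedule
#'
#' Trials are laid out sequentially: each onset follows the previous one by
#' the stimulus duration plus an interstimulus interval (ISI) drawn uniformly
#' from `[isi_min_s, isi_max_s]`. The defaults describe a 15-trial block of
#' 3 s stimuli with ISIs jittered between 20 and 35 s, the usual layout for
#' event-related electrodermal habituation runs.
#'
#' @param n_trials number of stimulus presentations (>= 1).
#' @param duration_s stimulus duration in seconds.
#' @param isi_min_s,isi_max_s bounds of the uniform ISI jitter in seconds.
#' @param seed integer seed; equal seeds give identical schedules.
#' @param start_s onset time of the first trial in seconds.
#' @return An object of class `stimulus_schedule`: a list with `onsets_s`
#'   (strictly increasing onset times), `duration_s` and `n_trials`.
#' @examples
#' sched <- make_schedule(15, seed = 1)
#' diff(sched$onsets_s)  # all gaps in [23, 38] s
#' @export
make_schedule <- function(n_trials, duration_s = 3, isi_min_s = 20,
                          isi_max_s = 35, seed = NULL, start_s = 10) {
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop_param("`n_trials` must be >= 1")
  }
  n_trials <- as.integer(n_trials)
  assert_scalar_num(duration_s, "duration_s")
  if (duration_s <= 0) stop_param("`duration_s` must be positive")
  if (!(isi_min_s > 0) || isi_min_s > isi_max_s) {
    stop_param("need 0 < isi_min_s <= isi_max_s (got %s, %s)",
               isi_min_s, isi_max_s)
  }
  gaps <- if (n_trials > 1) {
    duration_s + with_seed(seed, stats::runif(n_trials - 1L, isi_min_s, isi_max_s))
  } else {
    numeric(0)
  }
  structure(
    list(onsets_s = start_s + c(0, cumsum(gaps)),
         duration_s = duration_s,
         n_trials = n_trials),
    class = "stimulus_schedule"
  )
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %d trials, %.3g s stimuli, onsets %.1f..%.1f s\n",
              x$n_trials, x$duration_s, x$onsets_s[1],
              x$onsets_s[x$n_trials]))
  invisible(x)
}

#' Biexponential SCR kernel, rescaled to unit peak
#'
#' The canonical phasic skin-conductance shape
#' \eqn{k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}} with rise constant
#' \eqn{\tau_r < \tau_d}, rescaled so its maximum is exactly 1. The peak falls
#' at \eqn{t^* = \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)}.
#'
#' @param rise_tau_s,decay_tau_s rise and decay time constants in seconds;
#'   must satisfy `0 < rise_tau_s < decay_tau_s`.
#' @param dt_s sampling interval in seconds.
#' @param length_s kernel support in seconds; defaults to the peak time plus
#'   ten decay constants, by which point the tail is below 1e-4.
#' @return Numeric vector of kernel samples starting at t = 0, with
#'   attributes `peak_time_s` (closed-form argmax) and `dt_s`.
#' @export
scr_kernel <- function(rise_tau_s = 0.75, decay_tau_s = 2, dt_s = 0.001,
                       length_s = NULL) {
  if (!(rise_tau_s > 0) || !(rise_tau_s < decay_tau_s)) {
    stop_param("need 0 < rise_tau_s < decay_tau_s (got %s, %s)",
               rise_tau_s, decay_tau_s)
  }
  if (!(dt_s > 0)) stop_param("`dt_s` must be positive")
  t_peak <- log(decay_tau_s / rise_tau_s) *
    rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s)
  if (is.null(length_s)) length_s <- t_peak + 10 * decay_tau_s
  t <- seq(0, length_s, by = dt_s)
  k <- exp(-t / decay_tau_s) - exp(-t / rise_tau_s)
  peak <- exp(-t_peak / decay_tau_s) - exp(-t_peak / rise_tau_s)
  k <- k / peak
  attr(k, "peak_time_s") <- t_peak
  attr(k, "dt_s") <- dt_s
  k
}

#' Parameters for the ground-truth SCR generator
#'
#' Describes one simulated participant's electrodermal signal: the phasic
#' response amplitude on the first trial, its geometric per-trial decay
#' (habituation), response latency and its jitter, the biexponential kernel
#' time constants, and the tonic component (level, linear drift, noise).
#'
#' @param initial_amplitude_uS first-trial SCR amplitude in microsiemens.
#' @param decay_ratio per-trial multiplicative amplitude decay, in (0, 1].
#' @param latency_s mean SCR onset latency after stimulus onset, seconds.
#' @param latency_jitter_s half-width of the uniform latency jitter, seconds.
#' @param rise_tau_s,decay_tau_s kernel time constants (see [scr_kernel()]).
#' @param tonic_level_uS baseline skin-conductance level in microsiemens.
#' @param drift_uS_per_s linear tonic drift.
#' @param noise_sd_uS standard deviation of additive Gaussian noise.
#' @param response_prob per-trial probability that an SCR is emitted at all.
#' @param seed integer seed for emission, latency and noise draws.
#' @return A validated list of class `scr_gen_params`.
#' @export
scr_gen_params <- function(initial_amplitude_uS = 0.5, decay_ratio = 0.75,
                           latency_s = 1.8, latency_jitter_s = 0.3,
                           rise_tau_s = 0.75, decay_tau_s = 2,
                           tonic_level_uS = 32, drift_uS_per_s = 0.002,
                           noise_sd_uS = 0.01, response_prob = 1,
                           seed = NULL) {
  if (!(initial_amplitude_uS > 0)) stop_param("`initial_amplitude_uS` must be positive")
  if (!(decay_ratio > 0 && decay_ratio <= 1)) stop_param("`decay_ratio` must be in (0, 1]")
  if (!(response_prob >= 0 && response_prob <= 1)) stop_param("`response_prob` must be in [0, 1]")
  if (!(tonic_level_uS > 0)) stop_param("`tonic_level_uS` must be positive")
  if (!(rise_tau_s > 0 && rise_tau_s < decay_tau_s)) {
    stop_param("need 0 < rise_tau_s < decay_tau_s")
  }
  if (noise_sd_uS < 0 || latency_jitter_s < 0) {
    stop_param("`noise_sd_uS` and `latency_jitter_s` must be non-negative")
  }
  structure(
    list(initial_amplitude_uS = initial_amplitude_uS, decay_ratio = decay_ratio,
         latency_s = latency_s, latency_jitter_s = latency_jitter_s,
         rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
         tonic_level_uS = tonic_level_uS, drift_uS_per_s = drift_uS_per_s,
         noise_sd_uS = noise_sd_uS, response_prob = response_prob,
         seed = seed),
    class = "scr_gen_params"
  )
}

#' Generate a skin-conductance trace with known ground-truth SCRs
#'
#' Builds `tonic + drift + sum of emitted SCRs + noise` on a uniform grid.
#' The SCR emitted on trial k (1-based) has true amplitude
#' `initial_amplitude_uS * decay_ratio^(k-1)`, begins `latency_s` (plus
#' uniform jitter) after the stimulus onset, and follows the biexponential
#' kernel. Each trial independently emits a response with probability
#' `response_prob`.
#'
#' @param schedule a [make_schedule()] result.
#' @param params an [scr_gen_params()] object.
#' @param rate_hz sampling rate in samples/second (default 1000, the rate the
#'   scoring conventions here assume for acquisition).
#' @param total_s total trace duration; must cover the last onset + 10 s.
#'   Defaults to exactly that.
#' @return A list with `trace` (an [eda_trace()]) and `truth`, a data frame
#'   with one row per trial: `trial`, `stim_onset_s`, `emitted`,
#'   `scr_onset_s` and `amplitude_uS` (NA when not emitted).
#' @export
generate_eda_trace <- function(schedule, params = scr_gen_params(),
                               rate_hz = 1000, total_s = NULL) {
  stopifnot(inherits(schedule, "stimulus_schedule"),
            inherits(params, "scr_gen_params"))
  if (!(rate_hz > 0)) stop_param("`rate_hz` must be positive")
  need_s <- max(schedule$onsets_s) + 10
  if (is.null(total_s)) total_s <- need_s
  if (total_s < need_s) {
    stop_param("`total_s` (%.1f) must cover the last onset + 10 s (%.1f)",
               total_s, need_s)
  }
  n <- floor(total_s * rate_hz) + 1L
  t <- (seq_len(n) - 1L) / rate_hz
  values <- params$tonic_level_uS + params$drift_uS_per_s * t

  k_tr <- schedule$n_trials
  draws <- with_seed(params$seed, list(
    emitted = stats::runif(k_tr) < params$response_prob,
    lat_jit = stats::runif(k_tr, -params$latency_jitter_s, params$latency_jitter_s),
    noise = if (params$noise_sd_uS > 0) stats::rnorm(n, 0, params$noise_sd_uS) else 0
  ))

  kern <- scr_kernel(params$rise_tau_s, params$decay_tau_s, dt_s = 1 / rate_hz)
  amp <- params$initial_amplitude_uS * params$decay_ratio^(seq_len(k_tr) - 1L)
  onset_s <- schedule$onsets_s + params$latency_s + draws$lat_jit

  for (k in seq_len(k_tr)) {
    if (!draws$emitted[k]) next
    i0 <- round(onset_s[k] * rate_hz) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    values[idx] <- values[idx] + amp[k] * kern[seq_along(idx)]
  }
  values <- values + draws$noise

  truth <- data.frame(
    trial = seq_len(k_tr),
    stim_onset_s = schedule$onsets_s,
    emitted = draws$emitted,
    scr_onset_s = ifelse(draws$emitted, onset_s, NA_real_),
    amplitude_uS = ifelse(draws$emitted, amp, NA_real_)
  )
  list(trace = eda_trace(values, rate_hz), truth = truth)
}

#' Simulated yes/no psychometric observer
#'
#' An observer with a logistic psychometric function: the probability of
#' reporting "yes, I hear it" at presentation level L is
#' `guess + (1 - guess - lapse) * F((L - threshold)/slope)` where F is the
#' standard logistic CDF. `slope_db = 0` degenerates to the deterministic
#' step rule "yes iff L >= threshold".
#'
#' @param true_threshold_db level of 50% detection (before guess/lapse), dB.
#' @param slope_db psychometric spread in dB; 0 gives a step observer.
#' @param lapse_rate probability of "no" when clearly audible, in [0, 0.5).
#' @param guess_rate probability of "yes" when inaudible, in [0, 0.5).
#' @param seed integer seed consumed by staircase runs in presentation order.
#' @return A list of class `observer`.
#' @export
make_observer <- function(true_threshold_db, slope_db = 0, lapse_rate = 0,
                          guess_rate = 0, seed = NULL) {
  assert_scalar_num(true_threshold_db, "true_threshold_db")
  if (slope_db < 0) stop_param("`slope_db` must be >= 0")
  if (lapse_rate < 0 || lapse_rate >= 0.5 || guess_rate < 0 || guess_rate >= 0.5) {
    stop_param("`lapse_rate` and `guess_rate` must lie in [0, 0.5)")
  }
  structure(
    list(true_threshold_db = true_threshold_db, slope_db = slope_db,
         lapse_rate = lapse_rate, guess_rate = guess_rate, seed = seed),
    class = "observer"
  )
}

#' Draw one yes/no response from an observer
#'
#' Consumes one uniform deviate from the *current* RNG stream (except for
#' deterministic step observers with no lapses/guesses, which consume none),
#' so responses are reproducible given the seed and the order of
#' presentations. Staircase drivers seed the stream once per run from
#' `observer$seed`.
#'
#' @param observer a [make_observer()] object.
#' @param level_db presented level in dB.
#' @return `TRUE` for "yes, heard", `FALSE` for "no".
#' @export
observer_response <- function(observer, level_db) {
  stopifnot(inherits(observer, "observer"))
  f <- if (observer$slope_db == 0) {
    as.numeric(level_db >= observer$true_threshold_db)
  } else {
    stats::plogis((level_db - observer$true_threshold_db) / observer$slope_db)
  }
  p_yes <- observer$guess_rate +
    (1 - observer$guess_rate - observer$lapse_rate) * f
  if (p_yes <= 0) return(FALSE)
  if (p_yes >= 1) return(TRUE)
  stats::runif(1) < p_yes
}

#' Specification of a synthetic two-group cohort
#'
#' Per-group sample sizes and the mean/SD of each outcome the study design
#' measures: self-reported auditory sensitivity (AASP auditory-item total),
#' arousal and valence ratings for the tone and siren stimuli, the true
#' auditory detection threshold, and the distribution of each participant's
#' SCR-generator parameters (tonic level, first-trial amplitude, habituation
#' decay). A fraction of each group can be made electrodermally
#' non-responsive (`response_prob = 0`), emulating the non-responder
#' phenomenon. A target Spearman correlation couples the tone-arousal rating
#' to the AASP score through a shared latent Gaussian (Gaussian copula), so
#' the realized rank correlation approaches the target as n grows.
#'
#' Defaults mirror a two-group autism-spectrum (ASD) vs. typically-developing
#' (TD) design: n = 33/31, AASP auditory totals 35.61 (8.1) vs. 24.94 (6.0),
#' tonic level 32.31 (4.2) vs. 31.16 (3.0) microsiemens, detection thresholds
#' 15.45 (5.2) vs. 13.87 (4.6) dB, non-responder fractions 7/33 and 4/31, and
#' a 0.61 rank correlation between tone arousal and AASP.
#'
#' @param n per-group sample sizes (length 2, each >= 2).
#' @param group_labels group names, length 2.
#' @param aasp_mean,aasp_sd AASP auditory-item total per group.
#' @param arousal_tone_mean,arousal_tone_sd tone arousal rating (1-9 scale).
#' @param valence_tone_mean,valence_tone_sd tone valence rating.
#' @param arousal_siren_mean,arousal_siren_sd siren arousal rating.
#' @param valence_siren_mean,valence_siren_sd siren valence rating.
#' @param threshold_mean,threshold_sd true detection threshold, dB.
#' @param tonic_mean,tonic_sd tonic skin-conductance level, microsiemens.
#' @param amp_mean,amp_sd first-trial SCR amplitude, microsiemens.
#' @param decay_mean,decay_sd per-trial habituation decay ratio.
#' @param response_prob per-trial SCR emission probability for responders.
#' @param nonresponder_rate fraction of each group generated with
#'   `response_prob = 0`.
#' @param rho_arousal_aasp target Spearman correlation between the tone
#'   arousal rating and the AASP score, in [-1, 1].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(33, 31),
                        group_labels = c("ASD", "TD"),
                        aasp_mean = c(35.61, 24.94), aasp_sd = c(8.1, 6.0),
                        arousal_tone_mean = c(5.27, 3.47), arousal_tone_sd = c(0.3, 0.3),
                        valence_tone_mean = c(2.02, 2.14), valence_tone_sd = c(0.1, 0.1),
                        arousal_siren_mean = c(4.97, 3.57), arousal_siren_sd = c(0.3, 0.4),
                        valence_siren_mean = c(4.09, 4.73), valence_siren_sd = c(0.3, 0.3),
                        threshold_mean = c(15.45, 13.87), threshold_sd = c(5.2, 4.6),
                        tonic_mean = c(32.31, 31.16), tonic_sd = c(4.2, 3.0),
                        amp_mean = c(0.50, 0.45), amp_sd = c(0.12, 0.12),
                        decay_mean = c(0.69, 0.69), decay_sd = c(0.05, 0.05),
                        response_prob = c(0.95, 0.95),
                        nonresponder_rate = c(7 / 33, 4 / 31),
                        rho_arousal_aasp = 0.61) {
  if (length(n) != 2 || any(n < 2)) stop_param("`n` must be two sizes, each >= 2")
  if (abs(rho_arousal_aasp) > 1) stop_param("`rho_arousal_aasp` must be in [-1, 1]")
  sds <- list(aasp_sd, arousal_tone_sd, valence_tone_sd, arousal_siren_sd,
              valence_siren_sd, threshold_sd, tonic_sd, amp_sd, decay_sd)
  if (any(unlist(sds) < 0)) stop_param("spreads must be >= 0")
  if (any(nonresponder_rate < 0 | nonresponder_rate > 1)) {
    stop_param("`nonresponder_rate` must be in [0, 1]")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic two-group cohort table
#'
#' Draws one row per participant with group label, outcome scores, the
#' participant's SCR-generator parameters and true detection threshold.
#' The tone arousal rating and AASP score share a latent Gaussian with
#' Pearson correlation `2*sin(pi*rho_s/6)` (the Gaussian-copula inverse of
#' the Spearman target), so their rank correlation converges to the spec's
#' target. A master seed spawns one sub-seed per participant (stored in the
#' `seed` column) so each participant's trace generation is reproducible
#' row-by-row.
#'
#' @param spec a [cohort_spec()].
#' @param seed master integer seed.
#' @return A data frame, one row per participant, with columns `id`, `group`,
#'   `aasp`, `arousal_tone`, `valence_tone`, `arousal_siren`, `valence_siren`,
#'   `true_threshold_db`, `tonic_level_uS`, `initial_amplitude_uS`,
#'   `decay_ratio`, `response_prob`, `nonresponder_truth`, `seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_tot <- sum(spec$n)
  with_seed(seed, {
    g <- rep(1:2, spec$n)
    # latent Gaussian pair for the arousal--AASP rank coupling
    rho_p <- 2 * sin(pi * spec$rho_arousal_aasp / 6)
    z1 <- stats::rnorm(n_tot)
    z2 <- rho_p * z1 + sqrt(1 - rho_p^2) * stats::rnorm(n_tot)
    nonresp <- stats::runif(n_tot) < spec$nonresponder_rate[g]
    cohort <- data.frame(
      id = sprintf("P%03d", seq_len(n_tot)),
      group = factor(spec$group_labels[g], levels = spec$group_labels),
      aasp = spec$aasp_mean[g] + spec$aasp_sd[g] * z1,
      arousal_tone = spec$arousal_tone_mean[g] + spec$arousal_tone_sd[g] * z2,
      valence_tone = stats::rnorm(n_tot, spec$valence_tone_mean[g], spec$valence_tone_sd[g]),
      arousal_siren = stats::rnorm(n_tot, spec$arousal_siren_mean[g], spec$arousal_siren_sd[g]),
      valence_siren = stats::rnorm(n_tot, spec$valence_siren_mean[g], spec$valence_siren_sd[g]),
      true_threshold_db = stats::rnorm(n_tot, spec$threshold_mean[g], spec$threshold_sd[g]),
      tonic_level_uS = pmax(1, stats::rnorm(n_tot, spec$tonic_mean[g], spec$tonic_sd[g])),
      initial_amplitude_uS = pmax(0.05, stats::rnorm(n_tot, spec$amp_mean[g], spec$amp_sd[g])),
      decay_ratio = pmin(0.98, pmax(0.3, stats::rnorm(n_tot, spec$decay_mean[g], spec$decay_sd[g]))),
      response_prob = ifelse(nonresp, 0, spec$response_prob[g]),
      nonresponder_truth = nonresp,
      seed = spawn_seeds(sample.int(.Machine$integer.max - 1L, 1), n_tot)
    )
    cohort
  })
}
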