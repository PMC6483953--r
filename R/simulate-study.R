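# End-to-end study driver: generate per-participant traces from a cohort
# table, run the detection/scoring pipeline on each, measure detection
# thresholds with the staircase, and assemble the analysis report.

#' Score one participant's habituation run for one condition
#'
#' Generates (or accepts) a stimulus schedule, synthesizes the trace from
#' the participant's generator parameters, low-pass filters it, detects SCR
#' events, and scores the trials.
#'
#' @param params an [scr_gen_params()] for this participant/condition.
#' @param schedule a [make_schedule()]; built from `schedule_seed` when
#'   omitted.
#' @param n_trials,schedule_seed used when `schedule` is omitted.
#' @param rate_hz trace sampling rate.
#' @param criteria a [scoring_criteria()].
#' @return A list with `scores` (per-trial data frame), `habituation`
#'   ([trials_to_habituation()]), `blocks` ([block_means()]), `events`, and
#'   `truth` (the generator's ground-truth table).
#' @export
simulate_condition <- function(params, schedule = NULL, n_trials = 15,
                               schedule_seed = NULL, rate_hz = 1000,
                               criteria = scoring_criteria()) {
  if (is.null(schedule)) {
    schedule <- make_schedule(n_trials, seed = schedule_seed)
  }
  gen <- generate_eda_trace(schedule, params, rate_hz = rate_hz)
  filt <- lowpass_butterworth(gen$trace)
  events <- detect_scr_events(filt)
  scores <- score_trials(events, schedule, criteria)
  list(scores = scores,
       habituation = trials_to_habituation(scores),
       blocks = block_means(scores),
       events = events,
       truth = gen$truth)
}

#' Simulate and score a whole cohort
#'
#' For every participant in a [generate_cohort()] table, runs the two
#' habituation conditions (tone and siren) through trace synthesis,
#' filtering, SCR detection and trial scoring, classifies responders, and
#' measures the auditory detection threshold by the repeated staircase
#' against the participant's psychometric observer.
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param rate_hz trace sampling rate for the simulated runs. The default
#'   200 Hz keeps whole-cohort simulation light; single-trace analyses use
#'   the acquisition-style 1000 Hz.
#' @param n_trials trials per condition (default 15).
#' @param observer_slope_db,observer_lapse,observer_guess psychometric
#'   parameters shared by all simulated observers (their thresholds come
#'   from the cohort's `true_threshold_db`).
#' @param criteria a [scoring_criteria()].
#' @param noise_sd_uS,drift_uS_per_s trace noise and tonic drift passed to
#'   every participant's generator.
#' @return The cohort data frame with per-participant results appended:
#'   `hab_tone`, `hab_tone_censored`, `hab_siren`, `hab_siren_censored`,
#'   `responder`, `tone_b1..b3`, `siren_b1..b3` (block mean magnitudes),
#'   `detection_db`, `detection_passes`, `baseline_scl_uS`.
#' @export
score_cohort <- function(cohort, rate_hz = 200, n_trials = 15,
                         observer_slope_db = 0.5, observer_lapse = 0.005,
                         observer_guess = 0.005,
                         criteria = scoring_criteria(),
                         noise_sd_uS = 0.01, drift_uS_per_s = 0.002) {
  n <- nrow(cohort)
  res <- data.frame(
    hab_tone = integer(n), hab_tone_censored = logical(n),
    hab_siren = integer(n), hab_siren_censored = logical(n),
    responder = logical(n),
    tone_b1 = numeric(n), tone_b2 = numeric(n), tone_b3 = numeric(n),
    siren_b1 = numeric(n), siren_b2 = numeric(n), siren_b3 = numeric(n),
    detection_db = numeric(n), detection_passes = integer(n),
    baseline_scl_uS = numeric(n)
  )
  for (i in seq_len(n)) {
    row <- cohort[i, ]
    seeds <- spawn_seeds(row$seed, 5L)
    conds <- lapply(1:2, function(j) {
      params <- scr_gen_params(
        initial_amplitude_uS = row$initial_amplitude_uS,
        decay_ratio = row$decay_ratio,
        tonic_level_uS = row$tonic_level_uS,
        drift_uS_per_s = drift_uS_per_s,
        noise_sd_uS = noise_sd_uS,
        response_prob = row$response_prob,
        seed = seeds[j])
      simulate_condition(params, n_trials = n_trials,
                         schedule_seed = seeds[j + 2L],
                         rate_hz = rate_hz, criteria = criteria)
    })
    res$hab_tone[i] <- conds[[1]]$habituation$trials_to_habituation
    res$hab_tone_censored[i] <- conds[[1]]$habituation$censored
    res$hab_siren[i] <- conds[[2]]$habituation$trials_to_habituation
    res$hab_siren_censored[i] <- conds[[2]]$habituation$censored
    res$responder[i] <- classify_responder(list(conds[[1]]$scores,
                                                conds[[2]]$scores))
    res[i, c("tone_b1", "tone_b2", "tone_b3")] <- conds[[1]]$blocks
    res[i, c("siren_b1", "siren_b2", "siren_b3")] <- conds[[2]]$blocks

    obs <- make_observer(row$true_threshold_db, slope_db = observer_slope_db,
                         lapse_rate = observer_lapse,
                         guess_rate = observer_guess, seed = seeds[5])
    # a failed staircase (non-convergence or runaway) records NA
    thr <- tryCatch(detection_threshold(obs, max_passes = 25),
                    error = function(e) NULL)
    if (is.null(thr)) {
      res$detection_db[i] <- NA_real_
      res$detection_passes[i] <- NA_integer_
    } else {
      res$detection_db[i] <- thr$final_threshold_db
      res$detection_passes[i] <- thr$n_passes
    }

    # short synthetic rest baseline: tonic + noise around the true level
    bl <- with_seed(seeds[4],
                    row$tonic_level_uS + stats::rnorm(600 * 10, 0, noise_sd_uS))
    res$baseline_scl_uS[i] <- baseline_scl(eda_trace(bl, 10),
                                           total_baseline_s = 600, last_s = 300)
  }
  cbind(cohort, res)
}

#' Analyze a scored cohort
#'
#' Runs the full statistical stage over a [score_cohort()] table:
#' group descriptives with one-way ANOVA F/p and Cohen's d (Bonferroni
#' levels reported per family), detection-threshold and habituation
#' comparisons (habituation over responders only), subjective-rating
#' comparisons, the correlation panel (Pearson for detection and
#' habituation vs. self-reported auditory sensitivity; Spearman for the
#' ratings), and the mixed repeated-measures block-slope ANOVA per
#' condition. Each analysis variable passes through normality screening
#' ([screen_variable()]) and 3xIQR winsorization ([winsorize_outliers()]);
#' the decisions are returned in `screening`.
#'
#' @param scored a [score_cohort()] result (or any data frame with the same
#'   columns).
#' @param alpha family-wise significance level (default 0.05).
#' @param winsorize_unit measurement unit used when replacing outliers in
#'   physiological variables.
#' @return A list of class `edahab_report` with elements `descriptives`,
#'   `comparisons`, `correlations`, `block_anova` (one mixed ANOVA table
#'   per condition), `screening`, `n_responders` (per group) and
#'   `bonferroni`.
#' @export
analyze_cohort <- function(scored, alpha = 0.05, winsorize_unit = 0.1) {
  stopifnot(is.factor(scored$group) || is.character(scored$group))
  g <- factor(scored$group)
  if (nlevels(g) != 2) stop_param("expected exactly 2 groups")
  lv <- levels(g)
  if (any(table(g) == 0)) stop_param("empty group")
  split2 <- function(x) list(x[g == lv[1]], x[g == lv[2]])

  screening <- list()
  prepare <- function(x, name, unit = winsorize_unit) {
    w <- winsorize_outliers(x, unit = unit)
    sc <- screen_variable(w$x)
    screening[[name]] <<- data.frame(
      variable = name, n_outliers = length(w$outliers),
      z_skew = sc$z_skew, z_kurt = sc$z_kurt,
      normal = sc$normal_flag, transform = sc$applied_transform)
    sc$x
  }

  comp_row <- function(x, name, transform = TRUE, unit = winsorize_unit) {
    xt <- if (transform) prepare(x, name, unit) else x
    s <- split2(xt)
    an <- oneway_anova(s[[1]], s[[2]])
    raw <- split2(x)
    data.frame(variable = name,
               mean1 = mean(raw[[1]], na.rm = TRUE),
               sd1 = stats::sd(raw[[1]], na.rm = TRUE),
               mean2 = mean(raw[[2]], na.rm = TRUE),
               sd2 = stats::sd(raw[[2]], na.rm = TRUE),
               F = an$F_statistic, p = an$p_value, d = an$cohens_d)
  }

  descriptives <- comp_row(scored$aasp, "aasp_auditory", unit = 1)

  resp <- scored$responder
  hab_tone <- ifelse(resp, scored$hab_tone, NA_real_)
  hab_siren <- ifelse(resp, scored$hab_siren, NA_real_)
  comparisons <- rbind(
    comp_row(scored$detection_db, "detection_db"),
    comp_row(hab_tone, "habituation_tone", unit = 1),
    comp_row(hab_siren, "habituation_siren", unit = 1),
    # ordinal 1-9 ratings: compared untransformed, rank-based tests belong
    # in the correlation panel
    comp_row(scored$valence_tone, "valence_tone", transform = FALSE),
    comp_row(scored$valence_siren, "valence_siren", transform = FALSE),
    comp_row(scored$arousal_tone, "arousal_tone", transform = FALSE),
    comp_row(scored$arousal_siren, "arousal_siren", transform = FALSE)
  )

  corr_row <- function(x, y, name, kind) {
    ct <- correlations(x, y, kind)
    data.frame(pair = name, kind = kind, r = ct$r, p = ct$p, n = ct$n)
  }
  corrs <- rbind(
    corr_row(scored$detection_db, scored$aasp, "detection~aasp", "pearson"),
    corr_row(hab_tone, scored$aasp, "habituation_tone~aasp", "pearson"),
    corr_row(scored$arousal_tone, scored$aasp, "arousal_tone~aasp", "spearman"),
    corr_row(scored$arousal_siren, scored$aasp, "arousal_siren~aasp", "spearman"),
    corr_row(scored$valence_tone, scored$aasp, "valence_tone~aasp", "spearman"),
    corr_row(scored$valence_siren, scored$aasp, "valence_siren~aasp", "spearman")
  )

  block_anova <- list()
  for (cond in c("tone", "siren")) {
    cols <- paste0(cond, "_b", 1:3)
    bm <- as.matrix(scored[resp, cols])
    # square-root transform: block magnitudes are right-skewed
    block_anova[[cond]] <- rm_anova_blocks(sqrt(pmax(bm, 0)), g[resp])
  }

  structure(
    list(descriptives = descriptives, comparisons = comparisons,
         correlations = corrs, block_anova = block_anova,
         screening = do.call(rbind, screening),
         n_responders = table(g[resp]),
         bonferroni = c(descriptives = bonferroni_alpha(alpha, nrow(descriptives)),
                        ratings = bonferroni_alpha(alpha, 4))),
    class = "edahab_report"
  )
}

#' @export
print.edahab_report <- function(x, ...) {
  cat("== Group descriptives (mean1/sd1 vs mean2/sd2, F, p, d) ==\n")
  print(format(x$descriptives, digits = 3), row.names = FALSE)
  cat("\n== Detection / habituation / ratings ==\n")
  print(format(x$comparisons, digits = 3), row.names = FALSE)
  cat(sprintf("\nResponders per group: %s\n",
              paste(names(x$n_responders), x$n_responders,
                    sep = " = ", collapse = ", ")))
  cat("\n== Correlation panel ==\n")
  print(format(x$correlations, digits = 3), row.names = FALSE)
  cat("\n== Block-slope mixed ANOVA ==\n")
  for (cond in names(x$block_anova)) {
    cat(sprintf("-- %s --\n", cond))
    print(format(x$block_anova[[cond]], digits = 3), row.names = FALSE)
  }
  invisible(x)
}
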