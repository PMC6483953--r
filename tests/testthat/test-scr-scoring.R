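sched_for <- function(onsets, duration = 3) {
  structure(list(onsets_s = onsets, duration_s = duration,
                 n_trials = length(onsets)),
            class = "stimulus_schedule")
}

test_that("trial scoring applies the amplitude and latency window criteria", {
  sch <- sched_for(c(10, 40, 70))
  crit <- scoring_criteria()

  # qualifying event 2.5 s after onset
  sc <- score_trials(events_df(12.5, 13.5, 0.05), sch, crit)
  expect_equal(sc$scr_present, c(TRUE, FALSE, FALSE))
  expect_equal(sc$amplitude_uS[1], 0.05)

  # amplitude below 0.03: absent
  sc2 <- score_trials(events_df(12.5, 13.5, 0.02), sch, crit)
  expect_false(any(sc2$scr_present))
  expect_equal(sc2$amplitude_uS, c(0, 0, 0))

  # response 5 s after onset: outside the window
  sc3 <- score_trials(events_df(15.0, 15.8, 0.10), sch, crit)
  expect_false(any(sc3$scr_present))

  # window bounds inclusive at both ends
  sc4 <- score_trials(events_df(c(11, 44), c(11.5, 44.5), c(0.1, 0.1)),
                      sch, crit)
  expect_equal(sc4$scr_present, c(TRUE, TRUE, FALSE))

  # several qualifying events: largest amplitude kept
  sc5 <- score_trials(events_df(c(11.5, 13), c(12, 13.6), c(0.04, 0.09)),
                      sch, crit)
  expect_equal(sc5$amplitude_uS[1], 0.09)

  # peak-time matching by flag
  sc6 <- score_trials(events_df(9.5, 11.5, 0.1), sch, crit,
                      event_time = "peak")
  expect_true(sc6$scr_present[1])

  expect_error(score_trials(events_df(1, 2, 0.1), sched_for(c(10, 13)), crit),
               "overlap")
})

test_that("raising the amplitude criterion never adds present trials", {
  set.seed(77)
  sch <- sched_for(seq(10, 150, by = 35))
  for (rep in 1:20) {
    k <- sample(1:6, 1)
    tr <- runif(k, 10, 160)
    ev <- events_df(tr, tr + runif(k, 0.2, 2), runif(k, 0.005, 0.2))
    ev <- ev[order(ev$peak_time_s), ]
    for (thr in c(0.15, 0.08, 0.03, 0.01)) {
      n_present <- sum(score_trials(ev, sch,
                                    scoring_criteria(min_amplitude_uS = thr))$scr_present)
      expect_lte(sum(score_trials(ev, sch,
                                  scoring_criteria(min_amplitude_uS = thr * 2))$scr_present),
                 n_present)
    }
  }
})

test_that("trials-to-habituation matches its definition and the oracle", {
  mk <- function(present) data.frame(trial = seq_along(present),
                                     scr_present = present,
                                     amplitude_uS = ifelse(present, 0.1, 0))

  # responded on trials 1-4, silent from trial 5: habituation number 4
  h <- trials_to_habituation(mk(c(rep(TRUE, 4), rep(FALSE, 11))))
  expect_equal(h$trials_to_habituation, 4L)
  expect_false(h$censored)

  # never responded: first absent pair is trials 1-2
  h0 <- trials_to_habituation(mk(rep(FALSE, 15)))
  expect_equal(h0$trials_to_habituation, 0L)

  # alternating: no two consecutive absences, censored at 15
  ha <- trials_to_habituation(mk(rep(c(TRUE, FALSE), length.out = 15)))
  expect_equal(ha$trials_to_habituation, 15L)
  expect_true(ha$censored)

  # random sequences against the brute-force scan
  set.seed(5)
  for (i in 1:200) {
    p <- runif(15) < runif(1)
    expect_equal(trials_to_habituation(mk(p))$trials_to_habituation,
                 oracle_habituation(p))
  }
  expect_error(trials_to_habituation(mk(logical(0))), "empty")
})

test_that("responder classification distinguishes the two rules", {
  mk <- function(p) data.frame(trial = seq_along(p), scr_present = p,
                               amplitude_uS = ifelse(p, 0.1, 0))
  both <- mk(c(TRUE, TRUE, FALSE))
  none <- mk(c(FALSE, FALSE, TRUE))
  first_only <- mk(c(TRUE, FALSE, TRUE))
  second_only <- mk(c(FALSE, TRUE, TRUE))

  # enumeration of the four two-trial patterns under each rule
  expect_true(classify_responder(list(both)))
  expect_true(classify_responder(list(both), rule = "any_absent"))
  expect_false(classify_responder(list(none)))
  expect_false(classify_responder(list(none), rule = "any_absent"))
  expect_true(classify_responder(list(first_only)))
  expect_false(classify_responder(list(first_only), rule = "any_absent"))
  expect_true(classify_responder(list(second_only)))
  expect_false(classify_responder(list(second_only), rule = "any_absent"))

  # any condition can disqualify
  expect_false(classify_responder(list(both, none)))
  expect_error(classify_responder(list(mk(TRUE))), "2 trials")
})

test_that("block means average magnitudes and conserve the trial sum", {
  mk <- function(a) data.frame(trial = seq_along(a), scr_present = a > 0,
                               amplitude_uS = a)
  expect_equal(block_means(mk(rep(0, 15))), c(0, 0, 0))
  expect_equal(block_means(mk(1:15)), c(3, 8, 13))
  expect_error(block_means(mk(1:14)), "divisible")

  set.seed(8)
  a <- round(runif(15, 0, 0.5), 3) * (runif(15) > 0.3)
  bm <- block_means(mk(a))
  expect_equal(sum(bm) * 5, sum(a))

  # responded-trials-only convention
  a2 <- c(0.2, 0, 0, 0, 0, rep(0, 10))
  expect_equal(block_means(mk(a2), include_zeros = FALSE)[1], 0.2)
})

test_that("baseline SCL averages the last window of the baseline", {
  expect_equal(baseline_scl(eda_trace(rep(32, 6000), 10)), 32)

  # 0 -> 10 uS ramp over 600 s: mean of the 5 -> 10 half is 7.5
  t <- seq(0, 600, by = 0.1)
  ramp <- eda_trace(10 * t / 600, 10)
  expect_equal(baseline_scl(ramp), 7.5, tolerance = 0.01)

  set.seed(3)
  noisy <- eda_trace(30 + rnorm(6001, 0, 0.5), 10)
  se <- 0.5 / sqrt(3000)
  expect_equal(baseline_scl(noisy), 30, tolerance = 4 * se)

  expect_error(baseline_scl(eda_trace(rep(30, 100), 10)), "shorter")
})

test_that("end-to-end habituation matches the generator's analytic value", {
  # noise-free deterministic emission: habituation = first k with
  # a0 * r^k < 0.03 followed by another sub-threshold trial
  cases <- list(c(0.5, 0.6), c(0.45, 0.7), c(0.2, 0.5))
  for (cs in cases) {
    a0 <- cs[1]; r <- cs[2]
    sch <- make_schedule(15, seed = 21)
    p <- scr_gen_params(initial_amplitude_uS = a0, decay_ratio = r,
                        noise_sd_uS = 0, drift_uS_per_s = 0,
                        response_prob = 1, seed = 1)
    sim <- simulate_condition(p, schedule = sch, rate_hz = 100)
    amps <- a0 * r^(0:14)
    expected <- oracle_habituation(amps >= 0.03)
    expect_equal(sim$habituation$trials_to_habituation, expected)
  }
})
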