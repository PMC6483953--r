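---
title: "Methods: electrodermal habituation scoring and detection thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrodermal habituation scoring and detection thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edahab)
```

## The problem this package addresses

Auditory sensory sensitivities are commonly studied through two autonomic
and psychophysical mechanisms: *habituation* — the decline and eventual
disappearance of event-related skin conductance responses (SCRs) when a
sound is repeated — and the *auditory detection threshold*, the lowest
intensity at which a tone is reliably heard. `edahab` implements a complete
analysis chain for a two-group design built around these measures: SCR
detection on skin-conductance traces, trial scoring against amplitude and
latency criteria, trials-to-habituation and non-responder classification,
block-magnitude slope analysis, a method-of-limits staircase for detection
thresholds, and the accompanying statistical stage. A synthetic-data module
generates every input with known ground truth, so each stage and the whole
chain can be validated without real recordings.

## SCR detection

The electrodermal signal is a slow tonic level (skin conductance level,
SCL, tens of microsiemens) with superimposed phasic SCRs: transient rises
of a few tenths of a microsiemen, beginning one to a few seconds after an
eliciting stimulus.

The detection algorithm mirrors standard peak-scoring practice:

1. **Low-pass filtering.** A 4th-order Butterworth low-pass at 10 Hz
   (`lowpass_butterworth()`). By default the filter runs forward-backward
   (zero phase), so detected event times are not delayed by the filter —
   group delay would otherwise bias latencies by tens of milliseconds.
   Zero-phase filtering applies the magnitude response twice; the gain at
   the cutoff is 0.5 rather than the single-pass $1/\sqrt{2}$. A
   single-pass mode is available by flag for comparability with
   acquisition software whose phase handling is unknown.
2. **First derivative.** Central differences on interior samples
   (`first_derivative()`), exact for affine signals.
3. **Peak/trough pairing** (`detect_scr_events()`). A *peak* is a sample
   where the derivative crosses from positive to negative. For each peak
   the algorithm searches backward over a 4 s window for *troughs*
   (negative-to-positive crossings). When no strict crossing exists —
   e.g. a rise out of a flat or monotone segment — near-flat samples
   ("bends", $|x'| < \varepsilon$ with $\varepsilon = 0.001$ µS/s by
   default) are accepted instead. Among candidates, the one with minimal
   conductance is chosen, ties broken toward the latest (the onset closest
   to the rise). Amplitude is peak minus trough; peaks with no candidate
   are dropped.

### Numerical choices

* *Edge handling.* Naive zero-phase filtering rings at the trace edges
  (the filter state starts at zero). The implementation removes the mean
  and pads both ends by odd reflection (about 3 cutoff periods) before
  filtering, then trims. Without this, edge transients of ~0.01 µS appear
  as spurious event cascades on otherwise clean traces.
* *Amplitude floor.* Even on noise-free synthetic traces, the filter's
  response to the kernel's onset-slope discontinuity leaves ripple pairs
  of well under 0.001 µS. `detect_scr_events()` drops excursions below
  `amp_floor_uS` (default $10^{-4}$ µS — two orders of magnitude below the
  scoring criterion), a guard against floating-point dust, not a
  physiological threshold.
* *The bend tolerance* $\varepsilon$ operationalizes a qualitative notion
  (inflections without a strict sign change). It interacts with tonic
  drift: a drift rate above $\varepsilon$ suppresses the bend rule, which
  is irrelevant in practice because measurement noise always provides
  strict sign changes; it only matters on idealized noise-free signals.

## Trial scoring and habituation

`score_trials()` attributes events to stimulus trials: an event qualifies
when its **trough (response-onset) time** falls in $[t_k + 1, t_k + 4]$ s
after stimulus onset $t_k$ (both ends inclusive) and its amplitude reaches
**0.03 µS**. Matching on the trough rather than the peak follows the
reading of the latency window as constraining response *onset*; peak-time
matching is available by flag. When several events qualify, the largest
amplitude is kept, giving magnitude analyses a single value per trial.

`trials_to_habituation()` implements the trials-to-criterion measure:
habituation is complete at the first two consecutive trials without a
qualifying SCR, and the score is the number of trials *before* that pair
(responding on trials 1–4 and silent from trial 5 scores 4; never
responding scores 0). A block with no such pair is **censored** at the
number of trials (15); how real studies code such participants is rarely
stated, so the flag keeps both options open.

`classify_responder()` flags non-responders — participants with no
qualifying SCR at the start of a block. The default rule requires *both*
of the first two trials to lack an SCR in some condition; the stricter
"at least one of the first two" rule is selectable. The default was chosen
because the literal phrasing common in the literature ("no SCR on one of
the first two trials") conflicts with usual electrodermal practice, which
tolerates a single missed trial.

`block_means()` averages SCR magnitude over consecutive blocks (default 3
blocks of 5), *including zeros* for absent trials — the magnitude
convention — with a flag for the amplitude convention (responded trials
only). `baseline_scl()` averages the final 5 min of a 10-min rest
baseline, unfiltered, since averaging is itself a low-pass operation.

## The detection-threshold staircase

`run_pass()` implements one descending/ascending method-of-limits pass: a
1000 Hz tone starts at 60 dB HL, descends in 5 dB steps until the first
"no", then ascends in 5 dB steps from one step above that level until the
first "yes"; that level is the pass threshold. `detection_threshold()`
repeats passes (each restarting at 60 dB) until two consecutive passes
agree, the repeat-until-agreement termination used in clinical threshold
estimation. Guards: a 0 dB floor (treated as the threshold, with a
warning) and a ceiling at start + 20 dB (runaway error), for pathological
observers.

For a deterministic step observer with true threshold $T$, the final
threshold is exactly $5\lceil T/5\rceil$ — the closed form the test suite
checks over a fine grid of $T$.

For stochastic observers the estimator is *upward biased*: a lapse during
the descent stops it early, and the ascending phase then confirms a level
above the true threshold, while the converse error is not symmetric.
Monte-Carlo over seeded replicates (slope 3 dB, threshold 14) puts the
mean estimate near 19 dB with about 88% of runs converging within 6
passes. This bias is a property of the procedure, not a bug; the tests
assert it rather than assume unbiasedness.

## Simulated observers

`make_observer()` defines a yes/no observer with logistic psychometric
function
$P(\text{yes}) = \gamma + (1 - \gamma - \lambda)\,F((L - T)/\sigma)$,
with guess rate $\gamma$, lapse rate $\lambda$, spread $\sigma$ (in dB)
and threshold $T$; $\sigma = 0$ degenerates to the step rule
yes $\iff L \ge T$. Responses are consumed from a seeded stream in
presentation order, so whole staircase runs are reproducible.

The cohort driver's defaults ($\sigma = 0.5$ dB,
$\gamma = \lambda = 0.005$) were calibrated so that the fraction of
simulated participants needing more than two passes lands in the 30–40%
range reported for this procedure in adult cohorts — a deliberately
reported calibration, not a claim about real observers' parameters.

## The synthetic-data generator

`generate_eda_trace()` builds
$\text{tonic} + \text{drift}\cdot t + \sum_k a_k\,K(t - o_k) + \text{noise}$:

* **Kernel** $K$: biexponential
  $e^{-t/\tau_d} - e^{-t/\tau_r}$, rescaled to unit peak
  (`scr_kernel()`), with $\tau_r = 0.75$ s and $\tau_d = 2$ s — typical
  electrodermal morphology values. The closed-form peak time is
  $\ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d - \tau_r) \approx 1.18$ s.
* **Amplitudes**: geometric habituation,
  $a_k = a_0\, r^{k-1}$ on trial $k$. This makes the "true"
  trials-to-habituation analytic: the first $k$ with $a_k < 0.03$ µS
  followed by a second sub-threshold trial. Emission is Bernoulli per
  trial (`response_prob`).
* **Latency**: 1.8 s after stimulus onset ± 0.3 s uniform jitter. The
  center of the 1–4 s scoring window; a convention, since typical SCR
  onset latency in any given cohort is unknown.
* **Schedules** (`make_schedule()`): 15 trials of 3 s stimuli with ISIs
  uniform in [20, 35] s, the standard event-related electrodermal layout.
* **Sampling**: 1000 samples/s by default, matching acquisition practice.
  The whole-cohort driver simulates at 200 Hz — amply above the 10 Hz
  filter's Nyquist requirement — to keep a 64-participant, two-condition
  simulation around 20 s; the choice is a simulation problem-size
  decision and does not alter any scoring rule.

`generate_cohort()` draws a two-group cohort whose defaults mirror a
published autism-spectrum vs. typically-developing design: n = 33/31,
self-reported auditory sensitivity (AASP auditory totals) 35.61 (8.1) vs.
24.94 (6.0), detection thresholds 15.45 (5.2) vs. 13.87 (4.6) dB, tonic
SCL 32.31 (4.2) vs. 31.16 (3.0) µS, non-responder fractions 7/33 and
4/31, habituation decay 0.69 (placing mean trials-to-habituation near
9.4), and first-trial amplitudes 0.50/0.45 µS (a small physiological
magnitude difference). The tone-arousal rating and the AASP score share a
latent Gaussian with Pearson correlation $2\sin(\pi\rho_s/6)$ — the
Gaussian-copula inverse of the target Spearman $\rho_s = 0.61$.

Two caveats on what the generator does and does not emulate:

* The copula targets the *within-group* rank correlation. In a cohort
  whose group means differ, the pooled Spearman exceeds the target
  because the group shift itself contributes rank association; the
  convergence tests therefore use homogeneous-spec cohorts.
* Traces are stationary apart from a linear drift; real recordings show
  movement artifacts, electrode drift, nonspecific SCRs and
  non-stationary noise. Passing tests demonstrate correctness of the
  scoring chain under the stated signal model, not robustness to
  artifacts, which is out of scope.

A master seed spawns per-participant sub-seeds, so any single
participant's data can be regenerated without re-running the cohort.

## Statistical stage

* **Normality screening** (`shape_zscores()`, `screen_variable()`):
  sample skewness $G_1$ and excess kurtosis $G_2$ standardized by their
  exact small-sample standard errors; $|z| > 1.96$ flags non-normality
  (the conventional 5% cutoff). Failing variables try log, then square
  root, keeping the first transform that passes.
* **Outliers** (`winsorize_outliers()`): fences at $Q_3 + 3\,\text{IQR}$
  and $Q_1 - 3\,\text{IQR}$ with type-7 quartiles (fence positions depend
  on the quartile rule, hence documented). Outliers are replaced by the
  nearest non-outlier value ± one measurement unit — a rank-preserving
  winsorization. A strict-literal mode anchoring both fences at $Q_1$
  exists because the textbook phrasing this rule descends from is
  ambiguous; the $Q_3$ anchor is standard practice.
* **Group comparisons** (`oneway_anova()`): two-group fixed-effects
  ANOVA; $F = t^2$ of the pooled-variance t-test, an identity the suite
  property-tests. Cohen's d uses the pooled SD with the sign convention
  *second group minus first*, so with the clinical group first a higher
  clinical mean yields negative d.
* **Block slopes** (`rm_anova_blocks()`): the classical mixed-design
  partition (between-subject group, within-subject block, interaction),
  with subjects nested in groups. Sums of squares are additive (checked
  to $10^{-8}$), and results are verified in tests against
  `aov(y ~ group*block + Error(subject))`. Block magnitudes are
  square-root transformed in the cohort report, as right-skewed
  magnitude data conventionally are.
* **Correlations** (`correlations()`): Pearson for interval variables
  (detection threshold, habituation vs. questionnaire totals), Spearman
  for the ordinal 1–9 ratings.
* **Multiplicity** (`bonferroni_alpha()`): $\alpha/m$ per comparison
  family, reported unrounded.
* `analyze_cohort()` assembles the full report — descriptives,
  detection/habituation/ratings comparisons, correlation panel,
  block-slope ANOVAs, and the screening log — and is byte-identical
  across runs at equal seeds. Bayes-factor analyses are intentionally
  not computed (they depend on an external program's defaults and are
  out of scope).

## Known limitations

* No tonic/phasic decomposition by deconvolution; overlapping SCRs
  closer than the kernel support are scored by the single largest
  excursion per trial window.
* The ordinal ratings are compared with ANOVA in the report table for
  layout parity; rank-based inference for them lives in the Spearman
  panel.
* The staircase bias analysis covers the implemented restart-from-60
  variant only; procedures that resume near the last estimate would have
  different bias.
* Censored habituation (never two consecutive absences) is coded 15; if
  a study excluded such participants instead, results differ for cohorts
  where censoring occurs.

## Worked example

```{r example, eval = FALSE}
sch <- make_schedule(15, seed = 1)
params <- scr_gen_params(initial_amplitude_uS = 0.5, decay_ratio = 0.75,
                         noise_sd_uS = 0.01, seed = 7)
sim <- simulate_condition(params, schedule = sch, rate_hz = 200)
sim$habituation
#> <habituation_result> 12 trials

cohort <- generate_cohort(cohort_spec(), seed = 11)
scored <- score_cohort(cohort)
analyze_cohort(scored)
```
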