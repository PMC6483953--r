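test_that("shape z-scores behave under symmetry, skew, and mirroring", {
  set.seed(11)
  sym <- rnorm(5000)
  z <- shape_zscores(sym)
  expect_lt(abs(z[["z_skew"]]), 3)

  expo <- rexp(500)
  expect_gt(shape_zscores(expo)[["z_skew"]], 3)

  # mirroring flips the skewness z exactly
  x <- rgamma(80, 2)
  expect_equal(shape_zscores(-x)[["z_skew"]], -shape_zscores(x)[["z_skew"]])

  expect_error(shape_zscores(c(1, 2, 3)), "n >= 4")
  expect_error(shape_zscores(rep(2, 10)), "variance")
})

test_that("variable screening transforms only when normality fails", {
  set.seed(12)
  ok <- screen_variable(rnorm(200, 50, 5))
  expect_true(ok$normal_flag)
  expect_equal(ok$applied_transform, "none")

  ln <- screen_variable(exp(rnorm(200)))
  expect_true(ln$normal_flag)
  expect_equal(ln$applied_transform, "log")
})

test_that("winsorization replaces 3xIQR outliers with neighbour +/- unit", {
  w <- winsorize_outliers(c(1, 2, 3, 4, 100), unit = 1)
  expect_equal(w$x, c(1, 2, 3, 4, 5))
  expect_equal(w$outliers, 5L)

  clean <- c(3, 5, 6, 8, 9, 11)
  w2 <- winsorize_outliers(clean, unit = 1)
  expect_equal(w2$x, clean)
  expect_length(w2$outliers, 0)

  # symmetric outliers replaced symmetrically; mirror equivariance
  x <- c(-110, -4, -3, -2, 2, 3, 4, 110)
  w3 <- winsorize_outliers(x, unit = 1)
  expect_equal(w3$x, c(-5, -4, -3, -2, 2, 3, 4, 5))
  set.seed(13)
  y0 <- c(rnorm(20), 50, -60)
  expect_equal(winsorize_outliers(-y0, unit = 0.2)$x,
               -winsorize_outliers(y0, unit = 0.2)$x)

  # rank order of non-outliers is never changed
  set.seed(14)
  for (i in 1:20) {
    y <- c(rnorm(30), rnorm(2, 0, 40))
    w4 <- winsorize_outliers(y, unit = 0.1)
    keep <- setdiff(seq_along(y), w4$outliers)
    expect_equal(rank(w4$x[keep]), rank(y[keep]))
  }

  # literal mode anchors the upper fence at Q1
  lit <- winsorize_outliers(c(1, 2, 3, 4, 9), unit = 1, literal = TRUE)
  expect_equal(lit$x, c(1, 2, 3, 4, 5))
  expect_equal(winsorize_outliers(c(1, 2, 3, 4, 9), unit = 1)$outliers,
               integer(0))
})

test_that("Cohen's d from summaries is exact and sign-conventional", {
  expect_equal(cohens_d_from_summary(35.61, 8.1, 33, 24.94, 6.0, 31),
               -1.49, tolerance = 0.005)
  expect_equal(cohens_d_from_summary(10, 2, 20, 10, 3, 25), 0)
  # swapping groups flips the sign
  expect_equal(cohens_d_from_summary(1, 1, 10, 2, 1, 10),
               -cohens_d_from_summary(2, 1, 10, 1, 1, 10))
  expect_error(cohens_d_from_summary(1, 0, 10, 1, 0, 10), "pooled")
})

test_that("one-way ANOVA equals the squared pooled t and detects effects", {
  x <- c(4, 5, 6, 7)
  expect_equal(oneway_anova(x, x)$F_statistic, 0)

  set.seed(15)
  for (i in 1:25) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    an <- oneway_anova(a, b)
    tt <- t.test(b, a, var.equal = TRUE)
    expect_equal(an$F_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(an$p_value, tt$p.value, tolerance = 1e-10)
  }

  # power at d ~ 1.5 with n = 33/31: group difference detected
  coh <- generate_cohort(cohort_spec(), seed = 20)
  s <- split(coh$aasp, coh$group)
  expect_lt(oneway_anova(s$ASD, s$TD)$p_value, 0.001)
})

test_that("mixed block ANOVA matches aov and its sums of squares add up", {
  set.seed(16)
  n <- 17
  grp <- factor(rep(c("A", "B"), c(9, 8)))
  blocks <- matrix(rnorm(n * 3), n, 3) +
    outer(rnorm(n, sd = 0.8), rep(0, 3)) +      # subject effects
    outer(rep(1, n), c(0.9, 0.4, 0))            # block effects

  res <- rm_anova_blocks(blocks, grp)

  # independent oracle: base aov with an Error(subject) stratum
  long <- data.frame(y = as.vector(blocks),
                     subj = factor(rep(seq_len(n), 3)),
                     block = factor(rep(1:3, each = n)),
                     group = rep(grp, 3))
  fit <- summary(stats::aov(y ~ group * block + Error(subj), data = long))
  btw <- fit[["Error: subj"]][[1]]
  wth <- fit[["Error: Within"]][[1]]
  expect_equal(res$F[res$effect == "group"], btw["group", "F value"],
               tolerance = 1e-8)
  expect_equal(res$p[res$effect == "group"], btw["group", "Pr(>F)"],
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "block"], wth["block", "F value"],
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "group:block"],
               wth["group:block", "F value"], tolerance = 1e-8)

  # additivity of the decomposition
  expect_equal(sum(attr(res, "ss_parts")), attr(res, "ss_total"),
               tolerance = 1e-8)

  # pure block effect: interaction ~ 0, block F large
  pure <- matrix(rnorm(n * 3, sd = 0.05), n, 3) +
    outer(rep(1, n), c(2, 1, 0))
  rp <- rm_anova_blocks(pure, grp)
  expect_gt(rp$F[rp$effect == "block"], 100)
  expect_lt(rp$p[rp$effect == "block"], 1e-10)

  # all-equal data: zero F everywhere
  r0 <- rm_anova_blocks(matrix(5, 10, 3), factor(rep(c("A", "B"), 5)))
  expect_equal(r0$F, c(0, 0, 0))
})

test_that("correlations and Bonferroni arithmetic", {
  x <- c(1, 3, 2, 8, 5, 4, 9)
  expect_equal(correlations(x, x, "pearson")$r, 1)

  y <- exp(x)  # monotone nonlinear transform
  expect_equal(correlations(x, y, "spearman")$r, 1)
  expect_lt(correlations(x, y, "pearson")$r, 1)

  expect_equal(round(bonferroni_alpha(0.05, 11), 4), 0.0045)
  expect_equal(round(bonferroni_alpha(0.05, 4), 3), 0.013)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 7) * 7, 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "m")
})

test_that("cohort analysis is deterministic and recovers built-in effects", {
  spec <- cohort_spec(n = c(10, 10))
  coh <- generate_cohort(spec, seed = 30)
  sc1 <- score_cohort(coh, rate_hz = 100)
  sc2 <- score_cohort(coh, rate_hz = 100)
  expect_identical(sc1, sc2)

  rep1 <- analyze_cohort(sc1)
  expect_s3_class(rep1, "edahab_report")
  expect_true(all(c("descriptives", "comparisons", "correlations",
                    "block_anova", "screening") %in% names(rep1)))
  # the built-in AASP group effect comes out with the negative sign
  expect_lt(rep1$descriptives$d, 0)
  # blocks decay: mean magnitudes decrease across blocks for responders
  bm <- colMeans(sc1[sc1$responder, c("tone_b1", "tone_b2", "tone_b3")])
  expect_true(all(diff(bm) < 0))
  # byte-identical report on a rerun of the whole chain
  rep2 <- analyze_cohort(score_cohort(generate_cohort(spec, seed = 30),
                                      rate_hz = 100))
  expect_identical(rep1, rep2)
})
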