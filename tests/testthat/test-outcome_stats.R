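test_that("log10 transform targets the Lac/NAA columns only", {
  out <- data.frame(subject_id = c("a", "b", "c"),
                    bgt_lac_naa = c(0.39, 1.0, 0.07),
                    wm_lac_naa = c(0.5, 1.0, 0.05),
                    tunel_log10 = c(1.2, 0.3, -0.1),
                    aeeg_score = c(3, 1, 0))
  tr <- log10_outcomes(out)
  expect_equal(tr$bgt_log_lacnaa, log10(c(0.39, 1.0, 0.07)))
  expect_equal(tr$bgt_log_lacnaa[2], 0)
  expect_equal(tr$tunel_log10, out$tunel_log10)  # passed through

  out_bad <- out; out_bad$bgt_lac_naa[1] <- 0
  expect_error(log10_outcomes(out_bad), "log10")
})

test_that("D'Agostino-Pearson omnibus matches an independent reference", {
  # frozen reference values computed with scipy.stats.normaltest 1.17.1:
  # seed-42 normal n=50 -> K2 = 0.6863999832, p = 0.7094963041
  # seed-43 exponential n=200 -> K2 = 65.9145730872, p = 4.8622e-15
  set.seed(42); x <- round(rnorm(50), 6)
  set.seed(43); y <- round(rexp(200), 6)
  r1 <- normality_test(x)
  expect_equal(r1$statistic, 0.6863999832, tolerance = 1e-8)
  expect_equal(r1$p, 0.7094963041, tolerance = 1e-8)
  expect_true(r1$is_normal)
  r2 <- normality_test(y)
  expect_equal(r2$statistic, 65.9145730872, tolerance = 1e-8)
  expect_lt(r2$p, 1e-10)
  expect_error(normality_test(rnorm(5)), "n >= 8")
})

test_that("normality test is calibrated (type I) and has power (MC)", {
  # 500 seeds, n = 1000 standard normal: rejection rate 5% +/- 2%
  rej <- vapply(1:500, function(s) {
    set.seed(s)
    normality_test(rnorm(1000))$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)

  # exponential: rejected at p < 0.01 in >= 99% of seeds
  pow <- vapply(1:200, function(s) {
    set.seed(s)
    normality_test(rexp(1000))$p < 0.01
  }, TRUE)
  expect_gte(mean(pow), 0.99)
})

test_that("linear regression closed forms", {
  x <- 1:10
  r <- linear_regression(x, 2 * x + 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_lt(r$p_two_tailed, 1e-10)

  # hand-derived: Sxy = 1, Sxx = Syy = 2 -> r2 = 1/4
  r2 <- linear_regression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r2$r_squared, 0.25, tolerance = 1e-12)

  r3 <- linear_regression(c(1, 2, 3, 4), rep(5, 4))
  expect_equal(r3$r_squared, 0)
  expect_equal(r3$slope, 0)

  expect_error(linear_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(linear_regression(1:2, 1:2), "n >= 3")
})

test_that("one-way ANOVA closed forms", {
  g1 <- one_way_anova(list(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(g1$effect_size_r2, 1)
  expect_lt(g1$p, 1e-9)

  g0 <- one_way_anova(list(c(1, 2), c(1, 2)))
  expect_equal(g0$effect_size_r2, 0)
  expect_equal(g0$p, 1)

  # SSB = 1, SST = 2 by hand -> eta2 = 0.5, F = 2, p = pf(2, 1, 2, lower=F)
  gh <- one_way_anova(list(c(0, 1), c(1, 2)))
  expect_equal(gh$effect_size_r2, 0.5, tolerance = 1e-12)
  expect_equal(gh$statistic, 2, tolerance = 1e-12)
  expect_equal(gh$p, pf(2, 1, 2, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(one_way_anova(list(1, c(1, 2))), "n >= 2")
})

test_that("two-group test: identities, pooled closed form, Welch flag", {
  same <- two_group_test(c(1, 2, 3), c(1, 2, 3), "never")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # pooled t on {1,2,3} vs {4,5,6}: t = -3 / sqrt(2/3) = -3.674234614...
  tp <- two_group_test(c(1, 2, 3), c(4, 5, 6), "never")
  expect_equal(tp$statistic, -3 * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(tp$p, 2 * pt(-3 * sqrt(3 / 2), 4), tolerance = 1e-9)
  expect_equal(tp$effect_size_r2,
               tp$statistic ^ 2 / (tp$statistic ^ 2 + 4), tolerance = 1e-12)
  expect_false(tp$welch_used)

  aw <- two_group_test(c(1, 2, 3), c(4, 5, 6), "always")
  expect_true(aw$welch_used)
  expect_error(two_group_test(1, c(1, 2)), "n >= 2")
})

test_that("Welch auto mode controls type I error under unequal variances (MC)", {
  # equal means, sigma ratio 4, n = 7 vs 7, 2000 reps
  B <- 2000
  rej_w <- rej_p <- logical(B)
  set.seed(77)
  for (i in seq_len(B)) {
    a <- rnorm(7, 0, 1)
    b <- rnorm(7, 0, 4)
    rej_w[i] <- two_group_test(a, b, "always")$p < 0.05
    rej_p[i] <- two_group_test(a, b, "never")$p < 0.05
  }
  expect_gt(mean(rej_w), 0.035)
  expect_lt(mean(rej_w), 0.065)
  # equal n: pooled and Welch share the same statistic but pooled uses more
  # df, so pooled rejections strictly contain Welch rejections
  expect_gte(mean(rej_p), mean(rej_w))
})

test_that("outcome classification at the 0.39 threshold", {
  expect_equal(classify_outcome(0.66), "poor")   # above the max printed cutoff
  expect_equal(classify_outcome(0.07), "good")
  expect_equal(classify_outcome(0.39), "poor")   # boundary assigned to poor
  expect_equal(classify_outcome(c(0.1, 0.5)), c("good", "poor"))
  expect_error(classify_outcome(-0.1), ">= 0")
})

test_that("full outcome analysis crosses indices with outcomes", {
  set.seed(78)
  subs <- sprintf("S%02d", 1:19)
  groups <- rep(c("control", "moderate", "severe"), c(5, 7, 7))
  pairs <- vapply(slowwave:::DEFAULT_PAIRS, paste, "", collapse = "-")
  idx <- do.call(rbind, lapply(seq_along(subs), function(i) {
    data.frame(subject_id = subs[i], group = groups[i], pair = pairs,
               semblance = runif(7, -0.2, 0.8), coherence = runif(7),
               valid_fraction = 0.9, low_confidence = FALSE)
  }))
  class(idx) <- c("sw_index_table", "data.frame")
  out <- data.frame(subject_id = subs, group = groups,
                    bgt_lac_naa = runif(19, 0.05, 0.7),
                    wm_lac_naa = runif(19, 0.05, 0.6),
                    tunel_log10 = runif(19, -0.3, 1.6),
                    aeeg_score = sample(0:4, 19, TRUE))
  rep <- run_outcome_analysis(idx, out, analysis_config())
  # 7 pairs x 2 index kinds x 3 outcomes
  expect_equal(nrow(rep$regressions), 42)
  expect_true(all(rep$regressions$p_two_tailed >= 0 &
                    rep$regressions$p_two_tailed <= 1))
  expect_true(all(rep$group_tests$effect_size_r2 >= 0 &
                    rep$group_tests$effect_size_r2 <= 1))
  # both grouping families present for each index
  expect_setequal(unique(rep$group_tests$grouping),
                  c("insult-group", "LacNAA-threshold"))

  # join failure
  out_bad <- out; out_bad$subject_id <- paste0("X", out_bad$subject_id)
  expect_error(run_outcome_analysis(idx, out_bad, analysis_config()),
               "fewer than 3")
})

test_that("regression r2 equals ANOVA eta2 for a two-level dummy", {
  set.seed(79)
  y <- c(rnorm(8, 0), rnorm(8, 1.5))
  dummy <- rep(c(0, 1), each = 8)
  r <- linear_regression(dummy, y)
  a <- one_way_anova(split(y, dummy))
  expect_equal(r$r_squared, a$effect_size_r2, tolerance = 1e-12)
})
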