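#' Log10-transform the Lac/NAA outcome columns
#'
#' BGT and WM Lac/NAA distributions are right-skewed, so log10 values are
#' taken before regression and group analyses. The TUNEL column is already
#' on a log10 cells/mm^2 scale and passes through unchanged, as does the
#' aEEG score.
#'
#' @param outcomes Outcome data.frame (see [read_outcomes()]).
#' @return The data.frame with `bgt_lac_naa`/`wm_lac_naa` replaced by their
#'   log10 values (columns renamed `bgt_log_lacnaa`, `wm_log_lacnaa`).
#' @export
log10_outcomes <- function(outcomes) {
  outcomes <- validate_outcomes(outcomes)
  if (any(outcomes$bgt_lac_naa <= 0, na.rm = TRUE) ||
      any(outcomes$wm_lac_naa <= 0, na.rm = TRUE))
    sw_data_error("Lac/NAA must be > 0 for the log10 transform")
  outcomes$bgt_log_lacnaa <- log10(outcomes$bgt_lac_naa)
  outcomes$wm_log_lacnaa <- log10(outcomes$wm_lac_naa)
  outcomes
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the skewness and kurtosis z-statistics into
#' `K^2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2
#' degrees of freedom. The skewness transformation follows D'Agostino
#' (1970) and the kurtosis transformation Anscombe & Glynn (1983). Requires
#' `n >= 8` (the transformations are not defined below that) and errors
#' explicitly rather than silently passing small samples.
#'
#' @param x Numeric sample.
#' @param alpha Significance level for the `is_normal` verdict.
#' @return List: `statistic` (K^2), `p`, `is_normal`, `z_skew`, `z_kurt`,
#'   `n`.
#' @export
normality_test <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L)
    sw_data_error(sprintf("normality test requires n >= 8 (got %d)", n))
  m <- mean(x)
  m2 <- mean((x - m) ^ 2)
  m3 <- mean((x - m) ^ 3)
  m4 <- mean((x - m) ^ 4)
  if (m2 <= 0) sw_data_error("zero-variance sample")
  b1 <- m3 / m2 ^ 1.5
  b2 <- m4 / m2 ^ 2

  # skewness z (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n ^ 2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  a <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / a + sqrt((y / a) ^ 2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1) ^ 2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n ^ 2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1 ^ 2))
  denom <- 1 + xk * sqrt(2 / (aa - 4))
  term <- sign(denom) * abs((1 - 2 / aa) / abs(denom)) ^ (1 / 3)
  z2 <- (1 - 2 / (9 * aa) - term) / sqrt(2 / (9 * aa))

  k2 <- z1 ^ 2 + z2 ^ 2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(statistic = k2, p = p, is_normal = p >= alpha,
       z_skew = z1, z_kurt = z2, n = n)
}

#' Ordinary least squares regression of an outcome on an index
#'
#' Simple linear regression with `r_squared` equal to the squared Pearson
#' correlation and a two-tailed t-test of slope = 0.
#'
#' @param x Index values (predictor).
#' @param y Outcome values (response).
#' @param index,outcome Labels carried into the result.
#' @return List of class `sw_regression`: `index`, `outcome`, `n`, `slope`,
#'   `intercept`, `r_squared`, `p_two_tailed`.
#' @export
linear_regression <- function(x, y, index = "index", outcome = "outcome") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) sw_data_error("regression requires n >= 3")
  sxx <- sum((x - mean(x)) ^ 2)
  if (sxx <= 0) sw_data_error("zero variance in predictor")
  syy <- sum((y - mean(y)) ^ 2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (syy > 0) sxy ^ 2 / (sxx * syy) else 0
  df <- n - 2L
  sse <- max(syy - slope * sxy, 0)
  se <- sqrt(sse / df / sxx)
  p <- if (se > 0) 2 * stats::pt(-abs(slope / se), df) else
    if (abs(slope) > 0) 0 else 1
  structure(list(index = index, outcome = outcome, n = n, slope = slope,
                 intercept = intercept, r_squared = r2, p_two_tailed = p),
            class = "sw_regression")
}

#' One-way analysis of variance
#'
#' F-test across two or more groups with eta-squared
#' (`SS_between / SS_total`) reported as the variance-explained effect
#' size, the natural analogue of a regression r-squared for a group factor.
#'
#' @param groups List of numeric samples, each of length >= 2.
#' @param index,grouping Labels carried into the result.
#' @return List of class `sw_group_test`: `statistic` (F), `p`,
#'   `effect_size_r2` (eta-squared), `df1`, `df2`, `welch_used = FALSE`.
#' @export
one_way_anova <- function(groups, index = "index", grouping = "insult-group") {
  if (length(groups) < 2L) sw_data_error("ANOVA needs >= 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) sw_data_error("each ANOVA group needs n >= 2")
  all_x <- unlist(groups)
  gm <- mean(all_x)
  ssb <- sum(ns * (vapply(groups, mean, 0) - gm) ^ 2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g)) ^ 2), 0))
  sst <- ssb + ssw
  df1 <- length(groups) - 1L
  df2 <- length(all_x) - length(groups)
  f <- if (ssw > 0) (ssb / df1) / (ssw / df2) else Inf
  p <- if (is.finite(f)) stats::pf(f, df1, df2, lower.tail = FALSE) else 0
  structure(list(index = index, grouping = grouping, statistic = f, p = p,
                 effect_size_r2 = if (sst > 0) ssb / sst else 0,
                 df1 = df1, df2 = df2, welch_used = FALSE),
            class = "sw_group_test")
}

# Median-centred Levene test for equality of variances (robust choice for
# small skewed samples); returns the p-value.
levene_p <- function(a, b) {
  za <- abs(a - median(a))
  zb <- abs(b - median(b))
  one_way_anova(list(za, zb))$p
}

#' Two-group comparison with automatic Welch correction
#'
#' Two-tailed t-test. In `"auto"` mode a median-centred Levene pre-test at
#' alpha = 0.05 decides between the pooled-variance t-test and Welch's
#' unequal-variance correction; `"always"`/`"never"` force the choice.
#' The effect size is `r^2 = t^2 / (t^2 + df)`, the variance-explained
#' analogue for a two-level factor.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @param force_welch `"auto"`, `"always"` or `"never"`.
#' @param index,grouping Labels carried into the result.
#' @return List of class `sw_group_test`: `statistic` (t), `p`,
#'   `effect_size_r2`, `df`, `welch_used`.
#' @export
two_group_test <- function(a, b, force_welch = c("auto", "always", "never"),
                           index = "index", grouping = "LacNAA-threshold") {
  force_welch <- match.arg(force_welch)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    sw_data_error("two-group test needs n >= 2 per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(structure(list(index = index, grouping = grouping,
                            statistic = 0, p = 1, effect_size_r2 = 0,
                            df = length(a) + length(b) - 2L,
                            welch_used = FALSE),
                       class = "sw_group_test"))
    sw_data_error("degenerate zero-variance groups with unequal means")
  }
  welch <- switch(force_welch,
                  always = TRUE,
                  never = FALSE,
                  auto = levene_p(a, b) < 0.05)
  tt <- stats::t.test(a, b, var.equal = !welch)
  t <- unname(tt$statistic)
  df <- unname(tt$parameter)
  structure(list(index = index, grouping = grouping, statistic = t,
                 p = tt$p.value, effect_size_r2 = t ^ 2 / (t ^ 2 + df),
                 df = df, welch_used = welch),
            class = "sw_group_test")
}

#' Classify outcome by the BGT Lac/NAA threshold
#'
#' Poor outcome if the basal ganglia-thalamic Lac/NAA ratio is at or above
#' the threshold (default 0.39), good otherwise. The boundary itself is
#' assigned to "poor".
#'
#' @param bgt_lac_naa Non-negative ratio(s).
#' @param threshold Cutoff.
#' @return Character vector `"good"`/`"poor"`.
#' @export
classify_outcome <- function(bgt_lac_naa, threshold = 0.39) {
  if (any(bgt_lac_naa < 0, na.rm = TRUE))
    sw_data_error("Lac/NAA must be >= 0")
  ifelse(bgt_lac_naa >= threshold, "poor", "good")
}

# Benjamini-Hochberg adjusted p-values (emitted for transparency only; the
# primary analysis is uncorrected, alpha = 0.05).
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Full cohort outcome analysis
#'
#' The statistical stage: joins the per-subject index table with the
#' outcome table on `subject_id`, log10-transforms the Lac/NAA outcomes,
#' logs a D'Agostino-Pearson normality check per analysed variable (when n
#' allows), regresses every (pair x semblance/coherence) index against
#' each of BGT log Lac/NAA, WM log Lac/NAA and TUNEL, runs a one-way ANOVA
#' of each index across insult groups, and compares good vs poor outcome
#' groups (BGT Lac/NAA threshold) with an auto-Welch two-group test. No
#' multiple-testing correction is applied to the primary p-values; a
#' Benjamini-Hochberg column is attached for transparency.
#'
#' @param index_table An `sw_index_table` from [compute_cohort_indices()].
#' @param outcomes Outcome data.frame.
#' @param cfg An [analysis_config()].
#' @return Object of class `sw_stats_report`: data.frames `indices`,
#'   `regressions`, `group_tests`, `normality`, plus `config`.
#' @export
run_outcome_analysis <- function(index_table, outcomes,
                                 cfg = analysis_config()) {
  outcomes <- log10_outcomes(outcomes)
  merged <- merge(as.data.frame(index_table), outcomes, by = "subject_id",
                  suffixes = c("", ".outcome"))
  if (length(unique(merged$subject_id)) < 3L)
    sw_data_error("index and outcome tables share fewer than 3 subjects")
  merged$outcome_class <- classify_outcome(merged$bgt_lac_naa,
                                           cfg$lacnaa_threshold)
  outcome_vars <- c(bgt_log_lacnaa = "bgt_log_lacnaa",
                    wm_log_lacnaa = "wm_log_lacnaa",
                    tunel_log10 = "tunel_log10")
  pairs <- unique(merged$pair)
  kinds <- c("semblance", "coherence")

  norm_rows <- list()
  log_norm <- function(label, x) {
    res <- tryCatch(normality_test(x, cfg$alpha), error = function(e) NULL)
    norm_rows[[length(norm_rows) + 1L]] <<- if (is.null(res)) {
      data.frame(variable = label, n = sum(is.finite(x)),
                 statistic = NA_real_, p = NA_real_, is_normal = NA)
    } else {
      data.frame(variable = label, n = res$n, statistic = res$statistic,
                 p = res$p, is_normal = res$is_normal)
    }
  }
  sub1 <- merged[merged$pair == pairs[1L], ]
  for (ov in names(outcome_vars)) log_norm(ov, sub1[[ov]])

  reg_rows <- list()
  gt_rows <- list()
  for (p in pairs) {
    sub <- merged[merged$pair == p, ]
    for (k in kinds) {
      label <- paste(p, k)
      log_norm(label, sub[[k]])
      for (ov in names(outcome_vars)) {
        r <- tryCatch(
          linear_regression(sub[[k]], sub[[ov]], index = label, outcome = ov),
          error = function(e) NULL)
        if (!is.null(r))
          reg_rows[[length(reg_rows) + 1L]] <- as.data.frame(unclass(r))
      }
      grp <- split(sub[[k]], factor(sub$group,
                                    c("control", "moderate", "severe")))
      grp <- grp[lengths(grp) >= 2L]
      if (length(grp) >= 2L) {
        g <- one_way_anova(grp, index = label, grouping = "insult-group")
        gt_rows[[length(gt_rows) + 1L]] <-
          data.frame(index = label, grouping = "insult-group",
                     statistic = g$statistic, p = g$p,
                     effect_size_r2 = g$effect_size_r2,
                     welch_used = FALSE)
      }
      good <- sub[[k]][sub$outcome_class == "good"]
      poor <- sub[[k]][sub$outcome_class == "poor"]
      if (length(good) >= 2L && length(poor) >= 2L) {
        g <- two_group_test(good, poor, "auto", index = label)
        gt_rows[[length(gt_rows) + 1L]] <-
          data.frame(index = label, grouping = "LacNAA-threshold",
                     statistic = g$statistic, p = g$p,
                     effect_size_r2 = g$effect_size_r2,
                     welch_used = g$welch_used)
      }
    }
  }
  regressions <- do.call(rbind, reg_rows)
  if (!is.null(regressions))
    regressions$p_bh <- bh_adjust(regressions$p_two_tailed)
  group_tests <- do.call(rbind, gt_rows)
  if (!is.null(group_tests))
    group_tests$p_bh <- bh_adjust(group_tests$p)

  structure(
    list(indices = as.data.frame(index_table),
         regressions = if (is.null(regressions)) data.frame() else regressions,
         group_tests = if (is.null(group_tests)) data.frame() else group_tests,
         normality = do.call(rbind, norm_rows),
         config = cfg),
    class = "sw_stats_report")
}

#' @export
print.sw_stats_report <- function(x, ...) {
  cat(sprintf("<sw_stats_report> %d subjects, %d regressions, %d group tests\n",
              length(unique(x$indices$subject_id)),
              nrow(x$regressions), nrow(x$group_tests)))
  sig <- x$regressions[x$regressions$p_two_tailed < x$config$alpha, ,
                       drop = FALSE]
  if (nrow(sig)) {
    cat("significant regressions (p <", x$config$alpha, "):\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  %s ~ %s: r2 = %.2f, p = %.3g\n", sig$outcome[i],
                  sig$index[i], sig$r_squared[i], sig$p_two_tailed[i]))
  }
  invisible(x)
}
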