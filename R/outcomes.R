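# Pre/post descriptive inference: paired t-test and Cohen's d.

#' Paired admission-to-discharge change
#'
#' Classical paired t-test on admission minus discharge ClinFIT scores
#' (positive difference = improvement, since higher score = worse
#' functioning), with Cohen's d for paired designs: the mean difference
#' over the SD of the differences (d_z). The 95% CI uses the normal
#' approximation d +/- 1.96 * SE with SE = sqrt(1/n + d^2/(2n));
#' `ci_method = "noncentral"` inverts the noncentral t distribution
#' instead. The effect band applies the conventional 0.2/0.5/0.8
#' small/medium/large thresholds to |d|.
#'
#' Patients without a discharge score are excluded and counted in the
#' result. A zero-variance difference makes t and d undefined and is an
#' explicit error.
#'
#' @param x a [cohort()].
#' @param ci_method `"normal"` (default) or `"noncentral"`.
#' @param conf_level confidence level for the d interval.
#' @return a `clinstage_paired_change`: `n_pairs`, `n_excluded`,
#'   `mean_admission`, `mean_discharge`, `mean_difference`,
#'   `sd_difference`, `t_statistic`, `df`, `p_value`, `cohens_d`,
#'   `d_ci_low`, `d_ci_high`, `effect_band`.
#' @export
paired_change <- function(x, ci_method = c("normal", "noncentral"),
                          conf_level = 0.95) {
  stopifnot(inherits(x, "clinstage_cohort"))
  ci_method <- match.arg(ci_method)
  complete <- !is.na(x$clinfit_discharge)
  adm <- x$clinfit_admission[complete]
  dis <- x$clinfit_discharge[complete]
  n <- length(adm)
  if (n < 2) stopf("need at least 2 complete admission/discharge pairs (have %d)", n)
  diffs <- adm - dis
  s <- sd(diffs)
  if (s == 0) {
    stopf("all paired differences are identical (SD = 0): t and d undefined",
          class = "clinstage_undefined_metric")
  }
  tt <- stats::t.test(adm, dis, paired = TRUE)
  d <- mean(diffs) / s
  ci <- cohens_d_ci(d, n, tt$statistic, conf_level, ci_method)
  structure(list(
    n_pairs = n, n_excluded = sum(!complete),
    mean_admission = mean(adm), mean_discharge = mean(dis),
    mean_difference = mean(diffs), sd_difference = s,
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    cohens_d = d, d_ci_low = ci[1], d_ci_high = ci[2],
    effect_band = effect_band(d), ci_method = ci_method
  ), class = "clinstage_paired_change")
}

cohens_d_ci <- function(d, n, t_obs, conf_level, method) {
  alpha <- 1 - conf_level
  if (method == "normal") {
    se <- sqrt(1 / n + d^2 / (2 * n))
    z <- stats::qnorm(1 - alpha / 2)
    return(c(d - z * se, d + z * se))
  }
  # noncentral-t inversion: find ncp bounds at which the observed t sits
  # at the alpha/2 tails, then rescale by sqrt(n)
  df <- n - 1
  bound <- function(p) {
    # pt() warns about tail precision at large noncentrality; the root is
    # insensitive to that at the digits reported
    f <- function(ncp) suppressWarnings(pt(t_obs, df, ncp)) - p
    lo <- t_obs - 10 * max(1, abs(t_obs))
    hi <- t_obs + 10 * max(1, abs(t_obs))
    uniroot(f, c(lo, hi), extendInt = "yes")$root
  }
  c(bound(1 - alpha / 2), bound(alpha / 2)) / sqrt(n)
}

effect_band <- function(d) {
  a <- abs(d)
  if (a >= 0.8) "large" else if (a >= 0.5) "medium" else "small"
}

#' @export
print.clinstage_paired_change <- function(x, ...) {
  p_txt <- if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", round_half_up(x$p_value, 3))
  cat(sprintf(
    paste0("Paired change, n = %d pairs (%d excluded, missing discharge)\n",
           "  admission %.1f -> discharge %.1f; mean improvement %.1f (SD %.1f)\n",
           "  t(%d) = %.2f, p %s; Cohen's d = %.2f (95%% CI %.2f-%.2f), %s effect\n"),
    x$n_pairs, x$n_excluded,
    round_half_up(x$mean_admission, 1), round_half_up(x$mean_discharge, 1),
    round_half_up(x$mean_difference, 1), round_half_up(x$sd_difference, 1),
    x$df, x$t_statistic, p_txt,
    round_half_up(x$cohens_d, 2), round_half_up(x$d_ci_low, 2),
    round_half_up(x$d_ci_high, 2), x$effect_band))
  invisible(x)
}
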