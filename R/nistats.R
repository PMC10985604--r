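# Noninferiority statistics: paired-difference descriptives, 95% CIs,
# margins, and the three-way noninferior / inconclusive / inferior decision.

#' Packaged noninferiority margins for the primary outcomes
#'
#' The four a-priori margins defined by the study's expert physiotherapist
#' panel, one per task.  The margin's sign encodes the harmful direction: a
#' negative margin means "smaller under VR is harmful" (step height, step
#' length, shoulder clearance), a positive margin means "larger under VR is
#' harmful" (step width on the beam).  Units are cm.  The trailing-foot step
#' height shares the overstepping margin.  Margins for any other parameter
#' must come from explicit panel input via [summarize_margin_panel()].
#'
#' @return Tibble (task, parameter, margin).
#' @export
default_margins <- function() {
  tibble::tribble(
    ~task, ~parameter, ~margin,
    "overstepping", "max_step_height_L", -2,
    "overstepping", "max_step_height_T", -2,
    "crossing", "step_length", -10,
    "balancing", "step_width", 3,
    "circumventing", "min_shoulder_obstacle_distance", -2
  )
}

#' Paired-difference descriptive statistics with a 95% CI
#'
#' Mean, sample SD (n - 1 denominator) and a normal-approximation confidence
#' interval `mean +/- z * SD / sqrt(n)` for a vector of per-participant
#' paired differences.  The z-based interval (1.96 at 95%) is the study's
#' convention; a t-based interval is available behind `method = "t"`.
#'
#' @param differences Numeric vector of per-participant VR-minus-physical
#'   differences (cm or s).
#' @param level Confidence level (default 0.95).
#' @param method `"z"` (default) or `"t"`.
#' @return A `difference_stats` list: `n`, `mean_diff`, `sd_diff`, `ci_low`,
#'   `ci_high`, `level`, `method`, and `normality_p` (Shapiro-Wilk, `NA`
#'   when n < 3 or the sample is constant).
#' @export
difference_stats <- function(differences, level = 0.95, method = c("z", "t")) {
  method <- match.arg(method)
  differences <- differences[!is.na(differences)]
  n <- length(differences)
  if (n < 2) stopf("at least 2 paired differences are required")
  m <- mean(differences)
  s <- stats::sd(differences)
  ci <- ci_from_summary(m, s, n, level = level, method = method)
  np <- if (n >= 3 && s > 0) tryCatch(stats::shapiro.test(differences)$p.value,
                                      error = function(e) NA_real_) else NA_real_
  structure(list(n = n, mean_diff = m, sd_diff = s,
                 ci_low = ci[1], ci_high = ci[2],
                 level = level, method = method, normality_p = np),
            class = "difference_stats")
}

#' Confidence interval from printed summary statistics
#'
#' Computes the paired-difference CI directly from a reported mean and SD at
#' sample size n, as needed to reproduce published intervals from a summary
#' table.
#'
#' @param mean_diff,sd_diff Mean and SD of the paired differences.
#' @param n Sample size.
#' @param level Confidence level.
#' @param method `"z"` (normal quantile; default) or `"t"`.
#' @return Numeric vector `c(low, high)`.
#' @export
ci_from_summary <- function(mean_diff, sd_diff, n, level = 0.95,
                            method = c("z", "t")) {
  method <- match.arg(method)
  if (n < 2) stopf("n must be >= 2")
  alpha <- 1 - level
  q <- if (method == "z") stats::qnorm(1 - alpha / 2) else stats::qt(1 - alpha / 2, n - 1)
  half <- q * sd_diff / sqrt(n)
  c(mean_diff - half, mean_diff + half)
}

#' Shapiro-Wilk normality screen
#'
#' @param differences Numeric vector (3 <= n <= 5000, non-constant).
#' @param alpha Significance level of the screen (default 0.05).
#' @return List with `p_value` and `normal` (TRUE when p > alpha).
#' @export
normality_check <- function(differences, alpha = 0.05) {
  differences <- differences[!is.na(differences)]
  n <- length(differences)
  if (n < 3 || n > 5000) stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  if (stats::sd(differences) == 0) stopf("constant sample: normality is undefined")
  p <- stats::shapiro.test(differences)$p.value
  list(p_value = p, normal = p > alpha)
}

#' Summarize an expert-panel margin elicitation
#'
#' The noninferiority margin is the median of the panel's responses (the
#' panel size precludes a normality assumption), reported with the IQR.
#'
#' @param responses Numeric vector of margin responses (cm), all with the
#'   sign of the harmful direction.
#' @param task,parameter Identifiers carried on the result.
#' @return A `noninferiority_margin` list: `task`, `parameter`, `margin`
#'   (median), `panel_median`, `panel_iqr`, `panel_n`.
#' @export
summarize_margin_panel <- function(responses, task = NA_character_,
                                   parameter = NA_character_) {
  responses <- responses[!is.na(responses)]
  if (!length(responses)) stopf("empty margin panel")
  med <- stats::median(responses)
  structure(list(task = task, parameter = parameter, margin = med,
                 panel_median = med, panel_iqr = stats::IQR(responses),
                 panel_n = length(responses)),
            class = "noninferiority_margin")
}

#' Three-way noninferiority classification
#'
#' Compares the 95% CI of the paired mean difference against the
#' noninferiority margin, whose sign encodes the harmful direction.  With the
#' axis oriented so the margin lies on the harmful side:
#' \itemize{
#'   \item \strong{noninferior} - the CI lies wholly on the acceptable side
#'     of the margin and does not touch it;
#'   \item \strong{inferior} - the CI reaches the region at or beyond the
#'     margin (touching counts) \emph{and} excludes 0 (no-difference line);
#'   \item \strong{inconclusive} - the CI reaches that region but still
#'     includes 0.
#' }
#' The three outcomes are exhaustive and mutually exclusive.
#'
#' @param stats A `difference_stats` (or any list with `ci_low`/`ci_high`).
#' @param margin A scalar margin in the same units (sign = harmful
#'   direction), or a `noninferiority_margin`.
#' @return A `noninferiority_result` list: the inputs plus `decision`.
#' @export
classify_noninferiority <- function(stats, margin) {
  m <- if (inherits(margin, "noninferiority_margin")) margin$margin else margin
  if (!is_number(m) || m == 0) stopf("margin must be a nonzero number")
  lo <- stats$ci_low; hi <- stats$ci_high
  if (!is_number(lo) || !is_number(hi) || lo > hi) stopf("invalid CI [%s, %s]", lo, hi)
  if (m < 0) {
    decision <- if (lo > m) "noninferior"
      else if (hi < 0 || lo > 0) "inferior"
      else "inconclusive"
  } else {
    decision <- if (hi < m) "noninferior"
      else if (lo > 0 || hi < 0) "inferior"
      else "inconclusive"
  }
  structure(list(stats = stats, margin = m, decision = decision),
            class = "noninferiority_result")
}

#' Wilcoxon signed-rank comparison of paired enjoyment scores
#'
#' Two-sided signed-rank test with continuity correction on paired visual
#' analogue scores (physical vs VR), reporting the direction of the median
#' difference.
#'
#' @param physical,vr Paired numeric score vectors.
#' @return List with `statistic` (V), `p_value`, `median_difference`
#'   (VR minus physical) and `direction`.
#' @export
wilcoxon_fun_scores <- function(physical, vr) {
  stopifnot(length(physical) == length(vr))
  d <- vr - physical
  d <- d[!is.na(d)]
  if (!length(d) || all(d == 0)) stopf("all paired differences are zero")
  if (sum(d != 0) < 6) warnf("fewer than 6 non-zero differences: test is weakly informative")
  wt <- stats::wilcox.test(vr, physical, paired = TRUE, exact = FALSE,
                           correct = TRUE)
  md <- stats::median(d)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_difference = md,
       direction = if (md > 0) "vr_higher" else if (md < 0) "physical_higher" else "none")
}

#' @export
print.difference_stats <- function(x, ...) {
  cat(sprintf("mean difference %.2f (SD %.2f), n = %d, %d%% %s-CI [%.2f, %.2f]\n",
              x$mean_diff, x$sd_diff, x$n, round(x$level * 100), x$method,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
print.noninferiority_result <- function(x, ...) {
  cat(sprintf("CI [%.2f, %.2f] vs margin %+.2f -> %s\n",
              x$stats$ci_low, x$stats$ci_high, x$margin, x$decision))
  invisible(x)
}
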