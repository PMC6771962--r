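#' Standard error of a mean from a reported confidence interval
#'
#' Recovers the standard error of a group mean from a published symmetric
#' confidence interval: SE = (upper - lower) / (2 t), where t is the
#' two-sided critical value of Student's t with n - 1 degrees of freedom at
#' the stated level. The symmetric-CI assumption is recorded on the result.
#'
#' @param mean reported group mean (must lie inside the CI).
#' @param ci_low,ci_high reported confidence limits, `ci_low <= ci_high`.
#'   A degenerate interval (`ci_low == ci_high`) yields SE 0.
#' @param n group size, >= 2.
#' @param level confidence level of the reported interval (default 0.95).
#' @return The standard error (scalar, attribute `"assumption"` =
#'   `"symmetric-CI"`).
#' @examples
#' se_from_ci(10, 8, 12, n = 10)   # 2 / qt(0.975, 9)
#' @export
se_from_ci <- function(mean, ci_low, ci_high, n, level = 0.95) {
  stopifnot(is.numeric(mean), is.numeric(ci_low), is.numeric(ci_high),
            length(mean) == 1L, length(ci_low) == 1L, length(ci_high) == 1L)
  if (ci_low > ci_high) stop("inverted CI: ci_low > ci_high", call. = FALSE)
  if (mean < ci_low || mean > ci_high) {
    stop("`mean` lies outside the reported interval", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single count >= 2", call. = FALSE)
  }
  assert_scalar_in(level, 0, 1, "level")
  se <- (ci_high - ci_low) / (2 * stats::qt(1 - (1 - level) / 2, df = n - 1))
  attr(se, "assumption") <- "symmetric-CI"
  se
}

#' Dose-group summary
#'
#' Summary statistics for one dose group as published: size, mean and either
#' a confidence interval of the mean or a standard deviation, plus the group's
#' median exposure concentration. The standard error is recovered at
#' construction (from the SD when given, else from the CI via
#' [se_from_ci()]), so downstream tests need only summaries.
#'
#' @param label group label.
#' @param n group size, >= 2.
#' @param mean group mean on the outcome scale (e.g. million sperm/mL).
#' @param ci_low,ci_high optional 95% (or `level`) confidence limits.
#' @param sd optional standard deviation (takes precedence over the CI).
#' @param dose optional [serum_conc()]: the group's median exposure.
#' @param level confidence level of the supplied CI.
#' @return An object of class `group_summary` with a recovered `se` field.
#' @examples
#' group_summary("Q4", n = 34, mean = 53.6, sd = 40,
#'               dose = serum_conc(733, "TCDD"))
#' @export
group_summary <- function(label, n, mean, ci_low = NULL, ci_high = NULL,
                          sd = NULL, dose = NULL, level = 0.95) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single count >= 2", call. = FALSE)
  }
  stopifnot(is.numeric(mean), length(mean) == 1L)
  if (!is.null(dose) && !inherits(dose, "serum_conc")) {
    stop("`dose` must be NULL or a serum_conc", call. = FALSE)
  }
  if (!is.null(sd)) {
    stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
    se <- sd / sqrt(n)
  } else if (!is.null(ci_low) && !is.null(ci_high)) {
    se <- as.numeric(se_from_ci(mean, ci_low, ci_high, n, level))
    sd <- se * sqrt(n)
  } else {
    stop("supply either `sd` or both `ci_low` and `ci_high`", call. = FALSE)
  }
  structure(list(label = label, n = n, mean = mean, sd = sd, se = se,
                 ci_low = ci_low, ci_high = ci_high, dose = dose,
                 level = level),
            class = "group_summary")
}

#' Two-sample t test from group summaries
#'
#' Tests the difference of two group means using only published summaries.
#' The default is Welch's unequal-variance test with Welch-Satterthwaite
#' degrees of freedom; a pooled-variance Student test is available when the
#' equal-variance assumption is preferred. Identical summaries give t = 0,
#' p = 1. Computed from summaries, the test is numerically identical to the
#' corresponding raw-data test.
#'
#' @param g1,g2 [group_summary()] objects (reference group first by
#'   convention; swapping the arguments flips the sign of t only).
#' @param alpha significance threshold used to set the `significant` flag.
#' @param method `"welch"` (default) or `"pooled"`.
#' @return An object of class `group_comparison`: `group` (g2's label),
#'   `statistic`, `df`, `p_value`, `significant`, `alpha`, `dose` (g2's dose).
#' @examples
#' ctl <- group_summary("control", 184, 72.5, sd = 40)
#' q4  <- group_summary("Q4", 34, 53.6, sd = 40, dose = serum_conc(733, "TCDD"))
#' welch_test_from_summaries(ctl, q4)
#' @export
welch_test_from_summaries <- function(g1, g2, alpha = 0.05,
                                      method = c("welch", "pooled")) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  method <- match.arg(method)
  assert_scalar_in(alpha, 0, 1, "alpha")
  if (is.na(g1$se) || is.na(g2$se)) {
    stop("missing dispersion; supply a CI or SD for both groups",
         call. = FALSE)
  }
  v1 <- g1$sd^2; v2 <- g2$sd^2
  n1 <- g1$n;   n2 <- g2$n
  delta <- g1$mean - g2$mean
  if (method == "welch") {
    sed2 <- v1 / n1 + v2 / n2
    if (sed2 == 0) {
      stat <- 0; df <- n1 + n2 - 2
    } else {
      stat <- delta / sqrt(sed2)
      df <- sed2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    sed2 <- sp2 * (1 / n1 + 1 / n2)
    stat <- if (sed2 == 0) 0 else delta / sqrt(sed2)
  }
  p <- if (stat == 0) 1 else 2 * stats::pt(-abs(stat), df = df)
  structure(list(group = g2$label, statistic = stat, df = df, p_value = p,
                 significant = p < alpha, alpha = alpha, method = method,
                 dose = g2$dose),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: t = %.4g, df = %.3g, p = %.4g%s\n",
              x$group, x$statistic, x$df, x$p_value,
              if (x$significant) sprintf(" (significant at %g)", x$alpha) else ""))
  invisible(x)
}

#' Classify NOAEL and LOAEL from an ordered set of dose-group comparisons
#'
#' Given comparisons versus control for dose groups in strictly ascending
#' dose order, the LOAEL is the lowest dose with a significant effect and the
#' NOAEL is the highest non-significant dose strictly below the LOAEL. When
#' no group is significant the NOAEL is the top dose and there is no LOAEL;
#' when every group is significant there is no NOAEL. A significant group
#' above a non-significant one (after the LOAEL) is reported as a
#' non-monotone pattern, never silently repaired.
#'
#' @param comparisons either a list of [welch_test_from_summaries()] results
#'   (each carrying a dose) or a data frame with numeric column `dose` (ppt)
#'   and logical column `significant`, sorted by ascending dose.
#' @return A list with `noael` (ppt or `NA`), `loael` (ppt or `NA`) and
#'   logical `non_monotone`.
#' @examples
#' classify_noael_loael(data.frame(dose = c(68, 345, 733),
#'                                 significant = c(FALSE, FALSE, TRUE)))
#' @export
classify_noael_loael <- function(comparisons) {
  if (is.data.frame(comparisons)) {
    stopifnot(all(c("dose", "significant") %in% names(comparisons)))
    dose <- as.numeric(comparisons$dose)
    sig <- as.logical(comparisons$significant)
  } else if (is.list(comparisons)) {
    dose <- vapply(comparisons, function(cp) {
      stopifnot(inherits(cp, "group_comparison"))
      if (is.null(cp$dose)) {
        stop("every comparison must carry a dose", call. = FALSE)
      }
      cp$dose$value
    }, numeric(1))
    sig <- vapply(comparisons, `[[`, logical(1), "significant")
  } else {
    stop("`comparisons` must be a data frame or a list of group_comparison",
         call. = FALSE)
  }
  if (length(dose) < 1L) stop("no dose groups supplied", call. = FALSE)
  if (is.unsorted(dose, strictly = TRUE)) {
    stop("dose groups must be in strictly ascending dose order", call. = FALSE)
  }
  first_sig <- which(sig)[1]
  if (is.na(first_sig)) {
    loael <- NA_real_
    noael <- dose[length(dose)]
    non_monotone <- FALSE
  } else {
    loael <- dose[first_sig]
    below <- dose[!sig & dose < loael]
    noael <- if (length(below)) max(below) else NA_real_
    # non-monotone: a non-significant group at or above the LOAEL dose
    non_monotone <- any(!sig[dose > loael])
  }
  list(noael = noael, loael = loael, non_monotone = non_monotone)
}
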