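#' Parameters for the synthetic mother-infant TSH cohort
#'
#' Defines a small exposure-outcome cohort generator with the statistical
#' structure the calibration analysis assumes: right-skewed (lognormal)
#' maternal lipid-adjusted serum concentrations with a small high tail, and
#' neonatal TSH following a log-log linear model with lognormal noise.
#'
#' Defaults describe a cohort of 51 mother-infant pairs whose exposure
#' distribution has log-scale SD 1 and a location set so the expected number
#' of mothers above 50 ppt is 5, and whose dose-response line crosses
#' 5 uU/mL at 235 ppt and 10 uU/mL at 1513.56 ppt. The residual spread
#' (`noise_log_sd = 0.6`) reflects the natural variability of screening TSH
#' in healthy neonates (a reported range of roughly 1.7-9.1 uU/mL spans
#' about four log-scale SDs) inflated for sampling-time variability. See the
#' methods vignette for the full calibration rationale.
#'
#' @param n cohort size (>= 3; default 51).
#' @param exposure_log_sd log-scale SD of the exposure lognormal (default 1).
#' @param high_tail_count expected number of subjects above `high_tail_ppt`
#'   (default 5); determines the exposure location unless
#'   `exposure_log_mean` is supplied directly.
#' @param high_tail_ppt tail cutoff, ppt (default 50).
#' @param exposure_log_mean optional explicit log-scale mean; overrides the
#'   tail calibration.
#' @param intercept,slope log-log dose-response coefficients; defaults are
#'   solved from the two threshold anchors `(ppt = 235, tsh = 5)` and
#'   `(ppt = 1513.56, tsh = 10)`.
#' @param noise_log_sd residual SD on the log-TSH scale (>= 0, default 0.6).
#' @param seed integer seed (mandatory).
#' @return An object of class `tsh_cohort_params`; field
#'   `expected_high_tail` records the implied expected tail count.
#' @export
tsh_cohort_params <- function(n = 51, exposure_log_sd = 1,
                              high_tail_count = 5, high_tail_ppt = 50,
                              exposure_log_mean = NULL,
                              intercept = NULL, slope = NULL,
                              noise_log_sd = 0.6, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n >= 3, exposure_log_sd > 0, noise_log_sd >= 0,
            high_tail_count > 0, high_tail_count < n, high_tail_ppt > 0)
  if (is.null(exposure_log_mean)) {
    # place the lognormal so that n * P(X > cutoff) = high_tail_count
    exposure_log_mean <- log(high_tail_ppt) -
      stats::qnorm(1 - high_tail_count / n) * exposure_log_sd
  }
  if (is.null(slope) || is.null(intercept)) {
    # line through the two threshold anchors (235 ppt, 5) and (1513.56 ppt, 10)
    slope <- log(10 / 5) / log(1513.56 / 235)
    intercept <- log(5) - slope * log(235)
  }
  expected_tail <- n * stats::pnorm((log(high_tail_ppt) - exposure_log_mean) /
                                      exposure_log_sd, lower.tail = FALSE)
  structure(list(n = as.integer(n), exposure_log_mean = exposure_log_mean,
                 exposure_log_sd = exposure_log_sd,
                 high_tail_ppt = high_tail_ppt,
                 expected_high_tail = expected_tail,
                 intercept = intercept, slope = slope,
                 noise_log_sd = noise_log_sd, seed = as.integer(seed)),
            class = "tsh_cohort_params")
}

#' Generate a synthetic exposure-TSH cohort
#'
#' Draws exposures from the configured lognormal and outcomes from the
#' log-log model with lognormal noise:
#' `tsh = exp(intercept + slope * log(exposure) + N(0, noise_log_sd))`.
#' The generating parameters travel with the data as a truth sidecar
#' (attribute `"truth"`), so parameter-recovery tests consume only the
#' generated data plus the sidecar.
#'
#' @param params a [tsh_cohort_params()].
#' @param metric exposure metric tag (default `"TCDD"`).
#' @return A data frame of class `cohort_pairs` with columns
#'   `maternal_serum` (ppt) and `tsh` (uU/mL); attributes `truth` (the
#'   params) and `metric`.
#' @examples
#' coh <- generate_tsh_cohort(tsh_cohort_params(seed = 42))
#' fit_loglog(coh)
#' @export
generate_tsh_cohort <- function(params, metric = "TCDD") {
  stopifnot(inherits(params, "tsh_cohort_params"))
  metric <- match.arg(metric, c("TCDD", "TEQ"))
  set.seed(params$seed)
  x <- stats::rlnorm(params$n, params$exposure_log_mean,
                     params$exposure_log_sd)
  log_mu <- params$intercept + params$slope * log(x)
  y <- exp(log_mu + stats::rnorm(params$n, 0, params$noise_log_sd))
  out <- data.frame(maternal_serum = x, tsh = y)
  attr(out, "truth") <- params
  attr(out, "metric") <- metric
  class(out) <- c("cohort_pairs", "data.frame")
  out
}

#' Re-express a TCDD cohort on the TEQ metric
#'
#' Scales the exposure column by an aggregate TEQ/TCDD ratio, leaving the
#' outcomes unchanged -- the aggregate-level approximation that total toxic
#' equivalency is proportional to TCDD across the cohort. The default ratio
#' 41.8/18.9 is the cohort-mean TEQ over cohort-mean TCDD of the emulated
#' study population.
#'
#' @param pairs a `cohort_pairs` data frame on the TCDD metric.
#' @param ratio TEQ/TCDD scaling factor (> 1).
#' @return A `cohort_pairs` data frame tagged `"TEQ"`.
#' @export
as_teq_cohort <- function(pairs, ratio = 41.8 / 18.9) {
  stopifnot(inherits(pairs, "cohort_pairs"),
            identical(attr(pairs, "metric"), "TCDD"), ratio >= 1)
  out <- pairs
  out$maternal_serum <- out$maternal_serum * ratio
  attr(out, "metric") <- "TEQ"
  attr(out, "teq_ratio") <- ratio
  out
}

#' Parameters for synthetic dose-quartile summary tables
#'
#' Configures a control group and four exposure quartiles (sizes, means,
#' SDs, median doses) from which raw outcome draws and published-style
#' summaries are generated. Defaults emulate a sperm-concentration study:
#' control mean 72.5 million/mL, an effect confined to the top quartile
#' (mean 53.6), quartile median doses 68/172/345/733 ppt (the second-
#' quartile dose is an interpolated filler; only the first, third and fourth
#' medians are anchored to published values), and a common SD of
#' 40 million/mL on the reported scale.
#'
#' @param control list with `label`, `n`, `mean`, `sd`.
#' @param quartiles data frame with columns `label`, `n`, `mean`, `sd`,
#'   `dose_ppt` (strictly increasing).
#' @param seed integer seed (mandatory).
#' @return An object of class `quartile_summary_params`.
#' @export
quartile_summary_params <- function(
    control = list(label = "control", n = 184, mean = 72.5, sd = 40),
    quartiles = data.frame(
      label = c("Q1", "Q2", "Q3", "Q4"),
      n = 34, mean = c(72.5, 72.5, 72.5, 53.6), sd = 40,
      dose_ppt = c(68, 172, 345, 733)),
    seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(is.list(control),
            all(c("label", "n", "mean", "sd") %in% names(control)),
            is.data.frame(quartiles),
            all(c("label", "n", "mean", "sd", "dose_ppt") %in%
                  names(quartiles)))
  if (is.unsorted(quartiles$dose_ppt, strictly = TRUE)) {
    stop("quartile doses must be strictly increasing", call. = FALSE)
  }
  structure(list(control = control, quartiles = quartiles,
                 seed = as.integer(seed)),
            class = "quartile_summary_params")
}

#' Generate raw draws and published-style summaries for dose quartiles
#'
#' Draws each group's outcomes from a normal distribution and computes the
#' summaries a publication would report (mean and 95% t confidence
#' interval), so summary-based tests can be validated against tests on the
#' underlying raw data. The raw draws are returned alongside as the truth
#' sidecar.
#'
#' @param params a [quartile_summary_params()].
#' @return A list of class `quartile_summaries`: `control` (a
#'   [group_summary()]), `quartiles` (list of `group_summary`), `raw` (named
#'   list of numeric vectors) and `params`.
#' @examples
#' qs <- generate_quartile_summaries(quartile_summary_params(seed = 7))
#' classify_noael_loael(compare_quartiles(qs))
#' @export
generate_quartile_summaries <- function(params) {
  stopifnot(inherits(params, "quartile_summary_params"))
  set.seed(params$seed)
  draw_group <- function(n, mean, sd) stats::rnorm(n, mean, sd)
  summarize <- function(label, draws, dose = NULL) {
    n <- length(draws); mn <- mean(draws)
    half <- stats::qt(0.975, n - 1) * stats::sd(draws) / sqrt(n)
    group_summary(label, n = n, mean = mn,
                  ci_low = mn - half, ci_high = mn + half, dose = dose)
  }
  ctl_draws <- draw_group(params$control$n, params$control$mean,
                          params$control$sd)
  raw <- list(control = ctl_draws)
  quartiles <- vector("list", nrow(params$quartiles))
  for (i in seq_len(nrow(params$quartiles))) {
    q <- params$quartiles[i, ]
    d <- draw_group(q$n, q$mean, q$sd)
    raw[[q$label]] <- d
    quartiles[[i]] <- summarize(q$label, d, serum_conc(q$dose_ppt, "TCDD"))
  }
  names(quartiles) <- params$quartiles$label
  structure(list(control = summarize(params$control$label, ctl_draws),
                 quartiles = quartiles, raw = raw, params = params),
            class = "quartile_summaries")
}

#' Compare every quartile against control
#'
#' Runs [welch_test_from_summaries()] for each quartile versus the control
#' group, in ascending dose order, ready for [classify_noael_loael()].
#'
#' @param qs a [generate_quartile_summaries()] result.
#' @param alpha significance threshold (default 0.05).
#' @param method test family, `"welch"` or `"pooled"`.
#' @param p_adjust multiple-testing correction applied to the per-quartile
#'   p values before flagging significance: `"none"` (default, per-group
#'   conclusions as published), `"bonferroni"` or `"holm"`.
#' @return A list of `group_comparison` objects in ascending dose order.
#' @export
compare_quartiles <- function(qs, alpha = 0.05, method = c("welch", "pooled"),
                              p_adjust = c("none", "bonferroni", "holm")) {
  stopifnot(inherits(qs, "quartile_summaries"))
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  cmps <- lapply(qs$quartiles, function(g) {
    welch_test_from_summaries(qs$control, g, alpha = alpha, method = method)
  })
  ord <- order(vapply(cmps, function(cp) cp$dose$value, numeric(1)))
  cmps <- cmps[ord]
  if (p_adjust != "none") {
    p <- stats::p.adjust(vapply(cmps, `[[`, numeric(1), "p_value"),
                         method = p_adjust)
    for (i in seq_along(cmps)) {
      cmps[[i]]$p_value <- p[i]
      cmps[[i]]$significant <- p[i] < alpha
    }
  }
  unname(cmps)
}
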