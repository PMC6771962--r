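#' Log-log calibration fit of outcome against exposure
#'
#' Ordinary least squares of log outcome (e.g. neonatal blood TSH, uU/mL) on
#' log exposure (maternal lipid-adjusted serum concentration, ppt). Natural
#' logarithms are used internally throughout; all reported quantities are on
#' the original (ppt, uU/mL) scale, so the internal base is unobservable.
#' The fit stores the sufficient statistics needed for inverse prediction:
#' slope, intercept, residual standard error, n, and the mean and centred
#' sum of squares of the log predictor.
#'
#' @param pairs either a data frame with columns `maternal_serum` and `tsh`
#'   (a cohort from [generate_tsh_cohort()] works directly), or a numeric
#'   vector of exposures when `tsh` is supplied separately.
#' @param tsh numeric vector of outcomes when `pairs` is a bare exposure
#'   vector.
#' @param metric exposure metric tag carried through to predictions
#'   (`"TCDD"` or `"TEQ"`). When `pairs` carries a `metric` attribute it is
#'   used as the default.
#' @return An object of class `loglog_fit` with fields `slope`, `intercept`,
#'   `residual_se`, `n`, `xbar_log`, `ybar_log`, `sxx_log`, `metric`.
#' @examples
#' coh <- generate_tsh_cohort(tsh_cohort_params(seed = 1))
#' fit <- fit_loglog(coh)
#' fit
#' @export
fit_loglog <- function(pairs, tsh = NULL, metric = NULL) {
  if (is.data.frame(pairs)) {
    stopifnot(all(c("maternal_serum", "tsh") %in% names(pairs)))
    x <- pairs$maternal_serum
    y <- pairs$tsh
    if (is.null(metric)) metric <- attr(pairs, "metric")
  } else {
    x <- as.numeric(pairs)
    y <- as.numeric(tsh)
  }
  if (is.null(metric)) metric <- "TCDD"
  metric <- match.arg(metric, c("TCDD", "TEQ"))
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  bad <- which(!(is.finite(x) & is.finite(y) & x > 0 & y > 0))
  if (length(bad)) {
    stop("non-positive or non-finite value(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; all values must be log-transformable", call. = FALSE)
  }
  lx <- log(x); ly <- log(y)
  sxx <- sum((lx - mean(lx))^2)
  if (sxx <= 0) stop("zero variance in the log predictor", call. = FALSE)
  fit <- stats::lm(ly ~ lx)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 residual_se = stats::sigma(fit), n = n,
                 xbar_log = mean(lx), ybar_log = mean(ly), sxx_log = sxx,
                 metric = metric),
            class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<loglog_fit> log(outcome) = %.4f + %.4f log(%s serum), n = %d, ",
    "residual SE = %.4f\n"), x$intercept, x$slope, x$metric, x$n,
    x$residual_se))
  invisible(x)
}

#' Forward prediction from a log-log fit
#'
#' Predicted outcome (original scale) at given exposure(s): the fitted mean
#' on the log scale, exponentiated.
#'
#' @param fit a [fit_loglog()] result.
#' @param serum exposure value(s), ppt.
#' @return Predicted outcome value(s).
#' @export
predict_outcome <- function(fit, serum) {
  stopifnot(inherits(fit, "loglog_fit"), all(serum > 0))
  exp(fit$intercept + fit$slope * log(serum))
}

#' Inverse prediction of the exposure at an outcome threshold
#'
#' Estimates the exposure concentration at which the fitted log-log
#' calibration line attains a specified outcome threshold, with a confidence
#' interval computed on the log scale and exponentiated.
#'
#' The point estimate is the exact algebraic inversion
#' `exp((log(threshold) - intercept)/slope)`. Two interval methods are
#' offered:
#' \describe{
#'   \item{`approx_se`}{the calibration standard error of Massart et al.:
#'     `SE = (s/|b|) sqrt(1/m + 1/n + (log t - ybar)^2 / (b^2 Sxx))`, with a
#'     symmetric t interval on the log scale. `m` is the number of replicate
#'     response measurements; the default `m = Inf` drops the `1/m` term
#'     because a fixed regulatory threshold is not a measured response with
#'     sampling error. `m = 1` reproduces the single-observation convention
#'     of standard chemometric calibration software.}
#'   \item{`fieller`}{Fieller's interval for the ratio of normal means, exact
#'     under the regression model. When `g = t^2 s^2 / (b^2 Sxx) >= 1` the
#'     slope is not significantly distinct from zero at the working level and
#'     the interval is unbounded; this is signalled via the `unbounded` flags
#'     and a warning, never silently clipped.}
#' }
#' Upper limits beyond `cap` (default 1e7 ppt) are flagged
#' `unbounded_above` so reports can present them as "> cap".
#'
#' @param fit a [fit_loglog()] result.
#' @param threshold outcome threshold (> 0), e.g. 5 or 10 uU/mL.
#' @param level confidence level (default 0.95).
#' @param method `"approx_se"` or `"fieller"`.
#' @param m replicate count for the `1/m` term (default `Inf`).
#' @param cap upper-limit presentation cap in ppt (default 1e7).
#' @return An object of class `inverse_prediction`: `point`, `ci_low`,
#'   `ci_high`, `unbounded_above`, `unbounded_below`, `level`, `threshold`,
#'   `method`, `m`, `cap`, `se_log` (for `approx_se`).
#' @examples
#' coh <- generate_tsh_cohort(tsh_cohort_params(seed = 1))
#' fit <- fit_loglog(coh)
#' inverse_predict(fit, threshold = 5)
#' @export
inverse_predict <- function(fit, threshold, level = 0.95,
                            method = c("approx_se", "fieller"),
                            m = Inf, cap = 1e7) {
  stopifnot(inherits(fit, "loglog_fit"))
  method <- match.arg(method)
  assert_positive_scalar(threshold, "threshold")
  assert_scalar_in(level, 0, 1, "level")
  if (fit$slope == 0) stop("slope is zero; no point estimate", call. = FALSE)
  b <- fit$slope; a <- fit$intercept; s <- fit$residual_se
  n <- fit$n; sxx <- fit$sxx_log
  y0 <- log(threshold)
  x0 <- (y0 - a) / b
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  inv_m <- if (is.infinite(m)) 0 else 1 / m
  se_log <- NA_real_
  unbounded_below <- FALSE

  if (method == "approx_se") {
    se_log <- (s / abs(b)) *
      sqrt(inv_m + 1 / n + (y0 - fit$ybar_log)^2 / (b^2 * sxx))
    lo <- x0 - tq * se_log
    hi <- x0 + tq * se_log
  } else {
    g <- (tq * s)^2 / (b^2 * sxx)
    if (g >= 1) {
      warning(paste("slope not distinguishable from zero at this level;",
                    "Fieller interval is unbounded"), call. = FALSE)
      lo <- -Inf; hi <- Inf
      unbounded_below <- TRUE
    } else {
      d <- x0 - fit$xbar_log
      centre <- fit$xbar_log + d / (1 - g)
      half <- (tq * s / abs(b)) *
        sqrt(d^2 / sxx + (1 - g) * (inv_m + 1 / n)) / (1 - g)
      lo <- centre - half
      hi <- centre + half
    }
  }

  ci_low <- exp(lo)
  ci_high <- exp(hi)
  structure(list(point = exp(x0), ci_low = ci_low, ci_high = ci_high,
                 unbounded_above = !is.finite(ci_high) || ci_high > cap,
                 unbounded_below = unbounded_below,
                 level = level, threshold = threshold, method = method,
                 m = m, cap = cap, se_log = se_log),
            class = "inverse_prediction")
}

#' @export
print.inverse_prediction <- function(x, ...) {
  hi <- if (x$unbounded_above) sprintf("> %g", x$cap) else sprintf("%g", x$ci_high)
  lo <- if (x$unbounded_below) "unbounded" else sprintf("%g", x$ci_low)
  cat(sprintf(paste0(
    "<inverse_prediction> %g ppt at threshold %g (%.0f%% CI [%s, %s], ",
    "method %s)\n"), x$point, x$threshold, 100 * x$level, lo, hi, x$method))
  invisible(x)
}

#' Serum-typed point of departure from an outcome threshold
#'
#' Wraps the inverse-prediction point (and interval) at an outcome threshold
#' as a serum-typed [point_of_departure()]. The default classification
#' follows the screening-versus-clinical reading of neonatal TSH levels: the
#' 5 uU/mL population-screening level is treated as a LOAEL (the regulatory
#' reading) and the 10 uU/mL clinical recall threshold as a NOAEL; any other
#' threshold, or either default, can be overridden via `classification`.
#'
#' @param fit a [fit_loglog()] result.
#' @param threshold outcome threshold (typically 5 or 10 uU/mL).
#' @param classification optional `"NOAEL"`/`"LOAEL"` override.
#' @param ... passed on to [inverse_predict()].
#' @return A `point_of_departure` whose dose is a [serum_conc()] on the fit's
#'   metric, with the full `inverse_prediction` attached as attribute
#'   `"prediction"`.
#' @export
pod_from_threshold <- function(fit, threshold, classification = NULL, ...) {
  stopifnot(inherits(fit, "loglog_fit"))
  if (is.null(classification)) {
    classification <- if (isTRUE(all.equal(threshold, 5))) "LOAEL"
                      else if (isTRUE(all.equal(threshold, 10))) "NOAEL"
                      else stop("no default classification for threshold ",
                                threshold, "; supply `classification`",
                                call. = FALSE)
  }
  pred <- inverse_predict(fit, threshold, ...)
  pod <- point_of_departure(
    serum_conc(pred$point, fit$metric), classification,
    provenance = sprintf("inverse prediction at outcome threshold %g (%s)",
                         threshold, fit$metric))
  attr(pod, "prediction") <- pred
  pod
}
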