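#' Lognormal distribution specification
#'
#' A lognormal distribution parameterized on the natural-log scale. The
#' median is `exp(log_mean)`.
#'
#' @param log_mean mean of the log (real).
#' @param log_sd standard deviation of the log (> 0).
#' @param provenance free text recording how the parameters were obtained
#'   (e.g. which convention in [uf_prior()]).
#' @return An object of class `lognormal_spec`.
#' @export
lognormal_spec <- function(log_mean, log_sd, provenance = "") {
  stopifnot(is.numeric(log_mean), length(log_mean) == 1L, is.finite(log_mean))
  assert_positive_scalar(log_sd, "log_sd")
  structure(list(log_mean = log_mean, log_sd = log_sd,
                 provenance = provenance),
            class = "lognormal_spec")
}

#' @export
print.lognormal_spec <- function(x, ...) {
  cat(sprintf("<lognormal_spec> log-mean %.4f, log-sd %.4f (median %.4g)%s\n",
              x$log_mean, x$log_sd, exp(x$log_mean),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Lognormal prior for an uncertainty factor
#'
#' Turns a nominal uncertainty factor into a lognormal prior. Under the
#' default `p95_nominal` convention (the half-log convention of the
#' probabilistic uncertainty-factor literature) the nominal value sits at the
#' 95th percentile and the median is `sqrt(nominal)`, so
#' `log_sd = log(nominal/sqrt(nominal)) / z_0.95 = 0.5 log(nominal) / 1.6449`.
#' `median_nominal` places the median at the nominal with a caller-supplied
#' `log_sd`; `explicit` takes both parameters directly. A nominal of 1 is
#' degenerate and gets the configured minimum spread with median 1.
#'
#' @param nominal nominal UF value, >= 1.
#' @param convention `"p95_nominal"` (default), `"median_nominal"`, or
#'   `"explicit"`.
#' @param log_sd log-scale SD, required for `median_nominal` and `explicit`.
#' @param log_mean log-scale mean, required for `explicit`.
#' @param min_log_sd floor applied to the spread (default 1e-6), reached in
#'   the degenerate nominal-1 case.
#' @return A [lognormal_spec()] whose provenance records the convention.
#' @examples
#' uf_prior(10)  # median sqrt(10), P95 = 10
#' @export
uf_prior <- function(nominal,
                     convention = c("p95_nominal", "median_nominal", "explicit"),
                     log_sd = NULL, log_mean = NULL, min_log_sd = 1e-6) {
  convention <- match.arg(convention)
  if (!is.numeric(nominal) || length(nominal) != 1L || nominal < 1) {
    stop("`nominal` must be a single number >= 1", call. = FALSE)
  }
  if (convention == "p95_nominal") {
    lm_ <- 0.5 * log(nominal)
    ls_ <- max(min_log_sd, (log(nominal) - lm_) / stats::qnorm(0.95))
  } else if (convention == "median_nominal") {
    if (is.null(log_sd)) {
      stop("`median_nominal` requires `log_sd`", call. = FALSE)
    }
    lm_ <- log(nominal)
    ls_ <- max(min_log_sd, log_sd)
  } else {
    if (is.null(log_sd) || is.null(log_mean)) {
      stop("`explicit` requires both `log_mean` and `log_sd`", call. = FALSE)
    }
    lm_ <- log_mean
    ls_ <- max(min_log_sd, log_sd)
  }
  lognormal_spec(lm_, ls_,
                 provenance = sprintf("uf_prior(nominal=%g, %s)",
                                      nominal, convention))
}

#' Point-of-departure distribution
#'
#' A POD treated as a random variable: either a point mass or a lognormal,
#' on the serum (ppt) or intake (pg/kg/day) scale, tagged with exposure
#' metric, outcome threshold and NOAEL/LOAEL classification. For the
#' lognormal form the median equals the deterministic POD point estimate.
#'
#' @param form `"point"` or `"lognormal"`.
#' @param value point value (for `form = "point"`), or the median when a
#'   `spec` is not supplied.
#' @param spec a [lognormal_spec()] (for `form = "lognormal"`).
#' @param kind `"serum"` (ppt) or `"intake"` (pg/kg/day).
#' @param metric `"TCDD"` or `"TEQ"`.
#' @param threshold outcome threshold the POD was read at (e.g. 5 or 10).
#' @param classification `"NOAEL"` or `"LOAEL"`.
#' @return An object of class `pod_distribution`.
#' @export
pod_distribution <- function(form = c("point", "lognormal"), value = NULL,
                             spec = NULL, kind = c("serum", "intake"),
                             metric = c("TCDD", "TEQ"), threshold = NA_real_,
                             classification = c("NOAEL", "LOAEL")) {
  form <- match.arg(form)
  kind <- match.arg(kind)
  metric <- match.arg(metric)
  classification <- match.arg(classification)
  if (form == "point") {
    assert_positive_scalar(value, "value")
    spec <- NULL
  } else {
    stopifnot(inherits(spec, "lognormal_spec"))
    value <- exp(spec$log_mean)  # median = deterministic point estimate
  }
  structure(list(form = form, value = value, spec = spec, kind = kind,
                 metric = metric, threshold = threshold,
                 classification = classification),
            class = "pod_distribution")
}

#' POD distribution from an inverse prediction
#'
#' Builds a lognormal serum-scale POD distribution from an
#' [inverse_predict()] result: median at the point estimate and log-scale SD
#' set to the CI half-width on the log scale divided by the normal quantile
#' of the interval's level. When the upper limit is unbounded (or beyond the
#' cap) only the lower half-width is used.
#'
#' @param pred an `inverse_prediction`.
#' @param metric exposure metric of the fit that produced `pred`.
#' @param classification `"NOAEL"` or `"LOAEL"`.
#' @return A [pod_distribution()] of lognormal form on the serum scale.
#' @export
pod_dist_from_prediction <- function(pred, metric, classification) {
  stopifnot(inherits(pred, "inverse_prediction"))
  z <- stats::qnorm(1 - (1 - pred$level) / 2)
  lp <- log(pred$point)
  half <- if (pred$unbounded_above || !is.finite(pred$ci_high)) {
    lp - log(pred$ci_low)
  } else {
    (log(pred$ci_high) - log(pred$ci_low)) / 2
  }
  log_sd <- max(1e-12, half / z)
  pod_distribution(
    form = "lognormal",
    spec = lognormal_spec(lp, log_sd,
                          provenance = "inverse-prediction CI half-width"),
    kind = "serum", metric = metric, threshold = pred$threshold,
    classification = classification)
}

#' Induced-prior RfD distribution
#'
#' Combines a POD distribution with uncertainty-factor priors into the
#' implied ("induced prior") distribution of the RfD: Monte Carlo draws of
#' POD / product(UF), expressed in pg/kg/day. When the POD and every UF are
#' point or lognormal the closed lognormal form is also returned
#' (`log_mean = log_mean_POD - sum(log_mean_UF)`,
#' `log_sd = sqrt(log_sd_POD^2 + sum(log_sd_UF^2))`), which is what makes
#' extreme tail probabilities resolvable analytically. Applying UFs
#' sequentially ("first 10, then 3") is implemented as independent draws
#' whose logs add, which is identical to a single draw from the product
#' distribution.
#'
#' @param pod a [pod_distribution()]. Serum-scale PODs require `anchor`.
#' @param ufs list of [uf_spec()]; a UF with a `distribution` is drawn from
#'   it, otherwise it enters as its nominal point value.
#' @param n_samples number of Monte Carlo draws, >= 1e4.
#' @param seed integer seed; mandatory, recorded on the result.
#' @param anchor a [serum_intake_anchor()] used to scale serum-scale PODs to
#'   intake (proportional scaling; the anchor's metric must match the POD's).
#' @return An object of class `rfd_distribution`: `samples` (pg/kg/day),
#'   `closed_form` (a [lognormal_spec()] or `NULL` when degenerate),
#'   `point` (degenerate value or `NA`), `scenario` metadata, `seed`.
#' @examples
#' pod <- pod_distribution("point", 20, kind = "intake",
#'                         metric = "TCDD", classification = "LOAEL")
#' d <- induced_rfd(pod, list(uf_spec("UF_L", 10), uf_spec("UF_H", 3)),
#'                  n_samples = 1e4, seed = 1)
#' lower_bound(d)
#' @export
induced_rfd <- function(pod, ufs, n_samples = 1e5, seed, anchor = NULL) {
  stopifnot(inherits(pod, "pod_distribution"))
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory (reproducibility contract)", call. = FALSE)
  }
  if (!is.numeric(n_samples) || n_samples < 1e4) {
    stop("`n_samples` must be at least 1e4", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  stopifnot(is.list(ufs))
  lapply(ufs, function(u) stopifnot(inherits(u, "uf_spec")))

  # POD on the intake scale, pg/kg/day, as (log_mean, log_sd)
  if (pod$kind == "serum") {
    if (is.null(anchor)) {
      stop("serum-scale POD requires an `anchor` for intake scaling",
           call. = FALSE)
    }
    if (!identical(anchor$serum$metric, pod$metric)) {
      stop("anchor metric (", anchor$serum$metric,
           ") does not match POD metric (", pod$metric, ")", call. = FALSE)
    }
    scale_pg <- intake_pg(anchor$intake) / anchor$serum$value
  } else {
    scale_pg <- 1
  }
  pod_log_mean <- log(pod$value * scale_pg)
  pod_log_sd <- if (pod$form == "lognormal") pod$spec$log_sd else 0

  uf_log_mean <- vapply(ufs, function(u) {
    if (is.null(u$distribution)) log(u$nominal) else u$distribution$log_mean
  }, numeric(1))
  uf_log_sd <- vapply(ufs, function(u) {
    if (is.null(u$distribution)) 0 else u$distribution$log_sd
  }, numeric(1))

  cf_log_mean <- pod_log_mean - sum(uf_log_mean)
  cf_log_sd <- sqrt(pod_log_sd^2 + sum(uf_log_sd^2))

  set.seed(as.integer(seed))
  log_draws <- rep(pod_log_mean, n_samples)
  if (pod_log_sd > 0) log_draws <- log_draws + stats::rnorm(n_samples, 0, pod_log_sd)
  for (i in seq_along(ufs)) {
    log_draws <- log_draws -
      if (uf_log_sd[i] > 0) stats::rnorm(n_samples, uf_log_mean[i], uf_log_sd[i])
      else uf_log_mean[i]
  }
  samples <- exp(log_draws)

  degenerate <- cf_log_sd == 0
  structure(list(
    samples = samples,
    closed_form = if (!degenerate)
      lognormal_spec(cf_log_mean, cf_log_sd,
                     provenance = "lognormal product algebra") else NULL,
    point = if (degenerate) exp(cf_log_mean) else NA_real_,
    scenario = list(metric = pod$metric, threshold = pod$threshold,
                    classification = pod$classification,
                    uf_names = vapply(ufs, `[[`, character(1), "name"),
                    composite_uf_nominal = prod(vapply(ufs, `[[`, numeric(1),
                                                       "nominal"))),
    seed = as.integer(seed)),
    class = "rfd_distribution")
}

#' @export
print.rfd_distribution <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(paste0(
    "<rfd_distribution> %s, threshold %s, %s; %d draws (seed %d)\n",
    "  median %.4g pg/kg/day, 2.5th percentile %.4g\n"),
    sc$metric, format(sc$threshold), sc$classification, length(x$samples),
    x$seed, lower_bound(x, 0.5), lower_bound(x, 0.025)))
  invisible(x)
}

#' Lower-bound quantile of an RfD distribution
#'
#' The p-quantile of the induced RfD distribution, conventionally at
#' p = 0.025: the lower bound of the central 95% interval, used as a
#' conservative candidate RfD. The closed lognormal form is used when
#' available, otherwise the empirical sample quantile.
#'
#' @param dist an [induced_rfd()] result.
#' @param p quantile probability in (0, 1); default 0.025.
#' @return Scalar pg/kg/day.
#' @export
lower_bound <- function(dist, p = 0.025) {
  stopifnot(inherits(dist, "rfd_distribution"))
  assert_scalar_in(p, 0, 1, "p")
  if (!is.null(dist$closed_form)) {
    stats::qlnorm(p, dist$closed_form$log_mean, dist$closed_form$log_sd)
  } else if (!is.na(dist$point)) {
    dist$point
  } else {
    unname(stats::quantile(dist$samples, p))
  }
}

#' Percentile placement of a reference value in an RfD distribution
#'
#' Where a reference RfD sits in the induced distribution, as a percentile in
#' \[0, 100\]. With a closed lognormal form the CDF is evaluated
#' analytically, which resolves tail probabilities far below Monte Carlo
#' resolution (e.g. 1e-30). Without a closed form the empirical CDF is used;
#' a value below the Monte Carlo floor of `100 / n_samples` is reported *as*
#' that floor with attribute `censored = TRUE` (meaning "less than this") and
#' a warning, because sampling cannot certify smaller tail mass.
#'
#' @param dist an [induced_rfd()] result.
#' @param value reference RfD, pg/kg/day, > 0.
#' @return Percentile (scalar); possibly carrying attribute `censored`.
#' @export
percentile_of <- function(dist, value) {
  stopifnot(inherits(dist, "rfd_distribution"))
  assert_positive_scalar(value, "value")
  if (!is.null(dist$closed_form)) {
    return(100 * stats::plnorm(value, dist$closed_form$log_mean,
                               dist$closed_form$log_sd))
  }
  if (!is.na(dist$point)) {
    return(if (value < dist$point) 0 else 100)
  }
  n <- length(dist$samples)
  emp <- 100 * mean(dist$samples <= value)
  if (emp < 100 / n) {
    warning(sprintf(paste0(
      "value lies below Monte Carlo resolution; percentile reported as the ",
      "floor %g (interpret as '< %g')"), 100 / n, 100 / n), call. = FALSE)
    emp <- structure(100 / n, censored = TRUE)
  }
  emp
}

#' Eight-scenario induced-prior RfD grid
#'
#' Crosses exposure metric (TCDD, TEQ), outcome threshold (default 5 and
#' 10 uU/mL) and POD classification (NOAEL, LOAEL) into the full 2 x 2 x 2
#' grid of induced RfD distributions. For each scenario the POD is the
#' inverse prediction of the matching calibration fit at the threshold,
#' given a lognormal spread from its confidence interval
#' ([pod_dist_from_prediction()]), scaled to intake through the anchor, and
#' divided by the classification's uncertainty factors under lognormal
#' priors ([uf_prior()]). The anchored serum-to-intake scaling acts on the
#' lipid-adjusted concentration irrespective of metric, so the single anchor
#' is applied to both metrics.
#'
#' Per-scenario seeds are derived deterministically from `seed`, so the same
#' seed reproduces the summary table bit for bit.
#'
#' @param fit_tcdd,fit_teq [fit_loglog()] fits on the TCDD and TEQ metrics.
#' @param anchor a [serum_intake_anchor()].
#' @param thresholds outcome thresholds (default `c(5, 10)`).
#' @param uf_table named list mapping classification to a list of
#'   [uf_spec()]; the default applies `UF_H = 3` to a NOAEL and
#'   `UF_L = 10, UF_H = 3` to a LOAEL, each with a `p95_nominal` prior.
#' @param n_samples Monte Carlo draws per scenario (default 1e5).
#' @param seed master integer seed (mandatory).
#' @param reference_rfd reference RfD whose percentile placement is reported
#'   (default 0.7 pg/kg/day).
#' @param level,method,m passed to [inverse_predict()] for the POD CIs.
#' @param uf_convention convention passed to [uf_prior()].
#' @return A list of class `scenario_grid`: `distributions` (named list of 8
#'   [induced_rfd()] results) and `summary` (data frame with one row per
#'   scenario: lower bound, median, upper bound, deterministic branch RfD and
#'   reference percentile).
#' @export
scenario_grid <- function(fit_tcdd, fit_teq, anchor, thresholds = c(5, 10),
                          uf_table = NULL, n_samples = 1e5, seed,
                          reference_rfd = 0.7, level = 0.95,
                          method = "approx_se", m = Inf,
                          uf_convention = "p95_nominal") {
  stopifnot(inherits(fit_tcdd, "loglog_fit"), inherits(fit_teq, "loglog_fit"),
            inherits(anchor, "serum_intake_anchor"))
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(uf_table)) {
    uf_table <- list(
      NOAEL = list(uf_spec("UF_H", 3, uf_prior(3, uf_convention))),
      LOAEL = list(uf_spec("UF_L", 10, uf_prior(10, uf_convention)),
                   uf_spec("UF_H", 3, uf_prior(3, uf_convention))))
  }
  stopifnot(all(c("NOAEL", "LOAEL") %in% names(uf_table)))
  fits <- list(TCDD = fit_tcdd, TEQ = fit_teq)
  scale_pg <- intake_pg(anchor$intake) / anchor$serum$value

  combos <- expand.grid(classification = c("NOAEL", "LOAEL"),
                        threshold = thresholds,
                        metric = c("TCDD", "TEQ"),
                        stringsAsFactors = FALSE)
  ids <- sprintf("%s_t%g_%s", combos$metric, combos$threshold,
                 combos$classification)
  if (anyDuplicated(ids)) stop("duplicate scenario keys", call. = FALSE)

  dists <- vector("list", nrow(combos))
  names(dists) <- ids
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    metric <- combos$metric[i]
    thr <- combos$threshold[i]
    cls <- combos$classification[i]
    fit <- fits[[metric]]
    if (!identical(fit$metric, metric)) {
      stop("fit supplied for ", metric, " is tagged ", fit$metric,
           call. = FALSE)
    }
    pred <- inverse_predict(fit, thr, level = level, method = method, m = m)
    pod <- pod_dist_from_prediction(pred, metric, cls)
    # re-tag the anchor to the POD's metric: the kinetic scaling is
    # metric-agnostic (it acts on the lipid-adjusted concentration)
    anc <- serum_intake_anchor(serum_conc(anchor$serum$value, metric),
                               anchor$intake)
    d <- induced_rfd(pod, uf_table[[cls]], n_samples = n_samples,
                     seed = as.integer(seed) + i, anchor = anc)
    dists[[i]] <- d
    det_rfd <- pred$point * scale_pg /
      prod(vapply(uf_table[[cls]], `[[`, numeric(1), "nominal"))
    rows[[i]] <- data.frame(
      scenario = ids[i], metric = metric, threshold = thr,
      classification = cls,
      pod_median_ppt = pred$point,
      composite_uf = d$scenario$composite_uf_nominal,
      deterministic_rfd = det_rfd,
      p2.5 = lower_bound(d, 0.025),
      p50 = lower_bound(d, 0.5),
      p97.5 = lower_bound(d, 0.975),
      percentile_of_reference = as.numeric(percentile_of(d, reference_rfd)),
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(distributions = dists, summary = summary,
                 reference_rfd = reference_rfd, seed = as.integer(seed),
                 uf_convention = uf_convention),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("<scenario_grid> %d scenarios, reference RfD %g pg/kg/day, seed %d\n",
              nrow(x$summary), x$reference_rfd, x$seed))
  print(x$summary, digits = 4)
  invisible(x)
}
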