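#' Uncertainty-factor specification
#'
#' A named uncertainty factor (UF): a multiplicative divisor applied to a
#' point of departure. `UF_L` conventionally covers LOAEL-to-NOAEL
#' extrapolation, `UF_H` human interindividual variability. A UF may carry a
#' lognormal distribution (see [uf_prior()]) for probabilistic derivations;
#' deterministic arithmetic uses only the nominal value.
#'
#' @param name label, e.g. `"UF_L"`.
#' @param nominal point value, must be >= 1 (a UF never increases the RfD).
#' @param distribution optional [lognormal_spec()].
#' @return An object of class `uf_spec`.
#' @examples
#' uf_spec("UF_L", 10)
#' uf_spec("UF_H", 3)
#' @export
uf_spec <- function(name, nominal, distribution = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(nominal) || length(nominal) != 1L || !is.finite(nominal) ||
      nominal < 1) {
    stop("`nominal` must be a single number >= 1", call. = FALSE)
  }
  if (!is.null(distribution) && !inherits(distribution, "lognormal_spec")) {
    stop("`distribution` must be NULL or a lognormal_spec", call. = FALSE)
  }
  structure(list(name = name, nominal = nominal, distribution = distribution),
            class = "uf_spec")
}

#' Compose uncertainty factors into a single divisor
#'
#' Multiplies the nominal values of a set of uncertainty factors. The empty
#' set composes to 1 (the multiplicative identity), and the result is
#' order-independent.
#'
#' @param factors a list of [uf_spec()] objects, or a bare numeric vector of
#'   nominal values.
#' @return The composite UF (positive scalar).
#' @examples
#' compose_uf(list(uf_spec("UF_L", 10), uf_spec("UF_H", 3)))  # 30
#' compose_uf(c(10, 3))                                       # 30
#' compose_uf(list())                                         # 1
#' @export
compose_uf <- function(factors) {
  vals <- uf_nominals(factors)
  if (length(vals) == 0L) return(1)
  if (any(!is.finite(vals)) || any(vals < 1)) {
    stop("all uncertainty-factor nominals must be finite and >= 1",
         call. = FALSE)
  }
  prod(vals)
}

# internal: extract nominal values from a list of uf_spec or a numeric vector
uf_nominals <- function(factors) {
  if (is.numeric(factors)) return(as.numeric(factors))
  if (!is.list(factors)) {
    stop("`factors` must be a numeric vector or a list of uf_spec",
         call. = FALSE)
  }
  vapply(factors, function(f) {
    if (inherits(f, "uf_spec")) f$nominal
    else if (is.numeric(f) && length(f) == 1L) as.numeric(f)
    else stop("each factor must be a uf_spec or a single number", call. = FALSE)
  }, numeric(1))
}

#' Derive a reference dose from an intake-typed point of departure
#'
#' RfD = POD / composite UF, computed in pg/kg/day. The exact quotient is
#' retained; a presentation value rounded to `sigfigs` significant figures is
#' emitted alongside (one significant figure is the agency presentation
#' convention: 0.020 ng/kg/day over a composite UF of 30 is exactly
#' 0.6667 pg/kg/day, presented as 0.7).
#'
#' @param pod a [point_of_departure()] whose dose is an [intake_rate()]. A
#'   serum-typed POD must first go through [serum_to_intake()].
#' @param composite_uf composite uncertainty factor, >= 1 (see [compose_uf()]).
#' @param sigfigs significant figures for the presentation value (default 1).
#' @return An object of class `rfd_estimate` with `value` (exact, pg/kg/day),
#'   `rounded_value`, `sigfigs` and `provenance`.
#' @examples
#' pod <- point_of_departure(intake_rate(0.020, "ng/kg/day"), "LOAEL")
#' derive_rfd(pod, 30)  # 0.6667, presented as 0.7
#' derive_rfd(pod, 3)   # 6.667, presented as 7
#' @export
derive_rfd <- function(pod, composite_uf, sigfigs = 1L) {
  stopifnot(inherits(pod, "point_of_departure"))
  if (inherits(pod$dose, "serum_conc")) {
    stop("POD is serum-typed; convert it with serum_to_intake() first",
         call. = FALSE)
  }
  if (!is.numeric(composite_uf) || length(composite_uf) != 1L ||
      !is.finite(composite_uf) || composite_uf < 1) {
    stop("`composite_uf` must be a single number >= 1", call. = FALSE)
  }
  if (pod$dose$value <= 0) stop("POD must be positive", call. = FALSE)
  stopifnot(is.numeric(sigfigs), length(sigfigs) == 1L, sigfigs >= 1)
  value <- intake_pg(pod$dose) / composite_uf
  structure(list(value = value,
                 rounded_value = signif(value, sigfigs),
                 sigfigs = as.integer(sigfigs),
                 composite_uf = composite_uf,
                 provenance = pod$provenance,
                 classification = pod$classification),
            class = "rfd_estimate")
}

#' @export
print.rfd_estimate <- function(x, ...) {
  cat(sprintf("<rfd_estimate> %g pg/kg/day (presented: %g; POD %s / UF %g)\n",
              x$value, x$rounded_value, x$classification, x$composite_uf))
  invisible(x)
}

#' Average a peak intake and a critical-window average intake
#'
#' The arithmetic mean of a peak exposure rate and the average exposure over a
#' critical window, a construction used when a single daily-intake POD is
#' assembled from an acute exposure history. Units must match; no implicit
#' conversion is performed.
#'
#' @param peak,window_avg [intake_rate()] objects in the same unit.
#' @return An `intake_rate` in the shared unit.
#' @examples
#' average_peak_and_window(intake_rate(0.032, "ng/kg/day"),
#'                         intake_rate(0.0080, "ng/kg/day"))  # 0.020
#' @export
average_peak_and_window <- function(peak, window_avg) {
  stopifnot(inherits(peak, "intake_rate"), inherits(window_avg, "intake_rate"))
  if (!identical(peak$unit, window_avg$unit)) {
    stop("units differ (", peak$unit, " vs ", window_avg$unit,
         "); convert with convert_intake() first", call. = FALSE)
  }
  intake_rate((peak$value + window_avg$value) / 2, peak$unit)
}

#' Anchored proportional serum-to-intake scaling
#'
#' Converts a lipid-adjusted serum concentration to a daily intake rate by
#' proportional scaling through a known (serum, intake) anchor pair:
#' intake = anchor intake x serum / anchor serum. This deliberately replaces
#' no toxicokinetic model; it makes the serum-to-intake assumption a single
#' explicit linear factor. An optional multiplicative `kinetic_adjustment`
#' (>= 1, default 1 = off) is provided for analyses that posit the anchor's
#' underlying model underpredicts intake at low concentrations.
#'
#' @param serum a [serum_conc()] whose metric matches the anchor's.
#' @param anchor a [serum_intake_anchor()].
#' @param kinetic_adjustment multiplicative factor >= 1 applied to the result.
#' @return An [intake_rate()] in the anchor's unit, with the anchor recorded
#'   in attribute `"anchor"`.
#' @examples
#' anc <- serum_intake_anchor(serum_conc(235, "TCDD"),
#'                            intake_rate(0.020, "ng/kg/day"))
#' serum_to_intake(serum_conc(470, "TCDD"), anc)  # 0.040 ng/kg/day
#' @export
serum_to_intake <- function(serum, anchor, kinetic_adjustment = 1) {
  stopifnot(inherits(serum, "serum_conc"),
            inherits(anchor, "serum_intake_anchor"))
  if (!identical(serum$metric, anchor$serum$metric)) {
    stop("metric mismatch: serum is ", serum$metric, " but anchor is ",
         anchor$serum$metric, call. = FALSE)
  }
  if (!is.numeric(kinetic_adjustment) || length(kinetic_adjustment) != 1L ||
      kinetic_adjustment < 1) {
    stop("`kinetic_adjustment` must be a single number >= 1", call. = FALSE)
  }
  out <- intake_rate(anchor$intake$value * serum$value / anchor$serum$value *
                       kinetic_adjustment,
                     anchor$intake$unit)
  attr(out, "anchor") <- anchor
  out
}

#' Fold change between two serum concentrations
#'
#' Ratio of two concentrations on the same metric, with caller-specified
#' presentation rounding. Published fold statements mix conventions (a ratio
#' of 10.78 reported as "~10-fold" is one significant figure; 5.07 reported as
#' "fivefold" is nearest integer), so the rounding rule is explicit.
#'
#' @param numerator,denominator [serum_conc()] objects on the same metric.
#' @param rounding `"none"` (raw ratio), `"nearest_integer"`, or
#'   `"one_sigfig"`.
#' @return The (possibly rounded) ratio.
#' @examples
#' fold_change(serum_conc(733, "TCDD"), serum_conc(68, "TCDD"), "one_sigfig")      # 10
#' fold_change(serum_conc(345, "TCDD"), serum_conc(68, "TCDD"), "nearest_integer") # 5
#' @export
fold_change <- function(numerator, denominator,
                        rounding = c("none", "nearest_integer", "one_sigfig")) {
  stopifnot(inherits(numerator, "serum_conc"),
            inherits(denominator, "serum_conc"))
  rounding <- match.arg(rounding)
  if (!identical(numerator$metric, denominator$metric)) {
    stop("metric mismatch: ", numerator$metric, " vs ", denominator$metric,
         call. = FALSE)
  }
  ratio <- numerator$value / denominator$value
  switch(rounding,
         none = ratio,
         nearest_integer = round(ratio),
         one_sigfig = signif(ratio, 1))
}
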