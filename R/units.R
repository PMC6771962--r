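#' Lipid-adjusted serum concentration
#'
#' A lipid-adjusted serum concentration (LASC) in ppt (pg analyte per g serum
#' lipid), tagged with its exposure metric. The metric must be given
#' explicitly: a TCDD-only concentration and a toxic-equivalency (TEQ)
#' concentration are not interchangeable, and silent defaulting is the kind
#' of bookkeeping slip this type exists to prevent.
#'
#' @param value positive scalar, ppt (pg/g lipid).
#' @param metric `"TCDD"` or `"TEQ"`. No default.
#' @return An object of class `serum_conc` with fields `value` and `metric`.
#' @examples
#' serum_conc(68, "TCDD")
#' serum_conc(140.1, "TEQ")
#' @export
serum_conc <- function(value, metric) {
  if (missing(metric)) {
    stop("`metric` must be given explicitly (\"TCDD\" or \"TEQ\")", call. = FALSE)
  }
  metric <- match.arg(metric, c("TCDD", "TEQ"))
  assert_positive_scalar(value, "value")
  structure(list(value = value, metric = metric), class = "serum_conc")
}

#' @export
print.serum_conc <- function(x, ...) {
  cat(sprintf("<serum_conc> %g ppt %s (lipid-adjusted)\n", x$value, x$metric))
  invisible(x)
}

#' Daily intake rate
#'
#' A dose rate in ng/kg/day or pg/kg/day. Conversion between the two units is
#' exact (factor 1000); see [convert_intake()].
#'
#' @param value non-negative scalar.
#' @param unit `"ng/kg/day"` or `"pg/kg/day"`. No default.
#' @return An object of class `intake_rate`.
#' @examples
#' intake_rate(0.020, "ng/kg/day")
#' @export
intake_rate <- function(value, unit) {
  if (missing(unit)) {
    stop("`unit` must be given explicitly (\"ng/kg/day\" or \"pg/kg/day\")",
         call. = FALSE)
  }
  unit <- match.arg(unit, c("ng/kg/day", "pg/kg/day"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0) {
    stop("`value` must be a single non-negative finite number", call. = FALSE)
  }
  structure(list(value = value, unit = unit), class = "intake_rate")
}

#' @export
print.intake_rate <- function(x, ...) {
  cat(sprintf("<intake_rate> %g %s\n", x$value, x$unit))
  invisible(x)
}

#' Convert an intake rate between ng/kg/day and pg/kg/day
#'
#' The conversion is the exact factor 1000 in either direction; round-tripping
#' a representable value is lossless.
#'
#' @param x an [intake_rate()].
#' @param unit target unit.
#' @return An `intake_rate` in the requested unit.
#' @examples
#' convert_intake(intake_rate(0.020, "ng/kg/day"), "pg/kg/day")
#' @export
convert_intake <- function(x, unit) {
  stopifnot(inherits(x, "intake_rate"))
  unit <- match.arg(unit, c("ng/kg/day", "pg/kg/day"))
  if (identical(x$unit, unit)) return(x)
  value <- if (unit == "pg/kg/day") x$value * 1000 else x$value / 1000
  intake_rate(value, unit)
}

# internal: intake value expressed in pg/kg/day
intake_pg <- function(x) convert_intake(x, "pg/kg/day")$value

#' Point of departure
#'
#' A point of departure (POD): the dose anchoring low-dose extrapolation,
#' either a daily intake rate or a lipid-adjusted serum concentration,
#' together with its NOAEL/LOAEL classification. Every POD entering an RfD
#' derivation must carry a classification, because the classification decides
#' whether the LOAEL-to-NOAEL uncertainty factor applies.
#'
#' @param dose an [intake_rate()] or [serum_conc()].
#' @param classification `"NOAEL"` or `"LOAEL"`.
#' @param provenance free-text label recording where the value came from.
#' @return An object of class `point_of_departure`.
#' @examples
#' point_of_departure(intake_rate(0.020, "ng/kg/day"), "LOAEL",
#'                    "kinetic-model intake at 235 ppt maternal serum")
#' @export
point_of_departure <- function(dose, classification, provenance = "") {
  if (!inherits(dose, "intake_rate") && !inherits(dose, "serum_conc")) {
    stop("`dose` must be an intake_rate or serum_conc", call. = FALSE)
  }
  classification <- match.arg(classification, c("NOAEL", "LOAEL"))
  if (inherits(dose, "intake_rate") && dose$value <= 0) {
    stop("POD intake must be positive", call. = FALSE)
  }
  structure(list(dose = dose, classification = classification,
                 provenance = provenance),
            class = "point_of_departure")
}

#' @export
print.point_of_departure <- function(x, ...) {
  d <- x$dose
  dtxt <- if (inherits(d, "intake_rate")) sprintf("%g %s", d$value, d$unit)
          else sprintf("%g ppt %s", d$value, d$metric)
  cat(sprintf("<point_of_departure> %s [%s] %s\n", dtxt, x$classification,
              x$provenance))
  invisible(x)
}

#' Serum-to-intake anchor
#'
#' A (serum concentration, daily intake) pair used for proportional scaling in
#' [serum_to_intake()]. The full toxicokinetic model that produced such pairs
#' is not part of this package; the anchor makes the serum-to-intake step an
#' explicit, auditable linear scaling.
#'
#' @param serum a [serum_conc()].
#' @param intake an [intake_rate()].
#' @return An object of class `serum_intake_anchor`.
#' @examples
#' serum_intake_anchor(serum_conc(235, "TCDD"), intake_rate(0.020, "ng/kg/day"))
#' @export
serum_intake_anchor <- function(serum, intake) {
  stopifnot(inherits(serum, "serum_conc"), inherits(intake, "intake_rate"))
  if (serum$value <= 0 || intake$value <= 0) {
    stop("anchor serum and intake must both be positive", call. = FALSE)
  }
  structure(list(serum = serum, intake = intake), class = "serum_intake_anchor")
}

# internal validators ---------------------------------------------------------

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_scalar_in <- function(x, lo, hi, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= lo || x >= hi) {
    stop(sprintf("`%s` must be a single number in (%g, %g)", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
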