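#' Aggregate TEQ breakdown of a serum concentration
#'
#' Splits a lipid-adjusted serum concentration into its TCDD component and the
#' toxic-equivalency contribution of the other dioxin-like compounds (DLCs).
#' By default the total is the sum of the two components. An authoritative
#' modeled total may be supplied instead (agency TEQ totals are produced by
#' separate exposure modeling and need not equal the component sum); when the
#' supplied total disagrees with the component sum by more than 1% a warning
#' records the discrepancy, which is preserved rather than reconciled.
#'
#' Exactly one of `non_tcdd_teq` may be omitted when `total_teq` is supplied,
#' in which case it is derived as `total_teq - tcdd`.
#'
#' @param tcdd TCDD concentration, ppt, >= 0.
#' @param non_tcdd_teq TEQ of the non-TCDD DLCs, ppt, >= 0 (optional when
#'   `total_teq` is given).
#' @param total_teq optional authoritative total TEQ, ppt; must be at least
#'   the larger component.
#' @return An object of class `teq_breakdown` with fields `tcdd`,
#'   `non_tcdd_teq`, `total_teq` and flag `total_supplied`.
#' @examples
#' teq_breakdown(tcdd = 68, non_tcdd_teq = 72.5, total_teq = 140.1)
#' teq_breakdown(tcdd = 18.9, total_teq = 41.8)
#' @export
teq_breakdown <- function(tcdd, non_tcdd_teq = NULL, total_teq = NULL) {
  stopifnot(is.numeric(tcdd), length(tcdd) == 1L, tcdd >= 0)
  if (is.null(non_tcdd_teq)) {
    if (is.null(total_teq)) {
      stop("supply `non_tcdd_teq`, or `total_teq` from which to derive it",
           call. = FALSE)
    }
    non_tcdd_teq <- total_teq - tcdd
    if (non_tcdd_teq < 0) {
      stop("`total_teq` is smaller than `tcdd`", call. = FALSE)
    }
  }
  stopifnot(is.numeric(non_tcdd_teq), length(non_tcdd_teq) == 1L,
            non_tcdd_teq >= 0)
  total_supplied <- !is.null(total_teq)
  if (total_supplied) {
    stopifnot(is.numeric(total_teq), length(total_teq) == 1L)
    if (total_teq < max(tcdd, non_tcdd_teq)) {
      stop("`total_teq` must be at least the larger component", call. = FALSE)
    }
    comp_sum <- tcdd + non_tcdd_teq
    if (total_teq > 0 && abs(total_teq - comp_sum) / total_teq > 0.01) {
      warning(sprintf(paste0(
        "supplied total TEQ (%g ppt) differs from the component sum (%g ppt) ",
        "by more than 1%%; the supplied total is kept as authoritative"),
        total_teq, comp_sum), call. = FALSE)
    }
  } else {
    total_teq <- tcdd + non_tcdd_teq
  }
  structure(list(tcdd = tcdd, non_tcdd_teq = non_tcdd_teq,
                 total_teq = total_teq, total_supplied = total_supplied),
            class = "teq_breakdown")
}

#' @export
print.teq_breakdown <- function(x, ...) {
  cat(sprintf("<teq_breakdown> total %g ppt TEQ (TCDD %g, non-TCDD %g%s)\n",
              x$total_teq, x$tcdd, x$non_tcdd_teq,
              if (x$total_supplied) "; total supplied" else ""))
  invisible(x)
}

#' Non-TCDD share of the total TEQ
#'
#' The fraction of the total toxic equivalency contributed by dioxin-like
#' compounds other than TCDD.
#'
#' @param b a [teq_breakdown()] with positive total.
#' @param as_percent_rounded if `TRUE`, return the share as a percentage
#'   rounded to the nearest integer (presentation form); default `FALSE`
#'   returns the raw fraction in \[0, 1\].
#' @return Scalar fraction (or rounded percentage).
#' @examples
#' b <- teq_breakdown(tcdd = 68, non_tcdd_teq = 72.5, total_teq = 140.1)
#' fraction_non_tcdd(b)                      # 0.5175...
#' fraction_non_tcdd(b, as_percent_rounded = TRUE)  # 52
#' @export
fraction_non_tcdd <- function(b, as_percent_rounded = FALSE) {
  stopifnot(inherits(b, "teq_breakdown"))
  if (b$total_teq <= 0) stop("total TEQ must be positive", call. = FALSE)
  frac <- b$non_tcdd_teq / b$total_teq
  if (as_percent_rounded) round(100 * frac) else frac
}

#' Convert a TCDD-only POD concentration to a TEQ basis
#'
#' Re-expresses a TCDD-metric serum concentration on the TEQ metric using a
#' [teq_breakdown()] whose TCDD component equals the POD value: the result is
#' the breakdown's total TEQ (the supplied modeled total when present, else
#' the component sum). The TEQ-basis value can never be smaller than the
#' TCDD-only value.
#'
#' @param tcdd_pod a [serum_conc()] on the TCDD metric.
#' @param breakdown a [teq_breakdown()] with `tcdd` equal to the POD value.
#' @return A [serum_conc()] on the TEQ metric.
#' @examples
#' teq_basis_pod(serum_conc(68, "TCDD"),
#'               teq_breakdown(tcdd = 68, non_tcdd_teq = 72.5, total_teq = 140.1))
#' @export
teq_basis_pod <- function(tcdd_pod, breakdown) {
  stopifnot(inherits(tcdd_pod, "serum_conc"),
            inherits(breakdown, "teq_breakdown"))
  if (!identical(tcdd_pod$metric, "TCDD")) {
    stop("POD is already on the TEQ metric; nothing to convert", call. = FALSE)
  }
  if (abs(breakdown$tcdd - tcdd_pod$value) >
      1e-8 * max(1, abs(tcdd_pod$value))) {
    stop(sprintf(
      "breakdown TCDD component (%g) does not match the POD value (%g)",
      breakdown$tcdd, tcdd_pod$value), call. = FALSE)
  }
  serum_conc(breakdown$total_teq, "TEQ")
}
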