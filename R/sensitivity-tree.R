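#' Enumerate the sensitivity tree of candidate RfDs
#'
#' Deterministically enumerates every combination of branch choices --
#' point-of-departure option, TEQ accounting option and NOAEL/LOAEL
#' classification -- and derives the candidate RfD for each leaf through
#' [derive_rfd()]. The node count is always the product of the option-list
#' lengths, and nodes are emitted in lexicographic order of their branch
#' path, so the ensemble is reproducible and auditable.
#'
#' TEQ options: `NULL` means TCDD-only accounting (dose unchanged); a
#' [teq_breakdown()] rescales the POD to the TEQ basis. A serum-typed TCDD
#' POD whose value matches the breakdown's TCDD component goes through
#' [teq_basis_pod()]; otherwise the breakdown's total/TCDD ratio is applied
#' multiplicatively (the aggregate-level TEQ adjustment).
#'
#' @param pod_options named list of [point_of_departure()] objects (intake-
#'   or serum-typed; serum-typed PODs require `anchor`).
#' @param classifications character vector of classifications to branch over
#'   (default `c("NOAEL", "LOAEL")`); each must appear in `uf_table`.
#' @param teq_options named list of TEQ branch choices (default
#'   `list(tcdd_only = NULL)`); entries are `NULL` or [teq_breakdown()].
#' @param uf_table named list mapping each classification to a numeric vector
#'   of UF nominals or a list of [uf_spec()]; default
#'   `list(NOAEL = 3, LOAEL = c(10, 3))`.
#' @param anchor optional [serum_intake_anchor()], required when any POD is
#'   serum-typed.
#' @param sigfigs presentation rounding for the leaf RfDs (default 1).
#' @param confidence optional named character vector (`"low"`, `"medium"`,
#'   `"high"`) keyed by POD option name; a static annotation carried to the
#'   report, defaulting to `"medium"`.
#' @return A list of `scenario_node` objects, each with `branch_path`, `id`,
#'   `pod` (intake-typed), `composite_uf`, `rfd` (an `rfd_estimate`) and
#'   `confidence`.
#' @examples
#' pods <- list(epa = point_of_departure(intake_rate(0.020, "ng/kg/day"),
#'                                       "LOAEL", "kinetic-model intake"))
#' nodes <- enumerate_tree(pods)
#' tree_report(nodes)
#' @export
enumerate_tree <- function(pod_options,
                           classifications = c("NOAEL", "LOAEL"),
                           teq_options = list(tcdd_only = NULL),
                           uf_table = list(NOAEL = 3, LOAEL = c(10, 3)),
                           anchor = NULL, sigfigs = 1L, confidence = NULL) {
  stopifnot(is.list(pod_options), length(pod_options) >= 1L,
            is.list(teq_options), length(teq_options) >= 1L,
            length(classifications) >= 1L)
  if (is.null(names(pod_options)) || any(!nzchar(names(pod_options)))) {
    stop("`pod_options` must be a fully named list", call. = FALSE)
  }
  if (is.null(names(teq_options)) || any(!nzchar(names(teq_options)))) {
    stop("`teq_options` must be a fully named list", call. = FALSE)
  }
  missing_cls <- setdiff(classifications, names(uf_table))
  if (length(missing_cls)) {
    stop("unknown classification(s) in rules: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  lapply(pod_options, function(p) stopifnot(inherits(p, "point_of_departure")))

  nodes <- list()
  for (pn in sort(names(pod_options))) {
    for (tn in sort(names(teq_options))) {
      for (cls in sort(classifications)) {
        pod <- pod_options[[pn]]
        teq <- teq_options[[tn]]
        dose <- pod$dose
        metric <- if (inherits(dose, "serum_conc")) dose$metric else "TCDD"
        if (!is.null(teq)) {
          stopifnot(inherits(teq, "teq_breakdown"))
          if (inherits(dose, "serum_conc") && identical(dose$metric, "TCDD") &&
              isTRUE(all.equal(dose$value, teq$tcdd))) {
            dose <- teq_basis_pod(dose, teq)
          } else {
            ratio <- teq$total_teq / teq$tcdd
            dose <- if (inherits(dose, "serum_conc")) {
              serum_conc(dose$value * ratio, "TEQ")
            } else {
              intake_rate(dose$value * ratio, dose$unit)
            }
          }
          metric <- "TEQ"
        }
        if (inherits(dose, "serum_conc")) {
          if (is.null(anchor)) {
            stop("serum-typed POD '", pn, "' requires `anchor`", call. = FALSE)
          }
          anc <- serum_intake_anchor(
            serum_conc(anchor$serum$value, dose$metric), anchor$intake)
          dose <- serum_to_intake(dose, anc)
        }
        pod_i <- point_of_departure(dose, cls,
                                    provenance = sprintf("%s/%s/%s", pn, tn, cls))
        cuf <- compose_uf(uf_table[[cls]])
        node <- structure(list(
          branch_path = c(pod = pn, teq = tn, classification = cls),
          id = sprintf("%s/%s/%s", pn, tn, cls),
          pod = pod_i,
          metric = metric,
          composite_uf = cuf,
          rfd = derive_rfd(pod_i, cuf, sigfigs = sigfigs),
          confidence = if (!is.null(confidence) && pn %in% names(confidence))
            match.arg(confidence[[pn]], c("low", "medium", "high"))
          else "medium"),
          class = "scenario_node")
        nodes[[node$id]] <- node
      }
    }
  }
  nodes[order(names(nodes))]
}

#' Tabulate a sensitivity tree and summarize its RfD range
#'
#' Flattens a list of scenario nodes into a table sorted by branch path, and
#' reports the min-max envelope of the candidate RfDs. Adding nodes can only
#' widen (never narrow) the envelope.
#'
#' @param nodes a list of `scenario_node` objects from [enumerate_tree()].
#' @return An object of class `tree_report` with `table` (data frame:
#'   scenario_id, branch columns, pod value/units, metric, classification,
#'   composite_uf, exact and rounded RfD, confidence) and `range`
#'   (`c(min, max)` of the exact RfDs, pg/kg/day).
#' @export
tree_report <- function(nodes) {
  stopifnot(is.list(nodes), length(nodes) >= 1L)
  rows <- lapply(nodes, function(nd) {
    stopifnot(inherits(nd, "scenario_node"))
    data.frame(scenario_id = nd$id,
               pod_option = nd$branch_path[["pod"]],
               teq_option = nd$branch_path[["teq"]],
               classification = nd$branch_path[["classification"]],
               pod_value = nd$pod$dose$value,
               pod_units = nd$pod$dose$unit,
               metric = nd$metric,
               composite_uf = nd$composite_uf,
               rfd_exact_pg_kg_day = nd$rfd$value,
               rfd_rounded = nd$rfd$rounded_value,
               confidence = nd$confidence,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$scenario_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 range = c(min = min(tab$rfd_exact_pg_kg_day),
                           max = max(tab$rfd_exact_pg_kg_day))),
            class = "tree_report")
}

#' @export
print.tree_report <- function(x, ...) {
  cat(sprintf("<tree_report> %d scenario(s); candidate RfD range [%g, %g] pg/kg/day\n",
              nrow(x$table), x$range[["min"]], x$range[["max"]]))
  print(x$table, digits = 4)
  invisible(x)
}
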