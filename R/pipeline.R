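#' Read a pipeline configuration file
#'
#' Loads a YAML or JSON configuration (by extension) into a list; a list is
#' passed through unchanged.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @return The configuration list, with attribute `"path"` when read from a
#'   file.
#' @export
read_scenario_config <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), length(config) == 1L)
  if (!file.exists(config)) {
    config_error("config", paste("file not found:", config))
  }
  ext <- tolower(tools::file_ext(config))
  out <- switch(ext,
                yaml = , yml = yaml::read_yaml(config),
                json = jsonlite::read_json(config, simplifyVector = TRUE),
                config_error("config", paste("unsupported extension:", ext)))
  attr(out, "path") <- config
  out
}

config_error <- function(field, msg) {
  stop(structure(class = c("rfduq_config_error", "error", "condition"),
                 list(message = sprintf("config field `%s`: %s", field, msg),
                      call = NULL)))
}

require_field <- function(cfg, field, where = "config") {
  parts <- strsplit(field, "$", fixed = TRUE)[[1]]
  node <- cfg
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]])) {
      config_error(field, paste("missing (in", where, ")"))
    }
    node <- node[[p]]
  }
  node
}

write_once <- function(path) {
  if (file.exists(path)) {
    stop("refusing to overwrite existing output: ", path, call. = FALSE)
  }
  path
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in their declared order against a run
#' directory, writing CSV/JSON outputs plus a `manifest.json` recording the
#' command, configuration digest, seed, package version, timestamp and the
#' files written. Outputs are write-once: an existing file of the same name
#' aborts the run. Configuration problems are reported with their field
#' path before any computation; they carry class `rfduq_config_error` so a
#' caller (e.g. the command-line wrapper) can map them to a distinct exit
#' code.
#'
#' Stages:
#' \describe{
#'   \item{derive}{deterministic RfD derivations from a list of scenarios
#'     (`id`, `pod_value`, `pod_units`, `classification`, `metric`, `ufs`).}
#'   \item{tree}{sensitivity-tree enumeration from `pod_options`,
#'     `uf_table` and optional `teq` breakdowns / `anchor`.}
#'   \item{simulate}{synthetic TSH cohort written as CSV plus a JSON truth
#'     sidecar.}
#'   \item{calibrate}{log-log fit of a cohort CSV and inverse predictions at
#'     the requested thresholds.}
#'   \item{prob}{the eight-scenario induced-prior RfD grid from a simulated
#'     (or supplied) cohort.}
#' }
#'
#' An empty `stages` list is a manifest-only run.
#'
#' @param config configuration list or path (see [read_scenario_config()]).
#' @param out_dir run directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  raw <- config
  cfg <- read_scenario_config(config)
  stages <- cfg$stages
  if (is.null(stages)) stages <- character(0)
  known <- c("derive", "tree", "simulate", "calibrate", "prob")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    config_error("stages", paste("unknown stage(s):",
                                 paste(bad, collapse = ", ")))
  }
  seed <- cfg$seed
  if (length(stages) && is.null(seed)) config_error("seed", "missing")
  # validate stage blocks up front, before any computation
  for (st in stages) require_field(cfg, st)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit_csv <- function(df, name) {
    p <- write_once(file.path(out_dir, name))
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, name)
  }
  emit_json <- function(x, name) {
    p <- write_once(file.path(out_dir, name))
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, name)
  }

  for (st in stages) {
    blk <- cfg[[st]]
    switch(st,
      derive = {
        rows <- lapply(blk, function(sc) {
          for (f in c("id", "pod_value", "pod_units", "classification", "ufs"))
            if (is.null(sc[[f]])) config_error(paste0("derive$", f), "missing")
          pod <- point_of_departure(
            intake_rate(sc$pod_value, sc$pod_units), sc$classification,
            provenance = sc$id)
          cuf <- compose_uf(unlist(sc$ufs))
          est <- derive_rfd(pod, cuf,
                            sigfigs = if (is.null(sc$sigfigs)) 1L else sc$sigfigs)
          data.frame(scenario_id = sc$id, pod_value = sc$pod_value,
                     pod_units = sc$pod_units,
                     classification = sc$classification,
                     metric = if (is.null(sc$metric)) "TCDD" else sc$metric,
                     composite_uf = cuf,
                     rfd_exact_pg_kg_day = est$value,
                     rfd_rounded = est$rounded_value,
                     stringsAsFactors = FALSE)
        })
        emit_csv(do.call(rbind, rows), "derive.csv")
      },
      tree = {
        pods <- lapply(require_field(blk, "pod_options", "tree"), function(p) {
          point_of_departure(intake_rate(p$value, p$units),
                             if (is.null(p$classification)) "LOAEL"
                             else p$classification,
                             provenance = if (is.null(p$source)) "" else p$source)
        })
        uf_table <- lapply(require_field(blk, "uf_table", "tree"), unlist)
        teq_options <- list(tcdd_only = NULL)
        if (!is.null(blk$teq)) {
          teq_options$teq <- teq_breakdown(blk$teq$tcdd, blk$teq$non_tcdd_teq,
                                           blk$teq$total_teq)
        }
        nodes <- enumerate_tree(pods, classifications = names(uf_table),
                                teq_options = teq_options, uf_table = uf_table)
        rep <- tree_report(nodes)
        emit_csv(rep$table, "tree.csv")
        emit_json(list(range = as.list(rep$range)), "tree_range.json")
      },
      simulate = {
        params <- do.call(tsh_cohort_params,
                          c(blk[intersect(names(blk),
                                          names(formals(tsh_cohort_params)))],
                            list(seed = seed)))
        coh <- generate_tsh_cohort(params)
        emit_csv(data.frame(maternal_serum_ppt = coh$maternal_serum,
                            tsh_uU_mL = coh$tsh, metric = attr(coh, "metric")),
                 "cohort.csv")
        emit_json(unclass(attr(coh, "truth")), "cohort_truth.json")
      },
      calibrate = {
        inp <- require_field(blk, "input", "calibrate")
        df <- utils::read.csv(file.path_or_abs(inp, out_dir))
        fit <- fit_loglog(df$maternal_serum_ppt, df$tsh_uU_mL,
                          metric = if (is.null(blk$metric)) "TCDD" else blk$metric)
        thresholds <- if (is.null(blk$thresholds)) c(5, 10)
                      else unlist(blk$thresholds)
        preds <- lapply(thresholds, function(th) {
          pr <- inverse_predict(fit, th,
                                level = if (is.null(blk$level)) 0.95 else blk$level,
                                method = if (is.null(blk$method)) "approx_se"
                                         else blk$method,
                                cap = if (is.null(blk$cap)) 1e7 else blk$cap)
          data.frame(threshold = th, point_ppt = pr$point,
                     ci_low_ppt = pr$ci_low, ci_high_ppt = pr$ci_high,
                     unbounded_above = pr$unbounded_above,
                     method = pr$method, stringsAsFactors = FALSE)
        })
        emit_json(list(slope = fit$slope, intercept = fit$intercept,
                       residual_se = fit$residual_se, n = fit$n,
                       metric = fit$metric), "calibration_fit.json")
        emit_csv(do.call(rbind, preds), "inverse_predictions.csv")
      },
      prob = {
        params <- tsh_cohort_params(seed = seed)
        coh <- generate_tsh_cohort(params)
        fit_tcdd <- fit_loglog(coh)
        fit_teq <- fit_loglog(as_teq_cohort(coh))
        anchor <- serum_intake_anchor(
          serum_conc(require_field(blk, "anchor_serum_ppt", "prob"), "TCDD"),
          intake_rate(require_field(blk, "anchor_intake_ng_kg_day", "prob"),
                      "ng/kg/day"))
        grid <- scenario_grid(
          fit_tcdd, fit_teq, anchor,
          n_samples = if (is.null(blk$n_samples)) 1e5 else blk$n_samples,
          seed = seed,
          reference_rfd = if (is.null(blk$reference_rfd)) 0.7
                          else blk$reference_rfd)
        emit_csv(grid$summary, "prob_summary.csv")
        emit_json(list(seed = grid$seed, uf_convention = grid$uf_convention,
                       reference_rfd = grid$reference_rfd,
                       n_samples = length(grid$distributions[[1]]$samples)),
                  "prob_parameterization.json")
      })
  }

  cfg_digest <- if (is.character(raw)) unname(tools::md5sum(raw)) else {
    tf <- tempfile(fileext = ".json")
    on.exit(unlink(tf), add = TRUE)
    jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
    unname(tools::md5sum(tf))
  }
  manifest <- list(
    command = "run_pipeline",
    stages = as.list(stages),
    seed = seed,
    config_md5 = cfg_digest,
    package = "rfduq",
    package_version = as.character(utils::packageVersion("rfduq")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# internal: resolve a possibly relative input path against the run directory
file.path_or_abs <- function(p, out_dir) {
  if (file.exists(p)) p else file.path(out_dir, p)
}
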