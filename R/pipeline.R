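PIPELINE_REQUIRED_FIELDS <- c("inputs", "states", "out_dir")

validate_pipeline_config <- function(config) {
  miss <- setdiff(PIPELINE_REQUIRED_FIELDS, names(config))
  if (length(miss) > 0) {
    hdx_abort(sprintf("pipeline config missing field(s): %s",
                      paste(miss, collapse = ", ")), "hdx_config_error")
  }
  for (f in c("reference", "test")) {
    if (is.null(config$states[[f]])) {
      hdx_abort(sprintf("pipeline config missing field: states$%s", f),
                "hdx_config_error")
    }
  }
  for (f in c("uptake", "protein")) {
    if (is.null(config$inputs[[f]])) {
      hdx_abort(sprintf("pipeline config missing field: inputs$%s", f),
                "hdx_config_error")
    }
  }
  invisible(config)
}

#' Run the full HDX analysis pipeline
#'
#' Stages, in order: ingest (uptake table, protein, optional controls and
#' envelopes), uptake summarisation and back-exchange, differential analysis
#' (difference profiles, CI threshold, hybrid significance rule, residue
#' consolidation), EX1 calling on any supplied envelopes, and report tables.
#' A failing peptide or envelope is skipped with a logged message; the run
#' itself continues. Every run emits a manifest with the config snapshot,
#' input digests, seed, stage timings and the output inventory.
#'
#' @param config a list (or path to a YAML file, see [read_config()]) with
#'   `inputs` (`uptake`, `protein`, optional `controls`, `envelopes` dir),
#'   `states` (`reference`, `test`), `out_dir`, and optional `design`,
#'   `thresholds` (`confidence`, `alpha`, `n`), `convention`, `seed`,
#'   `butterfly_timepoint`, `plots`.
#' @return list: result tables (`summary`, `differences`, `calls`,
#'   `residue_map`, `ex1`, `butterfly`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_pipeline_config(config)
  design <- if (inherits(config$design, "labeling_design")) config$design
            else do.call(labeling_design, config$design %||% list())
  thr <- config$thresholds %||% list()
  confidence <- thr$confidence %||% 0.95
  alpha <- thr$alpha %||% 0.01
  n_rep <- thr$n %||% 3
  convention <- config$convention %||% "skip_first"
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- unlist(config$inputs[c("uptake", "protein", "controls")])
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  digests <- tools::md5sum(inputs)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  protein <- read_protein(config$inputs$protein)
  ingest <- read_uptake_table(config$inputs$uptake, protein,
                              convention = convention, design = design)
  controls <- NULL
  if (!is.null(config$inputs$controls)) {
    controls <- read_max_label_controls(config$inputs$controls, protein,
                                        design = design)
  }
  toc(t0, "ingest")

  t0 <- tic()
  series <- summarize_uptake(ingest$measurements)
  be <- NULL
  if (!is.null(controls)) {
    be <- back_exchange_table(controls, ingest$peptides, design$d_frac)
  }
  toc(t0, "uptake")

  t0 <- tic()
  ref <- config$states$reference
  tst <- config$states$test
  profiles <- difference_profile(series, ref, tst)
  ci <- ci_threshold_from_series(series, ref, tst, n = n_rep,
                                 confidence = confidence)
  calls <- classify_all(profiles, ci, ingest$measurements, alpha = alpha)
  resmap <- consolidate_residues(calls, ingest$peptides, protein)
  toc(t0, "differential")

  t0 <- tic()
  ex1_report <- NULL
  if (!is.null(config$inputs$envelopes) && dir.exists(config$inputs$envelopes)) {
    ex1_report <- ex1_stage(config$inputs$envelopes, ingest$peptides,
                            thr$ex1 %||% list())
  }
  toc(t0, "ex1")

  t0 <- tic()
  outputs <- c()
  summary_path <- file.path(out_dir, "summary.csv")
  write_summary_table(series, summary_path, calls = calls, be = be, ci = ci,
                      design = design)
  outputs <- c(outputs, summary_path)

  diff_path <- file.path(out_dir, "differences.csv")
  diff_tab <- dplyr::mutate(
    dplyr::left_join(profiles, calls[, c("peptide_id", "verdict", "rule_fired")],
                     by = "peptide_id"),
    ci = ci$ci)
  readr::write_csv(diff_tab, diff_path)
  outputs <- c(outputs, diff_path)

  res_path <- file.path(out_dir, "residue_map.csv")
  readr::write_csv(resmap$map, res_path)
  attr_path <- file.path(out_dir, "residue_attributes.txt")
  write_residue_attributes(resmap, attr_path)
  outputs <- c(outputs, res_path, attr_path)

  butterfly <- NULL
  if (!is.null(controls)) {
    tp <- config$butterfly_timepoint %||% design$time_grid_min[1]
    butterfly <- butterfly_series(
      dplyr::filter(series, .data$state == ref),
      dplyr::filter(series, .data$state == tst), controls, tp)
    bf_path <- file.path(out_dir, "butterfly.csv")
    readr::write_csv(butterfly, bf_path)
    outputs <- c(outputs, bf_path)
  }

  if (!is.null(ex1_report)) {
    ex1_path <- file.path(out_dir, "ex1_report.csv")
    readr::write_csv(ex1_report, ex1_path)
    outputs <- c(outputs, ex1_path)
  }

  if (isTRUE(config$plots)) {
    plot_path <- file.path(out_dir, "difference_plot.png")
    p <- render_difference_plot(diff_tab, ci)
    ggplot2::ggsave(plot_path, p$figure, width = 10, height = 5, dpi = 150)
    outputs <- c(outputs, plot_path)
  }
  toc(t0, "report")

  manifest <- list(config = config, input_digests = as.list(digests),
                   seed = config$seed %||% NA,
                   timings_sec = as.list(timings),
                   outputs = as.list(outputs))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  hdx_log(sprintf("run_pipeline: %d peptides, %d significant, outputs in %s",
                  nrow(calls), sum(calls$verdict != "none"), out_dir))

  list(summary = series, differences = diff_tab, calls = calls,
       residue_map = resmap, ci = ci, ex1 = ex1_report,
       butterfly = butterfly, be = be, manifest = manifest)
}

# EX1 stage: group envelope files by peptide, fit each time point, call.
# A file or peptide that fails is skipped with a logged message.
ex1_stage <- function(env_dir, peptides, criteria = list()) {
  files <- list.files(env_dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0) return(NULL)
  envs <- list()
  for (f in files) {
    env <- tryCatch(read_envelope(f), error = function(e) {
      hdx_log(sprintf("ex1 stage: skipping %s (%s)", basename(f),
                      conditionMessage(e)), "warn")
      NULL
    })
    if (!is.null(env)) envs[[length(envs) + 1]] <- env
  }
  if (length(envs) == 0) return(NULL)
  keys <- vapply(envs, function(e) paste(e$peptide, e$state %||% "?"), "")
  rows <- list()
  for (key in unique(keys)) {
    group <- envs[keys == key]
    times <- vapply(group, function(e) e$exposure_min %||% NA_real_, numeric(1))
    if (length(group) < 2 || anyNA(times)) next
    pep <- peptides[peptides$peptide_id == group[[1]]$peptide, ]
    m0 <- if (nrow(pep) == 1) pep$m0 else group[[1]]$m0
    fits <- lapply(group, function(e) {
      tryCatch(fit_bimodal(e, m0 = m0,
                           n_amides = if (nrow(pep) == 1) pep$n_amides else NULL),
               error = function(err) NULL)
    })
    keep <- !vapply(fits, is.null, logical(1))
    if (sum(keep) < 2) next
    call <- do.call(call_ex1, c(list(fits = fits[keep], times = times[keep]),
                                criteria))
    rows[[length(rows) + 1]] <- tibble::tibble(
      peptide_id = group[[1]]$peptide, state = group[[1]]$state %||% NA,
      verdict = call$verdict, mean_separation_D = call$mean_separation_D,
      k_open = call$k_open)
  }
  dplyr::bind_rows(rows)
}

#' Difference plot with the CI band
#'
#' Per-peptide uptake differences per time point, peptides ordered N- to
#' C-terminal, with the comparison-wide confidence band drawn at the exact
#' [ci_threshold()] value. The numbers behind the figure are always also
#' returned as a table: figures are conveniences, tables are the contract.
#'
#' @param diff_tab difference table (a [difference_profile()], optionally
#'   joined with verdicts).
#' @param ci a [ci_threshold()].
#' @return list: `figure` (a ggplot) and `table` (the plotted numbers).
#' @export
render_difference_plot <- function(diff_tab, ci) {
  tab <- dplyr::arrange(tibble::as_tibble(diff_tab), .data$start, .data$end,
                        .data$exposure_min)
  if (nrow(tab) == 0) {
    return(list(figure = ggplot2::ggplot(), table = tab))
  }
  tab$peptide_index <- match(tab$peptide_id, unique(tab$peptide_id))
  fig <- ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$peptide_index, y = .data$delta_D,
    colour = factor(.data$exposure_min))) +
    ggplot2::geom_hline(yintercept = c(-ci$ci, ci$ci), linetype = "dotted") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "peptide (N- to C-terminal)",
                  y = expression(Delta * "D (reference - test)"),
                  colour = "exposure (min)") +
    ggplot2::theme_minimal()
  list(figure = fig, table = tab)
}
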