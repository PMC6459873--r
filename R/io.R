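# Column-name shim: accepts the common commercial state-data export headers
# alongside the package's canonical lower-case names.
COLUMN_ALIASES <- c(
  start = "start", end = "end", sequence = "sequence", state = "state",
  exposure = "exposure_min", exposure_min = "exposure_min",
  replicate = "replicate", uptake = "uptake_D", uptake_d = "uptake_D",
  center = "center_mz", center_mz = "center_mz", charge = "charge",
  m0 = "m0", maxuptake = "max_uptake", protein = "protein_name"
)

normalize_columns <- function(nms) {
  key <- tolower(gsub("[ .]", "_", nms))
  out <- nms
  hit <- key %in% names(COLUMN_ALIASES)
  out[hit] <- unname(COLUMN_ALIASES[key[hit]])
  out
}

#' Read a protein sequence from FASTA or plain text
#'
#' @param path FASTA file (first record used) or a plain-text file holding a
#'   bare sequence.
#' @param residue_offset,name passed to [protein_context()].
#' @return a [protein_context()].
#' @export
read_protein <- function(path, residue_offset = 1L, name = NULL) {
  if (!file.exists(path)) {
    hdx_abort(sprintf("protein file not found: %s", path), "hdx_io_error")
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0 && startsWith(first, ">")) {
    set <- Biostrings::readAAStringSet(path)
    seqs <- as.character(set)
    protein_context(seqs[[1]], residue_offset,
                    name = name %||% names(set)[1])
  } else {
    txt <- paste(gsub("\\s", "", readLines(path, warn = FALSE)), collapse = "")
    protein_context(txt, residue_offset, name = name %||% basename(path))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a peptide-level uptake table
#'
#' Accepts two comma-separated dialects: "uptake" (a `uptake` column in Da)
#' and "centroid" (`center_mz` + `charge` columns; uptake is computed against
#' the undeuterated mass `m0`, taken from an `m0` column when present and
#' otherwise from the peptide sequence). Commercial state-data headers
#' (Start, End, Sequence, State, Exposure, Center, Uptake) are mapped
#' automatically; unknown columns are preserved.
#'
#' @param path CSV file; lines starting with `#` are treated as comments.
#' @param protein a [protein_context()] used to validate peptide sequences.
#' @param convention amide-count convention, see [compute_n_amides()].
#' @param design optional [labeling_design()]; when given, measured uptake is
#'   soft-checked against the theoretical maximum (warn, not fail).
#' @param noise_sd replicate noise SD used in the soft check.
#' @return list with `measurements` (tibble: one row per input row, with
#'   `peptide_id`, `state`, `exposure_min`, `replicate`, `uptake_D`,
#'   `source_row`, plus any extra input columns) and `peptides`
#'   (deduplicated [peptide_records()] table).
#' @export
read_uptake_table <- function(path, protein,
                              convention = c("skip_first", "skip_first_two"),
                              design = NULL, noise_sd = 0.079) {
  convention <- match.arg(convention)
  if (!file.exists(path)) {
    hdx_abort(sprintf("uptake table not found: %s", path), "hdx_io_error")
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(raw) <- normalize_columns(names(raw))
  need <- c("start", "end", "sequence", "state", "exposure_min", "replicate")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    hdx_abort(sprintf("uptake table missing required column(s): %s",
                      paste(miss, collapse = ", ")), "hdx_format_error")
  }
  has_uptake <- "uptake_D" %in% names(raw)
  has_centroid <- all(c("center_mz", "charge") %in% names(raw))
  if (!has_uptake && !has_centroid) {
    hdx_abort("uptake table needs either an 'uptake' column or 'center_mz' + 'charge'",
              "hdx_format_error")
  }
  if (any(raw$exposure_min <= 0)) {
    hdx_abort("exposure times must be positive (minutes)", "hdx_validation_error")
  }
  peptides <- peptide_records(raw, protein, convention)
  raw$source_row <- seq_len(nrow(raw))
  raw$peptide_id <- sprintf("%d-%d", raw$start, raw$end)
  if (!has_uptake) {
    m0 <- peptides$m0[match(raw$peptide_id, peptides$peptide_id)]
    neutral <- raw$center_mz * raw$charge - raw$charge * MASS_PROTON
    raw$uptake_D <- neutral - m0
  }
  if (any(raw$uptake_D < 0)) {
    hdx_abort("negative deuterium uptake in table", "hdx_validation_error")
  }
  if (!is.null(design)) {
    n_am <- peptides$n_amides[match(raw$peptide_id, peptides$peptide_id)]
    cap <- n_am * design$d_frac + 3 * noise_sd
    over <- raw$uptake_D > cap
    if (any(over)) {
      warning(sprintf("%d measurement(s) exceed the theoretical uptake ceiling (N x d_frac + 3 sigma)",
                      sum(over)), call. = FALSE)
    }
  }
  front <- c("peptide_id", "start", "end", "sequence", "state",
             "exposure_min", "replicate", "uptake_D", "source_row")
  meas <- dplyr::relocate(tibble::as_tibble(raw), dplyr::all_of(front))
  hdx_log(sprintf("read_uptake_table: %d rows, %d peptides, %d states from %s",
                  nrow(meas), nrow(peptides),
                  length(unique(meas$state)), basename(path)))
  list(measurements = meas, peptides = peptides)
}

#' Read maximally labelled control masses
#'
#' @param path CSV with columns `start`, `end`, `sequence`, and either
#'   `m_max` (plus optional `m0`) or `uptake_max_D`.
#' @param protein a [protein_context()].
#' @param design optional [labeling_design()] for the
#'   `uptake_max_D <= N x d_frac` soft check (0.2 D tolerance).
#' @return tibble with `peptide_id`, `m0`, `m_max`, `uptake_max_D`.
#' @export
read_max_label_controls <- function(path, protein, design = NULL) {
  if (!file.exists(path)) {
    hdx_abort(sprintf("control table not found: %s", path), "hdx_io_error")
  }
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(raw) <- normalize_columns(names(raw))
  peptides <- peptide_records(raw, protein)
  raw$peptide_id <- sprintf("%d-%d", raw$start, raw$end)
  m0 <- peptides$m0[match(raw$peptide_id, peptides$peptide_id)]
  if ("m_max" %in% names(raw)) {
    uptake_max <- raw$m_max - m0
  } else if ("uptake_max_D" %in% names(raw)) {
    uptake_max <- raw$uptake_max_D
  } else {
    hdx_abort("control table needs 'm_max' or 'uptake_max_D'", "hdx_format_error")
  }
  if (any(uptake_max < 0)) {
    hdx_abort("maximally labelled control lighter than undeuterated mass",
              "hdx_validation_error")
  }
  if (!is.null(design)) {
    n_am <- peptides$n_amides[match(raw$peptide_id, peptides$peptide_id)]
    over <- uptake_max > n_am * design$d_frac + 0.2
    if (any(over)) {
      warning(sprintf("%d control(s) exceed N x d_frac by more than 0.2 D",
                      sum(over)), call. = FALSE)
    }
  }
  tibble::tibble(peptide_id = raw$peptide_id, m0 = m0,
                 m_max = m0 + uptake_max, uptake_max_D = uptake_max)
}

#' Write the comparison summary table
#'
#' Emits one row per peptide with per-state per-time mean uptake, SD and
#' replicate count, back-exchange, the comparison-wide CI threshold and the
#' significance call, in a documented bit-stable column order. Metadata
#' (deuterium fraction, CI, column order) goes into `#`-prefixed header
#' lines, so the file reads back with any CSV reader that skips comments.
#'
#' @param series an uptake summary from [summarize_uptake()].
#' @param path output CSV path.
#' @param calls optional significance calls (from [classify_all()]).
#' @param be optional back-exchange table (`peptide_id`, `be_percent`).
#' @param ci optional [ci_threshold()] object.
#' @param design optional [labeling_design()] recorded in the header.
#' @return the written tibble, invisibly.
#' @export
write_summary_table <- function(series, path, calls = NULL, be = NULL,
                                ci = NULL, design = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  wide <- tidyr::pivot_wider(
    dplyr::select(series, "peptide_id", "start", "end", "sequence", "state",
                  "exposure_min", "mean_uptake_D", "sd_uptake_D", "n"),
    names_from = c("state", "exposure_min"),
    values_from = c("mean_uptake_D", "sd_uptake_D", "n"),
    names_glue = "{.value}_{state}_t{exposure_min}"
  )
  wide <- dplyr::arrange(wide, .data$start, .data$end)
  if (!is.null(be)) {
    wide <- dplyr::left_join(wide, be[, c("peptide_id", "be_percent")],
                             by = "peptide_id")
  }
  if (!is.null(calls)) {
    wide <- dplyr::left_join(
      wide, calls[, c("peptide_id", "verdict", "rule_fired")], by = "peptide_id")
  }
  hdr <- c(
    "# hdxstat summary table",
    if (!is.null(design)) sprintf("# d_frac: %g", design$d_frac),
    if (!is.null(ci)) sprintf("# ci_threshold_D: %.10g", ci$ci),
    sprintf("# columns: %s", paste(names(wide), collapse = ","))
  )
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    hdx_abort(sprintf("cannot open '%s' for writing", path), "hdx_io_error")
  }
  on.exit(close(con))
  writeLines(hdr, con)
  body <- strsplit(readr::format_csv(wide), "\n", fixed = TRUE)[[1]]
  writeLines(body, con)
  hdx_log(sprintf("write_summary_table: %d peptides -> %s", nrow(wide),
                  basename(path)))
  invisible(wide)
}

#' Read back a summary table written by [write_summary_table()]
#' @param path CSV path.
#' @return a tibble.
#' @export
read_summary_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Write / read isotope envelopes as two-column text
#'
#' The format is `#`-prefixed key: value metadata lines (peptide, charge,
#' state, exposure_min, seed) followed by whitespace-separated m/z and
#' intensity columns.
#'
#' @param env an [isotope_envelope()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  meta <- c(peptide = env$peptide %||% NA, charge = env$charge,
            state = env$state %||% NA, exposure_min = env$exposure_min %||% NA,
            m0 = env$m0 %||% NA, seed = env$seed %||% NA)
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, format, ""))
  body <- sprintf("%.6f %.8f", env$mz, env$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^# *([^:]+): *(.*)$", meta_lines))
  meta <- stats::setNames(
    lapply(kv, function(m) m[3]),
    vapply(kv, function(m) trimws(m[2]), "")
  )
  dat <- read.table(text = lines[!grepl("^#", lines)], col.names = c("mz", "intensity"))
  num <- function(x) if (is.null(x) || x == "NA") NULL else as.numeric(x)
  isotope_envelope(dat$mz, dat$intensity,
                   charge = as.integer(meta$charge),
                   peptide = meta$peptide,
                   state = if (identical(meta$state, "NA")) NULL else meta$state,
                   exposure_min = num(meta$exposure_min),
                   m0 = num(meta$m0))
}

#' Read a pipeline configuration file
#'
#' YAML key-value configuration covering the labeling design, amide-count
#' convention, significance thresholds and seeds. Returns the parsed list
#' with a `labeling_design` attached under `$design`.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    hdx_abort(sprintf("config not found: %s", path), "hdx_io_error")
  }
  cfg <- yaml::read_yaml(path)
  d <- cfg$design %||% list()
  cfg$design <- labeling_design(
    d_frac = d$d_frac %||% 0.85,
    time_grid_min = d$time_grid_min %||% c(0.25, 1, 10, 60, 480),
    temperature_C = d$temperature_C %||% 25
  )
  cfg
}
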