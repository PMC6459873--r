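#' Summarise replicate uptake measurements
#'
#' Per peptide x state x exposure time: mean uptake, sample standard
#' deviation (n-1 denominator, reported only where n >= 2) and replicate
#' count. Cells absent from the input stay absent - nothing is imputed.
#'
#' @param measurements measurement tibble from [read_uptake_table()] (or the
#'   simulator); needs `peptide_id`, `start`, `end`, `sequence`, `state`,
#'   `exposure_min`, `uptake_D`.
#' @return a tibble of class `uptake_series`, ordered N- to C-terminal.
#' @export
summarize_uptake <- function(measurements) {
  if (nrow(measurements) == 0) {
    out <- tibble::tibble(peptide_id = character(), start = integer(),
                          end = integer(), sequence = character(),
                          state = character(), exposure_min = numeric(),
                          mean_uptake_D = numeric(), sd_uptake_D = numeric(),
                          n = integer())
    return(structure(out, class = c("uptake_series", class(out))))
  }
  out <- measurements |>
    dplyr::group_by(.data$peptide_id, .data$start, .data$end, .data$sequence,
                    .data$state, .data$exposure_min) |>
    dplyr::summarise(
      mean_uptake_D = mean(.data$uptake_D),
      sd_uptake_D = ifelse(dplyr::n() >= 2, sd(.data$uptake_D), NA_real_),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$start, .data$end, .data$state, .data$exposure_min)
  structure(out, class = c("uptake_series", class(out)))
}

#' Back-exchange from a maximally labelled control
#'
#' \deqn{BE\% = \left(1 - \frac{m_{max} - m_0}{N \cdot D_{frac}}\right) \times 100}
#'
#' Values outside \[0, 100\] are reported with a warning rather than clipped:
#' a negative BE flags an inconsistency between the control and the
#' undeuterated mass, which is diagnostic information. Back-exchange here
#' serves quality control; uptake values are never BE-corrected by default.
#'
#' @param m_max mass of the maximally labelled peptide (Da).
#' @param m0 undeuterated mass (Da).
#' @param n_amides exchangeable-amide count (>= 1).
#' @param d_frac deuterium fraction of the labeling buffer.
#' @return back-exchange in percent (vectorized).
#' @export
#' @examples
#' back_exchange(m_max = 1006.8, m0 = 1000, n_amides = 10, d_frac = 0.85)  # 20
back_exchange <- function(m_max, m0, n_amides, d_frac = 0.85) {
  if (any(n_amides < 1)) {
    hdx_abort("n_amides must be >= 1", "hdx_validation_error")
  }
  if (any(d_frac <= 0 | d_frac > 1)) {
    hdx_abort("d_frac must be in (0, 1]", "hdx_validation_error")
  }
  be <- (1 - (m_max - m0) / (n_amides * d_frac)) * 100
  out_of_range <- be < 0 | be > 100
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sprintf("%d back-exchange value(s) outside [0, 100]%% - check controls and m0",
                    sum(out_of_range, na.rm = TRUE)), call. = FALSE)
  }
  be
}

#' Back-exchange for every peptide with a control
#'
#' @param controls control tibble from [read_max_label_controls()].
#' @param peptides [peptide_records()] table.
#' @param d_frac labeling deuterium fraction.
#' @return tibble `peptide_id`, `be_percent`, `flagged`.
#' @export
back_exchange_table <- function(controls, peptides, d_frac = 0.85) {
  n_am <- peptides$n_amides[match(controls$peptide_id, peptides$peptide_id)]
  be <- back_exchange(controls$m_max, controls$m0, n_am, d_frac)
  tibble::tibble(peptide_id = controls$peptide_id, be_percent = be,
                 flagged = be < 0 | be > 100)
}

#' Normalise uptake to the maximally labelled control
#'
#' Plain ratio `uptake / uptake_max`; values above 1 are flagged with a
#' warning but never clamped, and a missing or non-positive control marks the
#' peptide not-computable (NA).
#'
#' @param uptake_D measured uptake (D).
#' @param uptake_max_D control uptake (D).
#' @return numeric fraction (vectorized).
#' @export
normalized_uptake <- function(uptake_D, uptake_max_D) {
  bad <- is.na(uptake_max_D) | uptake_max_D <= 0
  if (any(bad)) {
    warning(sprintf("%d peptide(s) lack a positive maximally labelled control; normalized uptake set NA",
                    sum(bad)), call. = FALSE)
  }
  out <- ifelse(bad, NA_real_, uptake_D / uptake_max_D)
  if (any(out > 1, na.rm = TRUE)) {
    warning(sprintf("%d normalized uptake value(s) exceed 1", sum(out > 1, na.rm = TRUE)),
            call. = FALSE)
  }
  out
}

#' Optional back-exchange-corrected uptake view
#'
#' Divides observed uptake by (1 - BE). Clearly a derived view: reported
#' uptake elsewhere in the pipeline is never corrected.
#'
#' @param uptake_D observed uptake (D).
#' @param be_percent back-exchange in percent (must be < 100).
#' @return corrected uptake.
#' @export
be_corrected_uptake <- function(uptake_D, be_percent) {
  if (any(be_percent >= 100)) {
    hdx_abort("cannot correct with back-exchange >= 100%", "hdx_validation_error")
  }
  uptake_D / (1 - be_percent / 100)
}

#' Butterfly comparison of two states
#'
#' Normalised uptake of two states at one exposure time, the second state
#' negated to give the mirror-image (butterfly) layout, ordered by peptide
#' position N- to C-terminal. Only peptides present in both series and in
#' the control table are used; dropped peptides are logged.
#'
#' @param series_a,series_b `uptake_series` summaries of the two states
#'   (may be slices of one summary).
#' @param controls control tibble from [read_max_label_controls()] supplying
#'   `uptake_max_D` per peptide.
#' @param timepoint exposure time (min) to compare at.
#' @return tibble `peptide_id`, `start`, `end`, `normalized_a`,
#'   `normalized_b_neg` (negated), plus the state labels.
#' @export
butterfly_series <- function(series_a, series_b, controls, timepoint) {
  a <- dplyr::filter(series_a, .data$exposure_min == timepoint)
  b <- dplyr::filter(series_b, .data$exposure_min == timepoint)
  shared <- intersect(a$peptide_id, b$peptide_id)
  if (length(shared) == 0) {
    hdx_abort("butterfly comparison: the two series share no peptides",
              "hdx_validation_error")
  }
  dropped <- length(union(a$peptide_id, b$peptide_id)) - length(shared)
  if (dropped > 0) {
    hdx_log(sprintf("butterfly_series: dropped %d peptide(s) absent from one state",
                    dropped))
  }
  a <- dplyr::filter(a, .data$peptide_id %in% shared)
  b <- dplyr::filter(b, .data$peptide_id %in% shared)
  maxu <- controls$uptake_max_D[match(a$peptide_id, controls$peptide_id)]
  out <- tibble::tibble(
    peptide_id = a$peptide_id, start = a$start, end = a$end,
    state_a = a$state, state_b = b$state[match(a$peptide_id, b$peptide_id)],
    exposure_min = timepoint,
    normalized_a = normalized_uptake(a$mean_uptake_D, maxu),
    normalized_b_neg = -normalized_uptake(
      b$mean_uptake_D[match(a$peptide_id, b$peptide_id)], maxu)
  )
  dplyr::arrange(out, .data$start, .data$end)
}
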