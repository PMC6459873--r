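#' Protein context for an HDX experiment
#'
#' Holds the construct sequence and its residue numbering. All peptide
#' coordinates in the pipeline are 1-based inclusive in this numbering
#' (residue `residue_offset` is the first letter of `sequence`).
#'
#' @param sequence one-letter amino-acid string (20 canonical letters only).
#' @param residue_offset number of the first residue (>= 1).
#' @param name free-text label.
#' @return an object of class `protein_context`.
#' @export
#' @examples
#' prot <- protein_context("MSTTSAV", name = "toy")
protein_context <- function(sequence, residue_offset = 1L, name = "protein") {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    hdx_abort("sequence must be a single non-empty string", "hdx_validation_error")
  }
  sequence <- toupper(sequence)
  bad <- setdiff(strsplit(sequence, "")[[1]], CANONICAL_AA)
  if (length(bad) > 0) {
    hdx_abort(sprintf("sequence contains non-canonical letters: %s",
                      paste(unique(bad), collapse = ", ")),
              "hdx_validation_error")
  }
  if (residue_offset < 1) {
    hdx_abort("residue_offset must be >= 1", "hdx_validation_error")
  }
  structure(
    list(sequence = sequence, residue_offset = as.integer(residue_offset),
         name = name),
    class = "protein_context"
  )
}

#' @export
print.protein_context <- function(x, ...) {
  cat(sprintf("<protein_context> %s: %d residues (numbered %d-%d)\n",
              x$name, nchar(x$sequence), x$residue_offset,
              x$residue_offset + nchar(x$sequence) - 1L))
  invisible(x)
}

protein_length <- function(protein) nchar(protein$sequence)

protein_subseq <- function(protein, start, end) {
  i <- start - protein$residue_offset + 1L
  j <- end - protein$residue_offset + 1L
  if (any(i < 1) || any(j > nchar(protein$sequence))) {
    hdx_abort(sprintf("residue range %d-%d outside construct (%d-%d)",
                      start[1], end[1], protein$residue_offset,
                      protein$residue_offset + nchar(protein$sequence) - 1L),
              "hdx_validation_error")
  }
  substring(protein$sequence, i, j)
}

#' Count exchangeable backbone amide hydrogens
#'
#' The N-terminal amine exchanges too fast to retain label and proline has no
#' amide hydrogen, so the default convention counts `nchar - 1` minus prolines
#' at positions 2..n ("skip_first"). Some HDX software additionally discounts
#' the second residue, whose amide back-exchanges very rapidly; that
#' convention ("skip_first_two": `nchar - 2` minus prolines at positions 3..n)
#' is selectable because published workflows differ and rarely state which
#' was used.
#'
#' @param sequence character vector of peptide sequences (length >= 2 each).
#' @param convention `"skip_first"` (default) or `"skip_first_two"`.
#' @return integer vector of exchangeable-amide counts.
#' @export
#' @examples
#' compute_n_amides("AAAA")         # 3
#' compute_n_amides("APAP")         # 1
compute_n_amides <- function(sequence,
                             convention = c("skip_first", "skip_first_two")) {
  convention <- match.arg(convention)
  skip <- if (convention == "skip_first") 1L else 2L
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n < 2) {
      hdx_abort("peptide sequence must have length >= 2", "hdx_validation_error")
    }
    aa <- strsplit(s, "")[[1]]
    pro <- sum(aa[seq.int(skip + 1L, n)] == "P")
    as.integer(n - skip - pro)
  }, integer(1), USE.NAMES = FALSE)
}

#' Build a validated peptide table
#'
#' Deduplicates on (start, end, sequence), checks each sequence against the
#' protein construct, counts exchangeable amides and fills the undeuterated
#' mass `m0` (computed from sequence when not supplied).
#'
#' @param df data frame with columns `start`, `end`, `sequence` and optional
#'   `m0`.
#' @param protein a [protein_context()].
#' @param convention amide-count convention, see [compute_n_amides()].
#' @return a tibble with columns `peptide_id`, `start`, `end`, `sequence`,
#'   `n_amides`, `m0`, ordered N- to C-terminal by (start, end).
#' @export
peptide_records <- function(df, protein,
                            convention = c("skip_first", "skip_first_two")) {
  convention <- match.arg(convention)
  need <- c("start", "end", "sequence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    hdx_abort(sprintf("peptide table missing column(s): %s",
                      paste(miss, collapse = ", ")), "hdx_format_error")
  }
  pep <- dplyr::distinct(tibble::as_tibble(df[, intersect(c(need, "m0"), names(df))]),
                         .data$start, .data$end, .data$sequence,
                         .keep_all = TRUE)
  if (any(pep$start > pep$end)) {
    hdx_abort("peptide with start > end", "hdx_validation_error")
  }
  if (any(nchar(pep$sequence) != pep$end - pep$start + 1L)) {
    bad <- which(nchar(pep$sequence) != pep$end - pep$start + 1L)[1]
    hdx_abort(sprintf("peptide %d-%d: sequence length %d != residue span %d",
                      pep$start[bad], pep$end[bad], nchar(pep$sequence[bad]),
                      pep$end[bad] - pep$start[bad] + 1L),
              "hdx_validation_error")
  }
  expect_seq <- protein_subseq(protein, pep$start, pep$end)
  mismatch <- which(toupper(pep$sequence) != expect_seq)
  if (length(mismatch) > 0) {
    b <- mismatch[1]
    hdx_abort(sprintf(
      "peptide %d-%d sequence '%s' does not match protein ('%s')",
      pep$start[b], pep$end[b], pep$sequence[b], expect_seq[b]),
      "hdx_validation_error")
  }
  pep$sequence <- toupper(pep$sequence)
  pep$n_amides <- compute_n_amides(pep$sequence, convention)
  if (is.null(pep[["m0"]])) {
    pep$m0 <- peptide_mass(pep$sequence)
  } else {
    fill <- is.na(pep$m0)
    pep$m0[fill] <- peptide_mass(pep$sequence[fill])
  }
  pep <- dplyr::arrange(pep, .data$start, .data$end)
  pep$peptide_id <- sprintf("%d-%d", pep$start, pep$end)
  dplyr::select(pep, "peptide_id", "start", "end", "sequence", "n_amides", "m0")
}

#' Labeling design of an HDX experiment
#'
#' @param d_frac deuterium fraction of the labeling buffer (0 < d_frac <= 1).
#' @param time_grid_min strictly increasing exposure times in minutes.
#' @param temperature_C labeling temperature.
#' @return an object of class `labeling_design`.
#' @export
labeling_design <- function(d_frac = 0.85,
                            time_grid_min = c(0.25, 1, 10, 60, 480),
                            temperature_C = 25) {
  if (!(d_frac > 0 && d_frac <= 1)) {
    hdx_abort("d_frac must be in (0, 1]", "hdx_validation_error")
  }
  if (any(diff(time_grid_min) <= 0)) {
    hdx_abort("time grid must be strictly increasing", "hdx_validation_error")
  }
  structure(list(d_frac = d_frac, time_grid_min = time_grid_min,
                 temperature_C = temperature_C),
            class = "labeling_design")
}
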