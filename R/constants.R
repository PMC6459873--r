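# Mass constants used throughout. The deuterium-hydrogen difference converts
# deuteron counts to mass shifts; the proton mass converts neutral mass to m/z.
MASS_D_MINUS_H <- 1.00628
MASS_PROTON <- 1.00728
MASS_WATER <- 18.010565

# Monoisotopic residue masses (Da) for the 20 canonical amino acids.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

CANONICAL_AA <- names(RESIDUE_MASS)

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of an unlabelled peptide: the sum of residue
#' masses plus one water. Used to supply the undeuterated reference mass
#' \eqn{m_0} for synthetic peptides and for centroid-dialect uptake tables
#' that do not carry their own \code{m0} column.
#'
#' @param sequence character vector of one-letter amino-acid sequences.
#' @return numeric vector of masses in Da.
#' @export
#' @examples
#' peptide_mass("PEPTIDE")
peptide_mass <- function(sequence) {
  vapply(sequence, function(s) {
    aa <- strsplit(s, "")[[1]]
    bad <- setdiff(aa, CANONICAL_AA)
    if (length(bad) > 0) {
      hdx_abort(sprintf("non-canonical residue(s) in '%s': %s",
                        s, paste(unique(bad), collapse = ", ")),
                "hdx_validation_error")
    }
    sum(RESIDUE_MASS[aa]) + MASS_WATER
  }, numeric(1), USE.NAMES = FALSE)
}
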