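# Shared constants: residue alphabets, column orders, feature layout.

#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Column order of PSI-BLAST ASCII matrices (and of the PSSM feature block).
#' @keywords internal
PSSM_COLUMNS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Per-residue label codes used throughout: O = order, D = disorder,
# U = unknown (excluded from training and evaluation).
#' @keywords internal
LABEL_CODES <- c("O", "D", "U")

# Raw log-odds are divided by this before any use ("PSSM normalizing factor").
#' @keywords internal
PSSM_NORMALIZER <- 9

# Monogram/bigram sums are divided by exp(6): pooled log-scale MG/BG values
# on real profile data centre near 6, so this normalizer recentres them near 1.
#' @keywords internal
MGBG_NORMALIZER <- exp(6.0)

# Number of per-residue features: AA(1) + PP(7) + PSSM(20) + SS(3) + ASA(1)
# + torsion(2) + MG(1) + BG(20) + terminal(1).
#' @keywords internal
N_FEATURES <- 56L

# Seven physicochemical parameters per residue: graph-shape (steric) index,
# polarizability, volume, hydrophobicity, isoelectric point, helix
# propensity, sheet propensity.  The widely used seven-parameter
# representation; columns are z-standardized over the 20 residues before use.
#' @keywords internal
PHYSCHEM_RAW <- matrix(c(
  # steric, polar, volume, hydroph, iso_pt, helix, sheet
  1.28, 0.05, 1.00,  0.31, 6.11, 0.42, 0.23,  # A
  1.77, 0.13, 2.43,  1.54, 6.35, 0.17, 0.41,  # C
  1.60, 0.11, 2.78, -0.77, 2.95, 0.25, 0.20,  # D
  1.56, 0.15, 3.78, -0.64, 3.09, 0.42, 0.21,  # E
  2.94, 0.29, 5.89,  1.79, 5.67, 0.30, 0.38,  # F
  0.00, 0.00, 0.00,  0.00, 6.07, 0.13, 0.15,  # G
  2.99, 0.23, 4.66,  0.13, 7.69, 0.27, 0.30,  # H
  4.19, 0.19, 4.00,  1.80, 6.04, 0.30, 0.45,  # I
  1.89, 0.22, 4.77, -0.99, 9.99, 0.32, 0.27,  # K
  2.59, 0.19, 4.00,  1.70, 6.04, 0.39, 0.31,  # L
  2.35, 0.22, 4.43,  1.23, 5.71, 0.38, 0.32,  # M
  1.60, 0.13, 2.95, -0.60, 6.52, 0.21, 0.22,  # N
  2.67, 0.00, 2.72,  0.72, 6.80, 0.13, 0.34,  # P
  1.56, 0.18, 3.95, -0.22, 5.65, 0.36, 0.25,  # Q
  2.34, 0.29, 6.13, -1.01, 10.74, 0.36, 0.25, # R
  1.31, 0.06, 1.60, -0.04, 5.70, 0.20, 0.28,  # S
  3.03, 0.11, 2.60,  0.26, 5.60, 0.21, 0.36,  # T
  3.67, 0.14, 3.00,  1.22, 6.02, 0.27, 0.49,  # V
  3.21, 0.41, 8.08,  2.25, 5.94, 0.32, 0.42,  # W
  2.94, 0.30, 6.47,  0.96, 5.66, 0.25, 0.41   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(AA_ALPHABET,
                  c("steric", "polarizability", "volume", "hydrophobicity",
                    "isoelectric", "helix_prop", "sheet_prop")))

#' Standardized physicochemical property table
#'
#' Returns the packaged 20 x 7 table of per-residue physicochemical
#' parameters with each column z-standardized (zero mean, unit variance over
#' the 20 residues).  Any table of the same shape may be passed to
#' [assemble_features()] in its place.
#'
#' @return A 20 x 7 numeric matrix, rows named by one-letter residue code.
#' @export
aa_physchem <- function() {
  scale(PHYSCHEM_RAW)[, , drop = FALSE]
}
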