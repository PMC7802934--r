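# Amino-acid reference tables used throughout the package.
# All tables are keyed by one-letter code over the 20 standard residues.

#' @keywords internal
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

# PSI-BLAST ASCII PSSM column order (fixed alphabet).
PSSM_ALPHABET <- AA1

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"  # selenomethionine normalised to MET
)

AA1TO3 <- setNames(names(AA3TO1)[1:20], AA3TO1[1:20])

# Residue classes used by the composition and window features.
AA_AROMATIC    <- c("F", "W", "Y")
AA_CHARGED     <- c("R", "K", "D", "E")
AA_HYDROPHOBIC <- c("V", "I", "L", "F", "M", "W", "Y", "C")

#' Maximum solvent accessibility reference (extended tripeptide)
#'
#' Per-residue solvent accessible surface area (A^2) of residue X in an
#' extended Gly-X-Gly tripeptide (Miller et al. 1987 lineage), used as the
#' denominator of relative SASA.  Override via the `reference_table`
#' argument of [relative_sasa()].
#'
#' @return Named numeric vector over the 20 one-letter amino-acid codes.
#' @export
max_asa_reference <- function() {
  c(A = 113, R = 241, N = 158, D = 151, C = 140,
    Q = 189, E = 183, G =  85, H = 194, I = 182,
    L = 180, K = 211, M = 204, F = 218, P = 143,
    S = 122, T = 146, W = 259, Y = 229, V = 160)
}

#' Optimal matching hydrophobicity (OMH) scale
#'
#' Per-residue hydrophobicity derived from observed amino-acid replacement
#' frequencies among related structures (Sweet & Eisenberg 1983).  Used by
#' [delta_omh()]; override via its `scale` argument.
#'
#' @return Named numeric vector over the 20 one-letter amino-acid codes.
#' @export
omh_scale <- function() {
  c(A = -0.40, R = -0.59, N = -0.92, D = -1.31, C =  0.17,
    Q = -0.91, E = -1.22, G = -0.67, H = -0.64, I =  1.25,
    L =  1.22, K = -0.67, M =  1.02, F =  1.92, P = -0.49,
    S = -0.55, T = -0.28, W =  0.50, Y =  0.23, V =  0.91)
}

# Van der Waals radii (A) by element for SASA; Chothia-type set.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
               P = 1.80, H = 1.20)
VDW_DEFAULT <- 1.80

# Canonical order of the ten model features.
FEATURE_NAMES <- c("PSSM", "dCS", "dOMH", "SASA_pro", "SASA_sol",
                   "P_FWY", "P_RKDE", "P_L", "N_Hydro", "N_Charg")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mutstab <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mutstab_error")))
}
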