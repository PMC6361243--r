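# Amino-acid constant tables shared across modules.

#' Residue alphabet used for one-hot identity encoding
#'
#' The 22-symbol alphabet: the 20 standard amino acids in alphabetical
#' one-letter order, then `X` (unknown / nonstandard) at position 21 and the
#' gap symbol `-` at position 22.  The gap slot is reserved for sliding-window
#' padding beyond chain termini.
#'
#' @format Character vector of length 22.
#' @export
AA_ALPHABET22 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                   "X", "-")

# 20 standard residues (alphabetical one-letter order), used for profile columns
AA20 <- AA_ALPHABET22[1:20]

# Three-letter -> one-letter mapping. MSE (selenomethionine) maps to M; any
# three-letter code not listed maps to X.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

# Kyte-Doolittle hydropathy scale (kcal/mol-free units); X and gap get 0.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3,
  X =  0.0, `-` = 0.0
)

# Theoretical maximum accessible surface area per residue type (A^2),
# Tien et al. 2013 theoretical values; used to normalize SASA to [0,1].
MAX_ASA <- c(
  A = 129, C = 167, D = 193, E = 223, F = 240,
  G = 104, H = 224, I = 197, K = 236, L = 201,
  M = 224, N = 195, P = 159, Q = 225, R = 274,
  S = 155, T = 172, V = 174, W = 285, Y = 263,
  X = 197
)

# van der Waals radii (A) by element for SASA; default used for rare elements.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90, P = 1.80)
VDW_DEFAULT <- 1.70

# Uniform background frequencies over the 20 standard residues.
AA_BACKGROUND <- setNames(rep(1 / 20, 20), AA20)

# BLOSUM62 rows restricted to the 20-letter alphabet, taken from Biostrings'
# shipped substitution matrices; cached after first use.
.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62[AA20, AA20]
  }
  .pkg_cache$blosum62
}

# Map three-letter residue names to one-letter codes (MSE -> M, unknown -> X).
three_to_one <- function(resid3) {
  out <- AA_THREE_TO_ONE[toupper(resid3)]
  out[is.na(out)] <- "X"
  unname(out)
}
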