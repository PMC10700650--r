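# Amino-acid reference data shared across modules.

#' The 20 standard amino acids (one-letter codes)
#'
#' Ordered alphabetically; this ordering fixes the column order of PSSM score
#' matrices and of background-frequency vectors.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), unname(AA_THREE_TO_ONE))

#' @param resname character vector of 3-letter residue names
#' @return one-letter codes; unknown residue types render as "X"
#' @rdname aa-tables
#' @export
aa3to1 <- function(resname) {
  out <- AA_THREE_TO_ONE[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Amino-acid code conversion and reference tables
#'
#' `aa3to1()`/`aa1to3()` convert between 3- and 1-letter codes (unknowns map
#' to `"X"`/`NA`). `max_sasa_reference()` returns theoretical Gly-X-Gly
#' maximum accessible surface areas (A^2) used to normalize relative SASA.
#' `residue_volumes()` returns standard residue volumes (A^3) used by the
#' cavity-creation proxy rule.
#'
#' @param aa character vector of 1-letter codes
#' @rdname aa-tables
#' @export
aa1to3 <- function(aa) {
  unname(AA_ONE_TO_THREE[toupper(aa)])
}

# van der Waals radii (Angstrom) by element; Bondi-style values.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, H = 1.20, D = 1.20)
VDW_DEFAULT <- 1.70

vdw_radius <- function(element, radii = VDW_RADII) {
  r <- radii[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# Theoretical maximum SASA in a Gly-X-Gly tripeptide (A^2), Tien et al. style.
MAX_SASA_GXG <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167,
  E = 223, Q = 225, G = 104, H = 224, I = 197,
  L = 201, K = 236, M = 224, F = 240, P = 159,
  S = 155, T = 172, W = 285, Y = 263, V = 174
)

#' @rdname aa-tables
#' @export
max_sasa_reference <- function() MAX_SASA_GXG

# Standard residue volumes (A^3), Zamyatnin-style values.
RESIDUE_VOLUME <- c(
  A = 88.6,  R = 173.4, N = 114.1, D = 111.1, C = 108.5,
  Q = 143.8, E = 138.4, G = 60.1,  H = 153.2, I = 166.7,
  L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
  S = 89.0,  T = 116.1, W = 227.8, Y = 193.6, V = 140.0
)

#' @rdname aa-tables
#' @export
residue_volumes <- function() RESIDUE_VOLUME

#' Hydrophobic amino acids used by the exposure rule and contact term
#' @export
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C")

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
# Atom names excluded from the clash sum between sequence-adjacent residues
# (covalent/1-3 geometry, plus CB whose 1-4 contacts are near-constant).
ADJACENT_EXCLUDED_ATOMS <- c("N", "CA", "C", "O", "CB")

# Side-chain hydrogen-bond chemistry: donors carry their antecedent heavy
# atom (needed for the antecedent-donor-acceptor angle test).
SC_DONORS <- data.frame(
  resname = c("SER", "THR", "CYS", "TYR", "ASN", "GLN", "LYS",
              "ARG", "ARG", "ARG", "HIS", "HIS", "TRP"),
  atom    = c("OG", "OG1", "SG", "OH", "ND2", "NE2", "NZ",
              "NE", "NH1", "NH2", "ND1", "NE2", "NE1"),
  antecedent = c("CB", "CB", "CB", "CZ", "CG", "CD", "CE",
                 "CD", "CZ", "CZ", "CG", "CD2", "CD1"),
  stringsAsFactors = FALSE
)

SC_ACCEPTORS <- data.frame(
  resname = c("SER", "THR", "TYR", "ASN", "GLN", "ASP", "ASP",
              "GLU", "GLU", "HIS", "HIS"),
  atom    = c("OG", "OG1", "OH", "OD1", "OE1", "OD1", "OD2",
              "OE1", "OE2", "ND1", "NE2"),
  stringsAsFactors = FALSE
)

# Role availability per amino acid (side chain only), for the
# unsatisfied-hydrogen-bond rule.
SC_DONOR_AA    <- sort(unique(aa3to1(SC_DONORS$resname)))
SC_ACCEPTOR_AA <- sort(unique(aa3to1(SC_ACCEPTORS$resname)))
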