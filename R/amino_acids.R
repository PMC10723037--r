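# Amino-acid lookup tables used across the feature pipeline.

# 3-letter -> 1-letter, including common non-standard parents.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  # non-standard residues mapped to their parent amino acid
  MSE = "M", SEC = "C", PYL = "K", SEP = "S", TPO = "T",
  PTR = "Y", HYP = "P", MLY = "K", CSO = "C", KCX = "K"
)

aa_three_to_one <- function(resid) {
  out <- AA_THREE_TO_ONE[toupper(resid)]
  out[is.na(out)] <- "X"
  unname(out)
}

# Theoretical maximum accessible surface areas (Tien et al. 2013), Angstrom^2.
MAX_ASA_TIEN <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167,
  Q = 225, E = 223, G = 104, H = 224, I = 197,
  L = 201, K = 236, M = 224, F = 240, P = 159,
  S = 155, T = 172, W = 285, Y = 263, V = 174
)

max_asa_for <- function(aa, table = MAX_ASA_TIEN) {
  out <- table[aa]
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown residue type(s) ", paste(unique(aa[unknown]), collapse = ","),
            "; using glycine maximal ASA")
    out[unknown] <- table[["G"]]
  }
  unname(out)
}

# Van der Waals radii (Angstrom) for backbone atom types; CA treated as
# generic carbon. Used by the internal Shrake-Rupley accessibility code.
VDW_RADII <- c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52, CB = 1.70)

# Residue-envelope pseudo-atom radius for CA-only traces: sized so that an
# isolated average residue reaches its maximal ASA (coarse side-chain proxy).
CA_PSEUDO_RADIUS <- 2.8
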