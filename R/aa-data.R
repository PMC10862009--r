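## Amino-acid reference tables shared across modules.

#' @keywords internal
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' @keywords internal
AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

## Standard heavy-atom composition (PDB atom names) beyond the backbone
## (N, CA, C, O).  GLY has no side chain; all others start at CB.
#' @keywords internal
AA_SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

## Bond-graph depth of each side-chain atom beyond CB (CG = 1, ...);
## used for schematic side-chain placement with realistic radial reach.
#' @keywords internal
AA_SIDECHAIN_DEPTH <- list(
  ALA = c(),
  ARG = c(CG = 1, CD = 2, NE = 3, CZ = 4, NH1 = 5, NH2 = 5),
  ASN = c(CG = 1, OD1 = 2, ND2 = 2),
  ASP = c(CG = 1, OD1 = 2, OD2 = 2),
  CYS = c(SG = 1),
  GLN = c(CG = 1, CD = 2, OE1 = 3, NE2 = 3),
  GLU = c(CG = 1, CD = 2, OE1 = 3, OE2 = 3),
  GLY = c(),
  HIS = c(CG = 1, ND1 = 2, CD2 = 2, CE1 = 3, NE2 = 3),
  ILE = c(CG1 = 1, CG2 = 1, CD1 = 2),
  LEU = c(CG = 1, CD1 = 2, CD2 = 2),
  LYS = c(CG = 1, CD = 2, CE = 3, NZ = 4),
  MET = c(CG = 1, SD = 2, CE = 3),
  PHE = c(CG = 1, CD1 = 2, CD2 = 2, CE1 = 3, CE2 = 3, CZ = 4),
  PRO = c(CG = 1, CD = 2),
  SER = c(OG = 1),
  THR = c(OG1 = 1, CG2 = 1),
  TRP = c(CG = 1, CD1 = 2, CD2 = 2, NE1 = 3, CE2 = 3, CE3 = 3,
          CZ2 = 4, CZ3 = 4, CH2 = 5),
  TYR = c(CG = 1, CD1 = 2, CD2 = 2, CE1 = 3, CE2 = 3, CZ = 4, OH = 5),
  VAL = c(CG1 = 1, CG2 = 1)
)

## Apolar residues used for hydrophobic-contact and core detection.
#' @keywords internal
HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET",
                          "PHE", "TRP", "TYR", "PRO")

#' @keywords internal
AA_FORMAL_CHARGE <- c(
  ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0,
  GLN = 0, GLU = -1, GLY = 0, HIS = 0, ILE = 0,
  LEU = 0, LYS = 1, MET = 0, PHE = 0, PRO = 0,
  SER = 0, THR = 0, TRP = 0, TYR = 0, VAL = 0
)

#' Map three-letter residue names to one-letter codes
#'
#' Unknown residue names map to \code{"X"}.
#'
#' @param res_name character vector of three-letter residue names.
#' @return character vector of one-letter codes.
#' @keywords internal
aa_three_to_one <- function(res_name) {
  out <- AA_THREE_TO_ONE[toupper(res_name)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' @keywords internal
aa_one_to_three <- function(code) {
  out <- AA_ONE_TO_THREE[toupper(code)]
  if (anyNA(out)) {
    stop("invalid one-letter amino-acid code(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' @keywords internal
element_of_atom <- function(atom_name) {
  ## PDB heavy-atom names start with the element letter; amide H is "H".
  substr(gsub("[0-9]", "", atom_name), 1L, 1L)
}
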