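# Chemistry reference tables: per-residue donor/acceptor atoms, charged
# groups, aromatic ring systems, and per-element van der Waals radii.
# Covers the 20 standard amino acids and the standard RNA/DNA nucleotides.

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

RNA_NUCLEOTIDES <- c("A", "C", "G", "U")
DNA_NUCLEOTIDES <- c("DA", "DC", "DG", "DT")
NUCLEOTIDES <- c(RNA_NUCLEOTIDES, DNA_NUCLEOTIDES)

# Sidechain hydrogen-bond donors: donor heavy atom -> covalent antecedent.
# The backbone amide N (antecedent CA) is added programmatically for every
# amino acid except proline, which carries no amide hydrogen.
SIDECHAIN_DONORS <- list(
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  ASN = c(ND2 = "CG"),
  GLN = c(NE2 = "CD"),
  HIS = c(ND1 = "CG", NE2 = "CE1"),
  LYS = c(NZ = "CE"),
  SER = c(OG = "CB"),
  THR = c(OG1 = "CB"),
  TRP = c(NE1 = "CE2"),
  TYR = c(OH = "CZ"),
  # nucleotide base amino/imino nitrogens and the ribose 2'-hydroxyl
  A   = c(N6 = "C6", `O2'` = "C2'"),
  C   = c(N4 = "C4", `O2'` = "C2'"),
  G   = c(N1 = "C6", N2 = "C2", `O2'` = "C2'"),
  U   = c(N3 = "C4", `O2'` = "C2'"),
  DA  = c(N6 = "C6"),
  DC  = c(N4 = "C4"),
  DG  = c(N1 = "C6", N2 = "C2"),
  DT  = c(N3 = "C4")
)

# Sidechain hydrogen-bond acceptors. The backbone carbonyl O (and terminal
# OXT when present) is added programmatically for every amino acid.
SIDECHAIN_ACCEPTORS <- list(
  ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1",
  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), MET = "SD",
  SER = "OG", THR = "OG1", TYR = "OH",
  A   = c("N1", "N3", "N7", "OP1", "OP2", "O2'", "O3'", "O4'", "O5'"),
  C   = c("O2", "N3", "OP1", "OP2", "O2'", "O3'", "O4'", "O5'"),
  G   = c("O6", "N3", "N7", "OP1", "OP2", "O2'", "O3'", "O4'", "O5'"),
  U   = c("O2", "O4", "OP1", "OP2", "O2'", "O3'", "O4'", "O5'"),
  DA  = c("N1", "N3", "N7", "OP1", "OP2", "O3'", "O4'", "O5'"),
  DC  = c("O2", "N3", "OP1", "OP2", "O3'", "O4'", "O5'"),
  DG  = c("O6", "N3", "N7", "OP1", "OP2", "O3'", "O4'", "O5'"),
  DT  = c("O2", "O4", "OP1", "OP2", "O3'", "O4'", "O5'")
)

# Formally charged sidechain groups (atom sets whose centroid carries the
# charge). Histidine's imidazolium is optional: its protonation state is
# unknowable without hydrogens, so it is cationic only on request.
CATIONIC_GROUPS <- list(
  LYS = list(c("NZ")),
  ARG = list(c("CZ", "NE", "NH1", "NH2"))
)
HIS_CATIONIC_GROUP <- list(c("CG", "ND1", "CD2", "CE1", "NE2"))

ANIONIC_GROUPS <- list(
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2"))
)
# Nucleotide phosphates count as anionic groups.
PHOSPHATE_GROUP <- list(c("OP1", "OP2"))

# Aromatic ring systems (atom name sets). Tryptophan and the purines
# contribute two fused rings, each treated as an independent pi system.
AROMATIC_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  A   = list(c("N7", "C8", "N9", "C4", "C5"),
             c("N1", "C2", "N3", "C4", "C5", "C6")),
  G   = list(c("N7", "C8", "N9", "C4", "C5"),
             c("N1", "C2", "N3", "C4", "C5", "C6")),
  C   = list(c("N1", "C2", "N3", "C4", "C5", "C6")),
  U   = list(c("N1", "C2", "N3", "C4", "C5", "C6"))
)
AROMATIC_RINGS$DA <- AROMATIC_RINGS$A
AROMATIC_RINGS$DG <- AROMATIC_RINGS$G
AROMATIC_RINGS$DC <- AROMATIC_RINGS$C
AROMATIC_RINGS$DT <- AROMATIC_RINGS$U

# Van der Waals radii by element symbol (Angstrom), Bondi-style values.
VDW_RADII <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT_RADIUS <- 1.70

#' Default chemistry table
#'
#' Assembles the residue chemistry used by the interaction detectors:
#' hydrogen-bond donors (with their covalent antecedent atom), acceptors,
#' cationic and anionic groups, aromatic ring atom sets, and van der Waals
#' radii per element. Amino acids and standard RNA/DNA nucleotides are
#' covered; unknown residue names simply contribute no typed chemistry
#' (they remain visible to the van der Waals detector).
#'
#' @param his_cation logical; treat histidine's imidazole as a cationic
#'   group. Off by default because the protonation state is unknown
#'   without hydrogens.
#' @return object of class `rin_chemistry`: a list with elements
#'   `donors`, `acceptors`, `cations`, `anions`, `rings`, `vdw_radii`,
#'   `vdw_default`, `his_cation`.
#' @export
#' @examples
#' chem <- default_chemistry()
#' chem$donors$LYS
default_chemistry <- function(his_cation = FALSE) {
  donors <- SIDECHAIN_DONORS
  acceptors <- SIDECHAIN_ACCEPTORS
  for (aa in AMINO_ACIDS) {
    d <- donors[[aa]] %||% character(0)
    if (aa != "PRO") d <- c(d, c(N = "CA"))
    donors[[aa]] <- d
    acceptors[[aa]] <- c(acceptors[[aa]] %||% character(0), "O", "OXT")
  }
  cations <- CATIONIC_GROUPS
  if (his_cation) cations$HIS <- HIS_CATIONIC_GROUP
  anions <- ANIONIC_GROUPS
  for (nt in NUCLEOTIDES) anions[[nt]] <- PHOSPHATE_GROUP
  structure(list(
    donors = donors,
    acceptors = acceptors,
    cations = cations,
    anions = anions,
    rings = AROMATIC_RINGS,
    vdw_radii = VDW_RADII,
    vdw_default = VDW_DEFAULT_RADIUS,
    his_cation = his_cation
  ), class = "rin_chemistry")
}

# Polymer class of a residue name: amino_acid, nucleotide or other.
polymer_class_of <- function(resname) {
  out <- rep("other", length(resname))
  out[resname %in% AMINO_ACIDS] <- "amino_acid"
  out[resname %in% NUCLEOTIDES] <- "nucleotide"
  out
}

# vdW radius lookup for a vector of element symbols.
vdw_radius_of <- function(element, chemistry) {
  r <- chemistry$vdw_radii[toupper(element)]
  r[is.na(r)] <- chemistry$vdw_default
  unname(r)
}
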