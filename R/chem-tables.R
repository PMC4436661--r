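# Chemical reference tables for RNA nucleotides.
#
# Atom names follow current PDB convention (primed sugar atoms, OP1/OP2).
# All tables are keyed by the parent base letter A/C/G/U.

# purine / pyrimidine ring systems used for base frames and annotation
.ring_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.glyco_n <- c(A = "N9", G = "N9", C = "N1", U = "N1")

# ring atom bonded to the glycosidic nitrogen along the chi path
# (C4 for purines, C2 for pyrimidines); also the reference for frame chirality
.chi_ref <- c(A = "C4", G = "C4", C = "C2", U = "C2")

# hydrogen-bonding (N/O) atoms on each Leontis-Westhof edge; O2' joins the
# sugar edge.  Atoms shared between edges (O6, N6, O2, N4) appear twice;
# ties in edge assignment resolve W > H > S.
.edge_atoms <- list(
  A = list(W = c("N1", "N6"), H = c("N7", "N6"), S = c("N3", "O2'")),
  G = list(W = c("N1", "N2", "O6"), H = c("N7", "O6"), S = c("N3", "N2", "O2'")),
  C = list(W = c("N3", "N4", "O2"), H = c("N4"), S = c("O2", "O2'")),
  U = list(W = c("N3", "O2", "O4"), H = c("O4"), S = c("O2", "O2'"))
)

# intra-residue covalent bonds between heavy atoms
.sugar_bonds <- matrix(c(
  "P", "OP1",  "P", "OP2",  "P", "O5'",  "O5'", "C5'",  "C5'", "C4'",
  "C4'", "O4'", "C4'", "C3'", "O4'", "C1'", "C3'", "C2'", "C3'", "O3'",
  "C2'", "C1'", "C2'", "O2'"
), ncol = 2, byrow = TRUE)

.purine_ring_bonds <- matrix(c(
  "N9", "C8", "C8", "N7", "N7", "C5", "C5", "C6", "C6", "N1",
  "N1", "C2", "C2", "N3", "N3", "C4", "C4", "C5", "C4", "N9"
), ncol = 2, byrow = TRUE)

.pyrimidine_ring_bonds <- matrix(c(
  "N1", "C2", "C2", "N3", "N3", "C4", "C4", "C5", "C5", "C6", "C6", "N1"
), ncol = 2, byrow = TRUE)

.base_bonds <- list(
  A = rbind(.purine_ring_bonds, c("C6", "N6"), c("C1'", "N9")),
  G = rbind(.purine_ring_bonds, c("C6", "O6"), c("C2", "N2"), c("C1'", "N9")),
  C = rbind(.pyrimidine_ring_bonds, c("C2", "O2"), c("C4", "N4"), c("C1'", "N1")),
  U = rbind(.pyrimidine_ring_bonds, c("C2", "O2"), c("C4", "O4"), c("C1'", "N1"))
)

residue_bonds <- function(base) {
  if (is.na(base) || !base %in% names(.base_bonds)) return(.sugar_bonds)
  rbind(.sugar_bonds, .base_bonds[[base]])
}

# van der Waals radii (Angstrom) used by the clash detector
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, H = 1.20)

# modified nucleotides mapped to their parent base; extensible through the
# `modified_map` argument of read_pdb()
.modified_bases <- c(
  PSU = "U", H2U = "U", "5MU" = "U", "4SU" = "U", OMU = "U", UR3 = "U",
  "1MA" = "A", A2M = "A", MA6 = "A", "2MA" = "A",
  "5MC" = "C", OMC = "C", "4OC" = "C",
  "1MG" = "G", "2MG" = "G", M2G = "G", "7MG" = "G", OMG = "G", YG = "G",
  QUO = "G", G7M = "G"
)

.water_names <- c("HOH", "WAT", "DOD", "H2O", "SOL")

.rna_complement <- c(A = "U", C = "G", G = "C", U = "A")

# atom-name sets for superposition selections
.backbone_atoms <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                     "C3'", "O3'", "C2'", "O2'", "C1'")

selection_filter <- function(atoms, selection) {
  switch(selection,
    "all-heavy" = atoms[atoms$elem != "H", , drop = FALSE],
    "backbone"  = atoms[atoms$atom %in% .backbone_atoms, , drop = FALSE],
    "c1-prime"  = atoms[atoms$atom == "C1'", , drop = FALSE],
    "phosphate" = atoms[atoms$atom == "P", , drop = FALSE],
    abort(paste0("unknown selection '", selection, "'"))
  )
}
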