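# Residue topology compiled into the package: ideal side-chain internal
# coordinates, van der Waals radii, hydrogen-bond donor/acceptor chemistry
# and polar-hydrogen placement rules. One published-style union-radii set
# and one ideal-geometry set are pinned here for reproducibility; they are
# not configurable.

.AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.AA_1TO3 <- setNames(names(.AA_3TO1), .AA_3TO1)

.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
.VDW_DEFAULT <- 1.70

.vdwRadius <- function(element) {
  r <- .VDW_RADII[element]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# Improper dihedral C-N-CA-CB placing CB with L-chirality, and the CB
# internal coordinates shared by all non-GLY residues.
.CB_SPEC <- list(name = "CB", a = "C", b = "N", c = "CA",
                 len = 1.530, ang = 110.4, tors = 122.6)

# Side-chain heavy atoms beyond CB. Each entry: atom name, the three
# reference atoms (a, b, c; the new atom bonds to c), bond length, bond
# angle, and the torsion rule: list(chi = k, offset = deg) for rotatable
# bonds or a fixed dihedral in degrees (planar/ring geometry).
.SIDECHAIN <- list(
  ALA = list(),
  GLY = list(),
  SER = list(
    list("OG",  "N", "CA", "CB", 1.417, 110.8, list(chi = 1, offset = 0))),
  CYS = list(
    list("SG",  "N", "CA", "CB", 1.808, 113.8, list(chi = 1, offset = 0))),
  THR = list(
    list("OG1", "N", "CA", "CB", 1.433, 109.6, list(chi = 1, offset = 0)),
    list("CG2", "N", "CA", "CB", 1.521, 110.5, list(chi = 1, offset = -120))),
  VAL = list(
    list("CG1", "N", "CA", "CB", 1.527, 110.5, list(chi = 1, offset = 0)),
    list("CG2", "N", "CA", "CB", 1.527, 110.5, list(chi = 1, offset = 120))),
  LEU = list(
    list("CG",  "N", "CA", "CB", 1.530, 116.3, list(chi = 1, offset = 0)),
    list("CD1", "CA", "CB", "CG", 1.521, 110.7, list(chi = 2, offset = 0)),
    list("CD2", "CA", "CB", "CG", 1.521, 110.7, list(chi = 2, offset = 120))),
  ILE = list(
    list("CG1", "N", "CA", "CB", 1.530, 110.4, list(chi = 1, offset = 0)),
    list("CG2", "N", "CA", "CB", 1.521, 110.5, list(chi = 1, offset = -120)),
    list("CD1", "CA", "CB", "CG1", 1.513, 113.8, list(chi = 2, offset = 0))),
  ASP = list(
    list("CG",  "N", "CA", "CB", 1.516, 112.6, list(chi = 1, offset = 0)),
    list("OD1", "CA", "CB", "CG", 1.249, 118.4, list(chi = 2, offset = 0)),
    list("OD2", "CA", "CB", "CG", 1.249, 118.4, list(chi = 2, offset = 180))),
  ASN = list(
    list("CG",  "N", "CA", "CB", 1.516, 112.6, list(chi = 1, offset = 0)),
    list("OD1", "CA", "CB", "CG", 1.231, 120.8, list(chi = 2, offset = 0)),
    list("ND2", "CA", "CB", "CG", 1.328, 116.4, list(chi = 2, offset = 180))),
  GLU = list(
    list("CG",  "N", "CA", "CB", 1.520, 114.1, list(chi = 1, offset = 0)),
    list("CD",  "CA", "CB", "CG", 1.516, 112.6, list(chi = 2, offset = 0)),
    list("OE1", "CB", "CG", "CD", 1.249, 118.4, list(chi = 3, offset = 0)),
    list("OE2", "CB", "CG", "CD", 1.249, 118.4, list(chi = 3, offset = 180))),
  GLN = list(
    list("CG",  "N", "CA", "CB", 1.520, 114.1, list(chi = 1, offset = 0)),
    list("CD",  "CA", "CB", "CG", 1.516, 112.6, list(chi = 2, offset = 0)),
    list("OE1", "CB", "CG", "CD", 1.231, 120.8, list(chi = 3, offset = 0)),
    list("NE2", "CB", "CG", "CD", 1.328, 116.4, list(chi = 3, offset = 180))),
  MET = list(
    list("CG",  "N", "CA", "CB", 1.520, 114.1, list(chi = 1, offset = 0)),
    list("SD",  "CA", "CB", "CG", 1.803, 112.7, list(chi = 2, offset = 0)),
    list("CE",  "CB", "CG", "SD", 1.791, 100.9, list(chi = 3, offset = 0))),
  LYS = list(
    list("CG",  "N", "CA", "CB", 1.520, 114.1, list(chi = 1, offset = 0)),
    list("CD",  "CA", "CB", "CG", 1.520, 111.3, list(chi = 2, offset = 0)),
    list("CE",  "CB", "CG", "CD", 1.520, 111.3, list(chi = 3, offset = 0)),
    list("NZ",  "CG", "CD", "CE", 1.489, 111.9, list(chi = 4, offset = 0))),
  ARG = list(
    list("CG",  "N", "CA", "CB", 1.520, 114.1, list(chi = 1, offset = 0)),
    list("CD",  "CA", "CB", "CG", 1.520, 111.3, list(chi = 2, offset = 0)),
    list("NE",  "CB", "CG", "CD", 1.461, 112.0, list(chi = 3, offset = 0)),
    list("CZ",  "CG", "CD", "NE", 1.329, 124.2, list(chi = 4, offset = 0)),
    list("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
    list("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  PHE = list(
    list("CG",  "N", "CA", "CB", 1.502, 113.8, list(chi = 1, offset = 0)),
    list("CD1", "CA", "CB", "CG", 1.384, 120.8, list(chi = 2, offset = 0)),
    list("CD2", "CA", "CB", "CG", 1.384, 120.8, list(chi = 2, offset = 180)),
    list("CE1", "CB", "CG", "CD1", 1.382, 120.8, 180),
    list("CE2", "CB", "CG", "CD2", 1.382, 120.8, 180),
    list("CZ",  "CG", "CD1", "CE1", 1.382, 120.0, 0)),
  TYR = list(
    list("CG",  "N", "CA", "CB", 1.512, 113.9, list(chi = 1, offset = 0)),
    list("CD1", "CA", "CB", "CG", 1.389, 120.8, list(chi = 2, offset = 0)),
    list("CD2", "CA", "CB", "CG", 1.389, 120.8, list(chi = 2, offset = 180)),
    list("CE1", "CB", "CG", "CD1", 1.382, 121.1, 180),
    list("CE2", "CB", "CG", "CD2", 1.382, 121.1, 180),
    list("CZ",  "CG", "CD1", "CE1", 1.378, 119.5, 0),
    list("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = list(
    list("CG",  "N", "CA", "CB", 1.498, 113.6, list(chi = 1, offset = 0)),
    list("CD1", "CA", "CB", "CG", 1.365, 126.9, list(chi = 2, offset = 0)),
    list("CD2", "CA", "CB", "CG", 1.433, 126.6, list(chi = 2, offset = 180)),
    list("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180),
    list("CE2", "CB", "CG", "CD2", 1.409, 107.2, 180),
    list("CE3", "CD1", "CG", "CD2", 1.398, 133.9, 180),
    list("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180),
    list("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180),
    list("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 180)),
  HIS = list(
    list("CG",  "N", "CA", "CB", 1.497, 113.7, list(chi = 1, offset = 0)),
    list("ND1", "CA", "CB", "CG", 1.371, 122.7, list(chi = 2, offset = 0)),
    list("CD2", "CA", "CB", "CG", 1.356, 131.0, list(chi = 2, offset = 180)),
    list("CE1", "CB", "CG", "ND1", 1.319, 109.0, 180),
    list("NE2", "CB", "CG", "CD2", 1.374, 107.0, 180)),
  PRO = list(
    list("CG",  "N", "CA", "CB", 1.492, 104.5, list(chi = 1, offset = 0)),
    list("CD",  "CA", "CB", "CG", 1.503, 106.1, list(chi = 2, offset = 0)))
)

.N_CHI <- vapply(.SIDECHAIN, function(specs) {
  ks <- vapply(specs, function(sp) {
    if (is.list(sp[[7L]])) sp[[7L]]$chi else 0L
  }, numeric(1))
  as.integer(max(0, ks))
}, integer(1))

# Hydrogen-bond chemistry: side-chain donor/acceptor heavy atoms by
# residue. Backbone N (non-PRO) donates and backbone O/OXT accept for
# every residue; water O both donates and accepts; hetero (ligand) O/N
# accept, and donate only when a hydrogen is attached.
.SC_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2", TRP = "NE1",
  HIS = c("ND1", "NE2"))

.SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

# Polar-hydrogen placement rules per residue (side chains; the backbone
# amide H is handled generically). type:
#   hydroxyl   - torsion chosen toward the nearest acceptor (cone
#                projection), else anti to `anti`
#   sp2_bisector - one H opposite the bisector of two heavy neighbours
#   sp2_pair   - two in-plane H (amide / guanidinium)
#   sp3_three  - three staggered H (ammonium)
.POLAR_H <- list(
  SER = list(list(h = "HG",  type = "hydroxyl", parent = "OG",  sup = "CB",
                  anti = "CA", len = 0.96)),
  THR = list(list(h = "HG1", type = "hydroxyl", parent = "OG1", sup = "CB",
                  anti = "CA", len = 0.96)),
  TYR = list(list(h = "HH",  type = "hydroxyl", parent = "OH",  sup = "CZ",
                  anti = "CE1", len = 0.96)),
  CYS = list(list(h = "HG",  type = "hydroxyl", parent = "SG",  sup = "CB",
                  anti = "CA", len = 1.34)),
  LYS = list(list(h = c("HZ1", "HZ2", "HZ3"), type = "sp3_three",
                  parent = "NZ", sup = "CE", anti = "CD", len = 1.01)),
  ARG = list(list(h = "HE", type = "sp2_bisector", parent = "NE",
                  nb = c("CD", "CZ"), len = 1.01),
             list(h = c("HH11", "HH12"), type = "sp2_pair", parent = "NH1",
                  sup = "CZ", ref = "NE", len = 1.01),
             list(h = c("HH21", "HH22"), type = "sp2_pair", parent = "NH2",
                  sup = "CZ", ref = "NE", len = 1.01)),
  ASN = list(list(h = c("HD21", "HD22"), type = "sp2_pair", parent = "ND2",
                  sup = "CG", ref = "OD1", len = 1.01)),
  GLN = list(list(h = c("HE21", "HE22"), type = "sp2_pair", parent = "NE2",
                  sup = "CD", ref = "OE1", len = 1.01)),
  TRP = list(list(h = "HE1", type = "sp2_bisector", parent = "NE1",
                  nb = c("CD1", "CE2"), len = 1.01))
)

# Bond-graph depth of an atom to the peptide-linking atoms of its own
# residue (C on the next-residue side, N on the previous-residue side).
# Side-chain atoms are resolved by their Greek letter. Used to exclude
# close bonded neighbours (graph distance <= 4 across the peptide bond)
# from clash scoring: those contacts are fixed by covalent geometry, not
# by rotamer choice.
.GREEK_DEPTH <- c(B = 0, G = 1, D = 2, E = 3, Z = 4, H = 5)

.depthToLink <- function(name, side) {
  bb <- if (side == "C") c(N = 2, CA = 1, C = 0, O = 1, OXT = 1)
        else c(N = 0, CA = 1, C = 2, O = 3, OXT = 3)
  d <- bb[name]
  sc <- is.na(d)
  if (any(sc)) {
    g <- .GREEK_DEPTH[substr(name[sc], 2, 2)]
    g[is.na(g)] <- 5
    d[sc] <- 2 + g
  }
  unname(d)
}
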