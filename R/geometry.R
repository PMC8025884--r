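# Ideal-geometry templates for the 20 standard amino acids.
#
# Each residue is described as a placement table in the N->C orientation:
# every atom is placed from its parent by a bond length, the bond angle at
# the parent, and a dihedral.  Dihedrals are organised in torsion groups
# (all children of one atom share a rotation bond): the `driver` child
# carries the group's torsion variable (phi, psi, omega, chi1..chi5, or a
# fixed template value) and the remaining children are placed at fixed
# offsets from the driver.  Branch offsets encode L-amino-acid chirality
# (C-beta at -122.6 deg from the carbonyl C about the N-CA axis).
#
# Bond lengths and angles follow the canonical protein restraint values
# (Engh & Huber style); ring-internal and sp2-terminal torsions are fixed,
# side-chain chi torsions are refinable.  All hydrogens are (re)generated at
# a bond length of 0.968 A.

H_BOND_LENGTH <- 0.968

# row constructors for the template tables
.d <- function(name, parent, l, ang, var, tor0 = NA_real_, ref = FALSE)
  data.frame(name = name, parent = parent, l = l, ang = ang,
             off = NA_real_, tor0 = tor0, var = var, ref = ref,
             stringsAsFactors = FALSE)
.m <- function(name, parent, l, ang, off)
  data.frame(name = name, parent = parent, l = l, ang = ang,
             off = off, tor0 = NA_real_, var = "", ref = FALSE,
             stringsAsFactors = FALSE)
# two geminal hydrogens on an sp3 CH2 whose heavy driver child exists
.h2 <- function(stem, parent)
  rbind(.m(paste0("H", stem, "2"), parent, H_BOND_LENGTH, 109.5, -120),
        .m(paste0("H", stem, "3"), parent, H_BOND_LENGTH, 109.5, +120))
# methyl: staggered hydrogen triple, its own (fixed) torsion group
.met <- function(stem, parent, ang = 109.5)
  rbind(.d(paste0("H", stem, "1"), parent, H_BOND_LENGTH, ang, "fixed", 180),
        .m(paste0("H", stem, "2"), parent, H_BOND_LENGTH, ang, -120),
        .m(paste0("H", stem, "3"), parent, H_BOND_LENGTH, ang, +120))

#' Residue geometry templates
#'
#' Placement tables (atom, parent, ideal bond length, bond angle, torsion
#' group structure) for the 20 standard amino acids, used to impose
#' canonical geometry, to regenerate hydrogens and to build ideal-geometry
#' synthetic peptides.  Covalent rings are opened into trees (the closing
#' bond is not represented) with fixed ring torsions.
#'
#' @return named list of data frames, one per three-letter residue code.
#' @export
residue_templates <- function() {
  if (is.null(.pkgenv$templates)) .pkgenv$templates <- .build_templates()
  .pkgenv$templates
}

.pkgenv <- new.env(parent = emptyenv())

.build_templates <- function() {
  side <- list()

  side$ALA <- .met("B", "CB")

  side$ARG <- rbind(
    .d("CG", "CB", 1.520, 114.1, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("CD", "CG", 1.520, 111.3, "chi3", 180, TRUE), .h2("G", "CG"),
    .d("NE", "CD", 1.461, 112.0, "chi4", 180, TRUE), .h2("D", "CD"),
    .d("CZ", "NE", 1.329, 124.2, "chi5", 180, TRUE),
    .m("HE", "NE", H_BOND_LENGTH, 120.0, 180),
    .d("NH1", "CZ", 1.326, 120.0, "fixed", 0),
    .m("NH2", "CZ", 1.326, 120.0, 180),
    .d("HH11", "NH1", H_BOND_LENGTH, 120.0, "fixed", 0),
    .m("HH12", "NH1", H_BOND_LENGTH, 120.0, 180),
    .d("HH21", "NH2", H_BOND_LENGTH, 120.0, "fixed", 0),
    .m("HH22", "NH2", H_BOND_LENGTH, 120.0, 180))

  side$ASN <- rbind(
    .d("CG", "CB", 1.516, 112.6, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("OD1", "CG", 1.231, 120.8, "chi3", 0, TRUE),
    .m("ND2", "CG", 1.328, 116.4, 180),
    .d("HD21", "ND2", H_BOND_LENGTH, 120.0, "fixed", 180),
    .m("HD22", "ND2", H_BOND_LENGTH, 120.0, 180))

  side$ASP <- rbind(
    .d("CG", "CB", 1.516, 112.6, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("OD1", "CG", 1.249, 118.4, "chi3", 0, TRUE),
    .m("OD2", "CG", 1.249, 118.4, 180))

  side$CYS <- rbind(
    .d("SG", "CB", 1.808, 114.0, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("HG", "SG", H_BOND_LENGTH, 96.0, "fixed", 180))

  side$GLN <- rbind(
    .d("CG", "CB", 1.520, 114.1, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("CD", "CG", 1.516, 112.6, "chi3", 180, TRUE), .h2("G", "CG"),
    .d("OE1", "CD", 1.231, 120.8, "chi4", 0, TRUE),
    .m("NE2", "CD", 1.328, 116.4, 180),
    .d("HE21", "NE2", H_BOND_LENGTH, 120.0, "fixed", 180),
    .m("HE22", "NE2", H_BOND_LENGTH, 120.0, 180))

  side$GLU <- rbind(
    .d("CG", "CB", 1.520, 114.1, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("CD", "CG", 1.516, 112.6, "chi3", 180, TRUE), .h2("G", "CG"),
    .d("OE1", "CD", 1.249, 118.4, "chi4", 0, TRUE),
    .m("OE2", "CD", 1.249, 118.4, 180))

  side$GLY <- NULL

  side$HIS <- rbind(
    .d("CG", "CB", 1.497, 113.8, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("ND1", "CG", 1.378, 122.7, "chi3", 90, TRUE),
    .m("CD2", "CG", 1.356, 131.2, 180),
    .d("CE1", "ND1", 1.321, 109.0, "fixed", 180),
    .m("HD1", "ND1", H_BOND_LENGTH, 126.0, 180),
    .d("NE2", "CE1", 1.345, 111.2, "fixed", 0),
    .m("HE1", "CE1", H_BOND_LENGTH, 124.0, 180),
    .d("HE2", "NE2", H_BOND_LENGTH, 125.0, "fixed", 180),
    .d("HD2", "CD2", H_BOND_LENGTH, 126.0, "fixed", 180))

  side$ILE <- rbind(
    .d("CG1", "CB", 1.530, 110.4, "chi2", 180, TRUE),
    .m("CG2", "CB", 1.521, 110.5, -122.6),
    .m("HB", "CB", H_BOND_LENGTH, 109.0, +119),
    .d("CD1", "CG1", 1.513, 113.8, "chi3", 180, TRUE), .h2("G1", "CG1"),
    .met("G2", "CG2"), .met("D1", "CD1"))

  side$LEU <- rbind(
    .d("CG", "CB", 1.530, 116.3, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("CD1", "CG", 1.521, 110.7, "chi3", 180, TRUE),
    .m("CD2", "CG", 1.521, 110.7, +122.6),
    .m("HG", "CG", H_BOND_LENGTH, 109.0, -119),
    .met("D1", "CD1"), .met("D2", "CD2"))

  side$LYS <- rbind(
    .d("CG", "CB", 1.520, 114.1, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("CD", "CG", 1.520, 111.3, "chi3", 180, TRUE), .h2("G", "CG"),
    .d("CE", "CD", 1.520, 111.3, "chi4", 180, TRUE), .h2("D", "CD"),
    .d("NZ", "CE", 1.489, 111.5, "chi5", 180, TRUE), .h2("E", "CE"),
    .met("Z", "NZ"))

  side$MET <- rbind(
    .d("CG", "CB", 1.520, 114.1, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("SD", "CG", 1.803, 112.7, "chi3", 180, TRUE), .h2("G", "CG"),
    .d("CE", "SD", 1.791, 100.9, "chi4", 180, TRUE),
    .met("E", "CE"))

  # proline ring: opened at CD-N; fixed ring torsions approximate closure
  side$PRO <- rbind(
    .d("CG", "CB", 1.492, 104.5, "chi2", -15.5, FALSE), .h2("B", "CB"),
    .d("CD", "CG", 1.503, 106.1, "chi3", 1, FALSE), .h2("G", "CG"),
    .d("HD2", "CD", H_BOND_LENGTH, 109.5, "fixed", 80),
    .m("HD3", "CD", H_BOND_LENGTH, 109.5, +120))

  side$PHE <- rbind(
    .d("CG", "CB", 1.505, 113.8, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("CD1", "CG", 1.390, 120.0, "chi3", 90, TRUE),
    .m("CD2", "CG", 1.390, 120.0, 180),
    .d("CE1", "CD1", 1.390, 120.0, "fixed", 180),
    .m("HD1", "CD1", H_BOND_LENGTH, 120.0, 0),
    .d("CE2", "CD2", 1.390, 120.0, "fixed", 180),
    .m("HD2", "CD2", H_BOND_LENGTH, 120.0, 0),
    .d("CZ", "CE1", 1.390, 120.0, "fixed", 0),
    .m("HE1", "CE1", H_BOND_LENGTH, 120.0, 180),
    .d("HE2", "CE2", H_BOND_LENGTH, 120.0, "fixed", 180),
    .d("HZ", "CZ", H_BOND_LENGTH, 120.0, "fixed", 180))

  side$SER <- rbind(
    .d("OG", "CB", 1.417, 111.1, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("HG", "OG", H_BOND_LENGTH, 109.5, "fixed", 180))

  side$THR <- rbind(
    .d("OG1", "CB", 1.433, 109.6, "chi2", 180, TRUE),
    .m("CG2", "CB", 1.521, 110.5, -122.6),
    .m("HB", "CB", H_BOND_LENGTH, 109.0, +119),
    .d("HG1", "OG1", H_BOND_LENGTH, 109.5, "fixed", 180),
    .met("G2", "CG2"))

  side$TRP <- rbind(
    .d("CG", "CB", 1.498, 113.6, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("CD1", "CG", 1.365, 126.9, "chi3", 90, TRUE),
    .m("CD2", "CG", 1.433, 126.6, 180),
    .d("NE1", "CD1", 1.374, 110.2, "fixed", 180),
    .m("HD1", "CD1", H_BOND_LENGTH, 125.0, 0),
    .d("HE1", "NE1", H_BOND_LENGTH, 125.0, "fixed", 180),
    .d("CE2", "CD2", 1.409, 107.2, "fixed", 0),
    .m("CE3", "CD2", 1.398, 127.0, 180),
    .d("CZ2", "CE2", 1.398, 122.4, "fixed", 180),
    .d("CZ3", "CE3", 1.392, 118.8, "fixed", 180),
    .m("HE3", "CE3", H_BOND_LENGTH, 120.0, 0),
    .d("CH2", "CZ2", 1.372, 117.5, "fixed", 0),
    .m("HZ2", "CZ2", H_BOND_LENGTH, 120.0, 180),
    .d("HZ3", "CZ3", H_BOND_LENGTH, 120.0, "fixed", 180),
    .d("HH2", "CH2", H_BOND_LENGTH, 120.0, "fixed", 180))

  side$TYR <- rbind(
    .d("CG", "CB", 1.505, 113.8, "chi2", 180, TRUE), .h2("B", "CB"),
    .d("CD1", "CG", 1.390, 120.0, "chi3", 90, TRUE),
    .m("CD2", "CG", 1.390, 120.0, 180),
    .d("CE1", "CD1", 1.390, 120.0, "fixed", 180),
    .m("HD1", "CD1", H_BOND_LENGTH, 120.0, 0),
    .d("CE2", "CD2", 1.390, 120.0, "fixed", 180),
    .m("HD2", "CD2", H_BOND_LENGTH, 120.0, 0),
    .d("CZ", "CE1", 1.390, 120.0, "fixed", 0),
    .m("HE1", "CE1", H_BOND_LENGTH, 120.0, 180),
    .d("HE2", "CE2", H_BOND_LENGTH, 120.0, "fixed", 180),
    .d("OH", "CZ", 1.376, 120.0, "fixed", 180),
    .d("HH", "OH", H_BOND_LENGTH, 109.5, "fixed", 180))

  side$VAL <- rbind(
    .d("CG1", "CB", 1.521, 110.5, "chi2", 180, TRUE),
    .m("CG2", "CB", 1.521, 110.5, -122.6),
    .m("HB", "CB", H_BOND_LENGTH, 109.0, +119),
    .met("G1", "CG1"), .met("G2", "CG2"))

  res <- list()
  for (code in c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")) {
    bb <- rbind(
      .d("N", "-C", 1.329, 116.2, "psi", NA, TRUE),
      .d("CA", "N", 1.458, 121.7, "omega", 180, FALSE),
      .d("C", "CA", 1.525, 111.2, "phi", NA, TRUE),
      .m("O", "C", 1.231, 120.8, 180))
    if (code != "PRO")
      bb <- rbind(bb, .m("H", "N", H_BOND_LENGTH, 119.3, 180))
    if (code == "GLY") {
      bb <- rbind(bb,
                  .m("HA2", "CA", H_BOND_LENGTH, 109.0, -122.6),
                  .m("HA3", "CA", H_BOND_LENGTH, 109.0, +119))
    } else {
      bb <- rbind(bb,
                  .m("CB", "CA", 1.530, 110.5, -122.6),
                  .m("HA", "CA", H_BOND_LENGTH, 109.0, +119))
      # chi1 is carried by the children of CB (rotation about CA-CB);
      # proline's ring torsions are fixed
      cb_grp <- side[[code]]$parent == "CB" & is.na(side[[code]]$off)
      if (any(cb_grp)) {
        side[[code]]$var[cb_grp][1] <- "chi1"
        side[[code]]$ref[cb_grp][1] <- code != "PRO"
        if (code == "PRO") side[[code]]$tor0[cb_grp][1] <- -15.5
      }
    }
    tmpl <- rbind(bb, side[[code]])
    # renumber side-chain torsion groups by depth from CA: the group of
    # CB's children is chi1, of CG's children chi2, and so on
    depth <- function(atom) {
      d <- 0
      while (atom != "CA") {
        atom <- tmpl$parent[tmpl$name == atom]
        d <- d + 1
        if (d > 12) stop("template parent loop in ", code)  # nocov
      }
      d
    }
    chi <- grepl("^chi", tmpl$var)
    if (any(chi))
      tmpl$var[chi] <- paste0("chi", vapply(tmpl$parent[chi], depth, 0))
    res[[code]] <- tmpl
  }
  res
}

#' One-letter to three-letter residue codes
#' @param seq character string of one-letter codes, e.g. `"GAASV"`.
#' @return character vector of three-letter codes.
#' @export
aa_three <- function(seq) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", P = "PRO", S = "SER",
           T = "THR", W = "TRP", Y = "TYR", V = "VAL", F = "PHE")
  one <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(one, names(map))
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  unname(map[one])
}

#' Element of an atom from its PDB-style name
#' @param name atom name(s), e.g. `"CA"`, `"OD1"`, `"HB2"`.
#' @return character vector of element symbols.
#' @export
element_of <- function(name) {
  first <- substr(gsub("^[0-9]", "", name), 1, 1)
  ok <- first %in% c("C", "N", "O", "S", "H", "P")
  if (!any(ok)) stop("cannot infer element for atom name(s): ",
                     paste(name[!ok], collapse = ", "))
  ifelse(ok, first, NA_character_)
}
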