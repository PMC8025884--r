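#' Unit-cell description
#'
#' Construct a unit cell from the six cell constants and a space-group
#' symbol.  The returned object carries the orthogonalization matrix (PDB
#' convention: a along x, b in the xy plane), its inverse, the cell volume
#' and the space-group operator list, and is used throughout for
#' fractional/orthogonal conversion and resolution calculations.
#'
#' @param a,b,c cell edges in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @param spacegroup space-group symbol (see [sg_operators()]).
#' @return an object of class `bondflex_cell`.
#' @export
make_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                      spacegroup = "P 1") {
  stopifnot(a > 0, b > 0, c > 0)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  # PDB orthogonalization convention
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  M <- matrix(c(a, b * cg, c * cb,
                0, b * sg, c * (ca - cb * cg) / sg,
                0, 0,      c * v / sg), 3, 3, byrow = TRUE)
  cell <- list(abc = c(a, b, c), angles = c(alpha, beta, gamma),
               orth = M, frac = solve(M), volume = a * b * c * v,
               spacegroup = spacegroup, ops = sg_operators(spacegroup))
  class(cell) <- "bondflex_cell"
  cell
}

#' @export
print.bondflex_cell <- function(x, ...) {
  cat(sprintf("<cell %.3f %.3f %.3f  %.2f %.2f %.2f  %s  V=%.1f A^3>\n",
              x$abc[1], x$abc[2], x$abc[3], x$angles[1], x$angles[2],
              x$angles[3], x$spacegroup, x$volume))
  invisible(x)
}

#' Resolution of reflections
#'
#' d-spacing (Angstrom) of Miller indices in a given cell, from the
#' reciprocal metric.
#'
#' @param cell a `bondflex_cell`.
#' @param hkl integer matrix (n x 3) or length-3 vector of Miller indices.
#' @return numeric vector of d-spacings; `Inf` for (0,0,0).
#' @export
d_spacing <- function(cell, hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3)
  s <- hkl %*% cell$frac          # reciprocal vector components (cycles/A)
  inv_d <- sqrt(rowSums(s^2))
  ifelse(inv_d == 0, Inf, 1 / inv_d)
}

#' Fractional to orthogonal coordinates
#' @param cell a `bondflex_cell`.
#' @param x n x 3 matrix of fractional coordinates.
#' @return n x 3 matrix of orthogonal coordinates (Angstrom).
#' @export
frac_to_orth <- function(cell, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  x %*% t(cell$orth)
}

#' Orthogonal to fractional coordinates
#' @rdname frac_to_orth
#' @export
orth_to_frac <- function(cell, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  x %*% t(cell$frac)
}

#' Space-group operators
#'
#' Symmetry operators (rotation part in fractional coordinates, translation
#' as fractions of the cell edges) for the space groups the package
#' supports.  The table is intentionally small: the triclinic and the common
#' primitive orthorhombic/monoclinic protein groups used by the fixture
#' generators.
#'
#' @param symbol space-group symbol, e.g. `"P 1"`, `"P 21"`, `"P 21 21 21"`.
#' @return list of operators, each a list with rotation matrix `R` and
#'   translation vector `t`.
#' @export
sg_operators <- function(symbol) {
  key <- toupper(gsub("[[:space:]]+", "", symbol))
  id <- diag(3)
  op <- function(R, t) list(R = R, t = t)
  switch(key,
    "P1" = list(op(id, c(0, 0, 0))),
    "P21" = list(                       # unique axis b
      op(id, c(0, 0, 0)),
      op(diag(c(-1, 1, -1)), c(0, 0.5, 0))),
    "P212121" = list(
      op(id, c(0, 0, 0)),
      op(diag(c(-1, -1, 1)), c(0.5, 0, 0.5)),
      op(diag(c(1, -1, -1)), c(0.5, 0.5, 0)),
      op(diag(c(-1, 1, -1)), c(0, 0.5, 0.5))),
    stop("unsupported space group: ", symbol)
  )
}
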