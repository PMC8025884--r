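# Internal vector geometry used by the recursive ensemble builder.  All
# routines are row-vectorized: positions are n x 3 matrices and one position
# per conformer is processed in a single call.

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnorm <- function(a) sqrt(rowSums(a^2))

vunit <- function(a) {
  n <- vnorm(a)
  if (any(n < 1e-12)) stop("degenerate (zero-length) vector")
  a / n
}

as_row3 <- function(x) if (is.null(dim(x))) matrix(x, ncol = 3) else x

#' Dihedral angle of four points
#'
#' Signed torsion angle (degrees, IUPAC convention: cis = 0, positive when,
#' viewed from b towards c, the far bond rotates clockwise from the near
#' bond) for each row of four point sets.
#'
#' @param a,b,c,d n x 3 matrices (or length-3 vectors) of positions.
#' @return numeric vector of torsion angles in degrees, in (-180, 180].
#' @export
torsion_angle <- function(a, b, c, d) {
  a <- as_row3(a); b <- as_row3(b); c <- as_row3(c); d <- as_row3(d)
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (any(vnorm(n1) < 1e-10) || any(vnorm(n2) < 1e-10))
    stop("undefined dihedral: colinear atom triple")
  u2 <- b2 / vnorm(b2)
  m1 <- vcross(n1, u2)
  atan2(-rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

#' Bond angle of three points
#'
#' Interior angle at `b` (degrees) for each row.
#' @param a,b,c n x 3 matrices (or length-3 vectors) of positions.
#' @return numeric vector of angles in degrees.
#' @export
bond_angle <- function(a, b, c) {
  a <- as_row3(a); b <- as_row3(b); c <- as_row3(c)
  u <- vunit(a - b); v <- vunit(c - b)
  acos(pmin(1, pmax(-1, rowSums(u * v)))) * 180 / pi
}

#' Natural-extension (NeRF) placement
#'
#' Place a point `d` at bond length `len` from `c`, with bond angle `theta`
#' at `c` (relative to `b`) and torsion `tau` relative to the `a`-`b`-`c`
#' plane, such that `torsion_angle(a, b, c, d) == tau` and
#' `bond_angle(b, c, d) == theta` exactly.  Vectorized over rows; `tau`
#' (and `theta`, `len`) may be per-row vectors, which is how per-conformer
#' torsion deviations enter the ensemble.
#'
#' @param a,b,c n x 3 matrices of the three upstream positions.
#' @param len bond length(s), Angstrom.
#' @param theta bond angle(s), degrees.
#' @param tau torsion angle(s), degrees.
#' @return n x 3 matrix of placed positions.
#' @export
nerf_place <- function(a, b, c, len, theta, tau) {
  a <- as_row3(a); b <- as_row3(b); c <- as_row3(c)
  th <- theta * pi / 180; ta <- tau * pi / 180
  u2 <- vunit(c - b)
  n <- vunit(vcross(b - a, u2))        # normal to the a-b-c plane
  m <- vcross(n, u2)
  # local displacement: -cos(theta) along u2, sin(theta) split by torsion
  c + len * (-cos(th) * u2 + sin(th) * (cos(ta) * m + sin(ta) * n))
}
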