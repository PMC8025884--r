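# Real-space density segments, unit-cell maps, bulk solvent and structure
# factors.  Atom points deposit unit weight over the eight surrounding
# voxel corners (trilinear / opposite-fractional-volume weights, exactly
# conserving the deposited density), per-element maps are convolved with
# the element form factor in reciprocal space, and the asymmetric-unit
# density is remapped onto a unit-cell grid whose Fourier transform gives
# the structure factors.

# --- element scattering factors -----------------------------------------

#' Element scattering-factor table
#'
#' Four-Gaussian-plus-constant parametrization of the reciprocal-space
#' atomic form factors (International Tables for Crystallography Vol. C
#' style coefficients) for the elements occurring in proteins.  `f(0)`
#' equals the electron count of the neutral atom to about 1e-3.
#'
#' @return data frame with columns `elem`, `a1..a4`, `b1..b4`, `c`.
#' @export
element_form_factors <- function() {
  tab <- rbind(
    H = c(0.489918, 20.6593, 0.262003, 7.74039, 0.196767, 49.5519,
          0.049879, 2.20159, 0.001305),
    C = c(2.31000, 20.8439, 1.02000, 10.2075, 1.58860, 0.5687,
          0.865000, 51.6512, 0.215600),
    N = c(12.2126, 0.0057, 3.13220, 9.8933, 2.01250, 28.9975,
          1.16630, 0.5826, -11.529),
    O = c(3.04850, 13.2771, 2.28680, 5.7011, 1.54630, 0.3239,
          0.867000, 32.9089, 0.250800),
    S = c(6.90530, 1.4679, 5.20340, 22.2151, 1.43790, 0.2536,
          1.58630, 56.1720, 0.866900),
    P = c(6.43450, 1.9067, 4.17910, 27.1570, 1.78000, 0.5260,
          1.49080, 68.1645, 1.114900))
  out <- data.frame(elem = rownames(tab), tab, row.names = NULL)
  names(out) <- c("elem", "a1", "b1", "a2", "b2", "a3", "b3", "a4", "b4", "c")
  out
}

#' Evaluate an element form factor
#' @param elem element symbol (unknown elements fall back to carbon).
#' @param inv_d reciprocal resolution `1/d` in 1/Angstrom (`s = 1/(2d)`).
#' @return numeric vector of scattering factors (electrons).
#' @export
form_factor <- function(elem, inv_d) {
  ff <- element_form_factors()
  r <- ff[match(elem, ff$elem), ]
  if (any(is.na(r$elem))) r[is.na(r$elem), ] <- ff[ff$elem == "C", ]
  s2 <- (inv_d / 2)^2                      # (sin theta / lambda)^2
  r$a1 * exp(-r$b1 * s2) + r$a2 * exp(-r$b2 * s2) +
    r$a3 * exp(-r$b3 * s2) + r$a4 * exp(-r$b4 * s2) + r$c
}

# FFT-friendly dimension (products of 2, 3, 5)
next235 <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  ok <- function(m) {
    while (m %% 2 == 0) m <- m / 2
    while (m %% 3 == 0) m <- m / 3
    while (m %% 5 == 0) m <- m / 5
    m == 1
  }
  while (!ok(n)) n <- n + 1L
  n
}

#' Voxel edge for a nominal resolution
#'
#' Cube voxel length `d/4`, capped at a maximum of 0.8 Angstrom.
#' @param d nominal resolution, Angstrom.
#' @return voxel edge, Angstrom.
#' @export
voxel_edge <- function(d) min(d / 4, 0.8)

# signed FFT frequencies (cycles per grid length) for dimension n
.fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n %/% 2, k, k - n)
}

# |1/d| at every voxel of a cubic segment grid
.seg_inv_d <- function(dims, h) {
  f1 <- .fft_freq(dims[1]) / (dims[1] * h)
  f2 <- .fft_freq(dims[2]) / (dims[2] * h)
  f3 <- .fft_freq(dims[3]) / (dims[3] * h)
  sqrt(outer(outer(f1^2, f2^2, `+`), f3^2, `+`))
}

# reciprocal transfer function of the trilinear (triangle) deposition
# kernel; dividing the final structure factors by it deconvolves the
# smoothing of both deposition passes (atom points onto the segment grid,
# segment voxels onto the cell grid).  `h_seg` is the segment voxel edge;
# the segment axes are taken parallel to the cell axes.
.splat_transfer <- function(dims, cell = NULL, h_seg = NULL) {
  sinc2 <- function(x) ifelse(x == 0, 1, (sin(x) / x)^2)
  fac <- function(ax) {
    q <- .fft_freq(dims[ax])
    t <- sinc2(pi * q / dims[ax])                      # cell-grid push
    if (!is.null(h_seg)) t <- t * sinc2(pi * q / cell$abc[ax] * h_seg)
    t
  }
  outer(outer(fac(1), fac(2), `*`), fac(3), `*`)
}

# trilinear deposition of point masses into a (flattened) grid;
# wrap = TRUE treats the grid as periodic (unit-cell grids)
.splat <- function(vox, w, dims, wrap = FALSE) {
  f0 <- floor(vox)
  fr <- vox - f0
  acc <- numeric(prod(dims))
  for (corner in 0:7) {
    cx <- corner %% 2; cy <- (corner %/% 2) %% 2; cz <- corner %/% 4
    wt <- w *
      (cx * fr[, 1] + (1 - cx) * (1 - fr[, 1])) *
      (cy * fr[, 2] + (1 - cy) * (1 - fr[, 2])) *
      (cz * fr[, 3] + (1 - cz) * (1 - fr[, 3]))
    ix <- f0[, 1] + cx; iy <- f0[, 2] + cy; iz <- f0[, 3] + cz
    if (wrap) {
      ix <- ix %% dims[1]; iy <- iy %% dims[2]; iz <- iz %% dims[3]
    } else if (any(ix < 0 | ix >= dims[1] | iy < 0 | iy >= dims[2] |
                   iz < 0 | iz >= dims[3]))
      stop("atom point outside the density grid (margin violated)")
    lin <- 1 + ix + dims[1] * (iy + dims[2] * iz)
    s <- rowsum(wt, lin)
    acc[as.numeric(rownames(s))] <- acc[as.numeric(rownames(s))] + s[, 1]
  }
  acc
}

#' Rasterize an ensemble into a real-space structure segment
#'
#' Deposits every atom point onto a cubic-voxel grid (eight-corner
#' trilinear weights, total weight exactly preserved), then convolves each
#' per-element map with the element's reciprocal-space form factor and
#' sums the element maps.  HETATM-style atoms with their own isotropic B
#' factors are added analytically in reciprocal space.
#'
#' @param points list of `J x 3` atom-point matrices (one per atom).
#' @param elements element symbol per atom.
#' @param d nominal resolution (sets the voxel edge, see [voxel_edge()]).
#' @param weights total weight (occupancy) per atom; each atom point
#'   carries `weight/J`.
#' @param margin bounding-box margin, Angstrom.
#' @param het optional data frame of B-factor-model atoms
#'   (`x`, `y`, `z`, `b`, `occ`, `elem`).
#' @param grid optional existing grid definition (`origin`, `h`, `dims`)
#'   to rasterize into; points falling outside it are an error.
#' @param oversample internal deposition oversampling factor: atom points
#'   are deposited on a grid this many times finer, the deposition kernel
#'   is deconvolved there, and the result is band-limited back onto the
#'   `d/4` segment grid.  Suppresses deposition aliasing; `1` deposits
#'   directly on the segment grid.
#' @param lowpass optional resolution cutoff in Angstrom: frequencies
#'   beyond `1/lowpass` are removed, matching the band content of a map
#'   synthesized from data truncated at that resolution.
#' @return a `bondflex_grid`: `origin`, `h`, `dims`, `rho` (3-d array,
#'   electrons per cubic Angstrom).
#' @export
rasterize_segment <- function(points, elements, d, weights = 1,
                              margin = 2, het = NULL, grid = NULL,
                              oversample = 2, lowpass = NULL) {
  stopifnot(length(points) == length(elements))
  weights <- rep(weights, length.out = length(points))
  allp <- do.call(rbind, points)
  if (is.null(grid)) {
    h <- voxel_edge(d)
    lo <- apply(allp, 2, min) - margin
    hi <- apply(allp, 2, max) + margin
    dims <- vapply(hi - lo, function(e) next235(e / h + 1), 0L)
    origin <- lo
  } else {
    h <- grid$h; dims <- grid$dims; origin <- grid$origin
  }
  os <- max(1L, as.integer(oversample))
  dims_f <- dims * os
  h_f <- h / os
  npt <- vapply(points, nrow, 0L)
  wpt <- rep(weights / npt, npt)
  epts <- rep(elements, npt)
  Fsum <- array(0 + 0i, dims_f)
  inv_d <- .seg_inv_d(dims_f, h_f)
  transfer <- .splat_transfer(dims_f)
  for (el in unique(elements)) {
    sel <- epts == el
    vox <- sweep(allp[sel, , drop = FALSE], 2, origin) / h_f
    rho_el <- array(.splat(vox, wpt[sel], dims_f), dims_f)
    Fsum <- Fsum + fft(rho_el, inverse = TRUE) / transfer *
      form_factor(el, inv_d)
  }
  if (!is.null(het) && nrow(het)) {
    for (i in seq_len(nrow(het))) {
      x <- c(het$x[i], het$y[i], het$z[i]) - origin
      ph <- 2 * pi * (outer(.fft_freq(dims_f[1]) / (dims_f[1] * h_f) * x[1],
                            .fft_freq(dims_f[2]) / (dims_f[2] * h_f) * x[2],
                            `+`))
      ph <- outer(ph,
                  .fft_freq(dims_f[3]) / (dims_f[3] * h_f) * x[3] * 2 * pi,
                  `+`)
      fa <- het$occ[i] * form_factor(het$elem[i], inv_d) *
        exp(-het$b[i] * inv_d^2 / 4)
      Fsum <- Fsum + fa * exp(1i * ph)
    }
  }
  if (os > 1) {
    # band-limit back onto the segment grid: keep the central frequencies
    i1 <- (.fft_freq(dims[1]) %% dims_f[1]) + 1
    i2 <- (.fft_freq(dims[2]) %% dims_f[2]) + 1
    i3 <- (.fft_freq(dims[3]) %% dims_f[3]) + 1
    Fsum <- Fsum[i1, i2, i3]
  }
  if (!is.null(lowpass))
    Fsum[.seg_inv_d(dims, h) > 1 / lowpass] <- 0
  rho <- Re(fft(Fsum) / prod(dims)) / h^3
  g <- list(origin = origin, h = h, dims = dims, rho = rho, d = d,
            kind = "segment", deconvolved = TRUE)
  class(g) <- "bondflex_grid"
  g
}

#' Remap a structure segment onto the unit-cell grid
#'
#' Pushes the segment density into a cell-shaped voxel grid (sampling at
#' the `d/4` rule) with periodic wrapping, conserving the total density
#' exactly, and Fourier-transforms the result into the structure factors
#' of one asymmetric unit.
#'
#' @param segment a segment `bondflex_grid` (see [rasterize_segment()]).
#' @param cell a `bondflex_cell`.
#' @param dims optional explicit cell-grid dimensions.
#' @return list with `grid` (unit-cell `bondflex_grid`, fractional axes)
#'   and `F` (complex 3-d array of structure factors, Miller-indexed).
#' @export
remap_to_unit_cell <- function(segment, cell, dims = NULL) {
  if (is.null(dims)) {
    dims <- vapply(cell$abc, function(len) next235(len / segment$h), 0L)
  }
  nvox <- prod(segment$dims)
  idx <- arrayInd(seq_len(nvox), segment$dims) - 1
  orth <- sweep(idx * segment$h, 2, segment$origin, `+`)
  fr <- orth %*% t(cell$frac)
  fr <- fr - floor(fr)
  vox <- sweep(fr, 2, dims, `*`)
  mass <- as.vector(segment$rho) * segment$h^3
  keep <- mass != 0
  vox <- vox[keep, , drop = FALSE]
  aligned <- max(abs(vox - round(vox))) < 1e-6
  if (aligned) vox <- round(vox)
  acc <- .splat(vox, mass[keep], dims, wrap = TRUE)
  voxvol <- cell$volume / prod(dims)
  rho <- array(acc / voxvol, dims)
  g <- list(origin = c(0, 0, 0), h = NA, dims = dims, rho = rho,
            cell = cell, kind = "cell")
  class(g) <- "bondflex_grid"
  # the push onto the cell grid convolves with its own deposition kernel;
  # the segment's deposition was already deconvolved at rasterization
  seg_h <- if (isTRUE(segment$deconvolved)) NULL else segment$h
  Fg <- grid_structure_factors(g)
  # an aligned push lands every voxel on a single grid point (exact copy):
  # no deposition smoothing to deconvolve
  if (!aligned) Fg <- Fg / .splat_transfer(dims, cell, seg_h)
  else if (!is.null(seg_h)) Fg <- Fg / .splat_transfer(dims, cell, seg_h) *
      .splat_transfer(dims)
  list(grid = g, F = Fg)
}

#' Rasterize an ensemble directly onto the unit-cell grid
#'
#' Asymmetric-unit structure factors without an intermediate cubic
#' segment: atom points are deposited in cell-fractional coordinates on an
#' internally oversampled periodic grid, the deposition kernel is
#' deconvolved in reciprocal space, per-element form factors are applied
#' and the result is band-limited onto the `d/4` unit-cell grid.  The
#' remapping of density into the cell reduces to an exact index wrap, so
#' the structure factors match a direct summation over the atom points to
#' numerical precision.
#'
#' @param points list of `J x 3` atom-point matrices.
#' @param elements element symbol per atom.
#' @param cell a `bondflex_cell`.
#' @param d nominal resolution (sets the grid sampling).
#' @param weights occupancy per atom.
#' @param het optional B-factor-model atoms (see [rasterize_segment()]).
#' @param dims optional explicit cell-grid dimensions.
#' @param oversample internal deposition oversampling factor.
#' @return list with `grid` (unit-cell `bondflex_grid`) and `F` (complex
#'   Miller-indexed array of asymmetric-unit structure factors).
#' @export
rasterize_unit_cell <- function(points, elements, cell, d, weights = 1,
                                het = NULL, dims = NULL, oversample = 2) {
  if (is.null(dims))
    dims <- vapply(cell$abc, function(len) next235(len / voxel_edge(d)), 0L)
  os <- max(1L, as.integer(oversample))
  dims_f <- dims * os
  weights <- rep(weights, length.out = length(points))
  npt <- vapply(points, nrow, 0L)
  wpt <- rep(weights / npt, npt)
  epts <- rep(elements, npt)
  allp <- do.call(rbind, points)
  fr <- allp %*% t(cell$frac)
  fr <- fr - floor(fr)
  hklf <- .grid_miller(dims_f)
  inv_d <- array(1 / d_spacing(cell, hklf), dims_f)
  transfer <- .splat_transfer(dims_f)
  Fsum <- array(0 + 0i, dims_f)
  for (el in unique(elements)) {
    sel <- epts == el
    vox <- sweep(fr[sel, , drop = FALSE], 2, dims_f, `*`)
    rho_el <- array(.splat(vox, wpt[sel], dims_f, wrap = TRUE), dims_f)
    Fsum <- Fsum + fft(rho_el, inverse = TRUE) / transfer *
      form_factor(el, inv_d)
  }
  if (!is.null(het) && nrow(het)) {
    hfr <- cbind(het$x, het$y, het$z) %*% t(cell$frac)
    for (i in seq_len(nrow(het))) {
      ph <- 2 * pi * array(hklf %*% hfr[i, ], dims_f)
      fa <- het$occ[i] * form_factor(het$elem[i], inv_d) *
        exp(-het$b[i] * inv_d^2 / 4)
      Fsum <- Fsum + fa * exp(1i * ph)
    }
  }
  if (os > 1) {
    i1 <- (.fft_freq(dims[1]) %% dims_f[1]) + 1
    i2 <- (.fft_freq(dims[2]) %% dims_f[2]) + 1
    i3 <- (.fft_freq(dims[3]) %% dims_f[3]) + 1
    Fsum <- Fsum[i1, i2, i3]
  }
  rho <- Re(fft(Fsum)) / cell$volume
  g <- list(origin = c(0, 0, 0), h = NA, dims = dims, rho = rho,
            cell = cell, kind = "cell")
  class(g) <- "bondflex_grid"
  list(grid = g, F = Fsum)
}

#' Structure factors of a unit-cell grid
#'
#' `F(h) = V/N * sum rho exp(+2 pi i h.x)` over the cell grid.
#' @param grid a unit-cell `bondflex_grid`.
#' @return complex 3-d array indexed by Miller indices modulo grid size.
#' @export
grid_structure_factors <- function(grid) {
  fft(grid$rho, inverse = TRUE) * grid$cell$volume / prod(grid$dims)
}

#' Real-space synthesis from a structure-factor grid
#'
#' Inverse of [grid_structure_factors()]: `rho(x) = (1/V) sum F exp(-2 pi
#' i h.x)`.
#' @param F complex Miller-indexed array.
#' @param cell a `bondflex_cell`.
#' @return a unit-cell `bondflex_grid`.
#' @export
grid_from_structure_factors <- function(F, cell) {
  rho <- Re(fft(F)) / cell$volume
  g <- list(origin = c(0, 0, 0), h = NA, dims = dim(F), rho = rho,
            cell = cell, kind = "cell")
  class(g) <- "bondflex_grid"
  g
}

# Miller indices of every voxel of a reciprocal grid
.grid_miller <- function(dims) {
  as.matrix(expand.grid(h = .fft_freq(dims[1]), k = .fft_freq(dims[2]),
                        l = .fft_freq(dims[3])))
}

#' Extract structure factors at Miller indices
#' @param F complex Miller-indexed array.
#' @param hkl integer matrix (n x 3).
#' @return complex vector.
#' @export
extract_structure_factors <- function(F, hkl) {
  dims <- dim(F)
  i <- (hkl[, 1] %% dims[1]) + 1
  j <- (hkl[, 2] %% dims[2]) + 1
  k <- (hkl[, 3] %% dims[3]) + 1
  F[cbind(i, j, k)]
}

#' Reciprocal-space symmetry expansion
#'
#' Cumulatively adds the symmetry-transformed complex coefficients of the
#' asymmetric-unit structure factors to their symmetry-related Miller
#' indices: for each operator (R, t), `F(h R) += F_asu(h) exp(2 pi i
#' h.t)`.  In P 1 this is the identity.
#'
#' @param F_asu complex Miller-indexed array for one asymmetric unit.
#' @param cell a `bondflex_cell` carrying the operator list.
#' @return complex array of the full-cell structure factors.
#' @export
symmetry_expand <- function(F_asu, cell) {
  ops <- cell$ops
  if (length(ops) == 1) return(F_asu)
  dims <- dim(F_asu)
  hkl <- .grid_miller(dims)
  Fv <- as.vector(F_asu)
  out <- array(0 + 0i, dims)
  for (op in ops) {
    hR <- hkl %*% op$R
    i <- (hR[, 1] %% dims[1]) + 1
    j <- (hR[, 2] %% dims[2]) + 1
    k <- (hR[, 3] %% dims[3]) + 1
    phase <- exp(2i * pi * as.numeric(hkl %*% op$t))
    lin <- i + dims[1] * (j - 1) + dims[1] * dims[2] * (k - 1)
    contrib <- Fv * phase
    s <- rowsum(cbind(Re(contrib), Im(contrib)), lin)
    tgt <- as.numeric(rownames(s))
    out[tgt] <- out[tgt] + complex(real = s[, 1], imaginary = s[, 2])
  }
  out
}

# --- bulk solvent --------------------------------------------------------

#' Solvent probe radii
#'
#' Per-element masking radii for the flat bulk-solvent model (values of
#' the Jiang & Bruenger type used by standard refinement packages).
#'
#' @return named numeric vector, Angstrom.
#' @export
solvent_radii <- function() {
  c(H = 1.0, C = 1.85, N = 1.5, O = 1.4, S = 1.85, P = 1.9)
}

#' Multi-conformer bulk-solvent mask
#'
#' A separate binary solvent mask is computed from each conformer (protein
#' voxels 0, solvent 1, atoms masked within their element radii), each
#' mask is shrunk by switching model voxels within `shrink` Angstrom of a
#' solvent voxel to solvent, small internal solvent strips shorter than
#' `strip` Angstrom along every crystallographic axis are removed, and the
#' J masks are averaged.  Masks are carried bit-packed (16 per integer
#' word).
#'
#' @param points list of `J x 3` atom-point matrices (non-H atoms).
#' @param elements element per atom.
#' @param cell a `bondflex_cell`.
#' @param dims cell-grid dimensions.
#' @param shrink mask shrink distance, Angstrom (0.4).
#' @param strip minimum retained solvent strip length, Angstrom (2.0).
#' @return list with `fraction` (3-d array in [0,1]), `F` (structure
#'   factors of the averaged mask) and `packed` (bit-packed masks).
#' @export
compute_solvent_mask <- function(points, elements, cell, dims,
                                 shrink = 0.4, strip = 2.0) {
  nvox <- prod(dims)
  if (!length(points)) {
    fr <- array(1, dims)
    g <- list(origin = c(0, 0, 0), h = NA, dims = dims, rho = fr,
              cell = cell, kind = "cell")
    class(g) <- "bondflex_grid"
    return(list(fraction = fr, F = grid_structure_factors(g),
                packed = NULL))
  }
  J <- nrow(points[[1]])
  radii <- solvent_radii()
  spacing <- cell$abc / dims                     # along-axis voxel steps
  # pre-computed voxel-offset neighbourhoods per element radius
  nb <- list()
  for (el in unique(elements)) {
    r <- radii[[el]]
    if (is.null(r) || is.na(r)) r <- 1.7
    box <- ceiling(r / spacing)
    off <- as.matrix(expand.grid(-box[1]:box[1], -box[2]:box[2],
                                 -box[3]:box[3]))
    orth <- (off / rep(dims, each = nrow(off))) %*% t(cell$orth)
    nb[[el]] <- off[rowSums(orth^2) <= r^2, , drop = FALSE]
  }
  # shrink neighbourhood (often empty on working grids coarser than 0.4 A)
  sbox <- ceiling(shrink / spacing)
  soff <- as.matrix(expand.grid(-sbox[1]:sbox[1], -sbox[2]:sbox[2],
                                -sbox[3]:sbox[3]))
  sorth <- (soff / rep(dims, each = nrow(soff))) %*% t(cell$orth)
  soff <- soff[rowSums(sorth^2) <= shrink^2 & rowSums(abs(soff)) > 0,
               , drop = FALSE]
  strip_vox <- pmax(0, floor(strip / spacing))

  masks <- vector("list", J)
  for (j in seq_len(J)) {
    solvent <- rep(TRUE, nvox)
    for (ai in seq_along(points)) {
      p <- points[[ai]][j, ]
      f0 <- (cell$frac %*% p) * dims             # fractional voxel coords
      vv <- sweep(nb[[elements[ai]]], 2, round(as.numeric(f0)), `+`)
      vv <- vv %% rep(dims, each = nrow(vv))
      solvent[1 + vv[, 1] + dims[1] * (vv[, 2] + dims[2] * vv[, 3])] <- FALSE
    }
    m <- array(solvent, dims)
    if (nrow(soff)) {
      # model voxels at most `shrink` from a solvent voxel become solvent
      grow <- m
      for (r in seq_len(nrow(soff))) {
        sh <- soff[r, ]
        grow <- grow | .shift3(m, sh)
      }
      m <- grow
    }
    m <- .remove_strips(m, strip_vox)
    masks[[j]] <- m
  }
  packed <- pack_masks_bitwise(masks)
  fr <- array(average_packed_masks(packed, J), dims)
  g <- list(origin = c(0, 0, 0), h = NA, dims = dims, rho = fr,
            cell = cell, kind = "cell")
  class(g) <- "bondflex_grid"
  list(fraction = fr, F = grid_structure_factors(g), packed = packed)
}

.shift3 <- function(m, sh) {
  d <- dim(m)
  i1 <- ((seq_len(d[1]) - 1 - sh[1]) %% d[1]) + 1
  i2 <- ((seq_len(d[2]) - 1 - sh[2]) %% d[2]) + 1
  i3 <- ((seq_len(d[3]) - 1 - sh[3]) %% d[3]) + 1
  m[i1, i2, i3]
}

# remove solvent runs shorter than `strip_vox` voxels along *every* axis
.remove_strips <- function(m, strip_vox) {
  if (all(strip_vox == 0)) return(m)
  d <- dim(m)
  short <- array(TRUE, d)
  for (ax in 1:3) {
    lim <- strip_vox[ax]
    if (lim == 0) { next }
    runs <- apply(m, setdiff(1:3, ax), function(v) {
      r <- rle(v)
      rep(ifelse(r$values, r$lengths, Inf), r$lengths)
    })
    runs <- aperm(array(runs, dim = c(d[ax], d[setdiff(1:3, ax)])),
                  order(c(ax, setdiff(1:3, ax))))
    short <- short & (runs < lim)
  }
  m[short & m] <- FALSE
  m
}

#' Bit-packed solvent masks
#'
#' Packs J binary masks into integer words, 16 masks per 32-bit word, so
#' that many conformer masks can be carried and averaged cheaply.  The
#' unpacked average equals the naive average exactly.
#'
#' @param masks list of logical arrays/vectors of identical dimensions.
#' @return list of integer vectors (one word vector per group of 16
#'   masks), with the mask count and dimensions as attributes.
#' @export
pack_masks_bitwise <- function(masks) {
  J <- length(masks)
  dims <- dim(masks[[1]])
  words <- list()
  for (g in seq_len(ceiling(J / 16))) {
    w <- integer(length(masks[[1]]))
    for (b in seq_len(min(16, J - (g - 1) * 16))) {
      j <- (g - 1) * 16 + b
      w <- bitwOr(w, bitwShiftL(as.integer(as.vector(masks[[j]])), b - 1))
    }
    words[[g]] <- w
  }
  attr(words, "J") <- J
  attr(words, "dims") <- dims
  words
}

#' Average of bit-packed masks
#' @param packed output of [pack_masks_bitwise()].
#' @param J number of masks packed.
#' @return numeric vector of per-voxel solvent fractions.
#' @export
average_packed_masks <- function(packed, J = attr(packed, "J")) {
  tot <- numeric(length(packed[[1]]))
  for (g in seq_along(packed)) {
    nb <- min(16, J - (g - 1) * 16)
    for (b in seq_len(nb))
      tot <- tot + bitwAnd(bitwShiftR(packed[[g]], b - 1), 1L)
  }
  tot / J
}

# --- solvent scaling and F_calc -----------------------------------------

#' Scale the solvent contribution and assemble F_calc
#'
#' `F_calc(h) = F_explicit(h) + k exp(-B/(4 d^2)) F_solvent(h)` (complex
#' addition).  The scale `k` and B factor are fit by maximizing the
#' correlation of |F_calc| with F_obs using the simplex method (100
#' cycles, start values 0 and 40, step sizes 0.4 and 40), then |F_calc|
#' is scaled to F_obs in 20 equal-volume resolution bins.
#'
#' @param f_expl,f_solv complex structure factors on the reflection list.
#' @param f_obs observed amplitudes.
#' @param d resolution per reflection, Angstrom.
#' @param fit if `FALSE`, use the supplied `k`, `b` instead of fitting.
#' @param k,b solvent scale and B factor when `fit = FALSE`.
#' @param nbins resolution bins for the final amplitude scaling.
#' @return list with complex `f_calc`, fitted `k`, `b`, and the per-bin
#'   scale factors.
#' @export
scale_solvent_and_assemble <- function(f_expl, f_solv, f_obs, d,
                                       fit = TRUE, k = 0, b = 40,
                                       nbins = 20) {
  stopifnot(length(f_expl) == length(f_solv),
            length(f_expl) == length(f_obs))
  if (!length(f_obs)) stop("empty reflection overlap")
  assemble <- function(k, b) f_expl + k * exp(-b / (4 * d^2)) * f_solv
  if (fit && any(Mod(f_solv) > 0)) {
    obj <- function(p) {
      fc <- Mod(assemble(p[1], p[2]))
      if (stats::sd(fc) < 1e-12) return(1)
      -stats::cor(fc, f_obs)
    }
    res <- simplex_minimize(c(0, 40), c(0.4, 40), obj, max_cycles = 100)
    k <- res$par[1]; b <- res$par[2]
  }
  fc <- assemble(k, b)
  # 20 equal-volume bins: equal counts in 1/d^3
  s3 <- 1 / d^3
  br <- stats::quantile(s3, probs = seq(0, 1, length.out = nbins + 1),
                        names = FALSE)
  br[1] <- -Inf; br[nbins + 1] <- Inf
  bin <- cut(s3, breaks = unique(br), labels = FALSE)
  scale <- rep(1, max(bin))
  for (bi in seq_len(max(bin))) {
    sel <- bin == bi
    ma <- mean(Mod(fc[sel]))
    if (ma > 0) scale[bi] <- mean(f_obs[sel]) / ma
  }
  fc <- fc * scale[bin]
  list(f_calc = fc, k = k, b = b, scale = scale, bin = bin)
}

#' Direct-summation structure factors
#'
#' Exact structure factors of a set of atom-point clouds at given Miller
#' indices: `F(h) = sum_a f_a(1/d) (occ_a / J) sum_j exp(2 pi i h.x_aj)`.
#' Used where exactness matters more than speed (correlation targets on
#' small segments, test oracles); the FFT route scales better.
#'
#' @param points list of `J x 3` atom-point matrices.
#' @param elements element per atom.
#' @param cell a `bondflex_cell`.
#' @param hkl integer matrix of Miller indices (n x 3).
#' @param weights occupancy per atom.
#' @return complex vector of structure factors.
#' @export
direct_structure_factors <- function(points, elements, cell, hkl,
                                     weights = 1) {
  weights <- rep(weights, length.out = length(points))
  npt <- vapply(points, nrow, 0L)
  allp <- do.call(rbind, points)
  fr <- allp %*% t(cell$frac)
  ph <- exp(2i * pi * (fr %*% t(hkl)))       # points x reflections
  d <- d_spacing(cell, hkl)
  ff <- lapply(unique(elements), function(el) form_factor(el, 1 / d))
  names(ff) <- unique(elements)
  out <- rep(0 + 0i, nrow(hkl))
  row0 <- c(0, cumsum(npt))
  for (a in seq_along(points)) {
    rows <- (row0[a] + 1):row0[a + 1]
    cs <- if (length(rows) == 1) ph[rows, ] else colSums(ph[rows, ,
                                                            drop = FALSE])
    out <- out + ff[[elements[a]]] * (weights[a] / npt[a]) * cs
  }
  out
}

#' Unique reflection list to a resolution limit
#'
#' All Friedel-unique Miller indices with `d >= d_min` in the given cell
#' (hemisphere `h > 0`, or `h = 0, k > 0`, or `h = k = 0, l > 0`).
#'
#' @param cell a `bondflex_cell`.
#' @param d_min resolution limit, Angstrom.
#' @return integer matrix (n x 3).
#' @export
unique_millers <- function(cell, d_min) {
  hmax <- ceiling(cell$abc / d_min)
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                               l = -hmax[3]:hmax[3]))
  keep <- hkl[, 1] > 0 | (hkl[, 1] == 0 & hkl[, 2] > 0) |
    (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] > 0)
  hkl <- hkl[keep, , drop = FALSE]
  hkl[d_spacing(cell, hkl) >= d_min, , drop = FALSE]
}

#' Model structure factors end to end
#'
#' Rasterizes the ensemble into an asymmetric-unit segment, remaps it onto
#' the unit-cell grid, expands space-group symmetry in reciprocal space,
#' optionally adds the scaled multi-conformer bulk-solvent contribution,
#' and returns the structure factors on the unique reflection list.
#'
#' @param model a `bondflex_model`.
#' @param ensemble a `bondflex_ensemble` (defaults to building one).
#' @param d_min resolution limit, Angstrom.
#' @param solvent include the bulk-solvent term?
#' @param k_sol,b_sol solvent scale parameters applied when `solvent` is
#'   `TRUE` (no fitting here; see [scale_solvent_and_assemble()]).
#' @param hkl optional explicit Miller indices (defaults to the unique
#'   set to `d_min`).
#' @return list with `hkl`, `d`, complex `f_calc`, `f_expl`, `f_solv`,
#'   the reciprocal grids and the cell-grid dimensions.
#' @export
compute_f_model <- function(model, ensemble = NULL, d_min = 2,
                            solvent = FALSE, k_sol = 0.35, b_sol = 46,
                            hkl = NULL) {
  if (is.null(ensemble)) ensemble <- build_ensemble(model)
  g <- model$graph
  heavy <- which(!g$atoms$is_h)
  elem <- g$atoms$elem
  rem <- rasterize_unit_cell(ensemble$pts, elem, model$cell, d = d_min,
                             weights = 1, het = .het_frame(model))
  F_expl <- symmetry_expand(rem$F, model$cell)
  if (is.null(hkl)) hkl <- unique_millers(model$cell, d_min)
  f_expl <- extract_structure_factors(F_expl, hkl)
  f_solv <- rep(0 + 0i, nrow(hkl))
  F_solv <- NULL
  if (solvent) {
    sm <- compute_solvent_mask(ensemble$pts[heavy], elem[heavy],
                               model$cell, rem$grid$dims)
    F_solv <- symmetry_expand(sm$F, model$cell)
    f_solv <- extract_structure_factors(F_solv, hkl)
  }
  d <- d_spacing(model$cell, hkl)
  f_calc <- f_expl + if (solvent)
    k_sol * exp(-b_sol / (4 * d^2)) * f_solv else 0
  list(hkl = hkl, d = d, f_calc = f_calc, f_expl = f_expl,
       f_solv = f_solv, F_expl = F_expl, F_solv = F_solv,
       dims = rem$grid$dims)
}

.het_frame <- function(model) {
  h <- model$graph$het
  if (is.null(h) || !nrow(h)) return(NULL)
  data.frame(x = h$x, y = h$y, z = h$z,
             b = if (is.null(h$b)) 20 else h$b,
             occ = if (is.null(h$occ)) 1 else h$occ,
             elem = h$elem)
}
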