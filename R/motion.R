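# Whole-molecule motions (translation tensor, screw motions) act on the
# anchor atom-point cloud only; everything else inherits them through the
# recursive build.  Intramolecular flexibility enters as per-conformer
# torsion deviations (kicks) scaled by the flexless-structure s factors.

#' Apply the whole-molecule translation tensor
#'
#' The symmetric tensor `T` reshapes the isotropic anchor cloud: an SVD
#' `T = U W U'` gives principal axes `U` and scales `W`, and each point
#' displacement from the cloud centre is mapped through `U W^(1/2) U'` so
#' that `T` acts as a covariance.  `T = I` leaves the cloud unchanged.
#' Negative eigenvalues (which refinement may transiently produce) are
#' clamped to zero.
#'
#' @param cloud `J x 3` matrix: anchor atom points, or centred
#'   displacements if `centred = TRUE`.
#' @param T symmetric 3 x 3 tensor.
#' @param centred if `TRUE`, `cloud` already holds displacements and the
#'   mapped displacements are returned; otherwise positions are returned.
#' @return `J x 3` matrix.
#' @export
apply_translation_tensor <- function(cloud, T, centred = FALSE) {
  if (max(abs(T - t(T))) > 1e-9) stop("translation tensor must be symmetric")
  e <- eigen(T, symmetric = TRUE)
  M <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  if (centred) return(cloud %*% M)           # M symmetric
  mu <- colMeans(cloud)
  sweep(sweep(cloud, 2, mu) %*% M, 2, mu, `+`)
}

#' Apply screw motions to the anchor cloud
#'
#' For each screw (rotation vector `r`, translation vector `w` with third
#' component fixed to zero) and each atom point `j`: the dot product
#' `d_j = delta_j . r` sets a rotation of angle `d_j` about the unit axis
#' of `r` applied to the point's frame (fanning the conformers out), and a
#' translational offset `d_j * S w` is added, where `S` is an orthonormal
#' basis whose third axis lies along the translated displacement `delta_j`
#' (so the offset is perpendicular to it).  Screws are applied
#' sequentially; a zero-length `r` is skipped.
#'
#' @param cloud `J x 3` anchor point positions (translation applied).
#' @param frames `3 x 3 x J` per-conformer frame rotations.
#' @param screws list of screws, each `list(r = , w = )` (`w` length 2 or
#'   3 with `w[3] == 0`).
#' @param delta_t `J x 3` translated displacements from the cloud centre.
#' @return list with updated `cloud` and `frames`.
#' @export
apply_screw_motions <- function(cloud, frames, screws, delta_t) {
  J <- nrow(cloud)
  for (s in screws) {
    r <- s$r
    rmag <- sqrt(sum(r^2))
    if (rmag < 1e-12) next                    # no-op screw
    u <- r / rmag
    w <- c(s$w[1], s$w[2])
    d <- as.numeric(delta_t %*% r)
    for (j in seq_len(J)) {
      D <- .rot_axis(u, d[j])
      frames[, , j] <- D %*% frames[, , j]
      dj <- delta_t[j, ]
      nd <- sqrt(sum(dj^2))
      if (nd > 1e-12 && any(w != 0)) {
        e3 <- dj / nd
        eref <- diag(3)[, which.min(abs(e3))]
        e1 <- eref - sum(eref * e3) * e3
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
                e3[3] * e1[1] - e3[1] * e1[3],
                e3[1] * e1[2] - e3[2] * e1[1])
        cloud[j, ] <- cloud[j, ] + d[j] * (w[1] * e1 + w[2] * e2)
      }
      delta_t[j, ] <- D %*% delta_t[j, ]      # sequential composition
    }
  }
  list(cloud = cloud, frames = frames, delta_t = delta_t)
}

#' Two-angle axis rotation matrix
#'
#' Rotation first by `alpha` about the x axis, then by `beta` about the
#' image y' of the y axis under that first rotation.  The product can tilt
#' a reference axis to any direction with two angles and no gimbal lock;
#' with `alpha = beta = 0` it is the identity and kicks act about the
#' unmodified plane normal.
#'
#' @param alpha,beta angles in degrees.
#' @return orthogonal 3 x 3 matrix with determinant +1.
#' @export
build_alpha_beta_rotation <- function(alpha, beta) {
  a <- alpha * pi / 180; b <- beta * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  # rotation about y' = Rx e_y is Rx Ry Rx'; composing with Rx gives Rx Ry
  Rx %*% Ry
}

.group_row <- function(graph, group) {
  r <- match(group, graph$groups$id)
  if (is.na(r)) stop("no torsion group centred on atom ", group)
  r
}

#' Set / apply a forward kick
#'
#' A forward kick at a bond adds a per-conformer torsion deviation
#' `k * s_j` (radians) at that bond, propagated recursively through all
#' downstream bonds.  Kicks are only allowed on refinable torsion groups
#' (the peptide bond and proline ring are excluded).
#'
#' @param model a `bondflex_model`.
#' @param group atom index of the group centre (the bond's minor atom).
#' @param k dimensionless kick magnitude.
#' @return `set_kick`: the updated model.  `apply_forward_kick`: the
#'   rebuilt flexed `bondflex_ensemble`.
#' @export
set_kick <- function(model, group, k) {
  r <- .group_row(model$graph, group)
  if (!model$graph$groups$refinable[r])
    stop("kick not allowed on this bond (peptide bond, ring or fixed group)")
  model$graph$groups$kick[r] <- k
  model
}

#' @rdname set_kick
#' @export
apply_forward_kick <- function(model, group, k) {
  build_ensemble(set_kick(model, group, k))
}

#' Set / apply a reverse kick
#'
#' A reverse kick at a C-alpha rotates, per conformer, the anchor seed
#' about the flexless point-to-point bond that has the C-alpha as its
#' minor atom (centre of rotation: the C-alpha atom point), with a
#' cancelling torsion correction so that atoms downstream of the C-alpha
#' do not move.  Flexibility is thereby introduced on the anchor side
#' only.
#'
#' @param model a `bondflex_model`.
#' @param resno residue number of the C-alpha.
#' @param k dimensionless reverse-kick magnitude.
#' @return `set_reverse_kick`: the updated model.  `apply_reverse_kick`:
#'   the rebuilt flexed `bondflex_ensemble`.
#' @export
set_reverse_kick <- function(model, resno, k) {
  ci <- match(resno, model$graph$calphas$resno)
  if (is.na(ci)) stop("no C-alpha for residue ", resno)
  if (!model$graph$calphas$eligible[ci] && k != 0)
    stop("reverse kick on the anchor residue is undefined")
  model$graph$calphas$rkick[ci] <- k
  model
}

#' @rdname set_reverse_kick
#' @export
apply_reverse_kick <- function(model, resno, k) {
  build_ensemble(set_reverse_kick(model, resno, k))
}

#' Perturbation-response matrix
#'
#' Applies an equal small forward and reverse kick at each C-alpha
#' backbone torsion in turn and records the change in r.m.s. cloud spread
#' of every C-alpha atom-point cloud.  The block structure of the
#' resulting matrix identifies rigid domains; a contiguous segmentation is
#' derived by thresholded boundary detection on adjacent response
#' profiles.
#'
#' @param model a `bondflex_model`.
#' @param kick perturbation magnitude (dimensionless; 0.1 by default).
#' @return list with `matrix` (rows: perturbed C-alpha; columns: observed
#'   C-alpha cloud; entries: change in r.m.s. spread, Angstrom),
#'   `resnos`, and `segments` (integer domain label per residue).
#' @export
perturbation_response_matrix <- function(model, kick = 0.1) {
  g <- model$graph
  cas <- g$calphas[order(g$calphas$resno), ]
  if (nrow(cas) < 3) stop("chain too short for a response analysis")
  flexless <- build_flexless(model)
  spread <- function(ens) vapply(cas$idx, function(i) {
    p <- ens$pts[[i]]
    sqrt(sum(sweep(p, 2, colMeans(p))^2) / nrow(p))
  }, 0)
  base <- spread(flexless)
  M <- matrix(0, nrow(cas), nrow(cas),
              dimnames = list(cas$resno, cas$resno))
  for (i in seq_len(nrow(cas))) {
    mi <- model
    r <- match(cas$idx[i], g$groups$id)
    if (!is.na(r)) mi$graph$groups$kick[r] <- kick
    if (cas$eligible[i]) mi$graph$calphas$rkick[i] <- kick
    ens <- build_ensemble(mi, flexless = flexless)
    M[i, ] <- spread(ens) - base
  }
  list(matrix = M, resnos = cas$resno, segments = segment_domains(M))
}

#' Segment a response matrix into contiguous domains
#'
#' Recursive binary segmentation on the block structure of the response
#' matrix: a boundary is accepted where the mean absolute cross-block
#' response exceeds the mean absolute within-block response by at least
#' `factor` (inter-domain perturbations propagate strongly, intra-domain
#' ones do not), and each accepted side is split further in turn.
#'
#' @param M square response matrix (see [perturbation_response_matrix()]).
#' @param factor minimum cross/within block contrast for a boundary.
#' @param min_len smallest admissible domain length, residues.
#' @return integer vector of domain labels, one per chain position.
#' @export
segment_domains <- function(M, factor = 1.8, min_len = 3) {
  n <- ncol(M)
  lab <- rep(1L, n)
  if (n < 2 * min_len || max(abs(M)) < 1e-12) return(lab)
  contrast <- function(idx, b) {
    A <- abs(M[idx, idx, drop = FALSE])
    diag(A) <- NA
    i1 <- seq_len(b); i2 <- (b + 1):length(idx)
    cross <- mean(c(A[i1, i2], A[i2, i1]), na.rm = TRUE)
    within <- mean(c(A[i1, i1], A[i2, i2]), na.rm = TRUE)
    if (!is.finite(within) || within <= 1e-12) return(0)
    cross / within
  }
  split_rec <- function(idx) {
    if (length(idx) < 2 * min_len) return(list(idx))
    bs <- min_len:(length(idx) - min_len)
    cs <- vapply(bs, function(b) contrast(idx, b), 0)
    if (max(cs) < factor) return(list(idx))
    b <- bs[which.max(cs)]
    c(split_rec(idx[seq_len(b)]), split_rec(idx[(b + 1):length(idx)]))
  }
  segs <- split_rec(seq_len(n))
  for (k in seq_along(segs)) lab[segs[[k]]] <- k
  lab
}
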