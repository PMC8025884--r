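# Deterministic conformer-ensemble generation.  The anchor atom carries a
# cloud of J atom points on ten concentric Fibonacci-lattice shells; every
# other atom-point cloud is placed recursively from the previous three
# clouds through bond lengths, bond angles and torsion angles.  With no
# flexibility this duplicates the anchor cloud at every atom average
# position (the flexless structure); whole-molecule motions and torsion
# kicks then act per conformer.

#' Anchor atom-point cloud
#'
#' Arranges `J` atom points on ten concentric spherical shells around
#' `centre`.  Shell radii are `omega * i/10` (i = 1..10) and per-shell
#' counts are proportional to shell surface area (largest-remainder
#' apportionment); points on each shell follow the canonical golden-angle
#' Fibonacci lattice.  The construction contains no randomness.
#'
#' @param J number of atom points (conformers); `J >= 1`.
#' @param omega outermost shell radius in Angstrom (0.356 by default
#'   elsewhere in the package; `0` collapses the cloud onto `centre`).
#' @param centre length-3 centre position.
#' @return `J x 3` matrix of atom-point positions.
#' @export
build_anchor_cloud <- function(J, omega, centre = c(0, 0, 0)) {
  if (J < 1) stop("J must be >= 1")
  if (omega < 0) stop("omega must be >= 0")
  counts <- apportion_shells(J)
  pts <- matrix(0, 0, 3)
  for (i in seq_len(10)) {
    n <- counts[i]
    if (n == 0) next
    r <- omega * i / 10
    k <- seq_len(n) - 1
    z <- 1 - (2 * k + 1) / n
    phi <- k * pi * (3 - sqrt(5))        # golden angle
    rho <- sqrt(pmax(0, 1 - z^2))
    pts <- rbind(pts, r * cbind(rho * cos(phi), rho * sin(phi), z))
  }
  sweep(pts, 2, centre, `+`)
}

#' Largest-remainder shell apportionment
#'
#' Distributes `J` points over ten shells with counts proportional to the
#' shell surface areas (radius proportional to shell index, so area
#' proportional to index squared).
#'
#' @param J total number of points.
#' @return integer vector of length 10 summing to `J`.
#' @export
apportion_shells <- function(J) {
  w <- (1:10)^2 / sum((1:10)^2)
  q <- J * w
  base <- floor(q)
  rem <- J - sum(base)
  if (rem > 0) {
    extra <- order(q - base, 1:10, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Place the next atom-point cloud
#'
#' Natural-extension placement of a new cloud from the three upstream
#' clouds: for each conformer the new point satisfies the given bond
#' length, bond angle and (per-conformer) torsion angle exactly.
#'
#' @param ggp,gp,parent `J x 3` matrices of the three upstream clouds
#'   (paired point-by-point).
#' @param len bond length, Angstrom.
#' @param theta bond angle at the parent, degrees.
#' @param tau torsion angle(s), degrees; scalar or length `J`.
#' @return `J x 3` matrix.
#' @export
place_next_cloud <- function(ggp, gp, parent, len, theta, tau) {
  nerf_place(ggp, gp, parent, len, theta, tau)
}

.rot_axis <- function(u, theta) {
  # Rodrigues rotation about unit axis u (radians)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# core recursive build: anchor positions (J x 3), per-conformer frames
# (3 x 3 x J), per-group torsion deviations (G x J, degrees)
.build_points <- function(graph, J, anchor_pts, frames = NULL, dev = NULL) {
  a <- graph$atoms
  n <- nrow(a)
  u2 <- graph$frame[, 2]; u3 <- graph$frame[, 3]
  if (is.null(frames)) {
    V1 <- sweep(anchor_pts, 2, u2, `+`)
    V2 <- sweep(anchor_pts, 2, u3, `+`)
  } else {
    V1 <- anchor_pts + t(apply(frames, 3, function(R) R %*% u2))
    V2 <- anchor_pts + t(apply(frames, 3, function(R) R %*% u3))
  }
  gidx <- match(a$parent, graph$groups$id)       # group row per atom
  gt <- graph$groups$t
  pts <- vector("list", n)
  pts[[graph$anchor]] <- anchor_pts
  parent <- a$parent
  gp <- ifelse(is.na(parent), NA, parent[parent])
  ggp <- ifelse(is.na(gp), NA, parent[gp])
  for (i in graph$order) {
    if (i == graph$anchor) next
    P <- pts[[parent[i]]]
    G <- if (is.na(gp[i])) V1 else pts[[gp[i]]]
    GG <- if (is.na(gp[i])) V2 else if (is.na(ggp[i])) V1 else pts[[ggp[i]]]
    tau <- gt[gidx[i]] + a$toffset[i]
    if (!is.null(dev)) tau <- tau + dev[gidx[i], ]
    pts[[i]] <- nerf_place(GG, G, P, a$l[i], a$theta[i], tau)
  }
  pts
}

#' Build the flexless structure
#'
#' The ensemble generated with zero flexibility: a rigid duplication of the
#' anchor atom-point cloud at every atom average position.  The returned
#' object also caches the quantities later flex application needs and that
#' are only ever computed from the flexless structure: the raw anchor-cloud
#' displacements, the per-group plane normals and the per-point sine
#' factors s (the dot product of the unit point displacement with the
#' rotated plane normal, in [-1, 1]).
#'
#' @param model a `bondflex_model`.
#' @return a `bondflex_ensemble` with `flexless = TRUE`.
#' @export
build_flexless <- function(model) {
  g <- model$graph
  if (!isTRUE(g$rooted)) stop("graph not rooted")
  centre <- as.numeric(g$atoms[g$anchor, c("x", "y", "z")])
  # the Fibonacci cloud is generated in the anchor frame, so the whole
  # construction is equivariant under rigid motions of the input
  cloud <- build_anchor_cloud(model$J, model$omega) %*% t(g$frame)
  cloud <- sweep(cloud, 2, centre, `+`)
  pts <- .build_points(g, model$J, cloud)
  ens <- list(pts = pts, J = model$J, graph = g, flexless = TRUE,
              anchor_cloud = cloud,
              delta = sweep(cloud, 2, colMeans(cloud)))
  class(ens) <- "bondflex_ensemble"
  ens$cache <- .flex_cache(model, ens)
  ens
}

# plane normals p-hat per group and s factors per (group, point)
.flex_cache <- function(model, flexless) {
  g <- model$graph
  a <- g$atoms
  means <- ensemble_means(flexless)
  parent <- a$parent
  gp <- ifelse(is.na(parent), NA, parent[parent])
  grp <- g$groups
  phat <- matrix(NA_real_, nrow(grp), 3)
  for (r in seq_len(nrow(grp))) {
    p <- grp$id[r]
    if (p == g$anchor || is.na(gp[p])) {
      # anchor-adjacent groups: use the frame axes as the bond references
      b1 <- g$frame[, 2]
      b0 <- means[p, ] - (if (is.na(parent[p])) means[p, ] - g$frame[, 1]
                          else means[parent[p], ])
    } else {
      b0 <- means[p, ] - means[parent[p], ]
      b1 <- means[parent[p], ] - means[gp[p], ]
    }
    cr <- c(b1[2] * b0[3] - b1[3] * b0[2],
            b1[3] * b0[1] - b1[1] * b0[3],
            b1[1] * b0[2] - b1[2] * b0[1])
    nc <- sqrt(sum(cr^2))
    phat[r, ] <- if (nc < 1e-10) c(0, 0, 0) else cr / nc
  }
  delta <- flexless$delta
  dn <- sqrt(rowSums(delta^2))
  dhat <- delta / ifelse(dn < 1e-12, 1, dn)
  dhat[dn < 1e-12, ] <- 0
  list(phat = phat, dhat = dhat)
}

# s factors for the current alpha/beta angles: G x J matrix
.s_factors <- function(graph, cache) {
  grp <- graph$groups
  M_phat <- t(vapply(seq_len(nrow(grp)), function(r) {
    M <- build_alpha_beta_rotation(grp$alpha[r], grp$beta[r])
    as.numeric(M %*% cache$phat[r, ])
  }, numeric(3)))
  M_phat %*% t(cache$dhat)           # G x J
}

#' Build the full ensemble
#'
#' Applies, in order: the whole-molecule translation tensor to the anchor
#' cloud, the screw motions (rotating the per-conformer frames and
#' offsetting positions perpendicular to the translated displacement),
#' reverse kicks (rotating the anchor seed about flexless C-alpha bonds
#' with the cancelling torsion correction), and forward kick torsion
#' deviations; then rebuilds every atom-point cloud recursively.
#'
#' @param model a `bondflex_model`.
#' @param flexless optional pre-computed flexless structure (rebuilt when
#'   omitted).
#' @return a `bondflex_ensemble`.
#' @export
build_ensemble <- function(model, flexless = NULL) {
  g <- model$graph
  if (is.null(flexless)) flexless <- build_flexless(model)
  J <- model$J
  centre <- as.numeric(g$atoms[g$anchor, c("x", "y", "z")])
  cloud <- flexless$anchor_cloud
  mu <- colMeans(cloud)
  delta <- sweep(cloud, 2, mu)

  # translation tensor
  dT <- apply_translation_tensor(delta, model$motions$T, centred = TRUE)
  pos <- sweep(dT, 2, mu, `+`)
  frames <- array(rep(diag(3), J), c(3, 3, J))

  # screw motions
  if (length(model$motions$screws)) {
    sc <- apply_screw_motions(pos, frames, model$motions$screws,
                              delta_t = dT)
    pos <- sc$cloud; frames <- sc$frames
  }

  grp <- g$groups
  S <- .s_factors(g, flexless$cache)
  dev <- matrix(0, nrow(grp), J)
  kk <- which(grp$kick != 0)
  for (r in kk) dev[r, ] <- dev[r, ] + grp$kick[r] * S[r, ] * 180 / pi

  # reverse kicks, N- to C-terminal order, axes from the flexless structure
  cas <- g$calphas[order(g$calphas$resno), ]
  for (ci in seq_len(nrow(cas))) {
    kprime <- cas$rkick[ci]
    if (kprime == 0) next
    if (!cas$eligible[ci])
      stop("reverse kick on the anchor residue is undefined")
    ca <- cas$idx[ci]
    r <- match(ca, grp$id)
    if (is.na(r)) next
    sj <- S[r, ]
    axis_from <- flexless$pts[[g$atoms$parent[ca]]]
    axis_to <- flexless$pts[[ca]]
    for (j in seq_len(J)) {
      ang <- kprime * sj[j]
      if (ang == 0) next
      u <- axis_to[j, ] - axis_from[j, ]
      u <- u / sqrt(sum(u^2))
      R <- .rot_axis(u, ang)
      ctr <- axis_to[j, ]
      pos[j, ] <- ctr + R %*% (pos[j, ] - ctr)
      frames[, , j] <- R %*% frames[, , j]
    }
    dev[r, ] <- dev[r, ] - kprime * sj * 180 / pi
  }

  pts <- .build_points(g, J, pos, frames = frames, dev = dev)
  ens <- list(pts = pts, J = J, graph = g, flexless = all(dev == 0) &&
                identical(model$motions$T, diag(3)) &&
                !length(model$motions$screws) && all(cas$rkick == 0),
              anchor_cloud = cloud, delta = flexless$delta,
              cache = flexless$cache)
  class(ens) <- "bondflex_ensemble"
  ens
}

#' Atom average positions of an ensemble
#' @param ensemble a `bondflex_ensemble`.
#' @return n x 3 matrix of per-atom cloud means.
#' @export
ensemble_means <- function(ensemble) {
  t(vapply(ensemble$pts, colMeans, numeric(3)))
}

#' Isotropic-equivalent B factor of an atom-point cloud
#'
#' `B = (8 pi^2 / 3) * trace` of the point covariance matrix, the
#' isotropic B factor whose mean-square displacement matches the cloud.
#' A single-point cloud returns 0.
#'
#' @param cloud `J x 3` matrix of atom points.
#' @return B factor in Angstrom^2 (non-negative).
#' @export
derived_b_factor <- function(cloud) {
  if (nrow(cloud) < 2) return(0)
  d <- sweep(cloud, 2, colMeans(cloud))
  (8 * pi^2 / 3) * sum(d^2) / nrow(cloud)
}

#' Per-atom derived B factors
#' @param ensemble a `bondflex_ensemble`.
#' @return numeric vector (one per atom).
#' @export
ensemble_bfactors <- function(ensemble) {
  vapply(ensemble$pts, derived_b_factor, 0)
}

#' @export
print.bondflex_ensemble <- function(x, ...) {
  cat(sprintf("<bondflex ensemble: %d atoms x %d conformers%s>\n",
              length(x$pts), x$J, if (isTRUE(x$flexless)) " (flexless)"
              else ""))
  invisible(x)
}
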