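# The refinement engine.  Mode 1 fits torsions (and selected bond angles)
# of the bond model to the original positions; modes 2a/2b fit
# whole-molecule motions and clustered intramolecular kicks to the
# phase-spread weighted density; mode 3 refines side chains.  All modes
# use the simplex method with mode-specific step sizes, and the protocol
# enforces the R_work acceptance/reversion rules with omega contraction.

#' Weighted Pearson correlation
#'
#' Pearson correlation of `x` and `y` under non-negative weights `w`;
#' with uniform weights this reduces to the ordinary correlation.
#'
#' @param x,y numeric vectors.
#' @param w non-negative weights.
#' @return correlation coefficient.
#' @export
weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  if (sw <= 0) stop("non-positive weight total")
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  cxy <- sum(w * (x - mx) * (y - my))
  cx <- sum(w * (x - mx)^2); cy <- sum(w * (y - my)^2)
  if (cx <= 0 || cy <= 0) stop("zero-variance map in weighted correlation")
  cxy / sqrt(cx * cy)
}

#' Roughly uniform directions on the sphere
#'
#' Fibonacci-lattice unit vectors, used to scan candidate screw-rotation
#' directions.
#'
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  phi <- k * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# average (single-conformer) structure at the current mean torsions
.avg_positions <- function(model) {
  g <- model$graph
  anchor_pt <- matrix(as.numeric(g$atoms[g$anchor, c("x", "y", "z")]), 1)
  pts <- .build_points(g, 1, anchor_pt)
  t(vapply(pts, as.numeric, numeric(3)))
}

#' Real-space correlation target against a weighted map
#'
#' Prepares the cached parts of a segment comparison and returns a
#' closure that scores a model by the Pearson-weighted correlation
#' between the weighted density and the full calculated density, with
#' weights taken from the active-atom map alone.  Both maps live on the
#' unit-cell grid and the calculated coefficients are restricted to
#' exactly the Miller indices present in the data, so the two densities
#' carry identical Fourier content; the comparison runs over the voxel
#' list covering the active atoms plus the margin.  The surrounding-atom
#' density is computed once per target selection.
#'
#' @param model a `bondflex_model` (defines the segment bounds).
#' @param active integer indices of the active atoms.
#' @param wmap weighted density, a unit-cell `bondflex_grid`.
#' @param d nominal resolution, Angstrom.
#' @param refl the reflection data (defines the coefficient mask).
#' @param margin segment margin around the active atoms, Angstrom.
#' @param flexless optional flexless structure to reuse in rebuilds.
#' @return function(model) -> weighted correlation coefficient.
#' @export
make_cc_target <- function(model, active, wmap, d, refl, margin = 3,
                           flexless = NULL) {
  g <- model$graph
  cell <- model$cell
  dims <- wmap$dims
  ens0 <- build_ensemble(model, flexless = flexless)
  # coefficient mask: data Miller indices and their Friedel mates
  hkl <- as.matrix(refl$data[, c("h", "k", "l")])
  mask <- array(FALSE, dims)
  for (sgn in c(1, -1)) {
    ii <- cbind((sgn * hkl[, 1]) %% dims[1], (sgn * hkl[, 2]) %% dims[2],
                (sgn * hkl[, 3]) %% dims[3]) + 1
    mask[ii] <- TRUE
  }
  synth <- function(F) {
    F[!mask] <- 0
    Re(fft(F)) / cell$volume
  }
  synth_direct <- function(pts, elems) {
    fc <- direct_structure_factors(pts, elems, cell, hkl)
    Re(fft(.coeff_grid(hkl, fc, dims))) / cell$volume
  }
  # comparison voxel list: cell voxels covering the active clouds + margin
  act_pts <- do.call(rbind, ens0$pts[active])
  fr <- act_pts %*% t(cell$frac)
  lo <- floor((apply(fr, 2, min) - margin / cell$abc) * dims)
  hi <- ceiling((apply(fr, 2, max) + margin / cell$abc) * dims)
  vox <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  vox_idx <- cbind(vox[, 1] %% dims[1], vox[, 2] %% dims[2],
                   vox[, 3] %% dims[3]) + 1
  lin <- vox_idx[, 1] + dims[1] * (vox_idx[, 2] - 1) +
    dims[1] * dims[2] * (vox_idx[, 3] - 1)
  lin <- unique(lin)
  # surrounding atoms, computed once (exact direct summation)
  surround <- setdiff(seq_along(ens0$pts), active)
  surr_rho <- if (length(surround))
    synth_direct(ens0$pts[surround], g$atoms$elem[surround])
  else array(0, dims)
  wd <- as.vector(wmap$rho)[lin]
  surr_v <- as.vector(surr_rho)[lin]
  elem_act <- g$atoms$elem[active]
  function(m) {
    ens <- build_ensemble(m, flexless = flexless)
    act <- synth_direct(ens$pts[active], elem_act)
    av <- as.vector(act)[lin]
    weighted_pearson(wd, av + surr_v, pmax(av, 0))
  }
}

# periodic trilinear interpolation on a 3-d array at voxel coordinates
.interp_periodic <- function(arr, vox) {
  d <- dim(arr)
  f0 <- floor(vox)
  fr <- vox - f0
  out <- numeric(nrow(vox))
  for (corner in 0:7) {
    cx <- corner %% 2; cy <- (corner %/% 2) %% 2; cz <- corner %/% 4
    w <- (cx * fr[, 1] + (1 - cx) * (1 - fr[, 1])) *
      (cy * fr[, 2] + (1 - cy) * (1 - fr[, 2])) *
      (cz * fr[, 3] + (1 - cz) * (1 - fr[, 3]))
    ii <- cbind((f0[, 1] + cx) %% d[1], (f0[, 2] + cy) %% d[2],
                (f0[, 3] + cz) %% d[3]) + 1
    out <- out + w * arr[ii]
  }
  out
}

# ordered backbone torsion groups, anchor -> N terminus then anchor -> C
.backbone_group_lists <- function(graph) {
  grp <- graph$groups
  bb <- which(grp$backbone & grp$refinable)
  ordrank <- match(grp$id[bb], graph$order)
  bb <- bb[order(ordrank)]
  anchor_res <- graph$atoms$resno[graph$anchor]
  ctr <- grp$id[bb]
  nside <- graph$atoms$resno[ctr] < anchor_res |
    (graph$atoms$resno[ctr] == anchor_res & graph$atoms$name[ctr] == "N")
  list(n_side = bb[nside], c_side = bb[!nside])
}

#' Positional refinement against the original coordinates (mode 1)
#'
#' Removes the error propagated through the chain by imperfect initial
#' torsion estimates: windows of four sequential backbone torsions are
#' minimized in turn (simplex, max 60 steps, convergence at 0.005 deg)
#' against the mean absolute difference between the original positions
#' and the model average positions, evaluated over the refined bonds'
#' major and non-H minor atoms including sisters (carbonyl O, C-beta).
#' Windows run from the anchor to the N terminus, then to the C terminus;
#' side chains follow their supporting backbone.  Five passes: two
#' torsion-only at a 2 degree step, then three including C-beta /
#' aromatic C-gamma bond angles at 0.2 degrees.
#'
#' @param model a `bondflex_model`.
#' @param passes number of passes (5).
#' @param window window size in backbone bonds (4).
#' @param max_steps simplex step cap per window (60).
#' @return the refined model.
#' @export
refine_positions_mode1 <- function(model, passes = 5, window = 4,
                                   max_steps = 60) {
  g <- model$graph
  orig <- as.matrix(g$atoms[, c("x", "y", "z")])
  lists <- .backbone_group_lists(g)
  kids <- split(seq_len(nrow(g$atoms))[!is.na(g$atoms$parent)],
                g$atoms$parent[!is.na(g$atoms$parent)])
  eval_atoms <- function(grows) {
    ctr <- g$groups$id[grows]
    unique(c(ctr, unlist(lapply(ctr, function(p) {
      k <- kids[[as.character(p)]]
      k[!g$atoms$is_h[k]]
    }))))
  }
  sc_groups <- split(which(g$groups$sidechain & g$groups$refinable),
                     g$groups$resno[g$groups$sidechain & g$groups$refinable])
  ref_theta_by_res <- split(which(g$atoms$ref_theta),
                            g$atoms$resno[g$atoms$ref_theta])
  for (pass in seq_len(passes)) {
    with_angles <- pass > 2
    step <- if (with_angles) 0.2 else 2
    for (side in list(lists$n_side, lists$c_side)) {
      if (!length(side)) next
      starts <- seq_len(max(1, length(side) - window + 1))
      for (st in starts) {
        grows <- side[st:min(st + window - 1, length(side))]
        ev <- eval_atoms(grows)
        th_atoms <- integer(0)
        if (with_angles) {
          res_cov <- unique(g$groups$resno[grows])
          th_atoms <- unlist(ref_theta_by_res[as.character(res_cov)])
          th_atoms <- th_atoms[!is.na(th_atoms)]
        }
        par0 <- c(model$graph$groups$t[grows],
                  model$graph$atoms$theta[th_atoms])
        nt <- length(grows)
        obj <- function(p) {
          m <- model
          m$graph$groups$t[grows] <- p[seq_len(nt)]
          if (length(th_atoms))
            m$graph$atoms$theta[th_atoms] <- p[-seq_len(nt)]
          pos <- .avg_positions(m)
          mean(sqrt(rowSums((pos[ev, , drop = FALSE] -
                               orig[ev, , drop = FALSE])^2)))
        }
        res <- simplex_minimize(par0, step, obj, max_cycles = max_steps,
                                tol = 0.005)
        model$graph$groups$t[grows] <- res$par[seq_len(nt)]
        if (length(th_atoms))
          model$graph$atoms$theta[th_atoms] <- res$par[-seq_len(nt)]
      }
    }
    # side chains, once their supporting backbone has been refined
    for (res in names(sc_groups)) {
      grows <- sc_groups[[res]]
      ev <- eval_atoms(grows)
      par0 <- model$graph$groups$t[grows]
      obj <- function(p) {
        m <- model
        m$graph$groups$t[grows] <- p
        pos <- .avg_positions(m)
        mean(sqrt(rowSums((pos[ev, , drop = FALSE] -
                             orig[ev, , drop = FALSE])^2)))
      }
      res2 <- simplex_minimize(par0, step, obj, max_cycles = max_steps,
                               tol = 0.005)
      model$graph$groups$t[grows] <- res2$par
    }
  }
  model
}

# --- mode 2a: whole-molecule motions ------------------------------------

# T is refined through a Cholesky-like factor (T = L L', six free
# parameters) so candidate tensors stay positive semi-definite and the
# simplex never enters the clamped negative-eigenvalue region
.t_to_par <- function(T) {
  e <- eigen(T, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  L[lower.tri(L, diag = TRUE)]
}
.par_to_t <- function(p) {
  L <- matrix(0, 3, 3)
  L[lower.tri(L, diag = TRUE)] <- p
  L %*% t(L)
}

#' Whole-molecule refinement against the weighted density (mode 2a)
#'
#' Target: correlation of the backbone + C-beta density with the weighted
#' map.  On screw introduction, 31 Fibonacci-lattice directions are
#' scanned for the best rotation axis; then the three components of `r`,
#' the two of `w` (per screw) and the six of the translation tensor are
#' refined by simplex, at most 100 cycles each.  The first macrocycle
#' ends with three screw motions; later macrocycles re-refine the
#' existing parameters.
#'
#' @param model a `bondflex_model`.
#' @param wmap weighted density grid.
#' @param d nominal resolution.
#' @param refl reflection data (coefficient mask for the target).
#' @param first is this the first macrocycle (introduces 3 screws)?
#' @param max_cycles simplex cycle cap (100).
#' @param n_screws screws introduced in the first macrocycle.
#' @return the refined model.
#' @export
refine_whole_molecule_mode2a <- function(model, wmap, d, refl,
                                         first = TRUE,
                                         max_cycles = 100, n_screws = 3) {
  g <- model$graph
  active <- which(!g$atoms$is_h &
                    g$atoms$name %in% c("N", "CA", "C", "O", "CB"))
  flexless <- build_flexless(model)
  target <- make_cc_target(model, active, wmap, d, refl, margin = 3,
                           flexless = flexless)
  cc <- function(m) target(m)
  refine_r <- function(m, si) {
    obj <- function(p) { m$motions$screws[[si]]$r <- p; -cc(m) }
    res <- simplex_minimize(m$motions$screws[[si]]$r, 0.05, obj,
                            max_cycles = max_cycles, tol = 1e-5)
    m$motions$screws[[si]]$r <- res$par
    m
  }
  refine_w <- function(m, si) {
    obj <- function(p) { m$motions$screws[[si]]$w <- c(p, 0); -cc(m) }
    res <- simplex_minimize(m$motions$screws[[si]]$w[1:2], 0.2, obj,
                            max_cycles = max_cycles, tol = 1e-5)
    m$motions$screws[[si]]$w <- c(res$par, 0)
    m
  }
  introduce <- function(m) {
    dirs <- fibonacci_directions(31)
    r0 <- 0.1
    scores <- apply(dirs, 1, function(u) {
      m2 <- m
      m2$motions$screws <- c(m2$motions$screws,
                             list(list(r = u * r0, w = c(0, 0, 0))))
      cc(m2)
    })
    m$motions$screws <- c(m$motions$screws,
                          list(list(r = dirs[which.max(scores), ] * r0,
                                    w = c(0, 0, 0))))
    si <- length(m$motions$screws)
    m <- refine_r(m, si)
    refine_w(m, si)
  }
  if (first) {
    for (k in seq_len(n_screws)) model <- introduce(model)
  } else {
    for (si in seq_along(model$motions$screws)) {
      model <- refine_r(model, si)
      model <- refine_w(model, si)
    }
  }
  objT <- function(p) { model$motions$T <- .par_to_t(p); -cc(model) }
  res <- simplex_minimize(.t_to_par(model$motions$T), 0.1, objT,
                          max_cycles = max_cycles, tol = 1e-6)
  model$motions$T <- .par_to_t(res$par)
  model
}

# --- mode 2b: clustered intramolecular flexibility ----------------------

#' Group bonds with similar flex effects (mode 2b clustering)
#'
#' Scores every pair of refinable backbone bonds by the similarity of
#' their rotation effects on the C-alpha atom points: per point, the
#' cosine of the angle between the two rotation-effect vectors times the
#' smaller magnitude ratio, times both s factors, summed over points and
#' C-alpha atoms (unity for a perfect match).  The matrix is
#' antisymmetrized (score(q,p) = -score(p,q), zero diagonal) and SVD
#' decomposed; the top ten singular vectors, or as many as cover 50% of
#' the total singular-value sum, whichever is larger, become clusters,
#' each carrying independent k and k' multipliers (so at least 20
#' refined parameters).
#'
#' @param model a `bondflex_model`.
#' @param flexless flexless structure (rebuilt when omitted).
#' @return list with `bonds` (group rows), `score` (antisymmetric
#'   matrix), `weights` (bond x cluster matrix), `values` (singular
#'   values).
#' @export
cluster_bonds_for_flex <- function(model, flexless = NULL) {
  g <- model$graph
  if (is.null(flexless)) flexless <- build_flexless(model)
  grp <- g$groups
  bonds <- which(grp$backbone & grp$refinable)
  nb <- length(bonds)
  S <- .s_factors(g, flexless$cache)
  # descendants of each bond's minor atom
  parent <- g$atoms$parent
  desc <- vector("list", nrow(g$atoms))
  for (i in rev(g$order)) {
    ki <- which(parent == i)
    desc[[i]] <- c(i, unlist(desc[ki]))
  }
  cas <- g$calphas$idx
  # rotation-effect vectors: bond b on C-alpha c, per point (J x 3)
  eff <- vector("list", nb)
  for (bi in seq_len(nb)) {
    p <- grp$id[bonds[bi]]
    axis <- flexless$pts[[p]] - flexless$pts[[parent[p]]]
    axis <- axis / sqrt(rowSums(axis^2))
    down <- desc[[p]]
    eff[[bi]] <- lapply(seq_along(cas), function(ci) {
      if (!(cas[ci] %in% down)) return(NULL)
      arm <- flexless$pts[[cas[ci]]] - flexless$pts[[p]]
      vcross(axis, arm)
    })
  }
  score <- matrix(0, nb, nb)
  for (pq in which(upper.tri(matrix(0, nb, nb)))) {
    p <- (pq - 1) %% nb + 1
    q <- (pq - 1) %/% nb + 1
    tot <- 0
    for (ci in seq_along(cas)) {
      vp <- eff[[p]][[ci]]; vq <- eff[[q]][[ci]]
      if (is.null(vp) || is.null(vq)) next
      np <- sqrt(rowSums(vp^2)); nq <- sqrt(rowSums(vq^2))
      ok <- np > 1e-12 & nq > 1e-12
      if (!any(ok)) next
      cosang <- rowSums(vp * vq)[ok] / (np[ok] * nq[ok])
      ratio <- pmin(np[ok] / nq[ok], nq[ok] / np[ok])
      tot <- tot + sum(cosang * ratio * S[bonds[p], ok] * S[bonds[q], ok])
    }
    score[p, q] <- tot
    score[q, p] <- -tot
  }
  sv <- svd(score)
  cum <- cumsum(sv$d) / max(sum(sv$d), 1e-12)
  m50 <- which(cum >= 0.5)[1]
  m <- max(10, m50)
  if (m > nb) {
    message("chain provides only ", nb, " bond vectors; using all")
    m <- nb
  }
  list(bonds = bonds, score = score, weights = sv$v[, seq_len(m),
                                                    drop = FALSE],
       values = sv$d)
}

# apply cluster multipliers to per-bond kicks; k' goes to the bond's
# C-alpha when the bond's minor atom is a C-alpha
.apply_cluster_kicks <- function(model, clusters, mult) {
  nc <- ncol(clusters$weights)
  mk <- mult[seq_len(nc)]
  mkp <- mult[nc + seq_len(nc)]
  kb <- as.numeric(clusters$weights %*% mk)
  kpb <- as.numeric(clusters$weights %*% mkp)
  g <- model$graph
  model$graph$groups$kick[clusters$bonds] <- kb
  for (bi in seq_along(clusters$bonds)) {
    p <- g$groups$id[clusters$bonds[bi]]
    ci <- match(p, g$calphas$idx)
    if (!is.na(ci) && g$calphas$eligible[ci])
      model$graph$calphas$rkick[ci] <- kpb[bi]
  }
  model
}

#' Intramolecular flexibility refinement (mode 2b)
#'
#' Refines the cluster-level k and k' multipliers by simplex against the
#' backbone + C-beta correlation target; per-bond kicks are the
#' weighted sums of the cluster contributions.
#'
#' @param model a `bondflex_model`.
#' @param clusters output of [cluster_bonds_for_flex()].
#' @param wmap weighted density grid.
#' @param d nominal resolution.
#' @param refl reflection data (coefficient mask for the target).
#' @param max_cycles simplex cycle cap.
#' @param step multiplier step size.
#' @return the refined model (kicks set).
#' @export
refine_flex_mode2b <- function(model, clusters, wmap, d, refl,
                               max_cycles = 100, step = 0.2) {
  g <- model$graph
  active <- which(!g$atoms$is_h &
                    g$atoms$name %in% c("N", "CA", "C", "O", "CB"))
  flexless <- build_flexless(model)
  target <- make_cc_target(model, active, wmap, d, refl, margin = 3,
                           flexless = flexless)
  nc <- ncol(clusters$weights)
  obj <- function(p) -target(.apply_cluster_kicks(model, clusters, p))
  res <- simplex_minimize(rep(0, 2 * nc), step, obj,
                          max_cycles = max_cycles, tol = 1e-5)
  .apply_cluster_kicks(model, clusters, res$par)
}

#' Side-chain refinement (mode 3)
#'
#' Every side chain in turn is refined against the weighted density with
#' the whole monomer (including backbone) as active atoms and a 3 A
#' segment margin.  Parameters and step sizes: side-chain torsions and
#' refinable bond angles 0.1 degrees, kicks 0.5 (dimensionless),
#' alpha/beta angles 30 degrees.
#'
#' @param model a `bondflex_model`.
#' @param wmap weighted density grid.
#' @param d nominal resolution.
#' @param refl reflection data (coefficient mask for the target).
#' @param max_cycles simplex cycle cap per side chain.
#' @return the refined model.
#' @export
refine_sidechains_mode3 <- function(model, wmap, d, refl,
                                    max_cycles = 100) {
  g <- model$graph
  sc <- split(which(g$groups$sidechain & g$groups$refinable),
              g$groups$resno[g$groups$sidechain & g$groups$refinable])
  for (res in names(sc)) {
    grows <- sc[[res]]
    resno <- as.integer(res)
    monomer <- which(g$atoms$resno == resno & !g$atoms$is_h)
    th_atoms <- which(g$atoms$ref_theta & g$atoms$resno == resno)
    target <- make_cc_target(model, monomer, wmap, d, refl, margin = 3)
    nt <- length(grows); nth <- length(th_atoms)
    par0 <- c(model$graph$groups$t[grows],
              model$graph$atoms$theta[th_atoms],
              model$graph$groups$kick[grows],
              model$graph$groups$alpha[grows],
              model$graph$groups$beta[grows])
    steps <- c(rep(0.1, nt), rep(0.1, nth), rep(0.5, nt), rep(30, nt),
               rep(30, nt))
    build <- function(p) {
      m <- model
      m$graph$groups$t[grows] <- p[seq_len(nt)]
      if (nth) m$graph$atoms$theta[th_atoms] <- p[nt + seq_len(nth)]
      m$graph$groups$kick[grows] <- p[nt + nth + seq_len(nt)]
      m$graph$groups$alpha[grows] <- p[nt + nth + nt + seq_len(nt)]
      m$graph$groups$beta[grows] <- p[nt + nth + 2 * nt + seq_len(nt)]
      m
    }
    res2 <- simplex_minimize(par0, steps, function(p) -target(build(p)),
                             max_cycles = max_cycles, tol = 1e-4)
    model <- build(res2$par)
  }
  model
}

# --- protocol ------------------------------------------------------------

#' Contract the cloud radius omega while R_work decreases
#'
#' Implements the flexibility-contraction rule: omega is reduced by 10%
#' per step for as long as the contraction keeps lowering R_work.
#'
#' @param model a `bondflex_model`.
#' @param refl a `bondflex_reflections` object.
#' @param solvent include the bulk-solvent model in F_calc?
#' @return list with the (possibly) contracted `model`, its R factors
#'   `r`, and the number of accepted 10% `steps`.
#' @export
contract_omega <- function(model, refl, solvent = FALSE) {
  r <- model_r_factors(model, refl, solvent = solvent)
  steps <- 0
  repeat {
    cand <- model
    cand$omega <- model$omega * 0.9
    rc <- model_r_factors(cand, refl, solvent = solvent)
    if (rc$r_work < r$r_work) {
      model <- cand; r <- rc; steps <- steps + 1
    } else break
  }
  list(model = model, r = r, steps = steps)
}

#' R factors of a model against reflection data
#'
#' Computes model structure factors on the reflection list (with the
#' solvent contribution fitted when requested) and the R factors over the
#' working and free sets.
#'
#' @param model a `bondflex_model`.
#' @param refl a `bondflex_reflections` object.
#' @param solvent include and fit the bulk-solvent contribution?
#' @param method `"fft"` (grid deposition, scales to large systems) or
#'   `"direct"` (exact per-point summation, preferable for small
#'   fixtures; requires P 1 without B-factor-model atoms).
#' @return list with `r_work`, `r_free`, complex `f_calc`, solvent `k`,
#'   `b` and the cell-grid `dims`.
#' @export
model_r_factors <- function(model, refl, solvent = FALSE,
                            method = c("fft", "direct")) {
  method <- match.arg(method)
  hkl <- as.matrix(refl$data[, c("h", "k", "l")])
  dims <- vapply(model$cell$abc,
                 function(len) next235(len / voxel_edge(refl$d_min)), 0L)
  if (method == "direct" && !solvent &&
      length(model$cell$ops) == 1 &&
      (is.null(model$graph$het) || !nrow(model$graph$het))) {
    ens <- build_ensemble(model)
    f_expl <- direct_structure_factors(ens$pts, model$graph$atoms$elem,
                                       model$cell, hkl)
    f_solv <- rep(0 + 0i, nrow(hkl))
  } else {
    ens <- build_ensemble(model)
    fm <- compute_f_model(model, ens, d_min = refl$d_min,
                          solvent = solvent, hkl = hkl)
    f_expl <- fm$f_expl; f_solv <- fm$f_solv; dims <- fm$dims
  }
  sc <- scale_solvent_and_assemble(f_expl, f_solv, refl$data$fobs,
                                   refl$data$d, fit = solvent)
  r <- compute_r_factors(refl$data$fobs, Mod(sc$f_calc), refl$data$free)
  list(r_work = r$r_work, r_free = r$r_free, f_calc = sc$f_calc,
       k = sc$k, b = sc$b, dims = dims)
}

#' Run the full refinement protocol
#'
#' Mode 1 (five positional passes), then macrocycles of whole-molecule
#' (2a) and intramolecular (2b) refinement against freshly synthesized
#' phase-spread weighted maps with the acceptance rules: a stage that
#' increases R_work is reverted; after three rising intramolecular cycles
#' omega is contracted by 10% for as long as R_work keeps decreasing;
#' before side-chain refinement the state reverts to the best cycle; a
#' mode 3 that increases R_work is reverted too.  R_free is reported
#' every cycle but never drives any decision.
#'
#' @param model a `bondflex_model`.
#' @param refl a `bondflex_reflections` object.
#' @param n_macrocycles macrocycles of modes 2a/2b.
#' @param solvent include the bulk-solvent model in F_calc?
#' @param mode3 run side-chain refinement?
#' @param max_cycles simplex cycle cap for the density modes.
#' @param verbose print per-cycle R factors?
#' @return list with `model`, `log` (data frame of stage, r_work,
#'   r_free), and the final `r_work`/`r_free`.
#' @export
run_protocol <- function(model, refl, n_macrocycles = 3, solvent = FALSE,
                         mode3 = TRUE, max_cycles = 100, verbose = FALSE) {
  log <- data.frame(stage = character(), r_work = numeric(),
                    r_free = numeric())
  note <- function(stage, r) {
    log <<- rbind(log, data.frame(stage = stage, r_work = r$r_work,
                                  r_free = r$r_free))
    if (verbose)
      message(sprintf("%-12s R_work %.4f  R_free %.4f", stage, r$r_work,
                      r$r_free))
  }
  model <- refine_positions_mode1(model)
  r <- model_r_factors(model, refl, solvent = solvent)
  note("mode1", r)
  best <- list(model = model, r_work = r$r_work)
  rising <- 0
  d <- refl$d_min
  for (cyc in seq_len(n_macrocycles)) {
    wmap <- synthesize_weighted_map(refl, r$f_calc, r$dims)
    # mode 2a with reversion
    cand <- refine_whole_molecule_mode2a(model, wmap, d, refl,
                                         first = cyc == 1,
                                         max_cycles = max_cycles)
    rc <- model_r_factors(cand, refl, solvent = solvent)
    if (rc$r_work <= r$r_work) {
      model <- cand; r <- rc
    } else {
      # reverted: motions stay, so roll the candidate state back
      rc <- r
    }
    note(sprintf("mode2a.%d", cyc), rc)
    # mode 2b with reversion and omega contraction
    clusters <- cluster_bonds_for_flex(model)
    cand <- refine_flex_mode2b(model, clusters, wmap, d, refl,
                               max_cycles = max_cycles)
    rc <- model_r_factors(cand, refl, solvent = solvent)
    if (rc$r_work <= r$r_work) {
      model <- cand; r <- rc; rising <- 0
    } else {
      rising <- rising + 1
      rc <- r
      if (rising >= 3) {
        co <- contract_omega(model, refl, solvent = solvent)
        if (co$steps > 0) {
          model <- co$model; r <- co$r
          note("omega", r)
        }
        rising <- 0
      }
    }
    note(sprintf("mode2b.%d", cyc), rc)
    if (r$r_work < best$r_work)
      best <- list(model = model, r_work = r$r_work)
  }
  # revert to the best cycle before side-chain refinement
  if (best$r_work < r$r_work) {
    model <- best$model
    r <- model_r_factors(model, refl, solvent = solvent)
  }
  if (mode3) {
    wmap <- synthesize_weighted_map(refl, r$f_calc, r$dims)
    cand <- refine_sidechains_mode3(model, wmap, d, refl,
                                    max_cycles = max_cycles)
    rc <- model_r_factors(cand, refl, solvent = solvent)
    if (rc$r_work <= r$r_work) {
      model <- cand; r <- rc
    } else rc <- r
    note("mode3", rc)
  }
  list(model = model, log = log, r_work = r$r_work, r_free = r$r_free)
}
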