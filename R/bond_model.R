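# The bond-based model: a protein chain re-expressed as a tree of bonds
# rooted at a single anchor atom.  Every atom is generated from its parent
# through a bond length, a bond angle and a torsion angle; torsions are
# organised in groups (all children of one atom) so that rotating a bond
# moves the whole downstream branch rigidly.

.std_residues <- function() names(residue_templates())

#' Build bond connectivity from atom records
#'
#' Constructs the heavy-atom bond tree for a single polypeptide chain:
#' within-residue connectivity from the residue templates plus the peptide
#' C(i-1)-N(i) link.  Hydrogens in the input are discarded (they are
#' regenerated later); HETATM records and non-standard residues are kept
#' aside as B-factor-model atoms.  Records carrying alternate-location
#' indicators are rejected in strict mode or reduced to the
#' highest-occupancy conformer in lenient mode.
#'
#' @param records data frame of atom records (see [make_ideal_peptide()]
#'   or [read_pdb()]).
#' @param altloc `"strict"` (error on any alternate location) or
#'   `"lenient"` (keep the highest-occupancy conformer).
#' @return an (unrooted) `bondflex_graph`: atoms, edge list, het records.
#' @export
build_connectivity <- function(records, altloc = c("strict", "lenient")) {
  altloc <- match.arg(altloc)
  if (is.null(records) || nrow(records) == 0) stop("no atom records")
  if (is.null(records$is_h)) records$is_h <- element_of(records$name) == "H"
  if (!is.null(records$alt)) {
    has_alt <- !(records$alt %in% c("", " "))
    if (any(has_alt)) {
      if (altloc == "strict")
        stop("alternate-location records present (strict mode): residue ",
             records$resno[has_alt][1])
      ord <- order(records$resno, records$name, -records$occ)
      records <- records[ord, ]
      records <- records[!duplicated(records[, c("chain", "resno", "name")]), ]
      records <- records[order(records$serial), ]
      records$had_alt <- TRUE   # coarse marker used by anchor choice
    }
  }
  tmpl <- residue_templates()
  std <- records$type == "ATOM" & records$resname %in% names(tmpl)
  het <- records[!std, , drop = FALSE]
  rec <- records[std & !records$is_h, , drop = FALSE]
  if (nrow(rec) == 0) stop("no standard protein ATOM records")
  chains <- unique(rec$chain)
  if (length(chains) > 1)
    stop("one chain per bond graph; got: ", paste(chains, collapse = ", "))

  resnos <- sort(unique(rec$resno))
  if (length(resnos) > 1 && any(diff(resnos) != 1))
    stop("chain break: residue numbering gap after residue ",
         resnos[which(diff(resnos) != 1)[1]])

  atoms <- NULL
  edges <- NULL
  for (rn in resnos) {
    rr <- rec[rec$resno == rn, ]
    code <- rr$resname[1]
    tt <- tmpl[[code]]
    theavy <- tt[!grepl("^H", tt$name), ]
    missing <- setdiff(theavy$name, rr$name)
    if (length(missing))
      stop("incomplete residue ", code, " ", rn, ": missing ",
           paste(missing, collapse = ", "))
    keep <- rr[match(theavy$name, rr$name), ]
    atoms <- rbind(atoms, keep)
    within <- theavy[theavy$parent != "-C", ]
    edges <- rbind(edges,
                   data.frame(resno = rn, a = within$parent, b = within$name),
                   if (rn > resnos[1])
                     data.frame(resno = rn, a = "-C", b = "N"))
  }
  atoms$idx <- seq_len(nrow(atoms))
  g <- list(atoms = atoms, edges = edges, het = het,
            chain = atoms$chain[1], resnos = resnos)
  class(g) <- "bondflex_graph"
  g
}

.atom_idx <- function(g, resno, name) {
  i <- which(g$atoms$resno == resno & g$atoms$name == name)
  if (length(i) != 1) stop("atom lookup failed: ", resno, " ", name)
  i
}

#' Choose the anchor atom
#'
#' The anchor defaults to the backbone N atom of the residue whose N lies
#' closest to the centre of mass of the chain; N atoms that carried
#' alternate conformations in the input are not considered.
#'
#' @param graph a `bondflex_graph`.
#' @return atom index of the anchor.
#' @export
choose_anchor <- function(graph) {
  a <- graph$atoms
  com <- colMeans(a[!a$is_h, c("x", "y", "z")])
  ns <- a[a$name == "N", , drop = FALSE]
  if (!is.null(ns$had_alt)) ns <- ns[!isTRUE(ns$had_alt), , drop = FALSE]
  if (nrow(ns) == 0) stop("no eligible backbone N atom for the anchor")
  d2 <- (ns$x - com[1])^2 + (ns$y - com[2])^2 + (ns$z - com[3])^2
  ns$idx[which.min(d2)]
}

# --- canonical geometry (lengths/angles measured off ideal residues) -----

.ideal_tables <- function() {
  if (!is.null(.pkgenv$ideal)) return(.pkgenv$ideal)
  lengths <- new.env(parent = emptyenv())
  angles <- new.env(parent = emptyenv())
  codes <- .std_residues()
  one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PRO = "P", SER = "S",
           THR = "T", TRP = "W", TYR = "Y", VAL = "V", PHE = "F")
  for (code in codes) {
    pep <- make_ideal_peptide(paste0("G", one[[code]], "G"), ss = "loop")
    r <- pep$records
    pos <- function(resno, name) {
      z <- r[r$resno == resno & r$name == name, ]
      if (nrow(z) != 1) return(NULL)
      c(z$x, z$y, z$z)
    }
    # neighbour lists for residue 2 (centre) incl. cross-residue links
    tmpl <- residue_templates()[[code]]
    nb <- list()
    addnb <- function(a, b) {
      nb[[a]] <<- c(nb[[a]], b); nb[[b]] <<- c(nb[[b]], a)
    }
    for (i in seq_len(nrow(tmpl))) {
      p <- tmpl$parent[i]
      addnb(if (p == "-C") "C-1" else p, tmpl$name[i])
    }
    addnb("C", "N+1")
    resolve <- function(nm) {
      if (nm == "C-1") pos(1, "C")
      else if (nm == "N+1") pos(3, "N")
      else pos(2, nm)
    }
    for (ctr in names(nb)) {
      if (ctr %in% c("C-1", "N+1")) next
      pc <- resolve(ctr)
      nbs <- unique(nb[[ctr]])
      for (x in nbs) {
        px <- resolve(x)
        if (is.null(px) || is.null(pc)) next
        lengths[[paste(code, paste(sort(c(ctr, x)), collapse = "|"),
                       sep = "|")]] <- sqrt(sum((px - pc)^2))
      }
      if (length(nbs) >= 2) {
        cmb <- utils::combn(nbs, 2)
        for (k in seq_len(ncol(cmb))) {
          p1 <- resolve(cmb[1, k]); p2 <- resolve(cmb[2, k])
          if (is.null(p1) || is.null(p2)) next
          angles[[paste(code, ctr, paste(sort(cmb[, k]), collapse = "|"),
                        sep = "|")]] <- bond_angle(p1, pc, p2)
        }
      }
    }
  }
  .pkgenv$ideal <- list(lengths = lengths, angles = angles)
  .pkgenv$ideal
}

.canon_length <- function(code, a, b, fallback) {
  v <- .ideal_tables()$lengths[[paste(code, paste(sort(c(a, b)),
                                                  collapse = "|"), sep = "|")]]
  if (is.null(v)) fallback else v
}

.canon_angle <- function(code, ctr, a, b, fallback) {
  v <- .ideal_tables()$angles[[paste(code, ctr, paste(sort(c(a, b)),
                                                      collapse = "|"),
                                     sep = "|")]]
  if (is.null(v)) fallback else v
}

# --- hydrogen regeneration ----------------------------------------------

#' Regenerate hydrogen atoms
#'
#' Discards any hydrogens carried by the input and rebuilds them from the
#' heavy-atom geometry at template torsion angles, all at a bond length of
#' exactly 0.968 Angstrom.
#'
#' @param graph a `bondflex_graph` (heavy atoms connected).
#' @return the graph with hydrogen atoms appended (positions set).
#' @export
regenerate_hydrogens <- function(graph) {
  a <- graph$atoms
  tmpl <- residue_templates()
  pos <- function(resno, name) {
    i <- which(a$resno == resno & a$name == name)
    if (length(i) != 1) return(NULL)
    as.numeric(a[i, c("x", "y", "z")])
  }
  newrows <- list()
  for (rn in graph$resnos) {
    code <- a$resname[a$resno == rn][1]
    tt <- tmpl[[code]]
    fparent <- stats::setNames(tt$parent, tt$name)
    respos <- function(nm) {
      if (nm == "-C") pos(rn - 1, "C")
      else if (nm == "-CA") pos(rn - 1, "CA")
      else pos(rn, nm)
    }
    fgp <- function(nm) {
      p <- fparent[[nm]]
      if (is.null(p) || is.na(p)) return(NULL)
      if (p == "-C") return("-C")
      p
    }
    hrows <- tt[grepl("^H", tt$name), , drop = FALSE]
    for (i in seq_len(nrow(hrows))) {
      row <- hrows[i, ]
      P <- row$parent
      gpn <- fgp(P)
      ggn <- if (is.null(gpn)) NULL
             else if (gpn == "-C") "-CA" else fgp(gpn)
      pp <- respos(P); pg <- if (is.null(gpn)) NULL else respos(gpn)
      pgg <- if (is.null(ggn)) NULL else respos(ggn)
      ang <- row$ang; tau <- NA
      if (is.null(pg)) {
        # chain start: place the amide H from within-residue references
        pg <- respos("CA"); pgg <- respos("C")
        if (is.null(pg) || is.null(pgg)) next
        ang <- 117; tau <- 180
      } else if (is.null(pgg)) {
        # missing great-grandparent (chain start): any fixed non-colinear
        # reference works, offsets are measured in the same frame
        v <- pp - pg
        e <- diag(3)[, which.min(abs(v))]
        pgg <- pg + (e - sum(e * v) * v / sum(v^2))
        drv <- tt$name[tt$parent == P & is.na(tt$off)][1]
        dpos <- if (is.na(drv)) NULL else respos(drv)
        tau <- if (is.na(row$off)) row$tor0
               else torsion_angle(pgg, pg, pp, dpos) + row$off
      } else if (is.na(row$off)) {
        tau <- row$tor0
      } else {
        drv <- tt$name[tt$parent == P & is.na(tt$off)][1]
        if (is.na(drv) && P == "C") drv <- "N+1"
        dpos <- if (identical(drv, "N+1")) pos(rn + 1, "N") else respos(drv)
        if (!is.null(dpos)) {
          tau <- torsion_angle(pgg, pg, pp, dpos) + row$off
        } else if (!is.na(drv) && drv %in% tt$name &&
                   !is.na(tt$tor0[tt$name == drv])) {
          # driver is itself a generated hydrogen (methyl etc.): its
          # template torsion is absolute in the same reference frame
          tau <- tt$tor0[tt$name == drv] + row$off
        } else {
          tau <- row$off
        }
      }
      hp <- as.vector(nerf_place(pgg, pg, pp, H_BOND_LENGTH, ang, tau))
      tmplrow <- a[a$resno == rn, ][1, ]
      tmplrow$name <- row$name; tmplrow$elem <- "H"; tmplrow$is_h <- TRUE
      tmplrow$x <- hp[1]; tmplrow$y <- hp[2]; tmplrow$z <- hp[3]
      tmplrow$serial <- NA
      newrows[[length(newrows) + 1]] <-
        list(row = tmplrow, edge = data.frame(resno = rn, a = P, b = row$name))
    }
  }
  if (length(newrows)) {
    graph$atoms <- rbind(a, do.call(rbind, lapply(newrows, `[[`, "row")))
    graph$edges <- rbind(graph$edges,
                         do.call(rbind, lapply(newrows, `[[`, "edge")))
    graph$atoms$idx <- seq_len(nrow(graph$atoms))
  }
  graph
}

# --- rooting and torsion derivation -------------------------------------

.anchor_frame <- function(xyz, parent, anchor) {
  kids1 <- which(parent == anchor)
  u1 <- xyz[kids1[1], ] - xyz[anchor, ]
  u1 <- u1 / sqrt(sum(u1^2))
  # second reference: another child of the anchor, or a grandchild
  ref2 <- if (length(kids1) > 1) kids1[2] else which(parent == kids1[1])[1]
  v <- xyz[ref2, ] - xyz[anchor, ]
  u2 <- v - sum(v * u1) * u1
  if (sqrt(sum(u2^2)) < 1e-6) stop("degenerate anchor frame")
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  unname(cbind(u1, u2, u3))
}

.rotatable_pair <- function(code, gp_name, p_name) {
  pr <- sort(c(gp_name, p_name))
  if (identical(pr, c("CA", "N")) || identical(pr, c("C", "CA"))) return(TRUE)
  if (identical(pr, c("C", "N"))) return(FALSE)     # peptide bond
  # side chain: look up the template group at p
  tt <- residue_templates()[[code]]
  drv <- which(tt$parent == p_name & is.na(tt$off))
  if (!length(drv)) return(FALSE)
  isTRUE(tt$ref[drv[1]])
}

#' Derive initial torsion angles and finalize the bond graph
#'
#' Roots the bond tree at the anchor, measures every placement parameter
#' (bond length, bond angle, torsion) from the original positions, then
#' imposes canonical bond lengths and angles while keeping the measured
#' torsions.  Torsion groups, member offsets, refinability flags and the
#' anchor frame are all established here.
#'
#' @param graph a `bondflex_graph` with hydrogens regenerated.
#' @param anchor anchor atom index (default: [choose_anchor()]).
#' @return the rooted, parametrized graph.
#' @export
derive_initial_torsions <- function(graph, anchor = NULL) {
  if (is.null(anchor)) anchor <- choose_anchor(graph)
  a <- graph$atoms
  n <- nrow(a)
  # adjacency from the edge list
  eidx <- cbind(mapply(function(rn, nm) .atom_idx(graph, if (nm == "-C")
    rn - 1 else rn, if (nm == "-C") "C" else nm),
    graph$edges$resno, graph$edges$a),
    mapply(function(rn, nm) .atom_idx(graph, rn, nm),
           graph$edges$resno, graph$edges$b))
  adj <- vector("list", n)
  for (i in seq_len(nrow(eidx))) {
    adj[[eidx[i, 1]]] <- c(adj[[eidx[i, 1]]], eidx[i, 2])
    adj[[eidx[i, 2]]] <- c(adj[[eidx[i, 2]]], eidx[i, 1])
  }
  # BFS rooting; children ordered backbone-first, heavy before H
  prio <- function(i) {
    base <- match(a$name[i], c("CA", "N", "C"), nomatch = 10)
    if (a$is_h[i]) base <- base + 100
    base * 1e6 + i
  }
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  ord <- integer(0)
  queue <- anchor; visited[anchor] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ord <- c(ord, cur)
    kids <- adj[[cur]][!visited[adj[[cur]]]]
    if (length(kids)) {
      kids <- kids[order(vapply(kids, prio, 0))]
      parent[kids] <- cur
      visited[kids] <- TRUE
      queue <- c(queue, kids)
    }
  }
  if (!all(visited)) stop("disconnected bond graph")
  gp <- ifelse(is.na(parent), NA, parent[parent])
  ggp <- ifelse(is.na(gp), NA, parent[gp])

  # anchor frame from the original positions; built from structure
  # directions only, so it rotates with the molecule
  xyz <- as.matrix(a[, c("x", "y", "z")])
  frame <- .anchor_frame(xyz, parent, anchor)
  v1 <- xyz[anchor, ] + frame[, 2]  # virtual grandparent
  v2 <- xyz[anchor, ] + frame[, 3]  # virtual great-grandparent

  posof <- function(i, virt) {
    if (!is.na(i)) return(xyz[i, ])
    if (virt == 1) v1 else v2
  }
  l <- theta <- tor <- rep(NA_real_, n)
  for (i in ord) {
    if (i == anchor) next
    p <- parent[i]
    pg <- if (is.na(gp[i])) v1 else xyz[gp[i], ]
    pgg <- if (is.na(gp[i])) v2 else if (is.na(ggp[i])) v1 else xyz[ggp[i], ]
    l[i] <- sqrt(sum((xyz[i, ] - xyz[p, ])^2))
    theta[i] <- bond_angle(pg, xyz[p, ], xyz[i, ])
    tor[i] <- torsion_angle(pgg, pg, xyz[p, ], xyz[i, ])
  }
  # impose canonical geometry where tabulated (virtual-referenced atoms
  # keep their measured angles relative to the frame)
  for (i in ord) {
    if (i == anchor || is.na(gp[i])) next
    code <- a$resname[i]
    same_res <- a$resno[i] == a$resno[parent[i]]
    nm_i <- a$name[i]; nm_p <- a$name[parent[i]]; nm_g <- a$name[gp[i]]
    tagged <- function(j, ref) {
      if (a$resno[j] == ref) a$name[j]
      else paste0(a$name[j], ifelse(a$resno[j] > ref, "+1", "-1"))
    }
    if (a$is_h[i]) {
      l[i] <- H_BOND_LENGTH
    } else {
      lcode <- if (same_res) code else NA
      if (same_res) {
        l[i] <- .canon_length(code, nm_i, nm_p, l[i])
      } else l[i] <- 1.329                      # peptide bond
      ctr_res <- a$resname[parent[i]]
      theta[i] <- .canon_angle(ctr_res, nm_p,
                               tagged(i, a$resno[parent[i]]),
                               tagged(gp[i], a$resno[parent[i]]), theta[i])
    }
  }

  # torsion groups: children of each parent; driver = first child in order
  ordrank <- match(seq_len(n), ord)
  groups <- NULL
  toffset <- rep(0, n)
  for (p in unique(parent[!is.na(parent)])) {
    kids <- which(parent == p)
    kids <- kids[order(ordrank[kids])]
    drv <- kids[1]
    toffset[kids] <- tor[kids] - tor[drv]
    gpname <- if (p == anchor) NA_character_ else a$name[parent[p]]
    refin <- if (p == anchor) FALSE
             else .rotatable_pair(a$resname[p], gpname, a$name[p])
    # groups consisting solely of hydrogens are never refined
    if (all(a$is_h[kids])) refin <- FALSE
    groups <- rbind(groups, data.frame(
      id = p, driver = drv, t = tor[drv], refinable = refin,
      kick = 0, alpha = 0, beta = 0,
      sidechain = !(a$name[p] %in% c("N", "CA", "C")),
      backbone = a$name[p] %in% c("N", "CA", "C"),
      resno = a$resno[p]))
  }
  graph$atoms$parent <- parent
  graph$atoms$l <- l
  graph$atoms$theta <- theta
  graph$atoms$tor <- tor
  graph$atoms$toffset <- toffset
  graph$atoms$ref_theta <- with(graph$atoms,
    !is_h & (name == "CB" |
             (name == "CG" & resname %in% c("PHE", "TYR", "TRP", "HIS"))))
  graph$anchor <- anchor
  graph$order <- ord
  graph$frame <- frame
  graph$groups <- groups
  ca <- graph$atoms[graph$atoms$name == "CA", ]
  graph$calphas <- data.frame(resno = ca$resno, idx = ca$idx,
                              rkick = 0,
                              eligible = ca$resno != graph$atoms$resno[anchor])
  graph$rooted <- TRUE
  graph
}

#' Refinable-parameter inventory
#'
#' Enumerates the refinable parameters of the bond-based parametrization
#' (torsions, kicks, bond angles, alpha/beta axis pairs, whole-molecule
#' motion parameters) and compares against atomistic counting at four
#' parameters per non-hydrogen atom.
#'
#' @param graph a rooted `bondflex_graph`.
#' @param n_screws number of screw motions (5 parameters each).
#' @return list with the per-category counts, `total`, `atomistic`
#'   (4 x non-H atom count) and `reduction` (fraction).
#' @export
count_refinable_parameters <- function(graph, n_screws = 3) {
  stopifnot(isTRUE(graph$rooted))
  g <- graph$groups
  torsions <- sum(g$refinable)
  fwd_kicks <- sum(g$refinable)      # every refinable torsion carries a kick
  rev_kicks <- sum(graph$calphas$eligible)
  angles <- sum(graph$atoms$ref_theta)
  ab_pairs <- 2 * sum(g$refinable & g$sidechain)
  whole <- 6 + 5 * n_screws + 1      # T, screws, omega (per chain)
  total <- torsions + fwd_kicks + rev_kicks + angles + ab_pairs + whole
  n_atoms <- sum(!graph$atoms$is_h)
  atomistic <- 4 * n_atoms
  list(torsions = torsions, kicks = fwd_kicks + rev_kicks,
       bond_angles = angles, alpha_beta = ab_pairs,
       whole_molecule = whole, total = total,
       atomistic = atomistic, reduction = 1 - total / atomistic)
}

#' Assemble a refinable model from atom records
#'
#' Convenience constructor running connectivity building, anchor choice,
#' hydrogen regeneration and torsion derivation, and attaching the
#' whole-molecule motion state (translation tensor, screw motions, cloud
#' radius omega) and the unit cell.
#'
#' @param records atom records.
#' @param cell a `bondflex_cell` (or `NULL` for an automatic P1 box).
#' @param J number of conformers per atom-point cloud.
#' @param omega outermost anchor-cloud shell radius, Angstrom.
#' @param altloc alternate-location policy, see [build_connectivity()].
#' @return a `bondflex_model`.
#' @export
build_model <- function(records, cell = NULL, J = 120, omega = 0.356,
                        altloc = "strict") {
  g <- build_connectivity(records, altloc = altloc)
  g <- regenerate_hydrogens(g)
  g <- derive_initial_torsions(g)
  if (is.null(cell)) {
    xyz <- as.matrix(g$atoms[, c("x", "y", "z")])
    span <- apply(xyz, 2, function(v) diff(range(v))) + 14
    cell <- make_cell(span[1], span[2], span[3])
  }
  m <- list(graph = g, cell = cell, J = as.integer(J), omega = omega,
            motions = list(T = diag(3), screws = list()))
  class(m) <- "bondflex_model"
  m
}

#' @export
print.bondflex_model <- function(x, ...) {
  inv <- count_refinable_parameters(x$graph,
                                    n_screws = length(x$motions$screws))
  cat(sprintf(paste0("<bondflex model: %d atoms (%d heavy), %d residues, ",
                     "J=%d, omega=%.3f A, %d refinable parameters ",
                     "(%.0f%% below atomistic)>\n"),
              nrow(x$graph$atoms), sum(!x$graph$atoms$is_h),
              length(x$graph$resnos), x$J, x$omega, inv$total,
              100 * inv$reduction))
  invisible(x)
}
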