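# Crystallographic file handling.  PDB atom records are parsed through
# bio3d; the unit-cell line and multi-model ensemble output are handled
# here.  Reflections travel in a plain-text columnar format
# (h k l F SIGF FREE), and the refinable model state round-trips through a
# versioned text serialization.

#' Read a PDB file
#'
#' Parses atom records (via bio3d) and the CRYST1 cell.  ATOM and HETATM
#' records are distinguished; hydrogens are flagged; elements are taken
#' from the element column when present, else inferred from the atom
#' name.  A missing CRYST1 line is an error, as is an unrecognizable
#' element.
#'
#' @param path PDB file.
#' @return list with `records` (data frame: serial, name, alt, resname,
#'   chain, resno, x, y, z, occ, b, elem, type, is_h) and `cell`
#'   (a `bondflex_cell`).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) stop("no CRYST1 cell in ", path)
  cv <- c(substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33),
          substr(cl[1], 34, 40), substr(cl[1], 41, 47), substr(cl[1], 48, 54))
  cv <- as.numeric(cv)
  sg <- trimws(substr(cl[1], 56, 66))
  if (sg == "") sg <- "P 1"
  cell <- make_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6], spacegroup = sg)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  elem <- trimws(a$elesy)
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- element_of(a$elety[miss])
  elem <- toupper(substr(elem, 1, 1 + (nchar(elem) > 1 &
                                         !grepl("^[0-9]", elem) &
                                         toupper(elem) %in% c("FE", "ZN",
                                                              "MG", "CL"))))
  records <- data.frame(
    serial = a$eleno, name = a$elety,
    alt = ifelse(is.na(a$alt), "", a$alt),
    resname = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    elem = elem, type = a$type,
    is_h = toupper(substr(gsub("^[0-9]", "", a$elety), 1, 1)) == "H",
    stringsAsFactors = FALSE)
  if (nrow(records) == 0) stop("no atom records in ", path)
  list(records = records, cell = cell)
}

.fmt_atom <- function(serial, name, resname, chain, resno, xyz, occ, b,
                      elem, type = "ATOM") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial %% 100000, nm, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, b, elem)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per conformer; a companion average-coordinate
#' file carries the atom average positions with the B-factor equivalents
#' derived from each atom-point cloud.
#'
#' @param ensemble a `bondflex_ensemble`.
#' @param cell a `bondflex_cell` (written as CRYST1).
#' @param path output path for the ensemble file.
#' @param average_path optional output path for the average-coordinate
#'   file.
#' @return invisibly, the number of MODEL blocks written.
#' @export
write_ensemble_pdb <- function(ensemble, cell, path, average_path = NULL) {
  a <- ensemble$graph$atoms
  cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                cell$abc[1], cell$abc[2], cell$abc[3],
                cell$angles[1], cell$angles[2], cell$angles[3],
                cell$spacegroup)
  con <- file(path, "w")
  writeLines(cr, con)
  for (j in seq_len(ensemble$J)) {
    writeLines(sprintf("MODEL     %4d", j), con)
    for (i in seq_len(nrow(a)))
      writeLines(.fmt_atom(i, a$name[i], a$resname[i], a$chain[i],
                           a$resno[i], ensemble$pts[[i]][j, ], 1, 0,
                           a$elem[i]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  if (!is.null(average_path)) {
    mu <- ensemble_means(ensemble)
    bf <- ensemble_bfactors(ensemble)
    con <- file(average_path, "w")
    writeLines(cr, con)
    for (i in seq_len(nrow(a)))
      writeLines(.fmt_atom(i, a$name[i], a$resname[i], a$chain[i],
                           a$resno[i], mu[i, ], 1, bf[i], a$elem[i]), con)
    writeLines("END", con)
    close(con)
  }
  invisible(ensemble$J)
}

#' Read a reflection list
#'
#' Plain-text columnar reflection data: whitespace-separated columns
#' `h k l F SIGF [FREE]` with an optional header line.  The resolution of
#' every reflection is computed from the cell metric; the free set uses
#' the convention that flag value 0 marks a free reflection
#' (configurable).  A missing SIGF column is an error; an all-zero SIGF
#' column is accepted (all downweights become 1).
#'
#' @param path reflection file.
#' @param cell a `bondflex_cell`.
#' @param free_is configuration of the free-flag convention: reflections
#'   whose flag equals this value are free.
#' @return a `bondflex_reflections` object: `data` (h, k, l, fobs, sigf,
#'   free, d), `cell`, `d_min`.
#' @export
read_reflections <- function(path, cell, free_is = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  header <- !grepl("^\\s*-?[0-9]", first)
  tab <- utils::read.table(path, header = header)
  if (ncol(tab) < 4)
    stop("reflection list needs columns h k l F [SIGF] [FREE]")
  if (ncol(tab) == 4) {
    warning("no sigma-F column; sigmas set to 0 (all downweights 1)")
    tab[[5]] <- 0
  }
  names(tab)[1:5] <- c("h", "k", "l", "fobs", "sigf")
  if (any(tab$fobs < 0)) stop("negative amplitudes in reflection list")
  if (any(tab$sigf < 0)) stop("negative sigmas in reflection list")
  free <- if (ncol(tab) >= 6) tab[[6]] == free_is else rep(FALSE, nrow(tab))
  key <- paste(tab$h, tab$k, tab$l)
  if (anyDuplicated(key)) stop("duplicate Miller indices in reflection list")
  d <- d_spacing(cell, as.matrix(tab[, 1:3]))
  out <- list(data = data.frame(h = tab$h, k = tab$k, l = tab$l,
                                fobs = tab$fobs, sigf = tab$sigf,
                                free = free, d = d),
              cell = cell, d_min = min(d))
  class(out) <- "bondflex_reflections"
  out
}

#' Write a reflection list
#' @param refl a `bondflex_reflections` object.
#' @param path output path.
#' @param free_is flag value written for free reflections (work
#'   reflections get 1).
#' @return invisibly, the path.
#' @export
write_reflections <- function(refl, path, free_is = 0) {
  d <- refl$data
  tab <- data.frame(h = d$h, k = d$k, l = d$l,
                    F = sprintf("%.6g", d$fobs),
                    SIGF = sprintf("%.6g", d$sigf),
                    FREE = ifelse(d$free, free_is, 1))
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @export
print.bondflex_reflections <- function(x, ...) {
  cat(sprintf("<%d reflections to %.2f A, %d free, cell %s>\n",
              nrow(x$data), x$d_min, sum(x$data$free),
              paste(round(x$cell$abc, 1), collapse = " ")))
  invisible(x)
}

#' Write weighted map coefficients
#'
#' Columnar map-coefficient output: weighted 2Fo-Fc amplitude and phase
#' (FWT/PHWT) and Fo-Fc difference amplitude and phase (DELFWT/PHDELWT)
#' per reflection.  Unphased reflections are excluded, with the count
#' reported as a message.
#'
#' @param refl a `bondflex_reflections` object.
#' @param f_calc complex calculated structure factors on `refl$data`.
#' @param path output path.
#' @return invisibly, the number of rows written.
#' @export
write_map_coefficients <- function(refl, f_calc, path) {
  d <- refl$data
  ok <- !is.na(f_calc)
  if (any(!ok)) message(sum(!ok), " unphased reflections excluded")
  d <- d[ok, , drop = FALSE]; fc <- f_calc[ok]
  dw <- compute_downweight(d$fobs, d$sigf)
  att <- {
    sig <- sigma_from_downweight(dw$d)
    u <- seq(-2, 2, length.out = 25); w <- exp(-u^2 / 2)
    vapply(sig, function(s) sum(w * cos(u * s)) / sum(w), 0)
  }
  ph <- Arg(fc) * 180 / pi
  tab <- data.frame(h = d$h, k = d$k, l = d$l,
                    FWT = sprintf("%.6g", pmax(0, (2 * d$fobs - Mod(fc))) *
                                    att),
                    PHWT = sprintf("%.3f", ph),
                    DELFWT = sprintf("%.6g", abs(d$fobs - Mod(fc)) * att),
                    PHDELWT = sprintf("%.3f",
                                      ifelse(d$fobs >= Mod(fc), ph,
                                             (ph + 180) %% 360)),
                    FREE = ifelse(d$free, 0, 1))
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE)
  invisible(nrow(tab))
}

# --- model serialization -------------------------------------------------

.ser_num <- function(x) sprintf("%.17g", x)

#' Serialize a refinable model to a text file
#'
#' Versioned structured-text serialization of the full refinement state:
#' every per-bond parameter (length, angle, torsion, offsets, kicks,
#' alpha/beta), the anchor, cloud radius omega, translation tensor and
#' screw motions.  The round trip through [read_model()] reproduces every
#' parameter bit-identically.
#'
#' @param model a `bondflex_model`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_model <- function(model, path) {
  g <- model$graph
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("bondflex-model 1")
  w("J ", model$J)
  w("omega ", .ser_num(model$omega))
  w("anchor ", g$anchor)
  w("cell ", paste(.ser_num(c(model$cell$abc, model$cell$angles)),
                   collapse = " "), " ", model$cell$spacegroup)
  w("T ", paste(.ser_num(model$motions$T), collapse = " "))
  w("screws ", length(model$motions$screws))
  for (s in model$motions$screws)
    w("screw ", paste(.ser_num(c(s$r, s$w[1:2])), collapse = " "))
  # (vectors below are assembled into one field vector per line)
  a <- g$atoms
  w("atoms ", nrow(a))
  for (i in seq_len(nrow(a)))
    w("atom ", paste(c(a$name[i], a$resno[i], a$resname[i], a$chain[i],
                       a$elem[i], as.integer(a$is_h[i]),
                       ifelse(is.na(a$parent[i]), -1, a$parent[i]),
                       .ser_num(c(a$x[i], a$y[i], a$z[i], a$l[i],
                                  a$theta[i], a$tor[i], a$toffset[i]))),
                     collapse = " "))
  grp <- g$groups
  w("groups ", nrow(grp))
  for (r in seq_len(nrow(grp)))
    w("group ", paste(c(grp$id[r], grp$driver[r],
                        as.integer(grp$refinable[r]),
                        as.integer(grp$sidechain[r]), grp$resno[r],
                        .ser_num(c(grp$t[r], grp$kick[r], grp$alpha[r],
                                   grp$beta[r]))), collapse = " "))
  ca <- g$calphas
  w("calphas ", nrow(ca))
  for (r in seq_len(nrow(ca)))
    w("calpha ", paste(c(ca$resno[r], ca$idx[r],
                         as.integer(ca$eligible[r]),
                         .ser_num(ca$rkick[r])), collapse = " "))
  invisible(path)
}

#' Read a serialized model
#'
#' Restores the refinement state written by [write_model()].  Torsion
#' values, kicks and motion parameters are applied on top of a graph
#' rebuilt from the serialized atom table, giving an exact round trip.
#'
#' @param path file written by [write_model()].
#' @return a `bondflex_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  if (!grepl("^bondflex-model 1", lines[1]))
    stop("not a bondflex model file: ", path)
  fields <- strsplit(lines, " +")
  key <- vapply(fields, `[[`, "", 1)
  val <- function(k) fields[[match(k, key)]][-1]
  num <- function(x) suppressWarnings(as.numeric(x))   # "NA" fields
  J <- as.integer(val("J")[1])
  omega <- as.numeric(val("omega")[1])
  anchor <- as.integer(val("anchor")[1])
  cv <- val("cell")
  cell <- make_cell(as.numeric(cv[1]), as.numeric(cv[2]), as.numeric(cv[3]),
                    as.numeric(cv[4]), as.numeric(cv[5]), as.numeric(cv[6]),
                    spacegroup = paste(cv[-(1:6)], collapse = " "))
  Tm <- matrix(as.numeric(val("T")), 3, 3)
  screws <- lapply(which(key == "screw"), function(i) {
    v <- as.numeric(fields[[i]][-1])
    list(r = v[1:3], w = c(v[4], v[5], 0))
  })
  arows <- which(key == "atom")
  am <- do.call(rbind, lapply(fields[arows], function(f) f[-1]))
  atoms <- data.frame(
    name = am[, 1], resno = as.integer(am[, 2]), resname = am[, 3],
    chain = am[, 4], elem = am[, 5], is_h = am[, 6] == "1",
    parent = ifelse(am[, 7] == "-1", NA_integer_, as.integer(am[, 7])),
    x = num(am[, 8]), y = num(am[, 9]),
    z = num(am[, 10]), l = num(am[, 11]),
    theta = num(am[, 12]), tor = num(am[, 13]),
    toffset = num(am[, 14]), stringsAsFactors = FALSE)
  atoms$idx <- seq_len(nrow(atoms))
  grows <- which(key == "group")
  gm <- do.call(rbind, lapply(fields[grows], function(f) f[-1]))
  groups <- data.frame(
    id = as.integer(gm[, 1]), driver = as.integer(gm[, 2]),
    refinable = gm[, 3] == "1", sidechain = gm[, 4] == "1",
    resno = as.integer(gm[, 5]), t = as.numeric(gm[, 6]),
    kick = as.numeric(gm[, 7]), alpha = as.numeric(gm[, 8]),
    beta = as.numeric(gm[, 9]))
  groups$backbone <- !groups$sidechain
  crows <- which(key == "calpha")
  cm <- do.call(rbind, lapply(fields[crows], function(f) f[-1]))
  calphas <- data.frame(resno = as.integer(cm[, 1]),
                        idx = as.integer(cm[, 2]),
                        eligible = cm[, 3] == "1",
                        rkick = as.numeric(cm[, 4]))
  # rebuild derived graph structure (order, frame) from the atom table
  g <- .rebuild_graph(atoms, groups, calphas, anchor)
  m <- list(graph = g, cell = cell, J = J, omega = omega,
            motions = list(T = Tm, screws = screws))
  class(m) <- "bondflex_model"
  m
}

.rebuild_graph <- function(atoms, groups, calphas, anchor) {
  n <- nrow(atoms)
  kids <- split(seq_len(n)[!is.na(atoms$parent)],
                atoms$parent[!is.na(atoms$parent)])
  ord <- integer(0); queue <- anchor
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ord <- c(ord, cur)
    queue <- c(queue, kids[[as.character(cur)]])
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  frame <- .anchor_frame(xyz, atoms$parent, anchor)
  atoms$ref_theta <- !atoms$is_h &
    (atoms$name == "CB" | (atoms$name == "CG" &
                             atoms$resname %in% c("PHE", "TYR", "TRP",
                                                  "HIS")))
  g <- list(atoms = atoms, groups = groups, calphas = calphas,
            anchor = anchor, order = ord, frame = frame,
            chain = atoms$chain[1], resnos = sort(unique(atoms$resno)),
            het = NULL, rooted = TRUE)
  class(g) <- "bondflex_graph"
  g
}
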