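# Synthetic fixtures: ideal-geometry peptides, two-domain toys and
# simulated reflection data.  Everything the test-suite consumes is
# generated here from code; no external files are required.

.ss_angles <- function(ss) {
  switch(ss,
         helix  = c(phi = -57, psi = -47),
         strand = c(phi = -120, psi = 120),
         loop   = c(phi = -70, psi = 150),
         stop("unknown secondary-structure code: ", ss))
}

#' Ideal-geometry peptide generator
#'
#' Builds a single-chain peptide with canonical bond lengths and angles,
#' backbone torsions from a secondary-structure template (or explicit
#' phi/psi values) and extended side chains.  Hydrogens are included at a
#' bond length of 0.968 A.  The generator also returns a truth record with
#' every torsion it used, so tests can compare derived quantities against
#' known inputs.  The build is fully deterministic.
#'
#' @param sequence one-letter amino-acid sequence, e.g. `"GAG"`.
#' @param ss secondary structure: a single code (`"helix"`, `"strand"`,
#'   `"loop"`) or one code per residue.
#' @param phi,psi optional explicit backbone torsions (degrees), recycled
#'   or per-residue; override `ss`.
#' @param chain chain identifier.
#' @return list with `records` (a data frame of atom records: serial, name,
#'   resno, resname, chain, x, y, z, occ, b, elem, type, is_h) and `truth`
#'   (per-residue named torsion list plus the template values used).
#' @export
make_ideal_peptide <- function(sequence, ss = "helix", phi = NULL, psi = NULL,
                               chain = "A") {
  res3 <- aa_three(sequence)
  n <- length(res3)
  tmpl <- residue_templates()
  if (length(ss) == 1) ss <- rep(ss, n)
  stopifnot(length(ss) == n)
  ang <- t(vapply(ss, .ss_angles, c(phi = 0, psi = 0)))
  if (!is.null(phi)) ang[, "phi"] <- rep(phi, length.out = n)
  if (!is.null(psi)) ang[, "psi"] <- rep(psi, length.out = n)

  # virtual residue-0 atoms seed the recursive build
  v1 <- c(-4.1, 1.0, 0.3); v2 <- c(-2.9, 0.2, 0.5); v3 <- c(-1.4, 0.3, 0.0)
  attr(v2, "parent") <- "0.N"; attr(v3, "parent") <- "0.CA"
  pos <- list("0.N" = v1, "0.CA" = v2, "0.C" = v3)
  key <- function(i, nm) paste0(i, ".", nm)
  parent_key <- function(i, p) if (p == "-C") key(i - 1, "C") else key(i, p)

  records <- list()
  truth <- vector("list", n)
  serial <- 0
  for (i in seq_len(n)) {
    tt <- tmpl[[res3[i]]]
    # resolve driver torsion values for this residue
    tors <- c(phi = unname(ang[i, "phi"]), psi = unname(ang[i, "psi"]),
              omega = 180)
    placed_tor <- list()
    truth_i <- list()
    for (r in seq_len(nrow(tt))) {
      row <- tt[r, ]
      pk <- parent_key(i, row$parent)
      gpk <- attr(pos[[pk]], "parent")
      ggk <- attr(pos[[gpk]], "parent")
      if (is.na(row$off)) {                      # driver child
        if (row$name == "N") {
          # the peptide N of residue i is driven by psi of residue i-1
          tau <- if (i == 1) 150 else unname(ang[i - 1, "psi"])
        } else {
          tau <- if (row$var %in% names(tors)) tors[[row$var]] else row$tor0
          truth_i[[row$var]] <- tau
        }
        placed_tor[[pk]] <- tau
      } else {
        if (is.null(placed_tor[[pk]])) {
          # group whose driver lives in the next residue (O follows the
          # next N at psi); at the chain end O becomes the driver itself
          placed_tor[[pk]] <- tors[["psi"]]
        }
        tau <- placed_tor[[pk]] + row$off
      }
      p <- nerf_place(pos[[ggk]], pos[[gpk]], pos[[pk]], row$l, row$ang, tau)
      p <- as.vector(p)
      attr(p, "parent") <- pk
      pos[[key(i, row$name)]] <- p
      serial <- serial + 1
      records[[length(records) + 1]] <- data.frame(
        serial = serial, name = row$name, resno = i, resname = res3[i],
        chain = chain, x = p[1], y = p[2], z = p[3], occ = 1,
        b = 10, elem = element_of(row$name), type = "ATOM",
        is_h = substr(row$name, 1, 1) == "H" | grepl("^[0-9]H", row$name),
        stringsAsFactors = FALSE)
    }
    truth[[i]] <- truth_i
  }
  records <- do.call(rbind, records)
  # true peptide-bond N placement for residue i is driven by psi of i-1;
  # the virtual seed drives residue 1
  list(records = records, truth = list(residues = truth, ss = ss, angles = ang))
}

#' Two-domain toy structure
#'
#' Two helical segments joined by a short loop linker; the truth record
#' marks the linker C-alpha at which flexibility (a forward plus reverse
#' kick) is planted by downstream tests.  Supports the domain-segmentation
#' analysis of the perturbation-response matrix.
#'
#' @param len1,len2 residue counts of the two helices.
#' @param linker residue count of the loop linker (>= 2).
#' @param kick planted kick magnitude (dimensionless) recorded in the truth.
#' @return list with `records`, `truth` (`linker_ca`: residue index of the
#'   central linker C-alpha; `kick`).
#' @export
make_two_domain_toy <- function(len1 = 6, linker = 2, len2 = 6, kick = 0.3) {
  stopifnot(linker >= 2)
  n <- len1 + linker + len2
  ss <- c(rep("helix", len1), rep("loop", linker), rep("helix", len2))
  pep <- make_ideal_peptide(strrep("A", n), ss = ss)
  linker_ca <- len1 + ceiling(linker / 2)
  list(records = pep$records,
       truth = list(linker_ca = linker_ca, kick = kick, ss = ss))
}

#' Simulated reflection data
#'
#' Computes structure factors for a model ensemble (explicit atoms plus,
#' optionally, a scaled bulk-solvent contribution with known scale k and
#' B factor), then applies multiplicative Gaussian amplitude noise and
#' assigns a free set.  sigma(F) is set to `noise * |F_true|`; with
#' `noise = 0` amplitudes are exact and all downweights are 1.
#'
#' @param model a `bondflex_model` (see [build_model()]).
#' @param d_min high-resolution limit in Angstrom.
#' @param noise fractional amplitude noise (sigmaF / F).
#' @param free_frac fraction of reflections assigned to the free set.
#' @param seed integer seed; all randomness in the simulation flows from it.
#' @param k_sol,b_sol bulk-solvent scale and B factor (Angstrom^2) used to
#'   build the ground truth; `k_sol = 0` omits the solvent contribution.
#' @return a `bondflex_reflections` object (see [read_reflections()]) with
#'   an extra `truth` attribute (complex F_true, k_sol, b_sol).
#' @export
simulate_reflections <- function(model, d_min = 2.0, noise = 0.02,
                                 free_frac = 0.05, seed = 1,
                                 k_sol = 0, b_sol = 40) {
  cell <- model$cell
  ens <- build_ensemble(model)
  fc <- compute_f_model(model, ens, d_min = d_min,
                        solvent = k_sol > 0, k_sol = k_sol, b_sol = b_sol)
  hkl <- fc$hkl
  f_true <- fc$f_calc
  set.seed(seed)
  amp <- Mod(f_true)
  f_obs <- pmax(0, amp * (1 + noise * stats::rnorm(length(amp))))
  sig <- noise * amp
  nfree <- round(free_frac * length(amp))
  free <- rep(FALSE, length(amp))
  if (nfree > 0) free[sample.int(length(amp), nfree)] <- TRUE
  refl <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                     fobs = f_obs, sigf = sig, free = free,
                     d = d_spacing(cell, hkl))
  out <- list(data = refl, cell = cell, d_min = d_min)
  class(out) <- "bondflex_reflections"
  attr(out, "truth") <- list(f_true = f_true, k_sol = k_sol, b_sol = b_sol,
                             noise = noise)
  out
}
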