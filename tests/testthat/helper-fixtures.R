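# Shared fixtures (memoized; everything generated in code) and independent
# oracles used across the test files.

.fx <- new.env(parent = emptyenv())

fx_peptide <- function(seq = "GAASVKG", ss = "helix") {
  key <- paste0("pep_", seq, "_", paste(ss, collapse = ""))
  if (is.null(.fx[[key]])) .fx[[key]] <- make_ideal_peptide(seq, ss = ss)
  .fx[[key]]
}

fx_model <- function(seq = "GAASVKG", ss = "helix", J = 16,
                     cell = make_cell(26, 24, 22)) {
  key <- paste0("mod_", seq, "_", J)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- build_model(fx_peptide(seq, ss)$records, cell = cell,
                              J = J)
  .fx[[key]]
}

# independent structure-factor oracle: plain per-point summation written
# from the definition, no grids involved
oracle_direct_F <- function(cell, points, elems, hkl) {
  d <- d_spacing(cell, hkl)
  out <- rep(0 + 0i, nrow(hkl))
  for (a in seq_along(points)) {
    fr <- points[[a]] %*% t(cell$frac)
    for (i in seq_len(nrow(hkl))) {
      ph <- 2 * pi * as.numeric(fr %*% hkl[i, ])
      out[i] <- out[i] + form_factor(elems[a], 1 / d[i]) *
        mean(exp(1i * ph))
    }
  }
  out
}

# dihedral oracle from bio3d (independent of the package's own formula)
oracle_torsion <- function(a, b, c, d) {
  bio3d::torsion.xyz(c(a, b, c, d))
}

cloud_spread <- function(ens, i) {
  p <- ens$pts[[i]]
  sqrt(sum(sweep(p, 2, colMeans(p))^2) / nrow(p))
}
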