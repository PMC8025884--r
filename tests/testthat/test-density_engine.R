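test_that("the voxel-edge rule follows d/4 capped at 0.8 A", {
  expect_equal(voxel_edge(4), 0.8)     # cap active (d/4 = 1.0)
  expect_equal(voxel_edge(2), 0.5)
  expect_equal(voxel_edge(3.2), 0.8)
  expect_equal(voxel_edge(1.6), 0.4)
})

test_that("atom-point deposition conserves density exactly", {
  # one point exactly on a voxel centre: all weight on one voxel
  g <- list(origin = c(0, 0, 0), h = 0.5, dims = c(10L, 10L, 10L))
  seg <- rasterize_segment(list(matrix(c(1.5, 2, 2.5), 1)), "C", d = 2,
                           grid = g, oversample = 1)
  raw <- bondflex:::.splat(matrix(c(3, 4, 5), 1), 1, c(10L, 10L, 10L))
  expect_equal(sum(raw > 0), 1)
  expect_equal(sum(raw), 1)
  # a point at a cell-body centre: eight equal weights of 1/8
  raw8 <- bondflex:::.splat(matrix(c(3.5, 4.5, 5.5), 1), 1,
                            c(10L, 10L, 10L))
  expect_equal(sort(unique(round(raw8[raw8 > 0], 12))), 0.125)
  expect_equal(sum(raw8 > 0), 8)
  expect_equal(sum(raw8), 1)
  # conservation holds at arbitrary positions (exact)
  set.seed(1)
  pts <- matrix(runif(60, 1, 8), 20, 3)
  expect_equal(sum(bondflex:::.splat(pts, rep(0.05, 20),
                                     c(10L, 10L, 10L))), 1)
  # leaving the grid is an error (margin violated)
  expect_error(bondflex:::.splat(matrix(c(11, 2, 2), 1), 1,
                                 c(10L, 10L, 10L)), "outside")
  # total electrons in a rasterized segment equal sum f(0)
  elems <- c("C", "N", "O")
  pp <- lapply(1:3, function(i) matrix(runif(3, 8, 12), 1))
  sg <- rasterize_segment(pp, elems, d = 2.5)
  expect_equal(sum(sg$rho) * sg$h^3, sum(form_factor(elems, 0)),
               tolerance = 1e-6)
})

test_that("structure factors match the direct-summation oracle", {
  cell <- make_cell(20, 22, 24)
  xyz <- rbind(c(5, 6, 7), c(8, 6, 7), c(6.5, 9, 7), c(10, 12, 13),
               c(4, 15, 18))
  elems <- c("C", "N", "O", "C", "S")
  pts <- lapply(seq_len(5), function(i) matrix(xyz[i, ], 1))
  ruc <- rasterize_unit_cell(pts, elems, cell, d = 2.0)
  hkl <- unique_millers(cell, 2.0)
  fo <- oracle_direct_F(cell, pts, elems, hkl)
  fc <- extract_structure_factors(ruc$F, hkl)
  expect_gt(stats::cor(Mod(fo), Mod(fc)), 0.999)
  # complex (phased) agreement
  ccplx <- Mod(sum(Conj(fo) * fc)) /
    sqrt(sum(Mod(fo)^2) * sum(Mod(fc)^2))
  expect_gt(ccplx, 0.999)
  # single carbon at the origin: amplitudes proportional to the form
  # factor of carbon
  r1 <- rasterize_unit_cell(list(matrix(c(0, 0, 0), 1)), "C", cell,
                            d = 2.0)
  f1 <- extract_structure_factors(r1$F, hkl)
  expect_gt(stats::cor(Mod(f1), form_factor("C", 1 / d_spacing(cell,
                                                               hkl))),
            0.999)
  # form factors at zero angle count electrons
  expect_equal(form_factor(c("H", "C", "N", "O", "S"), 0),
               c(1, 6, 7, 8, 16), tolerance = 2e-3)
})

test_that("remapping a segment onto the cell grid conserves density", {
  cell <- make_cell(20, 22, 24)
  pts <- lapply(1:4, function(i) matrix(runif(3, 6, 14), 1))
  seg <- rasterize_segment(pts, rep("C", 4), d = 2.0)
  rem <- remap_to_unit_cell(seg, cell)
  m_seg <- sum(seg$rho) * seg$h^3
  m_cell <- sum(rem$grid$rho) * cell$volume / prod(rem$grid$dims)
  expect_equal(m_cell, m_seg, tolerance = 1e-9)
  # aligned grids: the remap is an exact copy
  ga <- list(origin = c(0, 0, 0), h = 0.5, dims = c(40L, 44L, 48L))
  sega <- rasterize_segment(pts, rep("C", 4), d = 2.0, grid = ga)
  rema <- remap_to_unit_cell(sega, cell, dims = c(40L, 44L, 48L))
  expect_equal(rema$grid$rho, sega$rho, tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant density transforms to a DC-only spectrum
  segc <- sega
  segc$rho <- array(1, sega$dims)
  segc$deconvolved <- TRUE
  remc <- remap_to_unit_cell(segc, cell, dims = c(40L, 44L, 48L))
  Fc <- remc$F
  expect_lt(max(Mod(Fc[-1])), Mod(Fc[1]) * 1e-9)
})

test_that("reciprocal symmetry expansion matches expanded coordinates", {
  cell <- make_cell(20, 24, 18, spacegroup = "P 21")
  xyz <- rbind(c(4, 3, 5), c(6, 4, 4), c(5, 6, 7))
  elems <- c("C", "N", "O")
  pts <- lapply(1:3, function(i) matrix(xyz[i, ], 1))
  ruc <- rasterize_unit_cell(pts, elems, cell, d = 2.0)
  F_full <- symmetry_expand(ruc$F, cell)
  # oracle: direct sum over the symmetry-expanded coordinate set
  fr <- xyz %*% t(cell$frac)
  fr2 <- sweep(fr %*% diag(c(-1, 1, -1)), 2, c(0, 0.5, 0), `+`)
  all_pts <- lapply(seq_len(6), function(i) {
    f <- if (i <= 3) fr[i, ] else fr2[i - 3, ]
    matrix(as.numeric(cell$orth %*% f), 1)
  })
  hkl <- unique_millers(cell, 2.0)
  fo <- oracle_direct_F(cell, all_pts, rep(elems, 2), hkl)
  fc <- extract_structure_factors(F_full, hkl)
  expect_gt(stats::cor(Mod(fo), Mod(fc)), 0.999)
  # P1 expansion is the identity
  p1 <- make_cell(20, 24, 18)
  expect_identical(symmetry_expand(ruc$F, p1), ruc$F)
  # Friedel mates conjugate for a real density
  dims <- dim(ruc$F)
  h <- c(3, 2, 1)
  expect_equal(ruc$F[cbind(h[1] + 1, h[2] + 1, h[3] + 1)],
               Conj(ruc$F[cbind(dims[1] - h[1] + 1, dims[2] - h[2] + 1,
                                dims[3] - h[3] + 1)]), tolerance = 1e-9)
})

test_that("the multi-conformer solvent mask behaves as specified", {
  cell <- make_cell(14, 14, 14)
  dims <- c(24L, 24L, 24L)
  # empty cell: all solvent
  sm0 <- compute_solvent_mask(list(), character(0), cell, dims)
  expect_true(all(sm0$fraction == 1))
  # a single atom carves a cavity of the tabulated radius (fine grid,
  # geometric oracle)
  fine <- c(56L, 56L, 56L)
  smc <- compute_solvent_mask(list(matrix(c(7, 7, 7), 1)), "C", cell,
                              fine, shrink = 0, strip = 0)
  idx <- arrayInd(which(smc$fraction == 0), fine)
  dd <- sqrt(rowSums((sweep(idx - 1, 2, fine, `/`) %*% t(cell$orth) -
                        matrix(7, nrow(idx), 3))^2))
  expect_lte(max(dd), solvent_radii()[["C"]] + 1e-9)
  prot_frac <- mean(smc$fraction == 0)
  vol_expect <- 4 / 3 * pi * solvent_radii()[["C"]]^3 / cell$volume
  expect_equal(prot_frac, vol_expect, tolerance = 0.1)
  # the shrink step switches model voxels near solvent to solvent
  smc2 <- compute_solvent_mask(list(matrix(c(7, 7, 7), 1)), "C", cell,
                               fine, shrink = 0.4, strip = 0)
  expect_gt(sum(smc2$fraction), sum(smc$fraction))
  idx2 <- arrayInd(which(smc2$fraction == 0), fine)
  dd2 <- sqrt(rowSums((sweep(idx2 - 1, 2, fine, `/`) %*% t(cell$orth) -
                         matrix(7, nrow(idx2), 3))^2))
  expect_lte(max(dd2), solvent_radii()[["C"]] - 0.4 + 0.3)
  # fractions always within [0, 1]
  m <- fx_model("GAG", ss = "loop", J = 6, cell = cell)
  ens <- build_flexless(m)
  heavy <- which(!m$graph$atoms$is_h)
  smp <- compute_solvent_mask(ens$pts[heavy], m$graph$atoms$elem[heavy],
                              cell, dims)
  expect_true(all(smp$fraction >= 0 & smp$fraction <= 1))
})

test_that("internal solvent strips shorter than 2 A are removed", {
  m <- array(FALSE, c(20, 8, 8))          # protein everywhere
  m[9:10, 4, 4] <- TRUE                   # 2-voxel channel, 0.5 A voxels
  out <- bondflex:::.remove_strips(m, strip_vox = c(4, 4, 4))
  expect_false(any(out))
  # a long channel along x survives
  m2 <- array(FALSE, c(20, 8, 8))
  m2[3:18, 4, 4] <- TRUE
  out2 <- bondflex:::.remove_strips(m2, strip_vox = c(4, 4, 4))
  expect_equal(sum(out2), 16)
})

test_that("bit-packed masks average exactly like the naive average", {
  set.seed(8)
  dims <- c(6L, 5L, 4L)
  masks <- lapply(1:32, function(i)
    array(runif(prod(dims)) > 0.5, dims))
  packed <- pack_masks_bitwise(masks)
  avg <- average_packed_masks(packed)
  naive <- Reduce(`+`, lapply(masks, as.numeric)) / 32
  expect_identical(avg, naive)
  # sixteen identical masks: the average is the mask itself
  same <- lapply(1:16, function(i) masks[[1]])
  expect_identical(average_packed_masks(pack_masks_bitwise(same)),
                   as.numeric(as.vector(masks[[1]])))
  # a single mask averages to itself
  expect_identical(average_packed_masks(pack_masks_bitwise(masks[1])),
                   as.numeric(as.vector(masks[[1]])))
})

test_that("solvent scaling recovers known parameters and bin-matches", {
  m <- fx_model("GAASVKG", J = 8)
  refl <- simulate_reflections(m, d_min = 2.2, noise = 0.01,
                               free_frac = 0, seed = 5, k_sol = 0.4,
                               b_sol = 45)
  ens <- build_ensemble(m)
  fm <- compute_f_model(m, ens, d_min = 2.2, solvent = TRUE,
                        hkl = as.matrix(refl$data[, c("h", "k", "l")]))
  sc <- scale_solvent_and_assemble(fm$f_expl, fm$f_solv, refl$data$fobs,
                                   refl$data$d)
  expect_equal(sc$k, 0.4, tolerance = 0.05 * 0.4 / 0.4 + 0.05)
  expect_lt(abs(sc$b - 45) / 45, 0.25)
  # per-bin mean amplitudes match after scaling
  for (b in unique(sc$bin)) {
    sel <- sc$bin == b
    expect_equal(mean(Mod(sc$f_calc[sel])), mean(refl$data$fobs[sel]),
                 tolerance = 1e-6)
  }
  # without solvent the scale is irrelevant: F_calc = F_expl up to
  # bin scaling
  sc0 <- scale_solvent_and_assemble(fm$f_expl, fm$f_solv * 0,
                                    refl$data$fobs, refl$data$d)
  ratio <- Mod(sc0$f_calc) / Mod(fm$f_expl)
  expect_equal(ratio, sc0$scale[sc0$bin], tolerance = 1e-9)
  expect_error(scale_solvent_and_assemble(complex(0), complex(0),
                                          numeric(0), numeric(0)),
               "empty")
})

test_that("solvent fraction decreases as the cloud radius grows", {
  cell <- make_cell(16, 16, 16)
  dims <- c(24L, 24L, 24L)
  frac_at <- function(omega) {
    pts <- list(build_anchor_cloud(12, omega, c(8, 8, 8)),
                build_anchor_cloud(12, omega, c(10, 8, 8)))
    mean(compute_solvent_mask(pts, c("C", "N"), cell, dims)$fraction)
  }
  f <- vapply(c(0.1, 0.5, 1.2), frac_at, 0)
  expect_true(all(diff(f) <= 0))
})
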