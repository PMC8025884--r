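test_that("the translation tensor reshapes the cloud through its SVD", {
  cl <- build_anchor_cloud(200, 0.356)
  expect_equal(apply_translation_tensor(cl, diag(3)), cl,
               tolerance = 1e-12, ignore_attr = TRUE)
  # diag(4,1,1): x extent doubles, y/z unchanged
  out <- apply_translation_tensor(cl, diag(c(4, 1, 1)))
  expect_equal(diff(range(out[, 1])), 2 * diff(range(cl[, 1])),
               tolerance = 1e-9)
  expect_equal(out[, 2:3], cl[, 2:3], tolerance = 1e-12,
               ignore_attr = TRUE)
  # covariance propagation: C -> M C M' with M = U W^(1/2) U'
  T <- matrix(c(2, 0.4, 0, 0.4, 1.2, -0.1, 0, -0.1, 0.8), 3, 3)
  e <- eigen(T, symmetric = TRUE)
  M <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
  cc <- function(x) stats::cov(x)
  mapped <- apply_translation_tensor(cl, T)
  expect_equal(cc(mapped), M %*% cc(cl) %*% t(M), tolerance = 1e-9)
  expect_error(apply_translation_tensor(cl, matrix(1:9, 3, 3)),
               "symmetric")
})

test_that("screw motions fan conformers out and translate in-plane", {
  J <- 50
  cl <- build_anchor_cloud(J, 0.356)
  delta <- sweep(cl, 2, colMeans(cl))
  frames <- array(rep(diag(3), J), c(3, 3, J))
  # r = 0: a no-op
  s0 <- apply_screw_motions(cl, frames, list(list(r = c(0, 0, 0),
                                                  w = c(1, 1, 0))),
                            delta)
  expect_identical(s0$cloud, cl)
  # w = 0, r != 0: positions unchanged, frames rotated by d_j
  s1 <- apply_screw_motions(cl, frames, list(list(r = c(0.3, 0, 0.1),
                                                  w = c(0, 0, 0))),
                            delta)
  expect_equal(s1$cloud, cl, tolerance = 1e-12)
  rotangles <- vapply(seq_len(J), function(j) {
    R <- s1$frames[, , j]
    acos(pmin(1, (sum(diag(R)) - 1) / 2))
  }, 0)
  dj <- abs(as.numeric(delta %*% c(0.3, 0, 0.1)))
  expect_equal(rotangles, dj, tolerance = 1e-9)
  # translational offsets are perpendicular to the displacement
  s2 <- apply_screw_motions(cl, frames, list(list(r = c(0.2, 0.1, 0),
                                                  w = c(0.5, -0.3, 0))),
                            delta)
  off <- s2$cloud - cl
  nd <- sqrt(rowSums(delta^2))
  proj <- rowSums(off * delta) / pmax(nd, 1e-12)
  expect_lt(max(abs(proj)), 1e-10)
})

test_that("the two-angle axis rotation is orthogonal and well-behaved", {
  expect_equal(build_alpha_beta_rotation(0, 0), diag(3))
  # alpha = 90, beta = 0: a pure rotation about x
  M <- build_alpha_beta_rotation(90, 0)
  expect_equal(M %*% c(0, 1, 0), matrix(c(0, 0, 1)), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    M <- build_alpha_beta_rotation(runif(1, -180, 180),
                                   runif(1, -180, 180))
    expect_equal(t(M) %*% M, diag(3), tolerance = 1e-12)
    expect_equal(det(M), 1, tolerance = 1e-12)
  }
})

test_that("forward kicks spread downstream clouds monotonically", {
  m <- fx_model("GAASVKG", J = 16)
  g <- m$graph
  fl <- build_flexless(m)
  grp <- g$groups
  bb <- which(grp$backbone & grp$refinable)
  gid <- grp$id[bb[5]]
  # k = 0 leaves the structure flexless
  e0 <- apply_forward_kick(m, gid, 0)
  expect_equal(e0$pts, fl$pts, tolerance = 1e-12, ignore_attr = TRUE)
  # monotone spread growth downstream, upstream untouched
  desc <- local({
    parent <- g$atoms$parent
    d <- gid
    repeat {
      nd <- unique(c(d, which(parent %in% d)))
      if (length(nd) == length(d)) break
      d <- nd
    }
    setdiff(d, gid)
  })
  last <- 0
  for (k in c(0.1, 0.25, 0.5)) {
    ek <- apply_forward_kick(m, gid, k)
    spread <- mean(vapply(desc, function(i) cloud_spread(ek, i), 0))
    expect_gt(spread, last)
    last <- spread
    ups <- setdiff(seq_len(nrow(g$atoms)), c(desc, gid))
    updev <- max(vapply(ups, function(i)
      max(abs(ek$pts[[i]] - fl$pts[[i]])), 0))
    expect_lt(updev, 1e-9)
  }
  # kicks are rejected on non-eligible groups (peptide bond)
  omega_grp <- g$groups$id[!g$groups$refinable &
                             g$atoms$name[g$groups$id] == "N"][1]
  expect_error(set_kick(m, omega_grp, 0.1), "not allowed")
})

test_that("reverse kicks move the anchor side only, with exact cancellation", {
  m <- fx_model("GAASVKG", J = 16)
  g <- m$graph
  fl <- build_flexless(m)
  anchor_res <- g$atoms$resno[g$anchor]
  res <- anchor_res + 1
  er <- apply_reverse_kick(m, res, 0.4)
  ca <- g$atoms$idx[g$atoms$resno == res & g$atoms$name == "CA"]
  # everything downstream of the kicked C-alpha is restored exactly
  desc <- local({
    parent <- g$atoms$parent
    d <- ca
    repeat {
      nd <- unique(c(d, which(parent %in% d)))
      if (length(nd) == length(d)) break
      d <- nd
    }
    setdiff(d, ca)
  })
  ddev <- max(vapply(desc, function(i) max(abs(er$pts[[i]] - fl$pts[[i]])),
                     0))
  expect_lt(ddev, 1e-8)
  # the anchor side moves, increasingly with |k'|
  expect_gt(max(abs(er$pts[[g$anchor]] - fl$pts[[g$anchor]])), 1e-3)
  s1 <- cloud_spread(apply_reverse_kick(m, res, 0.2), g$anchor)
  s2 <- cloud_spread(apply_reverse_kick(m, res, 0.5), g$anchor)
  expect_gt(s2, s1)
  # k' = 0 changes nothing
  e0 <- apply_reverse_kick(m, res, 0)
  expect_equal(e0$pts, fl$pts, tolerance = 1e-12, ignore_attr = TRUE)
  # the anchor residue itself cannot take a reverse kick
  expect_error(set_reverse_kick(m, anchor_res, 0.1), "anchor")
})

test_that("rigid-motion equivariance: rotating the input rotates the ensemble", {
  pep <- fx_peptide("GAGSG", ss = "loop")
  R <- bondflex:::.rot_axis(c(1 / sqrt(3), 1 / sqrt(3), 1 / sqrt(3)), 0.7)
  rec2 <- pep$records
  xyz <- as.matrix(rec2[, c("x", "y", "z")]) %*% t(R)
  rec2$x <- xyz[, 1]; rec2$y <- xyz[, 2]; rec2$z <- xyz[, 3]
  m1 <- build_model(pep$records, J = 8)
  m2 <- build_model(rec2, J = 8)
  k1 <- set_kick(m1, m1$graph$groups$id[which(m1$graph$groups$refinable)[4]],
                 0.3)
  k2 <- set_kick(m2, m2$graph$groups$id[which(m2$graph$groups$refinable)[4]],
                 0.3)
  e1 <- build_ensemble(k1)
  e2 <- build_ensemble(k2)
  # cloud spreads (rotation-invariant summaries) agree atom by atom
  s1 <- vapply(seq_along(e1$pts), function(i) cloud_spread(e1, i), 0)
  s2 <- vapply(seq_along(e2$pts), function(i) cloud_spread(e2, i), 0)
  expect_equal(s1, s2, tolerance = 1e-6)
  # and mean positions are related by the applied rotation
  expect_equal(ensemble_means(e2), ensemble_means(e1) %*% t(R),
               tolerance = 1e-6)
})

test_that("the perturbation response matrix segments rigid domains", {
  # a single helix: one domain
  m1 <- build_model(fx_peptide("AAAAAAAAA", ss = "helix")$records, J = 10)
  pr1 <- perturbation_response_matrix(m1)
  expect_equal(length(unique(pr1$segments)), 1)
  # zero perturbation magnitude gives the zero matrix
  pr0 <- perturbation_response_matrix(m1, kick = 0)
  expect_equal(max(abs(pr0$matrix)), 0)
  # two helices joined by a loop linker: the boundary falls at the linker
  toy <- make_two_domain_toy(len1 = 5, linker = 2, len2 = 5)
  m2 <- build_model(toy$records, J = 10)
  pr2 <- perturbation_response_matrix(m2)
  segs <- pr2$segments
  expect_gt(length(unique(segs)), 1)
  boundary <- which(diff(segs) != 0)
  expect_true(any(abs(boundary - toy$truth$linker_ca) <= 2))
  # too-short chains are rejected
  m3 <- build_model(fx_peptide("GA", ss = "loop")$records, J = 6)
  expect_error(perturbation_response_matrix(m3), "short")
})
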