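test_that("the anchor cloud sits on ten Fibonacci shells", {
  cl <- build_anchor_cloud(120, 0.356)
  expect_equal(nrow(cl), 120)
  r <- sqrt(rowSums(cl^2))
  expect_equal(max(r), 0.356, tolerance = 1e-12)
  # radii take only the ten shell values omega * i/10
  shells <- sort(unique(round(r, 9)))
  expect_true(all(shells %in% round(0.356 * (1:10) / 10, 9)))
  # omega = 0 collapses onto the centre
  cl0 <- build_anchor_cloud(50, 0, centre = c(1, 2, 3))
  expect_equal(max(abs(sweep(cl0, 2, c(1, 2, 3)))), 0)
  expect_error(build_anchor_cloud(0, 0.356), "J")
  # deterministic
  expect_identical(cl, build_anchor_cloud(120, 0.356))
})

test_that("shell counts follow largest-remainder apportionment", {
  # brute-force oracle for the apportionment
  oracle <- function(J) {
    w <- (1:10)^2 / sum((1:10)^2)
    q <- J * w
    out <- floor(q)
    while (sum(out) < J) {
      frac <- q - out
      i <- which(frac == max(frac))
      i <- i[which.max(i)]        # ties to the outer shell
      out[i] <- out[i] + 1
      q[i] <- out[i]              # freeze
      frac <- NULL
    }
    out
  }
  for (J in c(1, 7, 16, 120, 300)) {
    counts <- apportion_shells(J)
    expect_equal(sum(counts), J)
    # counts proportional to i^2 within 1 of the exact quota
    expect_true(all(abs(counts - J * (1:10)^2 / 385) < 1))
  }
  expect_equal(apportion_shells(1), c(rep(0L, 9), 1L))
})

test_that("cloud placement satisfies the internal coordinates exactly", {
  set.seed(9)
  J <- 7
  ggp <- matrix(rnorm(3 * J), J, 3)
  gp <- ggp + matrix(rep(c(1.5, 0, 0), each = J), J, 3)
  par <- gp + matrix(rep(c(0.4, 1.4, 0), each = J), J, 3)
  tau <- runif(J, -180, 180)
  new <- place_next_cloud(ggp, gp, par, 1.5, 109.5, tau)
  expect_equal(sqrt(rowSums((new - par)^2)), rep(1.5, J),
               tolerance = 1e-10)
  expect_equal(bond_angle(gp, par, new), rep(109.5, J), tolerance = 1e-10)
  # recomputing the dihedral returns the input torsion (inverse identity)
  expect_equal(torsion_angle(ggp, gp, par, new), tau, tolerance = 1e-10)
  # and the independent oracle agrees
  expect_equal(oracle_torsion(ggp[1, ], gp[1, ], par[1, ], new[1, ]),
               tau[1], tolerance = 1e-6)
  # a known trans placement, checked by hand geometry: torsion 180 puts
  # the new atom in the ggp-gp-par plane, anti to ggp
  a <- matrix(c(0, 0, 0), 1); b <- matrix(c(1.5, 0, 0), 1)
  c3 <- matrix(c(2, 1.4, 0), 1)
  d <- place_next_cloud(a, b, c3, 1.5, 109.5, 180)
  expect_equal(d[1, 3], 0, tolerance = 1e-10)     # in plane
  expect_gt(d[1, 1], c3[1, 1])                    # extends away from a
})

test_that("the flexless structure is a rigid duplication of the anchor cloud", {
  m <- fx_model("GAASVKG", J = 24)
  fl <- build_flexless(m)
  dev <- vapply(fl$pts, function(p)
    max(abs(sweep(p, 2, colMeans(p)) - fl$delta)), 0)
  expect_lt(max(dev), 1e-9)
  # all conformers congruent: per-conformer bond lengths identical
  a <- m$graph$atoms
  i <- which(!is.na(a$parent))[10]
  d <- sqrt(rowSums((fl$pts[[i]] - fl$pts[[a$parent[i]]])^2))
  expect_lt(diff(range(d)), 1e-9)
  # s factors lie in [-1, 1]
  S <- bondflex:::.s_factors(m$graph, fl$cache)
  expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))
  # cloud means reproduce the single-conformer average structure up to
  # the constant anchor-cloud mean offset
  mu <- ensemble_means(fl)
  avg <- bondflex:::.avg_positions(m)
  offs <- mu - avg
  expect_lt(max(abs(sweep(offs, 2, colMeans(offs)))), 1e-9)
  # no RNG anywhere: a second build is bit-identical
  fl2 <- build_flexless(m)
  expect_identical(fl$pts, fl2$pts)
})

test_that("derived B factors measure the cloud second moment", {
  expect_equal(derived_b_factor(matrix(1, 5, 3)), 0)
  expect_equal(derived_b_factor(matrix(c(0, 0, 0), 1, 3)), 0)
  # points on a shell of radius r: B = (8 pi^2 / 3) r^2
  r <- 0.5
  cl <- build_anchor_cloud(400, r)
  cl <- cl[abs(sqrt(rowSums(cl^2)) - r) < 1e-9, , drop = FALSE]
  expect_equal(derived_b_factor(cl), 8 * pi^2 / 3 * r^2,
               tolerance = 0.02)
  # flexless structure: every atom has the same B
  m <- fx_model("GAG", ss = "loop", J = 16)
  bf <- ensemble_bfactors(build_flexless(m))
  expect_lt(diff(range(bf)), 1e-9)
})

test_that("torsion-only flexibility leaves bond geometry invariant", {
  m <- fx_model("GAASVKG", J = 12)
  grp <- m$graph$groups
  bb <- which(grp$backbone & grp$refinable)
  m$graph$groups$kick[bb[2]] <- 0.4
  m$graph$groups$kick[bb[4]] <- -0.25
  ens <- build_ensemble(m)
  a <- m$graph$atoms
  ok <- which(!is.na(a$parent))
  maxdev <- 0
  for (i in ok) {
    d <- sqrt(rowSums((ens$pts[[i]] - ens$pts[[a$parent[i]]])^2))
    maxdev <- max(maxdev, max(abs(d - a$l[i])))
  }
  expect_lt(maxdev, 1e-9)
})
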