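test_that("connectivity follows the residue templates", {
  pep <- fx_peptide("GAG", ss = "loop")
  g <- build_connectivity(pep$records)
  # backbone N-CA-C chain plus O branches; GLY has no CB
  expect_equal(nrow(g$atoms), 13)            # 4 + 5 + 4 heavy atoms
  expect_equal(sum(g$edges$b == "CB"), 1)    # only the ALA
  expect_equal(sum(g$edges$a == "-C"), 2)    # two peptide links
  # single glycine: no side-chain branch
  g1 <- build_connectivity(make_ideal_peptide("G")$records)
  expect_equal(nrow(g1$atoms), 4)
  expect_false("CB" %in% g1$atoms$name)
  # a missing backbone atom is a hard error naming the residue
  rec <- pep$records
  rec <- rec[!(rec$resno == 2 & rec$name == "CA"), ]
  expect_error(build_connectivity(rec), "incomplete residue ALA 2")
  expect_error(build_connectivity(pep$records[0, ]), "no atom")
})

test_that("alternate-location handling is strict by default, lenient on request", {
  rec <- fx_peptide("GAG", ss = "loop")$records
  rec$alt <- ""
  extra <- rec[rec$resno == 2 & rec$name == "CB", ]
  rec$alt[rec$resno == 2 & rec$name == "CB"] <- "A"
  rec$occ[rec$resno == 2 & rec$name == "CB"] <- 0.6
  extra$alt <- "B"; extra$occ <- 0.4; extra$x <- extra$x + 0.5
  rec2 <- rbind(rec, extra)
  expect_error(build_connectivity(rec2, altloc = "strict"), "alternate")
  g <- build_connectivity(rec2, altloc = "lenient")
  cb <- g$atoms[g$atoms$name == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$occ, 0.6)                  # highest occupancy kept
})

test_that("the anchor is the backbone N nearest the centre of mass", {
  pep <- fx_peptide("AAAAA", ss = "helix")
  g <- build_connectivity(pep$records)
  anchor <- choose_anchor(g)
  expect_equal(g$atoms$name[anchor], "N")
  # independent oracle: distance of every backbone N to the heavy-atom
  # centroid of the chain
  heavy <- g$atoms[!g$atoms$is_h, ]
  com <- colMeans(heavy[, c("x", "y", "z")])
  ns <- heavy[heavy$name == "N", ]
  d2 <- (ns$x - com[1])^2 + (ns$y - com[2])^2 + (ns$z - com[3])^2
  expect_equal(g$atoms$resno[anchor], ns$resno[which.min(d2)])
  g1 <- build_connectivity(make_ideal_peptide("A")$records)
  a1 <- choose_anchor(g1)
  expect_equal(g1$atoms$resno[a1], 1)
  # determinism
  expect_identical(anchor, choose_anchor(g))
})

test_that("initial torsions reproduce the generator's angles", {
  truth_phi <- -63; truth_psi <- -41
  pep <- make_ideal_peptide("AAAAAAAAA", phi = truth_phi, psi = truth_psi)
  m <- build_model(pep$records, J = 4)
  g <- m$graph
  anchor_res <- g$atoms$resno[g$anchor]
  r0 <- anchor_res + 1           # C-terminal side, not the last residue
  expect_lt(r0, max(g$resnos))
  ca <- g$atoms$idx[g$atoms$resno == r0 & g$atoms$name == "CA"]
  expect_equal(g$groups$t[g$groups$id == ca], truth_phi, tolerance = 1e-6)
  cc <- g$atoms$idx[g$atoms$resno == r0 & g$atoms$name == "C"]
  expect_equal(g$groups$t[g$groups$id == cc], truth_psi, tolerance = 1e-6)
  # trans peptide: omega group (children of N) is 180
  nn <- g$atoms$idx[g$atoms$resno == r0 & g$atoms$name == "N"]
  expect_equal(abs(g$groups$t[g$groups$id == nn]), 180, tolerance = 1e-6)
})

test_that("measured dihedrals agree with the bio3d oracle", {
  set.seed(4)
  for (rep in 1:20) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    ours <- torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(ours, oracle_torsion(pts[1, ], pts[2, ], pts[3, ],
                                      pts[4, ]), tolerance = 1e-8)
  }
  expect_error(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)), "colinear")
})

test_that("hydrogens regenerate at exactly 0.968 A with template geometry", {
  m <- fx_model("GAASVKG")
  a <- m$graph$atoms
  hs <- which(a$is_h)
  expect_gt(length(hs), 20)
  for (i in hs) {
    p <- a$parent[i]
    d <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                     as.numeric(a[p, c("x", "y", "z")]))^2))
    expect_equal(d, 0.968, tolerance = 1e-9)
  }
  # glycine CA carries two hydrogens
  g1 <- derive_initial_torsions(regenerate_hydrogens(
    build_connectivity(make_ideal_peptide("G")$records)))
  expect_equal(sum(g1$atoms$is_h & g1$atoms$parent ==
                     g1$atoms$idx[g1$atoms$name == "CA"]), 2)
  # methyl hydrogens at 120 degree spacing about the bond axis
  ala <- a[a$resno == 2, ]                   # ALA in GAASVKG
  hb <- ala[ala$name %in% c("HB1", "HB2", "HB3"), ]
  cb <- as.numeric(ala[ala$name == "CB", c("x", "y", "z")])
  ca <- as.numeric(ala[ala$name == "CA", c("x", "y", "z")])
  nn <- as.numeric(ala[ala$name == "N", c("x", "y", "z")])
  taus <- sapply(seq_len(3), function(k)
    torsion_angle(nn, ca, cb, as.numeric(hb[k, c("x", "y", "z")])))
  gaps <- sort(diff(sort(taus)))
  expect_equal(gaps, c(120, 120), tolerance = 1e-6)
})

test_that("imposed geometry is reproduced exactly by the rebuild", {
  m <- fx_model("GAASVKG")
  g <- m$graph
  pos <- bondflex:::.avg_positions(m)
  ok <- which(!is.na(g$atoms$parent))
  lens <- sqrt(rowSums((pos[ok, ] - pos[g$atoms$parent[ok], ])^2))
  expect_equal(lens, g$atoms$l[ok], tolerance = 1e-9)
})

test_that("the parameter inventory matches the counting scheme", {
  m <- fx_model("AAAAAAAAAA", ss = "helix", J = 4)  # polyalanine 10-mer
  inv <- count_refinable_parameters(m$graph)
  expect_equal(inv$atomistic, 4 * sum(!m$graph$atoms$is_h))
  # bond-based parametrization reduces the count by roughly 60%
  expect_gt(inv$reduction, 0.50)
  expect_lt(inv$reduction, 0.70)
  # one extra screw motion adds exactly five parameters
  inv4 <- count_refinable_parameters(m$graph, n_screws = 4)
  expect_equal(inv4$total - inv$total, 5)
  # sampling invariance: J does not enter the inventory
  m2 <- fx_model("AAAAAAAAAA", ss = "helix", J = 4)
  m2$J <- 120L
  expect_identical(count_refinable_parameters(m2$graph), inv)
})
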