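test_that("the simplex minimizer solves convex problems", {
  bowl <- function(p) (p[1] - 2)^2 + 3 * (p[2] + 1)^2
  res <- simplex_minimize(c(0, 0), c(1, 1), bowl, max_cycles = 100)
  expect_lt(sum(abs(res$par - c(2, -1))), 1e-4)
  expect_lte(res$cycles, 100)
  # already-optimal start: no move beyond tolerance
  res0 <- simplex_minimize(c(2, -1), c(0.5, 0.5), bowl, max_cycles = 100)
  expect_lt(sum(abs(res0$par - c(2, -1))), 1e-3)
  # zero cycles returns the input unchanged
  resz <- simplex_minimize(c(5, 5), c(1, 1), bowl, max_cycles = 0)
  expect_identical(resz$par, c(5, 5))
  expect_error(simplex_minimize(c(0), c(1), function(p) NaN, 10),
               "non-finite")
})

test_that("the weighted Pearson correlation behaves at its limits", {
  set.seed(6)
  x <- rnorm(5000)
  expect_equal(weighted_pearson(x, x, rep(1, 5000)), 1)
  y <- rnorm(5000)
  # uniform weights reduce to the ordinary correlation
  expect_equal(weighted_pearson(x, y, rep(2, 5000)), stats::cor(x, y))
  # uncorrelated noise: |CC| stays small
  expect_lt(abs(weighted_pearson(x, y, runif(5000))), 0.1)
  expect_error(weighted_pearson(x, x * 0, rep(1, 5000)), "variance")
  expect_error(weighted_pearson(x, y, rep(0, 5000)), "weight")
})

test_that("bond clustering is antisymmetric with enough parameters", {
  m <- fx_model("GAASVKG", J = 10)
  cl <- cluster_bonds_for_flex(m)
  expect_equal(cl$score, -t(cl$score))
  expect_true(all(diag(cl$score) == 0))
  # at least 10 clusters (or all bonds) with k and k' each: >= 20
  # parameters unless the chain is too short
  nb <- length(cl$bonds)
  expect_equal(ncol(cl$weights), min(max(10, which(cumsum(cl$values) /
    sum(cl$values) >= 0.5)[1]), nb))
  expect_gte(2 * ncol(cl$weights), min(20, 2 * nb))
  # zero multipliers give back the flexless structure
  m0 <- bondflex:::.apply_cluster_kicks(m, cl, rep(0, 2 *
                                                     ncol(cl$weights)))
  expect_true(all(m0$graph$groups$kick == 0))
  expect_true(all(m0$graph$calphas$rkick == 0))
})

test_that("mode 1 recovers perturbed torsions against original positions", {
  m <- fx_model("GAASVKG", J = 4)
  g <- m$graph
  bb <- which(g$groups$backbone & g$groups$refinable)
  tg <- bb[6]
  truth <- m$graph$groups$t[tg]
  m2 <- m
  m2$graph$groups$t[tg] <- truth + 5
  m3 <- refine_positions_mode1(m2, passes = 2)
  err <- abs(m3$graph$groups$t[tg] - truth)
  expect_lt(min(err, 360 - err), 0.1)
  pos0 <- bondflex:::.avg_positions(m)
  pos3 <- bondflex:::.avg_positions(m3)
  bbat <- which(g$atoms$name %in% c("N", "CA", "C"))
  expect_lt(sqrt(mean(rowSums((pos3[bbat, ] - pos0[bbat, ])^2))), 0.05)
  # a model already at the original positions is a no-op
  m4 <- refine_positions_mode1(m, passes = 1)
  expect_lt(max(abs(m4$graph$groups$t - m$graph$groups$t)), 0.05)
})

test_that("mode 2a introduces three screws and respects a self-map", {
  m <- fx_model("GAASG", ss = "helix", J = 6,
                cell = make_cell(22, 20, 18))
  refl <- simulate_reflections(m, d_min = 2.5, noise = 0, free_frac = 0,
                               seed = 1)
  r <- model_r_factors(m, refl)
  wmap <- synthesize_weighted_map(refl, r$f_calc, r$dims)
  # the map equals the model's own: T stays near the identity
  m2 <- refine_whole_molecule_mode2a(m, wmap, d = refl$d_min, refl,
                                     first = FALSE, max_cycles = 30)
  expect_lt(max(abs(m2$motions$T - diag(3))), 0.3)
  # first macrocycle ends with three screw motions
  m3 <- refine_whole_molecule_mode2a(m, wmap, d = refl$d_min, refl,
                                     first = TRUE, max_cycles = 3)
  expect_equal(length(m3$motions$screws), 3)
})

test_that("mode 3 refines side chains only", {
  m <- fx_model("GAASG", ss = "helix", J = 6,
                cell = make_cell(22, 20, 18))
  refl <- simulate_reflections(m, d_min = 2.5, noise = 0, free_frac = 0,
                               seed = 2)
  r <- model_r_factors(m, refl)
  wmap <- synthesize_weighted_map(refl, r$f_calc, r$dims)
  m3 <- refine_sidechains_mode3(m, wmap, d = refl$d_min, refl,
                                max_cycles = 10)
  # backbone torsions and average backbone positions are untouched
  bb <- which(m$graph$groups$backbone)
  expect_identical(m3$graph$groups$t[bb], m$graph$groups$t[bb])
  pos0 <- bondflex:::.avg_positions(m)
  pos3 <- bondflex:::.avg_positions(m3)
  bbat <- which(m$graph$atoms$name %in% c("N", "CA", "C"))
  expect_lt(max(abs(pos3[bbat, ] - pos0[bbat, ])), 1e-9)
  # all-glycine chain: no side-chain parameters, a strict no-op
  mg <- build_model(make_ideal_peptide("GGGG", ss = "loop")$records,
                    J = 4)
  reflg <- simulate_reflections(mg, d_min = 3, noise = 0, free_frac = 0,
                                seed = 3)
  rg <- model_r_factors(mg, reflg)
  wg <- synthesize_weighted_map(reflg, rg$f_calc, rg$dims)
  mg3 <- refine_sidechains_mode3(mg, wg, d = reflg$d_min, reflg)
  expect_identical(mg3$graph$groups$t, mg$graph$groups$t)
})

test_that("omega contraction walks down by 10% while R_work improves", {
  pep <- fx_peptide("GAASG", ss = "helix")
  truth <- build_model(pep$records, J = 10, cell = make_cell(22, 20, 18))
  truth$omega <- 0.356 * 0.9^3
  refl <- simulate_reflections(truth, d_min = 2.5, noise = 0.01,
                               free_frac = 0, seed = 4)
  wide <- build_model(pep$records, J = 10, cell = make_cell(22, 20, 18))
  co <- contract_omega(wide, refl)
  expect_gte(co$steps, 2)
  expect_equal(co$model$omega, 0.356 * 0.9^co$steps)
  expect_lt(co$r$r_work, model_r_factors(wide, refl)$r_work)
})

test_that("the protocol's accepted R_work sequence never increases", {
  pep <- fx_peptide("GAASG", ss = "helix")
  m <- build_model(pep$records, J = 8, cell = make_cell(22, 20, 18))
  refl <- simulate_reflections(m, d_min = 2.5, noise = 0.02,
                               free_frac = 0.05, seed = 5)
  res <- run_protocol(m, refl, n_macrocycles = 1, max_cycles = 20)
  expect_true(all(diff(res$log$r_work) <= 1e-12))
  expect_lte(res$r_work, res$log$r_work[res$log$stage == "mode1"])
  # R_free is reported at every stage
  expect_true(all(is.finite(res$log$r_free)))
})
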