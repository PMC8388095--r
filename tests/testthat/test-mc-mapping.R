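# Metropolis Monte Carlo engine: energies against the pairwise oracle,
# acceptance rule, bookkeeping, determinism, occupancy maps.

test_that("interaction energy is zero for a neutral ligand and linear in phi", {
  s <- specificity_system()
  neutral <- s$lig_neg
  neutral$atoms$charge <- 0
  p <- pose(c(0, 0, 60))
  expect_equal(interaction_energy(neutral, p, s$grid, s$rec), 0)
  # single +1 e atom at a node where phi is known
  g <- potential_grid(c(-2, -2, -2), 2, array(-2, c(3, 3, 3)))
  e <- interaction_energy(probe_ligand(1), pose(c(0, 0, 0)), g)
  expect_equal(e, -2)
})

test_that("pose energies match a direct screened-Coulomb pairwise sum", {
  s <- specificity_system()
  set.seed(9)
  lf_com <- centroid(s$lig_neg)
  body <- sweep(coords(s$lig_neg), 2, lf_com)
  for (i in 1:5) {
    t <- runif(3, -1, 1); t <- 45 * t / sqrt(sum(t^2))
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    p <- pose(t, q)
    e_grid <- interaction_energy(s$lig_neg, p, s$grid, s$rec)
    pts <- sweep(quat_rotate(q, body), 2, t, "+")
    phi <- potential_at_points(s$rec, pts,
                               ionic_strength = s$ionic_strength)
    e_direct <- sum(s$lig_neg$atoms$charge * phi)
    bound <- sum(abs(s$lig_neg$atoms$charge) *
                   grid_error_bound(s$rec, pts, spacing = s$grid$spacing,
                                    ionic_strength = s$ionic_strength))
    expect_lt(abs(e_grid - e_direct), max(bound, 0.5))
  }
})

test_that("clashing poses get the infinite-energy sentinel", {
  s <- specificity_system()
  # ligand centred inside the receptor shell: guaranteed hard-core overlap
  e <- interaction_energy(s$lig_neg, pose(c(0, 0, 25)), s$grid, s$rec)
  expect_identical(e, Inf)
  # far outside: finite
  e2 <- interaction_energy(s$lig_neg, pose(c(0, 0, 80)), s$grid, s$rec)
  expect_true(is.finite(e2))
})

test_that("the Metropolis rule always accepts downhill moves", {
  set.seed(4)
  expect_true(all(replicate(200, metropolis_accept(-abs(rnorm(1))))))
  expect_true(all(replicate(50, metropolis_accept(0))))
})

test_that("metropolis_step returns valid poses and obeys d_max", {
  g <- step_field_grid(1)
  lig <- probe_ligand(1)
  cfg <- mc_config(n_runs = 1, n_steps = 10, burn_in = 0, record_every = 1,
                   translation_step = 3, d_max = 5, seed = 1)
  set.seed(7)
  p <- pose(c(0, 0, 0), energy = NA_real_)
  for (i in 1:200) {
    p <- metropolis_step(p, cfg, g, NULL, lig)
    expect_lte(sqrt(sum(p$translation^2)), 5 + 1e-9)
    expect_equal(sqrt(sum(p$rotation^2)), 1, tolerance = 1e-9)
  }
  # energy carried on the pose matches a fresh evaluation
  expect_equal(p$energy, interaction_energy(lig, p, g))
})

test_that("ensemble size, determinism, and energy bookkeeping hold", {
  s <- specificity_system()
  cfg <- mc_config(n_runs = 2, n_steps = 100, burn_in = 0, record_every = 10,
                   d_max = 60, seed = 42)
  ens <- run_mapping(s$rec, s$lig_neg, s$grid, cfg)
  expect_equal(nrow(ens$poses), 2 * 10)
  ens2 <- run_mapping(s$rec, s$lig_neg, s$grid, cfg)
  expect_identical(ens$poses, ens2$poses)
  # stored energies reproduce exactly under re-evaluation
  for (i in seq_len(nrow(ens$poses))) {
    p <- ens$poses[i, ]
    e <- interaction_energy(s$lig_neg,
                            pose(c(p$tx, p$ty, p$tz),
                                 c(p$qw, p$qx, p$qy, p$qz)),
                            s$grid, s$rec)
    expect_identical(e, p$energy)
  }
})

test_that("occupancy maps conserve counts and localize single poses", {
  s <- specificity_system()
  cfg <- mc_config(n_runs = 3, n_steps = 200, burn_in = 100,
                   record_every = 10, d_max = 60, seed = 5)
  ens <- run_mapping(s$rec, s$lig_neg, s$grid, cfg)
  occ <- occupancy_map(ens, spacing = 4)
  expect_equal(sum(occ), nrow(ens$poses))
  one <- ens
  one$poses <- ens$poses[1, , drop = FALSE]
  occ1 <- occupancy_map(one, spacing = 4)
  expect_equal(sum(occ1), 1L)
  expect_equal(max(occ1), 1L)
})

test_that("a uniform field yields no spurious density concentration", {
  g <- step_field_grid(0)   # phi identically zero
  lig <- probe_ligand(1)
  cfg <- mc_config(n_runs = 50, n_steps = 2000, burn_in = 500,
                   record_every = 25, translation_step = 3, d_max = 10,
                   seed = 9)
  ens <- run_mapping(NULL, lig, g, cfg)
  # hemisphere counts should be statistically balanced
  x <- ens$poses$tx
  p_hat <- mean(x > 0)
  expect_lt(abs(p_hat - 0.5), 0.05)
  # no voxel wildly exceeds the uniform expectation
  occ <- occupancy_map(ens, origin = c(-10, -10, -10), spacing = 5,
                       dims = c(4L, 4L, 4L))
  inside <- sum(occ)
  expect_gt(inside, 0.9 * nrow(ens$poses))
  expect_lt(max(occ), 5 * inside / 33)   # ~33 voxels intersect the ball
})

test_that("halving the translation step moves acceptance but not the density maximum", {
  s <- specificity_system()
  base <- mc_config(n_runs = 60, n_steps = 8000, d_max = 60, seed = 31)
  half <- mc_config(n_runs = 60, n_steps = 8000, d_max = 60, seed = 31,
                    translation_step = 1.0)
  e1 <- run_mapping(s$rec, s$lig_neg, s$grid, base)
  e2 <- run_mapping(s$rec, s$lig_neg, s$grid, half)
  expect_gt(mean(e2$acceptance), mean(e1$acceptance))
  for (ens in list(e1, e2)) {
    occ <- occupancy_map(ens, origin = c(-60, -60, -60), spacing = 4,
                         dims = c(31L, 31L, 31L))
    mx <- which(occ == max(occ), arr.ind = TRUE)[1, ]
    ctr <- attr(occ, "origin") + (mx - 0.5) * attr(occ, "spacing")
    # density maximum sits over the patch (+z) in both cases
    expect_gt(ctr[3] / sqrt(sum(ctr^2)), 0.7)
  }
})
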