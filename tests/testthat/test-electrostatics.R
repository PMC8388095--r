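# Screened-Coulomb electrostatics: ionic strength, Debye screening, grids
# and interpolation against the direct-sum reference.

test_that("ionic strength handles simple salts, phosphate speciation, and edge cases", {
  kcl <- data.frame(conc = c(0.1, 0.1), charge = c(1, -1))
  expect_equal(ionic_strength(kcl), 0.1)
  # independent Henderson-Hasselbalch oracle for 20 mM phosphate, pH 7
  f2 <- 1 / (1 + 10^(7.20 - 7.0))     # fraction HPO4^2-
  c1 <- 0.02 * (1 - f2); c2 <- 0.02 * f2
  cK <- c1 + 2 * c2                   # K+ to electroneutrality
  I_oracle <- (c1 * 1 + c2 * 4 + cK * 1) / 2
  expect_equal(ionic_strength(phosphate_buffer(0.02, 7, 7.20)), I_oracle,
               tolerance = 1e-12)
  expect_equal(I_oracle, 0.0355, tolerance = 2e-3)
  expect_equal(ionic_strength(NULL), 0)
  expect_equal(ionic_strength(data.frame(conc = numeric(), charge = numeric())), 0)
  expect_error(ionic_strength(data.frame(conc = -0.1, charge = 1)), "negative")
})

test_that("Debye kappa follows the closed form and is monotone in I", {
  expect_equal(debye_kappa(0), 0)
  # 1/kappa at 0.1 M, 298 K, eps 78.5: 9.617 A from CODATA constants
  expect_equal(1 / debye_kappa(0.1, 298, 78.5), 9.6174, tolerance = 1e-3)
  I <- c(0.001, 0.01, 0.05, 0.1, 0.5)
  expect_true(all(diff(debye_kappa(I)) > 0))
  expect_error(debye_kappa(-1), "negative")
})

test_that("a unit charge gives ~1 kBT/e at the Bjerrum length in vacuum at 300 K", {
  m <- probe_ligand(charge = 1)
  lB <- bjerrum_length(300, 1)
  phi <- potential_at_points(m, matrix(c(lB, 0, 0), 1), kappa = 0,
                             temperature = 300, dielectric = 1)
  expect_equal(as.numeric(phi), 1, tolerance = 1e-12)
  phi2 <- potential_at_points(m, matrix(c(560.2, 0, 0), 1), kappa = 0,
                              temperature = 300, dielectric = 1)
  expect_equal(as.numeric(phi2), 1, tolerance = 0.01)
})

test_that("kappa = 0, eps_r = 1 limit matches analytic Coulomb at 100 random points", {
  set.seed(1)
  n_at <- 12
  atoms <- data.frame(serial = 1:n_at, name = "CA", resname = "GLY",
                      resid = 1:n_at, chain = "A",
                      x = rnorm(n_at, 0, 4), y = rnorm(n_at, 0, 4),
                      z = rnorm(n_at, 0, 4),
                      charge = rnorm(n_at), radius = 0,
                      cofactor_id = NA_character_)
  m <- molecular_model(atoms)
  pts <- matrix(rnorm(300, 0, 25), ncol = 3)
  phi <- potential_at_points(m, pts, kappa = 0, temperature = 300,
                             dielectric = 1)
  lB <- bjerrum_length(300, 1)
  phi_ref <- apply(pts, 1, function(p) {
    r <- sqrt(colSums((t(as.matrix(atoms[, c("x", "y", "z")])) - p)^2))
    lB * sum(atoms$charge / r)
  })
  expect_equal(as.numeric(phi), phi_ref, tolerance = 1e-8)
})

test_that("the field is linear in the charges (superposition)", {
  a1 <- data.frame(serial = 1L, name = "CA", resname = "GLY", resid = 1L,
                   chain = "A", x = -3, y = 0, z = 0, charge = 1.7,
                   radius = 0, cofactor_id = NA_character_)
  a2 <- a1; a2$x <- 4; a2$charge <- -0.8; a2$serial <- 2L; a2$resid <- 2L
  box <- list(origin = c(-10, -10, -10), dims = c(11L, 11L, 11L))
  gr <- function(at) compute_potential_grid(
    molecular_model(at), spacing = 2, origin = box$origin, dims = box$dims,
    ionic_strength = 0.02)
  g12 <- gr(rbind(a1, a2)); g1 <- gr(a1); g2 <- gr(a2)
  expect_equal(g12$values, g1$values + g2$values, tolerance = 1e-10)
})

test_that("screening monotonically damps the potential magnitude", {
  m <- probe_ligand(charge = 1)
  pts <- matrix(c(3, 0, 0, 0, 8, 0, 5, 5, 5), ncol = 3, byrow = TRUE)
  kappas <- c(0, 0.05, 0.1, 0.3, 1)
  phis <- sapply(kappas, function(k)
    abs(potential_at_points(m, pts, kappa = k)))
  for (i in seq_len(nrow(pts)))
    expect_true(all(diff(phis[i, ]) <= 1e-14))
})

test_that("trilinear interpolation is exact at nodes and for linear fields", {
  # linear field phi = 2x + 3y - z sampled on a grid
  xs <- seq(-4, 4, 2)
  vals <- array(0, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    vals[i, j, k] <- 2 * xs[i] + 3 * xs[j] - xs[k]
  g <- potential_grid(c(-4, -4, -4), 2, vals)
  # node queries
  expect_equal(interpolate_potential(g, rbind(c(-4, -4, -4), c(0, 2, -2))),
               c(vals[1, 1, 1], vals[3, 4, 2]))
  # off-node queries of the linear field are exact
  set.seed(2)
  pts <- matrix(runif(60, -4, 4), ncol = 3)
  expect_equal(interpolate_potential(g, pts),
               2 * pts[, 1] + 3 * pts[, 2] - pts[, 3], tolerance = 1e-12)
  expect_error(interpolate_potential(g, matrix(c(9, 0, 0), 1)), "outside")
  expect_equal(interpolate_potential(g, matrix(c(9, 0, 0), 1),
                                     outside = "zero"), 0)
})

test_that("grid interpolation agrees with the direct sum within the stated bound", {
  set.seed(3)
  n_at <- 8
  atoms <- data.frame(serial = 1:n_at, name = "CA", resname = "GLY",
                      resid = 1:n_at, chain = "A",
                      x = rnorm(n_at, 0, 3), y = rnorm(n_at, 0, 3),
                      z = rnorm(n_at, 0, 3),
                      charge = sample(c(-1, 1), n_at, TRUE) * runif(n_at, 0.3, 1),
                      radius = 0, cofactor_id = NA_character_)
  m <- molecular_model(atoms)
  I <- 0.0355
  g <- compute_potential_grid(m, spacing = 1, padding = 15, ionic_strength = I)
  # query points kept a few spacings away from the atoms
  pts <- matrix(runif(300, -12, 12), ncol = 3)
  dmin <- apply(pts, 1, function(p)
    min(sqrt(colSums((t(coords(m)) - p)^2))))
  pts <- pts[dmin > 3, , drop = FALSE]
  phi_grid <- interpolate_potential(g, pts)
  phi_direct <- potential_at_points(m, pts, ionic_strength = I)
  bound <- grid_error_bound(m, pts, spacing = 1, ionic_strength = I)
  expect_true(all(abs(phi_grid - phi_direct) <= bound))
  # and the bound is not vacuous at this spacing
  expect_lt(max(abs(phi_grid - phi_direct)), 0.1)
})

test_that("isopotential masks capture sign and disjointness", {
  zero <- potential_grid(c(0, 0, 0), 1, array(0, c(4, 4, 4)))
  expect_false(any(isopotential_mask(zero, 1)))
  expect_error(isopotential_mask(zero, 0), "nonzero")
  plus <- compute_potential_grid(probe_ligand(1), spacing = 1, padding = 8)
  expect_true(any(isopotential_mask(plus, 1)))
  expect_false(any(isopotential_mask(plus, -1)))
  # dipole: both masks non-empty and disjoint
  a1 <- data.frame(serial = 1L, name = "CA", resname = "GLY", resid = 1L,
                   chain = "A", x = -3, y = 0, z = 0, charge = 1, radius = 0,
                   cofactor_id = NA_character_)
  a2 <- a1; a2$x <- 3; a2$charge <- -1; a2$serial <- 2L
  dip <- compute_potential_grid(molecular_model(rbind(a1, a2)),
                                spacing = 1, padding = 8)
  mp <- isopotential_mask(dip, 1); mn <- isopotential_mask(dip, -1)
  expect_true(any(mp) && any(mn))
  expect_false(any(mp & mn))
})
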