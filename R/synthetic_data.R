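# Synthetic structures and data with known ground truth, so every pipeline
# stage is testable without deposited coordinates. The structural toys
# emulate the study geometry at coarse-bead scale: a large receptor sphere
# with a charged concave-patch analogue and two surface cofactor sites (one
# inside, one opposite the patch), and a small single-cofactor ligand with a
# charged equatorial ring around its heme -- sign-switchable so that a
# negative-ring and a positive-ring ligand differ only in their charges.

# quasi-uniform points on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

# rotation taking c(0,0,1) onto unit vector v
rotate_z_to <- function(pts, v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(z * v)
  if (abs(c_ - 1) < 1e-12) return(pts)
  if (abs(c_ + 1) < 1e-12) return(cbind(pts[, 1], -pts[, 2], -pts[, 3]))
  ax <- c(z[2] * v[3] - z[3] * v[2], z[3] * v[1] - z[1] * v[3],
          z[1] * v[2] - z[2] * v[1])
  s <- sqrt(sum(ax^2)); ax <- ax / s
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + s * K + (1 - c_) * (K %*% K)
  pts %*% t(R)
}

#' Synthetic patch receptor
#'
#' A coarse-bead sphere with a charged surface patch (a cone of
#' `patch_half_angle` around `patch_center`) and two single-atom heme
#' cofactors: `"heme3"` placed inside the patch just below the surface and
#' `"heme1"` on the antipode. Patch beads are named LYS (positive charge)
#' or ASP (negative), background beads GLY, one bead per residue. The model
#' is deterministic given the seed (used only for a small positional
#' jitter).
#'
#' @param radius sphere radius, Angstrom.
#' @param n_atoms surface beads.
#' @param patch_center unit vector of the patch axis.
#' @param patch_half_angle degrees, in (0, 90).
#' @param patch_charge_per_atom e per patch bead.
#' @param background_charge e per non-patch bead.
#' @param bead_radius hard-core radius per bead, Angstrom.
#' @param jitter positional jitter sigma, Angstrom.
#' @param seed RNG seed.
#' @return A charged [molecular_model()] with attribute `patch_axis`.
#' @export
make_patch_receptor <- function(radius = 25, n_atoms = 400,
                                patch_center = c(0, 0, 1),
                                patch_half_angle = 30,
                                patch_charge_per_atom = 0.5,
                                background_charge = 0,
                                bead_radius = 2.0, jitter = 0.1, seed = 1) {
  stopifnot(patch_half_angle > 0, patch_half_angle < 90)
  axis <- patch_center / sqrt(sum(patch_center^2))
  pts <- fibonacci_sphere(n_atoms) * radius
  set.seed(seed)
  pts <- pts + matrix(rnorm(3 * n_atoms, 0, jitter), ncol = 3)
  cosang <- (pts %*% axis) / sqrt(rowSums(pts^2))
  in_patch <- as.vector(cosang >= cos(patch_half_angle * pi / 180))
  atoms <- data.frame(
    serial = seq_len(n_atoms),
    name = "CA",
    resname = ifelse(in_patch,
                     if (patch_charge_per_atom >= 0) "LYS" else "ASP",
                     "GLY"),
    resid = seq_len(n_atoms),
    chain = "R",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    charge = ifelse(in_patch, patch_charge_per_atom, background_charge),
    radius = bead_radius,
    cofactor_id = NA_character_,
    stringsAsFactors = FALSE)
  cof <- data.frame(
    serial = n_atoms + 1:2,
    name = "FE",
    resname = "HEC",
    resid = n_atoms + 1:2,
    chain = "R",
    x = c(axis[1], -axis[1]) * (radius - 1),
    y = c(axis[2], -axis[2]) * (radius - 1),
    z = c(axis[3], -axis[3]) * (radius - 1),
    charge = 0, radius = 1.3,
    cofactor_id = c("heme3", "heme1"),
    stringsAsFactors = FALSE)
  m <- molecular_model(rbind(atoms, cof))
  attr(m, "patch_axis") <- axis
  m
}

#' Synthetic ring ligand
#'
#' A small coarse-bead sphere with a charged equatorial ring of beads and a
#' single central heme cofactor. The geometry is a pure function of
#' `n_atoms`, `radius`, `ring_n` and `seed`; flipping the sign of
#' `ring_charge` negates the charges and renames the ring beads
#' (ASP for negative, LYS for positive) without moving a single atom, so
#' sign pairs are exact electrostatic controls.
#'
#' @param radius sphere radius, Angstrom.
#' @param n_atoms core surface beads (ring beads are additional).
#' @param ring_charge e per ring bead (sign selects the variant).
#' @param ring_n ring beads on the equator.
#' @param cofactor_id id of the central heme.
#' @param bead_radius hard-core radius per bead, Angstrom.
#' @param jitter positional jitter sigma, Angstrom.
#' @param seed RNG seed.
#' @return A charged [molecular_model()].
#' @export
make_ring_ligand <- function(radius = 8, n_atoms = 50, ring_charge = -0.5,
                             ring_n = 12, cofactor_id = "hemeL",
                             bead_radius = 2.0, jitter = 0.1, seed = 2) {
  pts <- fibonacci_sphere(n_atoms) * radius
  set.seed(seed)
  pts <- pts + matrix(rnorm(3 * n_atoms, 0, jitter), ncol = 3)
  ang <- 2 * pi * (seq_len(ring_n) - 1) / ring_n
  ring <- cbind(radius * cos(ang), radius * sin(ang), 0)
  ring_name <- if (ring_charge < 0) "ASP" else "LYS"
  atoms <- data.frame(
    serial = seq_len(n_atoms + ring_n + 1),
    name = c(rep("CA", n_atoms + ring_n), "FE"),
    resname = c(rep("GLY", n_atoms), rep(ring_name, ring_n), "HEC"),
    resid = seq_len(n_atoms + ring_n + 1),
    chain = "L",
    x = c(pts[, 1], ring[, 1], 0),
    y = c(pts[, 2], ring[, 2], 0),
    z = c(pts[, 3], ring[, 3], 0),
    charge = c(rep(0, n_atoms), rep(ring_charge, ring_n), 0),
    radius = c(rep(bead_radius, n_atoms + ring_n), 1.3),
    cofactor_id = c(rep(NA_character_, n_atoms + ring_n), cofactor_id),
    stringsAsFactors = FALSE)
  molecular_model(atoms)
}

#' Simulate spectroelectrochemical titrations
#'
#' Two limbs (oxidative and reductive) per experiment from the Nernstian
#' sigmoid on a potential ladder, plus Gaussian absorbance noise and a
#' limb-specific affine distortion emulating the hysteresis of repeated
#' oxidation/reduction sweeps (protein denaturation shrinks and offsets the
#' oxidative limb). Ground truth is attached as attributes.
#'
#' @param E_m true midpoint potential, mV vs SHE.
#' @param n electrons.
#' @param temperature K.
#' @param E_grid potential ladder, mV vs SHE (default 25 points from -300
#'   to +300 mV, the sweep range of the protocol).
#' @param noise_sd Gaussian absorbance noise on the normalized scale.
#' @param n_experiments independent experiments.
#' @param hysteresis_scale,hysteresis_offset affine distortion of the
#'   oxidative limb relative to the reductive one.
#' @param seed one seed per experiment (recycled if scalar).
#' @return Titration data.frame (`experiment`, `limb`, `E_mV`, `A420`) with
#'   attributes `E_m`, `n`, `temperature`.
#' @export
simulate_titration <- function(E_m, n = 1, temperature = 293,
                               E_grid = seq(-300, 300, length.out = 25),
                               noise_sd = 0.02, n_experiments = 2,
                               hysteresis_scale = 0.95,
                               hysteresis_offset = 0.05,
                               seed = 1) {
  seeds <- rep_len(seed, n_experiments)
  if (n_experiments > 1 && length(seed) == 1)
    seeds <- seed + seq_len(n_experiments) - 1
  out <- list()
  for (ex in seq_len(n_experiments)) {
    set.seed(seeds[ex])
    ideal <- nernst_absorbance(E_grid, E_m, A_ox = 0, a = 1, n = n,
                               temperature = temperature)
    red <- ideal + rnorm(length(E_grid), 0, noise_sd)
    oxi <- hysteresis_offset + hysteresis_scale * ideal +
      rnorm(length(E_grid), 0, noise_sd)
    out[[ex]] <- data.frame(
      experiment = ex,
      limb = rep(c("oxidative", "reductive"), each = length(E_grid)),
      E_mV = c(E_grid, rev(E_grid)),
      A420 = c(oxi, rev(red)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, E_m = E_m, n = n, temperature = temperature)
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' Replicated rates at each substrate level with multiplicative Gaussian
#' noise: `v = Vmax S/(Km + S) * (1 + eps)`, `eps ~ N(0, noise_frac)`.
#'
#' @param Vmax true maximal rate, umol min^-1 mg^-1.
#' @param Km true Michaelis constant, uM.
#' @param S substrate levels, uM (default 8 levels spanning 1-100 uM).
#' @param replicates technical replicates per level.
#' @param noise_frac relative noise sigma.
#' @param seed RNG seed.
#' @return data.frame (`S`, `replicate`, `v`) with attributes `Vmax`, `Km`.
#' @export
simulate_rates <- function(Vmax, Km, S = c(1, 2, 5, 10, 20, 40, 70, 100),
                           replicates = 3, noise_frac = 0.03, seed = 1) {
  set.seed(seed)
  d <- expand.grid(replicate = seq_len(replicates), S = S)[, 2:1]
  mu <- Vmax * d$S / (Km + d$S)
  d$v <- mu * (1 + rnorm(nrow(d), 0, noise_frac))
  rownames(d) <- NULL
  structure(d, Vmax = Vmax, Km = Km)
}

#' Simulate a progress curve
#'
#' Linear absorbance rise at 550 nm at the given cytochrome-reduction rate
#' until the acceptor equivalent of the substrate (3 cytochromes per
#' hydroxylamine) is exhausted, then flat; plus Gaussian absorbance noise.
#'
#' @param v_cyt_uM_min cytochrome-reduction rate, uM/min.
#' @param substrate_uM initial hydroxylamine, uM.
#' @param epsilon550 mM^-1 cm^-1.
#' @param enzyme_ug,volume_mL,path_cm cuvette metadata.
#' @param duration_s,dt_s sampling.
#' @param noise_sd absorbance noise.
#' @param stoichiometry cytochromes per substrate.
#' @param seed RNG seed.
#' @return A [progress_curve()] with attribute `v_cyt_uM_min`.
#' @export
simulate_progress <- function(v_cyt_uM_min, substrate_uM = 100,
                              epsilon550 = 19.1, enzyme_ug = 0.6,
                              volume_mL = 0.5, path_cm = 1,
                              duration_s = 120, dt_s = 2,
                              noise_sd = 0.001, stoichiometry = 3,
                              seed = 1) {
  set.seed(seed)
  t <- seq(0, duration_s, by = dt_s)
  cyt_max <- substrate_uM * stoichiometry          # uM acceptor reducible
  cyt <- pmin(v_cyt_uM_min * t / 60, cyt_max)      # uM reduced at t
  A <- cyt / 1000 * epsilon550 * path_cm + rnorm(length(t), 0, noise_sd)
  pc <- progress_curve(t, A, substrate_uM, enzyme_ug, volume_mL,
                       epsilon550, path_cm)
  attr(pc, "v_cyt_uM_min") <- v_cyt_uM_min
  pc
}
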