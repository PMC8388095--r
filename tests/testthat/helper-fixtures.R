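# Shared fixtures, built in code. The heavier mapping fixtures (receptor,
# ligands, field grid) are computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a single-atom probe "ligand" with unit charge and no hard core
probe_ligand <- function(charge = 1) {
  molecular_model(data.frame(
    serial = 1L, name = "CA", resname = "GLY", resid = 1L, chain = "L",
    x = 0, y = 0, z = 0, charge = charge, radius = 0,
    cofactor_id = NA_character_))
}

# minimal all-atom-ish tripeptide Lys-Gly-Glu with the atoms the charge
# table targets (N terminus, NZ, OE1/OE2, C-terminal O/OXT)
tripeptide_model <- function() {
  atoms <- data.frame(
    serial = 1:10,
    name    = c("N", "CA", "NZ", "N", "CA", "N", "CA", "OE1", "OE2", "OXT"),
    resname = c("LYS", "LYS", "LYS", "GLY", "GLY", "GLU", "GLU", "GLU", "GLU", "GLU"),
    resid   = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L, 3L),
    chain = "A",
    x = seq(0, 9) * 1.5, y = 0, z = 0,
    charge = 0, radius = 0,
    cofactor_id = NA_character_,
    stringsAsFactors = FALSE)
  molecular_model(atoms)
}

# small model with a two-atom heme (Fe + one propionate oxygen)
heme_model <- function() {
  atoms <- data.frame(
    serial = 1:4,
    name = c("CA", "CB", "FE", "O1A"),
    resname = c("ALA", "ALA", "HEC", "HEC"),
    resid = c(1L, 1L, 2L, 2L),
    chain = "A",
    x = c(0, 1, 5, 6), y = 0, z = 0,
    charge = 0, radius = 0,
    cofactor_id = c(NA, NA, "heme2", "heme2"),
    stringsAsFactors = FALSE)
  molecular_model(atoms)
}

# the synthetic specificity system shared by mapping tests: positive-patch
# receptor, negative- and positive-ring ligands, screened field grid at the
# 20 mM phosphate ionic strength
specificity_system <- function() {
  fixture("specificity_system", function() {
    rec <- make_patch_receptor(seed = 1)
    I <- ionic_strength(phosphate_buffer(0.02, 7, 7.2))
    grid <- compute_potential_grid(rec, spacing = 2,
                                   origin = c(-110, -110, -110),
                                   dims = c(111, 111, 111),
                                   ionic_strength = I)
    list(rec = rec,
         lig_neg = make_ring_ligand(ring_charge = -0.5, seed = 2),
         lig_pos = make_ring_ligand(ring_charge = +0.5, seed = 2),
         grid = grid,
         ionic_strength = I,
         patch_axis = attr(rec, "patch_axis"),
         patch_resids = rec$atoms$resid[rec$atoms$charge > 0])
  })
}

# ensembles for the specificity pair under the desk-scale config
specificity_ensembles <- function() {
  fixture("specificity_ensembles", function() {
    s <- specificity_system()
    cfg <- mc_config(n_runs = 400, d_max = 100, seed = 7)
    list(neg = run_mapping(s$rec, s$lig_neg, s$grid, cfg),
         pos = run_mapping(s$rec, s$lig_pos, s$grid, cfg),
         cfg = cfg)
  })
}

# small uniform step-field grid (phi = delta_e for x >= 0) for Metropolis
# statistics with the single-atom probe
step_field_grid <- function(delta_e = 1, half = 15) {
  n <- 2 * half + 1
  vals <- array(0, c(n, n, n))
  vals[seq(-half, half) >= 0, , ] <- delta_e
  potential_grid(c(-half, -half, -half), 1, vals)
}
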