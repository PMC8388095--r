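# Rigid-body Metropolis Monte Carlo of a ligand protein in the receptor's
# electrostatic field. The receptor is fixed; the ligand carries its partial
# charges and interacts through E = sum_j q_j phi(R x_j + t) in kBT, with a
# hard-core clash term (heavy-atom pair distance < overlap * (ri + rj) gives
# +Inf). The reference protocol is many independent runs of fixed length at
# 300 K within a maximum centre-of-mass distance; per-run RNG streams are
# derived from one master seed, so runs are order-independent.

#' Monte Carlo configuration
#'
#' The reference protocol is 1e6 runs of 25000 steps at 300 K with a 500 A
#' maximum centre-of-mass distance. The desk-scale default keeps the
#' reference per-run chain length (25000 steps, on which equilibration
#' within the sampling ball depends) and scales down the number of
#' independent runs to 400; the move sizes give 30-60% acceptance on the
#' coarse synthetic systems.
#'
#' @param n_runs independent runs, each from a fresh random pose.
#' @param n_steps Metropolis steps per run.
#' @param temperature K; must match the grid's kBT/e unit temperature
#'   (energies are rescaled if not).
#' @param d_max maximum ligand-to-receptor centre-of-mass distance, A;
#'   proposals beyond it are rejected.
#' @param translation_step Gaussian translation proposal sigma, A.
#' @param rotation_step rotation proposal angle sigma, radians.
#' @param burn_in discarded steps at the start of each run.
#' @param record_every thinning interval for recorded poses.
#' @param seed master seed; per-run streams are derived from it.
#' @param overlap hard-core clash factor on the sum of radii.
#' @param max_start_retries resampling attempts for a clash-free start.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_runs = 400, n_steps = 25000, temperature = 300,
                      d_max = 500, translation_step = 2.0,
                      rotation_step = 0.2, burn_in = round(0.2 * n_steps),
                      record_every = 50, seed = 1, overlap = 0.8,
                      max_start_retries = 1000) {
  stopifnot(n_runs >= 1, n_steps > 0, burn_in >= 0, n_steps > burn_in,
            record_every >= 1, d_max > 0, translation_step > 0,
            rotation_step > 0, temperature > 0, overlap > 0)
  structure(list(n_runs = as.integer(n_runs), n_steps = as.integer(n_steps),
                 temperature = temperature, d_max = d_max,
                 translation_step = translation_step,
                 rotation_step = rotation_step,
                 burn_in = as.integer(burn_in),
                 record_every = as.integer(record_every),
                 seed = seed, overlap = overlap,
                 max_start_retries = as.integer(max_start_retries)),
            class = "mc_config")
}

# body-frame ligand coordinates (centroid at origin) + metadata
ligand_frame <- function(ligand) {
  xyz <- coords(ligand)
  com <- colMeans(xyz)
  heavy <- !is_hydrogen(ligand$atoms$name)
  list(coords = sweep(xyz, 2, com),
       charges = ligand$atoms$charge,
       radii = ligand$atoms$radius,
       heavy = heavy, com = com)
}

# receptor heavy atoms for the clash term (zero-radius beads never clash)
receptor_frame <- function(receptor) {
  if (is.null(receptor))
    return(list(coords = matrix(numeric(), 0, 3), radii = numeric(),
                com = c(0, 0, 0)))
  heavy <- !is_hydrogen(receptor$atoms$name)
  list(coords = coords(receptor)[heavy, , drop = FALSE],
       radii = receptor$atoms$radius[heavy],
       com = centroid(receptor))
}

grid_scale <- function(grid, temperature) {
  # grid is in kBT/e at grid$temperature; convert energies to kBT at the MC
  # temperature
  grid$temperature / temperature
}

#' Ligand-in-field interaction energy of a pose
#'
#' `E = sum_j q_j phi(R x_j + t)` in kBT, with the hard-core clash sentinel
#' `+Inf` when any ligand/receptor heavy-atom pair is closer than
#' `overlap * (r_i + r_j)`. Ligand atoms outside the grid see `phi = 0`
#' (far field).
#'
#' @param ligand charged `MolecularModel`; its centroid is placed at the
#'   pose translation.
#' @param pose a [pose()].
#' @param grid `PotentialGrid` of the receptor field.
#' @param receptor `MolecularModel` for the clash term (NULL to disable
#'   clash checking).
#' @param temperature K for the kBT energy unit.
#' @param overlap clash factor.
#' @return Energy in kBT (`+Inf` on clash).
#' @export
interaction_energy <- function(ligand, pose, grid, receptor = NULL,
                               temperature = grid$temperature,
                               overlap = 0.8) {
  lf <- ligand_frame(ligand)
  rf <- receptor_frame(receptor)
  e <- cpp_pose_energy(lf$coords, lf$charges,
                       ifelse(lf$heavy, lf$radii, 0),
                       pose$translation, pose$rotation,
                       as.numeric(grid$values), grid$origin, grid$spacing,
                       as.integer(grid$dims),
                       rf$coords, rf$radii, rf$com, overlap)
  e * grid_scale(grid, temperature)
}

#' Metropolis acceptance decision
#'
#' Accepts an energy change `delta_e` (kBT) with probability
#' `min(1, exp(-delta_e))`, drawing from R's RNG.
#'
#' @param delta_e energy change, kBT.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_e) {
  delta_e <= 0 || runif(1) < exp(-delta_e)
}

#' One Metropolis step
#'
#' Proposes a Gaussian translation (sigma = `translation_step`) and a
#' small-angle rotation about a uniform random axis (angle sigma =
#' `rotation_step`), rejects proposals whose centre of mass leaves the
#' `d_max` ball, and accepts with probability `min(1, exp(-dE/kBT))`. Uses
#' R's RNG (set the seed outside). On rejection the previous pose is
#' returned.
#'
#' @param current a [pose()] with a valid `energy`.
#' @param config an [mc_config()].
#' @param grid `PotentialGrid`.
#' @param receptor,ligand `MolecularModel`s.
#' @return The new [pose()] (energy updated), with attribute `accepted`.
#' @export
metropolis_step <- function(current, config, grid, receptor, ligand) {
  e0 <- current$energy
  if (is.na(e0))
    e0 <- interaction_energy(ligand, current, grid, receptor,
                             config$temperature, config$overlap)
  t_new <- current$translation + rnorm(3, 0, config$translation_step)
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  angle <- rnorm(1, 0, config$rotation_step)
  dq <- c(cos(angle / 2), sin(angle / 2) * axis)
  q0 <- current$rotation
  q_new <- c(
    dq[1]*q0[1] - dq[2]*q0[2] - dq[3]*q0[3] - dq[4]*q0[4],
    dq[1]*q0[2] + dq[2]*q0[1] + dq[3]*q0[4] - dq[4]*q0[3],
    dq[1]*q0[3] - dq[2]*q0[4] + dq[3]*q0[1] + dq[4]*q0[2],
    dq[1]*q0[4] + dq[2]*q0[3] - dq[3]*q0[2] + dq[4]*q0[1])
  q_new <- q_new / sqrt(sum(q_new^2))
  com <- receptor_frame(receptor)$com
  accepted <- FALSE
  if (sqrt(sum((t_new - com)^2)) <= config$d_max) {
    cand <- pose(t_new, q_new)
    e1 <- interaction_energy(ligand, cand, grid, receptor,
                             config$temperature, config$overlap)
    if (metropolis_accept(e1 - e0)) {
      cand$energy <- e1
      return(structure(cand, accepted = TRUE))
    }
  }
  current$energy <- e0
  structure(current, accepted = FALSE)
}

#' Run the Monte Carlo interaction mapping
#'
#' Each run starts from a uniformly random pose within the `d_max` ball
#' (uniform random orientation; clash starts are resampled), equilibrates
#' for `burn_in` steps, and records every `record_every`-th pose thereafter.
#' The ensemble size is `n_runs * floor((n_steps - burn_in)/record_every)`
#' and is bit-reproducible for a given seed.
#'
#' @param receptor charged `MolecularModel`, held fixed.
#' @param ligand charged `MolecularModel`.
#' @param grid `PotentialGrid` of the receptor field.
#' @param config an [mc_config()].
#' @param redox optional [redox_state()] recorded with the ensemble.
#' @return Object of class `PoseEnsemble`: `poses` data.frame (tx ty tz
#'   qw qx qy qz energy, run), `config`, `acceptance` per run, `redox`.
#' @export
run_mapping <- function(receptor, ligand, grid, config = mc_config(),
                        redox = NULL) {
  lf <- ligand_frame(ligand)
  rf <- receptor_frame(receptor)
  scale <- grid_scale(grid, config$temperature)
  res <- cpp_run_mapping(rf$coords, rf$radii, rf$com,
                         lf$coords, lf$charges * scale,
                         ifelse(lf$heavy, lf$radii, 0),
                         as.numeric(grid$values), grid$origin, grid$spacing,
                         as.integer(grid$dims),
                         config$n_runs, config$n_steps, config$burn_in,
                         config$record_every,
                         config$translation_step, config$rotation_step,
                         config$d_max, config$overlap,
                         config$seed, config$max_start_retries)
  poses <- as.data.frame(res$poses)
  names(poses) <- c("tx", "ty", "tz", "qw", "qx", "qy", "qz", "energy")
  poses$run <- res$run
  if (nrow(poses) == 0L) stop("empty ensemble: check n_steps/burn_in/record_every")
  structure(list(poses = poses, config = config,
                 acceptance = res$acceptance,
                 receptor_com = rf$com, redox = redox),
            class = "PoseEnsemble")
}

#' @export
print.PoseEnsemble <- function(x, ...) {
  cat(sprintf(
    "PoseEnsemble: %d poses from %d runs, mean acceptance %.2f, E in [%.2f, %.2f] kBT\n",
    nrow(x$poses), x$config$n_runs, mean(x$acceptance),
    min(x$poses$energy), max(x$poses$energy)))
  invisible(x)
}

#' Occupancy map of ligand positions
#'
#' Histogram of the ligand centre of mass over the voxels of a grid
#' specification. Total counts equal the number of in-box poses (all poses
#' when the box covers the sampling ball).
#'
#' @param ensemble `PoseEnsemble`.
#' @param origin,spacing,dims voxel box; default derives a box covering all
#'   poses at `spacing`.
#' @return 3-D integer array of counts with attributes `origin`, `spacing`.
#' @export
occupancy_map <- function(ensemble, origin = NULL, spacing = 2, dims = NULL) {
  p <- as.matrix(ensemble$poses[, c("tx", "ty", "tz")])
  if (is.null(origin) || is.null(dims)) {
    lo <- apply(p, 2, min) - spacing
    hi <- apply(p, 2, max) + spacing
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    origin <- lo
  }
  idx <- floor(sweep(p, 2, as.numeric(origin)) / spacing) + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
            idx[, 2] >= 1 & idx[, 2] <= dims[2] &
            idx[, 3] >= 1 & idx[, 3] <= dims[3]
  idx <- idx[inside, , drop = FALSE]
  counts <- array(0L, dim = dims)
  if (nrow(idx)) {
    lin <- idx[, 1] + dims[1] * (idx[, 2] - 1 + dims[2] * (idx[, 3] - 1))
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- array(as.integer(tab), dim = dims)
  }
  attr(counts, "origin") <- as.numeric(origin)
  attr(counts, "spacing") <- spacing
  counts
}

#' Hemisphere pose-density enrichment
#'
#' Ratio of pose counts in the hemisphere around `direction` (seen from
#' `center`) to the opposite hemisphere; a Laplace-style +1 guards the
#' denominator when the far hemisphere is empty.
#'
#' @param ensemble `PoseEnsemble`.
#' @param direction patch axis (need not be normalized).
#' @param center receptor centre; defaults to the ensemble's receptor COM.
#' @return Enrichment ratio with attributes `n_toward`, `n_away`.
#' @export
hemisphere_enrichment <- function(ensemble, direction,
                                  center = ensemble$receptor_com) {
  d <- direction / sqrt(sum(direction^2))
  p <- as.matrix(ensemble$poses[, c("tx", "ty", "tz")])
  proj <- sweep(p, 2, center) %*% d
  n_to <- sum(proj > 0)
  n_away <- sum(proj < 0)
  structure(n_to / max(n_away, 1), n_toward = n_to, n_away = n_away)
}
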