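# Screened-Coulomb (linearized Debye-Hueckel) electrostatics on uniform
# grids. The native solver is a uniform-dielectric screened Coulomb sum,
#
#   phi(x) [kBT/e] = lB(T, eps_r) * sum_i q_i exp(-kappa r_i) / r_i
#
# with lB the Bjerrum length in Angstrom, so superposition holds exactly and
# every value is analytically checkable. Externally computed grids (full
# Poisson-Boltzmann, e.g. APBS) can be imported through read_dx() and used
# interchangeably downstream.

#' Bjerrum length
#'
#' Distance at which two unit charges interact with kBT:
#' `e^2 / (4 pi eps0 eps_r kB T)`, returned in Angstrom.
#'
#' @param temperature K.
#' @param dielectric relative dielectric constant.
#' @return Length in Angstrom.
#' @export
bjerrum_length <- function(temperature = 300, dielectric = 78.5) {
  with(.const, e^2 / (4 * pi * eps0 * dielectric * kB * temperature)) * 1e10
}

#' Ionic strength of a buffer
#'
#' `I = 1/2 sum c_i z_i^2` over all ionic species, after completing the
#' listed species with monovalent counterions (K+ or Cl-) to
#' electroneutrality.
#'
#' @param species data.frame with columns `conc` (mol/L) and `charge` (e),
#'   e.g. from [phosphate_buffer()]. An empty or NULL spec gives 0.
#' @return Ionic strength, mol/L.
#' @export
ionic_strength <- function(species) {
  if (is.null(species) || nrow(species) == 0L) return(0)
  if (any(species$conc < 0)) stop("negative species concentration")
  if (any(!is.finite(species$conc)) || any(!is.finite(species$charge)))
    stop("non-finite buffer species")
  net <- sum(species$conc * species$charge)
  if (abs(net) > 1e-12)   # complete with K+ or Cl-
    species <- rbind(species,
                     data.frame(conc = abs(net), charge = -sign(net)))
  sum(species$conc * species$charge^2) / 2
}

#' Phosphate buffer speciation
#'
#' Henderson-Hasselbalch split of total phosphate between H2PO4- and
#' HPO4^2- at the given pH (first and third pKa neglected near pH 7);
#' potassium counterions are added by [ionic_strength()].
#'
#' @param conc total phosphate concentration, mol/L.
#' @param ph pH.
#' @param pka2 second phosphate pKa.
#' @return data.frame of species with `conc` and `charge` columns.
#' @export
phosphate_buffer <- function(conc, ph = 7.0, pka2 = 7.20) {
  if (conc < 0) stop("negative concentration")
  frac_dibasic <- 1 / (1 + 10^(pka2 - ph))
  data.frame(conc = c(conc * (1 - frac_dibasic), conc * frac_dibasic),
             charge = c(-1, -2))
}

#' Inverse Debye screening length
#'
#' `kappa = sqrt(2 N_A e^2 (1000 I) / (eps0 eps_r kB T))`, in 1/Angstrom.
#'
#' @param I ionic strength, mol/L.
#' @param temperature K.
#' @param dielectric relative dielectric constant.
#' @return kappa in 1/Angstrom (0 when I = 0).
#' @export
debye_kappa <- function(I, temperature = 300, dielectric = 78.5) {
  if (any(I < 0)) stop("negative ionic strength")
  if (temperature <= 0) stop("temperature must be positive")
  k2 <- with(.const,
             2 * N_A * e^2 * (1000 * I) / (eps0 * dielectric * kB * temperature))
  sqrt(k2) * 1e-10
}

#' Direct screened-Coulomb potential at points
#'
#' Evaluates the screened-Coulomb sum directly (no grid); this is the
#' analytic reference the grid pipeline is tested against.
#'
#' @param model charged `MolecularModel`.
#' @param points n x 3 matrix, Angstrom.
#' @param kappa inverse screening length, 1/Angstrom; overrides
#'   `ionic_strength` when given.
#' @param ionic_strength mol/L (used to derive kappa when `kappa` is NULL).
#' @param temperature K (sets the kBT/e unit).
#' @param dielectric relative dielectric constant.
#' @param r_min distances are clamped below at this radius, Angstrom.
#' @return Numeric vector of potentials, kBT/e; attribute `n_clamped` counts
#'   points that hit the distance clamp.
#' @export
potential_at_points <- function(model, points, kappa = NULL,
                                ionic_strength = 0, temperature = 300,
                                dielectric = 78.5, r_min = 1e-6) {
  if (is.null(kappa))
    kappa <- debye_kappa(ionic_strength, temperature, dielectric)
  points <- matrix(as.numeric(points), ncol = 3)
  res <- cpp_potential_points(coords(model), model$atoms$charge, points,
                              kappa, bjerrum_length(temperature, dielectric),
                              r_min)
  structure(res$phi, n_clamped = res$n_clamped)
}

#' Screened-Coulomb potential on a uniform grid
#'
#' @param model charged `MolecularModel`.
#' @param spacing grid spacing, Angstrom.
#' @param padding box padding beyond the model bounding box, Angstrom
#'   (ignored when `origin` and `dims` are given).
#' @param origin,dims explicit box (origin of first node, node counts).
#' @param ionic_strength mol/L.
#' @param temperature K.
#' @param dielectric relative dielectric constant.
#' @param r_min clamp radius for near-singular nodes, Angstrom; defaults to
#'   half the spacing. Clamped nodes are counted in attribute `n_clamped`.
#' @return A [potential_grid()].
#' @export
compute_potential_grid <- function(model, spacing = 1.0, padding = 20,
                                   origin = NULL, dims = NULL,
                                   ionic_strength = 0, temperature = 300,
                                   dielectric = 78.5, r_min = spacing / 2) {
  xyz <- coords(model)
  if (is.null(origin) || is.null(dims)) {
    lo <- apply(xyz, 2, min) - padding
    hi <- apply(xyz, 2, max) + padding
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    origin <- lo
  }
  if (any(dims < 2L)) stop("grid needs at least 2 nodes per axis")
  kappa <- debye_kappa(ionic_strength, temperature, dielectric)
  res <- cpp_potential_grid(xyz, model$atoms$charge, as.numeric(origin),
                            spacing, as.integer(dims), kappa,
                            bjerrum_length(temperature, dielectric), r_min)
  g <- potential_grid(origin, spacing,
                      array(res$phi, dim = dims),
                      temperature = temperature,
                      ionic_strength = ionic_strength,
                      dielectric = dielectric)
  attr(g, "n_clamped") <- res$n_clamped
  g
}

#' Trilinear interpolation of a potential grid
#'
#' Exact at grid nodes and for fields linear in the coordinates.
#'
#' @param grid `PotentialGrid`.
#' @param points n x 3 matrix, Angstrom.
#' @param outside `"error"` to reject out-of-box points, `"zero"` to treat
#'   them as far field.
#' @return Numeric vector, kBT/e.
#' @export
interpolate_potential <- function(grid, points, outside = c("error", "zero")) {
  outside <- match.arg(outside)
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_trilinear(as.numeric(grid$values), grid$origin, grid$spacing,
                as.integer(grid$dims), points,
                if (outside == "error") 0L else 1L)
}

#' Isopotential mask
#'
#' Voxels at or beyond a potential level: `phi >= level` for positive
#' levels, `phi <= level` for negative ones (the +-1 kBT/e surfaces used to
#' compare interface electrostatics).
#'
#' @param grid `PotentialGrid`.
#' @param level kBT/e, nonzero.
#' @return Logical array with the grid's dimensions.
#' @export
isopotential_mask <- function(grid, level) {
  if (level == 0) stop("level must be nonzero")
  if (level > 0) grid$values >= level else grid$values <= level
}

#' Trilinear grid-resolution error bound
#'
#' Conservative per-point bound on |interpolated - direct| for the screened
#' Coulomb field: within a cell, the multilinear interpolation error is at
#' most `(h^2/8) * sum_k sup |d2 phi/dx_k^2|`, and each second derivative of
#' `q e^(-kr)/r` is bounded by `|q| (2/r^3 + 2k/r^2 + k^2/r) e^(-kr)` at the
#' cell's nearest approach to the atom (`dist - sqrt(3) h`).
#'
#' @inheritParams potential_at_points
#' @param spacing grid spacing h, Angstrom.
#' @return Numeric vector of error bounds, kBT/e.
#' @export
grid_error_bound <- function(model, points, spacing, kappa = NULL,
                             ionic_strength = 0, temperature = 300,
                             dielectric = 78.5, r_min = spacing / 2) {
  if (is.null(kappa))
    kappa <- debye_kappa(ionic_strength, temperature, dielectric)
  lB <- bjerrum_length(temperature, dielectric)
  xyz <- coords(model)
  q <- abs(model$atoms$charge)
  points <- matrix(as.numeric(points), ncol = 3)
  h <- spacing
  vapply(seq_len(nrow(points)), function(p) {
    r <- sqrt(colSums((t(xyz) - points[p, ])^2))
    r <- pmax(r - sqrt(3) * h, r_min)
    d2 <- (2 / r^3 + 2 * kappa / r^2 + kappa^2 / r) * exp(-kappa * r)
    lB * (3 * h^2 / 8) * sum(q * d2)
  }, numeric(1))
}
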