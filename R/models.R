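#' Molecular model container
#'
#' A `MolecularModel` is a light container around a per-atom table, the unit
#' conventions being Angstrom for coordinates and radii and elementary charge
#' for partial charges. Cofactor atoms (c-type hemes here) carry a non-empty
#' `cofactor_id` such as `"heme3"`; all other atoms have `NA`.
#'
#' @param atoms data.frame with columns `serial` (integer), `name`,
#'   `resname`, `resid` (integer), `chain`, `x`, `y`, `z`, `charge`,
#'   `radius`, `cofactor_id` (character, `NA` for non-cofactor atoms).
#' @param ph pH at which charges are (to be) assigned.
#' @return An object of class `MolecularModel` with elements `atoms`,
#'   `hemes` (unique cofactor ids) and `ph`.
#' @export
molecular_model <- function(atoms, ph = 7.0) {
  required <- c("serial", "name", "resname", "resid", "chain",
                "x", "y", "z", "charge", "radius", "cofactor_id")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atoms table lacks columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$radius < 0)) stop("negative atom radius")
  cof <- atoms$cofactor_id
  if (any(!is.na(cof) & !nzchar(cof)))
    stop("cofactor atoms must carry a non-empty cofactor_id")
  structure(
    list(atoms = atoms,
         hemes = unique(cof[!is.na(cof)]),
         ph = ph),
    class = "MolecularModel")
}

#' @export
print.MolecularModel <- function(x, ...) {
  cat(sprintf("MolecularModel: %d atoms, %d residues, net charge %+.3f e\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              net_charge(x)))
  if (length(x$hemes))
    cat("  cofactors:", paste(x$hemes, collapse = ", "), "\n")
  invisible(x)
}

#' Net charge of a model
#'
#' @param model `MolecularModel`.
#' @return Sum of atomic partial charges, in e.
#' @export
net_charge <- function(model) sum(model$atoms$charge)

#' Atom coordinates as a matrix
#'
#' @param model `MolecularModel`.
#' @param heavy_only drop hydrogens (atom names starting with H)?
#' @return Numeric matrix with columns x, y, z.
#' @export
coords <- function(model, heavy_only = FALSE) {
  at <- model$atoms
  if (heavy_only) at <- at[!is_hydrogen(at$name), , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

is_hydrogen <- function(name) {
  # PDB convention: element H atoms are named H*, 1H*, 2H*, 3H*
  grepl("^[0-9]?H", trimws(name))
}

#' Geometric centre of a model
#'
#' Unweighted centroid of the atom positions, used as the rigid-body
#' centre of mass throughout (coarse bead models carry no masses).
#'
#' @param model `MolecularModel`.
#' @return Length-3 numeric vector, Angstrom.
#' @export
centroid <- function(model) colMeans(coords(model))

#' Potential grid container
#'
#' A uniform 3-D scalar field of electrostatic potential in kBT/e units.
#'
#' @param origin position of the first grid node, Angstrom.
#' @param spacing uniform node spacing, Angstrom.
#' @param values 3-D numeric array (dims `nx, ny, nz`).
#' @param temperature temperature defining the kBT/e unit, K.
#' @param ionic_strength ionic strength used for screening, mol/L.
#' @param dielectric relative dielectric constant.
#' @return Object of class `PotentialGrid`.
#' @export
potential_grid <- function(origin, spacing, values, temperature = 300,
                           ionic_strength = 0, dielectric = 78.5) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (any(dim(values) < 2L)) stop("grid needs at least 2 nodes per axis")
  if (length(origin) != 3L) stop("origin must have length 3")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number")
  structure(
    list(origin = as.numeric(origin), spacing = as.numeric(spacing),
         dims = dim(values), values = values,
         temperature = temperature, ionic_strength = ionic_strength,
         dielectric = dielectric),
    class = "PotentialGrid")
}

#' @export
print.PotentialGrid <- function(x, ...) {
  cat(sprintf(
    "PotentialGrid: %d x %d x %d nodes, spacing %.2f A, range [%.3g, %.3g] kBT/e\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing,
    min(x$values), max(x$values)))
  invisible(x)
}

#' Rigid-body pose
#'
#' @param translation ligand centre-of-mass position, Angstrom.
#' @param rotation unit quaternion `c(w, x, y, z)`.
#' @param energy interaction energy in kBT (optional).
#' @return Object of class `Pose`.
#' @export
pose <- function(translation, rotation = c(1, 0, 0, 0), energy = NA_real_) {
  if (length(translation) != 3L) stop("translation must have length 3")
  if (length(rotation) != 4L) stop("rotation must be a quaternion of length 4")
  nrm <- sqrt(sum(rotation^2))
  if (abs(nrm - 1) > 1e-9) stop("rotation quaternion must be unit norm")
  # keep already-unit quaternions bit-identical (exact energy bookkeeping)
  if (abs(nrm - 1) > 1e-12) rotation <- rotation / nrm
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 energy = energy),
            class = "Pose")
}

#' Rotate points by a unit quaternion
#'
#' @param q unit quaternion `c(w, x, y, z)`.
#' @param pts n x 3 matrix.
#' @return n x 3 matrix of rotated points.
#' @export
quat_rotate <- function(q, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_quat_rotate(as.numeric(q), pts)
}
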