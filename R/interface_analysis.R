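# From pose ensemble to interaction-surface report: pose selection, contact
# residues with charge classification, and cofactor proximity.

#' Select the preferred poses of an ensemble
#'
#' `lowest_energy`: the bottom `fraction` of poses by interaction energy.
#' `densest_voxels`: poses lying in the most-occupied voxels, adding voxels
#' in occupancy order until they hold at least `fraction` of all poses.
#'
#' @param ensemble `PoseEnsemble`.
#' @param mode selection rule.
#' @param fraction in (0, 1].
#' @param spacing voxel size for `densest_voxels`, Angstrom.
#' @return A `PoseEnsemble` containing the selected poses.
#' @export
select_top_poses <- function(ensemble, mode = c("lowest_energy", "densest_voxels"),
                             fraction = 0.1, spacing = 2) {
  mode <- match.arg(mode)
  p <- ensemble$poses
  if (nrow(p) == 0L) stop("empty ensemble")
  stopifnot(fraction > 0, fraction <= 1)
  if (mode == "lowest_energy") {
    k <- ceiling(fraction * nrow(p))
    keep <- order(p$energy)[seq_len(k)]
  } else {
    occ <- occupancy_map(ensemble, spacing = spacing)
    dims <- dim(occ)
    origin <- attr(occ, "origin")
    idx <- floor(sweep(as.matrix(p[, c("tx", "ty", "tz")]), 2, origin) / spacing) + 1
    lin <- idx[, 1] + dims[1] * (idx[, 2] - 1 + dims[2] * (idx[, 3] - 1))
    counts <- as.vector(occ)
    ord <- order(counts, decreasing = TRUE)
    cum <- cumsum(counts[ord])
    n_vox <- which(cum >= fraction * nrow(p))[1]
    keep_vox <- ord[seq_len(n_vox)]
    keep <- which(lin %in% keep_vox)
  }
  out <- ensemble
  out$poses <- p[keep, , drop = FALSE]
  out
}

#' Charge class of a residue
#'
#' The four-way partition used for interface colouring: Asp/Glu negative;
#' Lys/Arg/His positive; Ser/Thr/Asn/Gln/Tyr neutral; the remaining standard
#' residues hydrophobic. Unknown codes classify as neutral with a warning.
#'
#' @param resname 3-letter residue code(s), case-insensitive.
#' @return Character vector in
#'   `c("negative", "positive", "neutral", "hydrophobic")`.
#' @export
classify_residue <- function(resname) {
  map <- c(ASP = "negative", GLU = "negative",
           LYS = "positive", ARG = "positive", HIS = "positive",
           SER = "neutral", THR = "neutral", ASN = "neutral",
           GLN = "neutral", TYR = "neutral",
           ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
           ILE = "hydrophobic", PHE = "hydrophobic", MET = "hydrophobic",
           TRP = "hydrophobic", PRO = "hydrophobic", GLY = "hydrophobic",
           CYS = "hydrophobic")
  rn <- toupper(resname)
  out <- unname(map[rn])
  if (anyNA(out)) {
    warning("unknown residue code(s) classed neutral: ",
            paste(unique(rn[is.na(out)]), collapse = ", "))
    out[is.na(out)] <- "neutral"
  }
  out
}

#' Contact residues of a pose ensemble
#'
#' A receptor residue is in contact in a pose when any of its heavy atoms
#' lies within `cutoff` of any transformed ligand heavy atom; its contact
#' frequency is the fraction of analysed poses with a contact. Cofactor
#' atoms are reported separately with their minimal approach distance.
#'
#' @param receptor,ligand `MolecularModel`s.
#' @param poses a `PoseEnsemble` (typically from [select_top_poses()]).
#' @param cutoff contact distance, Angstrom.
#' @return Object of class `InterfaceReport`: `entries` (residue table,
#'   frequency-descending), `cofactor_hits`, `n_poses`.
#' @export
contact_residues <- function(receptor, ligand, poses, cutoff = 5) {
  stopifnot(cutoff > 0)
  pm <- as.matrix(poses$poses[, c("tx", "ty", "tz", "qw", "qx", "qy", "qz")])
  at <- receptor$atoms
  heavy <- !is_hydrogen(at$name)
  at <- at[heavy, , drop = FALSE]
  is_cof <- !is.na(at$cofactor_id)
  gkey <- ifelse(is_cof, paste0("cof:", at$cofactor_id),
                 paste0("res:", at$chain, ":", at$resid))
  groups <- unique(gkey)
  gidx <- match(gkey, groups) - 1L
  lf <- ligand_frame(ligand)
  lig_xyz <- lf$coords[lf$heavy, , drop = FALSE]
  st <- cpp_contact_stats(as.matrix(at[, c("x", "y", "z")]), gidx,
                          length(groups), lig_xyz, pm, cutoff)
  n_poses <- nrow(pm)
  freq <- st$count / n_poses
  first <- match(groups, gkey)
  res_sel <- !is_cof[first]
  entries <- data.frame(
    resid = at$resid[first][res_sel],
    chain = at$chain[first][res_sel],
    resname = at$resname[first][res_sel],
    contact_frequency = freq[res_sel],
    stringsAsFactors = FALSE)
  entries$charge_class <- if (nrow(entries))
    classify_residue(entries$resname) else character()
  entries <- entries[entries$contact_frequency > 0, , drop = FALSE]
  entries <- entries[order(-entries$contact_frequency, entries$resid), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  cof_sel <- is_cof[first]
  cofactor_hits <- data.frame(
    cofactor_id = at$cofactor_id[first][cof_sel],
    min_dist = st$min_dist[cof_sel],
    contact_frequency = freq[cof_sel],
    stringsAsFactors = FALSE)
  rownames(cofactor_hits) <- NULL
  structure(list(entries = entries, cofactor_hits = cofactor_hits,
                 n_poses = n_poses, cutoff = cutoff),
            class = "InterfaceReport")
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf("InterfaceReport over %d poses (cutoff %.1f A): %d contact residues\n",
              x$n_poses, x$cutoff, nrow(x$entries)))
  print(head(x$entries, 10))
  if (nrow(x$cofactor_hits)) {
    cat("cofactors:\n")
    print(x$cofactor_hits)
  }
  invisible(x)
}

#' Is a cofactor part of the interaction surface?
#'
#' @param report an `InterfaceReport` from [contact_residues()].
#' @param cofactor_id e.g. `"heme3"`.
#' @param frequency_threshold minimum contact frequency.
#' @return Logical, with attributes `min_dist` and `frequency`.
#' @export
cofactor_in_interface <- function(report, cofactor_id,
                                  frequency_threshold = 0.25) {
  i <- match(cofactor_id, report$cofactor_hits$cofactor_id)
  if (is.na(i)) stop("unknown cofactor: ", cofactor_id)
  f <- report$cofactor_hits$contact_frequency[i]
  structure(f >= frequency_threshold,
            min_dist = report$cofactor_hits$min_dist[i],
            frequency = f)
}
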