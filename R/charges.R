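# Formal-charge assignment at pH 7 and the heme redox-state charge model.
#
# Instead of per-site pKa prediction, side chains carry their pH-7 formal
# charges: Asp/Glu -1, Lys/Arg +1, His 0, free termini +1/-1. The charge is
# placed on the canonical charged heavy atoms (split over symmetric pairs);
# if those atoms are absent (coarse bead models) the full formal charge goes
# on the first atom of the residue, so the table is united-atom tolerant.
#
# c-type hemes: the propionate carboxylates carry -0.5 per oxygen; the
# redox-dependent elementary charge sits entirely on the iron, +1 in the
# ferric and 0 in the ferrous state. This places the full 1 e redox
# difference on Fe -- a documented convention, configurable via fe_charge.

.sidechain_charges <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1),
  ARG = c(NH1 = 0.5, NH2 = 0.5)
)

.known_resnames <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                     "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                     "THR", "TRP", "TYR", "VAL", "HOH", "WAT")

# element radii (A), keyed on the leading element letter of the atom name
.element_radii <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
                    F = 1.3)  # F covers FE
.default_radius <- 1.5

#' Heme redox-state specification
#'
#' @param ... named states, e.g. `heme3 = "ferrous"`, or a single named
#'   character vector. States must be `"ferric"` or `"ferrous"`.
#' @return Named character vector of class `redox_state`.
#' @export
redox_state <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]])))
    args <- as.list(args[[1]])
  states <- unlist(args)
  if (!length(states)) return(structure(character(), class = "redox_state"))
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop("every redox state must be named by its heme id")
  bad <- !states %in% c("ferric", "ferrous")
  if (any(bad)) stop("unknown redox state: ", paste(states[bad], collapse = ", "))
  structure(states, class = "redox_state")
}

#' Assign formal charges and radii
#'
#' Resets all charges, then applies pH-7 formal charges to side chains and
#' free termini and the redox-state-dependent heme charges. The operation is
#' idempotent. Radii are set from a per-element table.
#'
#' @param model `MolecularModel`.
#' @param ph pH; only 7.0 is supported by the formal-charge table.
#' @param redox a [redox_state()] (or named character vector) giving the
#'   state of each heme; hemes not listed default to `ferric`. Naming a heme
#'   absent from the model is an error.
#' @param termini apply +1/-1 charges to free chain termini?
#' @param fe_charge charges placed on the heme iron,
#'   `c(ferric = 1, ferrous = 0)` by default; the difference must be 1 e.
#' @return The model with `charge` and `radius` columns populated.
#' @export
assign_charges <- function(model, ph = 7.0, redox = redox_state(),
                           termini = TRUE, fe_charge = c(ferric = 1, ferrous = 0)) {
  if (abs(ph - 7.0) > 1e-9)
    stop("only pH 7.0 formal charges are tabulated; import a PQR for other pH")
  if (!inherits(redox, "redox_state")) redox <- redox_state(redox)
  unknown_hemes <- setdiff(names(redox), model$hemes)
  if (length(unknown_hemes))
    stop("redox state names hemes absent from the model: ",
         paste(unknown_hemes, collapse = ", "))
  at <- model$atoms
  at$charge <- 0
  key <- substr(at$name, 1, 1)
  at$radius <- unname(ifelse(key %in% names(.element_radii),
                             .element_radii[key], .default_radius))

  is_cof <- !is.na(at$cofactor_id)
  unknown <- !is_cof & !at$resname %in% .known_resnames
  if (any(unknown))
    warning("unknown residue(s) assigned zero charge: ",
            paste(unique(at$resname[unknown]), collapse = ", "))

  # side chains
  res_key <- paste(at$chain, at$resid)
  for (rn in names(.sidechain_charges)) {
    tab <- .sidechain_charges[[rn]]
    in_res <- !is_cof & at$resname == rn
    if (!any(in_res)) next
    for (rk in unique(res_key[in_res])) {
      idx <- which(in_res & res_key == rk)
      hit <- idx[at$name[idx] %in% names(tab)]
      if (length(hit)) {
        at$charge[hit] <- at$charge[hit] + unname(tab[at$name[hit]])
      } else {
        at$charge[idx[1]] <- at$charge[idx[1]] + sum(tab)  # coarse fallback
      }
    }
  }

  # free termini, standard amino acid chains only
  if (termini) {
    aa <- !is_cof & at$resname %in% setdiff(.known_resnames, c("HOH", "WAT"))
    for (ch in unique(at$chain[aa])) {
      idx <- which(aa & at$chain == ch)
      first_res <- idx[at$resid[idx] == min(at$resid[idx])]
      tgt <- first_res[at$name[first_res] == "N"]
      tgt <- if (length(tgt)) tgt[1] else first_res[1]
      at$charge[tgt] <- at$charge[tgt] + 1
      last_res <- idx[at$resid[idx] == max(at$resid[idx])]
      tgt <- last_res[at$name[last_res] == "OXT"]
      if (!length(tgt)) tgt <- last_res[at$name[last_res] == "O"]
      tgt <- if (length(tgt)) tgt[1] else last_res[length(last_res)]
      at$charge[tgt] <- at$charge[tgt] - 1
    }
  }

  # hemes: propionate oxygens, then the redox charge on Fe
  if (diff(rev(fe_charge[c("ferric", "ferrous")])) != 1)
    stop("fe_charge must differ by exactly 1 e between ferric and ferrous")
  prop_o <- c("O1A", "O2A", "O1D", "O2D")
  for (h in model$hemes) {
    idx <- which(!is.na(at$cofactor_id) & at$cofactor_id == h)
    po <- idx[at$name[idx] %in% prop_o]
    at$charge[po] <- -0.5
    state <- if (h %in% names(redox)) redox[[h]] else "ferric"
    fe <- idx[toupper(at$name[idx]) == "FE"]
    fe <- if (length(fe)) fe[1] else idx[1]
    at$charge[fe] <- at$charge[fe] + unname(fe_charge[state])
  }

  model$atoms <- at
  model$ph <- ph
  model
}

#' Apply a heme redox state to an already-charged model
#'
#' Adjusts only the heme iron charges of `model` (leaving all other partial
#' charges untouched), so generator-built models with bespoke charges can be
#' switched between redox states. Ferric iron carries `fe_ferric`, ferrous
#' one elementary charge less.
#'
#' @inheritParams assign_charges
#' @param fe_ferric iron charge in the ferric state, e.
#' @return The model with updated heme iron charges.
#' @export
apply_redox_state <- function(model, redox = redox_state(), fe_ferric = 1) {
  if (!inherits(redox, "redox_state")) redox <- redox_state(redox)
  unknown <- setdiff(names(redox), model$hemes)
  if (length(unknown))
    stop("redox state names hemes absent from the model: ",
         paste(unknown, collapse = ", "))
  at <- model$atoms
  for (h in model$hemes) {
    idx <- which(!is.na(at$cofactor_id) & at$cofactor_id == h)
    fe <- idx[toupper(at$name[idx]) == "FE"]
    fe <- if (length(fe)) fe[1] else idx[1]
    state <- if (h %in% names(redox)) redox[[h]] else "ferric"
    at$charge[fe] <- if (state == "ferric") fe_ferric else fe_ferric - 1
  }
  model$atoms <- at
  model
}
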