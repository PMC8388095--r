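# Structure and grid file I/O: PDB (fixed columns), PQR (whitespace), and
# OpenDX scalar grids as written by APBS. Cofactor atoms are recognised on
# read by heme residue names and given ids "heme<resid>" (chain-qualified
# when the same number occurs on several chains).

.heme_resnames <- c("HEC", "HEM")

#' Read a PDB file
#'
#' Parses ATOM/HETATM records with the standard fixed columns. Charges and
#' radii are left at zero until [assign_charges()] or PQR input provides
#' them. HETATM records with heme residue names (HEC, HEM) are labelled as
#' cofactors.
#'
#' @param path file path.
#' @return A [molecular_model()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path)
  recs <- lines[sel]
  lineno <- which(sel)
  f <- function(from, to) substr(recs, from, to)
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("malformed %s field at line %d of %s",
                   what, lineno[bad[1]], path))
    v
  }
  atoms <- data.frame(
    serial = as.integer(num(f(7, 11), "serial")),
    name = trimws(f(13, 16)),
    resname = trimws(f(18, 20)),
    resid = as.integer(num(f(23, 26), "residue id")),
    chain = trimws(f(22, 22)),
    x = num(f(31, 38), "x"), y = num(f(39, 46), "y"), z = num(f(47, 54), "z"),
    charge = 0, radius = 0,
    cofactor_id = NA_character_,
    stringsAsFactors = FALSE)
  atoms$chain[!nzchar(atoms$chain)] <- "A"
  atoms$cofactor_id <- heme_ids(atoms)
  molecular_model(atoms)
}

# "heme<resid>", chain-qualified when one resid spans several chains
heme_ids <- function(atoms) {
  id <- rep(NA_character_, nrow(atoms))
  h <- atoms$resname %in% .heme_resnames
  if (!any(h)) return(id)
  key <- paste(atoms$chain[h], atoms$resid[h])
  multi <- vapply(split(atoms$chain[h], atoms$resid[h]),
                  function(ch) length(unique(ch)) > 1L, logical(1))
  needs_chain <- multi[as.character(atoms$resid[h])]
  id[h] <- ifelse(needs_chain,
                  sprintf("heme%d_%s", atoms$resid[h], atoms$chain[h]),
                  sprintf("heme%d", atoms$resid[h]))
  id
}

#' Write a PDB file
#'
#' @param model `MolecularModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  at <- model$atoms
  rec <- ifelse(at$resname %in% .heme_resnames | !is.na(at$cofactor_id),
                "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                  substr(at$name, 1, 4))
  lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f",
                   rec, at$serial %% 100000L, name4, at$resname,
                   substr(at$chain, 1, 1), at$resid %% 10000L,
                   at$x, at$y, at$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a PQR file
#'
#' Whitespace-separated PQR as produced by PDB2PQR: ATOM/HETATM records with
#' per-atom partial charge and radius as the last two fields. Both the
#' with-chain and without-chain dialects are accepted.
#'
#' @param path file path.
#' @return A [molecular_model()] with charges and radii populated.
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM|HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path)
  recs <- strsplit(trimws(lines[sel]), "[[:space:]]+")
  lineno <- which(sel)
  parse_one <- function(tok, ln) {
    if (length(tok) < 10L)
      stop(sprintf("line %d: expected >= 10 fields (charge/radius columns missing?)",
                   ln))
    # token 5 is the chain id in the with-chain dialect, the residue id otherwise
    has_chain <- is.na(suppressWarnings(as.numeric(tok[5])))
    if (!has_chain && length(tok) >= 11L &&
        !is.na(suppressWarnings(as.numeric(tok[11]))))
      has_chain <- FALSE
    if (has_chain && length(tok) < 11L)
      stop(sprintf("line %d: chain present but charge/radius columns missing", ln))
    i <- if (has_chain) 0L else -1L
    vals <- suppressWarnings(as.numeric(tok[c(2, 6 + i, 7 + i, 8 + i, 9 + i, 10 + i, 11 + i)]))
    if (any(!is.finite(vals)))
      stop(sprintf("line %d: malformed numeric field", ln))
    list(serial = vals[1], name = tok[3], resname = tok[4],
         chain = if (has_chain) tok[5] else "A",
         resid = vals[2], x = vals[3], y = vals[4], z = vals[5],
         charge = vals[6], radius = vals[7])
  }
  parsed <- mapply(parse_one, recs, lineno, SIMPLIFY = FALSE)
  atoms <- data.frame(
    serial = as.integer(vapply(parsed, `[[`, 0, "serial")),
    name = vapply(parsed, `[[`, "", "name"),
    resname = vapply(parsed, `[[`, "", "resname"),
    resid = as.integer(vapply(parsed, `[[`, 0, "resid")),
    chain = vapply(parsed, `[[`, "", "chain"),
    x = vapply(parsed, `[[`, 0, "x"),
    y = vapply(parsed, `[[`, 0, "y"),
    z = vapply(parsed, `[[`, 0, "z"),
    charge = vapply(parsed, `[[`, 0, "charge"),
    radius = vapply(parsed, `[[`, 0, "radius"),
    cofactor_id = NA_character_,
    stringsAsFactors = FALSE)
  atoms$cofactor_id <- heme_ids(atoms)
  molecular_model(atoms)
}

#' Write a PQR file
#'
#' Positions are written to 3 decimals, charges to 4; the write-read round
#' trip is lossless at that precision.
#'
#' @param model `MolecularModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(model, path) {
  at <- model$atoms
  rec <- ifelse(!is.na(at$cofactor_id), "HETATM", "ATOM")
  lines <- sprintf("%-6s %4d %-4s %-4s %1s %4d %11.3f %11.3f %11.3f %8.4f %7.4f",
                   rec, at$serial, at$name, at$resname,
                   substr(at$chain, 1, 1), at$resid,
                   at$x, at$y, at$z, at$charge, at$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Accepts the APBS-style OpenDX dialect: `gridpositions` counts, origin,
#' three axis-aligned `delta` rows (uniform spacing required), and a rank-0
#' data array with the z index varying fastest.
#'
#' @param path file path.
#' @param temperature,ionic_strength,dielectric metadata attached to the
#'   returned grid (a DX file does not carry them).
#' @return A [potential_grid()].
#' @export
read_dx <- function(path, temperature = 300, ionic_strength = 0,
                    dielectric = 78.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (!length(gp)) stop("not an OpenDX grid: no gridpositions object")
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp[1])),
                              "[[:space:]]+")[[1]])
  if (length(dims) != 3L || any(is.na(dims))) stop("malformed counts line")
  oline <- grep("^origin", lines, value = TRUE)
  if (!length(oline)) stop("missing origin line")
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", oline[1])),
                                "[[:space:]]+")[[1]])
  dlines <- grep("^delta", lines, value = TRUE)
  if (length(dlines) != 3L) stop("expected 3 delta lines")
  deltas <- t(vapply(dlines, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "[[:space:]]+")[[1]]),
    numeric(3)))
  diag_d <- diag(deltas)
  if (any(abs(deltas - diag(diag_d, 3)) > 1e-9) ||
      max(abs(diff(diag_d))) > 1e-9)
    stop("non-uniform or non-axis-aligned grid spacing")
  spacing <- diag_d[1]
  dstart <- grep("data follows", lines)
  if (!length(dstart)) stop("truncated DX file: no data section")
  data_lines <- lines[(dstart[1] + 1):length(lines)]
  data_lines <- data_lines[!grepl("^(object|attribute|component|end)", data_lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(data_lines),
                                                      "[[:space:]]+"))))
  vals <- vals[!is.na(vals)]
  n <- prod(dims)
  if (length(vals) < n) stop("truncated DX file: ", length(vals),
                             " values, expected ", n)
  # DX order: z fastest -> array index [iz,iy,ix], transpose to [ix,iy,iz]
  arr <- aperm(array(vals[seq_len(n)], dim = rev(dims)), c(3, 2, 1))
  potential_grid(origin, spacing, arr, temperature = temperature,
                 ionic_strength = ionic_strength, dielectric = dielectric)
}

#' Write an OpenDX scalar grid
#'
#' @param grid `PotentialGrid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid (kBT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z fastest
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.10e %.10e %.10e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.10e", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
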