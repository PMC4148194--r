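#' Charged molecular structure
#'
#' Atoms with coordinates (Angstrom), radii (Angstrom) and partial charges
#' (elementary charges), grouped into residues.  The residue id is
#' `"chain:number"` (with an insertion code appended when present) and is the
#' key used by nullification and the residue scans.
#'
#' @param atoms a data.frame with columns `serial`, `name`, `resname`,
#'   `chain`, `resnum`, `icode`, `x`, `y`, `z`, `radius`, `charge`.  Missing
#'   `serial`/`icode` are filled in.
#' @return object of class `"ep_structure"`.
#' @export
charged_structure <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$chain)) atoms$chain <- "A"
  need <- c("serial", "name", "resname", "chain", "resnum", "icode",
            "x", "y", "z", "radius", "charge")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms missing columns: ", paste(miss, collapse = ", "))
  atoms <- atoms[, need]
  atoms$icode[is.na(atoms$icode)] <- ""
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  if (any(!is.finite(atoms$radius)) || any(atoms$radius < 0))
    stop("atom radii must be finite and >= 0")
  if (any(!is.finite(atoms$charge))) stop("atom charges must be finite")
  structure(list(atoms = atoms), class = "ep_structure")
}

#' @export
print.ep_structure <- function(x, ...) {
  cat(sprintf("charged structure: %d atoms, %d residues, net charge %+.3f e\n",
              nrow(x$atoms), length(residue_ids(x)), net_charge(x)))
  invisible(x)
}

make_rid <- function(chain, resnum, icode = "") {
  icode[is.na(icode)] <- ""
  paste0(chain, ":", resnum, ifelse(nzchar(icode), paste0(":", icode), ""))
}

#' Residue ids of a structure
#'
#' Residue ids `"chain:number[:icode]"` in deterministic (chain, number,
#' insertion code) order.
#'
#' @param s a [charged_structure()].
#' @export
residue_ids <- function(s) {
  a <- s$atoms
  o <- order(a$chain, a$resnum, a$icode)
  unique(make_rid(a$chain[o], a$resnum[o], a$icode[o]))
}

atom_rids <- function(s) make_rid(s$atoms$chain, s$atoms$resnum, s$atoms$icode)

#' Atom coordinate matrix
#' @param s a [charged_structure()].
#' @export
atom_coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Net charge of a structure
#' @param s a [charged_structure()].
#' @export
net_charge <- function(s) sum(s$atoms$charge)

#' Nullify the charges of one residue
#'
#' Sets every partial charge of the residue to zero while leaving positions,
#' radii and atom count untouched.  The residue still displaces solvent, so
#' under the finite-difference Poisson-Boltzmann model its low-dielectric
#' footprint (and hence any electrostatic focusing it causes) is preserved;
#' only its source charges vanish.
#'
#' @param s a [charged_structure()].
#' @param rid a residue id as returned by [residue_ids()].
#' @export
nullify_residue <- function(s, rid) {
  stopifnot(inherits(s, "ep_structure"), length(rid) == 1L)
  rids <- atom_rids(s)
  hit <- rids == rid
  if (!any(hit))
    stop(sprintf("unknown residue id '%s'; valid ids: %s", rid,
                 paste(residue_ids(s), collapse = ", ")))
  s$atoms$charge[hit] <- 0
  s
}

# ---- PQR / PDB I/O ---------------------------------------------------------

#' Read a PQR file
#'
#' Whitespace-separated PQR: `ATOM`/`HETATM` records carrying per-atom charge
#' and radius as the last two numeric fields.  Both the 10-field (no chain)
#' and 11-field (with chain) layouts are accepted.  PQR is the canonical
#' charge source for the package.
#'
#' @param path file path.
#' @return a [charged_structure()].
#' @export
read_pqr <- function(path) {
  ln <- readLines(path)
  keep <- grepl("^(ATOM|HETATM)", ln)
  if (!any(keep)) stop("no ATOM/HETATM records in ", path)
  idx <- which(keep)
  rows <- vector("list", length(idx))
  for (u in seq_along(idx)) {
    tok <- strsplit(trimws(ln[idx[u]]), "\\s+")[[1]]
    # layouts: rec serial name resname [chain] resnum x y z charge radius
    if (length(tok) == 11L) {
      chain <- tok[5]; rest <- tok[6:11]
    } else if (length(tok) == 10L) {
      chain <- "A"; rest <- tok[5:10]
    } else {
      stop(sprintf("line %d: cannot parse PQR record (need charge and radius columns): %s",
                   idx[u], ln[idx[u]]))
    }
    num <- suppressWarnings(as.numeric(rest))
    if (anyNA(num))
      stop(sprintf("line %d: non-numeric field in PQR record", idx[u]))
    # resnum may carry an insertion code (e.g. 52A)
    resnum_tok <- rest[1]
    icode <- ""
    if (is.na(suppressWarnings(as.integer(resnum_tok)))) {
      icode <- substr(resnum_tok, nchar(resnum_tok), nchar(resnum_tok))
      resnum_tok <- substr(resnum_tok, 1, nchar(resnum_tok) - 1)
    }
    rows[[u]] <- data.frame(
      serial = suppressWarnings(as.integer(tok[2])),
      name = tok[3], resname = tok[4], chain = chain,
      resnum = as.integer(resnum_tok), icode = icode,
      x = num[2], y = num[3], z = num[4],
      charge = num[5], radius = num[6], stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  charged_structure(atoms)
}

#' Write a PQR file
#'
#' @param s a [charged_structure()].
#' @param path file path.
#' @export
write_pqr <- function(s, path) {
  stopifnot(inherits(s, "ep_structure"))
  a <- s$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ATOM %6d %-4s %-4s %s %s %10.4f %10.4f %10.4f %8.4f %7.4f",
                     a$serial, a$name, a$resname, a$chain,
                     paste0(a$resnum, a$icode),
                     a$x, a$y, a$z, a$charge, a$radius), con)
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file (geometry only)
#'
#' Fixed-column parse of `ATOM`/`HETATM` records.  PDB carries no charges or
#' radii, so both are set to `NA`-free placeholders (charge 0, radius 0) and
#' should be filled in with [assign_default_charges()], which also assigns
#' van der Waals radii.
#'
#' @param path file path.
#' @export
read_pdb <- function(path) {
  ln <- readLines(path)
  ln <- ln[grepl("^(ATOM  |HETATM)", ln)]
  if (!length(ln)) stop("no ATOM/HETATM records in ", path)
  atoms <- data.frame(
    serial = as.integer(substr(ln, 7, 11)),
    name = trimws(substr(ln, 13, 16)),
    resname = trimws(substr(ln, 18, 20)),
    chain = trimws(substr(ln, 22, 22)),
    resnum = as.integer(substr(ln, 23, 26)),
    icode = trimws(substr(ln, 27, 27)),
    x = as.numeric(substr(ln, 31, 38)),
    y = as.numeric(substr(ln, 39, 46)),
    z = as.numeric(substr(ln, 47, 54)),
    radius = 0, charge = 0, stringsAsFactors = FALSE)
  atoms$chain[atoms$chain == ""] <- "A"
  charged_structure(atoms)
}

# Bondi-style van der Waals radii by element (Angstrom)
vdw_radius_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                      P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR"), two, substr(nm, 1, 1))
  # leading digits already stripped; hydrogens like 1HB1 keep the H
  el
}

#' Assign fallback formal charges and van der Waals radii
#'
#' Approximate stand-in for a real charge assignment when only a plain PDB is
#' available.  Formal charges are placed on side-chain terminal atoms:
#' Asp OD1/OD2 and Glu OE1/OE2 get -0.5 each, Lys NZ +1, Arg NH1/NH2 +0.5
#' each, His 0; the N terminus gets +1 on N and the C terminus -1 on OXT
#' (or O when OXT is absent) when flagged.  All other atoms are 0.  Radii come
#' from a fixed Bondi van der Waals table keyed on the element.
#'
#' @param s a [charged_structure()].
#' @param n_terminus,c_terminus logical; when `TRUE` the first/last residue of
#'   each chain is treated as a charged terminus.
#' @return the structure with charges and radii replaced.
#' @export
assign_default_charges <- function(s, n_terminus = FALSE, c_terminus = FALSE) {
  stopifnot(inherits(s, "ep_structure"))
  a <- s$atoms
  el <- guess_element(a$name)
  r <- unname(vdw_radius_table[el])
  r[is.na(r)] <- 1.5
  a$radius <- r
  q <- numeric(nrow(a))
  known <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
  unknown <- setdiff(unique(a$resname), known)
  if (length(unknown))
    warning("unknown residue name(s) assigned zero charge: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  q[a$resname == "ASP" & a$name %in% c("OD1", "OD2")] <- -0.5
  q[a$resname == "GLU" & a$name %in% c("OE1", "OE2")] <- -0.5
  q[a$resname == "LYS" & a$name == "NZ"] <- 1
  q[a$resname == "ARG" & a$name %in% c("NH1", "NH2")] <- 0.5
  for (ch in unique(a$chain)) {
    sel <- a$chain == ch
    if (isTRUE(n_terminus)) {
      first <- min(a$resnum[sel])
      q[sel & a$resnum == first & a$name == "N"] <- 1
    }
    if (isTRUE(c_terminus)) {
      last <- max(a$resnum[sel])
      tgt <- sel & a$resnum == last
      if (any(tgt & a$name == "OXT")) q[tgt & a$name == "OXT"] <- -1
      else q[tgt & a$name == "O"] <- -1
    }
  }
  a$charge <- q
  message("assigned approximate formal charges (fallback); prefer a PQR file with real partial charges")
  s$atoms <- a
  s
}
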