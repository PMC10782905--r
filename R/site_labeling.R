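# Binding-site labels from protein-nucleic-acid complex structures.
#
# A protein residue is a binding residue when the distance between any of
# its heavy atoms and any nucleic-acid heavy atom is strictly less than the
# sum of the two atoms' van der Waals radii plus 0.5 Angstrom. Hydrogens
# (rarely present in crystal structures) are ignored.

PROTEIN_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common modified residues, mapped to 'X' in the one-letter sequence
  "MSE", "SEP", "TPO", "PTR", "PCA", "CSO", "KCX", "MLY", "HYP")
NUCLEIC_RESIDUES <- c("DA", "DC", "DG", "DT", "DU", "DI",
                      "A", "C", "G", "U", "I", "T")
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

#' Van der Waals radii table
#'
#' Bondi-type radii in Angstrom for the elements common in protein and
#' nucleic-acid structures. Override entries by passing a modified copy to
#' [label_binding_sites()].
#'
#' @return Named numeric vector, element symbol to radius.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    B = 1.92, SI = 2.10)
}

#' Read a protein-nucleic-acid complex structure
#'
#' Parses a PDB or mmCIF file (by extension), keeps the highest-occupancy
#' alternate conformers, drops waters and non-polymer heteroatoms, and
#' classifies each remaining atom as protein or nucleic acid by residue-name
#' dictionaries. Modified protein residues are retained (their one-letter
#' code is \code{'X'}); unrecognized residue names are dropped with a
#' message.
#'
#' @param path Path to a \code{.pdb} or \code{.cif} file.
#' @return A \code{complex_structure}: list with an \code{atoms} data.frame
#'   (chain, resno, resid, atom, element, x, y, z, class).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("pdb", "ent")) {
    bio3d::read.pdb(path, verbose = FALSE)
  } else if (ext == "cif") {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    stop("unsupported structure format '", ext, "' (expected .pdb or .cif)")
  }
  at <- pdb$atom
  # highest-occupancy altloc per atom position
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$resid, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      if (length(ix) == 1L) return(ix)
      occ <- at$o[ix]
      ix[which.max(ifelse(is.na(occ), 1, occ))]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  resid <- toupper(trimws(at$resid))
  elem <- toupper(trimws(at$elesy))
  no_elem <- is.na(elem) | !nzchar(elem)
  if (any(no_elem)) {
    # fall back to the leading letters of the atom name
    elem[no_elem] <- sub("[0-9'*].*$", "", toupper(trimws(at$elety[no_elem])))
    elem[no_elem] <- substr(elem[no_elem], 1L, 1L)
  }
  cls <- rep(NA_character_, nrow(at))
  cls[resid %in% PROTEIN_RESIDUES] <- "protein"
  cls[resid %in% NUCLEIC_RESIDUES] <- "nucleic"
  drop_water <- resid %in% WATER_RESIDUES
  unknown <- is.na(cls) & !drop_water
  if (any(unknown)) {
    message("dropping ", sum(unknown), " atom(s) with unrecognized residue ",
            "name(s): ", paste(unique(resid[unknown]), collapse = ", "))
  }
  keep <- !is.na(cls)
  atoms <- data.frame(chain = at$chain[keep], resno = at$resno[keep],
                      resid = resid[keep], atom = trimws(at$elety[keep]),
                      element = elem[keep],
                      x = at$x[keep], y = at$y[keep], z = at$z[keep],
                      class = cls[keep], stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  structure(list(atoms = atoms, source = path), class = "complex_structure")
}

# build a complex_structure from a plain atom table (used for toy complexes)
#' Assemble a complex structure from an atom table
#'
#' Convenience constructor used for hand-built toy complexes and tests; the
#' table must have columns chain, resno, resid, element, x, y, z, class
#' (\code{"protein"} or \code{"nucleic"}).
#'
#' @param atoms Atom data.frame as described above.
#' @return A \code{complex_structure}.
#' @export
complex_structure <- function(atoms) {
  need <- c("chain", "resno", "resid", "element", "x", "y", "z", "class")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(atoms$class %in% c("protein", "nucleic")),
            all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(atoms = atoms, source = NA_character_),
            class = "complex_structure")
}

#' Label binding residues of every protein chain in a complex
#'
#' A residue is labeled 1 when the minimum over its heavy-atom pairs with
#' nucleic-acid atoms of \eqn{d(a, b) - r_{vdw}(a) - r_{vdw}(b)} is strictly
#' less than \code{tol} (0.5 Angstrom by default).
#'
#' @param struct A \code{complex_structure}.
#' @param radii Named radii vector, as from [vdw_radii()].
#' @param tol Distance tolerance in Angstrom added to the vdW-radius sum.
#' @return Named list (one entry per protein chain) of lists with
#'   \code{sequence} (one-letter, modified residues as 'X'), \code{labels}
#'   (0/1 per residue, sequence order) and \code{resno} (author numbering).
#' @export
label_binding_sites <- function(struct, radii = vdw_radii(), tol = 0.5) {
  stopifnot(inherits(struct, "complex_structure"))
  at <- struct$atoms
  at <- at[at$element != "H", , drop = FALSE]  # heavy atoms only
  prot <- at[at$class == "protein", , drop = FALSE]
  nuc <- at[at$class == "nucleic", , drop = FALSE]
  if (nrow(prot) == 0L) stop("structure contains no protein chain")
  if (nrow(nuc) == 0L) stop("structure contains no nucleic-acid chain")
  unknown <- setdiff(unique(c(prot$element, nuc$element)), names(radii))
  if (length(unknown) > 0) {
    stop("element(s) missing from the radii table: ",
         paste(unknown, collapse = ", "))
  }
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  nxyz <- as.matrix(nuc[, c("x", "y", "z")])
  rp <- radii[prot$element]
  rn <- radii[nuc$element]
  # gap(a, b) = d(a, b) - r_a - r_b; per protein atom, min over nucleic atoms
  d2 <- outer(rowSums(pxyz^2), rowSums(nxyz^2), `+`) - 2 * (pxyz %*% t(nxyz))
  gap <- sqrt(pmax(d2, 0)) - outer(rp, rn, `+`)
  min_gap_atom <- apply(gap, 1L, min)
  out <- list()
  for (ch in unique(prot$chain)) {
    sel <- prot$chain == ch
    resnos <- unique(prot$resno[sel])
    resnos <- resnos[order(resnos)]
    labels <- integer(length(resnos))
    seq_chars <- character(length(resnos))
    for (k in seq_along(resnos)) {
      rsel <- sel & prot$resno == resnos[k]
      labels[k] <- as.integer(min(min_gap_atom[rsel]) < tol)
      rn3 <- prot$resid[which(rsel)[1L]]
      seq_chars[k] <- if (rn3 %in% names(AA_321)) AA_321[[rn3]] else "X"
    }
    out[[ch]] <- list(sequence = paste(seq_chars, collapse = ""),
                      labels = labels, resno = resnos)
  }
  out
}
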