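# Structure container: an ordered table of atom records for one model.

BACKBONE_REQUIRED <- c("N", "CA", "C", "O")
CAP_RESIDUES <- c("ACE", "NH2")
ANION_RESIDUES <- c("SO4", "PO4")

#' Construct a structure (one conformer's atom records)
#'
#' A `cann_structure` is an ordered data frame of atom records:
#' `serial`, `atom` (PDB atom name), `resno`, `resid` (three-letter code),
#' `element`, `x`, `y`, `z` (angstroms) and `record` ("ATOM"/"HETATM").
#' The N-acetyl cap is stored as residue `ACE` at `resno` 0 and the
#' C-amide cap as residue `NH2` following the last residue, so that the
#' terminal phi/psi torsions are defined.
#'
#' @param atoms data frame with the columns listed above (`serial` and
#'   `record` are filled in when missing).
#' @param model_id integer model number for ensemble members.
#' @param validate check invariants (unique atom names per residue, finite
#'   coordinates, backbone completeness for standard residues).
#' @return an object of class `cann_structure`.
#' @export
cann_structure <- function(atoms, model_id = 1L, validate = TRUE) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom", "resno", "resid", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$record)) {
    atoms$record <- ifelse(atoms$resid %in% ANION_RESIDUES, "HETATM", "ATOM")
  }
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom)
  atoms <- atoms[, c("serial", "atom", "resno", "resid", "element",
                     "x", "y", "z", "record")]
  if (validate) {
    if (nrow(atoms) == 0L) stop("structure has zero atoms")
    if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
      stop("structure contains non-finite coordinates")
    }
    key <- paste(atoms$resno, atoms$atom)
    if (anyDuplicated(key)) {
      stop("duplicate (residue, atom) records: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    }
    std <- !(atoms$resid %in% c(CAP_RESIDUES, ANION_RESIDUES))
    for (r in unique(atoms$resno[std])) {
      have <- atoms$atom[atoms$resno == r & std]
      lack <- setdiff(BACKBONE_REQUIRED, have)
      if (length(lack)) {
        stop(sprintf("residue %d is missing backbone atom(s) %s",
                     r, paste(lack, collapse = ", ")))
      }
    }
  }
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "cann_structure")
}

guess_element <- function(atom_name) {
  e <- sub("^([A-Za-z]).*$", "\\1", sub("^[0-9]*", "", atom_name))
  toupper(e)
}

#' @export
print.cann_structure <- function(x, ...) {
  a <- x$atoms
  res <- unique(a$resno[!(a$resid %in% c(CAP_RESIDUES, ANION_RESIDUES))])
  cat(sprintf("<cann_structure> model %d: %d atoms, %d residues",
              x$model_id, nrow(a), length(res)))
  if (any(a$resid %in% ANION_RESIDUES)) {
    cat(" + anion (", paste(unique(a$resid[a$resid %in% ANION_RESIDUES]),
                            collapse = ","), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

# Coordinates of one atom; errors with a precise message when absent.
atom_xyz <- function(structure, resno, atom) {
  a <- structure$atoms
  i <- which(a$resno == resno & a$atom == atom)
  if (length(i) != 1L) {
    stop(sprintf("atom %s of residue %d not found in structure", atom, resno),
         call. = FALSE)
  }
  c(a$x[i], a$y[i], a$z[i])
}

has_atom <- function(structure, resno, atom) {
  any(structure$atoms$resno == resno & structure$atoms$atom == atom)
}

# Residue numbers of the peptide proper (no caps, no anion).
peptide_resnos <- function(structure) {
  a <- structure$atoms
  sort(unique(a$resno[!(a$resid %in% c(CAP_RESIDUES, ANION_RESIDUES))]))
}

residue_code <- function(structure, resno) {
  a <- structure$atoms
  unique(a$resid[a$resno == resno])[1]
}

# Apply a rigid transform (function on an n x 3 matrix) to all atoms.
transform_structure <- function(structure, f) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- f(xyz)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
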