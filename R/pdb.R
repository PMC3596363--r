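# PDB reading/writing. Reading is delegated to bio3d; a pre-scan supplies
# line-precise parse errors. Writing emits fixed-column PDB v3.3 directly.

#' Read a PDB file into a list of structures
#'
#' Multi-model files (MODEL/ENDMDL) yield one `cann_structure` per model;
#' a file without MODEL records yields a list of length one.  HETATM
#' records (e.g. SO4/PO4 anions) are kept and flagged via the `record`
#' column.  Alternate locations are not supported: the first altLoc is
#' kept with a warning.
#'
#' @param path path to a PDB-dialect text file.
#' @return list of [cann_structure] objects, one per model.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records in ", path)
  for (i in which(is_atom)) {
    for (fld in list(c(31, 38, "x"), c(39, 46, "y"), c(47, 54, "z"))) {
      v <- suppressWarnings(as.numeric(substr(lines[i],
                                              as.integer(fld[1]),
                                              as.integer(fld[2]))))
      if (is.na(v)) {
        stop(sprintf("parse error at line %d of %s: malformed %s coordinate",
                     i, path, fld[3]))
      }
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    warning("alternate locations present; keeping first altLoc only")
    keep <- !duplicated(paste(at$resno, at$elety))
    at <- at[keep, ]
    pdb$xyz <- pdb$xyz[, as.vector(t(outer(which(keep) * 3 - 2, 0:2, "+"))),
                       drop = FALSE]
  }
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    cann_structure(data.frame(
      serial = at$eleno,
      atom = at$elety,
      resno = at$resno,
      resid = at$resid,
      element = ifelse(is.na(at$elesy) | at$elesy == "",
                       guess_element(at$elety), at$elesy),
      x = co[, 1], y = co[, 2], z = co[, 3],
      record = at$type,
      stringsAsFactors = FALSE
    ), model_id = m, validate = FALSE)
  })
}

#' Write structures to a PDB file
#'
#' A single structure is written without MODEL records; several are
#' wrapped in MODEL/ENDMDL pairs.  Anion residues (SO4/PO4) are written
#' as HETATM.  Coordinates are printed to 3 decimals (the PDB column
#' precision), so write-then-read is the identity at that precision.
#'
#' @param structures a [cann_structure] or a non-empty list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path) {
  if (inherits(structures, "cann_structure")) structures <- list(structures)
  if (!length(structures)) stop("no structures to write")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(structures) > 1L
  for (m in seq_along(structures)) {
    s <- structures[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- s$atoms
    nm <- ifelse(nchar(a$atom) <= 3, paste0(" ", a$atom), a$atom)
    writeLines(sprintf(
      "%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record, a$serial %% 100000L, nm, a$resid, "A", a$resno,
      a$x, a$y, a$z, 1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Split a structure into its peptide part and anion model
#'
#' @param structure a [cann_structure] possibly containing SO4/PO4
#'   HETATM records.
#' @return list with elements `peptide` (a [cann_structure]) and `anion`
#'   (a [cann_anion] or `NULL` when no anion records are present).
#' @export
split_anion <- function(structure) {
  a <- structure$atoms
  is_anion <- a$resid %in% ANION_RESIDUES
  pep <- cann_structure(a[!is_anion, , drop = FALSE],
                        model_id = structure$model_id, validate = FALSE)
  if (!any(is_anion)) return(list(peptide = pep, anion = NULL))
  anion <- anion_from_atoms(a[is_anion, , drop = FALSE])
  list(peptide = pep, anion = anion)
}

# Merge a peptide structure and an anion model into one structure for PDB
# output.
pose_structure <- function(structure, anion, model_id = structure$model_id) {
  a <- structure$atoms
  b <- anion_atoms(anion, resno = max(a$resno) + 1L)
  b$serial <- max(a$serial) + seq_len(nrow(b))
  cann_structure(rbind(a, b), model_id = model_id, validate = FALSE)
}
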