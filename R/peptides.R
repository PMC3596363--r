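# Residue specifications and the designed peptide registry.

# Monoisotopic-relevant elemental composition of each residue (the chain
# unit, i.e. amino acid minus water).  AIB is alpha-aminoisobutyric acid
# (two Calpha methyls, no Halpha).
RESIDUE_TABLE <- list(
  ALA = list(formula = c(C = 3, H = 5, N = 1, O = 1, S = 0), has_ha = TRUE),
  ARG = list(formula = c(C = 6, H = 12, N = 4, O = 1, S = 0), has_ha = TRUE),
  ASN = list(formula = c(C = 4, H = 6, N = 2, O = 2, S = 0), has_ha = TRUE),
  ASP = list(formula = c(C = 4, H = 5, N = 1, O = 3, S = 0), has_ha = TRUE),
  CYS = list(formula = c(C = 3, H = 5, N = 1, O = 1, S = 1), has_ha = TRUE),
  GLN = list(formula = c(C = 5, H = 8, N = 2, O = 2, S = 0), has_ha = TRUE),
  GLU = list(formula = c(C = 5, H = 7, N = 1, O = 3, S = 0), has_ha = TRUE),
  GLY = list(formula = c(C = 2, H = 3, N = 1, O = 1, S = 0), has_ha = TRUE),
  HIS = list(formula = c(C = 6, H = 7, N = 3, O = 1, S = 0), has_ha = TRUE),
  ILE = list(formula = c(C = 6, H = 11, N = 1, O = 1, S = 0), has_ha = TRUE),
  LEU = list(formula = c(C = 6, H = 11, N = 1, O = 1, S = 0), has_ha = TRUE),
  LYS = list(formula = c(C = 6, H = 12, N = 2, O = 1, S = 0), has_ha = TRUE),
  MET = list(formula = c(C = 5, H = 9, N = 1, O = 1, S = 1), has_ha = TRUE),
  PHE = list(formula = c(C = 9, H = 9, N = 1, O = 1, S = 0), has_ha = TRUE),
  PRO = list(formula = c(C = 5, H = 7, N = 1, O = 1, S = 0), has_ha = TRUE),
  SER = list(formula = c(C = 3, H = 5, N = 1, O = 2, S = 0), has_ha = TRUE),
  THR = list(formula = c(C = 4, H = 7, N = 1, O = 2, S = 0), has_ha = TRUE),
  TRP = list(formula = c(C = 11, H = 10, N = 2, O = 1, S = 0), has_ha = TRUE),
  TYR = list(formula = c(C = 9, H = 9, N = 1, O = 2, S = 0), has_ha = TRUE),
  VAL = list(formula = c(C = 5, H = 9, N = 1, O = 1, S = 0), has_ha = TRUE),
  AIB = list(formula = c(C = 4, H = 7, N = 1, O = 1, S = 0), has_ha = FALSE)
)

#' Residue specification
#'
#' @param code three-letter residue code (20 standard amino acids + AIB).
#' @return list with `code` and `has_alpha_hydrogen` (FALSE only for AIB).
#' @export
residue_spec <- function(code) {
  code <- toupper(code)
  if (!code %in% names(RESIDUE_TABLE)) {
    stop("unknown residue code: ", code,
         " (allowed: 20 standard amino acids + AIB)")
  }
  list(code = code, has_alpha_hydrogen = RESIDUE_TABLE[[code]]$has_ha)
}

# The designed anchor helix appended after the four motif residues.
ANCHOR_HELIX <- c("ALA", "AIB", "ALA", "LYS", "ALA", "AIB", "LYS",
                  "ALA", "LYS", "ALA", "AIB", "GLY", "GLY", "TYR")

# Registry of the six designed peptides: the 18-residue chimeric series
# (four motif residues + anchor helix) and the 5-residue truncations.
# `native` holds the crystal-structure phi/psi of the four motif residues.
PEPTIDE_REGISTRY <- list(
  CPS224Ac = list(
    motif = c("LEU", "GLY", "LYS", "GLN"),
    native = cbind(phi = c(-89.1, 130.6, -63.7, -59.2),
                   psi = c(87.2, 126.7, -45.1, -46.7))
  ),
  CPS226 = list(
    motif = c("GLY", "SER", "ALA", "LYS"),
    native = cbind(phi = c(-131.8, -97.3, -67.7, -68.1),
                   psi = c(-146.2, 115.6, -35.0, -47.8))
  ),
  CPS228 = list(
    motif = c("LEU", "GLY", "GLY", "LEU"),
    native = cbind(phi = c(-112.9, -95.1, -63.0, -62.1),
                   psi = c(46.7, -139.5, -56.2, -42.1))
  )
)

# Anchor-helix torsions used for residues 5..18 of every design.
HELIX_PHI <- -57
HELIX_PSI <- -47

#' Look up or construct a peptide model
#'
#' Known ids are the six designed sequences: `CPS224Ac`, `CPS226`,
#' `CPS228` (18 residues: four motif residues followed by the designed
#' anchor helix) and their 5-residue truncations `SCPS224Ac`, `SCPS226`,
#' `SCPS228` (motif residues + Ala).  All carry an N-acetyl and a
#' C-amide cap.
#'
#' @param id peptide identifier.
#' @return a `cann_peptide`: list with `id`, `residues` (character vector
#'   of three-letter codes), `n_cap` and `c_cap`.
#' @export
peptide_model <- function(id) {
  base <- sub("^S", "", id)
  if (!base %in% names(PEPTIDE_REGISTRY) ||
      !(id == base || id == paste0("S", base))) {
    stop("unknown peptide id: ", id, " (known: ",
         paste(c(names(PEPTIDE_REGISTRY),
                 paste0("S", names(PEPTIDE_REGISTRY))), collapse = ", "), ")")
  }
  entry <- PEPTIDE_REGISTRY[[base]]
  residues <- if (id == base) c(entry$motif, ANCHOR_HELIX)
              else c(entry$motif, "ALA")
  new_peptide(id, residues)
}

#' Construct a peptide model from an explicit sequence
#'
#' @param id label for the peptide.
#' @param residues character vector of three-letter codes.
#' @param n_cap `"acetyl"` or `"free"`.
#' @param c_cap `"amide"` or `"free"`.
#' @return a `cann_peptide`.
#' @export
new_peptide <- function(id, residues, n_cap = "acetyl", c_cap = "amide") {
  if (!length(residues)) stop("peptide must have at least one residue")
  residues <- toupper(residues)
  for (r in residues) residue_spec(r)  # validates codes
  n_cap <- match.arg(n_cap, c("acetyl", "free"))
  c_cap <- match.arg(c_cap, c("amide", "free"))
  structure(list(id = id, residues = residues, n_cap = n_cap, c_cap = c_cap),
            class = "cann_peptide")
}

#' @export
print.cann_peptide <- function(x, ...) {
  cat(sprintf("<cann_peptide> %s: %s%s%s\n", x$id,
              if (x$n_cap == "acetyl") "Ac-" else "",
              paste(x$residues, collapse = "-"),
              if (x$c_cap == "amide") "-NH2" else ""))
  invisible(x)
}

# Native (crystal-derived) motif torsions for a registry id.
native_motif_dihedrals <- function(id) {
  base <- sub("^S", "", id)
  if (!base %in% names(PEPTIDE_REGISTRY)) stop("unknown peptide id: ", id)
  PEPTIDE_REGISTRY[[base]]$native
}
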