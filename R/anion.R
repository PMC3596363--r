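# Tetrahedral oxyanion models (sulfate SO4^2-, hydrogen phosphate HPO4^2-).

ANION_BOND <- c(sulfate = 1.49, phosphate = 1.54) # central-O, angstroms
ANION_OH <- 0.96                                  # hydroxyl O-H, angstroms

#' Build an ideal tetrahedral anion
#'
#' Sulfate is built with S-O 1.49 angstrom bonds; hydrogen phosphate with
#' P-O 1.54 angstroms and a single hydroxyl hydrogen (O-H 0.96 angstroms)
#' on oxygen O4.  The central atom sits at the origin; all O-X-O angles
#' are the ideal tetrahedral 109.47 degrees.
#'
#' @param kind `"sulfate"` or `"phosphate"`.
#' @return a `cann_anion`: list with `kind`, `central` (element name),
#'   and `atoms` (data frame of atom name, element, x, y, z).
#' @export
build_anion <- function(kind = c("sulfate", "phosphate")) {
  kind <- match.arg(kind)
  r <- ANION_BOND[[kind]]
  central <- if (kind == "sulfate") "S" else "P"
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  atoms <- data.frame(
    atom = c(central, paste0("O", 1:4)),
    element = c(central, rep("O", 4)),
    rbind(c(0, 0, 0), v * r),
    stringsAsFactors = FALSE
  )
  names(atoms)[3:5] <- c("x", "y", "z")
  if (kind == "phosphate") {
    o4 <- as.numeric(atoms[5, c("x", "y", "z")])
    u <- vunit(o4)                       # P -> O4 direction
    w <- vunit(vcross(u, c(0, 0, 1)))    # any perpendicular
    # P-O4-H angle 109.47 deg: O4->H makes that angle with O4->P (= -u)
    h <- o4 + ANION_OH * (u * (-cos(109.47 * pi / 180)) +
                            w * sin(109.47 * pi / 180))
    atoms <- rbind(atoms, data.frame(atom = "HO4", element = "H",
                                     x = h[1], y = h[2], z = h[3]))
  }
  structure(list(kind = kind, central = central, atoms = atoms),
            class = "cann_anion")
}

#' @export
print.cann_anion <- function(x, ...) {
  cat(sprintf("<cann_anion> %s (%d atoms)\n", x$kind, nrow(x$atoms)))
  invisible(x)
}

# Coordinates of the anion's central atom / oxygens.
anion_central_xyz <- function(anion) {
  as.numeric(anion$atoms[1, c("x", "y", "z")])
}

anion_oxygen_xyz <- function(anion) {
  o <- anion$atoms[grepl("^O[0-9]$", anion$atoms$atom), ]
  m <- as.matrix(o[, c("x", "y", "z")])
  rownames(m) <- o$atom
  m
}

# Apply a rigid transform (function on an n x 3 matrix) to the anion.
transform_anion <- function(anion, f) {
  xyz <- f(as.matrix(anion$atoms[, c("x", "y", "z")]))
  anion$atoms$x <- xyz[, 1]
  anion$atoms$y <- xyz[, 2]
  anion$atoms$z <- xyz[, 3]
  anion
}

# HETATM atom table for PDB output.
anion_atoms <- function(anion, resno) {
  data.frame(
    serial = seq_len(nrow(anion$atoms)),
    atom = anion$atoms$atom,
    resno = resno,
    resid = if (anion$kind == "sulfate") "SO4" else "PO4",
    element = anion$atoms$element,
    x = anion$atoms$x, y = anion$atoms$y, z = anion$atoms$z,
    record = "HETATM",
    stringsAsFactors = FALSE
  )
}

# Rebuild a cann_anion from HETATM records read back from PDB.
anion_from_atoms <- function(atoms) {
  kind <- if (atoms$resid[1] == "SO4") "sulfate" else "phosphate"
  structure(list(
    kind = kind,
    central = if (kind == "sulfate") "S" else "P",
    atoms = data.frame(atom = atoms$atom, element = atoms$element,
                       x = atoms$x, y = atoms$y, z = atoms$z,
                       stringsAsFactors = FALSE)
  ), class = "cann_anion")
}
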