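# Geometric H-bond detection, point-charge Coulomb scoring and the
# canonical two-oxygen contact pattern of the CaNN motif.

#' Geometric H-bond acceptance cutoffs
#'
#' Distance cutoffs are donor-kind specific: (Calpha)H...O <= 3.0
#' angstroms and (N)H...O <= 2.7 angstroms, with the X-H...O angle >=
#' 90 degrees; all thresholds inclusive.  The N-donor cutoff is exposed
#' because the crystal-structure convention uses 3.0 angstroms for all
#' donors.
#'
#' @param d_calpha,d_n,angle_min override individual cutoffs.
#' @return named list of cutoffs.
#' @export
hbond_cutoffs <- function(d_calpha = 3.0, d_n = 2.7, angle_min = 90) {
  list(d_calpha = d_calpha, d_n = d_n, angle_min = angle_min)
}

#' Point charges for the Coulomb H-bond energy
#'
#' The four-term Coulomb sum uses the charge set (units of e): qS = 1.6,
#' qO = -0.9 on the anion; qH = 0.3, qN = -0.5 for amide donors; qH =
#' 0.06, qCalpha = -0.1 for Calpha donors; with the conversion factor
#' 332 kcal angstrom / (mol e^2).
#'
#' @return named list of charges and the scale factor.
#' @export
point_charges <- function() {
  list(scale = 332, q_s = 1.6, q_o = -0.9,
       q_h_amide = 0.3, q_n = -0.5,
       q_h_alpha = 0.06, q_calpha = -0.1)
}

#' Detect a single hydrogen bond geometrically
#'
#' Accepts a contact iff the H...O distance is within the donor-kind
#' cutoff and the X-H...O angle (at the hydrogen) is at least the angle
#' cutoff.
#'
#' @param donor_heavy,hydrogen,acceptor_o xyz coordinates (angstroms).
#' @param donor_kind `"Calpha"` or `"N"`.
#' @param cutoffs see [hbond_cutoffs()].
#' @return a list (class `cann_hbond`) with `d_ho`, `angle_xho`,
#'   `donor_kind`, or `NULL` when the geometry fails the criteria.
#' @export
detect_hbond <- function(donor_heavy, hydrogen, acceptor_o,
                         donor_kind = c("N", "Calpha"),
                         cutoffs = hbond_cutoffs()) {
  donor_kind <- match.arg(donor_kind)
  if (vnorm(hydrogen - donor_heavy) >= 1.2) {
    stop("hydrogen is not covalently bonded to the donor heavy atom ",
         "(distance >= 1.2 angstroms)")
  }
  d <- vnorm(acceptor_o - hydrogen)
  ang <- bond_angle(donor_heavy, hydrogen, acceptor_o)
  dmax <- if (donor_kind == "Calpha") cutoffs$d_calpha else cutoffs$d_n
  if (d > dmax || ang < cutoffs$angle_min) return(NULL)
  structure(list(donor_kind = donor_kind, d_ho = d, angle_xho = ang),
            class = "cann_hbond")
}

#' Point-charge Coulomb energy of an anion-donor contact
#'
#' Evaluates the four-term sum
#' `E = 332 (qS qH / rSH + qS qX / rSX + qO qH / rOH + qO qX / rOX)`
#' in kcal/mol, with (qH, qX) = (0.3, -0.5) for amide donors and
#' (0.06, -0.1) for Calpha donors.
#'
#' @param donor_kind `"N"` or `"Calpha"`.
#' @param s,o,h,x xyz coordinates of the anion central atom (S or P),
#'   the acceptor oxygen, the donor hydrogen and the donor heavy atom.
#' @param charges see [point_charges()].
#' @return energy in kcal/mol.
#' @export
hbond_energy <- function(donor_kind = c("N", "Calpha"), s, o, h, x,
                         charges = point_charges()) {
  donor_kind <- match.arg(donor_kind)
  qh <- if (donor_kind == "N") charges$q_h_amide else charges$q_h_alpha
  qx <- if (donor_kind == "N") charges$q_n else charges$q_calpha
  r <- c(sh = vnorm(s - h), sx = vnorm(s - x),
         oh = vnorm(o - h), ox = vnorm(o - x))
  if (any(r < 1e-6)) stop("singular geometry: coincident atoms")
  e <- charges$scale *
    (charges$q_s * qh / r[["sh"]] + charges$q_s * qx / r[["sx"]] +
       charges$q_o * qh / r[["oh"]] + charges$q_o * qx / r[["ox"]])
  unname(e)
}

#' Classify an H-bond energy
#'
#' Strong iff E <= -1.0 kcal/mol; weak iff -1.0 < E <= -0.5; otherwise
#' none.  The boundaries are inclusive on the stronger side.
#'
#' @param e energy (kcal/mol), vectorised.
#' @return character vector: `"strong"`, `"weak"` or `"none"`.
#' @export
classify_energy <- function(e) {
  stopifnot(all(is.finite(e)))
  ifelse(e <= -1.0, "strong", ifelse(e <= -0.5, "weak", "none"))
}

# Donor atoms of the motif: Calpha(-1)-H, N(0)-H, N(+1)-H.  Returns a
# list of donors, each with kind, label, X and candidate H coordinates.
motif_donors <- function(structure, motif_residues) {
  stopifnot(length(motif_residues) == 3)
  r <- motif_residues
  donors <- list()
  code <- residue_code(structure, r[1])
  ha <- intersect(c("HA", "HA2", "HA3"),
                  structure$atoms$atom[structure$atoms$resno == r[1]])
  if (length(ha)) {
    donors$Calpha_m1 <- list(kind = "Calpha", label = "Calpha_m1",
                             resno = r[1],
                             x = atom_xyz(structure, r[1], "CA"),
                             h = lapply(ha, function(a)
                               atom_xyz(structure, r[1], a)),
                             h_names = ha)
  } # Aib has no Halpha: the Calpha donor is simply absent
  for (k in 2:3) {
    lbl <- c("N_0", "N_p1")[k - 1]
    if (!has_atom(structure, r[k], "H")) {
      stop(sprintf(paste0("residue %d lacks an amide hydrogen; build ",
                          "hydrogens first (see build_backbone)"), r[k]))
    }
    donors[[lbl]] <- list(kind = "N", label = lbl, resno = r[k],
                          x = atom_xyz(structure, r[k], "N"),
                          h = list(atom_xyz(structure, r[k], "H")),
                          h_names = "H")
  }
  donors
}

#' Map anion-motif contacts and test the canonical pattern
#'
#' Evaluates [detect_hbond()] for the three motif donors (Calpha(-1)-H,
#' N(0)-H, N(+1)-H) against all four anion oxygens; for Gly the nearer
#' of the two Halpha is used per acceptor.  The canonical CaNN pattern
#' requires exactly two interacting oxygens: one bridging both
#' Calpha(-1)-H and N(0)-H, the other contacting only N(+1)-H.
#'
#' @param structure peptide [cann_structure] (with hydrogens).
#' @param anion a `cann_anion` positioned in the same frame.
#' @param motif_residues three residue numbers `(i-1, i0, i+1)`.
#' @param cutoffs see [hbond_cutoffs()].
#' @param charges see [point_charges()].
#' @return a `cann_motif_interaction`: list with `contacts` (data frame:
#'   donor, resno, oxygen, d_ho, angle_xho, energy, hclass),
#'   `oxygen_map` (oxygen -> donor labels), `n_interacting_oxygens` and
#'   `canonical`.
#' @export
map_anion_contacts <- function(structure, anion, motif_residues,
                               cutoffs = hbond_cutoffs(),
                               charges = point_charges()) {
  donors <- motif_donors(structure, motif_residues)
  oxy <- anion_oxygen_xyz(anion)
  s <- anion_central_xyz(anion)
  rows <- list()
  for (d in donors) {
    for (oi in seq_len(nrow(oxy))) {
      o <- oxy[oi, ]
      # nearer Halpha for Gly
      hi <- which.min(vapply(d$h, function(h) vnorm(h - o), numeric(1)))
      h <- d$h[[hi]]
      hb <- detect_hbond(d$x, h, o, donor_kind = d$kind, cutoffs = cutoffs)
      if (is.null(hb)) next
      e <- hbond_energy(d$kind, s, o, h, d$x, charges)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = d$label, resno = d$resno, oxygen = rownames(oxy)[oi],
        hydrogen = d$h_names[hi], d_ho = hb$d_ho, angle_xho = hb$angle_xho,
        energy = e, hclass = classify_energy(e),
        stringsAsFactors = FALSE)
    }
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = character(), resno = integer(), oxygen = character(),
               hydrogen = character(), d_ho = numeric(),
               angle_xho = numeric(), energy = numeric(),
               hclass = character(), stringsAsFactors = FALSE)
  oxygen_map <- split(contacts$donor, contacts$oxygen)
  structure(list(contacts = contacts, oxygen_map = oxygen_map,
                 n_interacting_oxygens = length(oxygen_map),
                 canonical = canonical_pattern(oxygen_map)),
            class = "cann_motif_interaction")
}

# The canonical-pattern predicate over an oxygen -> donors mapping.
canonical_pattern <- function(oxygen_map) {
  if (length(oxygen_map) != 2L) return(FALSE)
  sets <- lapply(oxygen_map, unique)
  bridging <- vapply(sets, function(s)
    all(c("Calpha_m1", "N_0") %in% s), logical(1))
  solo <- vapply(sets, function(s) identical(sort(s), "N_p1"), logical(1))
  any(bridging & !solo) && any(solo & !bridging) &&
    sum(bridging) >= 1 && sum(solo) >= 1 &&
    # the two roles must be taken by different oxygens
    length(unique(c(which(bridging)[1], which(solo)[1]))) == 2
}

#' @export
print.cann_motif_interaction <- function(x, ...) {
  cat(sprintf("<cann_motif_interaction> %d contact(s), %d oxygen(s), canonical = %s\n",
              nrow(x$contacts), x$n_interacting_oxygens, x$canonical))
  if (nrow(x$contacts)) print(x$contacts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Export contacts of one or more poses as TSV
#'
#' @param interactions a `cann_motif_interaction` or list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
contacts_to_tsv <- function(interactions, path) {
  if (inherits(interactions, "cann_motif_interaction")) {
    interactions <- list(interactions)
  }
  tab <- do.call(rbind, lapply(seq_along(interactions), function(m) {
    ct <- interactions[[m]]$contacts
    if (!nrow(ct)) return(NULL)
    cbind(model = m, ct)
  }))
  if (is.null(tab)) {
    tab <- data.frame(model = integer(), donor = character(),
                      resno = integer(), oxygen = character(),
                      hydrogen = character(), d_ho = numeric(),
                      angle_xho = numeric(), energy = numeric(),
                      hclass = character())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export motif interactions as JSON (one entry per model)
#'
#' @param interactions a `cann_motif_interaction` or list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
interactions_to_json <- function(interactions, path) {
  if (inherits(interactions, "cann_motif_interaction")) {
    interactions <- list(interactions)
  }
  payload <- lapply(interactions, function(mi) {
    list(contacts = mi$contacts, oxygen_map = mi$oxygen_map,
         n_interacting_oxygens = mi$n_interacting_oxygens,
         canonical = mi$canonical)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
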