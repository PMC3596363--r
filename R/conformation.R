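# Dihedral measurement, Ramachandran-window classification, NH-NH
# helicity tracking, and bound/unbound trajectory analysis.

#' Ramachandran window definitions
#'
#' The strict right-handed helical window is phi = -70 (+/- 15),
#' psi = -57 (+/- 12); polyproline II is phi = -70 (+/- 15),
#' psi = 150 (+/- 20).  "Non-canonical helical" is the broad
#' right-handed-helical box minus the strict window.
#'
#' @return list of window boxes, each `c(phi_min, phi_max, psi_min,
#'   psi_max)`.
#' @export
rama_windows <- function() {
  list(
    helical_R = c(phi_min = -85, phi_max = -55, psi_min = -69, psi_max = -45),
    ppII = c(phi_min = -85, phi_max = -55, psi_min = 130, psi_max = 170),
    noncanonical_helical = c(phi_min = -110, phi_max = -40,
                             psi_min = -80, psi_max = -5)
  )
}

#' Classify a (phi, psi) pair into a conformational state
#'
#' Total over defined (phi, psi): returns one of `helical_R`, `ppII`,
#' `noncanonical_helical` (the broad right-handed box excluding the
#' strict helical window) or `other`.  Window boundaries are inclusive;
#' ties go to the more specific region.
#'
#' @param phi,psi torsions in degrees (vectorised).
#' @param windows window list as from [rama_windows()].
#' @return character vector of state labels.
#' @export
classify_state <- function(phi, psi, windows = rama_windows()) {
  inbox <- function(w) {
    phi >= w["phi_min"] & phi <= w["phi_max"] &
      psi >= w["psi_min"] & psi <= w["psi_max"]
  }
  out <- rep("other", length(phi))
  out[inbox(windows$noncanonical_helical)] <- "noncanonical_helical"
  out[inbox(windows$ppII)] <- "ppII"
  out[inbox(windows$helical_R)] <- "helical_R"
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}

#' Measure backbone dihedrals from coordinates
#'
#' phi_i is C(i-1)-N(i)-CA(i)-C(i); psi_i is N(i)-CA(i)-C(i)-N(i+1);
#' omega_i is CA(i-1)-C(i-1)-N(i)-CA(i).  Cap atoms (ACE carbonyl C,
#' amide cap N) supply the terminal torsions; where no cap is present
#' the terminal torsion is `NA`.
#'
#' @param structure a [cann_structure] with complete backbone.
#' @return a `cann_dihedrals` data frame (see [backbone_dihedral_set()]).
#' @export
backbone_dihedrals <- function(structure) {
  res <- peptide_resnos(structure)
  n <- length(res)
  if (!n) stop("structure contains no peptide residues")
  get <- function(resno, atom) atom_xyz(structure, resno, atom)
  has_ace <- has_atom(structure, 0L, "C")
  cap_no <- max(res) + 1L
  has_cap <- has_atom(structure, cap_no, "N")
  phi <- psi <- omg <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    i <- res[k]
    nn <- get(i, "N"); ca <- get(i, "CA"); cc <- get(i, "C")
    c_prev <- if (k > 1) get(res[k - 1], "C")
              else if (has_ace) get(0L, "C") else NULL
    n_next <- if (k < n) get(res[k + 1], "N")
              else if (has_cap) get(cap_no, "N") else NULL
    if (!is.null(c_prev)) phi[k] <- dihedral_angle(c_prev, nn, ca, cc)
    if (!is.null(n_next)) psi[k] <- dihedral_angle(nn, ca, cc, n_next)
    ca_prev <- if (k > 1) get(res[k - 1], "CA")
               else if (has_ace) get(0L, "CH3") else NULL
    if (!is.null(ca_prev) && !is.null(c_prev)) {
      omg[k] <- dihedral_angle(ca_prev, c_prev, nn, ca)
    }
  }
  backbone_dihedral_set(phi, psi, omg, resno = res)
}

#' Consecutive amide-proton distances
#'
#' The NH-NH(i, i+1) distance is a standard helicity measure: values
#' below 4 angstroms indicate helical conformation at that step.  Pairs
#' where either residue lacks an amide hydrogen (e.g. proline) are
#' omitted.
#'
#' @param structure a [cann_structure] with amide hydrogens placed.
#' @param threshold helicity cutoff in angstroms (default 4).
#' @return data frame with columns `i`, `j` (= i + 1), `distance`,
#'   `helical`.
#' @export
nh_nh_distances <- function(structure, threshold = 4) {
  res <- peptide_resnos(structure)
  out <- list()
  if (length(res) >= 2) {
    for (k in seq_len(length(res) - 1)) {
      i <- res[k]; j <- res[k + 1]
      if (!has_atom(structure, i, "H") || !has_atom(structure, j, "H")) next
      d <- vnorm(atom_xyz(structure, i, "H") - atom_xyz(structure, j, "H"))
      out[[length(out) + 1L]] <- data.frame(i = i, j = j, distance = d,
                                            helical = d < threshold)
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(),
                      distance = numeric(), helical = logical()))
  }
  do.call(rbind, out)
}

#' Analyse a bound/unbound trajectory
#'
#' For every frame the motif contacts, per-residue (phi, psi) states and
#' NH-NH distances are recorded.  The anion residence is the initial
#' maximal run of frames with at least one motif contact, tolerating
#' contact gaps shorter than `gap_tol` frames.  The transition report
#' gives, per motif residue, the helical_R fraction before vs after the
#' end of residence.
#'
#' @param frames list of frames, each a list with elements `structure`
#'   (a [cann_structure]) and `anion` (a `cann_anion` or `NULL`).
#' @param motif_residues three residue numbers `(i-1, i0, i+1)`.
#' @param gap_tol gap tolerance in frames (default 10).
#' @param dt time per frame in ps (default 1).
#' @param cutoffs H-bond cutoffs, see [hbond_cutoffs()].
#' @return list of class `cann_trajectory_analysis` with elements
#'   `dihedrals` (long data frame: frame, time, resno, phi, psi, state),
#'   `nh` (frame, i, j, distance, helical), `contacts` (frame,
#'   n_contacts, n_oxygens, canonical), `residence_frames` and
#'   `transition` (per motif residue helical_R fractions before/after).
#' @export
analyze_trajectory <- function(frames, motif_residues, gap_tol = 10,
                               dt = 1, cutoffs = hbond_cutoffs()) {
  if (length(frames) < 2) stop("need at least 2 frames")
  dihe <- nh <- cont <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    d <- backbone_dihedrals(fr$structure)
    dihe[[f]] <- data.frame(frame = f, time = f * dt, resno = d$resno,
                            phi = d$phi, psi = d$psi,
                            state = classify_state(d$phi, d$psi))
    nhd <- nh_nh_distances(fr$structure)
    if (nrow(nhd)) nh[[f]] <- cbind(frame = f, nhd)
    nc <- 0L; nox <- 0L; canon <- FALSE
    if (!is.null(fr$anion)) {
      mi <- map_anion_contacts(fr$structure, fr$anion, motif_residues,
                               cutoffs = cutoffs)
      nc <- nrow(mi$contacts); nox <- mi$n_interacting_oxygens
      canon <- mi$canonical
    }
    cont[[f]] <- data.frame(frame = f, n_contacts = nc,
                            n_oxygens = nox, canonical = canon)
  }
  dihe <- do.call(rbind, dihe)
  nh <- do.call(rbind, nh)
  cont <- do.call(rbind, cont)

  bound <- cont$n_contacts > 0
  residence <- residence_run(bound, gap_tol)

  mot <- motif_residues
  before <- dihe$frame <= residence & dihe$resno %in% mot
  after <- dihe$frame > residence & dihe$resno %in% mot
  transition <- do.call(rbind, lapply(mot, function(r) {
    fb <- dihe$state[dihe$resno == r & dihe$frame <= residence]
    fa <- dihe$state[dihe$resno == r & dihe$frame > residence]
    data.frame(resno = r,
               frac_helical_before = if (length(fb)) mean(fb == "helical_R") else NA_real_,
               frac_helical_after = if (length(fa)) mean(fa == "helical_R") else NA_real_)
  }))
  structure(list(dihedrals = dihe, nh = nh, contacts = cont,
                 residence_frames = residence, transition = transition),
            class = "cann_trajectory_analysis")
}

# Length of the initial bound episode, tolerating gaps < gap_tol frames.
residence_run <- function(bound, gap_tol) {
  idx <- which(bound)
  if (!length(idx) || idx[1] > gap_tol) return(0L)
  last <- idx[1]
  for (i in idx[-1]) {
    if (i - last >= gap_tol + 1L) break
    last <- i
  }
  as.integer(last)
}

#' @export
print.cann_trajectory_analysis <- function(x, ...) {
  nf <- max(x$contacts$frame)
  cat(sprintf("<cann_trajectory_analysis> %d frames; residence %d frames\n",
              nf, x$residence_frames))
  print(x$transition, row.names = FALSE)
  invisible(x)
}

#' Write trajectory analysis to TSV/JSON files
#'
#' @param analysis a `cann_trajectory_analysis`.
#' @param prefix output path prefix; writes `<prefix>_dihedrals.tsv`,
#'   `<prefix>_nhnh.tsv`, `<prefix>_contacts.tsv` and
#'   `<prefix>_transition.json`.
#' @return character vector of written paths, invisibly.
#' @export
write_trajectory_report <- function(analysis, prefix) {
  paths <- c(paste0(prefix, "_dihedrals.tsv"), paste0(prefix, "_nhnh.tsv"),
             paste0(prefix, "_contacts.tsv"),
             paste0(prefix, "_transition.json"))
  utils::write.table(analysis$dihedrals, paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(analysis$nh, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(analysis$contacts, paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(residence_frames = analysis$residence_frames,
                            transition = analysis$transition),
                       paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
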