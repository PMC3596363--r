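# Seeded synthetic generators emulating the docking-pose ensembles and
# binding/unbinding trajectories that the analysis stages consume.
# These are statistical stand-ins with known ground truth, not physical
# simulations: the anion is treated as a rigid body and the peptide
# backbone is rebuilt from jittered torsions.

# Memo for deterministic base poses (keyed "peptide|anion").
.pose_cache <- new.env(parent = emptyenv())

#' Default target geometry for a canonical pose
#'
#' Distances are H...O in angstroms, angles are X-H...O in degrees; the
#' N-donor values sit in the middle of the ranges observed for docked
#' conformers (d ~ 1.9, angle ~ 160), the weaker Calpha donor at
#' d ~ 2.6, angle ~ 120.
#'
#' @return named list of targets.
#' @export
canonical_geometry <- function() {
  list(d_ca = 2.6, d_n0 = 1.9, d_n1 = 1.9,
       ang_ca = 120, ang_n0 = 160, ang_n1 = 160)
}

#' Place an anion in the canonical bridging pose
#'
#' Solves for the rigid-body placement of an ideal anion such that one
#' oxygen sits at the requested distance/angle from both the
#' Calpha(-1)-H and N(0)-H donors while a second oxygen serves only
#' N(+1)-H, by multi-start least squares over the six rigid degrees of
#' freedom.  The achieved geometry is checked against the targets
#' (tolerance 0.15 angstroms / 10 degrees) and reported back.
#'
#' @param structure peptide [cann_structure] with hydrogens.
#' @param motif_residues three residue numbers `(i-1, i0, i+1)`.
#' @param anion_kind `"sulfate"` or `"phosphate"`.
#' @param geometry targets, see [canonical_geometry()].
#' @param tol_d,tol_angle acceptance tolerances on the achieved
#'   geometry.
#' @return list with `structure` (unchanged), `anion` (posed
#'   `cann_anion`) and `achieved` (data frame of target vs achieved
#'   values).
#' @export
generate_canonical_pose <- function(structure, motif_residues,
                                    anion_kind = "sulfate",
                                    geometry = canonical_geometry(),
                                    tol_d = 0.15, tol_angle = 10) {
  donors <- motif_donors(structure, motif_residues)
  if (is.null(donors$Calpha_m1)) {
    stop("Calpha(-1) donor has no alpha hydrogen; cannot target it")
  }
  # nearest Halpha to the amide donors is the bridging-relevant one
  h_n0 <- donors$N_0$h[[1]]
  ca_h_idx <- which.min(vapply(donors$Calpha_m1$h,
                               function(h) vnorm(h - h_n0), numeric(1)))
  h_ca <- donors$Calpha_m1$h[[ca_h_idx]]
  x_ca <- donors$Calpha_m1$x
  x_n0 <- donors$N_0$x
  h_n1 <- donors$N_p1$h[[1]]
  x_n1 <- donors$N_p1$x

  anion0 <- build_anion(anion_kind)
  xyz0 <- as.matrix(anion0$atoms[, c("x", "y", "z")])
  o_idx <- grep("^O[0-9]$", anion0$atoms$atom)

  g <- geometry
  pose_xyz <- function(p) {
    R <- rotation_matrix(p[4:6])
    sweep(xyz0 %*% t(R), 2, p[1:3], "+")
  }
  # O1 bridges Calpha(-1)H + N(0)H; O2 serves N(+1)H.  The objective is
  # a smooth minimax (p = 8 norm) of the six tolerance-scaled geometry
  # errors, so a value <= 1 means every constraint is inside tolerance;
  # a soft hinge keeps the two spare oxygens (and the wrong pairings)
  # out of contact range.
  scaled_errors <- function(p) {
    xyz <- pose_xyz(p)
    o1 <- xyz[o_idx[1], ]; o2 <- xyz[o_idx[2], ]
    c(abs(vnorm(o1 - h_ca) - g$d_ca) / tol_d,
      abs(vnorm(o1 - h_n0) - g$d_n0) / tol_d,
      abs(vnorm(o2 - h_n1) - g$d_n1) / tol_d,
      abs(bond_angle(x_ca, h_ca, o1) - g$ang_ca) / tol_angle,
      abs(bond_angle(x_n0, h_n0, o1) - g$ang_n0) / tol_angle,
      abs(bond_angle(x_n1, h_n1, o2) - g$ang_n1) / tol_angle)
  }
  clearance_penalty <- function(p) {
    xyz <- pose_xyz(p)
    o1 <- xyz[o_idx[1], ]; o2 <- xyz[o_idx[2], ]
    pen <- 0
    for (oi in o_idx[3:4]) {
      pen <- pen + max(0, 3.4 - vnorm(xyz[oi, ] - h_ca))^2 +
        max(0, 3.1 - vnorm(xyz[oi, ] - h_n0))^2 +
        max(0, 3.1 - vnorm(xyz[oi, ] - h_n1))^2
    }
    pen + max(0, 3.1 - vnorm(o1 - h_n1))^2 +
      max(0, 3.4 - vnorm(o2 - h_ca))^2 + max(0, 3.1 - vnorm(o2 - h_n0))^2
  }
  objective <- function(p) {
    e <- scaled_errors(p)
    sum(e^8)^(1 / 8) + 2 * clearance_penalty(p)
  }
  # deterministic multi-start about a point just outside the donor face
  centre <- (h_ca + h_n0 + h_n1) / 3
  outward <- vunit(centre - (x_ca + x_n0 + x_n1) / 3)
  t0 <- centre + 1.6 * outward
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  set.seed(20260925L)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  best <- NULL
  for (k in 1:40) {
    p0 <- if (k == 1) c(t0, 0, 0, 0)
          else c(t0 + stats::rnorm(3, 0, 0.6), stats::runif(3, -pi, pi))
    fit <- stats::optim(p0, objective, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-13))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1.0) break  # every constraint inside tolerance
  }
  xyz <- pose_xyz(best$par)
  o1 <- xyz[o_idx[1], ]; o2 <- xyz[o_idx[2], ]
  achieved <- data.frame(
    constraint = c("d_ca", "d_n0", "d_n1", "ang_ca", "ang_n0", "ang_n1"),
    target = c(g$d_ca, g$d_n0, g$d_n1, g$ang_ca, g$ang_n0, g$ang_n1),
    achieved = c(vnorm(o1 - h_ca), vnorm(o1 - h_n0), vnorm(o2 - h_n1),
                 bond_angle(x_ca, h_ca, o1), bond_angle(x_n0, h_n0, o1),
                 bond_angle(x_n1, h_n1, o2)))
  achieved$abs_error <- abs(achieved$achieved - achieved$target)
  is_d <- grepl("^d_", achieved$constraint)
  feasible_needed <- all(c(g$d_ca, g$d_n0, g$d_n1) <= 4)  # near-contact targets
  if (feasible_needed &&
      (any(achieved$abs_error[is_d] > tol_d) ||
       any(achieved$abs_error[!is_d] > tol_angle))) {
    stop(sprintf(paste0("infeasible canonical-pose target set: residual ",
                        "%.3f angstroms / %.1f degrees exceeds tolerance"),
                 max(achieved$abs_error[is_d]),
                 max(achieved$abs_error[!is_d])))
  }
  anion <- anion0
  anion$atoms$x <- xyz[, 1]; anion$atoms$y <- xyz[, 2]
  anion$atoms$z <- xyz[, 3]
  list(structure = structure, anion = anion, achieved = achieved)
}

#' Perturb a base pose into a docking-style conformer ensemble
#'
#' Applies `n` rigid-body perturbations to the anion (Gaussian in
#' translation and in rotation angle about a random axis through the
#' anion centre), reproducibly from a seed.  The peptide is shared
#' across poses, emulating rigid docking.
#'
#' @param base_pose list with `structure` and `anion` (e.g. from
#'   [generate_canonical_pose()]).
#' @param n ensemble size (default 250, the conventional docking run).
#' @param noise `c(sigma_translation, sigma_rotation)` in angstroms and
#'   degrees (defaults 0.03 and 2).
#' @param seed integer seed.
#' @return list of `n` poses (lists with `structure`, `anion`).
#' @export
generate_pose_ensemble <- function(base_pose, n = 250,
                                   noise = c(0.03, 2), seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (any(noise < 0)) stop("noise standard deviations must be >= 0")
  sig_t <- noise[1]
  sig_r <- noise[2] * pi / 180
  xyz0 <- as.matrix(base_pose$anion$atoms[, c("x", "y", "z")])
  ctr <- xyz0[1, ]  # central atom
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  lapply(seq_len(n), function(k) {
    axis <- stats::rnorm(3)
    axis <- if (vnorm(axis) < 1e-9) c(0, 0, 1) else vunit(axis)
    rv <- axis * stats::rnorm(1, 0, sig_r)
    R <- rotation_matrix(rv)
    tr <- stats::rnorm(3, 0, sig_t)
    xyz <- sweep(sweep(xyz0, 2, ctr) %*% t(R), 2, ctr + tr, "+")
    anion <- base_pose$anion
    anion$atoms$x <- xyz[, 1]; anion$atoms$y <- xyz[, 2]
    anion$atoms$z <- xyz[, 3]
    list(structure = base_pose$structure, anion = anion)
  })
}

#' Generate a binding/unbinding switch trajectory
#'
#' Emulates the observed conformational switch: before `unbind_frame`
#' the motif residues hold torsions jittered within the strict
#' right-handed helical window and the anion occupies a (jittered)
#' canonical pose; afterwards the anion departs along a smooth path,
#' the N0 residue is resampled in the PPII window, and the N+1 residue
#' lags in the broad (non-canonical) helical box for `relax_frames`
#' frames before following (emulating the stabilising effect of the
#' neighbouring Aib).  One frame corresponds to 1 ps.
#'
#' @param peptide_id registry id (default CPS224Ac).
#' @param n_frames trajectory length (default 1000).
#' @param unbind_frame last bound frame (default 400).
#' @param relax_frames lag of the N+1 residue (default 100).
#' @param seed integer seed.
#' @param motif_residues three residue numbers (default 2, 3, 4).
#' @param anion_kind `"sulfate"` or `"phosphate"`.
#' @param torsion_sd jitter s.d. of (phi, psi) in degrees (default 4).
#' @param anion_noise rigid-body jitter as in
#'   [generate_pose_ensemble()].
#' @return list of frames (lists with `structure`, `anion`, `time`).
#' @export
generate_switch_trajectory <- function(peptide_id = "CPS224Ac",
                                       n_frames = 1000, unbind_frame = 400,
                                       relax_frames = 100, seed = 1,
                                       motif_residues = c(2, 3, 4),
                                       anion_kind = "sulfate",
                                       torsion_sd = 4,
                                       anion_noise = c(0.03, 2)) {
  if (unbind_frame <= 0 || unbind_frame >= n_frames) {
    stop("need 0 < unbind_frame < n_frames")
  }
  if (!identical(as.integer(motif_residues), 2:4)) {
    stop("the trajectory generator assumes the designed peptides' ",
         "CaNN motif at residues 2-4")
  }
  peptide <- peptide_model(peptide_id)
  n <- length(peptide$residues)
  w <- rama_windows()
  jit_in <- function(centre, sd, lo, hi) {
    pmin(hi, pmax(lo, centre + stats::rnorm(1, 0, sd)))
  }
  helical_pair <- function() c(
    jit_in(-70, torsion_sd, w$helical_R["phi_min"], w$helical_R["phi_max"]),
    jit_in(-57, torsion_sd, w$helical_R["psi_min"], w$helical_R["psi_max"]))
  ppii_pair <- function() c(
    jit_in(-70, torsion_sd, w$ppII["phi_min"], w$ppII["phi_max"]),
    jit_in(150, torsion_sd, w$ppII["psi_min"], w$ppII["psi_max"]))
  nonc_pair <- function() c(
    jit_in(-90, 1.5 * torsion_sd, w$noncanonical_helical["phi_min"],
           w$noncanonical_helical["phi_max"]),
    jit_in(-25, 1.5 * torsion_sd, w$noncanonical_helical["psi_min"],
           w$noncanonical_helical["psi_max"]))

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)

  # Bound-state torsion centres follow the beta-alphaR-alphaR starting
  # conformation of the bound motif: the residue preceding the Calpha
  # donor and the Calpha(-1) residue keep their native (crystal-derived)
  # torsions, while the N0/N+1 residues sit at the strict helical-window
  # centre; the anchor helix stays at its designed torsions.
  native <- native_motif_dihedrals(peptide_id)
  centres_phi <- c(native[1:2, "phi"], -70, -70, rep(HELIX_PHI, n - 4))
  centres_psi <- c(native[1:2, "psi"], -57, -57, rep(HELIX_PSI, n - 4))

  # base bound conformation and canonical pose, used as the rigid
  # reference for re-anchoring the anion frame by frame
  base_d <- backbone_dihedral_set(centres_phi, centres_psi)
  base_s <- build_backbone(peptide, base_d)
  # the base pose is deterministic in (peptide, anion); memoise it
  cache_key <- paste(peptide_id, anion_kind, sep = "|")
  if (is.null(.pose_cache[[cache_key]])) {
    .pose_cache[[cache_key]] <- generate_canonical_pose(
      base_s, motif_residues, anion_kind = anion_kind)
  }
  base_pose <- .pose_cache[[cache_key]]
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  anchor_names <- anchor_atoms(base_s, motif_residues)
  base_anchor <- anchor_coords(base_s, anchor_names)
  base_axyz <- as.matrix(base_pose$anion$atoms[, c("x", "y", "z")])
  escape_dir <- NULL

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    bound <- f <= unbind_frame
    phi <- numeric(n); psi <- numeric(n)
    for (i in seq_len(n)) {
      if (i <= 2) {
        # pre-motif + Calpha(-1) residues hold their native torsions
        phi[i] <- centres_phi[i] + stats::rnorm(1, 0, torsion_sd / 2)
        psi[i] <- centres_psi[i] + stats::rnorm(1, 0, torsion_sd / 2)
      } else if (i > 4) {
        phi[i] <- centres_phi[i] + stats::rnorm(1, 0, torsion_sd / 2)
        psi[i] <- centres_psi[i] + stats::rnorm(1, 0, torsion_sd / 2)
      } else if (bound) {
        p <- helical_pair(); phi[i] <- p[1]; psi[i] <- p[2]
      } else if (i == motif_residues[3] && f <= unbind_frame + relax_frames) {
        p <- nonc_pair(); phi[i] <- p[1]; psi[i] <- p[2]
      } else {
        p <- ppii_pair(); phi[i] <- p[1]; psi[i] <- p[2]
      }
    }
    s <- build_backbone(peptide, backbone_dihedral_set(phi, psi))
    tr <- kabsch_transform(base_anchor, anchor_coords(s, anchor_names))
    axyz <- tr(base_axyz)
    # rigid jitter about the anchored pose
    axis <- stats::rnorm(3); axis <- vunit(axis)
    rv <- axis * stats::rnorm(1, 0, anion_noise[2] * pi / 180)
    ctr <- axyz[1, ]
    axyz <- sweep(sweep(axyz, 2, ctr) %*% t(rotation_matrix(rv)), 2,
                  ctr + stats::rnorm(3, 0, anion_noise[1]), "+")
    if (!bound) {
      if (is.null(escape_dir)) {
        mot_ctr <- colMeans(anchor_coords(s, anchor_names))
        escape_dir <- vunit(axyz[1, ] - mot_ctr)
      }
      axyz <- sweep(axyz, 2,
                    escape_dir * (1.5 + 0.5 * (f - unbind_frame)), "+")
    }
    anion <- base_pose$anion
    anion$atoms$x <- axyz[, 1]; anion$atoms$y <- axyz[, 2]
    anion$atoms$z <- axyz[, 3]
    frames[[f]] <- list(structure = s, anion = anion, time = f)
  }
  frames
}

# Donor-region atoms used to re-anchor the anion (X and H of the three
# motif donors).
anchor_atoms <- function(structure, motif_residues) {
  r <- motif_residues
  ha <- intersect(c("HA", "HA2"),
                  structure$atoms$atom[structure$atoms$resno == r[1]])[1]
  rbind(c(r[1], "CA"), c(r[1], ha),
        c(r[2], "N"), c(r[2], "H"),
        c(r[3], "N"), c(r[3], "H"))
}

anchor_coords <- function(structure, anchor) {
  t(apply(anchor, 1, function(a)
    atom_xyz(structure, as.integer(a[1]), a[2])))
}

#' Write generated frames to disk with a provenance sidecar
#'
#' @param frames list of poses/frames (lists with `structure`,
#'   `anion`).
#' @param path output multi-model PDB path.
#' @param params list of generator parameters recorded in a JSON
#'   sidecar next to the PDB.
#' @return `path`, invisibly.
#' @export
write_pose_set <- function(frames, path, params = list()) {
  structs <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]
    if (is.null(fr$anion)) fr$structure
    else pose_structure(fr$structure, fr$anion, model_id = i)
  })
  write_pdb(structs, path)
  if (length(params)) {
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
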