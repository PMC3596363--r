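# Backbone model construction from per-residue torsions.
#
# Chains are extended atom by atom with internal-coordinate (NeRF-style)
# placement using fixed ideal bond lengths and angles (Engh-Huber-style
# values).  Torsion inputs are recovered exactly (to numerical precision)
# when re-measured from the coordinates.

IDEAL <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_n_h = 1.01, b_ca_ha = 1.09, b_ca_cb = 1.521, b_ch3_c = 1.508,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_c_o = 122.7, a_c_n_h = 119.3,
  a_n_ca_cb = 110.5, a_n_ca_ha = 109.0, a_ch3_c_n = 116.2
)

# Chirality offsets about the C(i-1)->N-CA torsion, relative to the
# placement torsion of C (= phi).  Frozen from a CORN-rule construction
# cross-checked against an L-alanine reference geometry: CB at phi - 120,
# HA at phi + 120 gives L-amino acids (improper N-C-CA-CB = +120).
CB_OFFSET <- -120
HA_OFFSET <- +120

#' Per-residue backbone dihedrals container
#'
#' @param phi,psi numeric vectors (degrees) of equal length; `NA` marks
#'   an undefined terminal torsion.
#' @param omega peptide-bond torsion preceding each residue; defaults to
#'   180 (trans) everywhere.
#' @param resno residue numbers (defaults to 1..n).
#' @return a `cann_dihedrals` data frame with columns `resno`, `phi`,
#'   `psi`, `omega`, all wrapped onto `(-180, 180]`.
#' @export
backbone_dihedral_set <- function(phi, psi, omega = NULL,
                                  resno = seq_along(phi)) {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(omega)) omega <- rep(180, n)
  d <- data.frame(resno = resno, phi = wrap_angle(phi),
                  psi = wrap_angle(psi), omega = wrap_angle(omega))
  class(d) <- c("cann_dihedrals", "data.frame")
  d
}

#' Build a peptide backbone from sequence plus torsions
#'
#' Extends the chain sequentially with ideal bond geometry.  Amide
#' hydrogens are placed on every non-proline nitrogen, Halpha on Calpha
#' (two for Gly, none for Aib whose two methyl carbons are placed
#' instead), and Cbeta for all other residues; side chains beyond Cbeta
#' are not built, since the motif's anion contacts use backbone atoms
#' only.  An N-acetyl cap (residue ACE, resno 0) defines phi of residue
#' 1 and a C-amide cap (residue NH2) defines psi of the last residue.
#'
#' @param peptide a `cann_peptide` (see [peptide_model()]).
#' @param dihedrals a `cann_dihedrals` with one row per residue.
#' @return a [cann_structure].
#' @export
build_backbone <- function(peptide, dihedrals) {
  n <- length(peptide$residues)
  if (nrow(dihedrals) != n) {
    stop("dihedrals must have one row per residue (",
         n, " residues, ", nrow(dihedrals), " rows)")
  }
  phi <- dihedrals$phi
  psi <- dihedrals$psi
  omg <- dihedrals$omega
  omg[is.na(omg)] <- 180
  acetyl <- peptide$n_cap == "acetyl"
  amide <- peptide$c_cap == "amide"
  if (!acetyl && !is.na(phi[1])) phi[1] <- NA  # undefined without cap
  if (!amide && !is.na(psi[n])) psi[n] <- NA
  for (i in seq_len(n)) {
    if (i > 1 || acetyl) {
      if (is.na(phi[i])) stop("undefined phi for residue ", i)
    }
    if (i < n || amide) {
      if (is.na(psi[i])) stop("undefined psi for residue ", i)
    }
  }

  n_est <- 8L * n + 8L
  A_atom <- character(n_est); A_resno <- integer(n_est)
  A_resid <- character(n_est); A_xyz <- matrix(0, n_est, 3)
  n_at <- 0L
  add <- function(atom, resno, resid, xyz) {
    n_at <<- n_at + 1L
    A_atom[n_at] <<- atom
    A_resno[n_at] <<- as.integer(resno)
    A_resid[n_at] <<- resid
    A_xyz[n_at, ] <<- xyz
  }

  deg <- pi / 180
  # seed the chain
  if (acetyl) {
    ch3 <- c(0, 0, 0)
    c_prev <- c(IDEAL$b_ch3_c, 0, 0)
    nn <- c_prev + IDEAL$b_c_n *
      c(-cos(IDEAL$a_ch3_c_n * deg), sin(IDEAL$a_ch3_c_n * deg), 0)
    add("CH3", 0L, "ACE", ch3)
    add("C", 0L, "ACE", c_prev)
    prev2 <- ch3        # atom before c_prev, for torsion frames
  } else {
    nn <- c(0, 0, 0)
    c_prev <- NULL
    prev2 <- NULL
  }

  ca_prev <- NULL
  o_ace_pending <- acetyl
  for (i in seq_len(n)) {
    code <- peptide$residues[i]
    if (i == 1 && !acetyl) {
      ca <- nn + c(IDEAL$b_n_ca, 0, 0)
      cc <- place_atom(nn + c(0, 1, 0), nn, ca,
                       IDEAL$b_ca_c, IDEAL$a_n_ca_c, 90)
      add("N", i, code, nn)
      add("CA", i, code, ca)
    } else {
      # CA via the omega torsion, amide H opposite it in the peptide plane
      ca <- place_atom(prev2, c_prev, nn, IDEAL$b_n_ca,
                       IDEAL$a_c_n_ca, omg[i])
      add("N", i, code, nn)
      if (code != "PRO") {
        h <- place_atom(prev2, c_prev, nn, IDEAL$b_n_h, IDEAL$a_c_n_h,
                        wrap_angle(omg[i] + 180))
        add("H", i, code, h)
      }
      add("CA", i, code, ca)
      if (o_ace_pending) {
        # acetyl carbonyl O: planar trans amide, cis to CA across C-N
        o_ace <- place_atom(ca, nn, c_prev, IDEAL$b_c_o, IDEAL$a_n_c_o, 0)
        add("O", 0L, "ACE", o_ace)
        o_ace_pending <- FALSE
      }
      cc <- place_atom(c_prev, nn, ca, IDEAL$b_ca_c, IDEAL$a_n_ca_c, phi[i])
    }
    # Calpha substituents (need the phi frame; for a free N-terminus use
    # a surrogate frame atom so geometry stays defined)
    frame_a <- if (i == 1 && !acetyl) nn + c(0, 1, 0) else c_prev
    tau_c <- if (i == 1 && !acetyl) 90 else phi[i]
    if (code == "GLY") {
      add("HA2", i, code,
          place_atom(frame_a, nn, ca, IDEAL$b_ca_ha, IDEAL$a_n_ca_ha,
                     wrap_angle(tau_c + HA_OFFSET)))
      add("HA3", i, code,
          place_atom(frame_a, nn, ca, IDEAL$b_ca_ha, IDEAL$a_n_ca_ha,
                     wrap_angle(tau_c + CB_OFFSET)))
    } else if (code == "AIB") {
      add("CB1", i, code,
          place_atom(frame_a, nn, ca, IDEAL$b_ca_cb, IDEAL$a_n_ca_cb,
                     wrap_angle(tau_c + CB_OFFSET)))
      add("CB2", i, code,
          place_atom(frame_a, nn, ca, IDEAL$b_ca_cb, IDEAL$a_n_ca_cb,
                     wrap_angle(tau_c + HA_OFFSET)))
    } else {
      add("HA", i, code,
          place_atom(frame_a, nn, ca, IDEAL$b_ca_ha, IDEAL$a_n_ca_ha,
                     wrap_angle(tau_c + HA_OFFSET)))
      add("CB", i, code,
          place_atom(frame_a, nn, ca, IDEAL$b_ca_cb, IDEAL$a_n_ca_cb,
                     wrap_angle(tau_c + CB_OFFSET)))
    }
    add("C", i, code, cc)

    if (i < n || amide) {
      n_next <- place_atom(nn, ca, cc, IDEAL$b_c_n, IDEAL$a_ca_c_n, psi[i])
      oo <- place_atom(nn, ca, cc, IDEAL$b_c_o, IDEAL$a_ca_c_o,
                       wrap_angle(psi[i] + 180))
      add("O", i, code, oo)
      prev2 <- ca_prev2_for_next <- ca
      c_prev <- cc
      ca_prev <- ca
      nn <- n_next
    } else {
      # free C-terminus: carbonyl O + OXT in an arbitrary planar frame
      oo <- place_atom(nn, ca, cc, IDEAL$b_c_o, IDEAL$a_ca_c_o, 0)
      oxt <- place_atom(nn, ca, cc, IDEAL$b_c_o, IDEAL$a_ca_c_o, 180)
      add("O", i, code, oo)
      add("OXT", i, code, oxt)
    }
  }

  if (amide) {
    # cap nitrogen is the nn produced by psi of the last residue
    cap_no <- n + 1L
    add("N", cap_no, "NH2", nn)
    h1 <- place_atom(ca_prev, c_prev, nn, IDEAL$b_n_h, IDEAL$a_c_n_h, 0)
    h2 <- place_atom(ca_prev, c_prev, nn, IDEAL$b_n_h, IDEAL$a_c_n_h, 180)
    add("HN1", cap_no, "NH2", h1)
    add("HN2", cap_no, "NH2", h2)
  }

  idx <- seq_len(n_at)
  atoms <- data.frame(atom = A_atom[idx], resno = A_resno[idx],
                      resid = A_resid[idx], x = A_xyz[idx, 1],
                      y = A_xyz[idx, 2], z = A_xyz[idx, 3],
                      stringsAsFactors = FALSE)
  cann_structure(atoms, model_id = 1L)
}

#' Build one of the designed model structures
#'
#' The `native` variant uses the crystal-derived motif torsions for
#' residues 1-4 and the designed right-handed helix (phi = -57, psi =
#' -47) for residues 5-18; `extended` replaces the motif torsions with
#' (180, 180); `experimental_like` takes user-supplied torsions for the
#' first four residues (a stand-in for NMR-derived coordinates that are
#' not tabulated).  For the 5-residue `S`-prefixed ids the corresponding
#' 18-residue model is built and truncated.
#'
#' @param peptide_id one of the six designed peptide ids.
#' @param variant `"native"`, `"extended"` or `"experimental_like"`.
#' @param motif_dihedrals 4 x 2 matrix (phi, psi) for
#'   `experimental_like`.
#' @return a [cann_structure].
#' @export
make_model <- function(peptide_id,
                       variant = c("native", "extended", "experimental_like"),
                       motif_dihedrals = NULL) {
  variant <- match.arg(variant)
  short <- grepl("^S", peptide_id)
  base_id <- sub("^S", "", peptide_id)
  peptide <- peptide_model(base_id)
  n <- length(peptide$residues)
  motif <- switch(variant,
    native = native_motif_dihedrals(base_id),
    extended = cbind(phi = rep(180, 4), psi = rep(180, 4)),
    experimental_like = {
      if (is.null(motif_dihedrals) ||
          !all(dim(as.matrix(motif_dihedrals)) == c(4, 2))) {
        stop("experimental_like requires a 4 x 2 (phi, psi) matrix")
      }
      m <- as.matrix(motif_dihedrals)
      colnames(m) <- c("phi", "psi")
      m
    })
  d <- backbone_dihedral_set(
    phi = c(motif[, "phi"], rep(HELIX_PHI, n - 4)),
    psi = c(motif[, "psi"], rep(HELIX_PSI, n - 4)))
  s <- build_backbone(peptide, d)
  if (short) s <- truncate_to_short(s, peptide)$structure
  s
}

#' Truncate an 18-residue model to its 5-residue short analogue
#'
#' Keeps residues 1-5 (and the N-acetyl cap) with coordinates unchanged
#' and converts residue 6's amide nitrogen into the C-amide cap, so the
#' kept atoms are exactly those of the parent model.
#'
#' @param structure a built [cann_structure] of the parent peptide.
#' @param peptide the parent `cann_peptide` (>= 5 residues).
#' @return list with the truncated `structure` and short `peptide`.
#' @export
truncate_to_short <- function(structure, peptide) {
  n <- length(peptide$residues)
  if (n < 5) stop("peptide must have at least 5 residues to truncate")
  a <- structure$atoms
  keep <- a[a$resno <= 5 & !(a$resid %in% ANION_RESIDUES), , drop = FALSE]
  # residue 5 keeps its carbonyl O; its psi is now defined by the cap N
  if (n > 5) {
    n6 <- a[a$resno == 6 & a$atom == "N", , drop = FALSE]
    h6 <- a[a$resno == 6 & a$atom == "H", , drop = FALSE]
    if (nrow(n6) != 1L) stop("parent structure lacks residue 6 N")
    cap <- rbind(n6, h6)
    cap$resid <- "NH2"
    cap$resno <- 6L
    cap$atom <- c("N", if (nrow(h6)) "HN1")
    # second cap hydrogen sits where CA of residue 6 pointed
    ca6 <- a[a$resno == 6 & a$atom == "CA", , drop = FALSE]
    if (nrow(ca6) == 1L) {
      nxyz <- as.numeric(n6[, c("x", "y", "z")])
      dir <- vunit(as.numeric(ca6[, c("x", "y", "z")]) - nxyz)
      h2 <- nxyz + IDEAL$b_n_h * dir
      cap <- rbind(cap, within(n6, {
        atom <- "HN2"; resid <- "NH2"; resno <- 6L
        x <- h2[1]; y <- h2[2]; z <- h2[3]; element <- "H"
      })[, names(cap)])
    }
    keep <- rbind(keep, cap)
  }
  keep$serial <- seq_len(nrow(keep))
  short_id <- if (grepl("^S", peptide$id)) peptide$id else paste0("S", peptide$id)
  list(structure = cann_structure(keep, model_id = structure$model_id),
       peptide = new_peptide(short_id, peptide$residues[1:5],
                             n_cap = peptide$n_cap, c_cap = "amide"))
}
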