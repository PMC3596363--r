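test_that("backbone_dihedrals recovers builder inputs and known table rows", {
  d <- backbone_dihedrals(make_model("CPS228", "native"))
  expect_equal(d$phi[3], -63.0, tolerance = 0.5)  # Gly3 of CPS228
  expect_equal(d$psi[3], -56.2, tolerance = 0.5)
  expect_equal(d$phi[2], -95.1, tolerance = 0.5)
})

test_that("mirrored structures negate every measured torsion", {
  s <- make_model("CPS226", "native")
  d <- backbone_dihedrals(s)
  m <- cannmotif:::transform_structure(s, function(x) {
    x[, 1] <- -x[, 1]; x
  })
  dm <- backbone_dihedrals(m)
  expect_lt(max(angle_diff(dm$phi, -d$phi)), 1e-6)
  expect_lt(max(angle_diff(dm$psi, -d$psi)), 1e-6)
})

test_that("missing backbone atoms are reported by residue and atom", {
  s <- make_model("SCPS226", "native")
  s$atoms <- s$atoms[!(s$atoms$resno == 3 & s$atoms$atom == "CA"), ]
  expect_error(backbone_dihedrals(s), "CA of residue 3")
})

test_that("classify_state reproduces the window centres and boundaries", {
  expect_equal(classify_state(-70, -57), "helical_R")
  expect_equal(classify_state(-70, 150), "ppII")
  expect_equal(classify_state(0, 0), "other")
  # broad box minus strict window
  expect_equal(classify_state(-100, -20), "noncanonical_helical")
  expect_equal(classify_state(-70, -30), "noncanonical_helical")
  # boundaries inclusive, specific region wins
  expect_equal(classify_state(-85, -69), "helical_R")
  expect_equal(classify_state(-55, -45), "helical_R")
  expect_equal(classify_state(-85, 130), "ppII")
})

test_that("classify_state is total and regions are mutually exclusive", {
  set.seed(616)
  phi <- stats::runif(500, -180, 180)
  psi <- stats::runif(500, -180, 180)
  lab <- classify_state(phi, psi)
  expect_true(all(lab %in% c("helical_R", "ppII", "noncanonical_helical",
                             "other")))
  # strict helical window is carved out of the broad box
  w <- rama_windows()
  in_strict <- phi >= w$helical_R["phi_min"] & phi <= w$helical_R["phi_max"] &
    psi >= w$helical_R["psi_min"] & psi <= w$helical_R["psi_max"]
  expect_true(all(lab[in_strict] == "helical_R"))
  expect_true(!any(lab[!in_strict] == "helical_R"))
})

test_that("NH-NH distances separate helix from extended chain", {
  p <- new_peptide("hex", rep("ALA", 8))
  helix <- build_backbone(p, backbone_dihedral_set(rep(-57, 8), rep(-47, 8)))
  nh <- nh_nh_distances(helix)
  expect_equal(nrow(nh), 7)
  expect_true(all(nh$distance < 4))
  expect_true(all(nh$helical))
  ext <- build_backbone(p, backbone_dihedral_set(rep(180, 8), rep(180, 8)))
  nhe <- nh_nh_distances(ext)
  expect_true(all(nhe$distance > 4))
  expect_false(any(nhe$helical))
})

test_that("single-residue structures yield an empty NH-NH list", {
  p <- new_peptide("mono", "ALA")
  s <- build_backbone(p, backbone_dihedral_set(-57, -47))
  expect_equal(nrow(nh_nh_distances(s)), 0)
})

test_that("residence detection handles always-bound and never-bound cases", {
  run <- cannmotif:::residence_run
  expect_equal(run(rep(TRUE, 50), 10), 50L)
  expect_equal(run(rep(FALSE, 50), 10), 0L)
  # short gaps are tolerated, long gaps end the episode
  b <- rep(TRUE, 100); b[40:44] <- FALSE
  expect_equal(run(b, 10), 100L)
  b2 <- c(rep(TRUE, 30), rep(FALSE, 15), rep(TRUE, 55))
  expect_equal(run(b2, 10), 30L)
})

test_that("analyze_trajectory reports residence and state flip on a tiny synthetic run", {
  frames <- generate_switch_trajectory("CPS224Ac", n_frames = 120,
                                       unbind_frame = 50,
                                       relax_frames = 20, seed = 5)
  res <- analyze_trajectory(frames, c(2, 3, 4))
  expect_equal(res$residence_frames, 50, tolerance = 10)
  tr <- res$transition
  expect_gte(tr$frac_helical_before[tr$resno == 3], 0.9)
  expect_lte(tr$frac_helical_after[tr$resno == 3], 0.1)
  expect_error(analyze_trajectory(frames[1], c(2, 3, 4)), "at least 2")
})

test_that("trajectory with the anion far away has zero residence", {
  frames <- generate_switch_trajectory("CPS224Ac", n_frames = 40,
                                       unbind_frame = 20, seed = 6)
  far <- lapply(frames, function(f) {
    f$anion <- cannmotif:::transform_anion(f$anion, function(x) x + 50)
    f
  })
  res <- analyze_trajectory(far, c(2, 3, 4))
  expect_equal(res$residence_frames, 0L)
})

test_that("trajectory reports are written to disk", {
  frames <- generate_switch_trajectory("CPS224Ac", n_frames = 30,
                                       unbind_frame = 12, seed = 8)
  res <- analyze_trajectory(frames, c(2, 3, 4))
  pref <- withr::local_tempfile()
  paths <- write_trajectory_report(res, pref)
  expect_true(all(file.exists(paths)))
  parsed <- jsonlite::read_json(paths[4])
  expect_equal(parsed$residence_frames, res$residence_frames)
})
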