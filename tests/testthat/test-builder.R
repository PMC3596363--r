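test_that("native CPS224Ac model recovers the tabulated motif torsions", {
  d <- backbone_dihedrals(native_model())
  expect_equal(d$phi[3], -63.7, tolerance = 0.5)  # Lys3
  expect_equal(d$psi[3], -45.1, tolerance = 0.5)
  expect_equal(d$phi[1], -89.1, tolerance = 0.5)  # Leu1
  expect_equal(d$psi[2], 126.7, tolerance = 0.5)  # Gly2
  expect_equal(d$phi[4], -59.2, tolerance = 0.5)  # Gln4
})

test_that("native CPS226 model recovers its motif torsions", {
  d <- backbone_dihedrals(make_model("CPS226", "native"))
  expect_equal(d$psi[3], -35.0, tolerance = 0.5)  # Ala3
  expect_equal(d$phi[2], -97.3, tolerance = 0.5)  # Ser2
})

test_that("anchor-helix residues measure (-57, -47)", {
  d <- backbone_dihedrals(native_model())
  for (i in 5:17) {   # psi of residue 18 defined by the amide cap too
    expect_equal(d$phi[i], -57, tolerance = 0.5)
    expect_equal(d$psi[i], -47, tolerance = 0.5)
  }
  expect_equal(d$psi[18], -47, tolerance = 0.5)
})

test_that("extended model puts residues 1-4 at (180, 180)", {
  d <- backbone_dihedrals(make_model("CPS224Ac", "extended"))
  for (i in 1:4) {
    expect_lt(angle_diff(d$phi[i], 180), 0.5)
    expect_lt(angle_diff(d$psi[i], 180), 0.5)
  }
  # native and extended differ only in the motif torsions
  dn <- backbone_dihedrals(native_model())
  expect_equal(d$phi[5:18], dn$phi[5:18], tolerance = 1e-6)
  expect_equal(d$psi[5:18], dn$psi[5:18], tolerance = 1e-6)
})

test_that("build-then-measure recovers random torsion sets within 0.5 deg", {
  set.seed(515)
  p <- new_peptide("rnd", c("ALA", "GLY", "LYS", "AIB", "SER", "LEU"))
  for (k in 1:8) {
    phi <- stats::runif(6, -179.9, 180)
    psi <- stats::runif(6, -179.9, 180)
    s <- build_backbone(p, backbone_dihedral_set(phi, psi))
    d <- backbone_dihedrals(s)
    expect_lt(max(angle_diff(d$phi, phi)), 0.5)
    expect_lt(max(angle_diff(d$psi, psi)), 0.5)
    expect_lt(max(angle_diff(d$omega, 180)), 0.5)
  }
})

test_that("two-residue chain at (180, 180) has the ideal Calpha-Calpha distance", {
  p <- new_peptide("dip", c("ALA", "ALA"))
  s <- build_backbone(p, backbone_dihedral_set(c(180, 180), c(180, 180)))
  d <- sqrt(sum((atom_xyz(s, 1, "CA") - atom_xyz(s, 2, "CA"))^2))
  expect_equal(d, 3.80, tolerance = 0.05 / 3.80)
})

test_that("built helices are right-handed and L-chiral", {
  p <- new_peptide("helix", rep("ALA", 8))
  s <- build_backbone(p, backbone_dihedral_set(rep(-57, 8), rep(-47, 8)))
  # consecutive Calpha-triad torsion is positive for a right-handed helix
  ca <- lapply(1:8, function(i) atom_xyz(s, i, "CA"))
  for (i in 1:5) {
    tw <- dihedral_angle(ca[[i]], ca[[i + 1]], ca[[i + 2]], ca[[i + 3]])
    expect_gt(tw, 0)
  }
  # L chirality: improper N-C-CA-CB near +120
  imp <- dihedral_angle(atom_xyz(s, 4, "N"), atom_xyz(s, 4, "C"),
                        atom_xyz(s, 4, "CA"), atom_xyz(s, 4, "CB"))
  expect_equal(imp, 120, tolerance = 6)
})

test_that("all covalent bond lengths sit within 0.02 A of ideal", {
  s <- native_model()
  ideal <- cannmotif:::IDEAL
  for (i in 1:17) {
    expect_equal(sqrt(sum((atom_xyz(s, i, "N") - atom_xyz(s, i, "CA"))^2)),
                 ideal$b_n_ca, tolerance = 0.02)
    expect_equal(sqrt(sum((atom_xyz(s, i, "CA") - atom_xyz(s, i, "C"))^2)),
                 ideal$b_ca_c, tolerance = 0.02)
    expect_equal(sqrt(sum((atom_xyz(s, i, "C") - atom_xyz(s, i + 1, "N"))^2)),
                 ideal$b_c_n, tolerance = 0.02)
    expect_equal(sqrt(sum((atom_xyz(s, i, "C") - atom_xyz(s, i, "O"))^2)),
                 ideal$b_c_o, tolerance = 0.02)
  }
})

test_that("residue content follows the sequence rules", {
  s <- native_model()
  a <- s$atoms
  # Gly2 has two alpha hydrogens, no CB
  expect_setequal(intersect(c("HA", "HA2", "HA3", "CB", "CB1", "CB2"),
                            a$atom[a$resno == 2]), c("HA2", "HA3"))
  # Aib6 has two methyl carbons and no alpha hydrogen
  expect_setequal(intersect(c("HA", "HA2", "HA3", "CB", "CB1", "CB2"),
                            a$atom[a$resno == 6]), c("CB1", "CB2"))
  # standard residues carry one HA and one CB
  expect_setequal(intersect(c("HA", "CB"), a$atom[a$resno == 3]),
                  c("HA", "CB"))
  # caps present
  expect_true(all(c("CH3", "C", "O") %in% a$atom[a$resid == "ACE"]))
  expect_true(all(c("N", "HN1", "HN2") %in% a$atom[a$resid == "NH2"]))
})

test_that("undefined required torsions and unknown residues are rejected", {
  p <- new_peptide("bad", c("ALA", "ALA"))
  expect_error(build_backbone(p, backbone_dihedral_set(c(NA, 180),
                                                       c(180, 180))),
               "undefined phi")
  expect_error(new_peptide("bad2", c("ALA", "XXX")), "unknown residue")
})

test_that("truncation keeps residues 1-5 unchanged and caps the C-terminus", {
  parent <- native_model()
  tr <- truncate_to_short(parent, peptide_model("CPS224Ac"))
  s5 <- tr$structure
  expect_equal(cannmotif:::peptide_resnos(s5), 1:5)
  expect_identical(tr$peptide$residues, c("LEU", "GLY", "LYS", "GLN", "ALA"))
  # kept atoms coincide with the parent's
  for (i in 1:5) {
    expect_equal(atom_xyz(s5, i, "CA"), atom_xyz(parent, i, "CA"))
    expect_equal(atom_xyz(s5, i, "C"), atom_xyz(parent, i, "C"))
  }
  # C-amide cap defines psi of residue 5
  d <- backbone_dihedrals(s5)
  expect_false(is.na(d$psi[5]))
  expect_error(truncate_to_short(
    build_backbone(new_peptide("tet", rep("ALA", 4)),
                   backbone_dihedral_set(rep(-57, 4), rep(-47, 4))),
    new_peptide("tet", rep("ALA", 4))), "at least 5")
})

test_that("S-prefixed model ids build truncated models directly", {
  s <- make_model("SCPS226", "native")
  expect_equal(cannmotif:::peptide_resnos(s), 1:5)
  d <- backbone_dihedrals(s)
  expect_equal(d$phi[3], -67.7, tolerance = 0.5)
  expect_error(make_model("BADID", "native"), "unknown peptide id")
})

test_that("ideal anions have exact tetrahedral geometry", {
  su <- build_anion("sulfate")
  oo <- cannmotif:::anion_oxygen_xyz(su)
  ctr <- cannmotif:::anion_central_xyz(su)
  for (i in 1:4) {
    expect_equal(sqrt(sum((oo[i, ] - ctr)^2)), 1.49, tolerance = 0.001)
  }
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(bond_angle(oo[i, ], ctr, oo[j, ]), 109.47, tolerance = 0.1)
  }
  # oxygen centroid coincides with the central atom
  expect_lt(sqrt(sum((colMeans(oo) - ctr)^2)), 1e-6)

  ph <- build_anion("phosphate")
  expect_equal(sum(ph$atoms$element == "H"), 1)
  po <- cannmotif:::anion_oxygen_xyz(ph)
  expect_equal(unname(sqrt(rowSums(sweep(po, 2,
    cannmotif:::anion_central_xyz(ph))^2))), rep(1.54, 4), tolerance = 0.001)
  expect_error(build_anion("nitrate"))
})
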