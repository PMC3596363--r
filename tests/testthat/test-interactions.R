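test_that("detect_hbond accepts the tabulated NMR-row N-donor geometry", {
  g <- hbond_probe(1.71, 160.03)
  hb <- detect_hbond(g$x, g$h, g$o, "N")
  expect_false(is.null(hb))
  expect_equal(hb$d_ho, 1.71, tolerance = 1e-9)
  expect_equal(hb$angle_xho, 160.03, tolerance = 1e-9)
})

test_that("detect_hbond applies donor-kind cutoffs inclusively", {
  # angle just below 90 fails
  g <- hbond_probe(1.9, 89.9)
  expect_null(detect_hbond(g$x, g$h, g$o, "N"))
  # angle exactly 90 passes
  g <- hbond_probe(1.9, 90)
  expect_false(is.null(detect_hbond(g$x, g$h, g$o, "N")))
  # Calpha: 3.0 exactly passes, 3.5 fails
  g <- hbond_probe(3.0, 150, d_xh = 1.09)
  expect_false(is.null(detect_hbond(g$x, g$h, g$o, "Calpha")))
  g <- hbond_probe(3.5, 150, d_xh = 1.09)
  expect_null(detect_hbond(g$x, g$h, g$o, "Calpha"))
  # N donors are tighter: 3.0 fails at 2.7 default, passes at 3.0 config
  g <- hbond_probe(3.0, 150)
  expect_null(detect_hbond(g$x, g$h, g$o, "N"))
  expect_false(is.null(detect_hbond(g$x, g$h, g$o, "N",
                                    cutoffs = hbond_cutoffs(d_n = 3.0))))
})

test_that("detect_hbond checks the covalent precondition", {
  g <- hbond_probe(1.9, 160, d_xh = 1.5)
  expect_error(detect_hbond(g$x, g$h, g$o, "N"), "not covalently bonded")
})

test_that("hbond_energy equals the hand-evaluated Coulomb sum", {
  # collinear S=O...H-N: r_OH 1.9, r_SH 3.39, r_ON 2.91, r_SN 4.40
  n <- c(-1.01, 0, 0); h <- c(0, 0, 0)
  o <- c(1.9, 0, 0); s <- c(3.39, 0, 0)
  expect_equal(hbond_energy("N", s, o, h, n),
               oracle_coulomb(1.6, -0.9, 0.3, -0.5, 3.39, 4.40, 1.9, 2.91),
               tolerance = 1e-12)
  # Calpha variant with its own charges
  expect_equal(hbond_energy("Calpha", s, o, h, n),
               oracle_coulomb(1.6, -0.9, 0.06, -0.1, 3.39, 4.40, 1.9, 2.91),
               tolerance = 1e-12)
})

test_that("hbond_energy is 1/r homogeneous and vanishes at infinity", {
  n <- c(-1.01, 0.2, 0); h <- c(0, 0, 0); o <- c(1.7, 0.5, 0.3)
  s <- c(3.1, 0.4, 0.4)
  e1 <- hbond_energy("N", s, o, h, n)
  e2 <- hbond_energy("N", 2 * s, 2 * o, 2 * h, 2 * n)
  expect_equal(e2, e1 / 2, tolerance = 1e-12)
  far <- hbond_energy("N", s * 1e6, o * 1e6, h * 1e6, n * 1e6 + 1)
  expect_lt(abs(far), 1e-4)
  expect_error(hbond_energy("N", h, o, h, n), "singular")
})

test_that("classify_energy partitions the line with inclusive boundaries", {
  expect_equal(classify_energy(-0.7), "weak")
  expect_equal(classify_energy(-1.0), "strong")
  expect_equal(classify_energy(-0.5), "weak")
  expect_equal(classify_energy(0), "none")
  expect_equal(classify_energy(-5), "strong")
  # exactly one label everywhere on a dense grid
  grid <- seq(-3, 1, by = 0.001)
  lab <- classify_energy(grid)
  expect_true(all(lab %in% c("strong", "weak", "none")))
  expect_error(classify_energy(Inf))
})

test_that("canonical-pattern predicate matches exhaustive enumeration", {
  donors <- c("Calpha_m1", "N_0", "N_p1")
  subsets <- lapply(0:7, function(m)
    donors[c(bitwAnd(m, 1) > 0, bitwAnd(m, 2) > 0, bitwAnd(m, 4) > 0)])
  count <- 0
  for (a in 1:8) for (b in 1:8) for (cc in 1:8) for (d in 1:8) {
    sets <- list(O1 = subsets[[a]], O2 = subsets[[b]],
                 O3 = subsets[[cc]], O4 = subsets[[d]])
    oxygen_map <- Filter(length, sets)
    got <- cannmotif:::canonical_pattern(oxygen_map)
    want <- oracle_canonical(sets)
    if (got != want) count <- count + 1
  }
  expect_equal(count, 0)
})

test_that("map_anion_contacts flags the generated canonical pose", {
  pose <- native_pose()
  mi <- map_anion_contacts(pose$structure, pose$anion, c(2, 3, 4))
  expect_true(mi$canonical)
  expect_equal(mi$n_interacting_oxygens, 2)
  expect_equal(length(mi$oxygen_map), 2)
  # all three donors appear; the bridging oxygen carries two contacts
  expect_setequal(unique(mi$contacts$donor), c("Calpha_m1", "N_0", "N_p1"))
  sizes <- sort(vapply(mi$oxygen_map, length, 0L))
  expect_equal(unname(sizes), c(1L, 2L))
})

test_that("a distant anion yields zero contacts", {
  pose <- native_pose()
  far <- cannmotif:::transform_anion(pose$anion, function(x) x + 20)
  mi <- map_anion_contacts(pose$structure, far, c(2, 3, 4))
  expect_equal(nrow(mi$contacts), 0)
  expect_false(mi$canonical)
  expect_equal(mi$n_interacting_oxygens, 0)
})

test_that("detection is invariant under rigid motion", {
  pose <- native_pose()
  mi0 <- map_anion_contacts(pose$structure, pose$anion, c(2, 3, 4))
  set.seed(77)
  for (k in 1:3) {
    mv <- random_rigid_motion()
    f <- function(m) t(apply(m, 1, mv))
    s2 <- cannmotif:::transform_structure(pose$structure, f)
    a2 <- cannmotif:::transform_anion(pose$anion, f)
    mi <- map_anion_contacts(s2, a2, c(2, 3, 4))
    expect_equal(mi$canonical, mi0$canonical)
    expect_equal(nrow(mi$contacts), nrow(mi0$contacts))
    expect_equal(mi$contacts$d_ho, mi0$contacts$d_ho, tolerance = 1e-8)
    expect_equal(mi$contacts$angle_xho, mi0$contacts$angle_xho,
                 tolerance = 1e-6)
    expect_equal(mi$contacts$energy, mi0$contacts$energy, tolerance = 1e-8)
  }
})

test_that("close, near-linear N-H contacts always score at least weak", {
  # agreement of the geometric and energetic criteria on generated poses
  poses <- small_ensemble()
  checked <- 0
  for (p in poses[1:60]) {
    mi <- map_anion_contacts(p$structure, p$anion, c(2, 3, 4))
    ct <- mi$contacts
    sel <- ct$donor %in% c("N_0", "N_p1") & ct$d_ho <= 2.1 &
      ct$angle_xho >= 150
    if (any(sel)) {
      checked <- checked + sum(sel)
      expect_true(all(ct$energy[sel] <= -0.5))
    }
  }
  expect_gt(checked, 0)
})

test_that("missing amide hydrogens give an instructive error", {
  pose <- native_pose()
  s <- pose$structure
  s$atoms <- s$atoms[!(s$atoms$resno == 3 & s$atoms$atom == "H"), ]
  expect_error(map_anion_contacts(s, pose$anion, c(2, 3, 4)),
               "build hydrogens")
})

test_that("contact reports export as TSV and JSON", {
  pose <- native_pose()
  mi <- map_anion_contacts(pose$structure, pose$anion, c(2, 3, 4))
  tf <- withr::local_tempfile(fileext = ".tsv")
  contacts_to_tsv(list(mi, mi), tf)
  tab <- utils::read.table(tf, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 2 * nrow(mi$contacts))
  jf <- withr::local_tempfile(fileext = ".json")
  interactions_to_json(mi, jf)
  parsed <- jsonlite::read_json(jf)
  expect_true(parsed[[1]]$canonical)
})
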