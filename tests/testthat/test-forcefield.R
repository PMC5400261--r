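test_that("Debye screening and Gamma calibration follow closed forms", {
  expect_equal(round(kappa_from_ionic_strength(0.15), 2), 1.24)
  expect_equal(kappa_from_ionic_strength(0), 0)
  expect_equal(kappa_from_ionic_strength(0.01), 0.32)
  expect_error(kappa_from_ionic_strength(-0.1), "non-negative")

  expect_equal(round(calibrate_gamma_dh(kappa = 1.24), 3), 0.535)
  # unscreened closed form
  expect_equal(calibrate_gamma_dh(kappa = 0), 80 * 0.5 / 138.94)
  # definitional round trip: |V| at r_ref equals the target
  g <- calibrate_gamma_dh(kappa = 1.24)
  p <- electrostatic_params(kappa = 1.24, gamma_dh = g)
  expect_equal(dh_pair_energy(0.5, 1, -1, p), -1, tolerance = 1e-12)
})

test_that("Debye-Huckel pair energies and neutral pairs behave as stated", {
  p <- electrostatic_params(kappa = 1.24,
                            gamma_dh = calibrate_gamma_dh(kappa = 1.24))
  expect_equal(round(dh_pair_energy(0.5, 1, -1, p), 3), -1)
  expect_equal(dh_pair_energy(0.7, 0, -1, p), 0)

  # a neutral bead contributes nothing to the system energy
  topo <- line_topology(c(0.5), charges = c(1, 0))
  e <- cg_energy(topo, elec = p)
  expect_equal(e$breakdown$electrostatic, 0)

  topo2 <- line_topology(c(0.5), charges = c(1, -1))
  e2 <- cg_energy(topo2, elec = p)
  expect_equal(e2$breakdown$electrostatic, -1, tolerance = 1e-9)

  # coincident charged beads are an error
  pos <- topo2$pos_native
  pos[2, ] <- pos[1, ]
  expect_error(cg_energy(topo2, pos, elec = p), "coincident|overflow")
})

test_that("12-10 contact term has its minimum at sigma and vanishes at range", {
  topo <- line_topology(c(0.5), sigma = 0.5, eps = 2)
  e <- cg_energy(topo)
  expect_equal(e$breakdown$contact, -2, tolerance = 1e-12)
  # force on the pair is zero at the minimum (excluded volume acts only on
  # non-native pairs, so the pair force here is purely the contact term)
  expect_lt(max(abs(e$forces)), 1e-9)

  pos <- topo$pos_native
  pos[2, 1] <- 60
  e_far <- cg_energy(topo, pos)
  expect_lt(abs(e_far$breakdown$contact), 1e-10)
  expect_lt(e_far$breakdown$contact, 0)
})

test_that("bonded terms evaluate the printed force constants", {
  topo <- toys$dimer$topology
  # native geometry: all bonded terms zero
  e0 <- cg_energy(topo)
  expect_equal(e0$breakdown$total, 0, tolerance = 1e-12)

  # stretch the bond by 0.01 nm (0.1 A): 100 eps/A^2 * 0.1^2 = 1 eps
  pos <- topo$pos_native
  pos[2, 1] <- pos[2, 1] + 0.01
  expect_equal(cg_energy(topo, pos)$breakdown$bond, 1, tolerance = 1e-9)

  # dihedral displaced by pi: the n = 1 term contributes K1 * 2
  hx <- idpbind:::ideal_helix_points(5)
  cas <- structure(list(pos = hx, chain = rep("A", 5), resid = rep("G", 5),
                        resno = 1:5), class = "calpha_set")
  topo5 <- build_topology(cas, idp_chain = "A", cutoff = 0.1)
  topo5$constants$kdih3 <- 0  # isolate the n = 1 term
  e_nat <- cg_energy(topo5)$breakdown$dihedral
  topo_shift <- topo5
  topo_shift$dihedrals[1, 5] <- topo5$dihedrals[1, 5] - pi
  e_pi <- cg_energy(topo_shift)$breakdown$dihedral
  expect_equal(e_nat, 0, tolerance = 1e-9)
  expect_equal(e_pi - e_nat, 2 * topo5$constants$kdih1, tolerance = 1e-9)

  # collinear angle triple is reported
  line <- structure(list(pos = matrix(c(0, 0, 0, 0.38, 0, 0, 0.76, 0, 0),
                                      3, 3, byrow = TRUE),
                         chain = rep("A", 3), resid = rep("G", 3),
                         resno = 1:3), class = "calpha_set")
  topo3 <- build_topology(structure(list(
    pos = idpbind:::ideal_helix_points(3), chain = rep("A", 3),
    resid = rep("G", 3), resno = 1:3), class = "calpha_set"),
    idp_chain = "A", cutoff = 0.1)
  expect_error(cg_energy(topo3, line$pos), "collinear")
})

test_that("excluded volume is purely repulsive r^-12", {
  # two beads, no bond: both in the excluded-volume set
  topo <- line_topology(c(0.4))
  topo$native_pairs <- matrix(numeric(0), 0, 5)
  e <- cg_energy(topo)   # r = 0.4 = sigma_nc
  expect_equal(e$breakdown$excluded_volume, 1, tolerance = 1e-12)
  pos <- topo$pos_native
  pos[2, 1] <- 0.8
  expect_equal(cg_energy(topo, pos)$breakdown$excluded_volume, 1 / 4096,
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on random systems", {
  for (seed in 1:3) {
    topo <- random_small_topology(n = 8, seed = seed)
    set.seed(seed + 100)
    pos <- topo$pos_native + matrix(rnorm(24, sd = 0.01), ncol = 3)
    elec <- electrostatic_params(ionic_strength = 0.05)
    an <- cg_energy(topo, pos, elec)$forces
    nu <- numeric_forces(topo, pos, elec)
    expect_lt(max(abs(an - nu)) / max(abs(an)), 1e-5)
    # translation invariance: total force sums to zero
    expect_lt(max(abs(colSums(an))), 1e-9)
  }
})

test_that("energy is invariant under rigid rotation and translation", {
  topo <- random_small_topology(n = 8, seed = 4)
  pos <- topo$pos_native
  elec <- electrostatic_params(ionic_strength = 0.15)
  e0 <- cg_energy(topo, pos, elec)$breakdown$total
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  posr <- pos %*% t(R) + matrix(c(1, -2, 0.5), nrow(pos), 3, byrow = TRUE)
  e1 <- cg_energy(topo, posr, elec)$breakdown$total
  expect_equal(e0, e1, tolerance = 1e-9)
})

test_that("disabling electrostatics equals zeroing all charges bit-for-bit", {
  topo <- random_small_topology(n = 10, seed = 5)
  topo0 <- topo
  topo0$charges[] <- 0
  pos <- topo$pos_native
  a <- cg_energy(topo, pos, elec = idpbind:::elec_disabled())
  b <- cg_energy(topo0, pos, elec = electrostatic_params(0.15))
  expect_identical(a$breakdown$total, b$breakdown$total)
  expect_identical(a$forces, b$forces)
})
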