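test_that("smooth Q saturates correctly and its gradient is analytic", {
  topo <- line_topology(c(0.5, 0.5, 0.5))
  q1 <- smooth_q(topo, topo$pos_native, steepness = 200, lambda = 1.5)
  expect_gt(q1$q, 0.99)

  far <- topo$pos_native
  far[c(2, 4, 6), 1] <- far[c(2, 4, 6), 1] + 30
  q0 <- smooth_q(topo, far, steepness = 200, lambda = 1.5)
  expect_lt(q0$q, 1e-6)

  # finite-difference gradient at an intermediate geometry
  pos <- topo$pos_native
  pos[2, 1] <- 0.72  # near lambda * sigma where the sigmoid is steep
  sq <- smooth_q(topo, pos, steepness = 30, lambda = 1.5)
  h <- 1e-7
  for (i in c(1, 2)) for (k in 1:3) {
    pp <- pos; pp[i, k] <- pp[i, k] + h
    pm <- pos; pm[i, k] <- pm[i, k] - h
    g <- (smooth_q(topo, pp, 30, 1.5)$q - smooth_q(topo, pm, 30, 1.5)$q) / (2 * h)
    expect_equal(sq$gradient[i, k], g, tolerance = 1e-5)
  }
})

test_that("trajectories are reproducible and respect the record contract", {
  cfg <- simulation_config(n_steps = 2000, record_stride = 100, seed = 77)
  t1 <- run_langevin(toys$dimer$topology, cfg)
  t2 <- run_langevin(toys$dimer$topology, cfg)
  expect_identical(t1$obs, t2$obs)
  expect_identical(t1$final_pos, t2$final_pos)
  expect_equal(nrow(t1$obs), 2000 / 100 + 1)

  cfg2 <- simulation_config(n_steps = 2000, record_stride = 100, seed = 78)
  t3 <- run_langevin(toys$dimer$topology, cfg2)
  expect_false(identical(t1$obs$e_kinetic, t3$obs$e_kinetic))
})

test_that("frictionless integration conserves energy (velocity Verlet limit)", {
  cfg <- simulation_config(friction = 0, n_steps = 10000, record_stride = 20,
                           seed = 5)
  tr <- run_langevin(toys$dimer$topology, cfg)
  etot <- tr$obs$e_potential + tr$obs$e_kinetic
  drift <- abs(mean(tail(etot, 50)) - mean(head(etot, 50)))
  expect_lt(drift, 1e-4)
})

test_that("the thermostat reproduces the target temperature", {
  cfg <- simulation_config(friction = 1, n_steps = 100000,
                           record_stride = 50, seed = 6, temperature = 1)
  tr <- run_langevin(toys$double_well$topology, cfg)
  tk <- 2 * tr$obs$e_kinetic[-(1:200)] / 3
  # block standard error over 20 blocks
  blocks <- split(tk, cut(seq_along(tk), 20))
  bm <- vapply(blocks, mean, numeric(1))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(tk) - 1), 2 * se)
})

test_that("a long dimer run reproduces the Boltzmann bond distribution", {
  cfg <- simulation_config(friction = 1, n_steps = 1000000,
                           record_stride = 2000, seed = 8,
                           record_frames = TRUE)
  tr <- run_langevin(toys$dimer$topology, cfg)
  r <- sqrt(colSums((tr$frames[1, , ] - tr$frames[2, , ])^2))[-(1:50)]
  k <- toys$dimer$analytic$bond_k
  r0 <- toys$dimer$analytic$bond_r0
  # analytic CDF of p(r) proportional to r^2 exp(-k (r - r0)^2)
  xs <- seq(r0 - 0.06, r0 + 0.06, length.out = 4001)
  dens <- xs^2 * exp(-k * (xs - r0)^2)
  cdf <- cumsum(dens) / sum(dens)
  ks <- suppressWarnings(
    stats::ks.test(r, function(q) stats::approx(xs, cdf, q, rule = 2)$y))
  expect_gt(ks$p.value, 0.01)
})

test_that("confinement keeps beads near the wall radius", {
  cfg <- simulation_config(n_steps = 50000, record_stride = 100, seed = 9,
                           confine_radius = 1, confine_k = 100,
                           confine_center = c(0, 0, 0),
                           record_frames = TRUE)
  tr <- run_langevin(toys$dimer$topology, cfg)
  rmax <- max(sqrt(apply(tr$frames^2, c(1, 3), sum)))
  expect_lt(rmax, 1 + 3 * sqrt(1 / 100))
})

test_that("umbrella biasing is recorded and zero-height metadynamics is inert", {
  dw <- toys$double_well$topology
  cfg <- simulation_config(n_steps = 5000, record_stride = 50, seed = 10,
                           bias = "umbrella", cv = "x", cv_bead = 1,
                           umbrella_center = 0.5, umbrella_k = 40)
  tr <- run_langevin(dw, cfg)
  expect_equal(tr$obs$e_bias,
               0.5 * 40 * (tr$obs$cv - 0.5)^2, tolerance = 1e-9)

  cfg0 <- simulation_config(n_steps = 5000, record_stride = 50, seed = 11,
                            bias = "metadynamics", cv = "x", cv_bead = 1,
                            wtm_height = 0, wtm_width = 0.1,
                            wtm_bias_factor = 5, wtm_stride = 100)
  trm <- run_metadynamics(dw, cfg0)
  cfgp <- simulation_config(n_steps = 5000, record_stride = 50, seed = 11)
  trp <- run_langevin(dw, cfgp)
  expect_equal(trm$obs$e_potential, trp$obs$e_potential, tolerance = 1e-12)
  expect_true(all(trm$ledger$height == 0))
})

test_that("the deposited-Gaussian ledger reconstructs the engine's bias", {
  dw <- toys$double_well$topology
  cfg <- simulation_config(n_steps = 40000, record_stride = 200, seed = 12,
                           bias = "metadynamics", cv = "x", cv_bead = 1,
                           wtm_height = 0.4, wtm_width = 0.1,
                           wtm_bias_factor = 6, wtm_stride = 500)
  tr <- run_metadynamics(dw, cfg)
  expect_equal(nrow(tr$ledger), 40000 / 500)
  # replay is deterministic
  xs <- seq(-1.5, 1.5, 0.05)
  expect_identical(bias_from_ledger(tr$ledger, xs, 0.1),
                   bias_from_ledger(tr$ledger, xs, 0.1))
  # heights decay according to the well-tempered rule at the deposit point
  led <- tr$ledger
  for (g in seq(2, nrow(led), by = 5)) {
    vb <- bias_from_ledger(led[seq_len(g - 1L), ], led$center[g], 0.1)
    expect_equal(led$height[g], 0.4 * exp(-vb / (6 - 1)),
                 tolerance = 0.02)
  }
  expect_error(simulation_config(bias = "metadynamics", wtm_bias_factor = 1),
               "bias_factor")
})

test_that("unbound starts are separated, seed-deterministic coils", {
  st1 <- generate_unbound_start(fix_topo, seed = 21, min_separation = 2,
                                confine_radius = 4)
  expect_equal(q_fraction(fix_topo, st1, "inter"), 0)
  st1b <- generate_unbound_start(fix_topo, seed = 21, min_separation = 2,
                                 confine_radius = 4)
  expect_identical(st1, st1b)
  st2 <- generate_unbound_start(fix_topo, seed = 22, min_separation = 2,
                                confine_radius = 4)
  expect_false(identical(st1, st2))

  # ligand centers of mass spread over the shell: no octant is empty and a
  # chi-square test against uniform octant occupancy is not rejected
  lig <- which(fix_topo$chain == fix_topo$idp_chain)
  ctr <- colMeans(fix_topo$pos_native[-lig, ])
  coms <- t(vapply(1:60, function(s)
    colMeans(generate_unbound_start(fix_topo, seed = 100 + s,
                                    min_separation = 2,
                                    confine_radius = 4)[lig, ]) - ctr,
    numeric(3)))
  oct <- 1 + (coms[, 1] > 0) + 2 * (coms[, 2] > 0) + 4 * (coms[, 3] > 0)
  tab <- tabulate(oct, 8)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  expect_error(generate_unbound_start(fix_topo, seed = 1,
                                      min_separation = 3.8,
                                      confine_radius = 4),
               "confine_radius")
})
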