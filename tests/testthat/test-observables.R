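test_that("hard-cutoff Q counts formed native contacts", {
  topo <- line_topology(c(0.5, 0.5, 0.5, 0.5), sigma = 0.5)
  expect_equal(q_fraction(topo, topo$pos_native, "inter"), 1)

  far <- topo$pos_native
  far[c(2, 4, 6, 8), 1] <- far[c(2, 4, 6, 8), 1] + 30
  expect_equal(q_fraction(topo, far, "inter"), 0)

  # half the pairs at sigma, half at 3 sigma
  half <- topo$pos_native
  half[c(2, 4), 1] <- 1.5
  expect_equal(q_fraction(topo, half, "inter"), 0.5)
})

test_that("radius of gyration matches closed forms and is rigid-motion invariant", {
  two <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 0.5)

  hx <- idpbind:::ideal_helix_points(34)
  # independent direct computation of sqrt(mean squared centroid distance)
  ctr <- colMeans(hx)
  ref <- sqrt(mean(rowSums((hx - matrix(ctr, 34, 3, byrow = TRUE))^2)))
  expect_equal(radius_of_gyration(hx), ref, tolerance = 1e-6)

  R <- rotation_matrix(c(0, 1, 1), 1.1)
  moved <- hx %*% t(R) + matrix(c(3, -1, 2), 34, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(hx),
               tolerance = 1e-12)
})

test_that("helix content classifies pseudo-dihedrals into the helical window", {
  hx <- idpbind:::ideal_helix_points(20)
  expect_equal(helix_content(hx), 1)

  # planar zigzag: all pseudo-dihedrals at 180 degrees
  zig <- cbind(0.33 * (0:19), rep(c(0, 0.2), 10), 0)
  expect_equal(helix_content(zig), 0)

  chimera <- rbind(hx[1:10, ],
                   matrix(hx[10, ], 10, 3, byrow = TRUE) +
                     cbind(0.33 * (1:10), rep(c(0.01, 0.21), 5), 0))
  expect_equal(helix_content(chimera), 0.5, tolerance = 0.2)
})

test_that("distance maps average frames and subtract elementwise", {
  f1 <- idpbind:::ideal_helix_points(6)
  m1 <- mean_distance_map(f1)
  expect_equal(m1, t(m1))
  expect_true(all(diag(m1) == 0))
  expect_equal(m1[1, 2], sqrt(sum((f1[1, ] - f1[2, ])^2)) * 10)

  f2 <- f1; f2[1, ] <- f2[1, ] + c(0.5, 0, 0)
  fr <- array(c(f1, f2), dim = c(6, 3, 2))
  m12 <- mean_distance_map(fr)
  d1 <- as.matrix(dist(f1)) * 10
  d2 <- as.matrix(dist(f2)) * 10
  expect_equal(m12, (d1 + d2) / 2, ignore_attr = TRUE)

  dd <- distance_map_difference(m12, m1)
  expect_equal(dd, m12 - m1)

  prof <- distance_scaling_profile(m1)
  expect_equal(nrow(prof), 5)
  expect_equal(prof$distance[prof$separation == 1],
               mean(d1[cbind(1:5, 2:6)]) / 10)
})

test_that("intra-chain charged contacts follow the 4.5/6.0 A weight rule", {
  mk <- function(d_nm) {
    pos <- matrix(0, 4, 3)
    pos[2, 1] <- 50; pos[3, ] <- c(0, d_nm, 0); pos[4, 1] <- 51
    structure(list(
      pos_native = pos, chain = rep(2L, 4), chain_labels = "B",
      idp_chain = 2L, resid = c("K", "G", "E", "G"),
      bonds = matrix(numeric(0), 0, 3), angles = matrix(numeric(0), 0, 4),
      dihedrals = matrix(numeric(0), 0, 5),
      native_pairs = matrix(numeric(0), 0, 5),
      charges = c(1, 0, -1, 0),
      constants = toys$dimer$topology$constants), class = "cg_topology")
  }
  w_at <- function(d_nm) {
    out <- count_intra_charged_contacts(mk(d_nm), mk(d_nm)$pos_native)
    out$contact_number[out$charge_class == "opposite" & out$pairs == "all"]
  }
  expect_equal(w_at(0.40), 1.0)
  expect_equal(w_at(0.50), 0.5)
  expect_equal(w_at(0.70), 0.0)

  # adjacent pairs are excluded from the non-adjacent tally
  topo <- mk(0.4)
  topo$charges <- c(1, -1, 0, 0)
  topo$resid <- c("K", "E", "G", "G")
  pos <- topo$pos_native
  pos[2, ] <- c(0.3, 0, 0)
  out <- count_intra_charged_contacts(topo, pos)
  expect_equal(out$contact_number[out$charge_class == "opposite" &
                                    out$pairs == "all"], 1.0)
  expect_equal(out$contact_number[out$charge_class == "opposite" &
                                    out$pairs == "nonadjacent"], 0.0)
})

test_that("intermolecular contact records classify nativeness and charge", {
  # receptor beads 1-3 (chain 1), ligand beads 4-6 (chain 2)
  pos <- matrix(c(0, 0, 0,   1, 0, 0,   2, 0, 0,
                  0, 0.8, 0, 1, 0.5, 0, 2, 1.2, 0), 6, 3, byrow = TRUE)
  np <- rbind(c(1, 4, 0.62, 1, 1))
  topo <- structure(list(
    pos_native = pos, chain = c(1L, 1L, 1L, 2L, 2L, 2L),
    chain_labels = c("A", "B"), idp_chain = 2L,
    resid = c("K", "G", "R", "E", "G", "E"),
    bonds = matrix(numeric(0), 0, 3), angles = matrix(numeric(0), 0, 4),
    dihedrals = matrix(numeric(0), 0, 5), native_pairs = np,
    charges = c(1, 0, 1, -1, 0, -1),
    constants = toys$dimer$topology$constants), class = "cg_topology")

  rec <- count_inter_contacts(topo, pos)
  # native charged pair 1-4 at 8 A: partial weight, native, opposite
  r14 <- rec[rec$i == 1 & rec$j == 4, ]
  expect_equal(r14$weight, 0.5)
  expect_equal(r14$nativeness, "native")
  expect_equal(r14$charge_class, "opposite")
  # neutral pair 2-5 at 5 A: full weight, non-electrostatic
  r25 <- rec[rec$i == 2 & rec$j == 5, ]
  expect_equal(r25$weight, 1.0)
  expect_equal(r25$nativeness, "non-native")
  expect_equal(r25$charge_class, "non-electrostatic")

  # totals equal a brute-force double loop
  brute <- 0
  for (i in 1:3) for (j in 4:6) {
    d <- sqrt(sum((pos[i, ] - pos[j, ])^2)) * 10
    brute <- brute + (d <= 6) + 0.5 * (d > 6 & d <= 10)
  }
  expect_equal(sum(rec$weight), brute)

  # class-resolved sums partition the total
  smry <- contact_number_summary(rec)
  expect_equal(sum(smry$contact_number), sum(rec$weight))
  expect_equal(nrow(smry), 6)
  expect_equal(r14$distance, 8, tolerance = 1e-9)
})

test_that("encounter detection is a hysteretic state machine", {
  mkobs <- function(d_A, q) tibble::tibble(
    time = seq_along(d_A) - 1, min_inter_dist = d_A / 10, q_inter = q)

  # starts bound
  segs <- detect_encounters(mkobs(c(3, 3, 3), c(0.9, 0.9, 0.9)))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$outcome, "bound")
  expect_equal(segs$capture_time, 0)

  # hand-traced series: dissolve then bind
  d <- c(11, 9, 11, 13, 9, 8, 5)
  q <- c(0, 0, 0, 0, 0, 0.2, 0.7)
  segs <- detect_encounters(mkobs(d, q))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$outcome, c("dissolved", "bound"))
  expect_equal(segs$capture_time, c(1, 4))
  expect_equal(segs$end_time, c(3, 6))

  # never approaches
  expect_equal(nrow(detect_encounters(mkobs(c(15, 14, 13), c(0, 0, 0)))), 0)

  # segments are ordered and non-overlapping
  d2 <- c(11, 9, 13, 9, 13, 9, 13)
  segs2 <- detect_encounters(mkobs(d2, rep(0, 7)))
  expect_true(all(diff(segs2$capture_time) > 0))
  expect_true(all(segs2$capture_time <= segs2$end_time))
  expect_true(all(segs2$end_time[-nrow(segs2)] <=
                    segs2$capture_time[-1]))

  expect_error(detect_encounters(mkobs(10, 0), approach = 12, release = 10),
               "exceed")
})

test_that("trajectory observables add helix content from stored frames", {
  cfg <- simulation_config(n_steps = 500, record_stride = 100, seed = 13,
                           record_frames = TRUE)
  tr <- run_langevin(fix_topo, cfg)
  obs <- trajectory_observables(tr, fix_topo)
  expect_true("helix" %in% names(obs))
  expect_true(all(obs$helix >= 0 & obs$helix <= 1))
  # the fixture ligand starts as an ideal helix
  expect_equal(obs$helix[1], 1)
})
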