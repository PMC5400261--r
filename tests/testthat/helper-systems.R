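# shared fixtures, built once per test run

fix <- make_mini_complex()
fix_topo <- build_topology(fix$calpha)
toys <- make_analytic_toys()

# a small random coil-and-contacts system for gradient / invariance checks:
# one chain grown by random internal coordinates, native pairs from the map
random_small_topology <- function(n = 8, seed = 1, charges = TRUE) {
  set.seed(seed)
  pos <- matrix(0, n, 3)
  pos[2, ] <- c(0.38, 0, 0)
  pos[3, ] <- pos[2, ] + 0.38 * c(cos(1), sin(1), 0)
  for (i in 4:n) {
    repeat {
      ang <- runif(1, 70, 150) * pi / 180
      dih <- runif(1, -180, 180) * pi / 180
      p <- idpbind:::nerf_place(pos[i - 3, ], pos[i - 2, ], pos[i - 1, ],
                                0.38, ang, dih)
      if (min(sqrt(rowSums((pos[1:(i - 2), , drop = FALSE] -
                              matrix(p, i - 2, 3, byrow = TRUE))^2))) > 0.35) break
    }
    pos[i, ] <- p
  }
  res <- sample(c("K", "E", "L", "A", "G", "S"), n, replace = TRUE)
  if (!charges) res <- sample(c("L", "A", "G", "S"), n, replace = TRUE)
  cas <- structure(list(pos = pos, chain = rep("A", n), resid = res,
                        resno = seq_len(n)), class = "calpha_set")
  build_topology(cas, idp_chain = "A", cutoff = 1.2, min_seq_sep = 3)
}

# central-difference gradient of the total energy
numeric_forces <- function(topo, pos, elec = idpbind:::elec_disabled(),
                           h = 1e-6) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (k in 1:3) {
      pp <- pos; pp[i, k] <- pp[i, k] + h
      pm <- pos; pm[i, k] <- pm[i, k] - h
      g[i, k] <- (cg_energy(topo, pp, elec)$breakdown$total -
                    cg_energy(topo, pm, elec)$breakdown$total) / (2 * h)
    }
  }
  -g
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  outer(a, a) * (1 - c) + diag(3) * c +
    matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3) * s
}

# minimal hand-built topology: beads on the x axis with explicit native pairs
line_topology <- function(r_pairs, sigma = 0.5, eps = 1, intermolecular = 1,
                          charges = NULL) {
  # r_pairs: distances for consecutive bead pairs (1-2), (3-4), ...
  n <- 2 * length(r_pairs)
  pos <- matrix(0, n, 3)
  yoff <- 0
  for (p in seq_along(r_pairs)) {
    i <- 2 * p - 1
    pos[i, ] <- c(0, yoff, 0)
    pos[i + 1, ] <- c(r_pairs[p], yoff, 0)
    yoff <- yoff + 50  # pairs far apart so they do not interact
  }
  pairs <- cbind(seq(1, n, 2), seq(2, n, 2), sigma, eps, intermolecular)
  chain <- rep(c(1L, 2L), length(r_pairs))
  if (is.null(charges)) charges <- numeric(n)
  structure(list(
    pos_native = pos, chain = chain, chain_labels = c("A", "B"),
    idp_chain = 2L, resid = rep("G", n),
    bonds = matrix(numeric(0), 0, 3), angles = matrix(numeric(0), 0, 4),
    dihedrals = matrix(numeric(0), 0, 5), native_pairs = pairs,
    charges = charges,
    constants = list(bond_k = 1e4, angle_k = 20, kdih1 = 1, kdih3 = 0.5,
                     eps_nc = 1, sigma_nc = 0.4, gamma = 0, beta = 1,
                     alpha = 1)), class = "cg_topology")
}
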