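#' Read a C-alpha bead set from a PDB structure
#'
#' One bead per residue at its C-alpha position.  Chains are preserved;
#' insertion codes are resolved into sequential residue indices; where a
#' C-alpha has alternate locations the highest-occupancy one is taken.
#' Coordinates are returned in nm.
#'
#' @param pdb path to a PDB file, PDB text (character vector with newlines),
#'   or a `bio3d` pdb object.
#' @param model_index which MODEL to use in a multi-model file (default 1).
#' @return an object of class `calpha_set`: list with `pos` (n x 3 matrix,
#'   nm), `chain` (character per bead), `resid` (one-letter codes), `resno`.
#' @export
read_calpha_structure <- function(pdb, model_index = 1L) {
  if (inherits(pdb, "pdb")) {
    p <- pdb
  } else {
    path <- pdb
    if (length(pdb) > 1L || grepl("\n", pdb[1]) || grepl("^ATOM", pdb[1])) {
      path <- tempfile(fileext = ".pdb")
      writeLines(unlist(strsplit(pdb, "\n")), path)
      on.exit(unlink(path))
    }
    p <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  }
  at <- p$atom
  at <- at[at$type %in% c("ATOM", "HETATM") & !is.na(at$resno), , drop = FALSE]
  # residue key in file order
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  key <- paste(at$chain, at$resno, ins, sep = "|")
  ukey <- unique(key)
  ca_rows <- integer(0)
  for (k in ukey) {
    rows <- which(key == k & at$elety == "CA")
    if (length(rows) == 0L) {
      r1 <- which(key == k)[1]
      stop(sprintf("residue %s %d%s (chain %s) has no C-alpha atom",
                   at$resid[r1], at$resno[r1], ins[r1], at$chain[r1]))
    }
    if (length(rows) > 1L) {
      occ <- at$o[rows]
      rows <- rows[which.max(ifelse(is.na(occ), 0, occ))]
    }
    ca_rows <- c(ca_rows, rows)
  }
  nmod <- nrow(p$xyz)
  if (is.null(nmod) || is.na(nmod)) nmod <- 1L
  if (model_index < 1L || model_index > nmod)
    stop(sprintf("model_index %d out of range (file has %d model(s))",
                 model_index, nmod))
  xyz <- if (is.matrix(p$xyz)) p$xyz[model_index, ] else p$xyz
  idx <- ca_rows
  pos <- cbind(xyz[3 * (idx - 1) + 1], xyz[3 * (idx - 1) + 2],
               xyz[3 * (idx - 1) + 3]) / 10  # Angstrom -> nm
  res3 <- at$resid[ca_rows]
  res1 <- suppressWarnings(bio3d::aa321(res3))
  res1[is.na(res1) | res1 == "X"] <- "G"
  structure(list(pos = pos,
                 chain = at$chain[ca_rows],
                 resid = res1,
                 resno = at$resno[ca_rows]),
            class = "calpha_set")
}

#' @export
print.calpha_set <- function(x, ...) {
  cat(sprintf("calpha_set: %d beads, %d chain(s) [%s]\n", nrow(x$pos),
              length(unique(x$chain)), paste(unique(x$chain), collapse = ", ")))
  invisible(x)
}

# internal: pseudo bond/angle/dihedral of an ideal alpha-helix C-alpha trace
# (rise 1.5 A, 100 deg/residue, radius 2.3 A), computed from the parametric
# helix so the placement below reproduces exact ideal geometry
ideal_helix_internal <- function(rise = 0.15, twist = 100 * pi / 180,
                                 radius = 0.23) {
  t <- 0:3
  pts <- cbind(radius * cos(twist * t), radius * sin(twist * t), rise * t)
  list(bond = sqrt(sum((pts[2, ] - pts[1, ])^2)),
       angle = vec_angle(pts[1, ], pts[2, ], pts[3, ]),
       dihedral = vec_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]))
}

vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# torsion with the convention that a right-handed alpha-helix C-alpha trace
# gives approximately +50 degrees (matches the compiled force kernel)
vec_dihedral <- function(p1, p2, p3, p4) {
  rij <- p1 - p2; rkj <- p3 - p2; rkl <- p3 - p4
  m <- cross3(rij, rkj); n <- cross3(rkj, rkl)
  atan2(sum(rij * n) * sqrt(sum(rkj^2)), sum(m * n))
}

# internal: place a new point at (bond, angle, dihedral) from anchors a-b-c
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle), bond * sin(angle) * cos(dihedral),
          bond * sin(angle) * sin(dihedral))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Extend a chain with an ideal alpha-helix continuation
#'
#' Appends and/or prepends beads continuing the chain on an ideal
#' alpha-helical C-alpha trace (rise 1.5 A per residue, 100 deg rotation,
#' helix radius 2.3 A), aligned to the local frame of the terminal residues.
#' Added residues carry the supplied sequence identities so charge and
#' flavoring assignment see them like any other residue.
#'
#' @param cas a `calpha_set` (single chain) or a chain subset of one.
#' @param n_prepend,n_append number of residues to add at each end (<= 20).
#' @param seq_prepend,seq_append one-letter codes for the added residues
#'   (`seq_prepend` given N- to C-terminal, i.e. the first letter becomes the
#'   new first residue).
#' @return a `calpha_set` with the extended chain.
#' @export
extend_helix <- function(cas, n_prepend = 0L, n_append = 0L,
                         seq_prepend = NULL, seq_append = NULL) {
  stopifnot(inherits(cas, "calpha_set"))
  if (length(unique(cas$chain)) != 1L)
    stop("extend_helix operates on a single chain")
  if (n_prepend > 20L || n_append > 20L)
    stop("refusing to extrapolate more than 20 residues of ideal helix")
  if (n_prepend == 0L && n_append == 0L) return(cas)
  if (nrow(cas$pos) < 4L) stop("need >= 4 residues to define the helical frame")
  sq_p <- if (is.null(seq_prepend)) rep("G", n_prepend) else {
    if (length(seq_prepend) == 1L) strsplit(seq_prepend, "")[[1]] else seq_prepend
  }
  sq_a <- if (is.null(seq_append)) rep("G", n_append) else {
    if (length(seq_append) == 1L) strsplit(seq_append, "")[[1]] else seq_append
  }
  if (length(sq_p) != n_prepend || length(sq_a) != n_append)
    stop("added sequence lengths must match n_prepend/n_append")
  geo <- ideal_helix_internal()
  pos <- cas$pos
  resid <- cas$resid
  resno <- cas$resno
  for (k in seq_len(n_append)) {
    n <- nrow(pos)
    newp <- nerf_place(pos[n - 2, ], pos[n - 1, ], pos[n, ],
                       geo$bond, geo$angle, geo$dihedral)
    pos <- rbind(pos, newp)
    resid <- c(resid, sq_a[k])
    resno <- c(resno, max(resno) + 1L)
  }
  for (k in seq_len(n_prepend)) {
    newp <- nerf_place(pos[3, ], pos[2, ], pos[1, ],
                       geo$bond, geo$angle, geo$dihedral)
    pos <- rbind(newp, pos)
    resid <- c(sq_p[n_prepend - k + 1L], resid)
    resno <- c(min(resno) - 1L, resno)
  }
  structure(list(pos = pos, chain = rep(cas$chain[1], nrow(pos)),
                 resid = resid, resno = resno),
            class = "calpha_set")
}

#' Build the native contact map from bead coordinates
#'
#' Cutoff contact map at the C-alpha level: an intra-chain pair (i, j) is
#' native iff |i - j| >= `min_seq_sep` and d_ij <= `cutoff`; an inter-chain
#' pair is native iff d_ij <= `cutoff`.  With `screening = TRUE` a pair is
#' discarded when a third bead lies within 1 A of the closest-approach point
#' of the i-j segment, a simplified stand-in for shadow-style occlusion.
#'
#' @param cas a `calpha_set` for the whole complex.
#' @param cutoff contact cutoff in nm (default 0.9, i.e. 9 A).
#' @param min_seq_sep minimum intra-chain sequence separation (default 4).
#' @param screening logical, geometric occlusion filter (default FALSE).
#' @return a tibble with columns `i`, `j` (bead indices, i < j), `distance`
#'   (nm), `sigma` (nm, equal to `distance`), `intermolecular` (0/1).
#' @export
build_contact_map <- function(cas, cutoff = 0.9, min_seq_sep = 4L,
                              screening = FALSE) {
  stopifnot(inherits(cas, "calpha_set"), cutoff > 0)
  pos <- cas$pos
  n <- nrow(pos)
  chain <- cas$chain
  # residue index within chain (sequence separation is within-chain)
  within <- stats::ave(seq_len(n), chain, FUN = seq_along)
  d <- as.matrix(stats::dist(pos))
  keep_i <- integer(0); keep_j <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d[i, j] > cutoff) next
      if (chain[i] == chain[j] && abs(within[i] - within[j]) < min_seq_sep) next
      keep_i <- c(keep_i, i); keep_j <- c(keep_j, j)
    }
  }
  if (screening && length(keep_i) > 0L) {
    keep <- vapply(seq_along(keep_i), function(r) {
      i <- keep_i[r]; j <- keep_j[r]
      !any_blocker(pos, i, j, radius = 0.1)
    }, logical(1))
    keep_i <- keep_i[keep]; keep_j <- keep_j[keep]
  }
  tibble(
    i = keep_i, j = keep_j,
    distance = d[cbind(keep_i, keep_j)],
    sigma = d[cbind(keep_i, keep_j)],
    intermolecular = as.integer(chain[keep_i] != chain[keep_j]))
}

# is any third bead within `radius` of the midpoint region of segment i-j?
any_blocker <- function(pos, i, j, radius = 0.1) {
  a <- pos[i, ]; b <- pos[j, ]
  ab <- b - a
  len2 <- sum(ab^2)
  for (k in seq_len(nrow(pos))) {
    if (k == i || k == j) next
    t <- sum((pos[k, ] - a) * ab) / len2
    if (t <= 0 || t >= 1) next
    close <- a + t * ab
    if (sqrt(sum((pos[k, ] - close)^2)) < radius) return(TRUE)
  }
  FALSE
}

#' Flavor native contacts with statistical contact energies
#'
#' Per-pair strengths epsilon_ij = gamma (e_ij / e_bar - 1) + 1, where e_ij is
#' the contact-energy magnitude for the residue types of the pair and e_bar
#' the mean magnitude over all native pairs of the system.  At gamma = 0 all
#' strengths are 1 (unflavored); at gamma = 1 the mean strength stays exactly
#' 1 while individual pairs are modulated by residue chemistry.
#'
#' @param native_pairs tibble from [build_contact_map()].
#' @param residues one-letter codes per bead.
#' @param gamma flavor strength in [0, 1] (default 1, the flavored model).
#' @param mj_table 20 x 20 symmetric positive matrix of contact-energy
#'   magnitudes (default [mj_contact_energies()]).
#' @return `native_pairs` with columns `mj` and `eps` added.
#' @export
flavor_contacts <- function(native_pairs, residues, gamma = 1,
                            mj_table = mj_contact_energies()) {
  if (!isTRUE(all.equal(mj_table, t(mj_table))))
    stop("mj_table must be symmetric")
  if (nrow(native_pairs) == 0L) {
    native_pairs$mj <- numeric(0); native_pairs$eps <- numeric(0)
    return(native_pairs)
  }
  ri <- residues[native_pairs$i]
  rj <- residues[native_pairs$j]
  miss <- unique(c(ri, rj))[!unique(c(ri, rj)) %in% rownames(mj_table)]
  if (length(miss) > 0L)
    stop("residue codes not covered by mj_table: ", paste(miss, collapse = ", "))
  mj <- mj_table[cbind(ri, rj)]
  eps <- gamma * (mj / mean(mj) - 1) + 1
  if (any(eps <= 0)) {
    bad <- which(eps <= 0)[1]
    stop(sprintf("flavored strength <= 0 for pair %d-%d (%s-%s); use a smaller gamma",
                 native_pairs$i[bad], native_pairs$j[bad], ri[bad], rj[bad]))
  }
  native_pairs$mj <- mj
  native_pairs$eps <- eps
  native_pairs
}

#' Rescale intermolecular and IDP intramolecular contact strengths
#'
#' Multiplies every intermolecular pair strength by `beta` (the binding
#' calibration knob) and every intramolecular pair within the disordered
#' chain by `alpha`; receptor-internal pairs are untouched.
#'
#' @param native_pairs flavored pair tibble (with `eps`).
#' @param beta intermolecular scale factor (> 0).
#' @param alpha IDP intramolecular scale factor (> 0, default 1).
#' @param chain chain label per bead.
#' @param idp_chain chain label of the disordered ligand.
#' @return the pair tibble with `eps` rescaled.
#' @export
apply_interaction_scaling <- function(native_pairs, beta = 1, alpha = 1,
                                      chain, idp_chain) {
  stopifnot(beta > 0, alpha > 0)
  inter <- native_pairs$intermolecular == 1L
  idp_intra <- !inter & chain[native_pairs$i] == idp_chain
  native_pairs$eps[inter] <- native_pairs$eps[inter] * beta
  native_pairs$eps[idp_intra] <- native_pairs$eps[idp_intra] * alpha
  native_pairs
}

#' Build the full coarse-grained topology of a receptor-IDP complex
#'
#' Assembles the simulable model from a C-alpha bead set: harmonic bonds
#' between consecutive beads (reference = native lengths), harmonic angles,
#' periodic dihedrals (n = 1, 3), the flavored native-contact pair list with
#' sigma_ij set to native distances, charges (+1e on K/R, -1e on D/E), and
#' the model constants.  Bonded force constants follow the C-alpha
#' structure-based-model convention (bond 100 epsilon/A^2, angle
#' 20 epsilon/rad^2, dihedral K(1) = epsilon, K(3) = 0.5 epsilon).
#'
#' @param cas `calpha_set` of the complex (>= 2 chains for a complex).
#' @param idp_chain chain label of the disordered ligand (default: the
#'   shortest chain).
#' @param cutoff,min_seq_sep,screening contact-map parameters
#'   (see [build_contact_map()]).
#' @param gamma flavor strength (default 1).
#' @param beta intermolecular strength scale (default 1).
#' @param alpha IDP intramolecular strength scale (default 1).
#' @param eps_nc,sigma_nc excluded-volume strength (epsilon) and radius (nm).
#' @param mj_table contact-energy magnitudes for flavoring.
#' @return an object of class `cg_topology`.
#' @export
build_topology <- function(cas, idp_chain = NULL, cutoff = 0.9,
                           min_seq_sep = 4L, screening = FALSE, gamma = 1,
                           beta = 1, alpha = 1, eps_nc = 1, sigma_nc = 0.4,
                           mj_table = mj_contact_energies()) {
  stopifnot(inherits(cas, "calpha_set"))
  pos <- cas$pos
  n <- nrow(pos)
  chains <- unique(cas$chain)
  if (is.null(idp_chain)) {
    idp_chain <- chains[which.min(table(cas$chain)[chains])]
  }
  chain_idx <- match(cas$chain, chains)
  idp_idx <- match(idp_chain, chains)

  bonds <- matrix(numeric(0), 0, 3)
  angles <- matrix(numeric(0), 0, 4)
  dihedrals <- matrix(numeric(0), 0, 5)
  for (ch in chains) {
    ids <- which(cas$chain == ch)
    m <- length(ids)
    if (m >= 2L) {
      i <- ids[1:(m - 1L)]; j <- ids[2:m]
      r0 <- sqrt(rowSums((pos[i, , drop = FALSE] - pos[j, , drop = FALSE])^2))
      bonds <- rbind(bonds, cbind(i, j, r0))
    }
    if (m >= 3L) {
      i <- ids[1:(m - 2L)]; j <- ids[2:(m - 1L)]; k <- ids[3:m]
      t0 <- vapply(seq_along(i), function(r)
        vec_angle(pos[i[r], ], pos[j[r], ], pos[k[r], ]), numeric(1))
      angles <- rbind(angles, cbind(i, j, k, t0))
    }
    if (m >= 4L) {
      i <- ids[1:(m - 3L)]; j <- ids[2:(m - 2L)]
      k <- ids[3:(m - 1L)]; l <- ids[4:m]
      p0 <- vapply(seq_along(i), function(r)
        vec_dihedral(pos[i[r], ], pos[j[r], ], pos[k[r], ], pos[l[r], ]),
        numeric(1))
      dihedrals <- rbind(dihedrals, cbind(i, j, k, l, p0))
    }
  }

  pairs <- build_contact_map(cas, cutoff = cutoff, min_seq_sep = min_seq_sep,
                             screening = screening)
  pairs <- flavor_contacts(pairs, cas$resid, gamma = gamma, mj_table = mj_table)
  pairs <- apply_interaction_scaling(pairs, beta = beta, alpha = alpha,
                                     chain = cas$chain, idp_chain = idp_chain)

  charges <- numeric(n)
  charges[cas$resid %in% c("K", "R")] <- 1
  charges[cas$resid %in% c("D", "E")] <- -1

  structure(list(
    pos_native = unname(pos),
    chain = chain_idx,
    chain_labels = chains,
    idp_chain = idp_idx,
    resid = cas$resid,
    bonds = unname(as.matrix(bonds)),
    angles = unname(as.matrix(angles)),
    dihedrals = unname(as.matrix(dihedrals)),
    native_pairs = unname(as.matrix(
      pairs[, c("i", "j", "sigma", "eps", "intermolecular")])),
    pairs_table = pairs,
    charges = charges,
    constants = list(bond_k = 1e4, angle_k = 20, kdih1 = 1, kdih3 = 0.5,
                     eps_nc = eps_nc, sigma_nc = sigma_nc,
                     gamma = gamma, beta = beta, alpha = alpha)),
    class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  np <- x$native_pairs
  cat("cg_topology\n")
  cat(sprintf("  beads: %d in %d chains (%s); IDP chain: %s\n",
              length(x$charges), length(x$chain_labels),
              paste(x$chain_labels, collapse = ", "),
              x$chain_labels[x$idp_chain]))
  cat(sprintf("  bonds %d | angles %d | dihedrals %d\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  intra_rec <- sum(np[, 5] == 0 & x$chain[np[, 1]] != x$idp_chain)
  intra_idp <- sum(np[, 5] == 0 & x$chain[np[, 1]] == x$idp_chain)
  cat(sprintf("  native pairs: %d receptor-intra, %d IDP-intra, %d intermolecular\n",
              intra_rec, intra_idp, sum(np[, 5] == 1)))
  cat(sprintf("  charges: %d positive, %d negative\n",
              sum(x$charges > 0), sum(x$charges < 0)))
  invisible(x)
}

#' Write / read a topology archive
#'
#' The archive is R's native keyed serialization of the topology object plus
#' a human-readable text summary next to it (`<path>.txt`).
#'
#' @param topology a `cg_topology`.
#' @param path output path (conventionally `.rds`).
#' @return `write_topology` returns `path` invisibly; `read_topology` the
#'   `cg_topology`.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "cg_topology"))
  saveRDS(topology, path)
  txt <- utils::capture.output(print(topology))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "cg_topology"))
  x
}
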