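test_that("C-alpha reading preserves beads, chains and coordinates", {
  cas <- read_calpha_structure(paste(fix$pdb, collapse = "\n"))
  expect_equal(nrow(cas$pos), 57)
  expect_equal(length(unique(cas$chain)), 2)
  # PDB stores 3 decimals in Angstrom: 1e-4 nm round-trip precision
  expect_lt(max(abs(cas$pos - fix$calpha$pos)), 1e-4)
  expect_equal(cas$resid, fix$calpha$resid)

  # a residue without a C-alpha is rejected by name
  bad <- c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
           "ATOM      2  CB  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
           "END")
  expect_error(read_calpha_structure(paste(bad, collapse = "\n")),
               "no C-alpha")

  expect_error(read_calpha_structure(paste(fix$pdb, collapse = "\n"),
                                     model_index = 5), "out of range")
})

test_that("alternate locations resolve to the highest occupancy", {
  alt <- c("ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
           "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.70  0.00           C",
           "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
           "END")
  cas <- read_calpha_structure(paste(alt, collapse = "\n"))
  expect_equal(nrow(cas$pos), 2)
  expect_equal(cas$pos[1, 1], 0.9)
})

test_that("ideal-helix extension adds beads with ideal geometry", {
  helix <- idpbind:::ideal_helix_points(27)
  cas <- structure(list(pos = helix, chain = rep("B", 27),
                        resid = rep("A", 27), resno = 1:27),
                   class = "calpha_set")
  expect_identical(extend_helix(cas, 0, 0), cas)

  ext <- extend_helix(cas, n_prepend = 0, n_append = 7,
                      seq_append = "EEEKKDD")
  expect_equal(nrow(ext$pos), 34)
  expect_equal(ext$resid[28:34], strsplit("EEEKKDD", "")[[1]])
  bonds <- sqrt(rowSums(diff(ext$pos)^2))
  expect_true(all(abs(bonds[27:33] * 10 - 3.8) < 0.1))
  dih <- vapply(28:31, function(i)
    idpbind:::vec_dihedral(ext$pos[i, ], ext$pos[i + 1, ], ext$pos[i + 2, ],
                           ext$pos[i + 3, ]) * 180 / pi, numeric(1))
  expect_true(all(abs(dih - 50) < 2))

  # prepending keeps sequence order and ideal geometry too
  ext2 <- extend_helix(cas, n_prepend = 3, seq_prepend = "KDE")
  expect_equal(ext2$resid[1:3], c("K", "D", "E"))
  expect_equal(nrow(ext2$pos), 30)
  d2 <- idpbind:::vec_dihedral(ext2$pos[1, ], ext2$pos[2, ], ext2$pos[3, ],
                               ext2$pos[4, ]) * 180 / pi
  expect_lt(abs(d2 - 50), 2)

  expect_error(extend_helix(cas, n_append = 25), "20")
  short <- structure(list(pos = helix[1:3, ], chain = rep("B", 3),
                          resid = rep("A", 3), resno = 1:3),
                     class = "calpha_set")
  expect_error(extend_helix(short, n_append = 1), ">= 4")
})

test_that("contact map applies cutoff, sequence separation and symmetry", {
  # two beads 5 A apart at |i - j| = 2 in one chain: excluded by seq sep
  pos <- idpbind:::ideal_helix_points(6)
  pos[3, ] <- pos[1, ] + c(0.5, 0, 0)
  cas <- structure(list(pos = pos, chain = rep("A", 6),
                        resid = rep("G", 6), resno = 1:6),
                   class = "calpha_set")
  cmap <- build_contact_map(cas, cutoff = 0.9, min_seq_sep = 4)
  expect_false(any(cmap$i == 1 & cmap$j == 3))

  # fixture ground truth is reproduced exactly
  cmap_fix <- build_contact_map(fix$calpha)
  expect_equal(as.data.frame(cmap_fix[, c("i", "j", "intermolecular")]),
               fix$truth$native_pairs)

  # invariant to chain relabeling/order: reverse the chain order
  n <- nrow(fix$calpha$pos)
  ord <- c(46:57, 1:45)
  cas_r <- structure(list(pos = fix$calpha$pos[ord, ],
                          chain = fix$calpha$chain[ord],
                          resid = fix$calpha$resid[ord],
                          resno = fix$calpha$resno[ord]),
                     class = "calpha_set")
  cmap_r <- build_contact_map(cas_r)
  pairs_a <- sort(paste(pmin(cmap_fix$i, cmap_fix$j),
                        pmax(cmap_fix$i, cmap_fix$j)))
  pairs_b <- sort(paste(pmin(ord[cmap_r$i], ord[cmap_r$j]),
                        pmax(ord[cmap_r$i], ord[cmap_r$j])))
  expect_equal(pairs_a, pairs_b)
})

test_that("geometric screening removes occluded pairs", {
  # bead 2 sits exactly on the segment between beads 1 and 3
  pos <- matrix(c(0, 0, 0,  0.4, 0, 0,  0.8, 0, 0,  0, 3, 0,  0.4, 3, 0),
                5, 3, byrow = TRUE)
  cas <- structure(list(pos = pos, chain = c("A", "A", "A", "B", "B"),
                        resid = rep("G", 5), resno = 1:5),
                   class = "calpha_set")
  m0 <- build_contact_map(cas, cutoff = 0.9, min_seq_sep = 2,
                          screening = FALSE)
  m1 <- build_contact_map(cas, cutoff = 0.9, min_seq_sep = 2,
                          screening = TRUE)
  expect_true(any(m0$i == 1 & m0$j == 3))
  expect_false(any(m1$i == 1 & m1$j == 3))
})

test_that("flavoring follows the statistical-potential formula", {
  cmap <- build_contact_map(fix$calpha)

  f0 <- flavor_contacts(cmap, fix$calpha$resid, gamma = 0)
  expect_true(all(f0$eps == 1))

  f1 <- flavor_contacts(cmap, fix$calpha$resid, gamma = 1)
  expect_equal(mean(f1$eps), 1, tolerance = 1e-9)

  # two-pair toy with contact-energy magnitudes {2, 4}
  toy_map <- tibble::tibble(i = c(1, 3), j = c(2, 4), distance = 0.5,
                            sigma = 0.5, intermolecular = c(1L, 1L))
  mj <- matrix(2, 20, 20,
               dimnames = list(rownames(mj_contact_energies()),
                               colnames(mj_contact_energies())))
  mj["K", "E"] <- mj["E", "K"] <- 4
  ft <- flavor_contacts(toy_map, c("A", "A", "K", "E"), gamma = 1,
                        mj_table = mj)
  expect_equal(ft$eps, c(2 / 3, 4 / 3))

  # strengths must stay positive
  mj["K", "E"] <- mj["E", "K"] <- 40
  expect_error(flavor_contacts(toy_map, c("A", "A", "K", "E"), gamma = 2,
                               mj_table = mj), "smaller gamma")
  expect_error(flavor_contacts(cmap, fix$calpha$resid,
                               mj_table = matrix(1:400, 20, 20)),
               "symmetric")
})

test_that("interaction scaling rescales the intended pair classes only", {
  cmap <- flavor_contacts(build_contact_map(fix$calpha), fix$calpha$resid)
  chain <- fix$calpha$chain

  s1 <- apply_interaction_scaling(cmap, beta = 1, alpha = 1, chain = chain,
                                  idp_chain = "B")
  expect_equal(s1$eps, cmap$eps)

  s2 <- apply_interaction_scaling(cmap, beta = 0.9, alpha = 1, chain = chain,
                                  idp_chain = "B")
  inter <- cmap$intermolecular == 1
  expect_equal(s2$eps[inter], 0.9 * cmap$eps[inter])
  expect_equal(s2$eps[!inter], cmap$eps[!inter])
  expect_equal(sum(s2$eps[inter]), 0.9 * sum(cmap$eps[inter]))

  s3 <- apply_interaction_scaling(cmap, beta = 1, alpha = 0.5, chain = chain,
                                  idp_chain = "B")
  idp_intra <- !inter & chain[cmap$i] == "B"
  expect_equal(s3$eps[idp_intra], 0.5 * cmap$eps[idp_intra])
  expect_equal(s3$eps[inter], cmap$eps[inter])
})

test_that("assembled topology satisfies its structural invariants", {
  topo <- fix_topo
  np <- topo$native_pairs

  # sigma equals the native distance for every pair
  d <- sqrt(rowSums((topo$pos_native[np[, 1], ] -
                       topo$pos_native[np[, 2], ])^2))
  expect_equal(unname(np[, 3]), d)

  # no pair duplicated, none a 1-2 or 1-3 neighbor
  keys <- paste(pmin(np[, 1], np[, 2]), pmax(np[, 1], np[, 2]))
  expect_equal(anyDuplicated(keys), 0L)
  b <- topo$bonds; a <- topo$angles
  near <- c(paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])),
            paste(pmin(a[, 1], a[, 3]), pmax(a[, 1], a[, 3])))
  expect_length(intersect(keys, near), 0L)

  # bonds connect consecutive beads within a chain only
  expect_true(all(topo$chain[topo$bonds[, 1]] == topo$chain[topo$bonds[, 2]]))
  expect_true(all(topo$bonds[, 3] > 0))

  # flavored strengths average to 1 at gamma = 1, beta = alpha = 1
  expect_equal(mean(np[, 4]), 1, tolerance = 1e-9)

  # charges only on K/R (+1) and D/E (-1)
  expect_true(all(topo$charges[topo$resid %in% c("K", "R")] == 1))
  expect_true(all(topo$charges[topo$resid %in% c("D", "E")] == -1))
  expect_true(all(topo$charges[!topo$resid %in% c("K", "R", "D", "E")] == 0))
})

test_that("topology archive round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".rds")
  write_topology(fix_topo, f)
  back <- read_topology(f)
  expect_identical(back, fix_topo)
  expect_true(file.exists(paste0(f, ".txt")))
})
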