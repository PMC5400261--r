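#' Specification for the synthetic mini-complex fixture
#'
#' Parameterizes the synthetic test system: a small antiparallel helix
#' bundle "receptor" with a groove, plus a short ideal-helix "ligand" docked
#' in the groove, carrying complementary interface charges (3 native
#' opposite-charge pairs) and 2 additional opposite charges placed so they
#' are not native contacts, so native and non-native electrostatic classes
#' are both populated in encounter analyses.  Entirely synthetic: it does
#' not mimic any real receptor fold or peptide sequence.
#'
#' @param receptor_helices number of receptor helices (default 3).
#' @param helix_length beads per receptor helix (default 15).
#' @param ligand_length ligand beads (default 12).
#' @param seed reserved for randomized variants (geometry is deterministic).
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(receptor_helices = 3L, helix_length = 15L,
                         ligand_length = 12L, seed = 1L) {
  total <- receptor_helices * helix_length + ligand_length
  if (total > 200L) stop("fixture limited to 200 beads")
  structure(list(receptor_helices = receptor_helices,
                 helix_length = helix_length,
                 ligand_length = ligand_length, seed = seed),
            class = "fixture_spec")
}

ideal_helix_points <- function(n, axis_xy = c(0, 0), z0 = 0, up = TRUE,
                               phase = 0, rise = 0.15, twist = 100 * pi / 180,
                               radius = 0.23) {
  t <- 0:(n - 1)
  z <- if (up) z0 + rise * t else z0 - rise * t
  ang <- phase + (if (up) twist * t else -twist * t)
  cbind(axis_xy[1] + radius * cos(ang), axis_xy[2] + radius * sin(ang), z)
}

#' Generate the synthetic mini-complex
#'
#' Builds the fixture geometry, assigns residue identities consistent with
#' the charge pattern (K for +1, E for -1, alternating hydrophobic/polar
#' letters otherwise), emits standard PDB text, and computes a ground-truth
#' sidecar (bead counts, charges, native pairs at the default builder
#' cutoff, ideal observable values).
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory; when given, writes
#'   `mini_complex.pdb` and `mini_complex_truth.json` there.
#' @return list with `calpha` (a `calpha_set`), `pdb` (character vector of
#'   PDB lines), `truth` (list), and `paths` (if written).
#' @export
make_mini_complex <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  hl <- spec$helix_length
  nh <- spec$receptor_helices
  ztop <- (hl - 1) * 0.15
  axes <- list(c(-0.5, 0), c(0.5, 0), c(0, -0.85), c(-1.0, -0.85),
               c(1.0, -0.85))[seq_len(nh)]
  rec <- NULL
  for (h in seq_len(nh)) {
    up <- h %% 2L == 1L
    pts <- ideal_helix_points(hl, axis_xy = axes[[h]],
                              z0 = if (up) 0 else ztop, up = up,
                              phase = (h - 1) * pi / 2)
    rec <- rbind(rec, pts)
  }
  lig <- ideal_helix_points(spec$ligand_length, axis_xy = c(0, 0.72),
                            z0 = 0.15, up = TRUE, phase = pi)
  pos <- rbind(rec, lig)
  n_rec <- nrow(rec)
  n <- nrow(pos)
  chain <- c(rep("A", n_rec), rep("B", spec$ligand_length))

  # clash check among non-consecutive beads
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  for (i in seq_len(n - 1)) if (i + 1 <= n && chain[i] == chain[i + 1]) d[i, i + 1] <- d[i + 1, i] <- Inf
  if (min(d) < 0.3)
    stop(sprintf("infeasible fixture geometry: clash at %.2f nm", min(d)))

  # Charge pattern mirrors the modeled biology: an acidic disordered ligand
  # docking into a basic groove.  Three native complementary pairs (ligand
  # acidic bead / closest groove bead basic), an acidic N-terminal cluster on
  # the ligand whose basic receptor counterparts sit outside the native
  # contact set (non-native steering charges), and one basic ligand bead
  # with a distal acidic receptor partner so both signs occur on each chain.
  lig_idx <- (n_rec + 1):n
  charges <- numeric(n)
  resid <- rep(c("L", "A", "G", "S", "V", "T"), length.out = n)
  for (li in lig_idx[c(3, 6, 9)]) {
    charges[li] <- -1
    ri <- which.min(colSums((t(pos[seq_len(n_rec), ]) - pos[li, ])^2))
    charges[ri] <- 1
  }
  # acidic cluster at the ligand N-terminus
  charges[lig_idx[1:2]] <- -1
  # their steering counterparts: receptor beads close to, but not in native
  # contact with, the ligand (just outside the contact cutoff)
  dmin <- d_to_set(pos, seq_len(n_rec), lig_idx)
  ring <- which(dmin > 0.95 & charges[seq_len(n_rec)] == 0)
  ring <- ring[order(dmin[ring])][1:2]
  charges[ring] <- 1
  # one basic ligand bead with a distal acidic receptor partner
  bl <- lig_idx[spec$ligand_length - 1L]
  if (charges[bl] == 0) charges[bl] <- 1
  far <- which(charges[seq_len(n_rec)] == 0)
  charges[far[which.max(dmin[far])]] <- -1
  resid[charges > 0] <- "K"
  resid[charges < 0] <- "E"

  cas <- structure(list(pos = pos, chain = chain, resid = resid,
                        resno = c(seq_len(n_rec), seq_len(spec$ligand_length))),
                   class = "calpha_set")
  pdb <- write_calpha_pdb(cas)
  cmap <- build_contact_map(cas)
  truth <- list(
    n_receptor = n_rec, n_ligand = spec$ligand_length, n_beads = n,
    chains = c("A", "B"), charges = charges,
    native_pairs = as.data.frame(cmap[, c("i", "j", "intermolecular")]),
    n_native_inter = sum(cmap$intermolecular == 1),
    ligand_helix_content = helix_content(lig),
    ligand_rg = radius_of_gyration(lig))
  out <- list(calpha = cas, pdb = pdb, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ppath <- file.path(dir, "mini_complex.pdb")
    jpath <- file.path(dir, "mini_complex_truth.json")
    writeLines(pdb, ppath)
    jsonlite::write_json(truth, jpath, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    out$paths <- c(pdb = ppath, truth = jpath)
  }
  out
}

d_to_set <- function(pos, from, to) {
  vapply(from, function(i)
    min(sqrt(rowSums((pos[to, , drop = FALSE] -
                        matrix(pos[i, ], length(to), 3, byrow = TRUE))^2))),
    numeric(1))
}

aa123 <- function(x) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  unname(map[x])
}

#' Write a C-alpha bead set as PDB text
#'
#' Fixed-width ATOM records (one CA per residue), normalized so output is
#' byte-identical across platforms.
#'
#' @param cas a `calpha_set` (coordinates in nm; written in Angstrom).
#' @return character vector of PDB lines.
#' @export
write_calpha_pdb <- function(cas) {
  n <- nrow(cas$pos)
  xyz <- cas$pos * 10
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, aa123(cas$resid[i]), cas$chain[i], cas$resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3])
  }, character(1))
  # TER between chains
  out <- character(0)
  for (i in seq_len(n)) {
    out <- c(out, lines[i])
    if (i < n && cas$chain[i] != cas$chain[i + 1]) out <- c(out, "TER")
  }
  c(out, "TER", "END")
}

#' Analytic toy systems
#'
#' Small systems with closed-form references so the integrator, thermostat,
#' and free-energy machinery can be validated:
#' \describe{
#'   \item{double_well}{one bead in V(x) = barrier ((x/x0)^2 - 1)^2 + tilt x
#'     on its x coordinate (y, z restrained); the analytic 1D free energy is
#'     V(x) itself.}
#'   \item{asymmetric_well}{the same with a linear tilt, giving a known
#'     basin free-energy difference by numeric quadrature.}
#'   \item{dimer}{two bonded beads (harmonic bond), with equipartition
#'     references for bond-length fluctuations.}
#' }
#'
#' @param barrier double-well barrier height (epsilon, default 5).
#' @param x0 well positions +/- x0 (nm, default 1).
#' @param tilt linear tilt of the asymmetric well (epsilon/nm, default 2).
#' @param bond_k dimer bond constant (epsilon/nm^2, default 1e4).
#' @param bond_r0 dimer bond length (nm, default 0.38).
#' @return named list of toys; each has `topology` (runnable by
#'   [run_langevin()]) and `analytic` (reference functions/values).
#' @export
make_analytic_toys <- function(barrier = 5, x0 = 1, tilt = 2, bond_k = 1e4,
                               bond_r0 = 0.38) {
  empty_bonds <- matrix(numeric(0), 0, 3)
  empty_angles <- matrix(numeric(0), 0, 4)
  empty_dih <- matrix(numeric(0), 0, 5)
  empty_pairs <- matrix(numeric(0), 0, 5)
  consts <- list(bond_k = bond_k, angle_k = 20, kdih1 = 1, kdih3 = 0.5,
                 eps_nc = 1, sigma_nc = 0.4, gamma = 0, beta = 1, alpha = 1)

  one_bead <- function(ext) {
    topo <- structure(list(
      pos_native = matrix(c(x0, 0, 0), 1, 3),
      chain = 1L, chain_labels = "A", idp_chain = 2L, resid = "G",
      bonds = empty_bonds, angles = empty_angles, dihedrals = empty_dih,
      native_pairs = empty_pairs, charges = 0, constants = consts),
      class = "cg_topology")
    attr(topo, "external_potential") <- ext
    topo
  }
  vdw <- function(x, tl) barrier * ((x / x0)^2 - 1)^2 + tl * x
  dg_quadrature <- function(tl, kT = 1) {
    # basin free energies by quadrature of exp(-V/kT) over x < 0 and x > 0
    zl <- stats::integrate(function(x) exp(-vdw(x, tl) / kT), -Inf, 0)$value
    zr <- stats::integrate(function(x) exp(-vdw(x, tl) / kT), 0, Inf)$value
    -kT * log(zl) - (-kT * log(zr))
  }

  dimer <- structure(list(
    pos_native = matrix(c(0, 0, 0, bond_r0, 0, 0), 2, 3, byrow = TRUE),
    chain = c(1L, 1L), chain_labels = "A", idp_chain = 2L,
    resid = c("G", "G"),
    bonds = matrix(c(1, 2, bond_r0), 1, 3), angles = empty_angles,
    dihedrals = empty_dih, native_pairs = empty_pairs, charges = c(0, 0),
    constants = consts), class = "cg_topology")

  list(
    double_well = list(
      topology = one_bead(list(barrier = barrier, x0 = x0, tilt = 0,
                               krest = 100)),
      analytic = list(potential = function(x) vdw(x, 0),
                      delta_g = 0,
                      delta_g_quadrature = function(kT = 1) dg_quadrature(0, kT))),
    asymmetric_well = list(
      topology = one_bead(list(barrier = barrier, x0 = x0, tilt = tilt,
                               krest = 100)),
      analytic = list(potential = function(x) vdw(x, tilt),
                      tilt = tilt,
                      delta_g_quadrature = function(kT = 1) dg_quadrature(tilt, kT))),
    dimer = list(
      topology = dimer,
      analytic = list(
        bond_k = bond_k, bond_r0 = bond_r0,
        # equipartition: <(r - r0)^2> ~= kT / (2 bond_k) for stiff bonds
        var_bond = function(kT = 1) kT / (2 * bond_k))))
}
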