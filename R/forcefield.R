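#' Inverse Debye screening length from ionic strength
#'
#' kappa = 3.2 sqrt(C_salt) with C_salt in molar and kappa in 1/nm; at
#' physiological ionic strength (0.15 M) kappa is 1.24 /nm.
#'
#' @param c_salt ionic strength in molar (>= 0), vectorized.
#' @return kappa in nm^-1.
#' @export
kappa_from_ionic_strength <- function(c_salt) {
  if (any(c_salt < 0)) stop("ionic strength must be non-negative")
  3.2 * sqrt(c_salt)
}

K_COULOMB <- 138.94  # kJ mol^-1 nm e^-2 (4 pi eps0 electric conversion)

#' Calibrate the Debye-Huckel scale factor
#'
#' Gamma_DH is set so that the screened-Coulomb energy magnitude of two unit
#' opposite charges at `r_ref` equals `target_energy` (the native-contact
#' energy scale): Gamma = target * dielectric * r_ref /
#' (K_coulomb * B * exp(-kappa r_ref)).  At kappa = 1.24 /nm this gives the
#' working value 0.535.
#'
#' @param kappa inverse Debye length (nm^-1).
#' @param r_ref reference separation in nm (default 0.5).
#' @param target_energy target |V| in kJ/mol (default 1).
#' @param dielectric relative dielectric constant (default 80).
#' @param b_kappa salt-dependent coefficient B(kappa) (default 1).
#' @param k_coulomb electric conversion factor (kJ mol^-1 nm e^-2).
#' @return Gamma_DH (dimensionless).
#' @export
calibrate_gamma_dh <- function(kappa, r_ref = 0.5, target_energy = 1,
                               dielectric = 80, b_kappa = 1,
                               k_coulomb = K_COULOMB) {
  stopifnot(kappa >= 0)
  target_energy * dielectric * r_ref / (k_coulomb * b_kappa * exp(-kappa * r_ref))
}

#' Electrostatics parameter set
#'
#' Bundles the Debye-Huckel parameters.  By default `kappa` is derived from
#' the ionic strength and `gamma_dh` is calibrated so a unit opposite-charge
#' pair at 0.5 nm contributes -1 kJ/mol at physiological screening
#' (kappa = 1.24 /nm), independent of the ionic strength being simulated.
#'
#' @param ionic_strength molar salt concentration (default 0.15).
#' @param enabled logical; `FALSE` turns all charge-charge forces off.
#' @param kappa override the inverse Debye length (nm^-1).
#' @param gamma_dh override the calibrated scale factor.
#' @param dielectric relative dielectric (default 80).
#' @param b_kappa salt coefficient B(kappa) (default 1).
#' @return a list of class `elec_params`.
#' @export
electrostatic_params <- function(ionic_strength = 0.15, enabled = TRUE,
                                 kappa = NULL, gamma_dh = NULL,
                                 dielectric = 80, b_kappa = 1) {
  if (is.null(kappa)) kappa <- kappa_from_ionic_strength(ionic_strength)
  if (is.null(gamma_dh)) {
    kappa_phys <- kappa_from_ionic_strength(0.15)
    gamma_dh <- calibrate_gamma_dh(kappa_phys, dielectric = dielectric,
                                   b_kappa = b_kappa)
  }
  structure(list(enabled = enabled, ionic_strength = ionic_strength,
                 kappa = kappa, gamma_dh = gamma_dh, dielectric = dielectric,
                 b_kappa = b_kappa, k_coulomb = K_COULOMB),
            class = "elec_params")
}

elec_disabled <- function() electrostatic_params(enabled = FALSE, kappa = 0)

#' Debye-Huckel pair energy
#'
#' V(r) = Gamma K_coulomb B(kappa) q1 q2 exp(-kappa r) / (dielectric r).
#'
#' @param r separation in nm (vectorized).
#' @param q1,q2 charges in e.
#' @param params an `elec_params`.
#' @return energy in kJ/mol.
#' @export
dh_pair_energy <- function(r, q1, q2, params = electrostatic_params()) {
  with(params, gamma_dh * k_coulomb * b_kappa * q1 * q2 *
         exp(-kappa * r) / (dielectric * r))
}

#' Potential energy and forces of a conformation
#'
#' Evaluates every term of the Hamiltonian (harmonic bonds and angles,
#' periodic dihedrals, 12-10 native contacts, r^-12 excluded volume over all
#' non-bonded non-native pairs, and Debye-Huckel electrostatics over charged
#' pairs excluding directly bonded ones) together with analytic forces.
#'
#' @param topology a `cg_topology`.
#' @param pos n x 3 coordinates in nm (default: the native coordinates).
#' @param elec an `elec_params` (default: electrostatics disabled).
#' @return list with `breakdown` (one-row tibble of per-term energies and
#'   `total`, kJ/mol) and `forces` (n x 3, kJ/mol/nm).
#' @export
cg_energy <- function(topology, pos = topology$pos_native,
                      elec = elec_disabled()) {
  stopifnot(inherits(topology, "cg_topology"))
  res <- cg_energy_cpp(as.matrix(pos), topology, unclass(elec))
  terms <- as.list(res$terms)
  breakdown <- tibble::as_tibble(terms)
  breakdown$total <- sum(res$terms)
  list(breakdown = breakdown, forces = res$forces)
}

#' Smooth fraction of native contacts
#'
#' Differentiable Q used as the biasing collective variable:
#' Q = (1/N) sum_ij 1 / (1 + exp(k (r_ij - lambda sigma_ij))) over the
#' selected native-pair subset.
#'
#' @param topology a `cg_topology`.
#' @param pos n x 3 coordinates (nm).
#' @param steepness sigmoid steepness k in nm^-1 (default 50).
#' @param lambda width factor (> 1, default 1.5).
#' @param subset `"inter"` (default) or `"all"`.
#' @return list with `q` and `gradient` (n x 3).
#' @export
smooth_q <- function(topology, pos, steepness = 50, lambda = 1.5,
                     subset = c("inter", "all")) {
  subset <- match.arg(subset)
  stopifnot(lambda > 1)
  smooth_q_cpp(as.matrix(pos), topology, steepness, lambda,
               subset == "inter")
}
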