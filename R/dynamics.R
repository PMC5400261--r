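#' Simulation configuration
#'
#' Reduced units throughout: lengths nm, energies epsilon (== kJ/mol), time
#' tau, mass 1, k_B = 1.  Defaults: BAOAB Langevin with timestep 5e-4 tau and
#' friction 1 /tau, temperature 1 epsilon/k_B.  With `friction = 0` the
#' integrator reduces to velocity Verlet (NVE).
#'
#' @param timestep integration step (tau).
#' @param friction Langevin friction (1/tau); 0 for NVE.
#' @param temperature bath temperature (epsilon/k_B).
#' @param n_steps number of steps.
#' @param seed RNG seed for thermostat noise and initial velocities.
#' @param record_stride record observables every this many steps.
#' @param record_frames keep coordinates at every record point.
#' @param confine_radius spherical confinement radius (nm); 0 disables.
#' @param confine_k wall stiffness (epsilon/nm^2).
#' @param confine_center centre of the confinement sphere (length-3, nm).
#' @param bias `"none"`, `"umbrella"`, or `"metadynamics"`.
#' @param cv collective variable: `"q_inter"` (smooth fraction of
#'   intermolecular native contacts) or `"x"` (x coordinate of `cv_bead`,
#'   for analytic toys).
#' @param cv_bead bead index when `cv = "x"`.
#' @param cv_steepness,cv_lambda smooth-Q parameters (see [smooth_q()]).
#' @param umbrella_center,umbrella_k harmonic bias centre and spring.
#' @param wtm_height,wtm_width,wtm_bias_factor,wtm_stride well-tempered
#'   metadynamics: initial Gaussian height (epsilon), width (CV units), bias
#'   factor (> 1), deposition stride (steps).
#' @param wtm_grid range and resolution of the tabulated bias grid
#'   (`c(min, max, n)`); defaults to `c(-0.05, 1.05, 1101)` for the Q CV and
#'   `c(-4, 4, 4001)` for the x CV.
#' @param stop_when_bound stop as soon as hard Q_inter reaches
#'   `bound_threshold`.
#' @param bound_threshold hard-Q_inter commit threshold (default 0.6).
#' @param q_lambda formed-contact ratio for the hard Q (default 1.2).
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(timestep = 5e-4, friction = 1, temperature = 1,
                              n_steps = 10000, seed = 1, record_stride = 100,
                              record_frames = FALSE, confine_radius = 0,
                              confine_k = 100, confine_center = c(0, 0, 0),
                              bias = c("none", "umbrella", "metadynamics"),
                              cv = c("q_inter", "x"), cv_bead = 1,
                              cv_steepness = 50, cv_lambda = 1.5,
                              umbrella_center = 0, umbrella_k = 0,
                              wtm_height = 0.5, wtm_width = 0.05,
                              wtm_bias_factor = 10, wtm_stride = 500,
                              wtm_grid = NULL,
                              stop_when_bound = FALSE, bound_threshold = 0.6,
                              q_lambda = 1.2) {
  bias <- match.arg(bias)
  cv <- match.arg(cv)
  stopifnot(timestep > 0, temperature > 0, n_steps >= 1, record_stride >= 1)
  if (bias == "metadynamics") {
    if (wtm_bias_factor <= 1) stop("wtm_bias_factor must be > 1")
    if (wtm_stride < 1) stop("wtm_stride must be >= 1")
  }
  if (is.null(wtm_grid)) {
    wtm_grid <- if (cv == "q_inter") c(-0.05, 1.05, 1101) else c(-4, 4, 4001)
  }
  structure(list(
    timestep = timestep, friction = friction, temperature = temperature,
    n_steps = n_steps, seed = seed, record_stride = record_stride,
    record_frames = record_frames, confine_radius = confine_radius,
    confine_k = confine_k, confine_center = confine_center, bias = bias,
    cv = cv, cv_bead = cv_bead, cv_steepness = cv_steepness,
    cv_lambda = cv_lambda, umbrella_center = umbrella_center,
    umbrella_k = umbrella_k, wtm_height = wtm_height, wtm_width = wtm_width,
    wtm_bias_factor = wtm_bias_factor, wtm_stride = wtm_stride,
    wtm_grid = wtm_grid,
    stop_when_bound = stop_when_bound, bound_threshold = bound_threshold,
    q_lambda = q_lambda), class = "sim_config")
}

cfg_to_cpp <- function(config, ext = NULL, vel0 = NULL) {
  bias_type <- match(config$bias, c("none", "umbrella", "metadynamics")) - 1L
  cv_type <- match(config$cv, c("q_inter", "x")) - 1L
  list(
    timestep = config$timestep, friction = config$friction,
    temperature = config$temperature, n_steps = config$n_steps,
    seed = config$seed, record_stride = as.integer(config$record_stride),
    record_frames = isTRUE(config$record_frames),
    confine_radius = config$confine_radius, confine_k = config$confine_k,
    confine_center = as.numeric(config$confine_center),
    bias_type = bias_type, cv_type = cv_type,
    cv_bead = as.integer(config$cv_bead),
    cv_steepness = config$cv_steepness, cv_lambda = config$cv_lambda,
    umbrella_k = config$umbrella_k, umbrella_center = config$umbrella_center,
    wtm_height = config$wtm_height, wtm_width = config$wtm_width,
    wtm_bias_factor = config$wtm_bias_factor,
    wtm_stride = as.integer(config$wtm_stride),
    wtm_grid_min = config$wtm_grid[1], wtm_grid_max = config$wtm_grid[2],
    wtm_grid_n = as.integer(config$wtm_grid[3]),
    stop_when_bound = isTRUE(config$stop_when_bound),
    bound_threshold = config$bound_threshold, q_lambda = config$q_lambda,
    ext_type = if (is.null(ext)) 0L else 1L,
    ext_barrier = if (is.null(ext)) 0 else ext$barrier,
    ext_x0 = if (is.null(ext)) 1 else ext$x0,
    ext_tilt = if (is.null(ext)) 0 else ext$tilt,
    ext_krest = if (is.null(ext)) 0 else ext$krest,
    vel0 = vel0)
}

#' Run Langevin dynamics
#'
#' BAOAB-discretized Langevin propagation of a topology, with optional
#' spherical confinement and optional bias (umbrella or well-tempered
#' metadynamics) on the configured collective variable.  Deterministic given
#' the seed.
#'
#' @param topology a `cg_topology` (or an analytic toy from
#'   [make_analytic_toys()]).
#' @param config a `sim_config`.
#' @param start n x 3 start coordinates (default: native).
#' @param elec an `elec_params` (default: disabled).
#' @param vel0 optional n x 3 start velocities (default: Maxwell-Boltzmann
#'   draw at the configured temperature).
#' @return a `cg_trajectory`: list with `obs` (tibble of per-frame records),
#'   `frames` (n x 3 x F array or NULL), `ledger` (deposited Gaussians for
#'   metadynamics), `final_pos`, `final_vel`, `stopped_early`, `stop_step`,
#'   `config`, `elec`.
#' @export
run_langevin <- function(topology, config, start = NULL,
                         elec = elec_disabled(), vel0 = NULL) {
  ext <- attr(topology, "external_potential")
  if (is.null(start)) start <- topology$pos_native
  res <- run_cg_cpp(as.matrix(start), topology, unclass(elec),
                    cfg_to_cpp(config, ext = ext, vel0 = vel0))
  obs <- tibble::as_tibble(as.data.frame(res$obs))
  frames <- NULL
  if (isTRUE(config$record_frames)) {
    frames <- array(res$frames, dim = c(length(topology$charges), 3,
                                        nrow(obs)))
  }
  ledger <- NULL
  if (!is.null(res$ledger)) {
    ledger <- tibble::as_tibble(as.data.frame(res$ledger))
  }
  structure(list(obs = obs, frames = frames, ledger = ledger,
                 final_pos = res$final_pos, final_vel = res$final_vel,
                 stopped_early = res$stopped_early,
                 stop_step = res$stop_step, config = config, elec = elec),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames over %g tau (%s bias)%s\n",
              nrow(x$obs), max(x$obs$time), x$config$bias,
              if (isTRUE(x$stopped_early))
                sprintf("; stopped bound at step %d", as.integer(x$stop_step))
              else ""))
  invisible(x)
}

#' Run well-tempered metadynamics
#'
#' Convenience wrapper around [run_langevin()] with `bias = "metadynamics"`:
#' Gaussians of initial height `wtm_height` are deposited on the smooth CV
#' every `wtm_stride` steps, scaled by exp(-V_bias / (k_B DeltaT)) with
#' DeltaT = (bias_factor - 1) T.  The deposited-Gaussian ledger is returned
#' on the trajectory and fully determines the bias potential.
#'
#' @inheritParams run_langevin
#' @return a `cg_trajectory` with a non-NULL `ledger`.
#' @export
run_metadynamics <- function(topology, config, start = NULL,
                             elec = elec_disabled(), vel0 = NULL) {
  config$bias <- "metadynamics"
  run_langevin(topology, config, start = start, elec = elec, vel0 = vel0)
}

#' Evaluate a metadynamics bias potential from its ledger
#'
#' @param ledger tibble with `center` and `height` columns.
#' @param cv_values points at which to evaluate the bias.
#' @param width Gaussian width used during deposition.
#' @return bias energies (epsilon) at `cv_values`.
#' @export
bias_from_ledger <- function(ledger, cv_values, width) {
  if (is.null(ledger) || nrow(ledger) == 0L) return(rep(0, length(cv_values)))
  vapply(cv_values, function(x)
    sum(ledger$height * exp(-(x - ledger$center)^2 / (2 * width^2))),
    numeric(1))
}

#' Generate an unbound starting conformation
#'
#' Receptor at its native geometry; the disordered ligand re-grown as a
#' self-avoiding random-walk coil (bond length 0.38 nm, bead-bead clearance
#' 0.4 nm) whose every bead lies at least `min_separation` from every
#' receptor bead and inside the confinement sphere.  Deterministic per seed.
#'
#' @param topology a `cg_topology`.
#' @param seed integer seed.
#' @param min_separation minimum ligand-receptor bead distance (nm).
#' @param confine_radius placement sphere radius (nm).
#' @param confine_center sphere centre (default receptor centroid).
#' @param max_tries regrowth attempts before giving up.
#' @return n x 3 coordinates (nm).
#' @export
generate_unbound_start <- function(topology, seed, min_separation = 2,
                                   confine_radius = 5,
                                   confine_center = NULL,
                                   max_tries = 2000) {
  stopifnot(inherits(topology, "cg_topology"))
  pos <- topology$pos_native
  rec <- which(topology$chain != topology$idp_chain)
  lig <- which(topology$chain == topology$idp_chain)
  if (is.null(confine_center)) confine_center <- colMeans(pos[rec, , drop = FALSE])
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  bond <- 0.38
  nlig <- length(lig)
  # clearance is checked against all earlier beads except the direct
  # predecessor (which sits at the bond length by construction)
  ok_bead <- function(p, placed) {
    if (sqrt(sum((p - confine_center)^2)) > confine_radius) return(FALSE)
    dr <- sqrt(rowSums((pos[rec, , drop = FALSE] -
                          matrix(p, length(rec), 3, byrow = TRUE))^2))
    if (any(dr < min_separation)) return(FALSE)
    if (!is.null(placed) && nrow(placed) > 1L) {
      prev <- placed[seq_len(nrow(placed) - 1L), , drop = FALSE]
      dd <- sqrt(rowSums((prev - matrix(p, nrow(prev), 3, byrow = TRUE))^2))
      if (any(dd < 0.4)) return(FALSE)
    }
    TRUE
  }
  for (try in seq_len(max_tries)) {
    # random first bead in the allowed shell
    u <- stats::rnorm(3)
    p1 <- confine_center + u / sqrt(sum(u^2)) *
      stats::runif(1, min_separation, confine_radius)
    placed <- matrix(p1, 1, 3)
    if (!ok_bead(p1, placed)) next
    failed <- FALSE
    while (nrow(placed) < nlig) {
      success <- FALSE
      for (k in seq_len(30)) {
        v <- stats::rnorm(3)
        v <- v / sqrt(sum(v^2)) * bond
        p <- placed[nrow(placed), ] + v
        if (ok_bead(p, placed)) {
          placed <- rbind(placed, p)
          success <- TRUE
          break
        }
      }
      if (!success) { failed <- TRUE; break }
    }
    if (!failed && nrow(placed) == nlig) {
      out <- pos
      out[lig, ] <- placed
      return(relax_start(topology, out))
    }
  }
  stop("could not place an unbound ligand coil; increase confine_radius")
}

# clamped steepest descent: a freshly grown coil can sit on the repulsive
# core of an IDP-internal native pair, so relax until forces are moderate
relax_start <- function(topology, pos, max_force = 200, max_iter = 500,
                        max_disp = 0.01) {
  for (it in seq_len(max_iter)) {
    e <- cg_energy(topology, pos)
    f <- e$forces
    fmax <- max(abs(f))
    if (fmax < max_force) break
    step <- f * (max_disp / fmax)
    pos <- pos + step
  }
  pos
}
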