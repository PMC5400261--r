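#' Event timeline of a binding trajectory
#'
#' Splits the binding process into capture and evolution: `fpt_on` is the
#' time of the first bound outcome; capture times are the segment open
#' times; `mpt_cap` is the mean waiting time between capture onsets
#' (the first capture time, then gaps between successive captures);
#' `fpt_evo` is the time from the opening of the successful segment until
#' bound.  Trajectories that never bind (or that start bound, fpt_on = 0)
#' are marked censored and excluded from rate estimation with a logged
#' count.
#'
#' @param segments tibble from [detect_encounters()].
#' @param id trajectory identifier stored on the row.
#' @return one-row tibble: `id`, `fpt_on`, `mpt_cap`, `fpt_evo`,
#'   `n_captures`, `censored`.
#' @export
extract_timeline <- function(segments, id = NA) {
  caps <- segments$capture_time
  bound <- segments[segments$outcome == "bound", , drop = FALSE]
  if (nrow(bound) == 0L || nrow(segments) == 0L) {
    return(tibble(id = id, fpt_on = NA_real_, mpt_cap = NA_real_,
                  fpt_evo = NA_real_, n_captures = length(caps),
                  censored = TRUE))
  }
  fpt_on <- bound$end_time[1]
  fpt_evo <- bound$end_time[1] - bound$capture_time[1]
  mpt_cap <- mean(diff(c(0, caps)))
  censored <- fpt_on <= 0
  tibble(id = id, fpt_on = fpt_on, mpt_cap = mpt_cap, fpt_evo = fpt_evo,
         n_captures = length(caps), censored = censored)
}

#' Geometric-mean rate from passage times
#'
#' ln k = (1/n) sum ln(1 / tau_i): the rate is the geometric mean of the
#' reciprocal passage times.  Also reports the standard error of ln k.
#'
#' @param taus positive passage times.
#' @param n ensemble size (default `length(taus)`).
#' @return one-row tibble: `rate`, `log_rate`, `se_log_rate`, `n`.
#' @export
geometric_rate <- function(taus, n = length(taus)) {
  taus <- taus[!is.na(taus)]
  if (length(taus) == 0L)
    return(tibble(rate = NA_real_, log_rate = NA_real_,
                  se_log_rate = NA_real_, n = 0L))
  if (any(taus <= 0)) stop("all passage times must be positive")
  lk <- -log(taus)
  tibble(rate = exp(mean(lk)), log_rate = mean(lk),
         se_log_rate = stats::sd(lk) / sqrt(length(lk)), n = length(lk))
}

#' Relative collision success probability
#'
#' (bind rate / capture rate) at a condition, divided by the same quotient
#' in the no-charge reference.
#'
#' @param bind_rate,capture_rate rates at the condition of interest.
#' @param ref_bind_rate,ref_capture_rate rates of the reference arm.
#' @return the ratio (dimensionless).
#' @export
relative_success_probability <- function(bind_rate, capture_rate,
                                         ref_bind_rate, ref_capture_rate) {
  stopifnot(bind_rate > 0, capture_rate > 0, ref_bind_rate > 0,
            ref_capture_rate > 0)
  (bind_rate / capture_rate) / (ref_bind_rate / ref_capture_rate)
}

run_binding_trajectory <- function(topology, config, elec, seed,
                                   min_separation, confine_radius) {
  config$seed <- seed
  config$stop_when_bound <- TRUE
  start <- generate_unbound_start(topology, seed = seed,
                                  min_separation = min_separation,
                                  confine_radius = confine_radius)
  run_langevin(topology, config, start = start, elec = elec)
}

#' Binding-kinetics scan over ionic strengths
#'
#' For each arm (a list of ionic strengths plus an optional no-charge arm),
#' runs `n` independent binding simulations from fresh unbound starts
#' (seeds = `base_seed` + run index), extracts capture/binding first-passage
#' times, and estimates bind, capture and evolution rates as geometric means
#' of reciprocal passage times, with fold-changes of each rate against the
#' no-charge arm and the relative collision success probability.
#'
#' @param topology a `cg_topology`.
#' @param config a `sim_config` template (`n_steps` acts as the step cap;
#'   confinement should be set here).
#' @param ionic_strengths molar concentrations to scan.
#' @param no_charge_arm include a reference arm with electrostatics off.
#' @param zero_charge_arm include a control arm with electrostatics on but
#'   every bead charge set to zero (physics identical to the no-charge arm;
#'   a null-equivalence control).
#' @param n trajectories per arm (>= 2).
#' @param base_seed seed offset; run r of arm a uses
#'   `base_seed + 10000 a + r`.
#' @param min_separation,confine_radius unbound-start placement (nm); the
#'   confinement radius is also applied during the runs.
#' @param approach,release,bound_threshold encounter/binding definition
#'   (see [detect_encounters()]).
#' @return list of class `kinetics_scan`: `rates` (tibble: one row per arm
#'   and rate type with fold-changes), `timelines` (per-trajectory tibble).
#' @export
ionic_strength_scan <- function(topology, config,
                                ionic_strengths = c(0.01, 0.25),
                                no_charge_arm = TRUE, zero_charge_arm = FALSE,
                                n = 50,
                                base_seed = 1, min_separation = 2,
                                confine_radius = 5, approach = 10,
                                release = 12, bound_threshold = 0.6) {
  stopifnot(n >= 2)
  arms <- list()
  if (no_charge_arm) arms[["no-charge"]] <- list(kind = "none")
  if (zero_charge_arm) arms[["zero-charge"]] <- list(kind = "zero")
  for (is_ in ionic_strengths)
    arms[[format(is_)]] <- list(kind = "salt", is = is_)
  config$confine_radius <- confine_radius
  rec <- which(topology$chain != topology$idp_chain)
  config$confine_center <- colMeans(topology$pos_native[rec, , drop = FALSE])
  config$bound_threshold <- bound_threshold

  timelines <- purrr::imap_dfr(arms, function(arm, arm_name) {
    elec <- switch(arm$kind,
                   none = elec_disabled(),
                   zero = electrostatic_params(ionic_strength = 0.15),
                   salt = electrostatic_params(ionic_strength = arm$is))
    topo_arm <- topology
    if (arm$kind == "zero") topo_arm$charges[] <- 0
    ai <- match(arm_name, names(arms))
    purrr::map_dfr(seq_len(n), function(r) {
      traj <- run_binding_trajectory(
        topo_arm, config, elec, seed = base_seed + 10000L * ai + r,
        min_separation = min_separation, confine_radius = confine_radius)
      segs <- detect_encounters(traj$obs, approach = approach,
                                release = release,
                                bound_threshold = bound_threshold)
      tl <- extract_timeline(segs, id = r)
      tl$arm <- arm_name
      tl
    })
  })

  rates <- timelines |>
    dplyr::filter(!.data$censored) |>
    tidyr::pivot_longer(c("fpt_on", "mpt_cap", "fpt_evo"),
                        names_to = "passage", values_to = "tau") |>
    dplyr::filter(!is.na(.data$tau) & .data$tau > 0) |>
    dplyr::group_by(.data$arm, .data$passage) |>
    dplyr::summarise(geometric_rate(.data$tau), .groups = "drop") |>
    dplyr::mutate(rate_type = dplyr::recode(.data$passage,
                                            fpt_on = "bind",
                                            mpt_cap = "capture",
                                            fpt_evo = "evolution"))
  censored <- timelines |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n_censored = sum(.data$censored), n_total = dplyr::n())

  ref_arm <- if (no_charge_arm) "no-charge" else names(arms)[1]
  ref <- rates[rates$arm == ref_arm, c("rate_type", "rate", "se_log_rate")]
  names(ref) <- c("rate_type", "ref_rate", "ref_se")
  rates <- dplyr::left_join(rates, ref, by = "rate_type") |>
    dplyr::mutate(fold_change = .data$rate / .data$ref_rate,
                  se_log_fold = sqrt(.data$se_log_rate^2 + .data$ref_se^2)) |>
    dplyr::left_join(censored, by = "arm")

  success <- rates |>
    dplyr::select("arm", "rate_type", "rate") |>
    tidyr::pivot_wider(names_from = "rate_type", values_from = "rate")
  ref_bind <- ref$ref_rate[ref$rate_type == "bind"]
  ref_cap <- ref$ref_rate[ref$rate_type == "capture"]
  success$success_ratio <-
    if (length(ref_bind) == 1 && length(ref_cap) == 1 &&
        all(c("bind", "capture") %in% names(success))) {
      (success$bind / success$capture) / (ref_bind / ref_cap)
    } else NA_real_

  structure(list(rates = rates, timelines = timelines, success = success,
                 reference = ref_arm),
            class = "kinetics_scan")
}

#' @export
print.kinetics_scan <- function(x, ...) {
  cat("kinetics_scan (reference arm:", x$reference, ")\n")
  print(as.data.frame(x$rates[, c("arm", "rate_type", "rate", "se_log_rate",
                                  "fold_change", "n", "n_censored")]))
  invisible(x)
}
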