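#' Plot a free-energy profile or surface
#'
#' 1D PMFs are drawn as a line with uncertainty ribbon; 2D PMFs as a filled
#' free-energy landscape.
#'
#' @param object a `cg_pmf`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cg_pmf <- function(object, ...) {
  coords <- attr(object, "coords")
  if ("bin_mid" %in% names(object)) {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid,
                                              y = .data$free_energy))
    if ("uncertainty" %in% names(object)) {
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$free_energy - .data$uncertainty,
                     ymax = .data$free_energy + .data$uncertainty),
        alpha = 0.25, na.rm = TRUE)
    }
    p + ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::labs(x = coords[1], y = "free energy (kJ/mol)")
  } else {
    ggplot2::ggplot(object,
                    ggplot2::aes(x = .data$bin_mid_x, y = .data$bin_mid_y,
                                 fill = .data$free_energy)) +
      ggplot2::geom_raster(na.rm = TRUE) +
      ggplot2::scale_fill_viridis_c(na.value = "white",
                                    name = "F (kJ/mol)") +
      ggplot2::labs(x = coords[1], y = coords[2])
  }
}

#' Plot rates versus ionic strength
#'
#' Bind/capture/evolution rates per arm with multiplicative error bars from
#' the standard error of ln k; the no-charge arm is shown as a reference
#' hline.
#'
#' @param scan a `kinetics_scan`.
#' @param what `"rate"` or `"fold_change"`.
#' @return a ggplot.
#' @export
plot_kinetics_scan <- function(scan, what = c("rate", "fold_change")) {
  what <- match.arg(what)
  d <- scan$rates
  d$is_ref <- d$arm == scan$reference
  dd <- d[!d$is_ref, ]
  dd$ionic_strength <- suppressWarnings(as.numeric(dd$arm))
  dd <- dd[!is.na(dd$ionic_strength), ]  # control arms have no salt axis
  y <- if (what == "rate") dd$rate else dd$fold_change
  dd$y <- y
  dd$ymin <- y * exp(-dd$se_log_rate)
  dd$ymax <- y * exp(dd$se_log_rate)
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$ionic_strength,
                                        y = .data$y)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ymin,
                                          ymax = .data$ymax)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~rate_type, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ionic strength (M)",
                  y = if (what == "rate") "rate (1/tau)" else
                    "fold change vs no charge")
  if (what == "rate") {
    refd <- d[d$is_ref, ]
    p <- p + ggplot2::geom_hline(data = refd,
                                 ggplot2::aes(yintercept = .data$rate),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a contact probability map
#'
#' @param records contact records from [count_inter_contacts()] pooled over
#'   frames.
#' @param n_frames number of frames pooled (for probabilities).
#' @return a ggplot of per-pair contact probability.
#' @export
plot_contact_map <- function(records, n_frames) {
  d <- records |>
    dplyr::group_by(.data$i, .data$j, .data$nativeness, .data$charge_class) |>
    dplyr::summarise(probability = sum(.data$weight) / n_frames,
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(nativeness ~ charge_class) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "receptor bead", y = "ligand bead")
}

#' Plot a mean distance map
#'
#' @param dist_map matrix from [mean_distance_map()] (Angstrom).
#' @return a ggplot.
#' @export
plot_distance_map <- function(dist_map) {
  d <- as.data.frame(as.table(dist_map))
  names(d) <- c("i", "j", "distance")
  d$i <- as.integer(d$i); d$j <- as.integer(d$j)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "distance (A)") +
    ggplot2::labs(x = "residue", y = "residue")
}
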