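new_pmf <- function(df, kT, coords) {
  structure(df, class = c("cg_pmf", class(df)), kT = kT, coords = coords)
}

finite_min0 <- function(f) {
  f - min(f[is.finite(f)])
}

#' Unbiased free-energy profile by WHAM
#'
#' Standard weighted-histogram self-consistency over umbrella windows on one
#' coordinate: window free energies f_w are iterated to |delta f| <
#' `tolerance`, then the unbiased probability per bin is converted to a PMF
#' with its minimum at 0.  A single unbiased window degenerates to
#' -kT ln(histogram).
#'
#' @param windows list of windows, each a list with `q` (samples of the
#'   coordinate) and either `bias_center` + `bias_k` (harmonic umbrella
#'   0.5 k (q - c)^2) or `bias = NULL` (unbiased).
#' @param bins number of bins or a vector of bin edges.
#' @param kT thermal energy (epsilon; default 1).
#' @param tolerance convergence threshold on window free energies (default
#'   1e-7).
#' @param max_iter iteration cap (default 1e5).
#' @return a `cg_pmf` tibble: `bin_mid`, `free_energy` (min 0), `count`,
#'   `uncertainty`.
#' @export
wham_1d <- function(windows, bins = 50, kT = 1, tolerance = 1e-7,
                    max_iter = 1e5) {
  stopifnot(length(windows) >= 1)
  allq <- unlist(lapply(windows, `[[`, "q"))
  edges <- if (length(bins) == 1L) {
    seq(min(allq), max(allq), length.out = bins + 1L)
  } else bins
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(mids)
  W <- length(windows)
  H <- matrix(0, W, nb)       # histogram counts
  U <- matrix(0, W, nb)       # bias energy at bin centre
  N <- numeric(W)
  for (w in seq_len(W)) {
    q <- windows[[w]]$q
    q <- q[q >= edges[1] & q <= edges[length(edges)]]  # outside bin range
    h <- graphics::hist(q, breaks = edges, plot = FALSE, right = TRUE,
                        include.lowest = TRUE)$counts
    H[w, ] <- h
    N[w] <- sum(h)
    if (!is.null(windows[[w]]$bias_center)) {
      U[w, ] <- 0.5 * windows[[w]]$bias_k * (mids - windows[[w]]$bias_center)^2
    }
  }
  # adjacent-window overlap check (ordered by mean coordinate)
  ord <- order(vapply(windows, function(w) mean(w$q), numeric(1)))
  if (W > 1L) {
    for (k in seq_len(W - 1L)) {
      a <- ord[k]; b <- ord[k + 1L]
      if (!any(H[a, ] > 0 & H[b, ] > 0)) {
        stop(sprintf("windows %d and %d have no overlapping histogram bins", a, b))
      }
    }
  }
  f <- numeric(W)
  expU <- exp(-U / kT)
  hsum <- colSums(H)
  for (it in seq_len(max_iter)) {
    denom <- colSums(N * exp(f / kT) * expU)
    p <- ifelse(denom > 0, hsum / denom, 0)
    fnew <- -kT * log(pmax(rowSums(expU * rep(p, each = W)), 1e-300))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tolerance) break
    if (it == max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                   as.integer(max_iter), delta))
  }
  denom <- colSums(N * exp(f / kT) * expU)
  p <- ifelse(denom > 0 & hsum > 0, hsum / denom, NA_real_)
  fe <- -kT * log(p)
  fe <- finite_min0(fe)
  new_pmf(tibble(bin_mid = mids, free_energy = fe, count = hsum,
                 uncertainty = ifelse(hsum > 0, kT / sqrt(hsum), NA_real_)),
          kT = kT, coords = "q")
}

#' Reweight a metadynamics trajectory into an unbiased PMF
#'
#' Frame weights are proportional to exp(+V_bias(cv_t) / kT) with V_bias the
#' final bias potential reconstructed from the deposited-Gaussian ledger;
#' the weighted histogram of any coordinate (not just the biased CV) gives
#' its unbiased PMF.  An empty ledger reduces to the raw histogram.
#'
#' @param trajectory a `cg_trajectory` from [run_metadynamics()] (or
#'   [run_langevin()], treated as unbiased).
#' @param coord coordinate to histogram: name of an `obs` column (e.g.
#'   `"cv"`, `"q_inter"`, `"q_intra"`) or a numeric vector per frame.
#' @param coord2 optional second coordinate for a 2D PMF.
#' @param bins,bins2 bin counts or edge vectors.
#' @param kT thermal energy (default: the simulation temperature).
#' @param drop_frac fraction of initial frames discarded as burn-in
#'   (default 0.1).
#' @return a `cg_pmf` tibble (`bin_mid` or `bin_mid_x`/`bin_mid_y`).
#' @export
reweight_metadynamics <- function(trajectory, coord = "cv", coord2 = NULL,
                                  bins = 50, bins2 = 30, kT = NULL,
                                  drop_frac = 0.1) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  if (is.null(kT)) kT <- trajectory$config$temperature
  obs <- trajectory$obs
  getcoord <- function(cc) {
    if (is.character(cc)) {
      if (!cc %in% names(obs)) stop("no observable column '", cc, "'")
      obs[[cc]]
    } else {
      if (length(cc) != nrow(obs))
        stop("coordinate vector length does not match trajectory frames")
      cc
    }
  }
  x <- getcoord(coord)
  keep <- seq_len(nrow(obs)) > floor(drop_frac * nrow(obs))
  ledger <- trajectory$ledger
  if (!is.null(ledger) && nrow(ledger) > 0L) {
    if (max(ledger$time) > max(obs$time) + 1e-9)
      stop("ledger is inconsistent with the trajectory length")
    cv <- obs$cv
    # evaluate the final bias on a fine grid, then interpolate per frame
    width <- trajectory$config$wtm_width
    gx <- seq(min(cv) - width, max(cv) + width, length.out = 2000L)
    vb <- stats::approx(gx, bias_from_ledger(ledger, gx, width),
                        xout = cv)$y
    logw <- vb / kT
  } else {
    logw <- rep(0, nrow(obs))
  }
  mkedges <- function(v, b) {
    if (length(b) > 1L) b else seq(min(v[keep]), max(v[keep]), length.out = b + 1L)
  }
  e1 <- mkedges(x, bins)
  keep <- keep & x >= e1[1] & x <= e1[length(e1)]
  if (!is.null(coord2)) {
    y2 <- getcoord(coord2)
    e2 <- mkedges(y2, bins2)
    keep <- keep & y2 >= e2[1] & y2 <= e2[length(e2)]
  }
  logw <- logw - max(logw[keep])
  wts <- exp(logw) * keep
  if (is.null(coord2)) {
    idx <- findInterval(x, e1, rightmost.closed = TRUE, all.inside = TRUE)
    wsum <- tapply(wts, factor(idx, levels = seq_len(length(e1) - 1L)), sum)
    wsum[is.na(wsum)] <- 0
    csum <- tapply(keep * 1, factor(idx, levels = seq_len(length(e1) - 1L)), sum)
    csum[is.na(csum)] <- 0
    fe <- -kT * log(as.numeric(wsum))
    fe[!is.finite(fe)] <- NA_real_
    fe <- finite_min0(fe)
    mids <- (e1[-1] + e1[-length(e1)]) / 2
    new_pmf(tibble(bin_mid = mids, free_energy = fe,
                   count = as.numeric(csum),
                   uncertainty = ifelse(csum > 0, kT / sqrt(csum), NA_real_)),
            kT = kT, coords = if (is.character(coord)) coord else "coord")
  } else {
    y <- y2
    ix <- findInterval(x, e1, rightmost.closed = TRUE, all.inside = TRUE)
    iy <- findInterval(y, e2, rightmost.closed = TRUE, all.inside = TRUE)
    nb1 <- length(e1) - 1L; nb2 <- length(e2) - 1L
    wmat <- matrix(0, nb1, nb2)
    cmat <- matrix(0, nb1, nb2)
    for (r in which(keep)) {
      wmat[ix[r], iy[r]] <- wmat[ix[r], iy[r]] + exp(logw[r])
      cmat[ix[r], iy[r]] <- cmat[ix[r], iy[r]] + 1
    }
    fe <- -kT * log(wmat)
    fe[!is.finite(fe)] <- NA_real_
    fe <- fe - min(fe, na.rm = TRUE)
    grid <- expand.grid(ixb = seq_len(nb1), iyb = seq_len(nb2))
    m1 <- (e1[-1] + e1[-length(e1)]) / 2
    m2 <- (e2[-1] + e2[-length(e2)]) / 2
    new_pmf(tibble(bin_mid_x = m1[grid$ixb], bin_mid_y = m2[grid$iyb],
                   free_energy = fe[cbind(grid$ixb, grid$iyb)],
                   count = cmat[cbind(grid$ixb, grid$iyb)]),
            kT = kT,
            coords = c(if (is.character(coord)) coord else "coord",
                       if (is.character(coord2)) coord2 else "coord2"))
  }
}

#' Binding free energy from a 1D PMF over Q_inter
#'
#' DeltaG = F(unbound window) - F(bound window), each basin free energy taken
#' as -kT ln sum(exp(-F_bin/kT)) over the bins inside its window.  The
#' default windows place the unbound state at Q_inter in [0, 0.05] and the
#' bound state in [0.6, 0.8] (around the bound-basin minimum near 0.72).
#' No standard-state volume correction is applied; the value is the raw
#' basin difference at the simulated effective concentration.
#'
#' @param pmf a 1D `cg_pmf` over Q_inter.
#' @param unbound_window,bound_window numeric length-2 coordinate windows.
#' @param block_pmfs optional list of PMFs from trajectory blocks; when
#'   given, `uncertainty` is the standard deviation of DeltaG over blocks.
#' @return one-row tibble: `delta_g` (kJ/mol), `uncertainty`, `f_unbound`,
#'   `f_bound`.
#' @export
binding_free_energy <- function(pmf, unbound_window = c(0, 0.05),
                                bound_window = c(0.6, 0.8),
                                block_pmfs = NULL) {
  kT <- attr(pmf, "kT")
  basin_f <- function(p, win) {
    sel <- p$bin_mid >= win[1] & p$bin_mid <= win[2] &
      is.finite(p$free_energy)
    if (!any(sel)) stop(sprintf("no sampled bins in window [%g, %g]",
                                win[1], win[2]))
    -kT * log(sum(exp(-p$free_energy[sel] / kT)))
  }
  fu <- basin_f(pmf, unbound_window)
  fb <- basin_f(pmf, bound_window)
  unc <- NA_real_
  if (!is.null(block_pmfs)) {
    dgs <- vapply(block_pmfs, function(p)
      basin_f(p, unbound_window) - basin_f(p, bound_window), numeric(1))
    unc <- stats::sd(dgs)
  }
  tibble(delta_g = fu - fb, uncertainty = unc, f_unbound = fu, f_bound = fb)
}
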