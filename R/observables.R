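chain_indices <- function(topology, which = c("idp", "receptor")) {
  which <- match.arg(which)
  sel <- topology$chain == topology$idp_chain
  if (which == "idp") which(sel) else which(!sel)
}

#' Fraction of native contacts (hard cutoff)
#'
#' Q = (#native pairs with r_ij < lambda sigma_ij) / N over the selected
#' subset: intermolecular pairs or intramolecular pairs of the disordered
#' chain.
#'
#' @param topology a `cg_topology`.
#' @param pos n x 3 coordinates (nm).
#' @param subset `"inter"` or `"intra_idp"`.
#' @param lambda formed-contact ratio (default 1.2).
#' @return Q in [0, 1].
#' @export
q_fraction <- function(topology, pos, subset = c("inter", "intra_idp"),
                       lambda = 1.2) {
  subset <- match.arg(subset)
  res <- hard_q_cpp(as.matrix(pos), topology, lambda)
  if (subset == "inter") res$q_inter else res$q_intra
}

#' Radius of gyration of a chain
#'
#' Mass-uniform Rg = sqrt(mean squared distance from the chain centroid).
#'
#' @param pos n x 3 coordinates (nm) of the chain beads (or of the whole
#'   system together with `select`).
#' @param select optional indices of the chain beads.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(pos, select = NULL) {
  p <- if (is.null(select)) as.matrix(pos) else as.matrix(pos)[select, , drop = FALSE]
  stopifnot(nrow(p) >= 2)
  ctr <- colMeans(p)
  sqrt(mean(rowSums((p - matrix(ctr, nrow(p), 3, byrow = TRUE))^2)))
}

#' Helix content from C-alpha pseudo-dihedrals
#'
#' Fraction of consecutive four-bead pseudo-dihedrals (i, i+1, i+2, i+3)
#' falling inside the alpha-helical window (default [30, 70] degrees around
#' the ideal value of about +50 degrees).
#'
#' @param pos n x 3 chain coordinates (nm), in sequence order.
#' @param window helical window in degrees (length 2).
#' @return fraction in [0, 1].
#' @export
helix_content <- function(pos, window = c(30, 70)) {
  p <- as.matrix(pos)
  n <- nrow(p)
  stopifnot(n >= 4)
  phi <- vapply(seq_len(n - 3L), function(i)
    vec_dihedral(p[i, ], p[i + 1, ], p[i + 2, ], p[i + 3, ]) * 180 / pi,
    numeric(1))
  mean(phi >= window[1] & phi <= window[2])
}

#' Mean C-alpha distance map over trajectory frames
#'
#' @param frames n x 3 x F array of coordinates (nm), or a single n x 3
#'   matrix.
#' @param select optional bead indices (e.g. the IDP chain).
#' @return a symmetric matrix of mean distances in Angstrom.
#' @export
mean_distance_map <- function(frames, select = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.null(select)) frames <- frames[select, , , drop = FALSE]
  nf <- dim(frames)[3]
  acc <- NULL
  for (f in seq_len(nf)) {
    d <- as.matrix(stats::dist(frames[, , f]))
    acc <- if (is.null(acc)) d else acc + d
  }
  acc / nf * 10  # nm -> Angstrom
}

#' Difference between two distance maps
#'
#' @param a,b matrices from [mean_distance_map()].
#' @return elementwise `a - b`.
#' @export
distance_map_difference <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a - b
}

#' Mean intra-chain distance versus sequence separation
#'
#' Averages the distance map over all pairs at each separation |i - j|,
#' giving the r(s) profile consumed by [fit_distance_scaling()].
#'
#' @param dist_map matrix from [mean_distance_map()] (Angstrom).
#' @return tibble with `separation` and `distance` (nm).
#' @export
distance_scaling_profile <- function(dist_map) {
  n <- nrow(dist_map)
  purrr::map_dfr(seq_len(n - 1L), function(s) {
    idx <- cbind(seq_len(n - s), seq_len(n - s) + s)
    tibble(separation = s, distance = mean(dist_map[idx]) / 10)
  })
}

contact_weight <- function(d, full, partial) {
  ifelse(d <= full, 1, ifelse(d <= partial, 0.5, 0))
}

#' Intra-IDP charged-contact counts for one conformation
#'
#' Contacts between charged residues of the disordered chain, weighted 1.0
#' when the bead distance is <= 4.5 A, 0.5 when in (4.5, 6.0] A, else 0;
#' classified attractive (opposite charges) or repulsive (same charges),
#' reported both over all charged pairs (|i - j| >= 1) and excluding
#' sequence-adjacent pairs (|i - j| > 1).
#'
#' @param topology a `cg_topology`.
#' @param pos n x 3 coordinates (nm).
#' @param full,partial thresholds in Angstrom (defaults 4.5, 6.0).
#' @return tibble: `charge_class`, `pairs` ("all" or "nonadjacent"),
#'   `contact_number`.
#' @export
count_intra_charged_contacts <- function(topology, pos, full = 4.5,
                                         partial = 6.0) {
  stopifnot(full < partial)
  idp <- chain_indices(topology, "idp")
  q <- topology$charges[idp]
  ch <- which(q != 0)
  if (length(ch) < 2L) {
    return(tidyr::expand_grid(charge_class = c("opposite", "same"),
                              pairs = c("all", "nonadjacent")) |>
             dplyr::mutate(contact_number = 0))
  }
  p <- as.matrix(pos)[idp, , drop = FALSE]
  combs <- utils::combn(ch, 2)
  i <- combs[1, ]; j <- combs[2, ]
  d <- sqrt(rowSums((p[i, , drop = FALSE] - p[j, , drop = FALSE])^2)) * 10
  w <- contact_weight(d, full, partial)
  opp <- q[i] * q[j] < 0
  adj <- abs(i - j) == 1L
  tibble(
    charge_class = rep(c("opposite", "same"), each = 2),
    pairs = rep(c("all", "nonadjacent"), 2),
    contact_number = c(sum(w[opp]), sum(w[opp & !adj]),
                       sum(w[!opp]), sum(w[!opp & !adj])))
}

#' Intermolecular contact records for one conformation
#'
#' Every receptor-IDP bead pair is weighted 1.0 when its distance is
#' <= 6.0 A, 0.5 when in (6.0, 10.0] A, else 0 (dropped); each contact is
#' classified native/non-native (membership in the intermolecular
#' native-pair set) and by charge class (opposite / same / non-electrostatic
#' when either bead is neutral).
#'
#' @param topology a `cg_topology`.
#' @param pos n x 3 coordinates (nm).
#' @param full,partial thresholds in Angstrom (defaults 6.0, 10.0).
#' @param frame optional frame index stored on the records.
#' @return tibble of contact records: `frame`, `i`, `j`, `distance` (A),
#'   `weight`, `nativeness`, `charge_class`.
#' @export
count_inter_contacts <- function(topology, pos, full = 6.0, partial = 10.0,
                                 frame = NA_integer_) {
  stopifnot(full < partial)
  rec <- chain_indices(topology, "receptor")
  idp <- chain_indices(topology, "idp")
  p <- as.matrix(pos)
  np <- topology$native_pairs
  native_keys <- character(0)
  inter_np <- np[np[, 5] == 1, , drop = FALSE]
  if (nrow(inter_np) > 0)
    native_keys <- paste(pmin(inter_np[, 1], inter_np[, 2]),
                         pmax(inter_np[, 1], inter_np[, 2]))
  grid <- expand.grid(i = rec, j = idp)
  d <- sqrt(rowSums((p[grid$i, , drop = FALSE] - p[grid$j, , drop = FALSE])^2)) * 10
  w <- contact_weight(d, full, partial)
  keep <- w > 0
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]; w <- w[keep]
  qi <- topology$charges[grid$i]
  qj <- topology$charges[grid$j]
  cls <- ifelse(qi * qj < 0, "opposite", ifelse(qi * qj > 0, "same",
                                                "non-electrostatic"))
  keys <- paste(pmin(grid$i, grid$j), pmax(grid$i, grid$j))
  tibble(frame = frame, i = grid$i, j = grid$j, distance = d, weight = w,
         nativeness = ifelse(keys %in% native_keys, "native", "non-native"),
         charge_class = cls)
}

#' Summarize contact records into class-resolved contact numbers
#'
#' @param records tibble from [count_inter_contacts()] over one or more
#'   frames.
#' @return tibble with summed weights per `frame`, `nativeness`,
#'   `charge_class` (missing classes appear with 0).
#' @export
contact_number_summary <- function(records) {
  base <- tidyr::expand_grid(
    nativeness = c("native", "non-native"),
    charge_class = c("opposite", "same", "non-electrostatic"))
  records |>
    dplyr::group_by(.data$frame, .data$nativeness, .data$charge_class) |>
    dplyr::summarise(contact_number = sum(.data$weight), .groups = "drop") |>
    tidyr::complete(frame = unique(records$frame), base,
                    fill = list(contact_number = 0))
}

#' Detect encounter-complex segments along a trajectory
#'
#' State machine over per-frame observables: a segment opens at the first
#' frame where the minimum intermolecular C-alpha distance is <= the
#' approach cutoff while Q_inter is below the bound threshold; it closes
#' either when every intermolecular distance exceeds the release cutoff
#' (outcome "dissolved") or when Q_inter reaches the bound threshold
#' (outcome "bound").  The release cutoff exceeds the approach cutoff so
#' boundary chatter does not split segments.
#'
#' @param obs per-frame tibble with `time`, `min_inter_dist` (nm) and
#'   `q_inter` columns (a `cg_trajectory$obs` works directly), or a
#'   `cg_trajectory`.
#' @param approach,release cutoffs in Angstrom (defaults 10, 12).
#' @param bound_threshold Q_inter commit threshold (default 0.6).
#' @return tibble of segments: `segment`, `capture_time`, `end_time`,
#'   `outcome`, `start_frame`, `end_frame`.
#' @export
detect_encounters <- function(obs, approach = 10, release = 12,
                              bound_threshold = 0.6) {
  if (inherits(obs, "cg_trajectory")) obs <- obs$obs
  if (release <= approach) stop("release cutoff must exceed approach cutoff")
  d <- obs$min_inter_dist * 10  # nm -> Angstrom
  q <- obs$q_inter
  t <- obs$time
  segs <- list()
  open <- FALSE
  t0 <- NA_real_; f0 <- NA_integer_
  for (f in seq_along(d)) {
    if (!open) {
      if (d[f] <= approach && q[f] < bound_threshold) {
        open <- TRUE; t0 <- t[f]; f0 <- f
        # a frame can both open and close (starts at/above bound threshold)
      } else if (d[f] <= approach && q[f] >= bound_threshold) {
        segs[[length(segs) + 1L]] <- list(capture_time = t[f], end_time = t[f],
                                          outcome = "bound", start_frame = f,
                                          end_frame = f)
        break
      }
    }
    if (open) {
      if (q[f] >= bound_threshold) {
        segs[[length(segs) + 1L]] <- list(capture_time = t0, end_time = t[f],
                                          outcome = "bound", start_frame = f0,
                                          end_frame = f)
        open <- FALSE
        break
      } else if (d[f] > release) {
        segs[[length(segs) + 1L]] <- list(capture_time = t0, end_time = t[f],
                                          outcome = "dissolved",
                                          start_frame = f0, end_frame = f)
        open <- FALSE
      }
    }
  }
  if (open) {
    segs[[length(segs) + 1L]] <- list(capture_time = t0, end_time = t[length(t)],
                                      outcome = "open", start_frame = f0,
                                      end_frame = length(t))
  }
  if (length(segs) == 0L) {
    return(tibble(segment = integer(0), capture_time = numeric(0),
                  end_time = numeric(0), outcome = character(0),
                  start_frame = integer(0), end_frame = integer(0)))
  }
  dplyr::bind_rows(lapply(segs, tibble::as_tibble)) |>
    dplyr::mutate(segment = dplyr::row_number(), .before = 1)
}

#' Per-frame structural observables of a stored trajectory
#'
#' Recomputes helix content of the IDP chain from stored frames and joins it
#' onto the engine's per-frame records.
#'
#' @param trajectory a `cg_trajectory` run with `record_frames = TRUE`.
#' @param topology the `cg_topology` it was run with.
#' @return the `obs` tibble with a `helix` column added.
#' @export
trajectory_observables <- function(trajectory, topology) {
  stopifnot(!is.null(trajectory$frames))
  idp <- chain_indices(topology, "idp")
  nf <- dim(trajectory$frames)[3]
  hx <- vapply(seq_len(nf), function(f)
    helix_content(trajectory$frames[idp, , f]), numeric(1))
  dplyr::mutate(trajectory$obs, helix = hx)
}
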