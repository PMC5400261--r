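#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy (unscaled)
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Synthetic PUMA-like 34-residue test sequence
#'
#' A synthetic BH3-like 34-mer constructed to carry the charge composition of
#' the PUMA BH3 peptide studied here (5 basic, 10 acidic residues, with an
#' acidic N-terminal cluster and an arginine pair mid-sequence).  It is a
#' stand-in for illustration and testing, not the biological sequence.
#'
#' @return a length-1 character string of one-letter codes.
#' @export
puma_like_sequence <- function() {
  "AEEEEWAREIGAQLRRMADDLNAQYEDRLQELKA"
}

#' Assign per-residue point charges to a sequence
#'
#' Lysine and arginine carry +1e, aspartate and glutamate carry -1e, all other
#' residues are neutral.  Optionally the free termini are modeled as one extra
#' +1 site at the N-terminal position and one extra -1 site at the C-terminal
#' position (extra sites, not folded onto the end residues); these terminal
#' sites enter pair counting but never the composition fractions.
#'
#' @param sequence one-letter amino-acid string (or character vector of codes).
#' @param include_termini logical; add the two terminal charge sites.
#' @return an object of class `charge_seq`: list with `residues`,
#'   `site_charges`, `site_position`, `termini_included`, `length`.
#' @export
assign_charges <- function(sequence, include_termini = FALSE) {
  res <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else as.character(sequence)
  res <- toupper(res)
  if (length(res) == 0L) stop("sequence must be non-empty")
  bad <- which(!res %in% AA1)
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue letter '%s' at position %d", res[bad[1]], bad[1]))
  }
  q <- integer(length(res))
  q[res %in% c("K", "R")] <- 1L
  q[res %in% c("D", "E")] <- -1L
  pos <- seq_along(res)
  if (include_termini) {
    q <- c(1L, q, -1L)
    pos <- c(1L, pos, length(res))
  }
  structure(
    list(residues = res, site_charges = q, site_position = pos,
         termini_included = include_termini, length = length(res)),
    class = "charge_seq")
}

#' Charge-composition metrics of a sequence
#'
#' Computes f+, f-, FCR = f+ + f-, NCPR = |f+ - f-| from the residue charges
#' (terminal charge sites, if present, are excluded from the fractions so the
#' denominator is the residue count), plus the mean scaled hydrophobicity: the
#' hydropathy scale is averaged in sliding windows of `window` residues,
#' linearly rescaled to [0, 1], and the window values averaged.
#'
#' @param cas a `charge_seq` from [assign_charges()], or a sequence string.
#' @param hydropathy_scale named numeric vector over the 20 amino acids
#'   (default Kyte-Doolittle).
#' @param window sliding-window width for hydrophobicity (default 5).
#' @return a one-row tibble: `f_plus`, `f_minus`, `fcr`, `ncpr`,
#'   `mean_hydrophobicity` (NA when length < window), `length`.
#' @export
composition_metrics <- function(cas, hydropathy_scale = KYTE_DOOLITTLE,
                                window = 5L) {
  if (is.character(cas)) cas <- assign_charges(cas)
  stopifnot(inherits(cas, "charge_seq"))
  n <- cas$length
  resq <- integer(n)
  resq[cas$residues %in% c("K", "R")] <- 1L
  resq[cas$residues %in% c("D", "E")] <- -1L
  f_plus <- sum(resq > 0) / n
  f_minus <- sum(resq < 0) / n
  h <- NA_real_
  if (n >= window) {
    hv <- unname(hydropathy_scale[cas$residues])
    win_means <- vapply(seq_len(n - window + 1L),
                        function(i) mean(hv[i:(i + window - 1L)]), numeric(1))
    lo <- min(hydropathy_scale)
    hi <- max(hydropathy_scale)
    h <- mean((win_means - lo) / (hi - lo))
  }
  tibble(
    f_plus = f_plus, f_minus = f_minus,
    fcr = f_plus + f_minus, ncpr = abs(f_plus - f_minus),
    mean_hydrophobicity = h, length = n)
}

#' Count potential charged site pairs
#'
#' All unordered pairs of charge sites regardless of sequence separation:
#' opposite-charged pairs number (#positive x #negative) and same-charged
#' pairs C(#pos, 2) + C(#neg, 2).  With terminal sites included this
#' reproduces the combinatorics used to discuss intra-chain electrostatics.
#'
#' @param cas a `charge_seq` (termini included or not, as built).
#' @return a one-row tibble with `n_opposite`, `n_same`, `n_positive`,
#'   `n_negative`.
#' @export
count_charge_pairs <- function(cas) {
  if (is.character(cas)) cas <- assign_charges(cas)
  stopifnot(inherits(cas, "charge_seq"))
  np <- sum(cas$site_charges > 0)
  nm <- sum(cas$site_charges < 0)
  tibble(
    n_opposite = np * nm,
    n_same = choose(np, 2) + choose(nm, 2),
    n_positive = np, n_negative = nm)
}

#' Classify a sequence on the charge-hydropathy and polyampholyte diagrams
#'
#' Places the composition on the Uversky charge-hydropathy plane (above or
#' below the boundary <H> = (NCPR + 1.151) / 2.785, the folded side being
#' above) and in the Das-Pappu diagram-of-states: R1 weak
#' polyampholyte/polyelectrolyte (FCR < 0.25), R2 boundary region
#' (0.25 <= FCR <= 0.35), R3 strong polyampholyte (FCR > 0.35, NCPR <= 0.35),
#' R4/R5 strong polyelectrolyte (NCPR > 0.35, negative or positive).
#' Depends only on composition, so it is invariant to residue order.
#'
#' @param metrics one-row tibble from [composition_metrics()].
#' @return a one-row tibble: `das_pappu_region`, `das_pappu_label`,
#'   `uversky_side`.
#' @export
classify_disorder <- function(metrics) {
  stopifnot(all(c("fcr", "ncpr") %in% names(metrics)))
  fcr <- metrics$fcr[1]
  ncpr <- metrics$ncpr[1]
  if (ncpr > 0.35) {
    region <- if (metrics$f_minus[1] >= metrics$f_plus[1]) "R4" else "R5"
    label <- if (region == "R4") "strong negative polyelectrolyte" else "strong positive polyelectrolyte"
  } else if (fcr > 0.35) {
    region <- "R3"
    label <- "strong polyampholyte"
  } else if (fcr >= 0.25) {
    region <- "R2"
    label <- "boundary weak/strong polyampholyte"
  } else {
    region <- "R1"
    label <- "weak polyampholyte or polyelectrolyte"
  }
  side <- NA_character_
  if (!is.na(metrics$mean_hydrophobicity[1])) {
    boundary <- (ncpr + 1.151) / 2.785
    side <- if (metrics$mean_hydrophobicity[1] >= boundary) "folded side" else "disordered side"
  }
  tibble(das_pappu_region = region, das_pappu_label = label,
         uversky_side = side)
}

#' Fit a power law to mean intra-chain distance versus sequence separation
#'
#' Ordinary least squares on log r = log a + nu log s, the standard scaling
#' analysis r(s) ~ a s^nu of disordered-chain compaction.
#'
#' @param r_ij_profile data frame (or tibble) with columns `separation`
#'   (|i - j|, positive integers) and `distance` (mean distance, nm).
#' @return a one-row tibble with `prefactor` (a), `exponent` (nu),
#'   `r_squared`, `n`.
#' @export
fit_distance_scaling <- function(r_ij_profile) {
  d <- as.data.frame(r_ij_profile)
  stopifnot(all(c("separation", "distance") %in% names(d)))
  if (any(d$distance <= 0)) stop("all distances must be positive")
  if (length(unique(d$separation)) < 5L)
    stop("need at least 5 separation classes")
  fit <- stats::lm(log(distance) ~ log(separation), data = d)
  co <- stats::coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  tibble(prefactor = exp(unname(co[1])), exponent = unname(co[2]),
         r_squared = r2, n = nrow(d))
}

#' Full sequence-charge report
#'
#' Convenience wrapper chaining [assign_charges()], [composition_metrics()],
#' [count_charge_pairs()] (with terminal sites) and [classify_disorder()]
#' into one tidy row per sequence.
#'
#' @param sequences named character vector of sequences.
#' @param window hydrophobicity window width.
#' @return a tibble, one row per sequence.
#' @export
sequence_charge_report <- function(sequences, window = 5L) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  purrr::map_dfr(names(sequences), function(nm) {
    cas <- assign_charges(sequences[[nm]], include_termini = FALSE)
    met <- composition_metrics(cas, window = window)
    prs <- count_charge_pairs(assign_charges(sequences[[nm]], include_termini = TRUE))
    cls <- classify_disorder(met)
    dplyr::bind_cols(tibble(id = nm), met, prs, cls)
  })
}

#' Read sequences from FASTA or plain text
#'
#' @param path file path; FASTA (">" headers) or one bare sequence per line.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no sequences in ", path)
  if (any(startsWith(lines, ">"))) {
    hdr <- which(startsWith(lines, ">"))
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    }, character(1))
    names(seqs) <- sub("^>\\s*", "", vapply(strsplit(lines[hdr], "\\s+"), `[`, character(1), 1))
    names(seqs) <- sub("^>", "", names(seqs))
    seqs
  } else {
    stats::setNames(lines, paste0("seq", seq_along(lines)))
  }
}
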