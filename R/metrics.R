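#' Call replication origins at track midpoints
#'
#' One origin is called at the midpoint of each labeled block. For
#' pulse/chase molecules a contiguous BrdU+EdU block counts as one track
#' (one origin) unless the segments are separated by unlabeled DNA.
#'
#' @param m A [molecule()].
#' @param channels Channels contributing to a block (default both).
#' @return Data frame `molecule_id`, `origin_kb` (block midpoint),
#'   `track_start_kb`, `track_end_kb`, `track_kb`.
#' @export
call_origins <- function(m, channels = c("BrdU", "EdU")) {
  blocks <- track_union(m, channels)
  data.frame(molecule_id = rep(m$id, nrow(blocks)),
             origin_kb = (blocks[, 1] + blocks[, 2]) / 2,
             track_start_kb = blocks[, 1], track_end_kb = blocks[, 2],
             track_kb = blocks[, 2] - blocks[, 1],
             stringsAsFactors = FALSE)
}

#' Replicated fraction of a molecule
#'
#' Total labeled length (all channels, overlaps and abutments counted once)
#' divided by molecule length.
#'
#' @param m A [molecule()].
#' @return Fraction in `[0, 1]`.
#' @export
replication_fraction <- function(m) {
  stop_if(m$length_kb <= 0, "zero-length molecule")
  min(interval_total(track_union(m)) / m$length_kb, 1)
}

#' Measure inter-origin distances with the standard eligibility filters
#'
#' Distances between midpoints of adjacent labeled blocks on each molecule.
#' A record is eligible only if the molecule is less than `max_fraction`
#' replicated (strict) and BOTH flanking tracks are shorter than
#' `max_track_kb` (strict) — long tracks risk hiding multiple origins.
#' Intervals from a molecule end to the first/last origin are censored and
#' never counted as IODs.
#'
#' @param molecules List of [molecule()] objects.
#' @param max_track_kb Flanking-track filter (kb, default 20).
#' @param max_fraction Molecule replication filter (default 0.5).
#' @return Data frame `molecule_id`, `left_kb`, `right_kb`, `iod_kb`,
#'   `left_track_kb`, `right_track_kb`, `mol_fraction`, `extent_bin`,
#'   `eligible`.
#' @examples
#' m <- molecule("m", 100, tracks_df(c(10, 30, 58), c(14, 36, 62)))
#' measure_iods(list(m))$iod_kb   # 21, 27
#' @export
measure_iods <- function(molecules, max_track_kb = 20, max_fraction = 0.5) {
  rows <- lapply(molecules, function(m) {
    calls <- call_origins(m)
    if (nrow(calls) < 2) return(NULL)
    frac <- replication_fraction(m)
    n <- nrow(calls)
    data.frame(molecule_id = m$id,
               left_kb = calls$origin_kb[-n], right_kb = calls$origin_kb[-1],
               iod_kb = diff(calls$origin_kb),
               left_track_kb = calls$track_kb[-n],
               right_track_kb = calls$track_kb[-1],
               mol_fraction = frac, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(molecule_id = character(0), left_kb = numeric(0),
                      right_kb = numeric(0), iod_kb = numeric(0),
                      left_track_kb = numeric(0), right_track_kb = numeric(0),
                      mol_fraction = numeric(0))
  }
  out$extent_bin <- bin_by_extent(out$mol_fraction)
  out$eligible <- out$mol_fraction < max_fraction &
    out$left_track_kb < max_track_kb & out$right_track_kb < max_track_kb
  rownames(out) <- NULL
  out
}

#' Eligible IOD values from a measurement table
#'
#' @param iods Output of [measure_iods()].
#' @return Numeric vector of eligible distances (kb).
#' @export
eligible_iods <- function(iods) iods$iod_kb[iods$eligible]

#' Mean inter-origin distance, averaged per molecule
#'
#' The summary convention of single-molecule studies: eligible IODs are
#' first averaged within each molecule, then across molecules, so every
#' molecule carries equal weight regardless of its origin count. (For a
#' tandem array with per-repeat firing probability p this estimator is
#' exactly unbiased for `repeat length / p`; the pooled mean is pulled down
#' a few percent by molecules with many origins.)
#'
#' @param iods Output of [measure_iods()].
#' @param by_molecule Average per molecule first (default) or pool all
#'   eligible IODs.
#' @return Mean IOD in kb.
#' @export
mean_iod <- function(iods, by_molecule = TRUE) {
  el <- iods[iods$eligible, , drop = FALSE]
  if (nrow(el) == 0) return(NA_real_)
  if (!by_molecule) return(mean(el$iod_kb))
  mean(tapply(el$iod_kb, el$molecule_id, mean))
}

#' Bin molecules (or fractions) by replication extent
#'
#' Left-open, right-closed binning: a molecule exactly 5% replicated falls
#' in the 0–5% bin. Molecules beyond the last edge are tagged for exclusion
#' from IOD statistics.
#'
#' @param x List of molecules or a numeric vector of replicated fractions.
#' @param edges Bin edges (fractions, default `c(0.05, 0.20, 0.50)`).
#' @return Factor of bin labels (e.g. `"0-5%"`, `"5-20%"`, `"20-50%"`,
#'   `">50%"`).
#' @export
bin_by_extent <- function(x, edges = c(0.05, 0.20, 0.50)) {
  frac <- if (is.list(x)) vapply(x, replication_fraction, numeric(1)) else x
  pct <- function(e) sub("\\.0*$", "", formatC(100 * e, format = "fg"))
  labs <- c(paste0(c("0", pct(edges[-length(edges)])), "-", pct(edges), "%"),
            paste0(">", pct(edges[length(edges)]), "%"))
  cut(frac, breaks = c(-Inf, edges, Inf), labels = labs, right = TRUE)
}

#' Moving-average replication profile
#'
#' Fraction of labeled DNA in a sliding window (default 200 kb, stepped at
#' the 2-kb combing resolution) along one molecule.
#'
#' @param m A [molecule()].
#' @param window_kb Window size (kb); must not exceed the molecule length.
#' @param step_kb Step size (kb).
#' @return Data frame `center_kb`, `fraction`.
#' @export
moving_average_profile <- function(m, window_kb = 200, step_kb = 2) {
  stop_if(window_kb > m$length_kb, "window larger than molecule")
  iv <- track_union(m)
  centers <- seq(window_kb / 2, m$length_kb - window_kb / 2, by = step_kb)
  # cumulative covered length, piecewise linear in x
  if (nrow(iv) == 0) {
    return(data.frame(center_kb = centers, fraction = 0))
  }
  xs <- c(0, as.vector(t(iv)), m$length_kb)
  cum <- c(0, cumsum(as.vector(rbind(0, iv[, 2] - iv[, 1]))))
  cum <- c(cum, cum[length(cum)])
  covfun <- stats::approxfun(xs, cum[seq_along(xs)], rule = 2, ties = "ordered")
  frac <- (covfun(centers + window_kb / 2) - covfun(centers - window_kb / 2)) /
    window_kb
  data.frame(center_kb = centers, fraction = pmin(pmax(frac, 0), 1))
}

#' Count track ends as a fork-number proxy
#'
#' Two ends per internal labeled block; block ends coinciding with the
#' molecule ends (truncated forks) are not counted.
#'
#' @param m A [molecule()].
#' @return Integer count.
#' @export
count_fork_ends <- function(m) {
  iv <- track_union(m)
  if (nrow(iv) == 0) return(0L)
  sum(iv[, 1] > 1e-9) + sum(iv[, 2] < m$length_kb - 1e-9)
}

#' Cut molecules in silico into fixed-size pieces
#'
#' Partitions each molecule into consecutive pieces (default 500 kb; the
#' last piece carries the remainder). Tracks are split at boundaries, so
#' IODs spanning a boundary are lost at the piece level — emulating the
#' analysis of short combed molecules.
#'
#' @param molecules List of [molecule()] objects.
#' @param piece_kb Piece length (kb).
#' @return List of piece molecules.
#' @export
cut_in_silico <- function(molecules, piece_kb = 500) {
  stop_if(piece_kb <= 0, "`piece_kb` must be > 0")
  out <- list()
  for (m in molecules) {
    edges <- unique(c(seq(0, m$length_kb, by = piece_kb), m$length_kb))
    iv <- track_intervals_by_channel(m)
    for (k in seq_len(length(edges) - 1)) {
      lo <- edges[k]; hi <- edges[k + 1]
      if (hi - lo <= 0) next
      tracks <- do.call(rbind, lapply(names(iv), function(ch) {
        civ <- clip_intervals(iv[[ch]], lo, hi)
        if (nrow(civ) == 0) return(NULL)
        tracks_df(civ[, 1], civ[, 2], ch)
      }))
      if (is.null(tracks)) tracks <- tracks_df()
      out[[length(out) + 1]] <-
        molecule(paste0(m$id, "_c", k), hi - lo, tracks, chrom = m$chrom,
                 offset_kb = if (is.na(m$offset_kb)) NA_real_ else m$offset_kb + lo,
                 strand = m$strand)
    }
  }
  out
}
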