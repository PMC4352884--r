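#' Apply combing measurement noise: fragmentation, stretch, grid rounding
#'
#' Molecules are broken at random points (exponential inter-breakpoint
#' distances, mean `fragment_mean_kb`); fragments shorter than
#' `min_fragment_kb` are discarded. Each fragment receives one multiplicative
#' stretch factor (normal, mean `stretch_mean`, CV `stretch_cv`; combing
#' stretch is a molecule-level phenomenon), after which all coordinates are
#' rounded to the `resolution_kb` grid. Same-channel tracks separated by
#' sub-resolution gaps are merged and tracks below the detection minimum are
#' dropped; track topology is otherwise preserved.
#'
#' Fragments keep their genomic provenance: `chrom` is inherited and
#' `offset_kb` is the (unstretched) genomic start of the fragment, so
#' planted truth can be mapped through the noise step via the recorded
#' `stretch` attribute.
#'
#' @param molecules List of [molecule()] objects.
#' @param noise A [combing_noise()].
#' @param seed Integer seed.
#' @return List of fragment molecules. Each carries attributes `src_id`,
#'   `src_start_kb` and `stretch`.
#' @export
fragment_and_stretch <- function(molecules, noise = combing_noise(),
                                 seed = NULL) {
  stopifnot(inherits(noise, "combing_noise"))
  if (!is.null(seed)) set.seed(seed)
  res <- noise$resolution_kb
  out <- list()
  for (m in molecules) {
    L <- m$length_kb
    # random breakpoints: exponential inter-breakpoint distances
    brk <- numeric(0)
    xx <- 0
    repeat {
      xx <- xx + stats::rexp(1, 1 / noise$fragment_mean_kb)
      if (xx >= L) break
      brk <- c(brk, xx)
    }
    edges <- c(0, brk, L)
    iv <- track_intervals_by_channel(m)
    for (k in seq_len(length(edges) - 1)) {
      lo <- edges[k]; hi <- edges[k + 1]
      flen <- hi - lo
      if (flen < noise$min_fragment_kb) next
      s <- draw_stretch(noise)
      frag_len <- grid_round(flen * s, res)
      tracks <- do.call(rbind, lapply(names(iv), function(ch) {
        civ <- clip_intervals(iv[[ch]], lo, hi)
        if (nrow(civ) == 0) return(NULL)
        st <- grid_round(civ[, 1] * s, res)
        en <- grid_round(civ[, 2] * s, res)
        en <- pmin(en, frag_len)
        tracks_df(st, en, ch)
      }))
      if (is.null(tracks)) tracks <- tracks_df()
      tracks <- normalize_tracks(tracks, min_track_kb = noise$min_track_kb,
                                 merge_gap_kb = res)
      frag <- molecule(paste0(m$id, "_f", k), max(frag_len, res), tracks,
                       chrom = m$chrom,
                       offset_kb = if (is.na(m$offset_kb)) NA_real_ else m$offset_kb + lo,
                       strand = m$strand)
      attr(frag, "src_id") <- m$id
      attr(frag, "src_start_kb") <- lo
      attr(frag, "stretch") <- s
      out[[length(out) + 1]] <- frag
    }
  }
  out
}

# One truncated-normal stretch factor (positivity enforced by redraw).
draw_stretch <- function(noise) {
  sd <- noise$stretch_mean * noise$stretch_cv
  repeat {
    s <- stats::rnorm(1, noise$stretch_mean, sd)
    if (s > 0.1) return(s)
  }
}

# Per-channel interval matrices for one molecule.
track_intervals_by_channel <- function(m) {
  chans <- unique(m$tracks$channel)
  iv <- lapply(chans, function(ch) {
    t2 <- m$tracks[m$tracks$channel == ch, , drop = FALSE]
    cbind(start = t2$start_kb, end = t2$end_kb)
  })
  names(iv) <- chans
  iv
}
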