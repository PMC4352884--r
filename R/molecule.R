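#' Construct a combed molecule
#'
#' A molecule is a single combed DNA fragment with labeled replication
#' tracks. Coordinates are kb, 0-based, half-open `[start, end)`. Tracks of
#' the same channel must be non-overlapping; tracks of different channels may
#' abut (pulse/chase blocks) but not overlap.
#'
#' @param id Molecule identifier.
#' @param length_kb Molecule length in kb.
#' @param tracks Data frame with columns `start_kb`, `end_kb`, `channel`
#'   (`"BrdU"` or `"EdU"`).
#' @param chrom,offset_kb,strand Optional genomic assignment (from
#'   [align_by_probes()] or a simulation).
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `molecule`.
#' @examples
#' m <- molecule("m1", 100, tracks_df(c(10, 30), c(14, 36)))
#' replication_fraction(m)
#' @export
molecule <- function(id, length_kb, tracks = tracks_df(),
                     chrom = NA_character_, offset_kb = NA_real_,
                     strand = NA_character_, validate = TRUE) {
  tracks <- as.data.frame(tracks)
  if (nrow(tracks) > 0) tracks <- tracks[order(tracks$start_kb, tracks$channel), , drop = FALSE]
  rownames(tracks) <- NULL
  m <- structure(list(id = as.character(id), length_kb = as.numeric(length_kb),
                      tracks = tracks, chrom = chrom, offset_kb = offset_kb,
                      strand = strand),
                 class = "molecule")
  if (validate) {
    problems <- validate_molecule(m)
    stop_if(length(problems) > 0,
            "invalid molecule '", id, "': ", paste(problems, collapse = "; "))
  }
  m
}

#' Build a track table
#'
#' @param start_kb,end_kb Track interval bounds (kb).
#' @param channel Label channel, `"BrdU"` (pulse) or `"EdU"` (chase).
#' @return A data frame of tracks.
#' @export
tracks_df <- function(start_kb = numeric(0), end_kb = numeric(0),
                      channel = "BrdU") {
  data.frame(start_kb = as.numeric(start_kb), end_kb = as.numeric(end_kb),
             channel = rep_len(as.character(channel), length(start_kb)),
             stringsAsFactors = FALSE)
}

#' Check molecule invariants
#'
#' @param m A [molecule()].
#' @return Character vector of problems (length 0 if valid).
#' @export
validate_molecule <- function(m) {
  p <- character(0)
  tr <- m$tracks
  if (!is.numeric(m$length_kb) || length(m$length_kb) != 1 || m$length_kb <= 0)
    p <- c(p, "molecule length must be a single positive number")
  if (nrow(tr) == 0) return(p)
  if (!all(c("start_kb", "end_kb", "channel") %in% names(tr)))
    return(c(p, "tracks need columns start_kb, end_kb, channel"))
  bad_chan <- !tr$channel %in% c("BrdU", "EdU")
  if (any(bad_chan))
    p <- c(p, paste0("unknown channel(s): ",
                     paste(unique(tr$channel[bad_chan]), collapse = ", ")))
  if (any(tr$end_kb <= tr$start_kb))
    p <- c(p, "tracks must have end_kb > start_kb")
  if (any(tr$start_kb < -1e-9) || any(tr$end_kb > m$length_kb + 1e-9))
    p <- c(p, "tracks must lie within [0, length_kb)")
  for (ch in unique(tr$channel)) {
    t2 <- tr[tr$channel == ch, , drop = FALSE]
    t2 <- t2[order(t2$start_kb), , drop = FALSE]
    if (nrow(t2) > 1 && any(t2$start_kb[-1] < t2$end_kb[-nrow(t2)] - 1e-9))
      p <- c(p, paste0("overlapping ", ch, " tracks"))
  }
  p
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$id, sprintf("%.1f kb,", x$length_kb),
      nrow(x$tracks), "tracks,",
      sprintf("%.1f%% replicated", 100 * replication_fraction(x)))
  if (!is.na(x$chrom)) cat(sprintf("  [%s:%+.0f %s]", x$chrom, x$offset_kb,
                                   x$strand %||% "+"))
  cat("\n")
  invisible(x)
}

# Union of tracks over the given channels as a merged interval matrix.
# Abutting tracks (gap <= gap_tol) fuse into one block.
track_union <- function(m, channels = c("BrdU", "EdU"), gap_tol = 1e-9) {
  tr <- m$tracks[m$tracks$channel %in% channels, , drop = FALSE]
  merge_intervals(tr$start_kb, tr$end_kb, gap_tol = gap_tol)
}

#' Flip a molecule end-for-end
#'
#' Reverses the coordinate system (`x -> length - x`). All measurements in
#' the package are invariant under this operation.
#'
#' @param m A [molecule()].
#' @return The flipped molecule.
#' @export
flip_molecule <- function(m) {
  tr <- m$tracks
  if (nrow(tr) > 0) {
    new_start <- m$length_kb - tr$end_kb
    tr$end_kb <- m$length_kb - tr$start_kb
    tr$start_kb <- new_start
  }
  m$tracks <- tr[order(tr$start_kb), , drop = FALSE]
  rownames(m$tracks) <- NULL
  if (!is.na(m$strand)) m$strand <- if (m$strand == "+") "-" else "+"
  m
}

# Drop tracks below the detection minimum and merge same-channel tracks
# separated by sub-resolution gaps.
normalize_tracks <- function(tracks, min_track_kb = 2, merge_gap_kb = 2) {
  if (nrow(tracks) == 0) return(tracks)
  out <- lapply(unique(tracks$channel), function(ch) {
    t2 <- tracks[tracks$channel == ch, , drop = FALSE]
    iv <- merge_intervals(t2$start_kb, t2$end_kb, gap_tol = merge_gap_kb - 1e-9)
    keep <- iv[, 2] - iv[, 1] >= min_track_kb - 1e-9
    tracks_df(iv[keep, 1], iv[keep, 2], ch)
  })
  res <- do.call(rbind, out)
  res[order(res$start_kb), , drop = FALSE]
}
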