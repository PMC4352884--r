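#' Read a molecule-track table
#'
#' The table is TSV with header and one row per track, columns
#' `molecule_id`, `mol_length_kb`, `track_start_kb`, `track_end_kb`,
#' `channel` (and optionally `chrom`, `offset_kb`, `strand`). A molecule
#' without tracks is represented by a single row with empty track fields.
#' Malformed rows (tracks outside the molecule, overlapping same-channel
#' tracks, unknown channels) raise an error naming the offending lines.
#'
#' @param path Path to a TSV file.
#' @return A list of [molecule()] objects.
#' @export
read_molecules <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(molecule_id = "character"))
  required <- c("molecule_id", "mol_length_kb", "track_start_kb",
                "track_end_kb", "channel")
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0,
          "missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) return(list())
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1

  errors <- character(0)
  mols <- list()
  for (mid in unique(df$molecule_id)) {
    rows <- df[df$molecule_id == mid, , drop = FALSE]
    len <- unique(rows$mol_length_kb)
    if (length(len) != 1) {
      errors <- c(errors, paste0("molecule ", mid,
                                 ": inconsistent mol_length_kb (lines ",
                                 paste(rows$.line, collapse = ","), ")"))
      next
    }
    has_track <- !(is.na(rows$track_start_kb) & is.na(rows$track_end_kb))
    tr_rows <- rows[has_track, , drop = FALSE]
    row_err <- character(0)
    if (nrow(tr_rows) > 0) {
      bad <- is.na(tr_rows$track_start_kb) | is.na(tr_rows$track_end_kb) |
        tr_rows$track_end_kb <= tr_rows$track_start_kb
      if (any(bad))
        row_err <- c(row_err, paste0("invalid track interval at line(s) ",
                                     paste(tr_rows$.line[bad], collapse = ",")))
      oob <- !bad & (tr_rows$track_start_kb < 0 | tr_rows$track_end_kb > len)
      if (any(oob))
        row_err <- c(row_err, paste0("track outside molecule at line(s) ",
                                     paste(tr_rows$.line[oob], collapse = ",")))
      chan <- !tr_rows$channel %in% c("BrdU", "EdU")
      if (any(chan))
        row_err <- c(row_err, paste0("unknown channel at line(s) ",
                                     paste(tr_rows$.line[chan], collapse = ",")))
    }
    if (length(row_err) > 0) {
      errors <- c(errors, paste0("molecule ", mid, ": ",
                                 paste(row_err, collapse = "; ")))
      next
    }
    tracks <- tracks_df(tr_rows$track_start_kb, tr_rows$track_end_kb,
                        tr_rows$channel)
    m <- tryCatch(
      molecule(mid, len, tracks,
               chrom = if ("chrom" %in% names(rows)) rows$chrom[1] else NA_character_,
               offset_kb = if ("offset_kb" %in% names(rows)) rows$offset_kb[1] else NA_real_,
               strand = if ("strand" %in% names(rows)) rows$strand[1] else NA_character_),
      error = function(e) conditionMessage(e))
    if (is.character(m)) {
      errors <- c(errors, paste0("molecule ", mid, " (lines ",
                                 paste(rows$.line, collapse = ","), "): ", m))
    } else {
      mols[[mid]] <- m
    }
  }
  stop_if(length(errors) > 0,
          "invalid molecule table:\n  ", paste(errors, collapse = "\n  "))
  unname(mols)
}

#' Write molecules to a molecule-track TSV
#'
#' Deterministic output: molecules in input order, tracks sorted by start,
#' coordinates rendered at 0.1-kb precision. Round-trips losslessly with
#' [read_molecules()] for grid-aligned data.
#'
#' @param molecules List of [molecule()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(molecules, path) {
  rows <- lapply(molecules, function(m) {
    if (nrow(m$tracks) == 0) {
      data.frame(molecule_id = m$id, mol_length_kb = round(m$length_kb, 1),
                 track_start_kb = NA_real_, track_end_kb = NA_real_,
                 channel = NA_character_, chrom = m$chrom,
                 offset_kb = m$offset_kb, strand = m$strand,
                 stringsAsFactors = FALSE)
    } else {
      tr <- m$tracks[order(m$tracks$start_kb, m$tracks$channel), , drop = FALSE]
      data.frame(molecule_id = m$id, mol_length_kb = round(m$length_kb, 1),
                 track_start_kb = round(tr$start_kb, 1),
                 track_end_kb = round(tr$end_kb, 1),
                 channel = tr$channel, chrom = m$chrom,
                 offset_kb = m$offset_kb, strand = m$strand,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(molecule_id = character(0), mol_length_kb = numeric(0),
                      track_start_kb = numeric(0), track_end_kb = numeric(0),
                      channel = character(0), chrom = character(0),
                      offset_kb = numeric(0), strand = character(0))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a FISH probe-signature library
#'
#' BED-like TSV with columns `chrom`, `start_kb`, `end_kb`, `probe_id`,
#' `pair_id`: each `pair_id` groups the two probes whose lengths and gap form
#' a unique signature.
#'
#' @param path Path to the TSV file.
#' @return Data frame of probe intervals.
#' @export
read_probe_signatures <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "start_kb", "end_kb", "probe_id", "pair_id")
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0,
          "missing column(s): ", paste(missing, collapse = ", "))
  stop_if(any(df$end_kb <= df$start_kb), "probe intervals must have end > start")
  df
}

# Signature (len1, gap, len2) of a probe pair given two sorted intervals.
probe_signature <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  c(len1 = ends[1] - starts[1], gap = starts[2] - ends[1],
    len2 = ends[2] - starts[2])
}

#' Align a molecule to the genome by its FISH probe signature
#'
#' Matches the detected (length, gap, length) signature of two probe
#' intervals against a signature library in both orientations, allowing a
#' relative error of `tolerance` on each component (default 0.12, about
#' twice the combing stretch CV). A unique in-tolerance match assigns
#' chromosome, offset and orientation; a reversed match flips the molecule.
#'
#' @param m A [molecule()].
#' @param probes Data frame of detected probe intervals on the molecule
#'   (columns `start_kb`, `end_kb`; at least two rows).
#' @param library Probe-signature library from [read_probe_signatures()].
#' @param tolerance Maximum relative error per signature component.
#' @return A list with `status` (`"matched"`, `"ambiguous"`, `"no_match"`),
#'   and on success `molecule` (with coordinates assigned), `chrom`,
#'   `offset_kb`, `strand` and `pair_id`.
#' @export
align_by_probes <- function(m, probes, library, tolerance = 0.12) {
  stop_if(nrow(probes) < 2, "need at least two detected probe intervals")
  probes <- probes[order(probes$start_kb), , drop = FALSE][1:2, ]
  obs <- probe_signature(probes$start_kb, probes$end_kb)

  rel_err <- function(a, b) {
    # gap may legitimately be small; floor the denominator at 1 kb
    max(abs(a - b) / pmax(abs(b), 1))
  }
  hits <- list()
  for (pid in unique(library$pair_id)) {
    lib <- library[library$pair_id == pid, , drop = FALSE]
    if (nrow(lib) != 2) next
    sig <- probe_signature(lib$start_kb, lib$end_kb)
    fwd <- max(mapply(rel_err, obs, sig))
    rev <- max(mapply(rel_err, obs, sig[c(3, 2, 1)]))
    if (min(fwd, rev) <= tolerance) {
      hits[[length(hits) + 1]] <- list(pair_id = pid, err = min(fwd, rev),
                                       orientation = if (fwd <= rev) "+" else "-",
                                       lib = lib)
    }
  }
  if (length(hits) == 0) return(list(status = "no_match"))
  if (length(hits) > 1) {
    return(list(status = "ambiguous",
                pair_ids = vapply(hits, `[[`, character(1), "pair_id")))
  }
  hit <- hits[[1]]
  lib <- hit$lib[order(hit$lib$start_kb), , drop = FALSE]
  out <- m
  if (hit$orientation == "-") {
    out <- flip_molecule(out)
    flipped_start <- out$length_kb - probes$end_kb
    probes <- data.frame(start_kb = rev(flipped_start),
                         end_kb = rev(out$length_kb - probes$start_kb))
    probes <- probes[order(probes$start_kb), , drop = FALSE]
  }
  offset <- lib$start_kb[1] - probes$start_kb[1]
  out$chrom <- lib$chrom[1]
  out$offset_kb <- offset
  out$strand <- hit$orientation
  list(status = "matched", molecule = out, chrom = lib$chrom[1],
       offset_kb = offset, strand = hit$orientation, pair_id = hit$pair_id)
}

#' Read region annotations (BED-like)
#'
#' Columns `chrom`, `start_kb`, `end_kb`, `name` — used for
#' centromere/subtelomere timing analyses.
#'
#' @param path Path to a TSV file.
#' @return Data frame of regions.
#' @export
read_regions <- function(path) {
  stop_if(!file.exists(path), "no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "start_kb", "end_kb", "name")
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0,
          "missing column(s): ", paste(missing, collapse = ", "))
  df
}
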