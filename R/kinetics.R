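#' Classify replicons on a pulse/chase molecule
#'
#' Each contiguous labeled block is one record. A block containing BrdU with
#' at least one progressive fork is an *active* replicon; an EdU-only block
#' is a *newly fired* origin (fired during the chase); a BrdU-containing
#' block with no progressive fork is *terminated/ambiguous* (forks merged or
#' truncated). A side is *progressive* when its outermost segment is EdU and
#' the block edge borders unlabeled DNA inside the molecule (not the
#' molecule end). Fork velocity is measured per progressive side as the
#' outer EdU segment length divided by the chase time, and only where that
#' segment directly abuts BrdU (the replicon's own fork).
#'
#' @param m A [molecule()] with channel information.
#' @param chase_min Chase duration (min).
#' @return Data frame with one row per block: `molecule_id`, `start_kb`,
#'   `end_kb`, `origin_kb`, `class` (`active`, `newly_fired`, `terminated`),
#'   `left_status`, `right_status` (`progressive`, `nonprogressive`,
#'   `truncated`), `v_left`, `v_right` (kb/min, `NA` if not measurable).
#' @export
classify_replicons <- function(m, chase_min = 3) {
  stop_if(nrow(m$tracks) > 0 && any(is.na(m$tracks$channel)),
          "molecule ", m$id, " lacks channel information")
  stop_if(chase_min <= 0, "`chase_min` must be > 0")
  blocks <- track_union(m)
  if (nrow(blocks) == 0) {
    return(data.frame(molecule_id = character(0), start_kb = numeric(0),
                      end_kb = numeric(0), origin_kb = numeric(0),
                      class = character(0), left_status = character(0),
                      right_status = character(0), v_left = numeric(0),
                      v_right = numeric(0)))
  }
  tr <- m$tracks[order(m$tracks$start_kb), , drop = FALSE]
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    lo <- blocks[i, 1]; hi <- blocks[i, 2]
    seg <- tr[tr$start_kb >= lo - 1e-9 & tr$end_kb <= hi + 1e-9, , drop = FALSE]
    has_brdu <- any(seg$channel == "BrdU")
    at_left <- lo <= 1e-9
    at_right <- hi >= m$length_kb - 1e-9
    left_seg <- seg[1, ]
    right_seg <- seg[nrow(seg), ]
    side <- function(at_end, outer_ch) {
      if (at_end) "truncated"
      else if (outer_ch == "EdU") "progressive"
      else "nonprogressive"
    }
    ls <- side(at_left, left_seg$channel)
    rs <- side(at_right, right_seg$channel)
    cls <- if (!has_brdu) "newly_fired"
    else if (ls == "progressive" || rs == "progressive") "active"
    else "terminated"
    # velocity only for a progressive EdU segment abutting BrdU proximally
    vel <- function(status, outer, inner_ch) {
      if (status != "progressive" || !has_brdu) return(NA_real_)
      if (!identical(inner_ch, "BrdU")) return(NA_real_)
      (outer$end_kb - outer$start_kb) / chase_min
    }
    vl <- vel(ls, left_seg, if (nrow(seg) > 1) seg$channel[2] else NA)
    vr <- vel(rs, right_seg, if (nrow(seg) > 1) seg$channel[nrow(seg) - 1] else NA)
    data.frame(molecule_id = m$id, start_kb = lo, end_kb = hi,
               origin_kb = (lo + hi) / 2, class = cls,
               left_status = ls, right_status = rs,
               v_left = vl, v_right = vr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fork velocities from progressive forks
#'
#' @param records Output of [classify_replicons()] (rows from one or many
#'   molecules).
#' @return List with `velocities` (kb/min), `mean_kb_min`, `sd_kb_min`, `n`.
#' @export
estimate_fork_velocities <- function(records) {
  v <- c(records$v_left[records$left_status == "progressive"],
         records$v_right[records$right_status == "progressive"])
  v <- v[!is.na(v) & v > 0]
  list(velocities = v, mean_kb_min = mean(v), sd_kb_min = stats::sd(v),
       n = length(v))
}

#' Per-molecule firing-rate and replicon-density measurements
#'
#' For each pulse/chase molecule: the firing rate is newly fired origins per
#' minute of chase per Mb of unreplicated DNA; the density is active
#' replicons per 100 kb of unreplicated DNA; genome-scaled counts multiply
#' per-molecule counts by (genome length / molecule length). Results are
#' also binned by replication fraction.
#'
#' @param molecules Pulse/chase molecules.
#' @param genome A [genome_spec()].
#' @param chase_min Chase duration (min).
#' @param bin_width Width of the replication-fraction bins.
#' @return List with `per_molecule` and `binned` data frames.
#' @export
firing_and_density_profiles <- function(molecules, genome = genome_spec(),
                                        chase_min = 3, bin_width = 0.05) {
  rows <- lapply(molecules, function(m) {
    rec <- classify_replicons(m, chase_min)
    f <- replication_fraction(m)
    unrep_kb <- m$length_kb * (1 - f)
    newly <- sum(rec$class == "newly_fired")
    active <- sum(rec$class == "active")
    data.frame(
      molecule_id = m$id, length_kb = m$length_kb, f = f,
      newly_fired = newly, active = active, unreplicated_kb = unrep_kb,
      rate_per_min_mb = if (unrep_kb > 1e-6) newly / (chase_min * unrep_kb / 1000) else NA_real_,
      density_per_100kb = if (unrep_kb > 1e-6) active / unrep_kb * 100 else NA_real_,
      active_per_genome = active * genome$total_kb / m$length_kb,
      newly_per_genome = newly * genome$total_kb / m$length_kb,
      stringsAsFactors = FALSE)
  })
  per_mol <- do.call(rbind, rows)
  rownames(per_mol) <- NULL
  bins <- cut(per_mol$f, breaks = seq(0, 1, by = bin_width),
              include.lowest = TRUE)
  agg <- function(v) tapply(v, bins, mean, na.rm = TRUE)
  binned <- data.frame(
    f_mid = tapply(per_mol$f, bins, mean),
    n = as.integer(table(bins)),
    rate_per_min_mb = agg(per_mol$rate_per_min_mb),
    density_per_100kb = agg(per_mol$density_per_100kb),
    active_per_genome = agg(per_mol$active_per_genome))
  binned <- binned[binned$n > 0, , drop = FALSE]
  rownames(binned) <- NULL
  list(per_molecule = per_mol, binned = binned)
}

#' Fork velocity versus local origin density
#'
#' Scores fired-origin counts and mean progressive-fork velocities in
#' consecutive windows (default 300 kb) along each molecule and reports
#' their correlation with a permutation p-value (velocities shuffled across
#' windows).
#'
#' @param molecules Pulse/chase molecules.
#' @param window_kb Window size (kb).
#' @param chase_min Chase duration (min).
#' @param n_perm Permutations.
#' @param seed Integer seed.
#' @return List with `table` (per window), `correlation`, `p`.
#' @export
velocity_vs_density <- function(molecules, window_kb = 300, chase_min = 3,
                                n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (m in molecules) {
    rec <- classify_replicons(m, chase_min)
    if (nrow(rec) == 0) next
    n_win <- floor(m$length_kb / window_kb)
    if (n_win < 1) next
    for (w in seq_len(n_win)) {
      lo <- (w - 1) * window_kb; hi <- w * window_kb
      inw <- rec$origin_kb >= lo & rec$origin_kb < hi
      vv <- c(rec$v_left[inw & rec$left_status == "progressive"],
              rec$v_right[inw & rec$right_status == "progressive"])
      vv <- vv[!is.na(vv)]
      rows[[length(rows) + 1]] <- data.frame(
        molecule_id = m$id, window = w, n_origins = sum(inw),
        mean_velocity = if (length(vv) > 0) mean(vv) else NA_real_,
        n_forks = length(vv), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$mean_velocity) & tab$n_origins > 0
  stop_if(sum(ok) < 3, "not enough windows with measurable forks")
  r_obs <- stats::cor(tab$n_origins[ok], tab$mean_velocity[ok])
  perm <- vapply(seq_len(n_perm), function(b)
    stats::cor(tab$n_origins[ok], sample(tab$mean_velocity[ok])), numeric(1))
  list(table = tab, correlation = r_obs,
       p = (1 + sum(abs(perm) >= abs(r_obs))) / (n_perm + 1))
}

#' Relative replication timing of annotated regions
#'
#' For each aligned molecule covering an annotated region (centromere,
#' subtelomere, ...), compares the replicated fraction inside the region
#' with the replicated fraction of the rest of the molecule. Early regions
#' plot above the diagonal, late regions below.
#'
#' @param molecules Aligned molecules (`chrom`, `offset_kb` set).
#' @param regions Data frame `chrom`, `start_kb`, `end_kb`, `name`.
#' @return Data frame `molecule_id`, `region`, `region_fraction`,
#'   `rest_fraction`.
#' @export
region_timing <- function(molecules, regions) {
  rows <- list()
  for (m in molecules) {
    if (is.na(m$chrom) || is.na(m$offset_kb)) next
    cov <- track_union(m)
    total_cov <- interval_total(cov)
    for (r in seq_len(nrow(regions))) {
      if (regions$chrom[r] != m$chrom) next
      lo <- regions$start_kb[r] - m$offset_kb
      hi <- regions$end_kb[r] - m$offset_kb
      lo2 <- max(lo, 0); hi2 <- min(hi, m$length_kb)
      if (hi2 - lo2 <= 0) next
      reg_cov <- intersect_length(cov, lo2, hi2)
      reg_len <- hi2 - lo2
      rest_len <- m$length_kb - reg_len
      # a region spanning the whole molecule is trivially on the diagonal
      rest_frac <- if (rest_len > 1e-9) (total_cov - reg_cov) / rest_len else
        reg_cov / reg_len
      rows[[length(rows) + 1]] <- data.frame(
        molecule_id = m$id, region = regions$name[r],
        region_fraction = reg_cov / reg_len,
        rest_fraction = rest_frac,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(molecule_id = character(0),
                                      region = character(0),
                                      region_fraction = numeric(0),
                                      rest_fraction = numeric(0))
  out
}

#' Overlap of early-firing origins between successive S-phases
#'
#' A second-round origin overlaps when it lies within `match_kb` of a
#' first-round early origin (or inside a supplied first-round early track).
#' The expectation under independence is obtained by permuting the
#' second-round positions uniformly over the genome (per chromosome,
#' preserving counts).
#'
#' @param early1,early2 Data frames `chrom`, `pos_kb` (e.g. from
#'   [generate_successive_sphases()]).
#' @param genome A [genome_spec()].
#' @param match_kb Matching window(s) (kb); a vector yields a sensitivity
#'   scan.
#' @param early1_intervals Optional list per chromosome of interval matrices
#'   for first-round early tracks.
#' @param n_perm Permutations.
#' @param seed Integer seed.
#' @return Data frame per `match_kb` value: `match_kb`, `n_second`,
#'   `overlap`, `non_overlap`, `fraction`, `expected_fraction`, `p_perm`.
#' @export
memory_overlap <- function(early1, early2, genome = genome_spec(),
                           match_kb = 5, early1_intervals = NULL,
                           n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n2 <- nrow(early2)
  stop_if(n2 == 0, "no second-round origins")
  count_overlap <- function(e2pos, e2chr, mk) {
    sum(vapply(seq_along(e2pos), function(i) {
      p1 <- early1$pos_kb[early1$chrom == e2chr[i]]
      hit <- length(p1) > 0 && any(abs(p1 - e2pos[i]) <= mk)
      if (!hit && !is.null(early1_intervals)) {
        iv <- early1_intervals[[e2chr[i]]]
        hit <- !is.null(iv) && nrow(iv) > 0 &&
          any(e2pos[i] >= iv[, 1] & e2pos[i] < iv[, 2])
      }
      hit
    }, logical(1)))
  }
  rows <- lapply(match_kb, function(mk) {
    obs <- count_overlap(early2$pos_kb, early2$chrom, mk)
    perm <- vapply(seq_len(n_perm), function(b) {
      pos_b <- unlist(lapply(names(genome$chromosomes), function(ch) {
        k <- sum(early2$chrom == ch)
        stats::runif(k, 0, genome$chromosomes[[ch]])
      }))
      chr_b <- rep(names(genome$chromosomes),
                   vapply(names(genome$chromosomes),
                          function(ch) sum(early2$chrom == ch), integer(1)))
      count_overlap(pos_b, chr_b, mk)
    }, integer(1))
    data.frame(match_kb = mk, n_second = n2, overlap = obs,
               non_overlap = n2 - obs, fraction = obs / n2,
               expected_fraction = mean(perm) / n2,
               p_perm = (1 + sum(perm >= obs)) / (n_perm + 1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate total origins fired per genome from late-S molecules
#'
#' Counts distinct labeled blocks on molecules at least `min_fraction`
#' replicated and scales by genome / molecule length. Merged replicons
#' count once, so this reproduces the deliberate underestimate of the
#' combing assay rather than correcting it.
#'
#' @param molecules Pulse/chase molecules.
#' @param genome A [genome_spec()].
#' @param min_fraction Minimum replicated fraction (default 0.85).
#' @return List with `estimate` (mean genome-scaled block count),
#'   `per_molecule` data frame and `n_molecules`.
#' @export
total_origins_estimate <- function(molecules, genome = genome_spec(),
                                   min_fraction = 0.85) {
  rows <- lapply(molecules, function(m) {
    f <- replication_fraction(m)
    if (f < min_fraction) return(NULL)
    k <- nrow(track_union(m))
    data.frame(molecule_id = m$id, f = f, blocks = k,
               scaled = k * genome$total_kb / m$length_kb,
               stringsAsFactors = FALSE)
  })
  per_mol <- do.call(rbind, rows)
  if (is.null(per_mol)) {
    return(list(estimate = NA_real_, per_molecule = NULL, n_molecules = 0L))
  }
  list(estimate = mean(per_mol$scaled), per_molecule = per_mol,
       n_molecules = nrow(per_mol))
}
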