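#' Call replication clusters on origin positions
#'
#' Single left-to-right sweep per molecule: adjacent origins are chained
#' while the gap is at most `d_max_kb` (inclusive), and maximal chains with
#' at least `min_n` origins are emitted. The result is deterministic and
#' unique. Cluster span runs from the first to the last member origin
#' midpoint.
#'
#' @param origins Data frame of origin calls (`molecule_id`, `origin_kb`),
#'   e.g. from [call_origins()] / [measure_iods()] upstream, or a list of
#'   molecules (origins are called first).
#' @param params A [cluster_params()] (defaults: gap <= 40 kb, >= 5 origins).
#' @return List of class `cluster_calls` with `clusters` (data frame
#'   `molecule_id`, `cluster_id`, `start_kb`, `end_kb`, `span_kb`,
#'   `n_origins`, `mean_iod_kb`) and `origins` (the input calls plus a
#'   `cluster_id` column, `NA` outside clusters).
#' @examples
#' o <- data.frame(molecule_id = "m", origin_kb = c(0, 30, 60, 90, 120))
#' call_clusters(o)$clusters$span_kb   # 120
#' @export
call_clusters <- function(origins, params = cluster_params()) {
  if (is.list(origins) && !is.data.frame(origins)) {
    origins <- do.call(rbind, lapply(origins, call_origins))
  }
  stopifnot(inherits(params, "cluster_params"))
  origins <- origins[order(origins$molecule_id, origins$origin_kb), ,
                     drop = FALSE]
  rownames(origins) <- NULL
  origins$cluster_id <- rep(NA_integer_, nrow(origins))
  clusters <- list()
  for (mid in unique(origins$molecule_id)) {
    idx <- which(origins$molecule_id == mid)
    pos <- origins$origin_kb[idx]
    if (length(pos) == 0) next
    chain <- cumsum(c(TRUE, diff(pos) > params$d_max_kb + 1e-9))
    cid <- 0L
    for (ch in unique(chain)) {
      members <- idx[chain == ch]
      if (length(members) < params$min_n) next
      cid <- cid + 1L
      origins$cluster_id[members] <- cid
      p <- origins$origin_kb[members]
      clusters[[length(clusters) + 1]] <- data.frame(
        molecule_id = mid, cluster_id = cid,
        start_kb = min(p), end_kb = max(p), span_kb = max(p) - min(p),
        n_origins = length(p), mean_iod_kb = mean(diff(p)),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(clusters) > 0) do.call(rbind, clusters) else {
    data.frame(molecule_id = character(0), cluster_id = integer(0),
               start_kb = numeric(0), end_kb = numeric(0),
               span_kb = numeric(0), n_origins = integer(0),
               mean_iod_kb = numeric(0))
  }
  structure(list(clusters = clusters, origins = origins, params = params),
            class = "cluster_calls")
}

#' @export
print.cluster_calls <- function(x, ...) {
  cat("<cluster_calls>", nrow(x$clusters), "clusters over",
      length(unique(x$origins$molecule_id)), "molecules",
      sprintf("(d_max %g kb, min_n %d)\n", x$params$d_max_kb, x$params$min_n))
  invisible(x)
}

# Two-segment least-squares elbow on a descending curve; the break is at an
# integer x shared by both segments.
two_segment_elbow <- function(x, y) {
  fit_sse <- function(xx, yy) {
    if (length(xx) < 2) return(0)
    sum(stats::resid(stats::lm(yy ~ xx))^2)
  }
  sse_one <- fit_sse(x, y)
  ks <- x[c(-1, -length(x))]
  sse <- vapply(ks, function(k) {
    fit_sse(x[x <= k], y[x <= k]) + fit_sse(x[x >= k], y[x >= k])
  }, numeric(1))
  k_best <- ks[which.min(sse)]
  list(elbow = k_best, sse_two = min(sse), sse_one = sse_one,
       improvement = 1 - min(sse) / max(sse_one, 1e-12))
}

#' Scan the minimum-origins-per-cluster threshold
#'
#' Varies `min_n` over a range (default 2–10) at fixed `d_max`, counts
#' clusters scaled to whole-genome terms, and locates the transition point
#' of the steeply descending segment as the break of a two-segment linear
#' least-squares fit.
#'
#' @param origins Origin calls (as for [call_clusters()]).
#' @param analyzed_kb Total analyzed molecule length (kb), for genome scaling.
#' @param d_max_kb Maximum within-cluster gap (kb).
#' @param min_n_range Integer range of `min_n` values.
#' @param genome A [genome_spec()].
#' @return List with `curve` (data frame `min_n`, `clusters_per_genome`),
#'   `elbow` (break of the two-segment linear fit) and `improvement`
#'   (fit-improvement ratio of the two-segment over the single-line fit on
#'   the semilog curve; near zero for geometric-null decay).
#' @export
transition_point_scan <- function(origins, analyzed_kb, d_max_kb = 40,
                                  min_n_range = 2:10,
                                  genome = genome_spec()) {
  if (is.list(origins) && !is.data.frame(origins)) {
    analyzed_kb <- sum(vapply(origins, function(m) m$length_kb, numeric(1)))
    origins <- do.call(rbind, lapply(origins, call_origins))
  }
  stop_if(missing(analyzed_kb) || is.null(analyzed_kb) || analyzed_kb <= 0,
          "`analyzed_kb` must be supplied (> 0) for genome scaling")
  # chain sizes once at d_max; count chains >= k for each k
  sizes <- integer(0)
  for (mid in unique(origins$molecule_id)) {
    pos <- sort(origins$origin_kb[origins$molecule_id == mid])
    if (length(pos) == 0) next
    chain <- cumsum(c(TRUE, diff(pos) > d_max_kb + 1e-9))
    sizes <- c(sizes, as.integer(table(chain)))
  }
  scale <- genome$total_kb / analyzed_kb
  counts <- vapply(min_n_range, function(k) sum(sizes >= k), numeric(1))
  curve <- data.frame(min_n = min_n_range,
                      clusters_per_genome = counts * scale)
  el <- two_segment_elbow(curve$min_n, curve$clusters_per_genome)
  # elbow strength on the semilog curve: under a no-cluster null the counts
  # decay ~geometrically (log-linear, little to gain from a second segment),
  # whereas a characteristic cluster size puts a kink in the log curve
  y <- curve$clusters_per_genome
  el_log <- two_segment_elbow(curve$min_n, log(pmax(y, max(y) * 1e-3)))
  list(curve = curve, elbow = el$elbow, improvement = el_log$improvement)
}

#' Summary statistics of called clusters
#'
#' Reports within-cluster IOD summaries, the cluster-size (span) histogram,
#' genome-scaled cluster counts (overall and per replication-extent bin),
#' origins per cluster, the fraction of origins inside clusters, a summary
#' of between-cluster IODs, and — when focus counts are supplied — a
#' cluster/foci correspondence table.
#'
#' @param calls A `cluster_calls` object.
#' @param molecules The molecules the origins were called on.
#' @param genome A [genome_spec()].
#' @param foci_counts Optional named numeric vector of focus counts per
#'   nucleus category (compared against scaled cluster counts).
#' @param size_bin_kb Bin width of the span histogram (kb).
#' @return List of class `cluster_summary`.
#' @export
cluster_statistics <- function(calls, molecules, genome = genome_spec(),
                               foci_counts = NULL, size_bin_kb = 20) {
  stopifnot(inherits(calls, "cluster_calls"))
  cl <- calls$clusters
  analyzed_kb <- sum(vapply(molecules, function(m) m$length_kb, numeric(1)))
  fracs <- vapply(molecules, replication_fraction, numeric(1))
  names(fracs) <- vapply(molecules, function(m) m$id, character(1))
  bins <- bin_by_extent(fracs)

  within_iods <- unlist(lapply(seq_len(nrow(cl)), function(i) {
    p <- calls$origins$origin_kb[
      calls$origins$molecule_id == cl$molecule_id[i] &
        !is.na(calls$origins$cluster_id) &
        calls$origins$cluster_id == cl$cluster_id[i]]
    diff(sort(p))
  }))
  # between-cluster IODs: consecutive-origin gaps not internal to a cluster
  between_iods <- unlist(lapply(unique(calls$origins$molecule_id), function(mid) {
    o <- calls$origins[calls$origins$molecule_id == mid, , drop = FALSE]
    if (nrow(o) < 2) return(NULL)
    g <- diff(o$origin_kb)
    same <- !is.na(o$cluster_id[-nrow(o)]) & !is.na(o$cluster_id[-1]) &
      o$cluster_id[-nrow(o)] == o$cluster_id[-1]
    g[!same]
  }))

  per_bin <- lapply(levels(bins), function(bn) {
    mids <- names(fracs)[bins == bn]
    kb <- sum(vapply(molecules[match(mids, names(fracs))],
                     function(m) m$length_kb, numeric(1)))
    ncl <- sum(cl$molecule_id %in% mids)
    data.frame(bin = bn, analyzed_kb = kb, clusters = ncl,
               clusters_per_genome = if (kb > 0) ncl * genome$total_kb / kb else NA_real_)
  })
  per_bin <- do.call(rbind, per_bin)

  size_hist <- if (nrow(cl) > 0) {
    h <- graphics::hist(cl$span_kb,
                        breaks = seq(0, max(cl$span_kb) + size_bin_kb,
                                     by = size_bin_kb), plot = FALSE)
    data.frame(mid_kb = h$mids, count = h$counts)
  } else data.frame(mid_kb = numeric(0), count = numeric(0))

  out <- list(
    n_clusters = nrow(cl),
    clusters_per_genome = nrow(cl) * genome$total_kb / analyzed_kb,
    clusters_per_genome_by_bin = per_bin,
    origins_per_cluster = if (nrow(cl) > 0) mean(cl$n_origins) else NA_real_,
    within_mean_iod_kb = if (length(within_iods)) mean(within_iods) else NA_real_,
    within_median_iod_kb = if (length(within_iods)) stats::median(within_iods) else NA_real_,
    between_mean_iod_kb = if (length(between_iods)) mean(between_iods) else NA_real_,
    between_median_iod_kb = if (length(between_iods)) stats::median(between_iods) else NA_real_,
    fraction_origins_in_clusters =
      if (nrow(calls$origins) > 0) mean(!is.na(calls$origins$cluster_id)) else 0,
    mean_span_kb = if (nrow(cl) > 0) mean(cl$span_kb) else NA_real_,
    size_histogram = size_hist,
    analyzed_kb = analyzed_kb)
  if (!is.null(foci_counts)) {
    out$foci_correspondence <- data.frame(
      category = names(foci_counts), foci = as.numeric(foci_counts),
      clusters_per_genome = out$clusters_per_genome)
  }
  structure(out, class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat("<cluster_summary>", x$n_clusters, "clusters,",
      sprintf("%.1f per genome; %.1f origins/cluster; within-IOD mean %.1f kb; %.0f%% of origins in clusters\n",
              x$clusters_per_genome, x$origins_per_cluster,
              x$within_mean_iod_kb, 100 * x$fraction_origins_in_clusters))
  invisible(x)
}

#' Test whether new origins fire adjacent to existing clusters
#'
#' Counts chase-phase (newly fired) origins within `adjacency_kb` of
#' pulse-phase cluster spans, against the expectation under uniform
#' placement on the unreplicated DNA of the same molecules (Monte-Carlo
#' permutation).
#'
#' @param calls `cluster_calls` on the pulse-phase origins.
#' @param new_origins Data frame `molecule_id`, `origin_kb` of chase-only
#'   origins.
#' @param molecules The molecules (for unreplicated territory).
#' @param adjacency_kb Adjacency window around cluster spans (kb).
#' @param n_perm Permutations.
#' @param seed Integer seed.
#' @return List with `observed`, `expected`, `enrichment`, `p`.
#' @export
cluster_extension <- function(calls, new_origins, molecules,
                              adjacency_kb = 40, n_perm = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mols <- stats::setNames(molecules,
                          vapply(molecules, function(m) m$id, character(1)))
  near_cluster <- function(mid, pos) {
    cl <- calls$clusters[calls$clusters$molecule_id == mid, , drop = FALSE]
    if (nrow(cl) == 0 || length(pos) == 0) return(0L)
    sum(vapply(pos, function(p)
      any(p >= cl$start_kb - adjacency_kb & p <= cl$end_kb + adjacency_kb),
      logical(1)))
  }
  mids <- unique(new_origins$molecule_id)
  observed <- sum(vapply(mids, function(mid)
    near_cluster(mid, new_origins$origin_kb[new_origins$molecule_id == mid]),
    integer(1)))
  n_new_total <- nrow(new_origins)
  if (n_new_total == 0) {
    return(list(observed = 0L, expected = 0, enrichment = NA_real_,
                p = NA_real_, n_new = 0L))
  }
  perm_counts <- vapply(seq_len(n_perm), function(b) {
    tot <- 0L
    for (mid in mids) {
      m <- mols[[mid]]
      k <- sum(new_origins$molecule_id == mid)
      if (is.null(m) || k == 0) next
      cov <- track_union(m)
      bounds <- c(0, as.vector(t(cov)), m$length_kb)
      gs <- bounds[seq(1, length(bounds), by = 2)]
      ge <- bounds[seq(2, length(bounds), by = 2)]
      keep <- ge - gs > 1e-9
      gaps <- cbind(gs[keep], ge[keep])
      glen <- gaps[, 2] - gaps[, 1]
      if (sum(glen) <= 0) next
      u <- stats::runif(k, 0, sum(glen))
      gi <- findInterval(u, c(0, cumsum(glen)), left.open = TRUE,
                         rightmost.closed = TRUE)
      gi <- pmin(pmax(gi, 1L), nrow(gaps))
      pos <- gaps[gi, 1] + (u - c(0, cumsum(glen))[gi])
      tot <- tot + near_cluster(mid, pos)
    }
    tot
  }, integer(1))
  expected <- mean(perm_counts)
  list(observed = observed, expected = expected,
       enrichment = if (expected > 0) observed / expected else NA_real_,
       p = (1 + sum(perm_counts >= observed)) / (n_perm + 1),
       n_new = n_new_total)
}

#' Fraction of aligned molecules with a cluster at reference positions
#'
#' For molecules aligned to a common genomic frame, reports per reference
#' interval the fraction of covering molecules whose called cluster spans
#' intersect it (any-intersection rule), with a permutation null obtained
#' by re-placing each molecule's cluster spans uniformly at random within
#' the molecule.
#'
#' @param molecules Aligned molecules (`chrom`, `offset_kb` set).
#' @param calls `cluster_calls` on those molecules (molecule frame).
#' @param reference Data frame `chrom`, `start_kb`, `end_kb`, `name` of
#'   reference positions (genomic frame).
#' @param n_perm Permutations.
#' @param seed Integer seed.
#' @return Data frame per reference: `name`, `n_molecules`, `n_overlap`,
#'   `fraction`, `p_perm`.
#' @export
positional_overlap <- function(molecules, calls, reference, n_perm = 1000,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  info <- lapply(molecules, function(m) {
    stop_if(is.na(m$chrom) || is.na(m$offset_kb),
            "molecule ", m$id, " is not aligned (chrom/offset missing)")
    cl <- calls$clusters[calls$clusters$molecule_id == m$id, , drop = FALSE]
    list(id = m$id, chrom = m$chrom, g_start = m$offset_kb,
         g_end = m$offset_kb + m$length_kb, L = m$length_kb,
         spans = cbind(cl$start_kb, cl$end_kb))
  })
  frac_at <- function(spans_list, ref) {
    cover <- vapply(info, function(x)
      x$chrom == ref$chrom && x$g_start < ref$end_kb && x$g_end > ref$start_kb,
      logical(1))
    if (!any(cover)) return(c(n = 0, k = 0))
    hit <- vapply(which(cover), function(i) {
      sp <- spans_list[[i]]
      if (nrow(sp) == 0) return(FALSE)
      gs <- info[[i]]$g_start + sp[, 1]
      ge <- info[[i]]$g_start + sp[, 2]
      any(gs < ref$end_kb & ge > ref$start_kb)
    }, logical(1))
    c(n = sum(cover), k = sum(hit))
  }
  spans_obs <- lapply(info, `[[`, "spans")
  rows <- lapply(seq_len(nrow(reference)), function(r) {
    ref <- reference[r, ]
    obs <- frac_at(spans_obs, ref)
    perm <- vapply(seq_len(n_perm), function(b) {
      sp_b <- lapply(info, function(x) {
        if (nrow(x$spans) == 0) return(x$spans)
        w <- x$spans[, 2] - x$spans[, 1]
        st <- stats::runif(length(w), 0, pmax(x$L - w, 1e-9))
        cbind(st, st + w)
      })
      f <- frac_at(sp_b, ref)
      if (f["n"] > 0) f["k"] / f["n"] else NA_real_
    }, numeric(1))
    perm <- perm[!is.na(perm)]
    obs_frac <- if (obs["n"] > 0) obs["k"] / obs["n"] else NA_real_
    data.frame(name = ref$name, n_molecules = obs["n"], n_overlap = obs["k"],
               fraction = obs_frac,
               p_perm = if (length(perm) > 0 && !is.na(obs_frac)) {
                 (1 + sum(perm >= obs_frac)) / (length(perm) + 1)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
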