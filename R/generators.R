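# Static molecule generators: clustered and uniform origin placements,
# rDNA arrays, and paired successive S-phases.

# Expand origin midpoints to tracks such that the union of tracks covers
# `extent * length_kb` of the molecule. Track lengths are staggered
# (exponential relative widths, emulating tracks of different ages from
# staggered firing) and scaled by a common factor solved by bisection;
# overlapping tracks merge into single blocks (the physical behavior of
# adjoining replicons). Uses the current RNG stream for the width draws.
origins_to_tracks <- function(origins, length_kb, extent, channel = "BrdU",
                              stagger = TRUE) {
  stop_if(extent <= 0 || extent >= 1, "replication extent must be in (0, 1)")
  n <- length(origins)
  if (n == 0) return(tracks_df())
  target <- extent * length_kb
  rel <- if (stagger) stats::rexp(n) else rep(1, n)
  union_len <- function(s) {
    interval_total(merge_intervals(pmax(origins - rel * s / 2, 0),
                                   pmin(origins + rel * s / 2, length_kb)))
  }
  lo <- 0; hi <- 4 * length_kb
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (union_len(mid) < target) lo <- mid else hi <- mid
  }
  s <- (lo + hi) / 2
  stop_if(abs(union_len(s) - target) > 1e-3 * length_kb,
          "infeasible replication extent ", extent, " for ", n,
          " origins on a ", length_kb, "-kb molecule")
  iv <- merge_intervals(pmax(origins - rel * s / 2, 0),
                        pmin(origins + rel * s / 2, length_kb))
  tracks_df(iv[, 1], iv[, 2], channel)
}

resolve_extent <- function(replication_extent, n, lo_ok = 0, hi_ok = 1) {
  ext <- if (length(replication_extent) == 2 && n != 2) {
    stats::runif(n, replication_extent[1], replication_extent[2])
  } else rep_len(replication_extent, n)
  stop_if(any(ext <= lo_ok) || any(ext > hi_ok),
          "replication extent must lie in (", lo_ok, ", ", hi_ok, "]")
  ext
}

#' Generate molecules with clustered origin placement (two-regime model)
#'
#' Static generator for the two regimes of stochastic origin selection:
#' cluster anchors are placed uniformly (on average `clusters_per_genome`
#' scaled to the molecule length, kept spatially distinct so the planted
#' count is observable), each cluster lays down its origins with
#' truncated-exponential spacings (median 17 kb, max 40 kb), and sparse
#' origins fill the molecule with exponential spacings (median 160 kb).
#' Each origin is expanded to a track so that the molecule's replicated
#' fraction matches `replication_extent`. The planted truth (cluster
#' membership per origin) is attached to each molecule as attribute
#' `truth` and can be collected with [planted_truth()].
#'
#' @param params A [clustered_placement_params()].
#' @param genome A [genome_spec()] (used to scale cluster counts).
#' @param replication_extent Replicated fraction per molecule, in (0, 0.5]
#'   (the analysis regime). A scalar, a vector per molecule, or a length-2
#'   range from which per-molecule extents are drawn uniformly.
#' @param seed Integer seed.
#' @param n_molecules Number of molecules.
#' @param mol_length_kb Molecule length(s) in kb (default 1800, the mean
#'   length of the analyzed cohort).
#' @return List of [molecule()] objects with `truth` attributes.
#' @export
generate_two_regime_molecules <- function(params = clustered_placement_params(),
                                          genome = genome_spec(),
                                          replication_extent = c(0.05, 0.5),
                                          seed = NULL, n_molecules = 131,
                                          mol_length_kb = 1800) {
  stopifnot(inherits(params, "clustered_placement_params"))
  if (!is.null(seed)) set.seed(seed)
  lens <- rep_len(mol_length_kb, n_molecules)
  ext <- resolve_extent(replication_extent, n_molecules, hi_ok = 0.5)

  sparse_rate <- log(2) / params$between_median_kb
  if (!is.null(params$target_cluster_fraction)) {
    # rescale sparse intensity so E[in-cluster fraction] hits the target
    exp_in <- params$clusters_per_genome * params$origins_per_cluster_mean
    exp_sparse <- exp_in * (1 - params$target_cluster_fraction) /
      params$target_cluster_fraction
    sparse_rate <- exp_sparse / genome$total_kb
  }
  # spacing law: exponential truncated at within_max_kb whose truncated
  # median equals within_median_kb (the quoted "50% of IODs < 17 kb")
  within_rate <- truncated_exp_rate(params$within_median_kb,
                                    params$within_max_kb)
  u_max <- stats::pexp(params$within_max_kb, within_rate)

  mols <- vector("list", n_molecules)
  for (i in seq_len(n_molecules)) {
    L <- lens[i]
    n_cl <- stats::rpois(1, params$clusters_per_genome * L / genome$total_kb)
    cl_pos <- numeric(0); cl_id <- integer(0)
    spans <- matrix(numeric(0), ncol = 2)
    if (n_cl > 0) {
      for (k in seq_len(n_cl)) {
        size <- params$origins_per_cluster_min +
          stats::rpois(1, params$origins_per_cluster_mean -
                         params$origins_per_cluster_min)
        sp <- stats::qexp(stats::runif(size - 1, 0, u_max), within_rate)
        rel <- cumsum(c(0, sp))
        # anchors are uniform, but planted clusters are kept spatially
        # distinct: an anchor whose cluster would chain (come within the
        # truncation bound) into an already-placed cluster is redrawn, so
        # the planted count matches the observable (distinct) cluster count
        po <- NULL
        for (try in 1:25) {
          anchor <- stats::runif(1, 0, L)
          cand <- anchor - max(rel) / 2 + rel
          cand <- cand + max(0, -min(cand)) - max(0, max(cand) - L)
          cand <- pmin(pmax(cand, 0), L)
          if (nrow(spans) == 0 ||
              all(min(cand) > spans[, 2] + params$within_max_kb |
                    max(cand) < spans[, 1] - params$within_max_kb)) {
            po <- cand
            break
          }
        }
        if (is.null(po)) next                      # molecule too crowded
        cl_pos <- c(cl_pos, po)
        cl_id <- c(cl_id, rep(k, size))
        spans <- rbind(spans, c(min(po), max(po)))
      }
    }
    # sparse background: renewal process, excluding planted cluster spans
    sp_pos <- numeric(0)
    xx <- stats::rexp(1, sparse_rate)
    while (xx < L) {
      sp_pos <- c(sp_pos, xx)
      xx <- xx + stats::rexp(1, sparse_rate)
    }
    if (nrow(spans) > 0 && length(sp_pos) > 0) {
      inside <- vapply(sp_pos, function(p)
        any(p >= spans[, 1] & p <= spans[, 2]), logical(1))
      sp_pos <- sp_pos[!inside]
    }
    pos <- c(cl_pos, sp_pos)
    id <- c(cl_id, rep(0L, length(sp_pos)))
    o <- order(pos)
    truth <- data.frame(pos_kb = pos[o], cluster = id[o])
    tracks <- if (length(pos) > 0) {
      origins_to_tracks(truth$pos_kb, L, ext[i])
    } else tracks_df()
    m <- molecule(sprintf("cl_mol_%03d", i), L, tracks)
    attr(m, "truth") <- truth
    attr(m, "extent") <- ext[i]
    mols[[i]] <- m
  }
  mols
}

#' Generate molecules with uniformly placed origins (stochastic null)
#'
#' Origin positions are i.i.d. uniform along each molecule, so spacings are
#' uniform order-statistic gaps (asymptotically exponential). This is both
#' the matched stochastic null for the survival-curve comparison and the
#' generator for evenly firing chromatin-mutant-like cohorts.
#'
#' @param n_origins Expected origins per genome (scalar; per-molecule counts
#'   are Poisson with mean scaled by molecule length), or a vector of exact
#'   per-molecule counts of length `n_molecules`.
#' @param genome A [genome_spec()].
#' @param replication_extent As in [generate_two_regime_molecules()] but
#'   allowed up to 1.
#' @param seed Integer seed.
#' @param n_molecules,mol_length_kb Cohort geometry.
#' @return List of [molecule()] objects; molecules with fewer than two
#'   origins (no measurable IOD) carry attribute `flagged = TRUE`.
#' @export
generate_uniform_molecules <- function(n_origins, genome = genome_spec(),
                                       replication_extent = 0.3, seed = NULL,
                                       n_molecules = 131,
                                       mol_length_kb = 1800) {
  if (!is.null(seed)) set.seed(seed)
  lens <- rep_len(mol_length_kb, n_molecules)
  ext <- resolve_extent(replication_extent, n_molecules, hi_ok = 1)
  counts <- if (length(n_origins) == n_molecules && n_molecules > 1) {
    as.integer(n_origins)
  } else {
    stats::rpois(n_molecules, n_origins * lens / genome$total_kb)
  }
  lapply(seq_len(n_molecules), function(i) {
    pos <- sort(stats::runif(counts[i], 0, lens[i]))
    tracks <- if (counts[i] > 0) origins_to_tracks(pos, lens[i], ext[i]) else tracks_df()
    m <- molecule(sprintf("unif_mol_%03d", i), lens[i], tracks)
    attr(m, "truth") <- data.frame(pos_kb = pos,
                                   cluster = rep(0L, length(pos)))
    attr(m, "extent") <- ext[i]
    if (counts[i] < 2) attr(m, "flagged") <- TRUE
    m
  })
}

#' Generate rDNA-array molecules
#'
#' Tandem arrays of identical repeats (default 100 x 10 kb), each containing
#' one potential origin at the repeat midpoint that fires independently with
#' probability `firing_prob`; fired origins carry a short-pulse track. With
#' firing probability p the measured inter-origin distance averages
#' `repeat_kb / p` (geometric spacing of fired repeats).
#'
#' @param n_molecules Number of array molecules.
#' @param n_repeats Repeats per array.
#' @param repeat_kb Repeat unit length (kb).
#' @param firing_prob Per-repeat firing probability in `[0, 1]`.
#' @param track_kb Track length produced by the short pulse (kb).
#' @param seed Integer seed.
#' @return List of [molecule()] objects.
#' @export
generate_rdna_array <- function(n_molecules = 200, n_repeats = 100,
                                repeat_kb = 10, firing_prob = 0.2,
                                track_kb = 4, seed = NULL) {
  stop_if(firing_prob < 0 || firing_prob > 1,
          "`firing_prob` must be in [0, 1]")
  stop_if(track_kb >= repeat_kb, "`track_kb` must be smaller than the repeat")
  if (!is.null(seed)) set.seed(seed)
  L <- n_repeats * repeat_kb
  lapply(seq_len(n_molecules), function(i) {
    fired <- which(stats::runif(n_repeats) < firing_prob)
    pos <- (fired - 0.5) * repeat_kb
    tracks <- if (length(pos) > 0) {
      tracks_df(pos - track_kb / 2, pos + track_kb / 2, "BrdU")
    } else tracks_df()
    m <- molecule(sprintf("rdna_%03d", i), L, tracks)
    attr(m, "truth") <- data.frame(pos_kb = pos,
                                   cluster = rep(0L, length(pos)))
    m
  })
}

#' Collect planted truth from generated molecules
#'
#' @param molecules Output of a generator.
#' @return Data frame `molecule_id`, `pos_kb`, `cluster` (0 = sparse).
#' @export
planted_truth <- function(molecules) {
  do.call(rbind, lapply(molecules, function(m) {
    tr <- attr(m, "truth")
    if (is.null(tr) || nrow(tr) == 0) return(NULL)
    cbind(data.frame(molecule_id = m$id, stringsAsFactors = FALSE), tr)
  }))
}

#' Simulate two successive S-phases and their early-firing origins
#'
#' Runs two whole-genome simulations and extracts the origins fired within
#' `early_window` minutes of each S-phase start. Under
#' `refire_model = "independent"` the second round is drawn afresh; under
#' `"inherited"` each first-round early origin re-fires early in round two
#' with probability `p_inherit` (the remainder of round two is filled with
#' independently simulated early origins thinned by `1 - p_inherit`).
#'
#' @param genome,profile Simulation parameters.
#' @param early_window Early-firing window (min, > 0).
#' @param refire_model `"independent"` or `"inherited"`.
#' @param p_inherit Re-firing probability for the inherited model.
#' @param seed Integer seed.
#' @return List with `early1`, `early2` (data frames `chrom`, `pos_kb`,
#'   `time_min`), the two `sphase_sim` objects and parameters; class
#'   `successive_sphases`.
#' @export
generate_successive_sphases <- function(genome = genome_spec(),
                                        profile = kinetic_profile(),
                                        early_window = 6,
                                        refire_model = c("independent", "inherited"),
                                        p_inherit = 1, seed = NULL) {
  refire_model <- match.arg(refire_model)
  stop_if(early_window <= 0, "`early_window` must be > 0")
  stop_if(p_inherit < 0 || p_inherit > 1, "`p_inherit` must be in [0, 1]")
  sim1 <- simulate_genome_sphase(genome, profile, seed = derive_seed(seed, 1))
  sim2 <- simulate_genome_sphase(genome, profile, seed = derive_seed(seed, 2))
  early1 <- sim1$events[sim1$events$time_min <= early_window, , drop = FALSE]
  e2 <- sim2$events[sim2$events$time_min <= early_window, , drop = FALSE]
  if (refire_model == "inherited") {
    if (!is.null(seed)) set.seed(derive_seed(seed, 3))
    kept <- early1[stats::runif(nrow(early1)) < p_inherit, , drop = FALSE]
    fresh <- e2[stats::runif(nrow(e2)) < 1 - p_inherit, , drop = FALSE]
    early2 <- rbind(kept, fresh)
  } else {
    early2 <- e2
  }
  rownames(early1) <- rownames(early2) <- NULL
  structure(list(early1 = early1, early2 = early2, sim1 = sim1, sim2 = sim2,
                 early_window = early_window, refire_model = refire_model,
                 p_inherit = p_inherit, genome = genome, profile = profile),
            class = "successive_sphases")
}
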