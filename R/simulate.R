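#' Simulate a whole-genome stochastic S-phase
#'
#' Time-stepped nucleation-and-growth simulation: at each step, new origins
#' fire as a Poisson draw with mean `r(f) * (unreplicated Mb) * dt`, placed
#' uniformly on unreplicated territory (no phantom origins inside replicated
#' DNA), and every fork advances `v * dt` bidirectionally, annihilating
#' pairwise on meeting. With a constant rate `I` per kb per min this process
#' obeys the one-dimensional KJMA law `f(t) = 1 - exp(-I v t^2)`.
#'
#' Because all forks move at the same speed and origins only fire in
#' unreplicated gaps, the replication-timing map is exactly
#' `T(x) = min_i (t_i + |x - x_i| / v)` over the fired origins; it is stored
#' analytically (piecewise linear) and used by [label_pulse_chase()].
#'
#' @param genome A [genome_spec()].
#' @param profile A [kinetic_profile()].
#' @param seed Integer seed (all randomness flows from it).
#' @param time_step Step size in minutes (default 0.1; firing probabilities
#'   per step are then well below 1 at the default rates).
#' @param max_time Safety bound on simulated time (min).
#' @return An object of class `sphase_sim` with elements `events` (data frame
#'   `chrom`, `pos_kb`, `time_min`), `timing` (piecewise-linear timing map),
#'   `trajectory` (data frame `time_min`, `f`, `forks`, `origins_cum`),
#'   `t_end`, plus the genome/profile/seed used.
#' @examples
#' sim <- simulate_genome_sphase(genome_spec(c(chr = 1000)), seed = 1)
#' tail(sim$trajectory, 1)$f  # 1: replication completes
#' @export
simulate_genome_sphase <- function(genome = genome_spec(),
                                   profile = kinetic_profile(),
                                   seed = NULL, time_step = 0.1,
                                   max_time = 500) {
  stop_if(time_step <= 0, "`time_step` must be > 0")
  stopifnot(inherits(genome, "genome_spec"), inherits(profile, "kinetic_profile"))
  if (!is.null(seed)) set.seed(seed)

  chroms <- names(genome$chromosomes)
  lens <- unname(genome$chromosomes)
  v <- profile$v
  pos <- lapply(chroms, function(i) numeric(0))
  tim <- lapply(chroms, function(i) numeric(0))
  names(pos) <- names(tim) <- chroms

  t <- 0
  traj_t <- traj_f <- traj_forks <- traj_orig <- numeric(0)
  n_steps <- ceiling(max_time / time_step)

  for (step in seq_len(n_steps)) {
    t <- step * time_step
    unrep <- 0
    forks <- 0L
    gaps <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      L <- lens[ci]
      if (length(pos[[ci]]) == 0) {
        unrep <- unrep + L
        gaps[[ci]] <- cbind(start = 0, end = L)
        next
      }
      radius <- v * (t - tim[[ci]])
      iv <- merge_intervals(pmax(pos[[ci]] - radius, 0),
                            pmin(pos[[ci]] + radius, L))
      forks <- forks + sum(iv[, 1] > 1e-9) + sum(iv[, 2] < L - 1e-9)
      # unreplicated gaps between replicated eyes
      bounds <- c(0, as.vector(t(iv)), L)
      gs <- bounds[seq(1, length(bounds), by = 2)]
      ge <- bounds[seq(2, length(bounds), by = 2)]
      keep <- ge - gs > 1e-9
      gaps[[ci]] <- cbind(start = gs[keep], end = ge[keep])
      unrep <- unrep + sum(ge[keep] - gs[keep])
    }
    f <- 1 - unrep / genome$total_kb

    n_new <- 0L
    if (unrep > 1e-9) {
      lambda <- firing_rate(profile, f) * (unrep / 1000) * time_step
      n_new <- stats::rpois(1, lambda)
      if (n_new > 0) {
        gap_len <- vapply(gaps, interval_total, numeric(1))
        u <- sort(stats::runif(n_new, 0, unrep))
        cum_chrom <- cumsum(gap_len)
        ci_for <- findInterval(u, c(0, cum_chrom), rightmost.closed = TRUE,
                               left.open = TRUE)
        ci_for <- pmin(pmax(ci_for, 1L), length(chroms))
        t_fire <- stats::runif(n_new, t - time_step, t)  # jitter within step
        for (k in seq_len(n_new)) {
          ci <- ci_for[k]
          within <- u[k] - if (ci > 1) cum_chrom[ci - 1] else 0
          g <- gaps[[ci]]
          glen <- g[, 2] - g[, 1]
          gi <- findInterval(within, c(0, cumsum(glen)), rightmost.closed = TRUE,
                             left.open = TRUE)
          gi <- pmin(pmax(gi, 1L), nrow(g))
          x <- g[gi, 1] + (within - c(0, cumsum(glen))[gi])
          pos[[ci]] <- c(pos[[ci]], x)
          tim[[ci]] <- c(tim[[ci]], t_fire[k])
        }
      }
    }

    traj_t <- c(traj_t, t)
    traj_f <- c(traj_f, f)
    traj_forks <- c(traj_forks, forks + 2L * n_new)
    traj_orig <- c(traj_orig, sum(lengths(pos)))
    if (unrep <= 1e-9) break
  }
  stop_if(traj_f[length(traj_f)] < 1 - 1e-9 &&
            firing_rate(profile, 0) > 0 && t >= max_time,
          "simulation did not complete within `max_time`")

  events <- data.frame(
    chrom = rep(chroms, lengths(pos)),
    pos_kb = unlist(pos, use.names = FALSE) %||% numeric(0),
    time_min = unlist(tim, use.names = FALSE) %||% numeric(0),
    stringsAsFactors = FALSE)
  events <- events[order(events$chrom, events$pos_kb), , drop = FALSE]
  rownames(events) <- NULL

  structure(list(events = events,
                 timing = timing_map(events, genome, v, t_end = t),
                 trajectory = data.frame(time_min = traj_t, f = traj_f,
                                         forks = traj_forks,
                                         origins_cum = traj_orig),
                 t_end = t, genome = genome, profile = profile, seed = seed),
            class = "sphase_sim")
}

#' @export
print.sphase_sim <- function(x, ...) {
  cat("<sphase_sim>", nrow(x$events), "origins fired,",
      sprintf("S-phase %.1f min, final f = %.3f\n",
              x$t_end, x$trajectory$f[nrow(x$trajectory)]))
  invisible(x)
}

#' Replication-timing map from a set of firing events
#'
#' Builds the exact piecewise-linear timing map `T(x) = min_i (t_i +
#' |x - x_i|/v)` for each chromosome. Valid whenever all forks move at speed
#' `v` and origins fire only in unreplicated DNA (so no origin is shadowed
#' by a neighbor).
#'
#' @param events Data frame with `chrom`, `pos_kb`, `time_min`.
#' @param genome A [genome_spec()].
#' @param v Fork velocity (kb/min).
#' @param t_end Simulation end time; positions with `T(x) > t_end` are
#'   unreplicated.
#' @return An object of class `timing_map`: per chromosome, a data frame of
#'   segments `start`, `end`, `t_start`, `t_end` with linear interpolation
#'   in between (`Inf` on never-replicated territory).
#' @export
timing_map <- function(events, genome, v, t_end = Inf) {
  segs <- lapply(seq_along(genome$chromosomes), function(ci) {
    ch <- names(genome$chromosomes)[ci]
    L <- unname(genome$chromosomes[ci])
    e <- events[events$chrom == ch, , drop = FALSE]
    if (nrow(e) == 0) {
      return(data.frame(start = 0, end = L, t_start = Inf, t_end = Inf))
    }
    e <- e[order(e$pos_kb), , drop = FALSE]
    x <- e$pos_kb; tt <- e$time_min
    n <- length(x)
    meet <- if (n > 1) {
      pmin(pmax((x[-n] + x[-1]) / 2 + v * (tt[-1] - tt[-n]) / 2, x[-n]), x[-1])
    } else numeric(0)
    # boundary sequence 0, x1, m1, x2, m2, ..., xn, L
    b <- c(0, as.vector(rbind(x, c(meet, NA)))[seq_len(2 * n - 1)], L)
    seg_start <- b[-length(b)]
    seg_end <- b[-1]
    t_at <- function(xx, oi) tt[oi] + abs(xx - x[oi]) / v
    oi <- rep(seq_len(n), each = 2)[seq_along(seg_start)]
    data.frame(start = seg_start, end = seg_end,
               t_start = t_at(seg_start, oi), t_end = t_at(seg_end, oi))
  })
  names(segs) <- names(genome$chromosomes)
  structure(list(segments = segs, genome = genome, v = v, t_end = t_end),
            class = "timing_map")
}

#' Evaluate a timing map
#'
#' @param tm A [timing_map()].
#' @param chrom Chromosome name.
#' @param x Positions in kb.
#' @return Replication times in minutes (`Inf` if never replicated).
#' @export
eval_timing <- function(tm, chrom, x) {
  seg <- tm$segments[[chrom]]
  stop_if(is.null(seg), "unknown chromosome: ", chrom)
  i <- findInterval(x, seg$start, rightmost.closed = FALSE)
  i <- pmin(pmax(i, 1L), nrow(seg))
  w <- (x - seg$start[i]) / pmax(seg$end[i] - seg$start[i], 1e-12)
  ifelse(is.infinite(seg$t_start[i]), Inf,
         seg$t_start[i] + w * (seg$t_end[i] - seg$t_start[i]))
}

# Intervals {x : a <= T(x) < b} for one chromosome, merged.
timing_window_intervals <- function(tm, chrom, a, b) {
  seg <- tm$segments[[chrom]]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(seg))) {
    t0 <- seg$t_start[i]; t1 <- seg$t_end[i]
    if (is.infinite(t0) && is.infinite(t1)) next
    lo <- min(t0, t1); hi <- max(t0, t1)
    ca <- max(a, lo); cb <- min(b, hi)
    if (cb <= ca) next
    len <- seg$end[i] - seg$start[i]
    if (abs(t1 - t0) < 1e-12) {            # flat segment (degenerate)
      xs <- seg$start[i]; xe <- seg$end[i]
    } else if (t1 > t0) {                  # T increasing along x
      xs <- seg$start[i] + (ca - t0) / (t1 - t0) * len
      xe <- seg$start[i] + (cb - t0) / (t1 - t0) * len
    } else {                               # T decreasing along x
      xs <- seg$start[i] + (cb - t0) / (t1 - t0) * len
      xe <- seg$start[i] + (ca - t0) / (t1 - t0) * len
    }
    out_s <- c(out_s, xs); out_e <- c(out_e, xe)
  }
  merge_intervals(out_s, out_e)
}

#' Pulse/chase label a simulated genome
#'
#' Positions replicated during `[t0, t0 + pulse)` are labeled BrdU
#' (channel 1); positions replicated during `[t0 + pulse, t0 + pulse +
#' chase)` are labeled EdU (channel 2). Maximal labeled runs become tracks;
#' tracks shorter than the detection minimum are dropped. DNA replicated
#' before `t0` or still unreplicated at the end of the chase is unlabeled.
#' Returns one molecule per chromosome (apply [fragment_and_stretch()] for
#' realistic combed fragments).
#'
#' @param tm A [timing_map()] (or an `sphase_sim`, whose map is used).
#' @param t0 Labeling start (min).
#' @param pulse Pulse duration (min).
#' @param chase Chase duration (min, default 3).
#' @param noise A [combing_noise()] supplying the detection minimum.
#' @return List of [molecule()] objects, one per chromosome, with `chrom`
#'   and `offset_kb = 0` set.
#' @export
label_pulse_chase <- function(tm, t0, pulse, chase = 3,
                              noise = combing_noise()) {
  if (inherits(tm, "sphase_sim")) tm <- tm$timing
  stopifnot(inherits(tm, "timing_map"))
  stop_if(pulse < 0 || chase < 0, "pulse and chase durations must be >= 0")
  stop_if(t0 < 0, "`t0` must be >= 0")
  stop_if(is.finite(tm$t_end) && t0 > tm$t_end,
          "labeling starts after the simulation ended (t0 > t_end)")
  lapply(names(tm$segments), function(ch) {
    L <- unname(tm$genome$chromosomes[ch])
    brdu <- timing_window_intervals(tm, ch, t0, t0 + pulse)
    edu <- if (chase > 0) {
      timing_window_intervals(tm, ch, t0 + pulse, t0 + pulse + chase)
    } else matrix(numeric(0), ncol = 2)
    tracks <- rbind(tracks_df(brdu[, 1], brdu[, 2], "BrdU"),
                    tracks_df(edu[, 1], edu[, 2], "EdU"))
    tracks <- normalize_tracks(tracks, min_track_kb = noise$min_track_kb,
                               merge_gap_kb = 0)
    molecule(ch, L, tracks, chrom = ch, offset_kb = 0, strand = "+")
  })
}

#' Label a simulation at a target replication fraction
#'
#' Convenience wrapper for the synchronized-culture design: the pulse runs
#' from the start of S-phase and is chased for `chase` minutes, with the
#' sampling time chosen (from the simulated trajectory) so that the genome
#' is a fraction `f_target` replicated at the end of the chase.
#'
#' @param sim An `sphase_sim`.
#' @param f_target Genome replicated fraction at sampling.
#' @param chase Chase duration (min).
#' @param noise A [combing_noise()].
#' @return List with `molecules` (per chromosome) and `t_sample`.
#' @export
label_at_fraction <- function(sim, f_target, chase = 3,
                              noise = combing_noise()) {
  stopifnot(inherits(sim, "sphase_sim"))
  stop_if(f_target <= 0 || f_target > 1, "`f_target` must be in (0, 1]")
  tr <- sim$trajectory
  ts <- if (f_target >= max(tr$f)) sim$t_end else {
    stats::approx(tr$f, tr$time_min, xout = f_target, ties = "ordered")$y
  }
  ts <- max(ts, chase)
  list(molecules = label_pulse_chase(sim$timing, 0, ts - chase, chase, noise),
       t_sample = ts)
}
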