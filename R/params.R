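#' Genome layout for the simulator
#'
#' The default corresponds to the three fission yeast chromosomes (5.6, 4.5
#' and 3.5 Mb), i.e. a 13.6-Mb genome. All coordinates in the package are in
#' kb, 0-based, half-open.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in kb.
#' @return An object of class `genome_spec` with elements `chromosomes` and
#'   `total_kb`.
#' @examples
#' genome_spec()$total_kb   # 13600
#' @export
genome_spec <- function(chromosomes = c(chrI = 5600, chrII = 4500, chrIII = 3500)) {
  stop_if(!is.numeric(chromosomes) || length(chromosomes) < 1,
          "`chromosomes` must be a numeric vector of lengths in kb")
  stop_if(any(chromosomes <= 0), "all chromosome lengths must be > 0")
  if (is.null(names(chromosomes))) {
    names(chromosomes) <- paste0("chr", seq_along(chromosomes))
  }
  structure(list(chromosomes = chromosomes, total_kb = sum(chromosomes)),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec>", length(x$chromosomes), "chromosomes,",
      x$total_kb, "kb total\n")
  invisible(x)
}

#' S-phase kinetic parameters
#'
#' The firing rate is expressed in origins per minute per Mb of *unreplicated*
#' DNA, as a function of the genome replicated fraction f: a linear ramp from
#' `r0` at f = 0 to `r_mid` at f = `f_knee`, constant afterwards. Defaults
#' (2 -> 8 over the first half of S-phase, forks at 2.8 kb/min, 3-min chase)
#' are the calibration used throughout the package.
#'
#' @param r0 Firing rate at the start of S-phase (origins/min/Mb unreplicated).
#' @param r_mid Plateau firing rate reached at `f_knee`.
#' @param f_knee Replicated fraction at which the ramp ends.
#' @param v Fork velocity in kb/min.
#' @param pulse_min Default labeling pulse duration (min).
#' @param chase_min Default chase duration (min).
#' @return An object of class `kinetic_profile`.
#' @export
kinetic_profile <- function(r0 = 2, r_mid = 8, f_knee = 0.5, v = 2.8,
                            pulse_min = 2, chase_min = 3) {
  stop_if(v <= 0, "fork velocity `v` must be > 0")
  stop_if(pulse_min < 0 || chase_min < 0, "pulse/chase durations must be >= 0")
  stop_if(f_knee <= 0 || f_knee > 1, "`f_knee` must lie in (0, 1]")
  prof <- structure(list(r0 = r0, r_mid = r_mid, f_knee = f_knee, v = v,
                         pulse_min = pulse_min, chase_min = chase_min),
                    class = "kinetic_profile")
  stop_if(any(firing_rate(prof, seq(0, 1, by = 0.01)) < 0),
          "firing rate must be non-negative on [0, 1]")
  prof
}

#' Firing rate at a given replicated fraction
#'
#' @param profile A [kinetic_profile()].
#' @param f Replicated fraction(s) in `[0, 1]`.
#' @return Origins per minute per Mb of unreplicated DNA (vectorized).
#' @export
firing_rate <- function(profile, f) {
  with(profile, r0 + (r_mid - r0) * pmin(f, f_knee) / f_knee)
}

#' Combing measurement-noise model
#'
#' Molecule-level multiplicative stretch (mean 146/150, CV 15/146, from
#' repeated measurement of a 150-kb probe), a 2-kb coordinate grid, a 2-kb
#' detection minimum for tracks, and exponential fragmentation with mean
#' 1800 kb (fragments under 200 kb are discarded, matching the analysis of
#' long molecules only).
#'
#' @param stretch_mean Mean multiplicative stretch factor.
#' @param stretch_cv Coefficient of variation of the stretch factor.
#' @param resolution_kb Coordinate grid (kb).
#' @param min_track_kb Minimum detectable track length (kb).
#' @param fragment_mean_kb Mean fragment length (kb).
#' @param min_fragment_kb Fragments shorter than this are discarded (kb).
#' @return An object of class `combing_noise`.
#' @export
combing_noise <- function(stretch_mean = 146 / 150, stretch_cv = 15 / 146,
                          resolution_kb = 2, min_track_kb = 2,
                          fragment_mean_kb = 1800, min_fragment_kb = 200) {
  stop_if(stretch_mean <= 0, "stretch factor mean must be > 0")
  stop_if(resolution_kb <= 0, "resolution must be > 0")
  stop_if(fragment_mean_kb <= 0, "fragment mean length must be > 0")
  structure(list(stretch_mean = stretch_mean, stretch_cv = stretch_cv,
                 resolution_kb = resolution_kb, min_track_kb = min_track_kb,
                 fragment_mean_kb = fragment_mean_kb,
                 min_fragment_kb = min_fragment_kb),
            class = "combing_noise")
}

#' Parameters of the static clustered origin placement
#'
#' Calibration of the two-regime generator: on average 25 clusters per genome
#' with a mean of 12 (minimum 5) origins each, within-cluster spacings
#' exponential with median 17 kb truncated at 40 kb, and sparse inter-cluster
#' origins with exponential spacings of median 160 kb. The emergent in-cluster
#' origin fraction under these laws is above the nominal 60%; setting
#' `target_cluster_fraction` rescales the sparse intensity so that the
#' expected in-cluster fraction matches the target (see the methods vignette).
#'
#' @param clusters_per_genome Expected clusters on a full genome.
#' @param origins_per_cluster_mean Mean origins per cluster.
#' @param origins_per_cluster_min Minimum origins per cluster (>= 5).
#' @param within_median_kb Median of within-cluster spacings (kb).
#' @param within_max_kb Truncation bound for within-cluster spacings (kb).
#' @param between_median_kb Median of sparse (between-cluster) spacings (kb).
#' @param target_cluster_fraction Optional target fraction of origins inside
#'   clusters; `NULL` (default) keeps the `between_median_kb` spacing law.
#' @return An object of class `clustered_placement_params`.
#' @export
clustered_placement_params <- function(clusters_per_genome = 25,
                                       origins_per_cluster_mean = 12,
                                       origins_per_cluster_min = 5,
                                       within_median_kb = 17,
                                       within_max_kb = 40,
                                       between_median_kb = 160,
                                       target_cluster_fraction = NULL) {
  stop_if(origins_per_cluster_min < 5, "clusters are defined by >= 5 origins")
  stop_if(within_max_kb < within_median_kb,
          "truncation bound must be >= the within-cluster median")
  stop_if(!is.null(target_cluster_fraction) &&
            (target_cluster_fraction <= 0 || target_cluster_fraction >= 1),
          "`target_cluster_fraction` must be in (0, 1)")
  structure(list(clusters_per_genome = clusters_per_genome,
                 origins_per_cluster_mean = origins_per_cluster_mean,
                 origins_per_cluster_min = origins_per_cluster_min,
                 within_median_kb = within_median_kb,
                 within_max_kb = within_max_kb,
                 between_median_kb = between_median_kb,
                 target_cluster_fraction = target_cluster_fraction),
            class = "clustered_placement_params")
}

#' Cluster-calling parameters
#'
#' @param d_max_kb Maximum inter-origin distance within a cluster (kb,
#'   inclusive).
#' @param min_n Minimum number of origins defining a cluster.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(d_max_kb = 40, min_n = 5) {
  stop_if(d_max_kb <= 0, "`d_max_kb` must be > 0")
  stop_if(min_n < 2, "`min_n` must be >= 2")
  structure(list(d_max_kb = d_max_kb, min_n = min_n), class = "cluster_params")
}
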