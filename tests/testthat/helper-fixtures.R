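# Shared fixtures: hand-built molecules and tiny timing maps.

make_mol <- function(id, len, starts = numeric(0), ends = numeric(0),
                     channel = "BrdU", ...) {
  molecule(id, len, tracks_df(starts, ends, channel), ...)
}

# Timing map for a single chromosome with origins at `pos` fired at `times`.
make_timing <- function(pos, times, L = 1000, v = 2.8, t_end = 100) {
  g <- genome_spec(c(chr = L))
  ev <- data.frame(chrom = rep("chr", length(pos)), pos_kb = pos,
                   time_min = times)
  timing_map(ev, g, v, t_end = t_end)
}

# Noise model that only rounds to the grid (no stretch, no fragmentation).
identity_noise <- function(resolution_kb = 2, min_track_kb = 2) {
  combing_noise(stretch_mean = 1, stretch_cv = 0,
                resolution_kb = resolution_kb, min_track_kb = min_track_kb,
                fragment_mean_kb = 1e9, min_fragment_kb = 0)
}

# Noise-free measurement: continuous coordinates, no detection floor, no
# stretch — but the usual fragmentation into ~1.8-Mb molecules.
clean_noise <- function() {
  combing_noise(stretch_mean = 1, stretch_cv = 0, resolution_kb = 1e-3,
                min_track_kb = 0)
}

# Match called origins to nearest planted origin per molecule; returns the
# calls with a `true_cluster` column.
match_to_truth <- function(calls_origins, truth) {
  out <- calls_origins
  out$true_cluster <- NA_integer_
  for (i in seq_len(nrow(out))) {
    tr <- truth[truth$molecule_id == out$molecule_id[i], , drop = FALSE]
    if (nrow(tr) == 0) next
    out$true_cluster[i] <- tr$cluster[which.min(abs(tr$pos_kb - out$origin_kb[i]))]
  }
  out
}

# Exact mean coverage fraction for nucleation rate I (per kb per min) and
# fork speed v on a finite chromosome of length L: numerical average over x
# of 1 - exp(-I * A(x, t)), where A is the nucleation cone clipped at the
# chromosome ends. Independent oracle for the simulator.
kjma_finite_f <- function(t, I, v, L, nx = 801) {
  x <- seq(0, L, length.out = nx)
  clip <- function(d) pmax(v * t - d, 0)^2 / (2 * v)
  A <- v * t^2 - clip(x) - clip(L - x)
  mean(1 - exp(-I * pmax(A, 0)))
}
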