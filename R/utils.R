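# Internal helpers shared across modules.

# Round to the combing coordinate grid (half-up, so 13 -> 14 at res 2 never
# depends on IEEE round-half-to-even).
grid_round <- function(x, resolution_kb) {
  floor(x / resolution_kb + 0.5) * resolution_kb
}

# Deterministic sub-seed derivation so one user-facing seed can drive several
# internal random stages without reusing the stream.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k * 1000003) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Merge a set of [start, end) intervals; intervals separated by gaps smaller
# than `gap_tol` are fused. Returns a two-column matrix.
merge_intervals <- function(start, end, gap_tol = 1e-9) {
  keep <- end - start > 0
  start <- start[keep]; end <- end[keep]
  if (length(start) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + gap_tol) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  cbind(start = out_s, end = out_e)
}

interval_total <- function(iv) {
  if (nrow(iv) == 0L) 0 else sum(iv[, 2] - iv[, 1])
}

# Clip intervals to [lo, hi) and express them relative to lo.
clip_intervals <- function(iv, lo, hi) {
  s <- pmax(iv[, 1], lo); e <- pmin(iv[, 2], hi)
  keep <- e - s > 1e-9
  cbind(start = s[keep] - lo, end = e[keep] - lo)
}

# Length of the intersection between one interval [a,b) and a set of intervals.
intersect_length <- function(iv, a, b) {
  if (nrow(iv) == 0L) return(0)
  sum(pmax(0, pmin(iv[, 2], b) - pmax(iv[, 1], a)))
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# Rate of an exponential truncated at `upper` whose TRUNCATED median equals
# `median`; requires median < upper / 2 (the truncated-uniform limit).
truncated_exp_rate <- function(median, upper) {
  if (!is.finite(upper)) return(log(2) / median)
  stop_if(median >= upper / 2,
          "median of the truncated law must be below half the truncation bound")
  stats::uniroot(function(l) stats::pexp(median, l) - 0.5 * stats::pexp(upper, l),
                 interval = c(1e-8, 10), tol = 1e-10)$root
}
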