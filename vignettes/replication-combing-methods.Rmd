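---
title: "Models and methods: stochastic origin firing on combed molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: stochastic origin firing on combed molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(replicomb)
```

## The system and the measurement

Fission yeast replicates its 13.6-Mb genome (chromosomes of 5.6, 4.5 and
3.5 Mb) from several hundred stochastically firing origins. DNA combing
stretches single molecules — here, long ones, mean ~1.8 Mb — on glass so
that nucleotide-analog labels (BrdU pulse, EdU chase) can be measured as
*tracks* at ~2-kb resolution. The package models both the biology and the
measurement:

* **origins** are called at the midpoints of labeled blocks; a contiguous
  BrdU+EdU block is one origin unless split by unlabeled DNA;
* **inter-origin distances** (IODs) are midpoint-to-midpoint distances of
  adjacent blocks, kept only when the molecule is *less than 50%* replicated
  and *both* flanking tracks are shorter than 20 kb (strict inequalities;
  long tracks risk hiding several merged origins). Intervals to molecule
  ends are censored and discarded;
* **replication clusters** are maximal chains of at least 5 origins with
  adjacent gaps of at most 40 kb (inclusive).

Coordinates are kb, 0-based, half-open, which keeps gap and IOD arithmetic
free of off-by-one adjustments.

## The S-phase simulator

`simulate_genome_sphase()` is a time-stepped (dt = 0.1 min)
nucleation-and-growth simulation. Per step, new origins fire as a Poisson
draw with mean $r(f)\,U\,\Delta t$, where $U$ is the unreplicated length in
Mb and $r(f)$ the firing rate per minute per Mb of unreplicated DNA — a
linear ramp from 2 at $f=0$ to 8 at $f=0.5$, constant thereafter (the
calibration used throughout). Origins are placed uniformly on unreplicated
gaps only, never inside replicated DNA, matching the "per Mb of
unreplicated DNA" definition of the rate; forks advance bidirectionally at
$v = 2.8$ kb/min and annihilate pairwise. Firing times are jittered
uniformly within the step: at the default rates the per-step firing probability
is far below one, and the jitter removes the $O(\Delta t)$ lag that firing
at step boundaries would otherwise introduce.

Because all forks share one speed and firing is confined to unreplicated
DNA, the replication-timing map is exactly
$T(x) = \min_i\, (t_i + |x - x_i|/v)$ over the fired origins. The package
stores it analytically (piecewise linear per chromosome), so pulse/chase
labeling — BrdU for $T(x) \in [t_0, t_0+\text{pulse})$, EdU for the chase
window — is computed in closed form rather than on a grid. With a constant
rate $I$ per kb per min the simulator obeys the one-dimensional
nucleation-and-growth (KJMA) law $f(t) = 1 - e^{-I v t^2}$; the test suite
checks this against the *finite-chromosome* version of the law (the
nucleation cone clipped at the ends, integrated numerically), because on a
3-Mb chromosome the infinite-line formula overestimates coverage near the
ends by more than the Monte-Carlo error of a hundred runs. Total origins
fired per kb converge on $\tfrac12\sqrt{\pi I / v}$.

## Combing noise

`fragment_and_stretch()` applies the measurement model: exponential
fragmentation (mean 1800 kb; fragments under 200 kb discarded, as only
long molecules are analyzed), one multiplicative stretch factor per
fragment — normal with mean 146/150 and CV 15/146, the calibration from
repeated measurements of a 150-kb probe — and rounding to the 2-kb grid.
Stretch is applied per fragment, not per coordinate, because combing
stretch is a molecule-level phenomenon. Tracks shorter than 2 kb (the
resolution) are dropped; same-channel tracks separated by sub-resolution
gaps are merged.

## Static generators and their calibration

`generate_two_regime_molecules()` plants the two regimes of origin
spacing: clusters (25 per genome on average, 5 + Poisson(7) origins each)
with within-cluster spacings from an exponential truncated at 40 kb, and a
sparse background with exponential spacings of median 160 kb. Two details
matter:

* the truncated spacing law is parameterized by its *truncated* median
  (17 kb): truncating a median-17 exponential at 40 kb would yield a
  median of 12.5 kb and contradict the calibration ("50% of IODs in the
  domain below 17 kb"). Solving the rate so the truncated median is 17 kb
  also puts the mean cluster span near 200 kb, the modal observed size;
* cluster anchors are uniform, but an anchor whose cluster would chain
  (come within 40 kb) into an already-placed cluster is redrawn. Without
  this, a quarter of planted clusters overlap and the planted count is
  unobservable *by construction*; with it, the caller recovers planted
  counts to a few percent.

Under these laws the emergent fraction of origins inside clusters is
~0.85, higher than the nominal 60%: the three calibration figures
(25 clusters × 12 origins, 160-kb sparse spacing, 60% in-cluster) are
mutually inconsistent, and the package treats the spacing laws and cluster
counts as primitive. Setting `target_cluster_fraction` instead rescales
the sparse intensity to meet a chosen fraction.

Each origin is expanded to a track so that the molecule's labeled fraction
matches the requested replication extent; track widths are staggered
(exponential relative widths, as replicons of different ages would be)
and overlapping tracks merge, as adjoining replicons physically do. This
rendering step is deliberately lossy: at extents above ~20%, adjacent
tracks fuse, origins disappear from view, and visible gaps inflate. The
cluster-caller recovery tests therefore distinguish the *caller* (tested
on origin positions, where planted counts and membership are recovered
within a few percent) from the *measurement* (tested through rendering at
10–20% extent, where precision and recall still exceed 90%). At higher
extents recall drops because planted spacings run up to the 40-kb chaining
bound, so any fusion pushes a visible gap past it — a property of the
assay geometry, not of the algorithm.

`generate_uniform_molecules()` is the stochastic null (and the model for
cohorts with evenly distributed firing, as in histone-modification
mutants): i.i.d. uniform positions whose gaps are asymptotically
exponential. `generate_rdna_array()` models the tandem rDNA repeats: one
potential origin per 10-kb repeat, fired independently.

## IOD statistics

`survival_curve()` is the empirical exceedance function; exponential
samples are straight lines on semilog axes. `fit_exponential_regimes()`
formalizes the "two straight lines" as a two-component exponential
mixture fitted by EM: mixtures reproduce the smooth inflexion of the
observed curves, and the steep-component weight *w* is directly the
"fraction of origins in the clustered domain". The two-line rendering is
derived for plotting parity, with the breakpoint at the crossing of the
steep line through the origin with the shallow component line,
$x^\* = -\log(1-w)/(\lambda_1-\lambda_2)$. Model preference uses a
likelihood-ratio test with a parametric-bootstrap null (mixture vs single
is non-regular, so a chi-squared cutoff would be wrong; default 500
replicates, $\alpha = 0.01$); a mixture whose rates agree within 5% is
declared degenerate and the single model preferred. If the EM lands below
the single-model optimum (possible on effectively single-exponential
data), the boundary solution is reported so the nesting inequality holds.

`lilliefors_exponential()` is the Kolmogorov–Smirnov distance to the
exponential with estimated rate; since the rate is estimated, the null is
built by Monte Carlo (the statistic is scale-free, so unit-rate draws with
re-estimated rates suffice) and p-values are reported with resolution
$1/(n_\text{null}+1)$.

One measurement caveat the tests make explicit: IODs measured *through
track rendering* are not exponential even for uniformly placed origins —
tracks merge below their own width, depleting short IODs — so
exponentiality calibration is checked on origin spacings (a point
process — the natural form of a numerical null),
while `compare_with_null()` achieves calibration by construction: the
matched null (same planted origin counts, lengths and extents) is rendered
and measured through the identical pipeline, and the Monte-Carlo p
compares observed-vs-reference against null-vs-reference distances.

## Pulse/chase kinetics

`classify_replicons()` reads each contiguous labeled block as one record:
EdU-only blocks are newly fired origins; BrdU-containing blocks with at
least one *progressive* fork (outermost segment EdU, bordering unlabeled
DNA inside the molecule) are active replicons; the rest are
terminated/ambiguous. Fork velocity is the outer EdU segment length
divided by the chase time, taken only where that segment directly abuts
BrdU. Firing rate is newly fired origins per chase-minute per Mb of
unreplicated DNA; densities are active replicons per 100 kb unreplicated;
genome scaling multiplies per-molecule counts by the length ratio (not
molecule counts — molecules vary in length). Summary statistics are
averaged per molecule first, the convention of single-molecule studies; on
finite tandem arrays this also makes the mean IOD exactly unbiased for
(repeat length)/(firing probability), where the pooled mean is biased a
few percent low by the span constraint.

Two estimator-vs-protocol distinctions, documented because the tests rely
on them:

* the *velocity estimator* is unbiased to ~1% when checked with a short
  (1-min) chase and noise-free rendering; the literal 3-min protocol
  inflates it by ~4–6% because origins that fire during the chase just
  ahead of a fork fuse with its EdU tip (no scorer, human or in silico,
  can separate them), partly offset by the −2.7% stretch factor;
* the *firing-rate estimator* recovers the generative ramp within ~6% in
  the same regime, but the full 3-min protocol under-counts by ~20–40%:
  chase-fired origins near forks merge before the chase ends, and tracks
  below the 2-kb detection floor (origins fired in the last
  $\approx$ 0.36 min) are invisible. The same biases act on the real
  assay, which matters for the calibration question below.

`memory_overlap()` tests epigenetic inheritance between successive
S-phases: a second-round early origin "overlaps" if within `match_kb`
(default 5 kb, with a built-in 2–10-kb sensitivity scan) of a first-round early origin, with the independence
expectation from permutation over the genome.

## A calibration gap the package reproduces honestly

With the default parameters — rate ramping 2 → 8 origins·min⁻¹·Mb⁻¹ of
unreplicated DNA, forks at 2.8 kb/min — the simulation fires ~540 origins
per genome and holds ~250 concurrent eyes at mid-S. A steady-state
argument shows this is forced, not a bug: with nucleation intensity $I$
(per kb·min) on $U$ kb of unreplicated DNA, eyes are created at rate $IU$
and live for (mean gap)/(2v), giving $\text{eyes} \approx
\sqrt{I U^2 / 2v} \approx 260$ at $f = 0.5$. The reference mid-S census these defaults were calibrated against
(350–400 active replicons, 700–800 forks), the late-S density (~10
active replicons per 100 kb unreplicated) and the ~500 distinct-track
count on nearly replicated molecules would require an underlying rate
several-fold higher than the default ramp. This is consistent with the
detection biases above: rates of this kind are *measured* through the
3-min chase, which under-counts, so the generative rate behind such data
must exceed the measured curve. The package deliberately simulates the
measured calibration, and its reproduction script reports the
pulse/chase-detected quantities that calibration actually yields
(~120 track-count estimate, peak ~220 detected active replicons, ~8 per
100 kb late in S) rather than tuning the generator until the census
matches. Similarly, in-silico cutting of clustered molecules into 500-kb
pieces compresses the sparse regime (shallow median ~160 → 50–90 kb) but
does *not* erase the mixture's statistical detectability at cohort sample
sizes; the historical failure to see clusters on short molecules is
reproduced as a loss of visual, not likelihood-ratio, separation.

## Numerical choices and problem sizes

Bisection solves track widths to match replication extents (60 iterations
on a bracket of four molecule lengths); EM stops on a relative
log-likelihood change of 1e-7 with 300-iteration cap; elbow detection in
the min-origins scan is two-segment least squares with an integer break,
with elbow *strength* measured on the semilog curve (a no-cluster null
decays geometrically, i.e. log-linearly, so a second segment adds little
there). Permutation and bootstrap nulls default to 1000 and 500 draws with
explicit seeds; every generator draws all randomness from one seed
argument, and runs are bit-reproducible. The test suite uses 100-run
Monte-Carlo ensembles for the kinetic law, 20-seed ensembles for recovery
experiments, cohorts of 10–131 molecules, and 200–5000-draw Monte-Carlo
nulls; the reproduction script uses 20 simulation seeds and a
10,000-draw Lilliefors null.

## Limitations

The simulator has no fork stalling, no chromatin state, and no mechanistic
cluster feedback: static clustered placements model the *spatial*
two-regime structure phenomenologically at a chosen replication extent.
Probe detection errors (false merges/splits) are not modeled. The
generators' defaults encode the measured calibration; as discussed
above, detected kinetic censuses under that calibration sit below the
reference census values, and the package reports them as such.
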