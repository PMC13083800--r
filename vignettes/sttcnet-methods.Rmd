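---
title: "Methods: STTC-based functional networks from spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: STTC-based functional networks from spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sttcnet characterizes the functional organization of a population of
spiking neurons — for example, units sorted from a high-density
multielectrode array (MEA) recording of a neural organoid — from nothing
but their spike times. This vignette is the package's account of the
method: the statistics it computes, the assumptions behind them, the
parameters that matter, and what the synthetic-data tests do and do not
establish.

## The recording object

Everything consumes a `spike_train_set`: per-unit ascending spike times
in seconds over a half-open window `[t_start, t_end)`, plus metadata
(organoid id, region label DF/VF, age in days, condition). The window is
half-open so that rate denominators are unambiguous; a spike at exactly
`t_end` is rejected. Units with zero spikes are retained — they are real
units that carry no synchrony information — and are excluded only where
a statistic is undefined for them (their STTC entries are `NA`, and they
are dropped from graph construction rather than fabricated as isolated
correlates).

Developmental comparisons bin recordings by age into early (days
23–33), mid (34–45) and late (46–64) stages; ages outside 23–64 are
processed per-recording but excluded from stage contrasts. Firing-rate
and STTC summaries are reported on a log10 scale, because both
quantities are approximately log-normal across units and pairs in this
kind of preparation; the base is a documented convention (rank-based
comparisons are base-invariant) and values at or below a configurable
positive floor (default `1e-6`) are clipped with a reported tally.

## Pairwise synchrony: the spike-time tiling coefficient

For trains A and B and a coincidence half-window `dt` (default 10 ms),

$$\mathrm{STTC} = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
  \frac{P_B - T_A}{1 - P_B T_A}\right)$$

where `T_X` is the fraction of the recording tiled by `[t - dt, t + dt]`
around X's spikes (tiles clipped at the window edges and merged where
they overlap — edge handling dominates small-sample bias, so the tile
union is computed exactly) and `P_X` is the fraction of X's spikes
within `dt` of any spike of the other train. The `T` correction makes
the coefficient largely insensitive to firing rate, which matters in a
developing preparation where rates and synchrony change together.

Conventions worth stating because they are easy to get wrong:

* `dt` is a **half**-window — a tile spans `2*dt`. "A 10 ms window" is
  read as `dt = 10` ms, the standard usage; `dt` is a parameter if the
  other reading is wanted.
* Pairs involving an empty train, and pairs where a denominator is
  exactly zero, are **undefined** (`NA`), not zero. Self-pairs are
  always undefined. Undefined pairs are excluded from summaries,
  nulls and graphs; fabricating 0-correlations for silent units would
  bias every downstream density.
* The optimized implementation (interval-union by running maximum,
  nearest-spike search by `findInterval`) is validated against a
  brute-force tiling oracle to `1e-12` in the test suite, together with
  exact symmetry and translation invariance.

## Edge selection: a surrogate permutation null

Observed STTC values are compared with a null distribution computed
from surrogate data that preserve each unit's spike count, rate and ISI
structure while destroying cross-unit timing. The default surrogate is
a **circular shift**: each unit's train is rotated by an independent
uniform offset modulo the window. An alternative `isi_shuffle` permutes
each unit's inter-spike intervals. A third option, `id_shuffle`,
permutes unit labels; it is provided because label permutation is
sometimes described as a surrogate scheme, but a label permutation
leaves the *multiset* of pairwise STTC values unchanged, so it cannot
separate signal from chance — the package warns if it is used for a
null. This is a deliberate design choice in favor of statistical
validity over a literal reading of common shorthand.

By default 1,000 surrogates are generated (configurable; the package's
own tests use fewer at smaller problem sizes) and all defined pair
values are pooled into one recording-wide distribution; the edge
threshold is its 90th percentile, and an edge requires the observed
STTC to *strictly exceed* it. Pooled scope is the default because one
percentile criterion per recording is the simplest defensible rule; a
per-pair scope is available for heterogeneous-rate populations, at the
cost of far noisier per-pair thresholds. Calibration is testable: when
the observed data are themselves null (independent Poisson trains), the
suprathreshold fraction must fall in the exact binomial interval around
10%, and the test suite checks precisely that.

## Topology of the binary graph

On the thresholded graph (STTC weights retained on surviving edges):

* **Small-worldness.** `C` is the mean local clustering coefficient
  (degree < 2 contributes 0); `L` is the mean shortest path over
  connected pairs in the largest component — graphs thresholded at the
  90th percentile are often disconnected, so the component coverage is
  reported with `L` rather than silently averaging infinities.
  Normalizers `C_rand`, `L_rand` come from degree-preserving rewiring
  (double-edge swaps, `10·|E|` swaps, default 100 references): degree
  preservation is the stricter reference class and avoids inflating
  `C_norm` on heavy-tailed degree sequences. `S = (C/C_rand)/(L/L_rand)`;
  matched random graphs sit near 1 by construction, lattice-like graphs
  well above it.
* **Core–periphery.** Standard k-core decomposition; the "core" is the
  maximum k-core (parameter-free; a fixed `k` is an option) and the
  core–periphery density is the realized fraction of possible
  core–periphery edges. Both the core numbers and the density are
  tested against exhaustive oracles.
* **Hubs.** Composite hubness is the mean of four z-scored
  centralities: binary degree, strength (sum of retained STTC weights),
  normalized betweenness, and harmonic closeness (finite under
  disconnection). Equal weighting is the simplest defensible composite;
  the hub set is the top decile (configurable). A zero-variance metric
  contributes zeros with a warning rather than NaNs.
* **Communities.** Louvain on the weighted graph at resolution 1.
  Louvain is visit-order sensitive, so vertices are canonicalized
  (sorted by unit id) and shuffled under a seed: results are
  reproducible and invariant to input relabeling up to module-id
  permutation. The reported Q is verified against direct evaluation of
  the weighted modularity formula in the tests.

## Network bursts, backbone units, module timing

The burst detector is deliberately plain and fully parameterized,
because population-burst detection has no single standard: pooled spike
counts in 10 ms bins, Gaussian-smoothed (sd 50 ms), thresholded at
`mean + 2·sd` of the smoothed rate, extended outward to the flanking
rate minima, merged across gaps < 100 ms, minimum duration 50 ms. All
parameters travel with the result. Smoothing uses direct (not FFT)
convolution so that silence is exactly zero — downstream logic
distinguishes "module silent in this burst" from "tiny numerical
residue".

A **backbone unit** fires at least 2 spikes in at least 90% of network
bursts; the backbone proportion (the fraction of units that qualify) is
the network's rigidity summary. Both constants are arguments with these
defaults. Burst-to-burst stability is the mean Pearson correlation of
per-burst unit-participation vectors (constant vectors excluded with a
tally). Module-level dynamics use each module's per-unit-normalized
smoothed rate (so large modules do not dominate): module-pair
correlations are computed over concatenated burst windows, and each
module's timing spread is the SD across bursts of its peak lag relative
to the global burst peak, in ms.

## Developmental and pharmacological contrasts

The pipeline (`run_recording`) chains the stages under one master seed
(fanned out to per-stage seeds, all recorded in the report) and emits a
flat report per recording. `compare_groups` fits a per-organoid OLS
slope of log-mean STTC (and log-mean rate) against age in days,
averages slopes within groups, and bootstraps the between-group
contrast over organoids (default 10,000 resamples). Mixed-effects
models and the classical post-hoc tests are intentionally out of scope
here: they are standard library calls, whereas the OLS + bootstrap
contrast is fully specified, seeded and testable. `pharm_compare`
matches units by id between a baseline and a post-treatment recording
and reports per-unit rate deltas and per-pair STTC deltas with paired
bootstrap CIs — the signature of a pure synchrony effect (e.g. GABA-A
blockade) is an STTC delta whose CI excludes zero at a rate delta whose
CI does not.

## The synthetic generator: what it emulates, and what it does not

The generator produces fixtures with known ground truth for every
stage:

* per-unit rates drawn log-normally (`10^N(mu, sigma)`, defaults
  `mu = 0`, `sigma = 0.25`, i.e. ~1 Hz median), durations of 300 s at
  which empirical rates sit within ~3 SE of target;
* pairwise correlation by **common-parent thinning**: a coupled group
  shares a hidden parent Poisson train; members copy each parent spike
  with the group's coupling probability and jitter it (default sd 2 ms,
  well inside the 10 ms STTC window, keeping the coupling→STTC map
  steep), with independent background topping each unit up to its
  target rate. Parent rates equal the group's minimum target rate, so
  any coupling in [0,1] is feasible; an infeasible demand errors.
  Coupling is therefore a group-level parameter — block-modular
  structures and explicit coupled groups cover the use cases without
  simulating membrane dynamics;
* bursting fixtures with scripted (deterministic) or Poisson burst
  onsets, planted backbone units that emit ≥2 spikes per burst by
  construction, optional exact scripted per-burst spike counts for
  boundary-case tests, and background strictly between bursts;
* developmental series: `DF_like` ramps 2-module coupling
  (intra 0.08→0.30, inter 0.4×intra) and log10-rate mean (−0.2→0.2)
  linearly over days 23–64; `VF_like` holds a segregated 4-module
  structure (intra 0.30, inter 0.02) with the rate ramp saturating near
  day 39. These values are free parameters chosen to give realistic
  magnitudes (mean STTC of order 0.01–0.1, ~1 Hz rates), not calibrated
  claims about any real preparation; burst rates and durations in vitro
  are likewise not pinned by published numbers, so the defaults are
  declared, not inferred.

What passing these tests shows: the estimators recover planted
structure (coupling monotonicity, module partitions with ARI ≥ 0.9,
exact backbone sets, slope contrasts with the right sign and coverage)
under data whose marginal statistics resemble the target preparation.
What it does not show: robustness to spike-sorting artifacts,
non-stationarity within a recording, electrode drift, or biophysical
burst shapes — none of which the generator models.

## Numerical choices and degenerate inputs

* Problem sizes in the shipped tests: recordings of 15–30 units ×
  60–300 s, 2–100 surrogates, 4–100 random graph references, 10 master
  seeds for the recovery experiment. These are the package's default
  verification scales; every routine accepts larger inputs unchanged.
* Quantiles use R's default type-7 definition; the threshold is a
  strict `>` (an STTC exactly at the percentile is not an edge).
* Seeded routines restore the caller's RNG state; derived stage seeds
  stay within 32-bit integer range.
* Degenerate inputs degrade explicitly: < 3 nodes or < 1 edge flags
  topology as `NA`; no bursts flags backbone as `NA`; a single module
  flags module correlations; an edgeless graph yields singleton
  modules with `Q = 0` and a warning. The pipeline completes on a
  2-unit recording with every undefined field flagged.

## Known limitations

* The common-parent mechanism gives group-level, not arbitrary
  per-pair, coupling; fine-grained coupling matrices would need a
  different construction (e.g. dichotomized-Gaussian samplers).
* `id_shuffle` exists only for completeness; it is not a usable null.
* The burst detector is threshold-based and will merge genuinely
  distinct bursts closer than the merge gap; parameters must be tuned
  to the preparation's timescales.
* Strength centrality uses suprathreshold STTC weights only; with very
  sparse graphs it degenerates toward degree.
* `L` on the largest component understates path lengths of fragmented
  networks; always read it together with the reported coverage.
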