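---
title: "Deriving movement-category velocity thresholds by traversal-graph spectral clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving movement-category velocity thresholds by traversal-graph spectral clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velozone)
```

## The problem

Athlete tracking in field sports summarises external load as distance
covered inside velocity zones ("movement categories"): standing/walking,
jogging, and so on up to sprinting. The zone boundaries in routine use are
arbitrary legacy cut-offs, originally derived from video analysis of other
sports, and they misrepresent cohorts — notably women's teams — whose
velocity distributions differ from the cohort the cut-offs were built on.
`velozone` implements a data-driven alternative: the zone boundaries are
learned from the match velocity distribution itself, by unsupervised
clustering of a velocity-bin transition graph, separately for each cohort
(for example men's and women's rugby sevens squads).

## The model

**Traversal graph.** Instantaneous velocity from a 10 Hz tracking device
is discretised onto 100 half-open bins of width 0.1 m/s covering 0–10 m/s
(the top bin closed at 10.0). A *traversal* is the transition between the
bins of two adjacent samples; counting all traversals of a match file
gives a 100×100 matrix whose diagonal carries bin occupancy
(self-traversals) and whose off-diagonal mass concentrates near the
diagonal because acceleration is physiologically bounded.

**Affinity.** Spectral clustering needs a symmetric affinity. We use

\[ W = \tfrac{S}{\max S} + \beta\,C, \qquad
   S = \tfrac{1}{2}(T + T^\top), \]

where \(T\) is the traversal count matrix, \(C\) is the chain adjacency
between velocity-adjacent bins and \(\beta = 0.1\). The data term is
max-normalised so that \(\beta\) sits on a comparable scale regardless of
how many matches are pooled (the affinity is exactly invariant to uniform
scaling of the counts); the chain term keeps every bin connected to its
velocity neighbours so that bins with no shared traversals can never be
grouped across a gap, and the graph has a single connected component
(exactly one zero Laplacian eigenvalue — tested).

**Clustering.** Standard normalised spectral clustering: symmetric
normalised Laplacian \(L = I - D^{-1/2} W D^{-1/2}\), embedding by the
eigenvectors of the \(k\) smallest eigenvalues, row-normalisation to unit
length, then seeded k-means (10 restarts) on the embedded rows. Clusters
are relabelled in ascending order of occupancy-weighted mean bin velocity,
so labels always read low → high along the velocity axis.

**Occupied support.** The embedding and k-means run on the bins between
the first and the last occupied bin. Bins above a cohort's maximum
velocity (typically everything above ~8.5 m/s) carry only \(\beta\) chain
edges and no distance mass; left in, this low-volume chain is exactly what
a normalised cut splits off first, manufacturing a spurious empty
category and shifting the elbow one k upward. Excluding the unvisited
tail — while interior empty bins still participate through their chain
edges — is the same judgement the \(\beta\) term encodes: velocities never
observed must not form categories. Leading/trailing empty bins inherit
the adjacent end cluster, so derived zones still partition all of
[0, 10] m/s.

**Contiguity.** The chain term makes non-contiguous solutions rare; when
they occur, a deterministic local repair runs: one pass of an
occupancy-weighted mode filter (window of three bins), then any remaining
run of a label that also occurs elsewhere is merged into the neighbouring
run with the larger summed affinity across the boundary,
smallest-occupancy run first. Repair preserves k and is independent of
the k-means seed.

**Choosing k (elbow method).** For each k in 2..10 the within-cluster sum
of squares is computed *in velocity space*: bin-centre velocities weighted
by bin occupancy, cluster centres being occupancy-weighted means. The
selected k maximises the discrete second difference
\(\mathrm{WCSS}(k-1) - 2\,\mathrm{WCSS}(k) + \mathrm{WCSS}(k+1)\) over
interior k, ties broken toward smaller k. Computing WCSS in velocity
space rather than embedding space is an interpretation: the elbow should
reflect the physical velocity structure the thresholds live in, and it
makes the WCSS of different k directly comparable. WCSS is monotone
non-increasing in k up to k-means local optima; an increase beyond
\(10^{-6}\) of WCSS(2) is flagged with a warning, not an error.

**Two-stage cohort procedure.** Stage 1 pools the traversal matrices of
every retained match file of a cohort and selects k by the elbow. Stage 2
re-clusters *each match file independently* at that fixed k and extracts
its k−1 boundaries (the lower edge of the first bin of each upper
cluster). The cohort thresholds are the per-rank arithmetic means of the
per-match boundaries, reported to 0.01 m/s (unrounded values kept in the
provenance). Per-match clustering failures — e.g. a file whose occupied
support holds fewer than k bins — are excluded from the mean and logged.

## Data cleaning

Two rules, applied in order: any sample with velocity strictly above
10 m/s is removed (a GPS artefact; 10.0 exactly is legal and occupies the
top bin), and a file with more than 3% of its points removed is excluded
entirely (fraction relative to the original count). Removed samples leave
gaps: traversals are never counted across a gap, because bridging it would
fabricate a velocity transition that never happened. Isolated-point
removal (not segment removal) is implemented. No smoothing, interpolation
or imputation is applied anywhere.

## Zone quantification and cohort comparison

Distance is the rectangle-rule integral of velocity at the sampling rate
(v × 0.1 s per sample); each sample's distance accrues to the zone
containing its velocity. Zones are half-open [lower, upper), the final
zone closed at 10, mirroring the bin convention — published interval
notations like "2.0–3.5" are ambiguous at shared edges, so one convention
is fixed everywhere. Duration uses retained samples only, so heavy spike
removal slightly shortens effective duration (logged per file). Relative
distance is total distance per minute of retained trace; whether a study
clock or ball-in-play clock is meant by "per minute" is unknowable from
summary tables, so retained-trace duration is used.

Cohort comparisons follow a normality-gated two-sample procedure:
Shapiro–Wilk on each group at α = 0.05; Welch's t (not pooled-variance
Student: safer under the 55-vs-33 cohort imbalance) when both groups pass;
otherwise Mann–Whitney U, exact when the combined n ≤ 20 without ties,
else normal approximation with continuity and tie corrections. Constant
samples, where normality is undefined, fall through to Mann–Whitney. No
multiple-testing correction is applied by default, mirroring per-zone
reporting practice; `compare_cohorts(..., p_adjust = "holm")` enables one.
`welch_from_summary()` recomputes Welch tests from published mean ± SD
tables alone; its p agrees with the raw-sample branch to 10⁻¹².

## The synthetic locomotion generator

Real match files are not distributable, so the package ships a
first-class simulator: a semi-Markov chain over movement states
(e.g. standing/walking, jogging, striding, sprinting). Dwell times are
geometric — the simplest law with a controllable mean, since nothing in
match data constrains dwell structure — with mean 4 s per state; the next
state is drawn proportionally to a transition-weight row. Within a state,
velocity is pulled fully toward the state mean plus Gaussian noise
(sd 0.3 m/s), the per-step change clipped to ±a_max/10 with
a_max = 6 m/s², then clamped to [0, 10]. The pull-to-mean rate of 1 makes
the noise-free dynamics an exact fixed point at the state mean, which
keeps burn-in analytically predictable (start velocity 0, start state
drawn from the stationary distribution). Spikes are substitution
artefacts — the recorded value is replaced by a uniform draw in
(10, 13] — because that is what the cleaning rule targets; the dynamics
underneath are untouched.

Default cohort models place state means at (1.2, 3.2, 5.8, 7.8) m/s
(male) and (1.0, 3.0, 5.0, 7.0) m/s (female), calibrated so cleaned match
maxima land near the reported cohort maximum velocities (~8.3 and
~7.4 m/s); defaults live in `default_config()`, not in code constants.
The generator's stationary occupancy is available in closed form
(`expected_state_occupancy()`: embedded-chain stationary vector weighted
by mean dwells), which is the oracle used in the tests.

What the generator does *not* emulate: positional (x, y) structure,
satellite/HDOP error, realistic occupancy shares (symmetric transition
weights give each state ~25% of time, so simulated total distances are
several times larger than real matches, which are dominated by
low-velocity activity), heavy-tailed dwell times, or between-player
heterogeneity. Passing recovery tests therefore shows that the pipeline
recovers the generative category structure of well-separated multi-state
traces — not that real rugby data contain exactly four categories.

## Numerical choices and degenerate inputs

* Bin assignment uses `floor((v − v_min)/width)` with a 10⁻⁹ guard against
  representation error at bin edges; 10.0 maps to the top bin.
* Eigendecomposition is the deterministic base `eigen` on the symmetrised
  Laplacian; k-means uses a fixed default seed (20230021) and 10 restarts,
  with a deterministic fallback to spread initial centres when identical
  embedding rows defeat random centre sampling.
* The elbow search range is 2..10: published category counts in this
  literature span 4–6, so 10 is a generous ceiling.
* Empty bins contribute zero weight to WCSS and cluster means; clusters
  that end up with zero occupancy are ordered by unweighted bin centre.
* Per-boundary cohort averaging aligns boundaries by rank, well-defined
  because every match is clustered at the same k.
* Sub-seeds for simulation are derived with a fixed linear-congruential
  map, keeping every derived seed a valid 32-bit integer.

## Problem sizes

The bundled tests and the acceptance script run on synthetic cohorts of
20 match files of 20 minutes at 10 Hz (12,000 samples per file), ten
replicate cohorts for recovery checks, and 55 + 33 files of 14–20 minutes
for the full workflow under `analysis/` — sizes chosen to exercise every
stage at match-realistic sampling while keeping a full run in the order
of seconds to minutes on one CPU.

## Known limitations

* Thresholds are cohort-specific by construction; they describe the
  matches they were fitted on, not individual physiological capacity.
* The affinity formula (max-normalised symmetrised counts plus β-chain)
  is one defensible construction of an affinity that the source
  literature leaves unspecified; alternatives (row-stochastic smoothing,
  Gaussian kernels on transition rates) would shift boundaries slightly.
* The elbow second-difference rule inherits the usual brittleness of
  elbow heuristics when the WCSS curve is nearly linear; ties resolve to
  smaller k by design.
* With fewer than ~5 occupied bins per intended category, per-match
  clustering degenerates; such files are dropped from the cohort mean and
  reported, which biases thresholds toward the richer files.
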