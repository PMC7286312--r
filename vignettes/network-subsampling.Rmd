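---
title: "Quantifying the robustness of iEEG functional networks to electrode subsampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the robustness of iEEG functional networks to electrode subsampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegjack)
```

## The problem

Intracranial EEG networks are built from whatever electrodes a surgical
team implanted: a spatial sample of the brain chosen on clinical, not
statistical, grounds. Any graph statistic computed on such a network — the
strongest contact, the most synchronizing region, the network's global
efficiency — is therefore conditional on the sampling. `ieegjack`
operationalizes "how conditional?" by virtually removing contacts,
recomputing the statistics, and summarizing the variation three ways:
metric-level *reliability*, perturbation-level *agreement*, and
patient-level *jackknife confidence* sets/intervals.

## Network construction

Signals are conditioned in the order common average reference → elliptic
bandpass → AR prewhitening, each stage preserving the channel count.

* **Bandpass**: elliptic, 5–115 Hz, order 4, 0.5 dB passband ripple, 40 dB
  stopband attenuation, applied forward–backward for zero phase. The filter
  family and band edges are standard for seizure-band analysis; order,
  ripple and attenuation are conventional defaults and are exposed as
  arguments.
* **Notch**: second-order IIR biquad at 60 Hz, quality factor 30, also
  zero-phase. Attenuation at the notch exceeds 30 dB (tested); passband
  tones pass within ripple.
* **Prewhitening**: per-channel AR residuals, default order 1, fitted by
  minimum-norm least squares. The order is deliberately config-exposed: the
  aim is only to flatten slow dynamics and accentuate the high-frequency
  content that carries seizure dynamics, and order 1 already removes the
  bulk of the lag-1 autocorrelation (tested on AR(1) input with
  coefficient 0.9). A constant channel yields zero residuals rather than an
  error, so flat-lined contacts do not abort a batch run.

Edges are band-averaged multitaper magnitude-squared coherences on short
windows (1 s default, 2 s as a sensitivity setting), anchored so the window
*begins* at the requested offset. Slepian tapers are computed by the exact
symmetric-tridiagonal formulation with time–bandwidth product 2 and 3
tapers — a conventional choice for 1-s windows; both are arguments. Band
aggregation is the arithmetic mean of magnitude-squared coherence over the
FFT bins inside the band, bounds inclusive. The default band is high gamma
(95–105 Hz), with beta (15–25 Hz) as the usual alternative. Coherence
weights are clipped to [0, 1]; the matrix is symmetrized and its diagonal
zeroed, and these invariants plus permutation equivariance are enforced by
tests.

**Density thresholding** zeroes edges strictly below a cutoff chosen so the
retained fraction of unordered pairs hits the target (0.5 by default)
within one edge; ties at the cutoff are retained. With heavily tied weights
the target may be unreachable, in which case a warning reports the closest
achievable density — degenerate, but it must not fail silently because
subsampled matrices can be small.

## Graph metrics

All metrics follow the weighted Brain Connectivity Toolbox conventions:

* shortest paths use Dijkstra with edge length 1/weight; a zero weight is
  "no edge" (infinite length);
* betweenness is reported as raw path counts (a normalization flag is
  provided);
* transitivity and clustering normalize weights by the network maximum
  before the cube-root geometric mean of triangle weights;
* eigenvector centrality is the leading eigenvector of the adjacency,
  nonnegative, unit Euclidean norm.

Two conventions deserve comment because subsampling *creates* the edge
cases they govern. A subsampled network can be disconnected, so
synchronizability is defined as 0 when the Laplacian's second-smallest
eigenvalue (or its largest, for an edgeless network) vanishes; global
efficiency simply drops the disconnected pairs (they contribute 0).
Eigenvector centrality on a disconnected network is computed on the full
matrix with a warning — the alternative (per-component computation) changes
the meaning of the ranking that downstream agreement statistics compare.
Control centrality is the relative change in synchronizability when a
contact is deleted; it equals −1 exactly when the deletion disconnects the
network, and it is undefined (an error, and a dropped iteration in
ensembles) when the starting synchronizability is already 0. Regional
control centrality evaluates the same quantity for a seed contact plus its
`region_size − 1` nearest neighbors (Euclidean distance on the layout,
distance ties broken by lowest contact index, as everywhere in the
package).

Every metric is checked against an independent brute-force oracle —
exhaustive path/triplet enumeration, dense eigendecomposition, power
iteration — on hundreds of small random networks, and against closed forms
on complete and path graphs.

## Subsampling schemes and statistics

Four removal schemes: uniformly random sets of `round(fraction × N)`
contacts (the rounding rule is the package's choice; percentages alone
don't fix it); deterministic contiguous patches (one per seed contact);
removal of exactly the seizure-onset-zone (SOZ) contacts; and random
SOZ-sparing sets matched in size to the SOZ (degenerating to a single
deterministic set when the SOZ is the majority). One master seed drives
per-iteration substreams, so ensembles are reproducible and extensible.

Reliability is the classical variance partition R = σ²T/(σ²T + σ²E).
For nodal metrics, σ²E is the across-iteration variance per contact
averaged over contacts, and σ²T the across-contact variance per iteration
averaged over iterations; for global metrics the true-score variance is
taken across patients instead. Two choices here were genuinely open. First,
a removed contact has no value in that iteration: we compute each contact's
error variance over only the iterations retaining it, and exclude (with a
warning) contacts retained fewer than twice, rather than imputing. Second,
variances use the unbiased n−1 denominator. Both components use subsampled
(not original) networks, which avoids the size bias whereby metrics with
larger values in larger networks would look paradoxically *more* reliable
at heavier removal. R is invariant to affine rescaling of the metric and
strictly decreasing in σ²E (tested).

Agreement compares one subsampled network with the original: Spearman's ρ
over the retained contacts (nodal) or −|(m_new − m_old)/m_old| (global,
0 at perfect agreement); a signed variant preserves the direction of global
perturbations. The association of agreement with the removed patch's
centroid distance from the SOZ is summarized by Spearman's ρ and its
Fisher transform atanh(ρ) for cohort aggregation (an exact ±1 correlation
has an infinite transform and is reported as an error). Cohort-level
comparisons use a Friedman test blocked by patient with Dunn–Šidák mean-rank
post hocs; the familywise correction for the package's canonical family of
eight metrics is Bonferroni α = 0.05/8 = 0.00625.

## Jackknife confidence

For a nodal metric, each of 1000 random 20%-removal iterations votes for
the contact attaining the optimal value (maximum, or minimum for control
centrality; within-iteration ties go to the lowest contact index). Contacts
are sorted by descending vote count and accumulated greedily until they
cover ≥95% of votes — the 95% confidence contact set. The ≥ threshold and
the lowest-index tie-breaks are determinism choices. Iterations where the
metric is undefined are dropped and the coverage denominator is the
successful count. For regional control centrality the winning *region's
members* are each tallied (membership, not seed identity — the natural
reading when confidence sets are to be interpretable as candidate tissue,
and the construction under which set sizes can greatly exceed the region
size); the set size divided by the region size gives a cross-patient ratio
with lower bound 1. For global metrics, the 95% confidence interval is the
2.5th–97.5th percentile span of the subsampled values, with linear
interpolation between order statistics (R's default type-7 rule; no rule is
canonical here, and the choice is stated so results are exactly
reproducible).

## What the synthetic data emulate — and what they don't

`simulate_recording` drives contiguous groups of contacts with shared
latent narrowband sources (white noise bandpass-filtered to the analysis
band, unit variance) plus i.i.d. Gaussian channel noise (default SD 0.5,
i.e. −6 dB relative to the source), on planar grids at 10-mm spacing with a
contiguous SOZ grown by nearest-neighbor accretion. This reproduces the one
property the pipeline's correctness arguments need — known block-coherence
structure: with the default noise, within-block coherence exceeds
between-block coherence in ≥95% of seeded replicates (tested over 100
seeds). `simulate_cohort` draws per-patient sizes uniformly from 16–118
contacts, the span typical of surgical iEEG cohorts.

The generator is *not* a seizure model: no 1/f background by default (an
optional flag adds it), no nonstationarity, no volume-conduction mixing
beyond the shared sources, no traveling ictal dynamics. Passing tests on
these data therefore validate the estimators and the resampling machinery,
not any clinical claim about real seizures.

## Problem sizes and numerical choices

The test suite validates cohort-level monotonicity — every metric's
reliability non-increasing from 20% to 80% removal — on 12 simulated
patients of 16–48 contacts with 1000 iterations per fraction, sizes chosen
to exercise the full pipeline at desk scale while keeping the suite fast;
the monotonicity itself is size-free. Eigenvalue computations use dense
symmetric solvers with relative tolerances of 1e-10 for the
zero-eigenvalue guards; oracle-equivalence tests assert agreement at 1e-8
to 1e-10 depending on the amount of floating-point accumulation involved.

## Known limitations

Subsampling can only remove contacts; nothing can be said about contacts
that were never implanted. EDF ingestion is not provided — recordings enter
as delimited matrices with a JSON sidecar (the canonical fixture format),
or adjacency matrices can be supplied directly. The Dunn–Šidák post hoc
uses the large-sample normal approximation for mean-rank differences, which
is the standard choice but approximate below ~10 patients.
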