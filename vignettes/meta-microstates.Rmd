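---
title: "Comparing EEG microstate template maps across studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing EEG microstate template maps across studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamicrostates)
```

## The problem

Resting-state EEG microstate analysis summarizes the ongoing scalp field
as a sequence of sub-second quasi-stable topographies, each represented
by a per-channel *template map*.  Findings from different studies are
usually related to each other through class *labels* ("microstate A",
"microstate C", ...), but labels are only a proxy: what actually
justifies carrying a finding from one study to another is the
topographic similarity of the underlying maps, which also survives
differences in the number of classes a study extracted.  Comparing maps
directly is complicated by heterogeneous electrode montages (19 to 256
channels), by arbitrary map scaling, and by the polarity ambiguity of
resting-state topographies (a map and its negation describe the same
state).

`metamicrostates` implements that comparison machinery end to end:
canonicalization, cross-montage spherical-spline resampling, shared
variance, multidimensional scaling, subject-weighted meta-clustering,
backfitting, commonality matrices, and a findings table queryable by
topography.

## Canonical form of a map

All comparisons operate on canonicalized maps: average-referenced
(channel mean removed) and scaled to unit L2 norm
(`canonicalize_map()`).  Unit norm and "unit GFP" differ only by a
constant factor of $\sqrt{n}$ per montage — GFP is the per-map standard
deviation across channels — and every similarity measure used here is
invariant to that factor, so the choice is internal.  We canonicalize on
load and record, per map, whether the stored values already were
canonical; the original scale of published maps is not needed by any
downstream operation.  No channels are excluded from the average
reference, and electrode coordinates are taken as supplied
(head-centered); we deliberately do not attempt to re-center or re-fit
coordinates, since doing so silently could corrupt a montage.

## Shared variance and dissimilarity

For canonical maps $u, v$ on one montage the spatial correlation is the
plain dot product $r = u^\top v$, identical to the Pearson correlation
over channels.  Similarity is reported as shared variance
$SV = 100\,r^2$ (percent), which is invariant to polarity and scaling.
The corresponding global map dissimilarity is

$$d = \sqrt{2\,(1 - |r|)} \;=\; \min(\|u - v\|_2, \|u + v\|_2),$$

the L2 distance after choosing the polarity that minimizes it, and is a
monotone transform of SV.  Folding the sign keeps the dissimilarity
consistent with $r^2$-based similarity and with microstate convention; a
signed variant ($\sqrt{2(1-r)}$) is available via
`map_dissimilarity(..., polarity = "signed")` for workflows where
polarity is meaningful.  Note that sign-folding can make a dissimilarity
matrix slightly non-Euclidean when a map set contains genuinely
ambiguous polarities; on map sets without such ambiguity (all pairwise
$r > 0$) $d$ is the plain chordal distance and embeds exactly.

## Spherical-spline resampling between montages

Maps from different montages are compared after interpolating the map
from the montage with **more** electrodes onto the montage with fewer
electrodes (when counts are equal but electrode sets differ, the second
study is resampled onto the first; the choice is documented because it
is order-dependent, though symmetric within spline fidelity).
Interpolation uses spherical splines on the unit sphere with kernel

$$g(x) = \frac{1}{4\pi}\sum_{n=1}^{N}
  \frac{2n+1}{n^m(n+1)^m}\,P_n(x),$$

with Legendre polynomials evaluated by the stable three-term
recurrence.  Defaults are $m = 4$ (the customary order for scalp
potentials), $N = 50$ (the neglected tail is below $10^{-10}$ for
$m = 4$), and a ridge of $10^{-8}$ added to the spline system to guard
against nearly coincident electrodes; all three are exposed in
`spline_config()`.  Electrodes are projected onto the unit sphere by
dividing each position by its own length — deterministic and
montage-agnostic; users who prefer a best-fit sphere can pre-transform
their coordinates.  The fitted system is precomposed into a single
linear target x source transfer matrix, which reproduces constants
exactly and the node values of an interpolating spline to numerical
precision.

## Meta-microstate maps: subject-weighted modified k-means

To derive across-study *meta-microstate maps*, all study maps are
resampled onto a common montage (the built-in 19-channel 10-20 layout by
default — a reasonably general setup; any montage can be supplied) and
clustered with the polarity-invariant modified k-means: item $i$ is
assigned to class $L_i = \arg\max_k (x_i^\top t_k)^2$, and each class
map $t_k$ is updated as the dominant eigenvector of
$S_k = \sum_{i: L_i = k} w_i x_i x_i^\top$, where $w_i$ is the owning
study's subject count.  Weighting inside $S_k$ is exact and fast, and is
equivalent to replicating items (a tested invariant).  The objective is
the weighted explained variance
$\sum_i w_i (x_i^\top t_{L_i})^2 / \sum_i w_i$; both steps are monotone
in it.

Unstated algorithmic details were fixed as follows and are all exposed
as arguments: 50 random restarts (initial maps drawn as K distinct items
without replacement), convergence at unchanged assignments or a relative
objective change below $10^{-9}$, an iteration cap of 500, a
deterministic sign rule for eigenvectors (largest-magnitude element
positive), ties in assignment broken toward the lowest class index, and
an emptied class reseeded with the worst-fit item that is not the sole
member of its own class.  Items here are study template maps, one vector
each — not EEG samples — so GFP-peak selection does not apply.
Clustering runs for K = 4..7 by default, the usual range in
resting-state microstate work; the package deliberately does not try to
pick the "correct" K.

Classes are aligned across K (`align_solutions()`): each solution is
matched one-to-one against the previous K by maximizing total shared
variance (exhaustive over injections, exact for the K range used), the
unmatched class is appended last, and the smallest-K solution is ordered
by descending assigned weight or against a user-supplied reference set.
A manual permutation override is accepted and recorded.

## Backfitting and commonality of assignment

`backfit_maps()` labels study template maps by their best-matching
meta-map (maximal SV, ties to the lowest class).  `backfit_eeg()` labels
every EEG sample by the polarity-invariant squared correlation between
the canonicalized sample and the meta-maps.  All time points are
assigned by default — no temporal smoothing and no GFP-peak restriction;
optional minimum-GFP exclusion and majority-vote smoothing exist but are
off by default, and zero-variance samples inherit the previous label and
are tallied.

Two assignment series of the same recording obtained with different
cluster numbers are compared with `commonality()`:

$$C[j,k] = 100\cdot\frac{\#\{t : a_t = k \wedge b_t = j\}}
  {\#\{t : a_t = k\}},$$

so every column over a non-empty source class sums to exactly 100%.
Columns index the first ("from") solution's classes.

## What the synthetic generators emulate

The package is exercised on seeded synthetic data
(`sim_montage()`, `sim_prototypes()`, `sim_atlas()`, `sim_eeg()`):

* **Montages**: the idealized spherical 10-20 layout for 19 channels,
  otherwise near-uniform points on the upper hemisphere with at least 5
  degrees of separation.
* **Prototypes**: smooth random fields built from low-order polynomial
  basis functions on the sphere (surrogates of spherical harmonics up to
  order 2 by default), sequentially accepted so all pairwise SV stays
  below 25%.  Sequential acceptance makes prototype sets nested across K
  at a fixed seed, which is what the commonality experiments need.
* **Atlases**: 20 studies of 5 prototype classes by default, montages
  cycling through 19/32/64 channels, subject counts uniform in 10..50,
  and per-map noise applied as a rotation of 0.3 rad on the map
  hypersphere toward a random orthogonal direction.  A fixed-angle
  rotation was chosen because it maps monotonically to expected SV loss:
  a study map then shares $100\cos^2(0.3) \approx 91\%$ variance with
  its prototype, a realistic cross-study replication level, and two
  independently perturbed maps of the same class share
  $\approx 100\cos^4(0.3) \approx 83\%$.
* **EEG**: piecewise-constant state sequences with geometric run lengths
  (memoryless, the simplest duration model; the commonality mathematics
  is duration-distribution-agnostic), consecutive states forced to
  differ so the empirical mean run length equals the nominal mean
  duration (80 ms at 250 Hz by default), per-sample random polarity and
  amplitude, and spatial white noise at a map-to-noise GFP ratio of 4.

These fixtures reproduce the *geometry* of the problem — montage
heterogeneity, polarity ambiguity, class structure, weighting — but not
the physiology: no dipolar lead fields, no 1/f spectra, no artifacts, no
temporal autocorrelation of noise.  Passing tests therefore demonstrate
the correctness of the machinery, not the empirical content of any
specific multi-study collection; users reproduce published similarity
structures by importing the corresponding template-map files.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately compact
problem sizes chosen to probe each property: 19-64 channel montages,
atlases of 5-20 studies, recordings of 20-300 seconds at 250 Hz, 5
replicate seeds for the recovery experiment, and exhaustive-enumeration
oracles at 8 items / K = 2, where brute force is exact.  Degenerate
inputs are handled explicitly: constant maps raise a degenerate-map
error naming the study and label; zero-variance EEG samples inherit the
previous label; an all-zero dissimilarity matrix embeds to all-zero
coordinates (with a warning about zero-padded axes).  Classical
(Torgerson) scaling was preferred over iterative stress-minimizing MDS
because it is deterministic, seed-free, and matches the
Euclidean-distance construction of the dissimilarities; axis signs are
fixed by making each axis's largest-magnitude coordinate positive.

## Known limitations

* No claim of numeric agreement with any specific MATLAB implementation:
  spline order/truncation and k-means restart/convergence settings of
  existing GUI tools are unpublished, so only the documented contracts
  above are guaranteed.
* Interpolation assumes a spherical head; realistic BEM/FEM head models
  and bad-channel handling are out of scope.
* The findings store is a validated table, not a curation pipeline:
  effect vocabulary is normalized to the directions More/Less and the
  parameters Duration, Occurrence, Contribution, GEV, CurrentDensity
  (with an `Other` escape that preserves the verbatim text), and
  current-density findings are stored as text only — no inverse
  solutions are computed.
* Microstate statistics beyond what commonality needs (duration /
  occurrence / coverage testing) are intentionally not provided.
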