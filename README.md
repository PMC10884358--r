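# metamicrostates

Cross-study comparison and meta-clustering of EEG microstate template
maps.

Resting-state EEG microstate analysis describes the ongoing scalp field
as a sequence of sub-second quasi-stable topographies, summarized by
per-class **template maps**.  Relating findings across studies by class
*labels* ("microstate A", "microstate C") is unreliable: labels need not
mean the same topography, and studies differ in electrode montages and
in the number of classes they extract.  This package makes the
comparison quantitative, for microstate researchers who want to relate
their template maps — and the findings attached to them — to other
studies by **topographic similarity** instead of by label.

## What it computes

* **Canonicalization** — maps are average-referenced and scaled to unit
  vector length (equivalently, equal GFP), the form every comparison
  uses: `canonicalize_map()`.
* **Similarity** — for canonical maps *u*, *v* on one montage the
  spatial correlation is *r* = *u*ᵀ*v*; similarity is the
  polarity-invariant **shared variance** SV = 100 *r*² (%).  Maps on
  different montages are first spherical-spline interpolated (Perrin
  kernel, m = 4, N = 50) onto the montage with fewer electrodes:
  `shared_variance()`, `similarity_matrix()`, `spline_operator()`.
* **Embedding** — global map dissimilarity d = √(2(1 − |r|)) feeds a
  deterministic classical (Torgerson) MDS: `dissimilarity_matrix()`,
  `mds_embed()`.
* **Meta-microstate maps** — all study maps, weighted by each study's
  subject count, are clustered on a common montage with the
  polarity-invariant modified k-means (assignment by squared
  correlation; class maps as dominant eigenvectors of the weighted
  outer-product sum S_k = Σ wᵢ xᵢ xᵢᵀ), for K = 4..7, with classes
  aligned across K: `metacluster()`, `modified_kmeans()`,
  `align_solutions()`.
* **Backfitting & commonality** — meta-maps are backfit to study maps
  and to continuous EEG (per-sample polarity-invariant argmax), and
  assignment series from different K are cross-tabulated into
  column-normalized **commonality matrices** (each column over a
  non-empty source class sums to 100%): `backfit_maps()`,
  `backfit_eeg()`, `commonality()`.
* **Findings database** — validated empirical findings (contrast +
  More/Less × Duration/Occurrence/Contribution/GEV/current density)
  attached to maps, queryable by explicit selection or by meta-class,
  exportable to CSV: `query_findings()`, `query_metaclass_findings()`.
* **Synthetic fixtures** — seeded generators for montages, decorrelated
  smooth prototype topographies, noisy multi-study atlases with ground
  truth, and microstate-structured EEG: `sim_montage()`,
  `sim_prototypes()`, `sim_atlas()`, `sim_eeg()`.

Study files are plain JSON (montage + maps + metadata + findings);
montages are `.sfp` or CSV; EEG and all tabular outputs are CSV.  A thin
command-line interface (`inst/cli/msx`, subcommands `import`,
`resample`, `similarity`, `mds`, `metacluster`, `backfit`,
`commonality`, `findings`, `simulate`) wraps the same functions.

## Worked example

```r
library(metamicrostates)

atlas <- sim_atlas(n_studies = 8, seed = 42)   # 5 prototype classes
sim <- similarity_matrix(atlas)
sim
#> Shared-variance matrix: 40 maps from 8 studies
#>   off-diagonal range: 0 - 92.8 %

run <- metacluster(atlas, k_min = 4, k_max = 6, restarts = 20, seed = 7)
run
#> Meta-microstate clustering over K = 4, 5, 6 ( 40 maps from 8 studies )
#>   weighted explained variance: K=4: 0.8390  K=5: 0.9294  K=6: 0.9348

head(backfit_maps(run$solutions[["5"]], atlas), 3)
#>        study_id map_label class       sv
#> 1 Synthetic 001         A     3 91.49613
#> 2 Synthetic 001         B     1 93.56968
#> 3 Synthetic 001         C     4 91.43946
```

The explained-variance jump up to K = 5 (0.84 → 0.93) and the small gain
beyond it recover the five generating prototypes; each study map backfits
to its meta-class with ~91% shared variance, the level implied by the
generator's 0.3 rad topographic noise.

Backfitting the 4- and 5-class solutions to a synthetic recording that
contains all five states shows how assignment reorganizes when a class
is added:

```r
rec <- sim_eeg(attr(atlas, "prototypes"), montage_1020(),
               duration_s = 20, snr = 4, seed = 11)
commonality(backfit_eeg(run$solutions[["4"]], rec$eeg),
            backfit_eeg(run$solutions[["5"]], rec$eeg))
#> Commonality of assignment: K = 4 -> 5 (percent per source-class column)
#>     from1 from2 from3 from4
#> to1  59.4     0     0     0
#> to2   0.0   100     0     0
#> to3   0.0     0   100     0
#> to4   0.0     0     0   100
#> to5  40.6     0     0     0
```

Three of the four classes are untouched (100% on the diagonal); the
added fifth class splits exactly one column — the class that had been
absorbing the unmodeled state.  Findings attached to any meta-class are
one query away:

```r
query_metaclass_findings(atlas, run$solutions[["5"]], k = 1)
#> Findings table: 8 row(s) (meta-class 1 of the 5-class solution: 8 map(s))
#>             label                       contrast            effect
#> 1 Synthetic 001_B Synthetic condition 2 vs. rest          Less GEV
#> 2 Synthetic 002_B                                      No findings
#> 3 Synthetic 003_B Synthetic condition 2 vs. rest     Less Duration
#> ...
```

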