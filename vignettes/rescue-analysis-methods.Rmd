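---
title: "Methods: heterochronic parabiosis rescue analysis"
author: "parabioRescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterochronic parabiosis rescue analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design and the question

Heterochronic parabiosis joins the circulation of a young and an aged
animal. With isochronic controls this yields four groups — Yiso, Aiso,
Yhet, Ahet — and three informative contrasts per cell type: the aging
signature (Aiso vs Yiso), the response of aged tissue to young blood
(Ahet vs Aiso), and the response of young tissue to aged blood (Yhet vs
Yiso). The workflow quantifies, per cell type, how much of the aging
signature is reversed (prorejuvenative, PR) or recapitulated in the young
(progeronic, PG), scores gene-program activity per cell, and ranks
candidate genes by how many cell types show them as differential under the
PR-relevant contrasts.

## Statistical core

**Rank-sum test.** All group comparisons use the two-sided
Wilcoxon/Mann-Whitney rank-sum test with midranks for ties. When the number
of label assignments `choose(m+n, m)` is at most `2e5` the permutation
distribution of the rank sum is computed exactly with a generating-function
dynamic program over doubled midranks (doubling makes midranks integral);
the two-sided p is `min(1, 2*min(P(W<=w), P(W>=w)))`. Beyond that bound a
normal approximation with tie correction and a 0.5 continuity correction is
used. The exact branch is pinned in the tests against brute-force
enumeration over all assignments (tolerance 1e-12); the approximate branch
against the reference implementation in base R.

**Fold change.** Single-cell fold changes are computed on back-transformed
normalized expression with a pseudocount:
`log2((mean(expm1(x)) + c) / (mean(expm1(y)) + c))`, default `c = 1`. The
pseudocount guarantees finiteness and shrinks ratios of barely-expressed
genes toward zero; it is configurable because no universal convention
exists.

**Multiple testing.** Benjamini-Hochberg step-up, implemented directly
(sort ascending, scale by `n/i`, cumulative minimum from the largest rank,
cap at one) and verified against an independently coded naive version and
against `p.adjust` on random inputs. The adjustment family is one
(cell type × contrast) stratum, matching per-cell-type DEG reporting;
correcting globally instead is a one-line change at the call site.

**DEG thresholds.** `|log2FC| > 0.25` and adjusted `p < 0.05`, both strict
inequalities, as are all three QC bounds (more than 200 genes, fewer than
4000 genes, less than 20% mitochondrial counts). Genes enter testing when
detected (raw count > 0) in at least `min_cells = 3` cells of either group;
the floor avoids degenerate all-zero tests and is exposed as a parameter.

**Hypergeometric over-representation.** Upper-tail `P(X >= k)` by direct
summation of the hypergeometric mass on log-binomial coefficients. The
universe defaults to genes detected in at least `min_cells` cells —
an expressed-gene background avoids inflation from never-observed genes.

## Rescue classification

The intersections that define PR and PG genes are direction-aware by
default (`mode = "strict"`): a PR gene must reverse its aging direction
under HP, a PG gene must move the young tissue in the aging direction.
The motivation is interpretive — "rescue" means reversal — and the
up/down stratification of the classified sets only makes sense with
directions attached. Because a plain-intersection reading is also
defensible, `mode = "loose"` preserves it, and the strict PR set plus the
non-reversed overlap partition the loose set exactly (tested property).
Responsiveness percentages are always per cell type, never pooled; a cell
type with zero Aged-DEGs gets a flagged undefined percentage rather than a
division by zero and sorts last.

## Gene-set scoring

The module score follows the established bin-matched-control scheme: genes
are binned by average normalized expression (25 equal-frequency bins via a
deterministic rank-based cut; equal-width binning is available behind a
flag), and each set gene contributes 100 control genes drawn from its bin
(seeded, with replacement when the bin is small). The per-cell score is the
mean set-gene expression minus the mean over the pooled control draw. Both
sides are accumulated over the same number of rows (set genes repeated
`n_ctrl` times), which makes the two sums structurally identical and the
score exactly zero on a constant matrix. The score is location-free by
construction. Control draws are seeded per set; cell-type assignment uses
one shared control seed across marker sets so that identical marker sets
produce identical scores and therefore a true zero margin.

The rank-AUC score ranks each cell's genes by descending expression with
lexicographic tie-breaking (reproducibility) and reports the area under
the set's recovery curve within the top 5% of ranks, normalized by the
maximal achievable area, hence in [0, 1] and invariant to any monotone
transform of a cell's expression vector.

Cell typing assigns the argmax marker-set score with a minimum
top-minus-runner-up margin of 0.05 on the module-score scale; ambiguous
cells become "unassigned". With a single candidate set the runner-up is
taken as negative infinity. Score-based assignment was chosen over graph
clustering because it is deterministic, directly testable against planted
types, and reflects marker expression rather than neighborhood structure.

## The synthetic study

The generator emulates the statistical structure the analysis must
resolve, not a particular tissue:

* **Counts**: gamma-Poisson (negative binomial) with one global
  inverse-dispersion (default `size = 5`, i.e. quadratic overdispersion
  coefficient 0.2, mid-range for droplet data) and log-normal per-cell
  depth factors (`sigma = 0.3`) around a 2000-count mean.
* **Baseline abundances** sit on a fixed tier grid (0.1–30 relative units)
  so expression spans realistic orders of magnitude; mitochondrial-prefixed
  genes (2% of genes) are pinned near 8% of counts so the default QC bound
  of 20% is meaningfully exercised but not binding.
* **Effects are additive on log2 mean expression before depth scaling**, so
  a planted effect is directly an expected log2 fold change: Yiso is
  baseline, Aiso adds the aging effect, Ahet reverts
  `rescue_magnitude` of it on a seed-chosen `rescue_fraction` of the
  program, Yhet adds `accel_magnitude` of it on an accelerated subset.
  Marker genes are up-only in their own type with zero cross-type leakage.
* **Programs are planted in expressed tiers** (baseline at least one
  relative unit). Effects planted in genes with mean counts far below one
  per cell would be undetectable at any realistic cell number and would
  only blur recovery measurements.
* The **hub gene** (default symbol `Adipor1`) is planted — and forced
  rescued — in a configurable number of cell types' programs, giving the
  prioritization stage a ground-truth target.

Defaults are the demo study conditions: 3 cell types, 200 cells per group
per type, 1000 genes, 20 markers and a 60-gene program per type, aging
effects of ±1 log2 (half up), rescue and acceleration fractions 0.5 with
magnitude 1. The generator is fully deterministic given its seed and
restores the caller's RNG state.

What the simulator does **not** emulate: doublets, ambient RNA, batch
effects, per-gene dispersion, gene-gene correlation beyond the shared
depth factor, and trajectory structure. Passing recovery tests therefore
demonstrates the correctness and calibration of the analysis logic on
clean overdispersed data, not robustness to the full noise anatomy of real
droplet experiments — in particular, real data would require the batch
integration and clustering steps that are deliberately out of scope here.

## Determinism and seeds

One run seed fans out to per-stage seeds through an FNV-1a hash of the
stage name, so any stage can be re-run in isolation with its saved inputs
and reproduce its saved outputs. All tables are written with fixed column
order, fixed row order (cell type, contrast, ascending adjusted p, gene)
and 15 significant digits, and the run report carries no timestamps, so
identical (config, seed) runs are byte-identical. Logging goes to stderr
only.

## Test problem sizes

The test suite verifies calibration and recovery at the study conditions
of the demo design: 20 replicate null simulations for the false-positive
rate; 10 replicates each for DEG parameter recovery (sensitivity/FDR at
effect 1.0, 200 cells per group), rescue-subset recovery (Jaccard against
the planted rescued genes), responsiveness ordering (rescue fractions 0.8
vs 0.2), module-score group ordering (rescue magnitude 0.5), and hub-gene
prioritization (8 cell types at 150 cells per group per type, hub planted
in 6). Exactness checks (rank-sum enumeration, BH, hypergeometric mass) run
at tolerances of 1e-10 to 1e-12.

## Known limitations

* Gene identity is the verbatim, case-sensitive symbol string; no alias or
  human–mouse ortholog mapping is attempted, so overlaps with external
  collections are conservative and symbol-convention-sensitive.
* The rank-sum test is the only DE model: no covariates, no pseudobulk, no
  mixed models; with few truly independent animals per group, per-cell
  tests overstate replication, which is a known property of this analysis
  style rather than of the implementation.
* A single global dispersion understates the heavy per-gene dispersion
  tails of real data; recovery rates measured on the simulator are
  accordingly optimistic.
* The frequency statistic counts distinct cell types (a gene hit in two
  contrasts of one type counts once) over the Aged and Ahet tables by
  default; which contrast scope best mirrors a given study is recorded in
  the run configuration rather than hard-coded.
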