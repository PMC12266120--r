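# parabioRescue

Rescue analysis for four-group heterochronic parabiosis (HP) single-cell
RNA-seq designs.

In a heterochronic parabiosis experiment a young and an aged animal share
circulation, giving four groups: young and aged isochronic controls
(**Yiso**, **Aiso**) and young and aged heterochronic parabionts (**Yhet**,
**Ahet**). The analytical question is which aging-associated expression
changes the young systemic environment *reverses* in aged tissue, which
cell types respond most, and which individual genes recur across cell types
as candidate drivers of rejuvenation. This package implements that analysis
as a tested, deterministic workflow for cell-by-gene count matrices, and
ships a negative-binomial simulator with planted ground truth so every
stage has a measurable recovery target.

## Method

For each cell type the three contrasts are

* **Aged-DEGs** — Aiso vs Yiso (the aging signature),
* **Ahet-DEGs** — Ahet vs Aiso (the effect of young blood on aged tissue),
* **Yhet-DEGs** — Yhet vs Yiso (the effect of aged blood on young tissue).

Per gene, a two-sided Wilcoxon rank-sum test is computed on log-CP10K
normalized expression (exact permutation p-value by dynamic programming
when `choose(m+n, m) <= 2e5`, normal approximation with tie and continuity
correction otherwise), the fold change is
`log2((mean(expm1(x)) + 1) / (mean(expm1(y)) + 1))`, and Benjamini-Hochberg
correction is applied within each (cell type, contrast) stratum. A gene is
a DEG when `|log2FC| > 0.25` **and** adjusted `p < 0.05`, both strict.
Cells enter the analysis when they detect more than 200 and fewer than
4000 genes with less than 20% mitochondrial counts.

Downstream:

* **PR-DEGs** (prorejuvenative) = Aged-DEGs ∩ Ahet-DEGs with *opposite*
  directions (the aging change is reversed under HP); **PG-DEGs**
  (progeronic) = Aged-DEGs ∩ Yhet-DEGs with *concordant* directions. Plain
  intersections are available as `mode = "loose"`.
* **Responsiveness** of a cell type = 100·|PR|/|Aged-DEGs| (and the PG
  analogue).
* **Gene-set activity**: bin-matched-control module scores (mean set-gene
  expression minus expression-matched control genes, 25 bins / 100 controls
  per gene) and a rank-AUC regulon-style score on the top 5% of each cell's
  expression ranking.
* **Prioritization**: PR-DEGs are intersected with aging gene-set
  collections (GMT), and the overlap is ranked by the number of distinct
  cell types in which each gene recurs as a DEG; hypergeometric
  over-representation against the detected-gene universe is provided for
  any gene list.

## Worked example

The `analysis/` scripts run the demo study end to end (3 cell types, 200
cells per group per type, 1000 genes, a 60-gene aging program per type with
half of it rescued in Ahet, and the hub gene *Adipor1* planted as rescued
in all three types):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_rescue_classification.R
Rscript analysis/05_geneset_scores.R
Rscript analysis/06_prioritization.R
```

Representative output (seed 1):

```
T1: Aged-DEG sensitivity 1.00, false-discovery proportion 0.091
  cell_type n_aged n_pr n_pg pct_pr pct_pg defined
1        T3     60   29   30  48.33  50.00    TRUE
2        T1     66   31   30  46.97  45.45    TRUE
3        T2     63   28   29  44.44  46.03    TRUE
T1 module score means: Yiso -0.282 | Aiso 0.286 | Ahet -0.009 | Yhet 0.017
     gene n_cell_types cell_types    collections_hit tie_break_score
1 Adipor1            3   T1,T2,T3 synthetic_aging_db            4.89
```

Reading this: the rank-sum engine recovers essentially all planted aging
genes; roughly half of each type's Aged-DEGs are classified
prorejuvenative, matching the planted rescue fraction of 0.5; the
inflammatory-style module score rises with age (Yiso → Aiso) and falls back
toward young under HP (Ahet between the two); and the planted hub gene tops
the candidate table because it recurs as a rescued DEG in all three cell
types. Equivalently, `run_pipeline(default_config(seed = 1))` executes all
stages in one call and writes every table plus a JSON run report.

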