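# scvuln

Single-cell RNA-seq analysis for locating cell clusters that are
**vulnerable** to genetic risk-factor gene sets — clusters with enriched
expression of, for example, high-confidence monogenic autism risk genes or
the 27 protein-coding genes of the 16p11.2 microdeletion locus.

## Who this is for

Developmental transcriptomics groups asking "which cell populations in this
tissue express a disproportionate share of a risk gene set, and does the
set alone distinguish them?" — and methods developers who want each stage
of that pipeline as a tested, scriptable unit with a synthetic ground-truth
world to validate against.

## What it computes

For a gene × cell expression matrix `X` with library-size normalization
`norm_gc = log(1 + X_gc / L_c · 10^4)`:

* **QC / feature selection** — cells with < 1000 expressed genes removed;
  genes kept when ≥ 1 normalized unit in ≥ 3 cells; blacklist exclusion;
  highly variable genes by mean-log-expression window and variance-to-mean
  ratio (VMR), with the conventional top-n ranking available.
* **Dimensionality reduction** — PCA on standardized HVGs; jackstraw
  permutation p-values per component (100 iterations, α = 0.01);
  deterministic 2-D embedding.
* **Clustering** — Louvain community detection at resolution γ on a
  k-nearest-neighbour graph (k = 30) with shared-neighbour Jaccard edge
  weights `|N(i) ∩ N(j)| / |N(i) ∪ N(j)|`; per-class sub-clustering at the
  published resolutions (NPC 1, ExN 0.1, IN 0.5).
* **Differential expression** — one-vs-rest Wilcoxon rank-sum with a 33%
  detection gate; significant when adjusted p < 0.05 and
  `ln FC = ln(mean expm1(in)+1) − ln(mean expm1(out)+1) > 0.33`;
  per-gene-set summaries ("k of 83 risk transcripts DE in ≥ 1 cluster").
* **Gene-set AUROC** — neighbour voting on a rank-standardized Spearman
  affinity network restricted to the set; AUROC = P(target cell outranks
  non-target by votes), 0.5 = chance.
* **Enrichment** — upper-tail hypergeometric ORA with BH correction and
  fold enrichment `(k/n)/(K/N)`.
* **Label transfer** — diagonal CCA across datasets (first 4 components),
  per-component quantile alignment, then the exact published voting rule:
  a query cell takes the identity held by a unique plurality of ≥ 5 of its
  30 nearest reference cells; ties stay unassigned.
* **Synthetic data** — negative-binomial generator with planted classes,
  nested subclusters, one risk-set-enriched vulnerable subcluster, a
  batch-shifted paired reference, and JSON ground truth.

## Worked example

```r
library(scvuln)

spec <- sim_spec(seed = 1)              # the default stated world:
sim  <- simulate_dataset(spec)          # 2000 genes x 2000 cells, 6 classes,
                                        # vulnerable IN subcluster, 50 risk genes
m <- normalize_counts(sim$matrix)
m <- filter_cells(m)$matrix
m <- filter_genes(m)$matrix
m
#> ExpressionMatrix: 2000 genes x 1811 cells [layers: counts, norm]

truth <- sim$truth
in_cells <- intersect(truth$cell_id[truth$true_class == "IN"], m$cell_ids)
grp <- setNames(truth$true_subcluster[match(in_cells, truth$cell_id)], in_cells)

de <- wilcoxon_one_vs_rest(m[, in_cells], grp)
risk <- structure(list(RISK = structure(
  list(name = "RISK", description = "planted", genes = truth$risk_set),
  class = "GeneSet")), class = "GeneSetCollection")
rs <- summarise_risk_sets(de, risk, m[, in_cells], grp)
sprintf("%d/%d risk transcripts significantly DE in >=1 IN subcluster",
        rs$RISK$n_significant, rs$RISK$n_in_set)
#> "48/50 risk transcripts significantly DE in >=1 IN subcluster"

geneset_discrimination_auroc(m, grp, "IN_1", "IN_2", truth$risk_set, seed = 7)
#> 0.982
```

48 of the 50 planted risk genes are recovered by differential expression in
the vulnerable subcluster, and the risk set alone separates the vulnerable
subcluster from its sibling with AUROC 0.98 (random size-matched sets sit
at ~0.5): the readout that flags a cluster as vulnerable.

The full pipeline — simulate, preprocess, cluster, DE, AUROC, enrichment,
transfer — runs from one configuration:

```r
manifest <- run_all(read_config("inst/extdata/config_small.json"))
```

or from the command line via the bundled launcher:

```sh
Rscript inst/cli/scvuln.R run-all --config inst/extdata/config_small.json \
    --out out/ --seed 0
```

## Documentation

The methods vignette (`vignettes/vulnerability-analysis.Rmd`) explains the
model and assumptions of every stage, the tunable parameters with their
defaults and provenance, what the synthetic generator does and does not
emulate, and the package's numerical conventions.
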