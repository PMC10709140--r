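# spatlas

Tools for building annotated atlases from targeted in situ transcriptomic
measurements of tissue — the kind of data where every RNA molecule is an
amplicon spot with coordinates and a decoded gene identity, cells are
segmented upstream, and a deep single-cell RNA-seq reference with a nested
cell-type taxonomy is available for label transfer.

The package covers the full analysis chain:

* **Spot QC** — removal of the lowest-density fraction of amplicon spots
  (distance to the k-th nearest spot as the density score), nucleus-mask
  filtering, and nearest-spot assignment of viral barcode amplicons to
  cells.
* **Cell QC and preprocessing** — detection/count filters (defaults
  20 genes per cell, 20 cells per gene, totals in [30, 1300]),
  median-target normalization, `log1p`, total-count regression, unit
  scaling, and per-gene location/scale (ComBat-style) batch correction.
* **Consensus cell typing** — joint PCA embedding of query and reference,
  Leiden clustering, and the consensus transfer rule: a joint cluster's
  query cells inherit the modal reference label only when its fraction
  strictly exceeds a threshold (0.8 by default), independently at each of
  four taxonomy ranks; otherwise NA. Subclustering and Wilcoxon marker
  ranking included.
* **Molecular tissue regions** — each cell's spatial-niche vector
  (its expression block concatenated with its k nearest same-sample
  neighbours' blocks, k = 30 at the top level) is PCA-embedded and
  Leiden-clustered into regions; hierarchical subclustering with
  region-specific neighbourhood sizes; kNN label filling (k = 5) and
  majority-vote smoothing (k = 50) with excluded and frozen region sets;
  region marker z-scores and composition z-scores.
* **Gene imputation** — leave-one-gene-out intermediate mappings tune the
  reference neighbour count (grid 10–400, typically choosing 200); the
  final imputation is the occurrence-weighted mean of log reference counts
  over the multiset union of neighbours across all mappings. Moran's I
  quantifies the spatial structure that predicts imputability.
* **Adjacency and tropism** — per-sample Delaunay mesh graphs, type-by-type
  edge-count matrices with sequential row/column normalization, and
  per-group percentile summaries (2.5/25/50/75/97.5) of per-cell barcode
  counts.
* **Synthetic data** — a generator producing tissue, reference, spots,
  masks and barcode counts with complete ground truth (regions, types,
  four-rank taxonomy, per-gene heterogeneity, tropism multipliers), so
  every stage above is tested as a recovery problem.

## Worked example

```r
library(spatlas)

cfg    <- synth_config(n_slices = 1, n_cells_per_slice = 1500, n_regions = 4,
                       panel_genes = 40, reference_genes = 80, seed = 42)
tissue <- generate_tissue(cfg)
ref    <- generate_reference(cfg, tissue$truth, n_ref_cells = 2000)

cells <- filter_cells_genes(tissue$cells)
proc  <- normalize_log_scale(cells)
proc
#> <processed_matrix> 1500 cells x 40 genes [normalized, log_transformed, total_regressed, scaled]

shared <- intersect(proc$genes, ref$genes)
emb    <- joint_embed(proc, spatlas:::standardize_columns(
            spatlas:::lognorm_counts(ref$counts[, shared])),
            shared_genes = shared, seed = 42)
cl     <- cluster_communities(emb, seed = 42)
labels <- hierarchical_transfer(cl, ref$labels, emb$origin, threshold = 0.8)
table(labels$rank4, useNA = "ifany")
#>  T1  T2  T3  T4  T5  T6  T7  T8
#> 327 320 306 310  69  58  61  49

niche   <- build_niche_matrix(proc, k = 30)
regions <- cluster_regions(niche, seed = 42)[proc$cells$cell_id]
table(regions)
#>  L1  L2  L3  L4
#> 409 363 370 358
```

Against the generator's ground truth, 100% of cells receive a rank-4 label,
99.3% of those labels are the true type, and the four recovered regions
match the true layered regions at adjusted Rand index 0.88 — the numbers a
correct implementation should reach under the generator's low-noise default
conditions. `run_pipeline(pipeline_config(), out_dir)` chains all stages
(simulation through tropism summaries) and writes label tables, matrices
and a JSON manifest with a parameter hash.

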