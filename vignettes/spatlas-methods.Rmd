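---
title: "Methods: from amplicon spots to an annotated spatial atlas"
author: "spatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from amplicon spots to an annotated spatial atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatlas)
```

# Overview

`spatlas` implements the computational stages needed to turn targeted in situ
transcriptomic measurements — per-molecule amplicon spots with decoded gene
identities — into an annotated atlas: quality-controlled cells, consensus
cell-type labels transferred from a single-cell reference, molecular tissue
regions segmented from spatial-niche expression, transcriptome-scale imputed
profiles, cell-cell adjacency statistics and viral-barcode tropism summaries.
Every stage is exercised against a synthetic generator that knows the ground
truth, so the package's claims about recovery are measurable rather than
anecdotal.

This vignette explains each model and procedure, the parameters that matter,
the numerical conventions, and what the synthetic benchmark does and does not
establish about real tissue data.

# The synthetic tissue model

`synth_config()` / `generate_tissue()` simulate multi-slice 2D tissue. The
default configuration — two 1000 x 1000 um slices of 2,500 cells, six layered
regions, eight cell types, a 50-gene panel inside a 150-gene reference
universe — is the package's reference condition for all recovery tests.

* **Geometry.** Cells are uniform in each slice. Region labels are assigned
  by construction (horizontal bands, Voronoi cells of random seed points, or
  a mixture), so contiguity is guaranteed without rejection sampling and the
  generator stays deterministic and fast.
* **Composition.** Each region draws cell types from its own probability row;
  by default one type dominates each region at 75%, the rest spread evenly.
  This mirrors the situation in layered neural tissue where domains are
  defined by a characteristic mixture rather than a single type.
* **Expression.** Counts are negative binomial. Type profiles follow
  `log mu[t, g] = log(base_mean) + h_g z[t, g] - h_g^2 / 2` with standard
  normal `z` fixed by the seed and a deterministic heterogeneity ladder `h_g`
  spanning 0.25-1.5, so the panel contains everything from flat housekeeping
  genes to strongly type-specific markers and the generating heterogeneity of
  every gene is known. The defaults `base_mean = 4` and dispersion size 20
  (variance close to Poisson) define the "low-noise" condition: deep enough
  that per-cell totals (~150-450) pass the quality-control window and types
  are resolvable, noisy enough that recovery is not trivial.
* **Batch effects** are applied per slice on the log mean — an additive
  per-gene shift (sd 0.05) and a multiplicative scale (log-sd 0.02) — so
  negative-binomial sampling stays valid. This is exactly the location/scale
  family the correction stage models.
* **Spots.** Each transcript count emits a configurable number of amplicons
  jittered isotropically (sd 2 um) around the centroid; a configurable
  fraction (default 10%) of the real spot total is added as uniform
  background with random identities. Barcode spots are Poisson per cell with
  rate `baseline_barcode_rate x tropism_multiplier[region, type]`.
* **Reference.** Reference cells are drawn from the same type profiles
  extended to the full gene universe, without batch effects or coordinates,
  and carry a fixed balanced four-rank taxonomy (each rank-4 type has exactly
  one parent at rank 3, and so on).

What the generator does **not** emulate: segmentation errors and doublets,
optical point-spread artefacts, spatial gradients within a region,
cross-slice registration error, and reference/query platform differences
beyond a location-scale batch family. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct and well-calibrated under
its own model assumptions — not that real-data performance will match.

# Spot quality control

"Local density" of a spot is defined here as the Euclidean distance to its
`density_k`-th nearest neighbour within the same sample (default k = 10);
the `ceiling(fraction x N)` spots with the greatest such distance — the
conventional 10% — are removed. The neighbourhood definition is a package
choice (the underlying workflow does not pin one down); the k-th-neighbour
distance is simple, monotone in true local density, and easy to verify
against a dense-distance oracle. Ties are broken by spot id so the filter is
deterministic and permutation-invariant.

Cells are then intersected with the nucleus mask by a floor-convention pixel
lookup of their centroid (z is ignored: slices are thin). Barcode spots
outside the mask are discarded, and each survivor inherits the cell of its
single nearest mRNA spot in the x-y plane, exact ties resolving to the
smallest cell id.

# Cell quality control, normalization, batch correction

The count filter applies four rules in one fixed pass — minimum 20 detected
genes per cell, per-cell total within [30, 1300], then minimum 20 cells per
gene — without iteration, so the result is order-independent and exactly
reproducible. Note the interaction with panel size: on panels much smaller
than ~30 genes the detected-genes rule becomes the binding constraint.

Normalization follows the standard chain: per-cell totals scaled to the
median total (the target is a convention, configurable), `log1p`, per-gene
OLS regression on the per-cell total keeping residuals, then per-gene
scaling to zero mean and unit variance. The intermediate normalized-log
matrix is retained alongside the scaled one because niche construction
(below) concatenates expression blocks and would otherwise double-scale.

Batch correction is per-gene location/scale: in plain mode each gene is
standardized within batch and re-expressed at its grand mean and pooled
standard deviation, which makes per-batch means and variances exactly equal
and preserves the grand mean — the idealized form of the family the
generator injects. An optional empirical-Bayes mode shrinks the per-batch
moments (non-iterative method-of-moments priors) for small batches; it is
off by default because the correction settings of the original workflow are
not specified beyond the method family.

# Reference integration and consensus label transfer

Query and reference are embedded jointly: PCA (d = 50 by default) on the
standardized concatenation over shared genes, followed by an alignment step.
The default alignment removes the per-origin mean in PC space; an iterative
mode refines this with cluster-anchored centroid matching (k-means anchors,
per-origin shift toward each anchor's global centroid, at most 10 seeded
iterations). These are deliberately lightweight, transparent alignments
fulfilling the same contract as mixture-model integrators; the pipeline is
agnostic to which integration backend produced the latent space.

Joint Leiden clustering (modularity objective, resolution 1, symmetric
unweighted 15-NN graph) is followed by the consensus rule: within each joint
cluster, if the modal reference label's fraction among reference cells
strictly exceeds the threshold (0.8 for atlas-level transfer; 0.6 for
regional correspondence analyses), all query cells in the cluster inherit
that label, otherwise they are NA. Reference cells with missing labels are
excluded from the denominator — the rule judges agreement among labelled
evidence. Two boundary conventions are fixed deliberately: a fraction of
exactly the threshold does *not* transfer (strict inequality), and a
perfectly pure cluster (fraction exactly 1) always transfers, which keeps
the rule usable at threshold 1. The rule is applied independently at each
of the four taxonomy ranks, so a cell can be confidently coarse-labelled yet
NA at a finer rank.

A note on resolution: modularity-based community detection on kNN graphs
over-splits large tight clusters in low-dimensional geometric settings, but
in the >= 10-dimensional latent spaces this package operates on, two
well-separated populations resolve into exactly two communities at
resolution 1, and over-splitting — when it occurs — is harmless to the
consensus rule, because sub-clusters of a pure cluster are themselves pure.
This is why the transfer stage keeps resolution 1 while remaining robust.

Subclustering within a main cluster first filters genes (keep when per-cell
maximum count >= 10 *and* detected at count >= 5 in >= 10 cells — both
bounds verified at their boundaries in the tests), then reprocesses and
clusters the remaining matrix. Marker ranking uses the tie-corrected normal
approximation of the Wilcoxon rank-sum statistic, cluster versus rest, with
the top five genes reported per cluster.

# Molecular tissue regions

The niche expression vector of a cell concatenates its own normalized-log
expression block with those of its nearest same-sample spatial neighbours,
ordered by ascending distance. Two conventions exist for whether the cell
counts toward the neighbourhood size; this package includes the cell as one
of the `k` (vector length `k x G`) and exposes `include_self = FALSE` for
the self-plus-k reading. Cells whose sample stratum is smaller than the
neighbourhood are rejected and later rescued by label post-processing.

Level-1 regions come from PCA on the standardized niche matrix, per-batch
centering, and Leiden at resolution 1 with k = 30 — the scale of broad
anatomical domains. Sub-regions are found by rebuilding the niche matrix
within each parent with a region-specific, typically smaller `k`
(default 15, resolution 0.8): a neighbourhood that is wide relative to a
structure's thickness smooths the structure away, which is demonstrated in
the tests by a three-cell-wide stripe that survives k = 6 but not k = 30.
Per-level `k` and resolution are exposed as configuration because the
appropriate values depend on the morphology sought — they are tuning
parameters of the workflow, not constants of nature.

Post-processing has two passes with distinct roles. *Filling* assigns each
unlabelled cell the majority label of its 5 nearest labelled same-sample
neighbours. *Smoothing* is one simultaneous majority vote over 50
neighbours, with two escape hatches: labels listed as excluded (thin
compartments like meninges) neither vote nor change, and frozen labels vote
but never change (protecting cell-sparse layers from being overwhelmed by
dense neighbours). Majority ties resolve to the nearest voter's label —
deterministic and local.

Region markers are scored by converting each gene's per-region mean
expression into its percentage distribution across regions and z-scoring
that distribution per gene; enrichment calls use a strict z > 5. Cell-type
composition is summarized the same way: per-region type percentages,
z-scored per type across regions.

# Transcriptome-scale imputation

For each panel gene in turn, the gene is held out, query and reference are
re-embedded on the remaining shared panel, and each query cell's
`n_neighbors` nearest reference cells are recorded; the held-out gene's
imputed value is their unweighted mean log1p count, and the per-gene
performance score is the Pearson correlation across cells between imputed
and measured values. The neighbour count is tuned on the grid
{10, 50, 100, 200, 400} by the median per-gene score (median rather than
mean for robustness to the panel's flat genes; ties go to the smaller
count). Because neighbour lists at smaller counts are prefixes of the list
at the largest count, the whole grid costs one embedding per gene.

The final imputation aggregates all per-gene mappings: for each query cell,
the multiset of its reference neighbours across mappings defines weights
proportional to occurrence counts, and any reference gene passing the
eligibility filter (mean count >= 0.005 and per-cell maximum > 10) is
imputed as the occurrence-weighted mean of log1p reference counts. Weighted
means are convex, so imputed values always lie inside the reference gene's
observed range, and scaling all weights leaves the output unchanged — both
properties are asserted in the tests.

Imputability is diagnosed with Moran's I under binary symmetric kNN weights
(k = 6): genes with stronger spatial or cell-type expression structure
impute better, and on synthetic panels the per-gene score correlates
positively with the generating heterogeneity ladder.

# Adjacency and tropism

Cell-cell adjacency uses per-sample Delaunay triangulation of centroids with
no edge-length cutoff by default (an optional pruning threshold exists).
Edge counts between types use symmetric double counting — each edge
contributes to both ordered type pairs, same-type edges add two to the
diagonal — so the matrix total is exactly twice the edge count and the
subsequent row-then-column normalization is reproducible. Zero rows and
columns pass through unchanged and are flagged.

Barcode tropism is summarized per group (cell type or region) by the 2.5th,
25th, 50th, 75th and 97.5th percentiles of per-cell barcode counts under the
linear-interpolation quantile convention (R type 7; the convention is stated
because the source workflow does not fix one), with groups ranked by median
and ties by group size.

# Numerical conventions and degenerate inputs

* All spatial operations use (x, y) in micrometres; z identifies the slice.
* One seeded generator per operation; seeds are arguments, never global
  state, and a fixed seed reproduces outputs bit-for-bit.
* PCA dimensions are truncated to the data rank with a message rather than
  an error; constant columns standardize to zero.
* Constant genes: excluded from imputation scoring; Moran's I returns a
  flagged 0; marker scores are finite by construction.
* Empty inputs: the QC filter errors only when *all cells* are removed; an
  all-empty nucleus mask warns and returns an empty result; an empty
  neighbour multiset in the final imputation is an error.
* Tie-breaks are always deterministic and documented at the operation:
  density ties by spot id, assignment ties by smallest cell id, vote ties by
  nearest voter, marker ties by gene order, tuning ties by smaller
  neighbour count.

# Problem sizes used for verification

The recovery suite runs at deliberately desk-sized conditions chosen to make
each stage's signal unambiguous while keeping the full test suite fast:
5,000 cells / 6 regions / 50 genes for region recovery and label transfer
(adjusted Rand index >= 0.8; rank-4 accuracy >= 95% of labelled cells),
3,000 cells / 60 panel genes / 2,000 reference cells for imputation tuning
(median leave-one-gene-out r >= 0.7), and 20 replicates of 400 cells for
tropism ranking (a 3x region multiplier must rank first in >= 95%). These
sizes are the package's reference benchmark, not limits of the
implementation; the same code paths scale to atlas-sized inputs with sparse
matrices and irlba-backed PCA.

# Known limitations

* The alignment steps are linear (centering / centroid matching); strongly
  non-linear batch distortions are out of reach by design, and the joint
  embedding contract allows swapping in a heavier integrator.
* The empirical-Bayes batch mode is non-iterative and covariate-free.
* The manual curation steps of atlas construction — merging fragmented
  subclusters, naming regions anatomically — are represented as
  user-supplied label edits, not automated.
* Per-gene leave-one-out embeddings are recomputed exactly as specified;
  at transcriptome scale this is the dominant cost and an approximate
  shared-embedding mode would trade fidelity for speed (not implemented).
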