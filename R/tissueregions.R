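# Spatial-niche expression construction and molecular tissue-region
# segmentation with label post-processing.

#' Build the spatial-niche expression matrix
#'
#' Each cell's niche vector concatenates its own expression block with the
#' blocks of its nearest same-sample spatial neighbours, ordered by
#' ascending Euclidean distance in the (x, y) plane. Under the default
#' convention the cell itself counts as one of the `k` (`include_self =
#' TRUE`, vector length `k * G`); with `include_self = FALSE` the vector is
#' self plus `k` neighbours (`(k+1) * G`). Neighbours never cross sample
#' boundaries. Cells belonging to a sample stratum with fewer cells than the
#' required neighbourhood are rejected and listed in `rejected_cells`.
#'
#' Expression blocks use the normalized log values (the `lognorm` slot of a
#' [processed_matrix()]) when available, avoiding double-scaling of
#' concatenated blocks; scaling happens inside the PCA of
#' [cluster_regions()].
#'
#' @param p a [processed_matrix()] (its `lognorm` slot is preferred) or a
#'   plain matrix
#' @param coords cell-by-2 matrix of (x, y); default from `p$cells`
#' @param sample_id per-cell sample factor; default from `p$cells`
#' @param k niche size (default 30, the broad-anatomical-region scale)
#' @param include_self whether the cell itself is one of the `k`
#' @return object of class `niche_matrix`: list with `values`
#'   (included-cell-by-(k*G)), `k`, `cells` (metadata of included cells),
#'   `genes`, `rejected_cells`
#' @export
build_niche_matrix <- function(p, coords = NULL, sample_id = NULL, k = 30,
                               include_self = TRUE) {
  if (k <= 0) stop("k must be positive")
  if (inherits(p, "processed_matrix")) {
    values <- if (!is.null(p$lognorm)) p$lognorm else p$values
    if (is.null(coords)) coords <- as.matrix(p$cells[, c("x", "y")])
    if (is.null(sample_id)) sample_id <- p$cells$sample_id
    cells <- p$cells
  } else {
    values <- as.matrix(p)
    stopifnot(!is.null(coords), !is.null(sample_id))
    cells <- data.frame(cell_id = rownames(values) %||% paste0("c", seq_len(nrow(values))),
                        x = coords[, 1], y = coords[, 2])
  }
  stopifnot(nrow(values) == nrow(coords), nrow(values) == length(sample_id))
  G <- ncol(values)
  n_nbr <- if (include_self) k - 1L else k           # neighbours beyond self
  blocks <- n_nbr + 1L
  keep <- logical(nrow(values))
  nbr_idx <- matrix(NA_integer_, nrow(values), blocks)
  for (s in unique(sample_id)) {
    i <- which(sample_id == s)
    if (length(i) < blocks) next                     # stratum too small: reject
    keep[i] <- TRUE
    if (n_nbr == 0) { nbr_idx[i, 1] <- i; next }
    nn <- knn_index(coords[i, , drop = FALSE], k = n_nbr)
    nbr_idx[i, ] <- cbind(i, matrix(i[nn$idx], ncol = n_nbr))
  }
  inc <- which(keep)
  vals <- do.call(cbind, lapply(seq_len(blocks), function(b)
    values[nbr_idx[inc, b], , drop = FALSE]))
  colnames(vals) <- paste0(rep(colnames(values) %||% paste0("g", seq_len(G)), blocks),
                           ".b", rep(seq_len(blocks), each = G))
  rownames(vals) <- cells$cell_id[inc]
  structure(list(values = vals, k = k, cells = cells[inc, , drop = FALSE],
                 genes = colnames(values), include_self = include_self,
                 rejected_cells = cells$cell_id[!keep]),
            class = "niche_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cluster cells into molecular tissue regions
#'
#' PCA on the standardized niche matrix, optional per-batch centering in PC
#' space, then Leiden community detection. Niche concatenation makes
#' same-region cells extremely similar, so the default resolution of 1
#' recovers broad domains directly; per-level resolutions remain tuning
#' parameters of the workflow (see the methods vignette).
#'
#' @param n a `niche_matrix` from [build_niche_matrix()]
#' @param batch per-included-cell batch factor (default: `batch_id` of the
#'   niche's cells when present); `NULL` disables alignment
#' @param d PCA dimensionality (default 50)
#' @param resolution Leiden resolution (default 1.0)
#' @param knn kNN graph size (default 15)
#' @param seed integer seed
#' @return named character vector of region labels for every cell of the
#'   original matrix: `"L<g>"` for included cells, NA for rejected cells
#' @export
cluster_regions <- function(n, batch = NULL, d = 50, resolution = 1.0,
                            knn = 15, seed = 0) {
  stopifnot(inherits(n, "niche_matrix"))
  if (is.null(batch) && "batch_id" %in% names(n$cells)) batch <- n$cells$batch_id
  co <- pca_embed(n$values, d, seed)
  if (!is.null(batch) && length(unique(batch)) > 1) {
    for (b in unique(batch)) {
      i <- batch == b
      co[i, ] <- sweep(co[i, , drop = FALSE], 2, colMeans(co[i, , drop = FALSE]), "-")
    }
  }
  cl <- cluster_communities(co, knn = knn, resolution = resolution, seed = seed)
  lab <- stats::setNames(rep(NA_character_, length(n$rejected_cells) + nrow(n$values)),
                         c(n$cells$cell_id, n$rejected_cells))
  lab[n$cells$cell_id] <- paste0("L", as.integer(cl))
  lab[c(n$cells$cell_id, n$rejected_cells)]
}

#' Subcluster tissue regions within each parent region
#'
#' For every parent region, rebuilds the niche matrix restricted to the
#' region's cells with a region-specific neighbourhood size and re-clusters.
#' Smaller `k` preserves thin structures (a band a few cells wide that a
#' large neighbourhood would smooth away). Cells of strata smaller than the
#' neighbourhood, or of parents with fewer cells than `k`, are NA.
#'
#' @param p the [processed_matrix()] used for [build_niche_matrix()]
#' @param parent_labels per-cell parent (level-j) region labels; NA allowed
#' @param params optional named list `parent -> list(k, resolution)`
#'   overriding the defaults per parent region
#' @param k default neighbourhood size for subclustering (default 15)
#' @param resolution default Leiden resolution (default 0.8)
#' @param d,knn,seed passed to the embedding/clustering
#' @return character vector of child labels `"<parent>.<i>"`, NA where
#'   rejected
#' @export
subcluster_regions <- function(p, parent_labels, params = list(), k = 15,
                               resolution = 0.8, d = 50, knn = 15, seed = 0) {
  stopifnot(inherits(p, "processed_matrix"),
            length(parent_labels) == nrow(p$values))
  out <- rep(NA_character_, length(parent_labels))
  for (parent in sort(unique(parent_labels[!is.na(parent_labels)]))) {
    i <- which(parent_labels == parent)
    kk <- params[[parent]]$k %||% k
    rr <- params[[parent]]$resolution %||% resolution
    if (length(i) < kk) {
      warning(sprintf("parent region %s has %d cells < k = %d: all NA", parent, length(i), kk))
      next
    }
    sub <- processed_matrix(p$values[i, , drop = FALSE], p$cells[i, , drop = FALSE],
                            genes = p$genes, flags = p$flags,
                            lognorm = if (!is.null(p$lognorm)) p$lognorm[i, , drop = FALSE])
    nm <- build_niche_matrix(sub, k = kk)
    lab <- cluster_regions(nm, d = d, resolution = rr, knn = knn, seed = seed)
    lab <- lab[sub$cells$cell_id]                    # original order of the subset
    out[i][!is.na(lab)] <- paste0(parent, ".", sub("^L", "", lab[!is.na(lab)]))
  }
  out
}

#' Region marker z-scores
#'
#' For each gene, computes its mean expression per region, converts the
#' means to the gene's percentage distribution across regions, and
#' normalizes that distribution to z-scores across regions (mean 0, unit
#' variance per gene). Genes with zero total expression get z = 0 and are
#' flagged. Enrichment calls conventionally use a strict `z > 5` cutoff
#' (see [region_markers()]).
#'
#' @param p a [processed_matrix()] or [cell_matrix()]; non-negative values
#'   (normalized log or raw counts) are recommended
#' @param regions per-cell region labels (NA cells are dropped)
#' @return object of class `marker_table`: list with `zscores`
#'   (gene-by-region), `shares`, `means`, `flagged_genes`
#' @export
region_marker_zscores <- function(p, regions) {
  x <- if (inherits(p, "processed_matrix")) (p$lognorm %||% p$values)
       else if (inherits(p, "cell_matrix")) as.matrix(p$counts)
       else as.matrix(p)
  stopifnot(length(regions) == nrow(x))
  ok <- !is.na(regions)
  x <- x[ok, , drop = FALSE]; regions <- regions[ok]
  regs <- sort(unique(as.character(regions)))
  if (length(regs) < 2) stop("need at least 2 regions")
  nr <- table(factor(regions, levels = regs))
  means <- t(rowsum(x, factor(regions, levels = regs)) / as.vector(nr))  # gene x region
  tot <- rowSums(means)
  flagged <- tot == 0
  shares <- means
  shares[!flagged, ] <- means[!flagged, , drop = FALSE] / tot[!flagged]
  shares[flagged, ] <- 0
  z <- t(apply(shares, 1, function(v) {
    s <- sd(v)
    if (s == 0 || !is.finite(s)) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(means)
  structure(list(zscores = z, shares = shares, means = means,
                 flagged_genes = rownames(means)[flagged]),
            class = "marker_table")
}

#' Call enriched region markers from a marker table
#'
#' @param mt a `marker_table` from [region_marker_zscores()]
#' @param z_cutoff strict lower bound on the z-score (default 5)
#' @return data.frame of (gene, region, z) pairs with `z > z_cutoff`
#' @export
region_markers <- function(mt, z_cutoff = 5) {
  stopifnot(inherits(mt, "marker_table"))
  hit <- which(mt$zscores > z_cutoff, arr.ind = TRUE)
  data.frame(gene = rownames(mt$zscores)[hit[, 1]],
             region = colnames(mt$zscores)[hit[, 2]],
             z = mt$zscores[hit], stringsAsFactors = FALSE)
}

# majority vote with ties broken by the nearest voting neighbour's label
vote_majority <- function(nbr_labels, nbr_order) {
  tab <- table(nbr_labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1) return(top)
  for (j in nbr_order) if (nbr_labels[j] %in% top) return(nbr_labels[j])
  top[1]
}

#' Fill missing region labels by spatial kNN vote
#'
#' Each NA cell takes the majority label of its `k` nearest labelled
#' same-sample cells; ties are broken by the nearest neighbour's label.
#'
#' @param labels per-cell labels with NA holes
#' @param coords cell-by-2 (x, y) matrix
#' @param sample_id per-cell sample factor; `NULL` treats all cells as one
#'   sample
#' @param k neighbourhood size (default 5)
#' @return labels with NA holes filled (where labelled neighbours exist)
#' @export
fill_missing_labels <- function(labels, coords, sample_id = NULL, k = 5) {
  labels <- as.character(labels)
  coords <- as.matrix(coords)
  if (is.null(sample_id)) sample_id <- rep("all", length(labels))
  out <- labels
  for (s in unique(sample_id)) {
    i <- which(sample_id == s)
    na_i <- i[is.na(labels[i])]
    lab_i <- i[!is.na(labels[i])]
    if (length(na_i) == 0 || length(lab_i) == 0) next
    kk <- min(k, length(lab_i))
    nn <- RANN::nn2(coords[lab_i, , drop = FALSE], coords[na_i, , drop = FALSE], k = kk)
    for (a in seq_along(na_i)) {
      nl <- labels[lab_i[nn$nn.idx[a, ]]]
      out[na_i[a]] <- vote_majority(nl, seq_len(kk))
    }
  }
  out
}

#' Smooth region labels by spatial kNN majority vote
#'
#' One simultaneous pass of majority voting over each cell's `k` nearest
#' voting neighbours (the cell itself does not vote for itself). Cells whose
#' label is in `excluded_regions` neither vote nor change; cells whose label
#' is in `frozen_regions` vote but never change. Ties go to the nearest
#' voting neighbour's label. NA-labelled cells are left untouched (fill
#' first with [fill_missing_labels()]).
#'
#' @param labels per-cell labels
#' @param coords cell-by-2 (x, y) matrix
#' @param sample_id per-cell sample factor, or `NULL`
#' @param k neighbourhood size (default 50)
#' @param excluded_regions labels excluded from voting and from change
#'   (e.g. meninges-like thin compartments)
#' @param frozen_regions labels that vote but are never changed
#' @return the smoothed label vector
#' @export
smooth_labels <- function(labels, coords, sample_id = NULL, k = 50,
                          excluded_regions = character(),
                          frozen_regions = character()) {
  labels <- as.character(labels)
  coords <- as.matrix(coords)
  if (is.null(sample_id)) sample_id <- rep("all", length(labels))
  out <- labels
  for (s in unique(sample_id)) {
    i <- which(sample_id == s)
    voter <- i[!is.na(labels[i]) & !(labels[i] %in% excluded_regions)]
    target <- i[!is.na(labels[i]) & !(labels[i] %in% excluded_regions) &
                  !(labels[i] %in% frozen_regions)]
    if (length(voter) < 2 || length(target) == 0) next
    kk <- min(k, length(voter) - 1L)
    nn <- RANN::nn2(coords[voter, , drop = FALSE], coords[target, , drop = FALSE],
                    k = kk + 1L)
    for (a in seq_along(target)) {
      row <- nn$nn.idx[a, ]
      self <- match(match(target[a], voter), row)
      if (!is.na(self)) row <- row[-self] else row <- row[-length(row)]
      nl <- labels[voter[row]]
      out[target[a]] <- vote_majority(nl, seq_along(row))
    }
  }
  out
}

#' Cell-type composition z-scores across regions
#'
#' Computes, per region, the percentage composition over cell types
#' (columns sum to 100), then z-scores each type's percentages across
#' regions.
#'
#' @param cell_types per-cell type labels
#' @param regions per-cell region labels
#' @return list with `percent` (type-by-region, columns sum to 100) and
#'   `zscores` (type-by-region; 0 when a type is flat or a single region)
#' @export
composition_zscores <- function(cell_types, regions) {
  ok <- !is.na(cell_types) & !is.na(regions)
  tab <- table(factor(cell_types[ok]), factor(regions[ok]))
  pct <- sweep(tab, 2, pmax(colSums(tab), 1), "/") * 100
  z <- t(apply(pct, 1, function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(pct)
  list(percent = as.matrix(pct), zscores = as.matrix(z))
}
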