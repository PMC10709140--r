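# Joint embedding with a reference, community clustering, the consensus
# label-transfer rule, and subcluster/marker machinery.

#' Jointly embed query and reference cells
#'
#' Concatenates the two matrices restricted to shared genes, standardizes
#' columns, and computes a `d`-dimensional PCA. The `align` step then
#' reduces origin (query vs reference) separation in PC space: `"none"`
#' leaves scores untouched; `"center"` removes the per-origin mean;
#' `"iterative"` performs up to `max_iter` rounds of cluster-anchored
#' centroid matching (k-means soft anchors; per-origin shift toward the
#' cluster's global centroid), a lightweight stand-in for the
#' mixture-model integration used at atlas scale. If `d` exceeds the data
#' rank the embedding is truncated to the rank, with a message.
#'
#' @param query a [processed_matrix()] of query cells
#' @param reference a [processed_matrix()] (or matrix) of reference cells,
#'   processed identically on the shared genes
#' @param shared_genes genes to use; default the intersection
#' @param d target dimensionality (default 50)
#' @param align `"center"` (default), `"none"`, or `"iterative"`
#' @param seed integer seed (PCA initialisation and anchor clustering)
#' @param max_iter iteration cap for `align = "iterative"`
#' @return object of class `latent_embedding`: list with `coords`
#'   (cell-by-d), `origin` (`"query"`/`"reference"`), `d`
#' @export
joint_embed <- function(query, reference, shared_genes = NULL, d = 50,
                        align = c("center", "none", "iterative"), seed = 0,
                        max_iter = 10) {
  align <- match.arg(align)
  qv <- if (inherits(query, "processed_matrix")) query$values else as.matrix(query)
  rv <- if (inherits(reference, "processed_matrix")) reference$values else as.matrix(reference)
  if (is.null(shared_genes)) shared_genes <- intersect(colnames(qv), colnames(rv))
  if (length(shared_genes) < 2) stop("need at least 2 shared genes")
  x <- rbind(qv[, shared_genes, drop = FALSE], rv[, shared_genes, drop = FALSE])
  origin <- c(rep("query", nrow(qv)), rep("reference", nrow(rv)))
  co <- pca_embed(x, d, seed)
  if (align == "center") {
    for (o in unique(origin)) {
      i <- origin == o
      co[i, ] <- sweep(co[i, , drop = FALSE], 2, colMeans(co[i, , drop = FALSE]), "-")
    }
  } else if (align == "iterative") {
    # start from per-origin centering, then refine with cluster anchors
    for (o in unique(origin)) {
      i <- origin == o
      co[i, ] <- sweep(co[i, , drop = FALSE], 2, colMeans(co[i, , drop = FALSE]), "-")
    }
    co <- with_seed(seed, {
      k <- max(2L, min(10L, floor(nrow(co) / 20)))
      for (it in seq_len(max_iter)) {
        km <- suppressWarnings(kmeans(co, centers = k, nstart = 1, iter.max = 20))
        shift_norm <- 0
        for (cl in seq_len(k)) {
          i <- km$cluster == cl
          if (!any(i)) next
          gc_ <- colMeans(co[i, , drop = FALSE])
          for (o in unique(origin[i])) {
            io <- i & origin == o
            if (sum(io) == 0) next
            delta <- gc_ - colMeans(co[io, , drop = FALSE])
            co[io, ] <- sweep(co[io, , drop = FALSE], 2, delta, "+")
            shift_norm <- shift_norm + sqrt(sum(delta^2))
          }
        }
        if (shift_norm < 1e-6) break
      }
      co
    })
  }
  structure(list(coords = co, origin = origin, d = ncol(co)),
            class = "latent_embedding")
}

# standardize columns then PCA; truncates d to the available rank
pca_embed <- function(x, d, seed = 0) {
  x <- standardize_columns(x)
  rank_cap <- min(nrow(x) - 1L, ncol(x))
  if (d > rank_cap) {
    message(sprintf("embedding dimension truncated from %d to data rank %d", d, rank_cap))
    d <- rank_cap
  }
  if (d >= 0.5 * rank_cap || rank_cap <= 60) {
    pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = d)
    sc <- pc$x[, seq_len(min(d, ncol(pc$x))), drop = FALSE]
  } else {
    sc <- with_seed(seed, {
      fit <- irlba::prcomp_irlba(x, n = d, center = FALSE, scale. = FALSE)
      fit$x
    })
  }
  unname(sc)
}

#' Community detection on a latent embedding
#'
#' Builds a symmetric unweighted kNN graph on the latent coordinates and
#' partitions it with the Leiden algorithm (modularity objective) at the
#' given resolution. Labels are arbitrary integers; a fixed seed gives
#' identical labels across runs. A zero-variance (all-identical) embedding
#' yields a single cluster with a warning.
#'
#' @param e a `latent_embedding` or a numeric matrix of coordinates
#' @param knn number of nearest neighbours for the graph (default 15)
#' @param resolution Leiden modularity resolution (default 1.0)
#' @param seed integer seed
#' @return object of class `cluster_labels`: integer vector with attributes
#'   `resolution` and `seed`
#' @export
cluster_communities <- function(e, knn = 15, resolution = 1.0, seed = 0) {
  co <- if (inherits(e, "latent_embedding")) e$coords else as.matrix(e)
  n <- nrow(co)
  if (n == 1) return(structure(1L, class = "cluster_labels",
                               resolution = resolution, seed = seed))
  if (all(apply(co, 2, function(v) diff(range(v))) == 0)) {
    warning("zero-variance embedding: returning a single cluster")
    return(structure(rep(1L, n), class = "cluster_labels",
                     resolution = resolution, seed = seed))
  }
  if (n < knn + 1) knn <- n - 1L
  nn <- RANN::nn2(co, co, k = knn + 1)
  el <- cbind(rep(seq_len(n), knn), as.vector(nn$nn.idx[, -1, drop = FALSE]))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  memb <- with_seed(seed, {
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
    igraph::membership(cl)
  })
  structure(as.integer(memb), class = "cluster_labels",
            resolution = resolution, seed = seed)
}

#' Transfer reference labels to query cells by cluster consensus
#'
#' Within each joint cluster, the modal reference label's fraction is
#' computed among reference cells (reference cells with NA labels are
#' excluded from the denominator). If that fraction strictly exceeds
#' `threshold`, every query cell in the cluster receives the modal label;
#' otherwise the cluster's query cells are NA. A perfectly pure cluster
#' (fraction exactly 1) always transfers, so the rule remains usable at
#' `threshold = 1`. Clusters containing no
#' reference cells are NA. Use `threshold = 0.8` for atlas-level transfer
#' and `0.6` for regional-dataset correspondence.
#'
#' @param joint cluster labels over all (query + reference) cells, e.g. from
#'   [cluster_communities()]
#' @param ref_labels per-reference-cell labels, in reference order
#' @param origin per-cell `"query"`/`"reference"` vector aligned with `joint`
#' @param threshold consensus fraction in (0, 1]; strict inequality
#' @return character vector of labels (NA where transfer failed) for query
#'   cells, in query order
#' @export
transfer_labels <- function(joint, ref_labels, origin, threshold = 0.8) {
  stopifnot(length(joint) == length(origin), threshold > 0, threshold <= 1)
  is_ref <- origin == "reference"
  if (sum(is_ref) != length(ref_labels))
    stop("ref_labels length must match the number of reference cells")
  full_ref <- rep(NA_character_, length(joint))
  full_ref[is_ref] <- as.character(ref_labels)
  out <- rep(NA_character_, sum(!is_ref))
  qpos <- which(!is_ref)
  for (cl in unique(joint)) {
    i <- joint == cl
    rl <- full_ref[i & is_ref]
    rl <- rl[!is.na(rl)]
    qi <- which(i[qpos])
    if (length(qi) == 0) next
    if (length(rl) == 0) next                      # no reference cells: NA
    tab <- sort(table(rl), decreasing = TRUE)
    frac <- tab[1] / length(rl)
    # strict inequality; a perfectly pure cluster always transfers, so the
    # rule stays usable at threshold = 1
    if (frac > threshold || frac == 1) out[qi] <- names(tab)[1]
  }
  out
}

#' Hierarchical consensus transfer over a rank-1..4 taxonomy
#'
#' Applies [transfer_labels()] independently at each taxonomy rank; a query
#' cell can be labelled at a coarse rank and NA at a finer one.
#'
#' @param joint cluster labels over all cells
#' @param ref_rank_labels data.frame with columns `rank1`..`rank4` for
#'   reference cells
#' @param origin per-cell origin vector
#' @param threshold consensus threshold (default 0.8)
#' @return data.frame of rank1..rank4 labels for query cells
#' @export
hierarchical_transfer <- function(joint, ref_rank_labels, origin, threshold = 0.8) {
  ranks <- paste0("rank", 1:4)
  stopifnot(all(ranks %in% names(ref_rank_labels)))
  out <- lapply(ranks, function(r)
    transfer_labels(joint, ref_rank_labels[[r]], origin, threshold))
  names(out) <- ranks
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Subcluster cells of one main cluster
#'
#' Restricted gene filter, then the standard processing and clustering
#' chain. Genes are kept only if their per-cell maximum count is at least
#' 10 AND they are detected at a count of at least 5 in at least 10 cells
#' (both bounds inclusive). Counts are then normalized, log-transformed,
#' regressed and scaled; PCA and Leiden community detection follow.
#'
#' @param m a [cell_matrix()] restricted to one main cluster (>= 20 cells)
#' @param resolution Leiden resolution (default 1.0)
#' @param seed integer seed
#' @param d embedding dimensionality (default 30)
#' @param knn kNN graph size (default 15)
#' @param max_count_min,detect_count,detect_cells_min gene-filter thresholds
#' @return a `cluster_labels` vector over the cells of `m`
#' @export
# genes retained for subclustering: per-cell max count >= max_count_min AND
# detected at count >= detect_count in at least detect_cells_min cells
subcluster_gene_filter <- function(m, max_count_min = 10, detect_count = 5,
                                   detect_cells_min = 10) {
  mx <- apply(as.matrix(m$counts), 2, max)
  ndet <- Matrix::colSums(m$counts >= detect_count)
  m$genes[mx >= max_count_min & ndet >= detect_cells_min]
}

subcluster <- function(m, resolution = 1.0, seed = 0, d = 30, knn = 15,
                       max_count_min = 10, detect_count = 5, detect_cells_min = 10) {
  stopifnot(inherits(m, "cell_matrix"))
  if (nrow(m$counts) < 20) stop("subclustering needs at least 20 cells")
  keep <- subcluster_gene_filter(m, max_count_min, detect_count, detect_cells_min)
  if (length(keep) == 0) stop("all genes removed by the subcluster gene filter")
  sub <- subset_cells(m, genes = match(keep, m$genes))
  p <- normalize_log_scale(sub)
  co <- pca_embed(p$values, min(d, ncol(p$values) - 1L, nrow(p$values) - 1L), seed)
  cluster_communities(co, knn = knn, resolution = resolution, seed = seed)
}

#' Rank marker genes per cluster by Wilcoxon score
#'
#' For each gene and cluster, computes the tie-corrected normal
#' approximation z-score of the Wilcoxon rank-sum statistic for
#' cluster-versus-rest, and reports the top `n_top` genes per cluster
#' (ties broken by gene order). Singleton clusters are scored but flagged
#' in the `singleton` column.
#'
#' @param p a [processed_matrix()] (any real-valued expression works)
#' @param labels per-cell cluster labels
#' @param n_top number of markers per cluster (default 5)
#' @return data.frame with columns `cluster`, `gene`, `score`, `rank`,
#'   `singleton`
#' @export
rank_markers <- function(p, labels, n_top = 5) {
  x <- if (inherits(p, "processed_matrix")) p$values else as.matrix(p)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("need at least 2 clusters to rank markers")
  n <- nrow(x)
  # per-gene ranks and tie correction, computed once
  rk <- apply(x, 2, rank)
  tie_term <- apply(x, 2, function(v) {
    t <- table(v); sum(t^3 - t)
  })
  res <- vector("list", length(cls))
  for (ci in seq_along(cls)) {
    i <- labels == cls[ci]
    n1 <- sum(i); n2 <- n - n1
    r1 <- colSums(rk[i, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- (u - mu) / sqrt(pmax(sig2, 1e-12))
    ord <- order(-z, seq_along(z))[seq_len(min(n_top, length(z)))]
    res[[ci]] <- data.frame(cluster = cls[ci], gene = colnames(x)[ord],
                            score = z[ord], rank = seq_along(ord),
                            singleton = n1 == 1L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
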