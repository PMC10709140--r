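# Leave-one-gene-out-tuned mutual-nearest-neighbour gene imputation from a
# targeted panel to reference-transcriptome scale, plus Moran's I.

#' Select reference genes eligible for imputation
#'
#' Keeps genes whose average count over reference cells is at least
#' `avg_min` and whose per-cell maximum count strictly exceeds `max_min`
#' (genes with maximum at or below `max_min` are filtered).
#'
#' @param reference a `reference_matrix` (or any cell-by-gene count matrix)
#' @param avg_min minimum average read (default 0.005)
#' @param max_min maximum-read bound; genes with max <= this are dropped
#'   (default 10)
#' @return character vector of retained gene names
#' @export
filter_imputation_genes <- function(reference, avg_min = 0.005, max_min = 10) {
  cnt <- if (inherits(reference, "reference_matrix")) reference$counts else as_dgc(reference)
  avg <- Matrix::colMeans(cnt)
  mx <- apply(cnt, 2, max)
  colnames(cnt)[avg >= avg_min & mx > max_min]
}

# normalize -> log1p a raw count matrix (per-cell total to median target)
lognorm_counts <- function(cnt, target = NULL) {
  cnt <- as.matrix(cnt)
  tot <- rowSums(cnt)
  tot[tot == 0] <- 1
  if (is.null(target)) target <- median(rowSums(cnt))
  log1p(sweep(cnt, 1, tot, "/") * target)
}

# shared embedding machinery for the intermediate mappings: process query and
# reference identically on `genes`, embed jointly, return split coordinates
impute_embed <- function(query_cnt, ref_cnt, genes, d, seed, align) {
  qx <- standardize_columns(lognorm_counts(query_cnt[, genes, drop = FALSE]))
  rx <- standardize_columns(lognorm_counts(ref_cnt[, genes, drop = FALSE]))
  emb <- joint_embed(qx, rx, shared_genes = genes, d = d, align = align, seed = seed)
  list(q = emb$coords[emb$origin == "query", , drop = FALSE],
       r = emb$coords[emb$origin == "reference", , drop = FALSE])
}

#' Leave-one-gene-out intermediate mapping
#'
#' Embeds query and reference cells jointly on the shared panel minus the
#' held-out gene, finds each query cell's `n_neighbors` nearest reference
#' cells in latent space, and imputes the held-out gene as the unweighted
#' mean of those neighbours' log1p reference counts. Imputed values
#' therefore lie within the observed range of the reference gene.
#'
#' @param query a [cell_matrix()] (raw counts)
#' @param reference a `reference_matrix` (raw counts)
#' @param held_out_gene gene symbol to hold out (must be shared)
#' @param n_neighbors number of reference neighbours (<= reference size)
#' @param d embedding dimensionality (default 50)
#' @param seed integer seed
#' @param align alignment mode for [joint_embed()] (default `"center"`)
#' @return list with `neighbors` (query-by-n index matrix into reference
#'   rows), `imputed` (per-query-cell value), `gene`, `n_neighbors`
#' @export
intermediate_mapping <- function(query, reference, held_out_gene, n_neighbors = 200,
                                 d = 50, seed = 0, align = "center") {
  stopifnot(inherits(query, "cell_matrix"), inherits(reference, "reference_matrix"))
  shared <- intersect(query$genes, reference$genes)
  if (!held_out_gene %in% shared) stop("held-out gene must be in the shared panel")
  if (n_neighbors > nrow(reference$counts)) stop("n_neighbors exceeds the reference size")
  genes <- setdiff(shared, held_out_gene)
  if (length(genes) < 2) stop("need at least 2 remaining shared genes")
  co <- impute_embed(query$counts, reference$counts, genes, d, seed, align)
  nn <- RANN::nn2(co$r, co$q, k = n_neighbors)
  ref_log <- log1p(as.matrix(reference$counts[, held_out_gene]))
  imp <- rowMeans(matrix(ref_log[nn$nn.idx], ncol = n_neighbors))
  list(neighbors = nn$nn.idx, imputed = imp, gene = held_out_gene,
       n_neighbors = n_neighbors)
}

#' Tune the neighbour count by leave-one-gene-out performance
#'
#' For every shared panel gene, runs the leave-one-gene-out intermediate
#' mapping once at the largest candidate neighbour count (the neighbour
#' lists for smaller candidates are prefixes of that list) and computes the
#' per-gene performance score: the Pearson correlation across cells between
#' the imputed values and the measured log1p query expression. Genes with
#' constant measured expression are excluded. The chosen neighbour count
#' maximizes the median per-gene score, ties toward the smaller candidate.
#' The default grid spans 10-400 and includes the atlas-scale operating
#' point of 200 neighbours.
#'
#' @param query a [cell_matrix()]
#' @param reference a `reference_matrix`
#' @param candidate_ns candidate neighbour counts
#'   (default `c(10, 50, 100, 200, 400)`)
#' @param genes panel genes to evaluate; default all shared genes
#' @param d,seed,align embedding parameters
#' @return list with `performance` (data.frame: gene, n, r), `chosen_n`,
#'   `median_r` (per candidate), and `mappings` (per-gene neighbour index
#'   matrices at the largest candidate, reusable by [final_impute()])
#' @export
loo_tuning <- function(query, reference, candidate_ns = c(10, 50, 100, 200, 400),
                       genes = NULL, d = 50, seed = 0, align = "center") {
  stopifnot(length(candidate_ns) >= 1)
  candidate_ns <- sort(unique(candidate_ns))
  shared <- intersect(query$genes, reference$genes)
  if (is.null(genes)) genes <- shared
  stopifnot(all(genes %in% shared))
  nmax <- max(candidate_ns)
  if (nmax > nrow(reference$counts)) stop("largest candidate exceeds the reference size")
  measured <- log1p(as.matrix(query$counts[, genes, drop = FALSE]))
  perf <- vector("list", length(genes))
  maps <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    emb_genes <- setdiff(shared, g)
    co <- impute_embed(query$counts, reference$counts, emb_genes, d, seed, align)
    nn <- RANN::nn2(co$r, co$q, k = nmax)
    maps[[gi]] <- nn$nn.idx
    ref_log <- log1p(as.vector(reference$counts[, g]))
    mvals <- measured[, gi]
    if (sd(mvals) == 0) {
      perf[[gi]] <- data.frame(gene = g, n = candidate_ns, r = NA_real_)
      next
    }
    vals <- matrix(ref_log[nn$nn.idx], ncol = nmax)
    csum <- t(apply(vals, 1, cumsum))
    rr <- vapply(candidate_ns, function(k) cor(csum[, k] / k, mvals), numeric(1))
    perf[[gi]] <- data.frame(gene = g, n = candidate_ns, r = rr)
  }
  performance <- do.call(rbind, perf)
  med <- vapply(candidate_ns, function(k)
    median(performance$r[performance$n == k], na.rm = TRUE), numeric(1))
  chosen <- candidate_ns[which.max(med)]   # which.max takes the first (smaller) on ties
  names(maps) <- genes
  list(performance = performance, chosen_n = chosen,
       median_r = stats::setNames(med, candidate_ns), mappings = maps)
}

#' Final occurrence-weighted imputation
#'
#' Aggregates the per-gene intermediate mappings: for each query cell, the
#' multiset union of its reference neighbours across all mappings defines
#' weights proportional to the number of times each reference cell occurs.
#' Every requested gene is imputed as the weight-averaged log1p reference
#' count over that multiset, so the output is on the reference log-count
#' scale and weights are scale-invariant.
#'
#' @param query a [cell_matrix()]
#' @param reference a `reference_matrix`
#' @param mappings list of neighbour index matrices (query-by-n), e.g. the
#'   `mappings` of [loo_tuning()] or `neighbors` of
#'   [intermediate_mapping()]; columns beyond `n_use` are ignored
#' @param genes genes to impute; default [filter_imputation_genes()] applied
#'   to the reference
#' @param n_use number of neighbours to use from each mapping (default all)
#' @return dense query-by-genes matrix of imputed log expression
#' @export
final_impute <- function(query, reference, mappings, genes = NULL, n_use = NULL) {
  stopifnot(length(mappings) >= 1)
  if (is.null(genes)) genes <- filter_imputation_genes(reference)
  stopifnot(all(genes %in% reference$genes))
  nq <- nrow(query$counts)
  nr <- nrow(reference$counts)
  ii <- integer(0); jj <- integer(0)
  for (m in mappings) {
    idx <- if (is.list(m)) m$neighbors else m
    if (!is.null(n_use)) idx <- idx[, seq_len(min(n_use, ncol(idx))), drop = FALSE]
    stopifnot(nrow(idx) == nq)
    ii <- c(ii, rep(seq_len(nq), ncol(idx)))
    jj <- c(jj, as.vector(idx))
  }
  if (length(ii) == 0) stop("empty neighbour multiset")
  w <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nq, nr))
  w <- w / Matrix::rowSums(w)
  ref_log <- log1p(as.matrix(reference$counts[, genes, drop = FALSE]))
  out <- as.matrix(w %*% ref_log)
  rownames(out) <- query$cells$cell_id
  colnames(out) <- genes
  out
}

#' Moran's I spatial autocorrelation
#'
#' Global Moran's I with binary symmetric kNN weights:
#' `I = (N/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`,
#' where `w_ij = 1` when j is among i's k nearest neighbours or vice versa.
#' A constant field returns 0 with attribute `undefined = TRUE`.
#'
#' @param values per-cell numeric values
#' @param coords cell-by-2 coordinate matrix
#' @param k neighbourhood size (default 6)
#' @return Moran's I (numeric scalar, possibly with `undefined` attribute)
#' @export
morans_i <- function(values, coords, k = 6) {
  coords <- as.matrix(coords)
  n <- length(values)
  stopifnot(nrow(coords) == n, n >= 2)
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) return(structure(0, undefined = TRUE))
  kk <- min(k, n - 1L)
  nn <- knn_index(coords, k = kk)
  ii <- rep(seq_len(n), kk)
  jj <- as.vector(nn$idx)
  a <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  a <- ((a + Matrix::t(a)) > 0) * 1          # symmetric binary weights
  wsum <- sum(a)
  num <- as.numeric(Matrix::crossprod(z, a %*% z))
  (n / wsum) * num / s2
}
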