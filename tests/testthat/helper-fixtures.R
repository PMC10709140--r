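# Shared fixture builders and independent brute-force oracles.
# Oracles deliberately avoid the package's own code paths: dense distance
# matrices, explicit loops, closed forms.

make_cells <- function(counts, x = NULL, y = NULL, sample_id = "S1", batch_id = "B1") {
  n <- nrow(counts)
  if (is.null(x)) x <- seq_len(n)
  if (is.null(y)) y <- rep(0, n)
  cell_matrix(counts, data.frame(
    cell_id = sprintf("c%03d", seq_len(n)), x = x, y = y, z = 0,
    sample_id = rep_len(sample_id, n), batch_id = rep_len(batch_id, n),
    stringsAsFactors = FALSE))
}

make_reference <- function(counts, type, tree = NULL) {
  # hand-built reference container mirroring generate_reference()'s shape
  tt <- as.integer(sub("^T", "", type))
  if (is.null(tree)) tree <- spatlas:::type_rank_tree(max(tt))
  rownames(counts) <- sprintf("ref%03d", seq_len(nrow(counts)))
  structure(list(counts = spatlas:::as_dgc(counts), genes = colnames(counts),
                 labels = tree[tt, c("rank1", "rank2", "rank3", "rank4")],
                 type = type, profiles = NULL),
            class = "reference_matrix")
}

# dense-matrix distance to the k-th nearest other point
brute_kth_dist <- function(xy, k) {
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  apply(d, 1, function(r) sort(r)[k])
}

# nearest-row index of `data` for each row of `query`, smallest index on ties
brute_nearest <- function(data, query, tol = 1e-9) {
  vapply(seq_len(nrow(query)), function(i) {
    dd <- sqrt(colSums((t(data) - query[i, ])^2))
    which(dd <= min(dd) + tol)[1]
  }, integer(1))
}

# percentile by explicit linear interpolation between order statistics
brute_quantile7 <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p
  lo <- floor(h)
  v[lo + 1] + (h - lo) * (ifelse(lo + 2 > n, v[n], v[pmin(lo + 2, n)]) - v[lo + 1])
}

expect_ari_at_least <- function(a, b, bound) {
  ari <- mclust::adjustedRandIndex(a, b)
  expect_gte(ari, bound)
  invisible(ari)
}
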