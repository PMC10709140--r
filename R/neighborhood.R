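# Near-range cell-cell adjacency from Delaunay triangulation.

#' Per-sample Delaunay mesh graph of cell centroids
#'
#' Triangulates cell centroids within each sample and returns the
#' deduplicated undirected edge list. Edges never cross samples. No edge
#' length cutoff is applied by default; `max_edge_length` prunes long edges
#' if desired.
#'
#' @param coords cell-by-2 (x, y) matrix
#' @param sample_id per-cell sample factor, or `NULL` for a single sample
#' @param max_edge_length optional pruning threshold in coordinate units
#' @return data.frame with integer columns `from`, `to` (row indices into
#'   `coords`, `from < to`) and `sample_id`
#' @export
delaunay_graph <- function(coords, sample_id = NULL, max_edge_length = NULL) {
  coords <- as.matrix(coords)
  if (is.null(sample_id)) sample_id <- rep("all", nrow(coords))
  out <- list()
  for (s in unique(sample_id)) {
    i <- which(sample_id == s)
    if (length(i) < 3)
      stop(sprintf("sample %s has fewer than 3 cells; cannot triangulate", s))
    xy <- coords[i, , drop = FALSE]
    cx <- sweep(xy, 2, colMeans(xy), "-")
    if (qr(cx)$rank < 2)
      stop(sprintf("cells of sample %s are collinear; jitter coordinates or drop the sample", s))
    dd <- deldir::deldir(xy[, 1], xy[, 2])
    a <- pmin(dd$delsgs$ind1, dd$delsgs$ind2)
    b <- pmax(dd$delsgs$ind1, dd$delsgs$ind2)
    keep <- !duplicated(cbind(a, b))
    a <- a[keep]; b <- b[keep]
    if (!is.null(max_edge_length)) {
      len <- sqrt(rowSums((xy[a, , drop = FALSE] - xy[b, , drop = FALSE])^2))
      a <- a[len <= max_edge_length]; b <- b[len <= max_edge_length]
    }
    out[[s]] <- data.frame(from = i[a], to = i[b], sample_id = s,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Type-by-type interaction (edge count) matrix
#'
#' `counts[i, j]` is the number of mesh edges joining a type-i cell with a
#' type-j cell under the symmetric double-counting convention: each
#' undirected edge contributes 1 to `[i, j]` and 1 to `[j, i]`, so a
#' same-type edge adds 2 to the diagonal and the matrix total equals twice
#' the number of edges.
#'
#' @param edges edge list from [delaunay_graph()]
#' @param labels per-cell type labels (indexed by the edge endpoints)
#' @return object of class `adjacency_matrix`: list with `raw`
#'   (type-by-type integer matrix) and `normalized` (NULL until
#'   [normalize_sequential()])
#' @export
interaction_matrix <- function(edges, labels) {
  labels <- as.character(labels)
  la <- labels[edges$from]; lb <- labels[edges$to]
  lev <- sort(unique(labels))
  m <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  t1 <- table(factor(la, lev), factor(lb, lev))
  m <- m + as.matrix(t1) + t(as.matrix(t1))
  structure(list(raw = m, normalized = NULL, normalization = NULL),
            class = "adjacency_matrix")
}

#' Sequential row-then-column normalization
#'
#' Divides each row of the raw matrix by its sum, then each column of the
#' result by its sum; all-zero rows/columns pass through as zeros and are
#' flagged. Non-zero columns of the result sum to 1.
#'
#' @param a an `adjacency_matrix` (or plain matrix)
#' @return the `adjacency_matrix` with `normalized` filled and a
#'   `normalization` record
#' @export
normalize_sequential <- function(a) {
  m <- if (inherits(a, "adjacency_matrix")) a$raw else as.matrix(a)
  rs <- rowSums(m)
  zero_rows <- rs == 0
  rs[zero_rows] <- 1
  x <- m / rs
  cs <- colSums(x)
  zero_cols <- cs == 0
  cs[zero_cols] <- 1
  x <- sweep(x, 2, cs, "/")
  rec <- list(order = c("row", "column"),
              zero_rows = rownames(m)[zero_rows],
              zero_cols = colnames(m)[zero_cols])
  if (inherits(a, "adjacency_matrix")) {
    a$normalized <- x; a$normalization <- rec; a
  } else structure(list(raw = m, normalized = x, normalization = rec),
                   class = "adjacency_matrix")
}
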