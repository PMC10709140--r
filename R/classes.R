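#' @importFrom stats prcomp quantile rnbinom rnorm rpois runif sd var median cor kmeans
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

# coerce any matrix-like input to a double general CsparseMatrix
as_dgc <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# ---- lightweight S3 containers ------------------------------------------------

#' Construct a cell-by-gene matrix container
#'
#' Bundles a sparse cell-by-gene count matrix with per-cell metadata
#' (centroid coordinates in micrometres, sample and batch labels) and gene
#' symbols. This is the central container passed between pipeline stages.
#'
#' @param counts cell-by-gene matrix of non-negative integer counts
#'   (coerced to `dgCMatrix`); rownames are cell ids, colnames gene symbols.
#' @param cells data.frame with columns `cell_id`, `x`, `y`, `z`,
#'   `sample_id`, `batch_id` (one row per row of `counts`).
#' @param genes character vector of gene symbols; defaults to
#'   `colnames(counts)`.
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cells, genes = colnames(counts)) {
  counts <- as_dgc(counts)
  stopifnot(nrow(counts) == nrow(cells))
  need <- c("cell_id", "x", "y", "z", "sample_id", "batch_id")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0L) stop("cells metadata missing columns: ", paste(miss, collapse = ", "))
  if (nrow(counts) > 0 && any(counts@x < 0)) stop("counts must be non-negative")
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(counts)))
  if (length(genes) != ncol(counts)) stop("genes length must match ncol(counts)")
  dimnames(counts) <- list(if (nrow(counts)) as.character(cells$cell_id) else NULL,
                           if (ncol(counts)) as.character(genes) else NULL)
  structure(list(counts = counts, cells = as.data.frame(cells), genes = as.character(genes)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes, %d sample(s), %d batch(es)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$sample_id)), length(unique(x$cells$batch_id))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset a cell_matrix by cells and/or genes
#'
#' @param m a `cell_matrix`
#' @param cells logical/integer/character index over cells
#' @param genes logical/integer/character index over genes
#' @return the subsetted `cell_matrix`
#' @export
subset_cells <- function(m, cells = NULL, genes = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  ci <- if (is.null(cells)) seq_len(nrow(m$counts)) else cells
  gi <- if (is.null(genes)) seq_len(ncol(m$counts)) else genes
  cnt <- m$counts[ci, gi, drop = FALSE]
  cell_matrix(cnt, m$cells[ci, , drop = FALSE], genes = colnames(cnt))
}

#' Construct a spot table
#'
#' Amplicon-level records: one row per detected spot with coordinates in
#' micrometres and a decoded feature identity (gene or barcode).
#'
#' @param df data.frame with columns `spot_id`, `x`, `y`, `z`, `feature_id`,
#'   `feature_kind` (`"gene"` or `"barcode"`), `sample_id`, and optionally
#'   `cell_id` (NA where unassigned).
#' @return data.frame of class `spot_table`
#' @export
spot_table <- function(df) {
  need <- c("spot_id", "x", "y", "z", "feature_id", "feature_kind", "sample_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("spot table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df) > 0 && !all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("spot coordinates must be finite")
  if (!"cell_id" %in% names(df)) df$cell_id <- NA_character_
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Construct a binary nucleus mask
#'
#' A rasterized nucleus-occupancy grid used to reject spots and cells that
#' fall outside nuclei. Pixel (i, j) of `grid` covers the half-open square
#' `[x0+(j-1)*px, x0+j*px) x [y0+(i-1)*px, y0+i*px)`; a point maps to a pixel
#' by the floor convention.
#'
#' @param grid logical (or 0/1) matrix, rows indexing y and columns x
#' @param origin numeric length-2: (x0, y0) of the grid corner, micrometres
#' @param pixel_size pixel edge length in micrometres (> 0)
#' @return object of class `nucleus_mask`
#' @export
nucleus_mask <- function(grid, origin = c(0, 0), pixel_size = 1) {
  stopifnot(pixel_size > 0, length(origin) == 2)
  grid <- matrix(as.logical(grid), nrow = nrow(grid))
  structure(list(grid = grid, origin = as.numeric(origin), pixel_size = pixel_size),
            class = "nucleus_mask")
}

#' Look up mask occupancy at point coordinates
#'
#' @param mask a `nucleus_mask`
#' @param x,y point coordinates in micrometres
#' @return logical vector; FALSE for points outside the grid frame
#' @export
mask_lookup <- function(mask, x, y) {
  stopifnot(inherits(mask, "nucleus_mask"))
  j <- floor((x - mask$origin[1]) / mask$pixel_size) + 1L
  i <- floor((y - mask$origin[2]) / mask$pixel_size) + 1L
  ok <- i >= 1L & i <= nrow(mask$grid) & j >= 1L & j <= ncol(mask$grid)
  out <- logical(length(x))
  out[ok] <- mask$grid[cbind(i[ok], j[ok])]
  out
}

#' Construct a processed expression matrix
#'
#' Dense cell-by-gene real-valued matrix with provenance flags recording
#' which transformations have been applied.
#'
#' @param values dense numeric cell-by-gene matrix
#' @param cells per-cell metadata data.frame (as in [cell_matrix()])
#' @param genes gene symbols
#' @param flags named logical vector with entries `normalized`,
#'   `log_transformed`, `total_regressed`, `scaled`, `batch_corrected`
#' @param lognorm optional matrix of normalized log1p values kept from before
#'   regression/scaling (used for niche construction)
#' @return object of class `processed_matrix`
#' @export
processed_matrix <- function(values, cells, genes = colnames(values),
                             flags = c(normalized = FALSE, log_transformed = FALSE,
                                       total_regressed = FALSE, scaled = FALSE,
                                       batch_corrected = FALSE),
                             lognorm = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(cells))
  if (nrow(values) > 0 && !all(is.finite(values))) stop("processed values must be finite")
  if (flags[["scaled"]] && !flags[["normalized"]])
    stop("provenance flags must be monotone: scaled implies normalized")
  colnames(values) <- genes
  rownames(values) <- cells$cell_id
  structure(list(values = values, cells = as.data.frame(cells),
                 genes = as.character(genes), flags = flags, lognorm = lognorm),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  on <- names(x$flags)[x$flags]
  cat(sprintf("<processed_matrix> %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values),
              if (length(on)) paste(on, collapse = ", ") else "raw"))
  invisible(x)
}

# ---- internal helpers ---------------------------------------------------------

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit, so no global state leaks.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Column standardization with zero-variance guard: constant columns map to 0.
standardize_columns <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, s, "/")
}

# kNN indices among `data` rows for `query` rows (self excluded when the two
# are the same matrix). Returns list(idx, dist), idx is n_query x k.
knn_index <- function(data, query = data, k, self = identical(data, query)) {
  n <- nrow(data)
  kk <- min(k + as.integer(self), n)
  res <- RANN::nn2(data, query, k = kk)
  if (self) {
    idx <- matrix(0L, nrow(query), kk - 1L)
    dst <- matrix(0, nrow(query), kk - 1L)
    for (i in seq_len(nrow(query))) {
      row <- res$nn.idx[i, ]
      drop <- match(i, row)
      if (is.na(drop)) drop <- kk  # self lost to distance ties; drop the farthest
      idx[i, ] <- row[-drop]
      dst[i, ] <- res$nn.dists[i, -drop]
    }
    list(idx = idx, dist = dst)
  } else {
    list(idx = res$nn.idx, dist = res$nn.dists)
  }
}
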