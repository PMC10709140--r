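# Spot-level quality control and barcode-to-cell assignment.

#' Remove low-density background spots
#'
#' Scores each spot by its local density, defined as the Euclidean distance
#' to its `density_k`-th nearest other spot within the same sample, and
#' removes the `ceiling(fraction * N)` spots with the largest such distance
#' (the lowest-density spots). Ties in the density score are broken by row
#' order of `spot_id`, so the result is deterministic and invariant to input
#' row permutation.
#'
#' With more than one sample present the rule is applied independently per
#' sample. `fraction = 0` returns the input unchanged.
#'
#' @param spots a [spot_table()]
#' @param fraction fraction of spots to remove, in [0, 1); default 0.10
#' @param density_k neighbour rank used for the density score (default 10);
#'   each sample must contain more than `density_k` spots
#' @return the filtered [spot_table()]
#' @export
filter_background_spots <- function(spots, fraction = 0.10, density_k = 10) {
  stopifnot(inherits(spots, "spot_table"), fraction >= 0, fraction < 1, density_k >= 1)
  if (fraction == 0) return(spots)
  keep <- logical(nrow(spots))
  for (s in unique(spots$sample_id)) {
    i <- which(spots$sample_id == s)
    n <- length(i)
    if (n < density_k + 1)
      stop(sprintf("sample %s has %d spots; need more than density_k = %d", s, n, density_k))
    xy <- cbind(spots$x[i], spots$y[i])
    nn <- RANN::nn2(xy, xy, k = density_k + 1)
    score <- nn$nn.dists[, density_k + 1]      # distance to k-th nearest other spot
    m <- ceiling(fraction * n)
    ord <- order(-score, spots$spot_id[i])  # ties -> spot_id order
    keep[i[ord[-seq_len(m)]]] <- TRUE
  }
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  spot_table(out)
}

#' Retain cells whose centroid lies inside the nucleus mask
#'
#' A cell is kept when the mask pixel containing its (x, y) centroid (floor
#' convention, z ignored) is occupied. A degenerate all-empty mask yields an
#' empty result with a warning.
#'
#' @param cells a [cell_matrix()]
#' @param mask a [nucleus_mask()]
#' @return the filtered [cell_matrix()]
#' @export
filter_cells_by_mask <- function(cells, mask) {
  stopifnot(inherits(cells, "cell_matrix"), inherits(mask, "nucleus_mask"))
  if (!any(mask$grid)) {
    warning("nucleus mask is empty; all cells removed")
    return(subset_cells(cells, cells = integer(0)))
  }
  keep <- mask_lookup(mask, cells$cells$x, cells$cells$y)
  subset_cells(cells, cells = which(keep))
}

#' Assign barcode spots to cells via their nearest mRNA spot
#'
#' Barcode spots falling outside the nucleus mask are removed first. Each
#' surviving barcode spot then inherits the `cell_id` of its single nearest
#' mRNA spot (k = 1, Euclidean distance in the x-y plane); exact distance
#' ties are resolved toward the smallest `cell_id`. Returns the total barcode
#' count for every cell present in `mrna_spots`, including zeros.
#'
#' @param barcode_spots a [spot_table()] of barcode amplicons
#' @param mrna_spots a [spot_table()] with non-NA `cell_id` assignments
#' @param mask a [nucleus_mask()]; pass `NULL` to skip mask filtering
#' @return named integer vector of per-cell barcode counts
#' @export
assign_barcode_spots <- function(barcode_spots, mrna_spots, mask) {
  stopifnot(inherits(barcode_spots, "spot_table"), inherits(mrna_spots, "spot_table"))
  mrna_spots <- mrna_spots[!is.na(mrna_spots$cell_id), , drop = FALSE]
  if (nrow(mrna_spots) == 0) stop("mrna_spots must contain cell-assigned spots")
  cells <- sort(unique(mrna_spots$cell_id))
  counts <- stats::setNames(integer(length(cells)), cells)
  if (!is.null(mask)) {
    inside <- mask_lookup(mask, barcode_spots$x, barcode_spots$y)
    barcode_spots <- barcode_spots[inside, , drop = FALSE]
  }
  if (nrow(barcode_spots) == 0) return(counts)
  q <- cbind(barcode_spots$x, barcode_spots$y)
  d <- cbind(mrna_spots$x, mrna_spots$y)
  kk <- min(8L, nrow(mrna_spots))
  nn <- RANN::nn2(d, q, k = kk)
  assigned <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    dmin <- nn$nn.dists[i, 1]
    tied <- which(nn$nn.dists[i, ] <= dmin + 1e-9)
    assigned[i] <- min(mrna_spots$cell_id[nn$nn.idx[i, tied]])
  }
  tab <- table(assigned)
  counts[names(tab)] <- as.integer(tab)
  counts
}
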