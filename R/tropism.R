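# Per-group viral-barcode tropism summaries.

#' Percentile summaries of per-cell barcode counts by group
#'
#' For each group (cell type or tissue region), reports the 2.5th, 25th,
#' 50th, 75th and 97.5th percentiles of the per-cell barcode counts,
#' using the linear-interpolation quantile convention (R type 7), plus the
#' group size. Empty or all-NA groups are skipped with a warning. The
#' result is invariant to cell ordering.
#'
#' @param barcode_counts per-cell non-negative counts
#' @param groups per-cell group labels, aligned with `barcode_counts`
#' @return data.frame of class `tropism_summary` with columns `group`,
#'   `p2.5`, `p25`, `p50`, `p75`, `p97.5`, `n`
#' @export
summarize_by_group <- function(barcode_counts, groups) {
  stopifnot(length(barcode_counts) == length(groups))
  probs <- c(0.025, 0.25, 0.50, 0.75, 0.975)
  out <- list()
  for (g in sort(unique(as.character(groups[!is.na(groups)])))) {
    v <- barcode_counts[!is.na(groups) & groups == g]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warning(sprintf("group %s is empty; skipped", g))
      next
    }
    q <- quantile(v, probs, type = 7, names = FALSE)
    out[[g]] <- data.frame(group = g, p2.5 = q[1], p25 = q[2], p50 = q[3],
                           p75 = q[4], p97.5 = q[5], n = length(v),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("tropism_summary", "data.frame")
  res
}

#' Rank groups by median barcode expression
#'
#' Stable descending sort by the median (p50), ties broken by larger group
#' size.
#'
#' @param summaries a `tropism_summary` from [summarize_by_group()]
#' @return the reordered summary table
#' @export
rank_groups <- function(summaries) {
  stopifnot(inherits(summaries, "tropism_summary"))
  out <- summaries[order(-summaries$p50, -summaries$n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
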