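# Cell/gene quality control, normalization and batch correction.

#' Filter cells and genes by detection and count thresholds
#'
#' Applies four rules in a single fixed pass, without iteration:
#' (1) drop cells detecting fewer than `min_genes_per_cell` genes;
#' (2) drop cells with total count below `min_counts`;
#' (3) drop cells with total count above `max_counts`;
#' (4) drop genes detected in fewer than `min_cells_per_gene` of the
#' remaining cells. The defaults (20 / 20 / 30 / 1300) are the standard
#' thresholds for targeted in situ panels of this depth. The result is
#' independent of input row/column order.
#'
#' @param m a [cell_matrix()] of raw counts
#' @param min_genes_per_cell minimum detected genes per cell
#' @param min_cells_per_gene minimum cells per gene (after cell filtering)
#' @param min_counts minimum total count per cell
#' @param max_counts maximum total count per cell
#' @return the filtered [cell_matrix()]
#' @export
filter_cells_genes <- function(m, min_genes_per_cell = 20, min_cells_per_gene = 20,
                               min_counts = 30, max_counts = 1300) {
  stopifnot(inherits(m, "cell_matrix"))
  if (nrow(m$counts) == 0) return(m)
  ngenes <- Matrix::rowSums(m$counts > 0)
  total <- Matrix::rowSums(m$counts)
  keep_cell <- ngenes >= min_genes_per_cell & total >= min_counts & total <= max_counts
  if (!any(keep_cell)) stop("all cells removed by quality-control thresholds")
  sub <- m$counts[keep_cell, , drop = FALSE]
  keep_gene <- Matrix::colSums(sub > 0) >= min_cells_per_gene
  subset_cells(m, cells = which(keep_cell), genes = which(keep_gene))
}

#' Normalize, log-transform, regress out totals and scale
#'
#' The processing chain applied to filtered counts: (1) per-cell total-count
#' normalization to the median pre-normalization total; (2) `log(1 + x)`;
#' (3) per-gene ordinary-least-squares regression of expression on the
#' per-cell total count, keeping residuals; (4) per-gene scaling to zero
#' mean and unit variance. Entirely deterministic. The intermediate
#' normalized log values (after step 2) are retained in the result's
#' `lognorm` slot for downstream niche construction.
#'
#' @param m a [cell_matrix()] of filtered counts
#' @param target_sum normalization target; default the median per-cell total
#' @return a [processed_matrix()]
#' @export
normalize_log_scale <- function(m, target_sum = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  total <- Matrix::rowSums(m$counts)
  if (any(total == 0)) stop("zero-total cell encountered; apply filter_cells_genes first")
  if (is.null(target_sum)) target_sum <- median(total)
  x <- as.matrix(m$counts)
  x <- sweep(x, 1, total, "/") * target_sum
  x <- log1p(x)
  lognorm <- x
  # regress each gene on the per-cell total (with intercept), keep residuals
  tc <- total - mean(total)
  stc <- sum(tc^2)
  if (stc > 0) {
    beta <- as.vector(crossprod(tc, x)) / stc
    x <- x - outer(tc, beta)
  }
  x <- sweep(x, 2, colMeans(x), "-")
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  x <- sweep(x, 2, sdv, "/")
  processed_matrix(x, m$cells, genes = m$genes,
                   flags = c(normalized = TRUE, log_transformed = TRUE,
                             total_regressed = TRUE, scaled = TRUE,
                             batch_corrected = FALSE),
                   lognorm = lognorm)
}

#' Location-scale batch correction
#'
#' Per-gene, per-batch adjustment in the style of ComBat. In the default
#' plain mode each gene is standardized within batch and re-expressed at the
#' gene's grand mean and pooled standard deviation, so post-correction
#' per-batch gene means are equal and per-batch gene variances are equal,
#' exactly, and the grand mean of every gene is preserved. The optional
#' `eb = TRUE` mode shrinks the per-batch location and scale estimates with
#' non-iterative parametric empirical-Bayes moments before adjusting;
#' residual batch differences then reflect the shrinkage.
#'
#' @param p a [processed_matrix()]
#' @param batches per-cell batch factor; defaults to the `batch_id` column
#' @param eb use empirical-Bayes shrinkage of batch effects (default FALSE)
#' @return the corrected [processed_matrix()] with `batch_corrected = TRUE`
#' @export
correct_batch <- function(p, batches = NULL, eb = FALSE) {
  stopifnot(inherits(p, "processed_matrix"))
  if (is.null(batches)) batches <- p$cells$batch_id
  batches <- as.factor(batches)
  stopifnot(length(batches) == nrow(p$values))
  nb <- table(batches)
  if (length(nb) < 2) return(p)  # single batch: identity transform
  if (any(nb < 2)) stop("singleton batch: cannot estimate a batch scale")
  x <- p$values
  grand_mu <- colMeans(x)
  grand_sd <- apply(x, 2, sd)
  grand_sd[grand_sd == 0] <- 1
  bm <- rowsum(x, batches) / as.vector(nb)                 # batch means
  bv <- rowsum(x^2, batches) / as.vector(nb) - bm^2        # batch variances (ML)
  bv <- bv * as.vector(nb) / pmax(as.vector(nb) - 1, 1)    # unbiased
  bs <- sqrt(bv)
  if (any(bs == 0)) stop("a gene is constant within a batch: cannot estimate scale")
  if (eb) {
    # standardized batch effects, shrunk by method-of-moments EB
    gamma <- sweep(sweep(bm, 2, grand_mu, "-"), 2, grand_sd, "/")
    g_bar <- rowMeans(gamma); t2 <- apply(gamma, 1, var)
    delta2 <- sweep(bv, 2, grand_sd^2, "/")
    d_bar <- rowMeans(delta2); d_var <- apply(delta2, 1, var)
    # inverse-gamma prior moments per batch
    lambda <- 2 + d_bar^2 / pmax(d_var, 1e-12)
    theta <- d_bar * (lambda - 1)
    ni <- as.vector(nb)
    for (b in seq_along(ni)) {
      w <- ni[b] * t2[b] / (ni[b] * t2[b] + delta2[b, ])
      gamma[b, ] <- w * gamma[b, ] + (1 - w) * g_bar[b]
      delta2[b, ] <- (theta[b] + 0.5 * ni[b] * delta2[b, ]) / (lambda[b] + ni[b] / 2 - 1)
    }
    bm_adj <- sweep(sweep(gamma, 2, grand_sd, "*"), 2, grand_mu, "+")
    bs_adj <- sweep(sqrt(delta2), 2, grand_sd, "*")
  } else {
    bm_adj <- bm; bs_adj <- bs
  }
  bi <- as.integer(batches)
  z <- (x - bm_adj[bi, , drop = FALSE]) / bs_adj[bi, , drop = FALSE]
  out <- sweep(sweep(z, 2, grand_sd, "*"), 2, grand_mu, "+")
  p$values <- out
  p$flags[["batch_corrected"]] <- TRUE
  p
}
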