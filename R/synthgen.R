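# Synthetic spatial-atlas generator.
#
# Produces multi-slice 2D tissue with contiguous regions, region-specific
# cell-type composition, negative-binomial expression over a targeted panel,
# per-batch location/scale effects on the log mean, a matched reference over a
# larger gene set, amplicon spot clouds with uniform background, and per-cell
# viral-barcode counts with region/type-dependent multipliers. Every output
# carries full ground truth so downstream stages have a recoverable target.

#' Configuration for the synthetic atlas generator
#'
#' The defaults define the package's reference simulation conditions: two
#' 1000 x 1000 um slices of 2,500 cells each, six layered regions, eight cell
#' types with region-biased composition, a 50-gene targeted panel drawn from a
#' 150-gene reference universe, near-Poisson negative-binomial counts
#' (dispersion size 20) and mild per-slice batch effects.
#'
#' Per-gene expression heterogeneity across types is controlled by a
#' deterministic ladder `h_g` ranging over `heterogeneity_range`: type
#' profiles are `log mu[t,g] = log(base_mean) + h_g * z[t,g] - h_g^2/2` with
#' standard-normal `z` fixed by `seed`, so genes span flat to strongly
#' type-specific and the generating heterogeneity of every gene is known.
#'
#' @param n_slices number of tissue slices (samples)
#' @param slice_extent (width, height) of each slice in micrometres
#' @param n_regions number of spatial regions per slice
#' @param region_layout `"layers"` (horizontal bands), `"blobs"` (Voronoi
#'   cells of random seed points) or `"mixed"`
#' @param n_cell_types number of cell types
#' @param composition region-by-type probability matrix (rows sum to 1);
#'   default gives each region a 0.75-dominant type in rotation
#' @param n_cells_per_slice cells per slice
#' @param panel_genes number of genes in the targeted panel (G)
#' @param reference_genes number of genes in the reference universe
#'   (G_ref >= G; the panel is the first G of them)
#' @param base_mean baseline negative-binomial mean per gene
#' @param heterogeneity_range range of the per-gene type-heterogeneity ladder
#' @param nb_mean optional explicit type-by-gene mean matrix (overrides the
#'   ladder construction)
#' @param nb_dispersion negative-binomial size parameter (larger = closer to
#'   Poisson)
#' @param batch_shift_sd sd of the per-batch per-gene additive shift on
#'   log(mean)
#' @param batch_scale_sd sd of log of the per-batch per-gene multiplicative
#'   scale on log(mean)
#' @param spots_per_count amplicons emitted per transcript count
#' @param spot_jitter_sd sd (um) of spot displacement around the centroid
#' @param background_spot_fraction uniform background spots added, as a
#'   fraction of real mRNA spots (in [0, 1))
#' @param tropism_multipliers region-by-type positive multipliers on the
#'   barcode rate; default all 1
#' @param baseline_barcode_rate expected barcode count per cell at
#'   multiplier 1
#' @param mask_pixel_size nucleus-mask pixel edge (um)
#' @param nucleus_radius nucleus disc radius (um) marked in the mask
#' @param seed integer seed; fixed seed gives bit-identical outputs
#' @return validated list of class `synth_config`
#' @export
synth_config <- function(n_slices = 2, slice_extent = c(1000, 1000),
                         n_regions = 6, region_layout = c("layers", "blobs", "mixed"),
                         n_cell_types = 8, composition = NULL,
                         n_cells_per_slice = 2500, panel_genes = 50,
                         reference_genes = 150, base_mean = 4,
                         heterogeneity_range = c(0.25, 1.5),
                         nb_mean = NULL, nb_dispersion = 20,
                         batch_shift_sd = 0.05, batch_scale_sd = 0.02,
                         spots_per_count = 1, spot_jitter_sd = 2,
                         background_spot_fraction = 0.10,
                         tropism_multipliers = NULL, baseline_barcode_rate = 20,
                         mask_pixel_size = 4, nucleus_radius = 6, seed = 0) {
  region_layout <- match.arg(region_layout)
  stopifnot(n_slices >= 1, n_regions >= 1, n_cell_types >= 1,
            n_cells_per_slice >= 0, panel_genes >= 1,
            reference_genes >= panel_genes, nb_dispersion > 0,
            batch_shift_sd >= 0, batch_scale_sd >= 0, spots_per_count >= 1,
            spot_jitter_sd >= 0, base_mean > 0,
            background_spot_fraction >= 0, background_spot_fraction < 1,
            baseline_barcode_rate > 0, mask_pixel_size > 0, nucleus_radius > 0,
            length(slice_extent) == 2, all(slice_extent > 0))
  R <- n_regions; Tt <- n_cell_types; G <- panel_genes
  if (is.null(composition)) {
    composition <- matrix(0.25 / max(Tt - 1, 1), R, Tt)
    if (Tt == 1) composition[] <- 1
    else for (r in seq_len(R)) composition[r, ((r - 1) %% Tt) + 1] <- 0.75
  }
  composition <- as.matrix(composition)
  if (nrow(composition) != R || ncol(composition) != Tt)
    stop("composition must be n_regions x n_cell_types")
  if (any(composition < 0) || any(abs(rowSums(composition) - 1) > 1e-8))
    stop("composition rows must be non-negative and sum to 1")
  h <- if (G == 1) mean(heterogeneity_range) else
    seq(heterogeneity_range[1], heterogeneity_range[2], length.out = G)
  if (is.null(nb_mean)) {
    z <- with_seed(seed, matrix(rnorm(Tt * G), Tt, G))
    nb_mean <- exp(log(base_mean) + sweep(z, 2, h, "*") - matrix(h^2 / 2, Tt, G, byrow = TRUE))
  }
  nb_mean <- as.matrix(nb_mean)
  if (nrow(nb_mean) != Tt || ncol(nb_mean) != G) stop("nb_mean must be n_cell_types x panel_genes")
  if (any(nb_mean <= 0) || any(!is.finite(nb_mean))) stop("nb_mean must be strictly positive and finite")
  rownames(nb_mean) <- paste0("T", seq_len(Tt))
  colnames(nb_mean) <- paste0("g", seq_len(G))
  if (is.null(tropism_multipliers)) tropism_multipliers <- matrix(1, R, Tt)
  tropism_multipliers <- as.matrix(tropism_multipliers)
  if (nrow(tropism_multipliers) != R || ncol(tropism_multipliers) != Tt ||
      any(tropism_multipliers <= 0))
    stop("tropism_multipliers must be a positive n_regions x n_cell_types matrix")
  dimnames(tropism_multipliers) <- list(paste0("R", seq_len(R)), paste0("T", seq_len(Tt)))
  structure(list(
    n_slices = n_slices, slice_extent = as.numeric(slice_extent),
    n_regions = R, region_layout = region_layout, n_cell_types = Tt,
    composition = composition, n_cells_per_slice = n_cells_per_slice,
    panel_genes = G, reference_genes = reference_genes,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    gene_heterogeneity = h,
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    spots_per_count = spots_per_count, spot_jitter_sd = spot_jitter_sd,
    background_spot_fraction = background_spot_fraction,
    tropism_multipliers = tropism_multipliers,
    baseline_barcode_rate = baseline_barcode_rate,
    mask_pixel_size = mask_pixel_size, nucleus_radius = nucleus_radius,
    seed = as.integer(seed)), class = "synth_config")
}

# fixed balanced 4-rank tree over types: rank4 = type, each higher rank
# merges pairs, so every rank-k label has exactly one rank-(k-1) parent
type_rank_tree <- function(n_types) {
  t4 <- seq_len(n_types)
  data.frame(rank4 = paste0("T", t4),
             rank3 = paste0("C3_", ceiling(t4 / 2)),
             rank2 = paste0("C2_", ceiling(t4 / 4)),
             rank1 = paste0("C1_", ceiling(t4 / 8)),
             stringsAsFactors = FALSE)
}

region_labels_for <- function(x, y, cfg, blob_seeds) {
  W <- cfg$slice_extent[1]; H <- cfg$slice_extent[2]; R <- cfg$n_regions
  if (cfg$region_layout == "layers") {
    pmin.int(R, floor(y / H * R) + 1L)
  } else if (cfg$region_layout == "blobs") {
    nn <- RANN::nn2(blob_seeds, cbind(x, y), k = 1)
    as.integer(nn$nn.idx[, 1])
  } else { # mixed: bands for the first half, blob discs override on top
    nb <- max(1L, floor(R / 2))
    lab <- pmin.int(nb, floor(y / H * nb) + 1L)
    if (R > nb) {
      rad <- H / 6
      for (j in seq.int(nb + 1L, R)) {
        c_j <- blob_seeds[j, ]
        inside <- (x - c_j[1])^2 + (y - c_j[2])^2 <= rad^2
        lab[inside] <- j
      }
    }
    lab
  }
}

#' Generate a synthetic tissue: cells, counts and ground truth
#'
#' Cells are placed uniformly inside each slice; spatially contiguous region
#' labels follow the configured layout; each cell's type is drawn from its
#' region's composition row; counts are negative binomial with type-profile
#' means modified per batch (= slice) by an additive shift and a
#' multiplicative scale on the log mean, so NB sampling stays valid.
#'
#' @param config a [synth_config()]
#' @return list with elements `cells` (a [cell_matrix()]) and `truth`
#'   (list: `true_type`, `true_region`, `rank_labels` data.frame with
#'   columns rank1..rank4, `type_profiles`, `tropism_multipliers`,
#'   `gene_heterogeneity`, `type_tree`)
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  G <- cfg$panel_genes; Tt <- cfg$n_cell_types
  tree <- type_rank_tree(Tt)
  gene_names <- colnames(cfg$nb_mean)
  if (cfg$n_cells_per_slice == 0) {
    cells <- cell_matrix(Matrix::Matrix(0, 0, G, sparse = TRUE),
                         data.frame(cell_id = character(0), x = numeric(0), y = numeric(0),
                                    z = numeric(0), sample_id = character(0),
                                    batch_id = character(0)),
                         genes = gene_names)
    truth <- list(true_type = character(0), true_region = character(0),
                  rank_labels = tree[0, c("rank1", "rank2", "rank3", "rank4")],
                  type_profiles = cfg$nb_mean,
                  tropism_multipliers = cfg$tropism_multipliers,
                  gene_heterogeneity = cfg$gene_heterogeneity, type_tree = tree)
    return(list(cells = cells, truth = truth))
  }
  with_seed(cfg$seed + 1L, {
    W <- cfg$slice_extent[1]; H <- cfg$slice_extent[2]
    blob_seeds <- cbind(runif(cfg$n_regions, 0, W), runif(cfg$n_regions, 0, H))
    meta <- vector("list", cfg$n_slices)
    counts <- vector("list", cfg$n_slices)
    for (s in seq_len(cfg$n_slices)) {
      n <- cfg$n_cells_per_slice
      x <- runif(n, 0, W); y <- runif(n, 0, H)
      region <- region_labels_for(x, y, cfg, blob_seeds)
      type <- integer(n)
      for (r in unique(region)) {
        i <- which(region == r)
        type[i] <- sample.int(cfg$n_cell_types, length(i), replace = TRUE,
                              prob = cfg$composition[r, ])
      }
      # batch effects on log(mean): per-gene additive shift + multiplicative scale
      shift <- rnorm(G, 0, cfg$batch_shift_sd)
      scale <- exp(rnorm(G, 0, cfg$batch_scale_sd))
      logmu <- log(cfg$nb_mean)[type, , drop = FALSE]
      logmu <- sweep(logmu, 2, scale, "*")
      logmu <- sweep(logmu, 2, shift, "+")
      cnt <- matrix(rnbinom(n * G, mu = exp(logmu), size = cfg$nb_dispersion), n, G)
      counts[[s]] <- cnt
      meta[[s]] <- data.frame(
        cell_id = sprintf("S%d_c%05d", s, seq_len(n)),
        x = x, y = y, z = (s - 1) * 10,
        sample_id = paste0("S", s), batch_id = paste0("B", s),
        region = region, type = type, stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, meta)
    counts <- do.call(rbind, counts)
    colnames(counts) <- gene_names
    cells <- cell_matrix(counts, meta[, c("cell_id", "x", "y", "z", "sample_id", "batch_id")],
                         genes = gene_names)
    truth <- list(
      true_type = paste0("T", meta$type),
      true_region = paste0("R", meta$region),
      rank_labels = tree[meta$type, c("rank1", "rank2", "rank3", "rank4")],
      type_profiles = cfg$nb_mean,
      tropism_multipliers = cfg$tropism_multipliers,
      gene_heterogeneity = cfg$gene_heterogeneity, type_tree = tree)
    rownames(truth$rank_labels) <- meta$cell_id
    list(cells = cells, truth = truth)
  })
}

#' Generate a matched reference expression matrix
#'
#' Reference cells are drawn from the same type profiles as the tissue,
#' extended deterministically to the full reference gene universe, with no
#' batch effects and no spatial coordinates. Labels are populated at all four
#' taxonomy ranks from the fixed type tree. Every type is represented.
#'
#' @param config the [synth_config()] used for the tissue
#' @param truth ground truth from [generate_tissue()] (supplies the type tree)
#' @param n_ref_cells number of reference cells (>= number of types)
#' @return object of class `reference_matrix`: list with `counts` (sparse
#'   cell-by-gene), `genes`, `labels` (data.frame rank1..rank4), `type`,
#'   and `profiles` (type-by-gene means over the full universe)
#' @export
generate_reference <- function(config, truth, n_ref_cells = 5000) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  Tt <- cfg$n_cell_types
  if (n_ref_cells < Tt) stop("n_ref_cells must be at least the number of types")
  G <- cfg$panel_genes; Gr <- cfg$reference_genes
  profiles <- with_seed(cfg$seed + 7777L, {
    extra <- Gr - G
    if (extra > 0) {
      h2 <- if (extra == 1) 0.9 else seq(0.25, 1.5, length.out = extra)
      z2 <- matrix(rnorm(Tt * extra), Tt, extra)
      ex <- exp(log(4) + sweep(z2, 2, h2, "*") - matrix(h2^2 / 2, Tt, extra, byrow = TRUE))
      colnames(ex) <- paste0("x", seq_len(extra))
      cbind(cfg$nb_mean, ex)
    } else cfg$nb_mean
  })
  tree <- truth$type_tree
  with_seed(cfg$seed + 2L, {
    type <- rep_len(seq_len(Tt), n_ref_cells)   # round-robin: every type covered
    cnt <- matrix(rnbinom(n_ref_cells * Gr, mu = profiles[type, , drop = FALSE],
                          size = cfg$nb_dispersion), n_ref_cells, Gr)
    colnames(cnt) <- colnames(profiles)
    rownames(cnt) <- sprintf("ref%05d", seq_len(n_ref_cells))
    structure(list(counts = as_dgc(cnt), genes = colnames(profiles),
                   labels = tree[type, c("rank1", "rank2", "rank3", "rank4")],
                   type = paste0("T", type), profiles = profiles),
              class = "reference_matrix")
  })
}

#' @export
print.reference_matrix <- function(x, ...) {
  cat(sprintf("<reference_matrix> %d cells x %d genes, %d rank-4 types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$type))))
  invisible(x)
}

#' Generate amplicon spot clouds, barcode spots and a nucleus mask
#'
#' Each transcript count emits `spots_per_count` mRNA spots jittered around
#' the cell centroid; a `background_spot_fraction` of the real spot total is
#' added uniformly over the slice with random panel identities. Per-cell
#' barcode counts are Poisson with rate
#' `baseline_barcode_rate * tropism_multipliers[region, type]`. The mask
#' marks a disc of `nucleus_radius` around every centroid.
#'
#' @param cells a [cell_matrix()] from [generate_tissue()]
#' @param truth the matching ground truth
#' @param config the [synth_config()]
#' @return list with `mrna` and `barcode` [spot_table()]s and `mask`
#'   (a [nucleus_mask()]); real mRNA spots carry their generating `cell_id`
#' @export
generate_spots <- function(cells, truth, config) {
  stopifnot(inherits(cells, "cell_matrix"), inherits(config, "synth_config"))
  if (nrow(cells$counts) == 0) stop("cells must be non-empty")
  cfg <- config
  with_seed(cfg$seed + 3L, {
    tr <- Matrix::summary(cells$counts)
    reps <- tr$x * cfg$spots_per_count
    idx <- rep.int(seq_len(nrow(tr)), reps)
    ci <- tr$i[idx]
    n_real <- length(ci)
    mx <- cells$cells$x[ci] + rnorm(n_real, 0, cfg$spot_jitter_sd)
    my <- cells$cells$y[ci] + rnorm(n_real, 0, cfg$spot_jitter_sd)
    real <- data.frame(
      spot_id = sprintf("m%07d", seq_len(n_real)),
      x = mx, y = my, z = cells$cells$z[ci],
      feature_id = cells$genes[tr$j[idx]], feature_kind = "gene",
      sample_id = cells$cells$sample_id[ci],
      cell_id = cells$cells$cell_id[ci], stringsAsFactors = FALSE)
    n_bg <- round(cfg$background_spot_fraction * n_real)
    if (n_bg > 0) {
      sl <- sample(unique(cells$cells$sample_id), n_bg, replace = TRUE)
      zmap <- tapply(cells$cells$z, cells$cells$sample_id, function(v) v[1])
      bg <- data.frame(
        spot_id = sprintf("b%07d", seq_len(n_bg)),
        x = runif(n_bg, 0, cfg$slice_extent[1]),
        y = runif(n_bg, 0, cfg$slice_extent[2]),
        z = as.numeric(zmap[sl]),
        feature_id = sample(cells$genes, n_bg, replace = TRUE),
        feature_kind = "gene", sample_id = sl, cell_id = NA_character_,
        stringsAsFactors = FALSE)
      mrna <- rbind(real, bg)
    } else mrna <- real
    # barcode spots: Poisson counts scaled by region/type tropism multiplier
    reg <- as.integer(sub("^R", "", truth$true_region))
    typ <- as.integer(sub("^T", "", truth$true_type))
    lam <- cfg$baseline_barcode_rate * cfg$tropism_multipliers[cbind(reg, typ)]
    nk <- rpois(length(lam), lam)
    bi <- rep.int(seq_along(nk), nk)
    nb <- length(bi)
    barcode <- data.frame(
      spot_id = sprintf("v%07d", seq_len(nb)),
      x = cells$cells$x[bi] + rnorm(nb, 0, cfg$spot_jitter_sd),
      y = cells$cells$y[bi] + rnorm(nb, 0, cfg$spot_jitter_sd),
      z = cells$cells$z[bi], feature_id = "BC1", feature_kind = "barcode",
      sample_id = cells$cells$sample_id[bi], cell_id = NA_character_,
      stringsAsFactors = FALSE)
    # nucleus mask: disc around every centroid, all slices overlaid
    px <- cfg$mask_pixel_size
    nx <- ceiling(cfg$slice_extent[1] / px)
    ny <- ceiling(cfg$slice_extent[2] / px)
    grid <- matrix(FALSE, ny, nx)
    rpx <- ceiling(cfg$nucleus_radius / px)
    for (i in seq_len(nrow(cells$cells))) {
      cx <- cells$cells$x[i]; cy <- cells$cells$y[i]
      j0 <- floor(cx / px) + 1L; i0 <- floor(cy / px) + 1L
      jj <- max(1L, j0 - rpx):min(nx, j0 + rpx)
      ii <- max(1L, i0 - rpx):min(ny, i0 + rpx)
      pcx <- (jj - 0.5) * px; pcy <- (ii - 0.5) * px
      d2 <- outer(pcy - cy, pcx - cx, function(a, b) a^2 + b^2)
      grid[ii, jj] <- grid[ii, jj] | (d2 <= cfg$nucleus_radius^2)
    }
    list(mrna = spot_table(mrna), barcode = spot_table(barcode),
         mask = nucleus_mask(grid, origin = c(0, 0), pixel_size = px))
  })
}
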