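# File I/O, configuration and the end-to-end pipeline driver.
#
# On-disk conventions: coordinates are micrometres; tables are cell_id-keyed
# TSV; count matrices are MatrixMarket coordinate files (1-based indices on
# disk, 0-based only ever inside compiled libraries) with genes.tsv and
# cells.tsv sidecars; masks are 0/1 TSV grids with a JSON sidecar giving the
# origin and pixel size.

#' Write a cell matrix as sparse MTX plus metadata tables
#'
#' @param m a [cell_matrix()]
#' @param path directory to create/fill with `matrix.mtx`, `genes.tsv`,
#'   `cells.tsv`
#' @return `path`, invisibly
#' @export
write_cell_matrix <- function(m, path) {
  stopifnot(inherits(m, "cell_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
  write.table(data.frame(gene = m$genes), file.path(path, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$cells, file.path(path, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell matrix written by [write_cell_matrix()]
#'
#' @param path directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`
#' @return a [cell_matrix()]
#' @export
read_cell_matrix <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  gf <- file.path(path, "genes.tsv")
  cf <- file.path(path, "cells.tsv")
  for (f in c(mtx, gf, cf)) if (!file.exists(f)) stop("missing file: ", f)
  counts <- as_dgc(Matrix::readMM(mtx))
  genes <- read.delim(gf, stringsAsFactors = FALSE)$gene
  cells <- read.delim(cf, stringsAsFactors = FALSE)
  if (nrow(counts) != nrow(cells))
    stop(sprintf("dimension mismatch: %s has %d rows but %s has %d",
                 mtx, nrow(counts), cf, nrow(cells)))
  if (ncol(counts) != length(genes))
    stop(sprintf("dimension mismatch: %s has %d columns but %s has %d",
                 mtx, ncol(counts), gf, length(genes)))
  for (col in c("cell_id", "sample_id", "batch_id"))
    if (col %in% names(cells)) cells[[col]] <- as.character(cells[[col]])
  cell_matrix(counts, cells, genes = as.character(genes))
}

#' Write / read a spot table as CSV
#'
#' @param spots a [spot_table()]
#' @param file CSV path
#' @return `file` (write) or the [spot_table()] (read)
#' @export
write_spot_table <- function(spots, file) {
  stopifnot(inherits(spots, "spot_table"))
  write.csv(as.data.frame(spots), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  if ("cell_id" %in% names(df)) df$cell_id <- as.character(df$cell_id)
  spot_table(df)
}

#' Write / read a nucleus mask as a 0/1 grid with JSON sidecar
#'
#' @param mask a [nucleus_mask()]
#' @param file grid TSV path; the sidecar is `<file>.json`
#' @return `file` (write) or the [nucleus_mask()] (read)
#' @export
write_mask <- function(mask, file) {
  stopifnot(inherits(mask, "nucleus_mask"))
  write.table(mask$grid * 1L, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(origin = mask$origin, pixel_size = mask$pixel_size),
                       paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_mask
#' @export
read_mask <- function(file) {
  grid <- as.matrix(read.delim(file, header = FALSE))
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  nucleus_mask(grid, origin = meta$origin, pixel_size = meta$pixel_size)
}

#' Pipeline configuration
#'
#' Stage parameter blocks mirroring each module's defaults. Unknown keys in
#' `...` or inside a stage block are rejected. The defaults reproduce the
#' workflow's operating parameters: QC thresholds 20/20/30/1300, background
#' spot fraction 0.10, transfer threshold 0.8, level-1 niche k = 30, label
#' fill k = 5, smoothing k = 50, and 200 imputation neighbours.
#'
#' @param ... named stage blocks (`synth`, `spots`, `qc`, `transfer`,
#'   `regions`, `impute`, `tropism`) given as lists of overrides, plus the
#'   top-level `seed`
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 0,
    synth = list(n_slices = 2, n_cells_per_slice = 400, panel_genes = 30,
                 reference_genes = 60, n_regions = 4, n_cell_types = 4,
                 n_ref_cells = 1200),
    spots = list(run = TRUE, fraction = 0.10, density_k = 10),
    qc = list(min_genes_per_cell = 20, min_cells_per_gene = 20,
              min_counts = 30, max_counts = 1300),
    transfer = list(threshold = 0.8, resolution = 1.0, d = 50, knn = 15),
    regions = list(k = 30, resolution = 1.0, d = 50, knn = 15,
                   fill_k = 5, smooth_k = 50, excluded_regions = character()),
    impute = list(run = TRUE, n_neighbors = 200, d = 50, genes = 10),
    tropism = list(run = TRUE))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg <- defaults
  if ("seed" %in% names(over)) cfg$seed <- over$seed
  for (blk in setdiff(names(over), "seed")) {
    bad2 <- setdiff(names(over[[blk]]), names(defaults[[blk]]))
    if (length(bad2))
      stop(sprintf("unknown keys in block %s: %s", blk, paste(bad2, collapse = ", ")))
    cfg[[blk]][names(over[[blk]])] <- over[[blk]]
  }
  structure(cfg, class = "pipeline_config")
}

# rolling polynomial hash (mod 2^31-1) of the JSON-serialized parameters;
# changes whenever any parameter changes
param_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full synthetic-atlas pipeline
#'
#' Executes simulate -> spot QC -> cell QC/normalization/batch correction ->
#' reference integration and consensus label transfer -> tissue-region
#' segmentation with label fill and smoothing -> (optionally) imputation ->
#' Delaunay adjacency -> barcode tropism summaries, writing each stage's
#' artifacts and a JSON manifest (seed, parameters, parameter hash, per-stage
#' cell counts) under `out_dir`. Reruns with the same configuration are
#' byte-identical. A stage failure stops with the failing stage named.
#'
#' @param config a [pipeline_config()]
#' @param out_dir artifact directory (created if needed)
#' @return (invisibly) a list of in-memory stage results
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE))
  }
  counts_log <- list()

  sim <- run_stage("simulate", {
    sc <- do.call(synth_config, c(config$synth[setdiff(names(config$synth), "n_ref_cells")],
                                  list(seed = config$seed)))
    tg <- generate_tissue(sc)
    ref <- generate_reference(sc, tg$truth, n_ref_cells = config$synth$n_ref_cells)
    sp <- generate_spots(tg$cells, tg$truth, sc)
    stage_log("simulate", "%d cells, %d mRNA spots, %d barcode spots",
              nrow(tg$cells$counts), nrow(sp$mrna), nrow(sp$barcode))
    list(cfg = sc, cells = tg$cells, truth = tg$truth, ref = ref, spots = sp)
  })
  counts_log$simulate <- nrow(sim$cells$counts)

  spots_qc <- run_stage("spots-qc", {
    if (config$spots$run) {
      out <- filter_background_spots(sim$spots$mrna, fraction = config$spots$fraction,
                                     density_k = config$spots$density_k)
      stage_log("spots-qc", "%d -> %d mRNA spots", nrow(sim$spots$mrna), nrow(out))
      out
    } else sim$spots$mrna
  })
  counts_log$spots_qc <- nrow(spots_qc)

  pre <- run_stage("preprocess", {
    filt <- filter_cells_genes(sim$cells, config$qc$min_genes_per_cell,
                               config$qc$min_cells_per_gene,
                               config$qc$min_counts, config$qc$max_counts)
    p <- normalize_log_scale(filt)
    if (length(unique(filt$cells$batch_id)) > 1) p <- correct_batch(p)
    stage_log("preprocess", "%d -> %d cells, %d -> %d genes",
              nrow(sim$cells$counts), nrow(filt$counts),
              ncol(sim$cells$counts), ncol(filt$counts))
    list(filtered = filt, processed = p)
  })
  counts_log$preprocess <- nrow(pre$filtered$counts)

  transfer <- run_stage("transfer", {
    ref_sub <- lognorm_counts(sim$ref$counts[, intersect(pre$processed$genes, sim$ref$genes),
                                             drop = FALSE])
    ref_p <- standardize_columns(ref_sub)
    emb <- joint_embed(pre$processed, ref_p, d = config$transfer$d, seed = config$seed)
    cl <- cluster_communities(emb, knn = config$transfer$knn,
                              resolution = config$transfer$resolution, seed = config$seed)
    lab <- hierarchical_transfer(cl, sim$ref$labels, emb$origin,
                                 threshold = config$transfer$threshold)
    stage_log("transfer", "%d joint clusters; %.1f%% rank-4 labelled",
              length(unique(cl)), 100 * mean(!is.na(lab$rank4)))
    lab
  })

  regions <- run_stage("regions", {
    nm <- build_niche_matrix(pre$processed, k = config$regions$k)
    l1 <- cluster_regions(nm, d = config$regions$d,
                          resolution = config$regions$resolution,
                          knn = config$regions$knn, seed = config$seed)
    l1 <- l1[pre$processed$cells$cell_id]
    l1 <- fill_missing_labels(l1, as.matrix(pre$processed$cells[, c("x", "y")]),
                              pre$processed$cells$sample_id, k = config$regions$fill_k)
    l1 <- smooth_labels(l1, as.matrix(pre$processed$cells[, c("x", "y")]),
                        pre$processed$cells$sample_id, k = config$regions$smooth_k,
                        excluded_regions = config$regions$excluded_regions)
    stage_log("regions", "%d level-1 regions", length(unique(l1[!is.na(l1)])))
    l1
  })

  imput <- if (config$impute$run) run_stage("impute", {
    panel <- intersect(pre$filtered$genes, sim$ref$genes)
    use <- panel[seq_len(min(config$impute$genes, length(panel)))]
    nnb <- min(config$impute$n_neighbors, nrow(sim$ref$counts))
    maps <- lapply(use, function(g)
      intermediate_mapping(pre$filtered, sim$ref, g, n_neighbors = nnb,
                           d = config$impute$d, seed = config$seed)$neighbors)
    gl <- filter_imputation_genes(sim$ref)
    im <- final_impute(pre$filtered, sim$ref, maps, genes = gl)
    stage_log("impute", "%d genes imputed over %d cells from %d mappings",
              ncol(im), nrow(im), length(maps))
    im
  }) else NULL

  adjacency <- run_stage("adjacency", {
    keep <- !is.na(transfer$rank4)
    cellsk <- pre$processed$cells[keep, , drop = FALSE]
    ed <- delaunay_graph(as.matrix(cellsk[, c("x", "y")]), cellsk$sample_id)
    am <- normalize_sequential(interaction_matrix(ed, transfer$rank4[keep]))
    stage_log("adjacency", "%d edges, %d types", nrow(ed), nrow(am$raw))
    am
  })

  trop <- if (config$tropism$run) run_stage("tropism", {
    bc <- assign_barcode_spots(sim$spots$barcode, spots_qc, sim$spots$mask)
    idx <- match(pre$processed$cells$cell_id, names(bc))
    counts <- ifelse(is.na(idx), 0L, bc[idx])
    by_type <- summarize_by_group(counts, transfer$rank4)
    by_region <- summarize_by_group(counts, regions)
    stage_log("tropism", "%d typed groups, %d region groups",
              nrow(by_type), nrow(by_region))
    list(counts = stats::setNames(counts, pre$processed$cells$cell_id),
         by_type = rank_groups(by_type), by_region = rank_groups(by_region))
  }) else NULL

  run_stage("write", {
    write_cell_matrix(pre$filtered, file.path(out_dir, "cells"))
    labels <- data.frame(cell_id = pre$processed$cells$cell_id,
                         transfer[, paste0("rank", 1:4)],
                         level1 = unname(regions), stringsAsFactors = FALSE)
    write.table(labels, file.path(out_dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(adjacency$normalized),
                file.path(out_dir, "adjacency.tsv"), sep = "\t", quote = FALSE)
    if (!is.null(trop)) {
      write.table(trop$by_type, file.path(out_dir, "tropism_by_type.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(trop$by_region, file.path(out_dir, "tropism_by_region.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- list(package = "spatlas",
                     version = as.character(utils::packageVersion("spatlas")),
                     seed = config$seed,
                     parameters = unclass(config),
                     parameter_hash = param_hash(unclass(config)),
                     stage_counts = counts_log)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(list(sim = sim, processed = pre$processed, transfer = transfer,
                 regions = regions, imputed = imput, adjacency = adjacency,
                 tropism = trop, out_dir = out_dir))
}
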