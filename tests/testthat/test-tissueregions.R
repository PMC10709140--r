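# Niche construction, region clustering, markers and label post-processing.

grid_tissue <- function(nx, ny, G = 20, spacing = 10, mu_fun, seed = 1,
                        sample_id = "S1") {
  # deterministic grid of cells; mu_fun(x, y) returns a length-G mean vector
  set.seed(seed)
  pos <- expand.grid(x = seq_len(nx), y = seq_len(ny)) * spacing
  n <- nrow(pos)
  mus <- t(vapply(seq_len(n), function(i) mu_fun(pos$x[i], pos$y[i]), numeric(G)))
  cnt <- matrix(rpois(n * G, as.vector(mus)), n, G)
  make_cells(cnt, x = pos$x, y = pos$y, sample_id = sample_id)
}

test_that("a k = 1 niche matrix equals the expression matrix itself", {
  set.seed(30)
  m <- make_cells(matrix(rpois(50 * 8, 5) + 1, 50, 8), x = runif(50), y = runif(50))
  p <- normalize_log_scale(m)
  nm <- build_niche_matrix(p, k = 1)
  expect_equal(unname(nm$values), unname(p$lognorm))
  expect_length(nm$rejected_cells, 0)
})

test_that("niche neighbours follow ascending distance with self first", {
  # collinear cells at x = 0, 1, 3: the middle cell's niche is [self | x=0]
  x <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2)   # distinct expression rows
  colnames(x) <- c("g1", "g2")
  rownames(x) <- c("a", "b", "c")
  nm <- build_niche_matrix(x, coords = cbind(c(0, 1, 3), 0),
                           sample_id = rep("S1", 3), k = 2)
  expect_equal(unname(nm$values[2, ]), c(x["b", ], x["a", ]), ignore_attr = TRUE)
  expect_equal(unname(nm$values[1, ]), c(x["a", ], x["b", ]), ignore_attr = TRUE)
  expect_equal(unname(nm$values[3, ]), c(x["c", ], x["b", ]), ignore_attr = TRUE)
})

test_that("niche blocks never cross sample boundaries (exhaustive check)", {
  set.seed(31)
  n <- 60
  x <- matrix(rnorm(n * 5), n, 5)
  colnames(x) <- paste0("g", 1:5)
  rownames(x) <- sprintf("c%02d", 1:n)
  sid <- rep(c("S1", "S2"), each = n / 2)
  coords <- cbind(runif(n), runif(n))  # interleaved in space
  nm <- build_niche_matrix(x, coords = coords, sample_id = sid, k = 5)
  for (i in seq_len(nrow(nm$values))) {
    own <- which(rownames(x) == rownames(nm$values)[i])
    for (b in 1:5) {
      blk <- nm$values[i, ((b - 1) * 5 + 1):(b * 5)]
      src <- which(apply(x, 1, function(r) all(r == blk)))
      expect_true(all(sid[src] == sid[own]))
    }
  }
  # strata smaller than k are rejected
  nm2 <- build_niche_matrix(x, coords = coords, sample_id = c(rep("S1", 57), rep("S3", 3)),
                            k = 5)
  expect_setequal(nm2$rejected_cells, sprintf("c%02d", 58:60))
})

test_that("region clustering recovers layered bands and is deterministic", {
  cfg <- synth_config(n_slices = 1, n_cells_per_slice = 1200, n_regions = 3,
                      panel_genes = 30, reference_genes = 30, n_cell_types = 6,
                      seed = 32)
  tg <- generate_tissue(cfg)
  p <- normalize_log_scale(filter_cells_genes(tg$cells))
  nm <- build_niche_matrix(p, k = 20)
  l1 <- cluster_regions(nm, seed = 0)[p$cells$cell_id]
  truth <- tg$truth$true_region[match(p$cells$cell_id, tg$cells$cells$cell_id)]
  expect_ari_at_least(l1, truth, 0.8)
  l1b <- cluster_regions(nm, seed = 0)[p$cells$cell_id]
  expect_identical(l1, l1b)
})

test_that("a spatially uniform tissue collapses to one dominant region at low resolution", {
  m <- grid_tissue(25, 25, mu_fun = function(x, y) rep(4, 20), seed = 33)
  p <- normalize_log_scale(m)
  nm <- build_niche_matrix(p, k = 20)
  lab <- cluster_regions(nm, resolution = 0.01, seed = 0)
  expect_gt(max(table(lab)) / length(lab), 0.9)
})

test_that("region subclustering recovers subregions within a parent", {
  mu_fun <- function(x, y) {
    band <- pmin(4, floor(y / 10 / 8) + 1)    # 4 bands of 8 rows
    mu <- rep(2, 20); mu[((band - 1) * 5 + 1):(band * 5)] <- 8
    mu
  }
  m <- grid_tissue(30, 32, mu_fun = mu_fun, seed = 34)
  band <- pmin(4, floor(m$cells$y / 10 / 8) + 1)
  p <- normalize_log_scale(m)
  parent <- ifelse(band <= 2, "P", NA)        # parent = true bands 1+2 merged
  l2 <- subcluster_regions(p, parent, k = 15, seed = 0)
  i <- which(!is.na(parent))
  expect_true(all(startsWith(l2[i][!is.na(l2[i])], "P.")))
  expect_ari_at_least(l2[i], band[i], 0.8)
  # k larger than the parent yields all-NA with a warning
  expect_warning(l2b <- subcluster_regions(p, ifelse(band == 1, "Q", NA), k = 5000),
                 "all NA")
  expect_true(all(is.na(l2b)))
})

test_that("a small niche preserves a thin stripe that a large niche merges away", {
  mu_fun <- function(x, y) {
    stripe <- y / 10 >= 15 & y / 10 <= 17     # 3 rows out of 32
    mu <- rep(3, 20); if (stripe) mu[1:8] <- 12
    mu
  }
  m <- grid_tissue(30, 32, mu_fun = mu_fun, seed = 35)
  stripe <- m$cells$y / 10 >= 15 & m$cells$y / 10 <= 17
  p <- normalize_log_scale(m)
  ari_for_k <- function(k) {
    lab <- cluster_regions(build_niche_matrix(p, k = k), seed = 0)[p$cells$cell_id]
    mclust::adjustedRandIndex(lab, stripe)
  }
  expect_gt(ari_for_k(6), ari_for_k(30))
})

test_that("region marker z-scores match the closed form and flag degenerate genes", {
  # 4 equal regions; gene 1 expressed only in region 1; gene 2 uniform; gene 3 zero
  n <- 80
  reg <- rep(paste0("R", 1:4), each = 20)
  x <- cbind(g1 = c(rep(4, 20), rep(0, 60)), g2 = rep(2, n), g3 = rep(0, n))
  mt <- region_marker_zscores(x, reg)
  # shares (1,0,0,0): z = (1.5, -0.5, -0.5, -0.5) under sample-sd convention
  expect_equal(unname(mt$zscores["g1", ]), c(1.5, -0.5, -0.5, -0.5))
  expect_equal(unname(mt$zscores["g2", ]), rep(0, 4))
  expect_equal(unname(mt$zscores["g3", ]), rep(0, 4))
  expect_equal(mt$flagged_genes, "g3")
  # strict threshold: z exactly 5 is not called
  fake <- mt
  fake$zscores["g1", 1] <- 5
  expect_false("g1" %in% region_markers(fake, 5)$gene)
  fake$zscores["g1", 1] <- 5.0001
  expect_true("g1" %in% region_markers(fake, 5)$gene)
})

test_that("label filling matches a brute-force kNN vote on random holes", {
  set.seed(36)
  n <- 200
  coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  lab <- ifelse(coords[, 1] < 50, "A", "B")
  full <- lab
  holes <- sample(n, 20)
  lab[holes] <- NA
  expect_identical(fill_missing_labels(full, coords), full)   # no NA: identity
  got <- fill_missing_labels(lab, coords, k = 5)
  expect_true(all(!is.na(got)))
  # oracle: dense distances, majority of 5 nearest labelled, tie -> nearest
  labelled <- which(!is.na(lab))
  for (h in holes) {
    dd <- sqrt(colSums((t(coords[labelled, ]) - coords[h, ])^2))
    nb <- labelled[order(dd)][1:5]
    tb <- table(lab[nb])
    top <- names(tb)[tb == max(tb)]
    want <- if (length(top) == 1) top else lab[nb][which(lab[nb] %in% top)[1]]
    expect_equal(got[h], want)
  }
})

test_that("a single NA cell surrounded by one label takes that label", {
  coords <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1))
  lab <- c(NA, rep("A", 5))
  expect_equal(fill_missing_labels(lab, coords, k = 5)[1], "A")
})

test_that("smoothing relabels isolated errors, honours frozen and excluded regions", {
  set.seed(37)
  n <- 100
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  lab <- rep("A", n)
  lab[1] <- "B"                                  # isolated mislabeled cell
  sm <- smooth_labels(lab, coords, k = 20)
  expect_equal(sm[1], "A")
  expect_true(all(sm[-1] == "A"))
  # frozen thin stripe survives intact
  stripe <- coords[, 2] > 4.9 & coords[, 2] < 5.5
  lab2 <- ifelse(stripe, "S", "A")
  sm2 <- smooth_labels(lab2, coords, k = 30, frozen_regions = "S")
  expect_identical(sm2[stripe], lab2[stripe])
  # excluded cells neither vote nor change: exhaustive oracle
  lab3 <- ifelse(coords[, 1] < 5, "A", "B")
  lab3[c(3, 7)] <- "X"
  sm3 <- smooth_labels(lab3, coords, k = 10, excluded_regions = "X")
  expect_identical(sm3[c(3, 7)], c("X", "X"))
  voters <- which(lab3 != "X")
  for (i in setdiff(seq_len(n), c(3, 7))) {
    others <- setdiff(voters, i)
    dd <- sqrt(colSums((t(coords[others, ]) - coords[i, ])^2))
    nb <- others[order(dd)][1:10]
    tb <- table(lab3[nb])
    top <- names(tb)[tb == max(tb)]
    want <- if (length(top) == 1) top else lab3[nb][which(lab3[nb] %in% top)[1]]
    expect_equal(sm3[i], want)
  }
})

test_that("smoothing contracts to a fixed point on a uniform field", {
  set.seed(38)
  n <- 150
  coords <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  uniform <- rep("A", n)
  expect_identical(smooth_labels(uniform, coords, k = 15), uniform)
  # scattered errors vanish in one pass; a second pass then changes nothing
  lab <- uniform
  lab[sample(n, 3)] <- "B"
  once <- smooth_labels(lab, coords, k = 15)
  expect_identical(once, uniform)
  expect_identical(smooth_labels(once, coords, k = 15), once)
})

test_that("composition z-scores match brute-force percentages", {
  set.seed(39)
  ct <- sample(c("T1", "T2", "T3"), 300, replace = TRUE)
  rg <- sample(c("R1", "R2", "R3", "R4"), 300, replace = TRUE)
  cz <- composition_zscores(ct, rg)
  expect_equal(unname(colSums(cz$percent)), rep(100, 4))
  for (t in unique(ct)) {
    pct <- vapply(sort(unique(rg)), function(r) 100 * sum(ct == t & rg == r) / sum(rg == r),
                  numeric(1))
    expect_equal(unname(cz$percent[t, ]), unname(pct))
    expect_equal(unname(cz$zscores[t, ]), unname((pct - mean(pct)) / sd(pct)))
  }
  # one type only: percentages 100, z all 0
  cz1 <- composition_zscores(rep("T1", 50), rg[1:50])
  expect_true(all(cz1$percent == 100))
  expect_true(all(cz1$zscores == 0))
  # a type present in exactly one region peaks there
  ct2 <- c(rep("T1", 100), rep("T9", 10))
  rg2 <- c(sample(paste0("R", 1:4), 100, replace = TRUE), rep("R2", 10))
  cz2 <- composition_zscores(ct2, rg2)
  expect_equal(names(which.max(cz2$zscores["T9", ])), "R2")
})
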