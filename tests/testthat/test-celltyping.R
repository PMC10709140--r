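# Joint embedding, community clustering and the consensus transfer rule.

rand_processed <- function(n, g, seed, shift = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * g), n, g) + shift
  colnames(x) <- paste0("g", seq_len(g))
  x
}

test_that("identical query and reference centre onto each other exactly", {
  x <- rand_processed(100, 20, seed = 20)
  emb <- joint_embed(x, x, d = 10, align = "center")
  cq <- colMeans(emb$coords[emb$origin == "query", ])
  cr <- colMeans(emb$coords[emb$origin == "reference", ])
  expect_lt(sqrt(sum((cq - cr)^2)), 1e-8)
})

test_that("an embedding dimension beyond the data rank is truncated with a message", {
  x <- rand_processed(12, 6, seed = 21)
  expect_message(emb <- joint_embed(x, x, d = 50), "truncated")
  expect_lte(emb$d, 23)
  expect_error(joint_embed(x[, 1, drop = FALSE], x[, 1, drop = FALSE]), "shared genes")
})

test_that("centering restores neighbour mixing destroyed by an additive batch offset", {
  q <- rand_processed(300, 20, seed = 22)
  r <- rand_processed(300, 20, seed = 23)
  mixing <- function(emb, k = 10) {
    nn <- RANN::nn2(emb$coords, emb$coords, k = k + 1)
    other <- matrix(emb$origin[nn$nn.idx[, -1]], ncol = k)
    mean(other != emb$origin)
  }
  baseline <- mixing(joint_embed(q, r, d = 10, align = "none"))
  offset <- mixing(joint_embed(q, r + 5, d = 10, align = "none"))
  centered <- mixing(joint_embed(q, r + 5, d = 10, align = "center"))
  expect_lt(offset, 0.05)                       # the offset separates origins
  expect_lt(abs(centered - baseline), 0.05)     # centering restores mixing
  iter <- mixing(joint_embed(q, r + 5, d = 10, align = "iterative", seed = 1))
  expect_gt(iter, offset)
})

test_that("two well-separated blobs in latent space form exactly two communities", {
  set.seed(24)
  d <- 10
  x <- rbind(matrix(rnorm(250 * d), ncol = d),
             sweep(matrix(rnorm(250 * d), ncol = d), 2, rep(10 / sqrt(d), d), "+"))
  cl <- cluster_communities(x, knn = 15, resolution = 1.0, seed = 0)
  expect_equal(length(unique(cl)), 2)
  truth <- rep(1:2, each = 250)
  expect_ari_at_least(as.integer(cl), truth, 0.99)
  # determinism under a fixed seed
  cl2 <- cluster_communities(x, knn = 15, resolution = 1.0, seed = 0)
  expect_identical(as.integer(cl), as.integer(cl2))
})

test_that("degenerate embeddings collapse to one cluster", {
  expect_equal(length(unique(cluster_communities(matrix(0, 1, 3)))), 1)
  expect_warning(cl <- cluster_communities(matrix(1, 40, 3)), "zero-variance")
  expect_equal(length(unique(cl)), 1)
})

test_that("the consensus rule assigns the modal label only above the strict threshold", {
  # one joint cluster: 85% A / 15% B among reference cells
  joint <- rep(1L, 120)
  origin <- c(rep("query", 20), rep("reference", 100))
  ref <- c(rep("A", 85), rep("B", 15))
  expect_true(all(transfer_labels(joint, ref, origin, 0.8) == "A"))
  # exactly 80%: strict inequality fails the transfer
  ref80 <- c(rep("A", 80), rep("B", 20))
  expect_true(all(is.na(transfer_labels(joint, ref80, origin, 0.8))))
  # no reference cells in the cluster
  joint2 <- c(rep(1L, 20), rep(2L, 100))
  expect_true(all(is.na(transfer_labels(joint2, ref, origin, 0.8))))
})

test_that("random cluster compositions match brute-force evaluation of the rule", {
  set.seed(25)
  n_cl <- 50
  joint <- integer(0); origin <- character(0); ref <- character(0)
  for (cl in seq_len(n_cl)) {
    nq <- sample(1:5, 1); nr <- sample(0:30, 1)
    joint <- c(joint, rep(cl, nq + nr))
    origin <- c(origin, rep("query", nq), rep("reference", nr))
    ref <- c(ref, sample(LETTERS[1:4], nr, replace = TRUE))
  }
  got <- transfer_labels(joint, ref, origin, 0.6)
  # oracle
  ref_full <- rep(NA_character_, length(joint))
  ref_full[origin == "reference"] <- ref
  expected <- rep(NA_character_, sum(origin == "query"))
  qmap <- which(origin == "query")
  for (cl in seq_len(n_cl)) {
    rl <- ref_full[joint == cl & origin == "reference"]
    ans <- NA_character_
    if (length(rl) > 0) {
      tb <- table(rl)
      fr <- max(tb) / length(rl)
      if (fr > 0.6 || fr == 1) ans <- names(tb)[which.max(tb)]
    }
    expected[joint[qmap] == cl] <- ans
  }
  expect_identical(got, expected)
  # never a label absent from the reference
  expect_true(all(got[!is.na(got)] %in% ref))
  # monotonicity: raising the threshold never labels an NA cluster
  prev <- got
  for (th in c(0.7, 0.8, 0.9, 1.0)) {
    cur <- transfer_labels(joint, ref, origin, th)
    expect_true(all(is.na(cur) | cur == prev))
    expect_true(all(!is.na(cur[!is.na(cur)])))
    expect_true(all(which(!is.na(cur)) %in% which(!is.na(prev))))
    prev <- cur
  }
})

test_that("hierarchical transfer respects the taxonomy and boundary thresholds", {
  tree <- spatlas:::type_rank_tree(8)
  set.seed(26)
  joint <- rep(1:8, each = 30)
  origin <- rep(c("query", "reference"), times = 120)
  ref_t <- joint[origin == "reference"]
  ref_labels <- tree[ref_t, c("rank1", "rank2", "rank3", "rank4")]
  out <- hierarchical_transfer(joint, ref_labels, origin, 0.8)
  # pure clusters: all four ranks assigned everywhere
  expect_true(all(!is.na(out)))
  # parent consistency whenever both ranks are assigned
  for (k in 2:4) {
    child <- out[[paste0("rank", k)]]; parent <- out[[paste0("rank", k - 1)]]
    both <- !is.na(child) & !is.na(parent)
    expmap <- unique(tree[, c(paste0("rank", k), paste0("rank", k - 1))])
    expect_true(all(parent[both] ==
      expmap[[2]][match(child[both], expmap[[1]])]))
  }
  # threshold 1.0: only perfectly pure clusters transfer
  mixed_ref <- ref_labels
  mixed_ref$rank4[1] <- tree$rank4[((ref_t[1]) %% 8) + 1]
  out2 <- hierarchical_transfer(joint, mixed_ref, origin, 1.0)
  impure <- joint[origin == "query"] == joint[1]
  expect_true(all(is.na(out2$rank4[impure])))
  expect_true(all(!is.na(out2$rank4[!impure])))
})

test_that("the subcluster gene filter honours both boundary rules", {
  set.seed(27)
  n <- 40
  base <- matrix(rpois(n * 3, 20), n, 3)
  g_max9 <- rep(9, n)                                  # max 9 < 10: out
  g_edge <- c(rep(5, 10), 12, rep(0, n - 11))          # count>=5 in 11 cells, max 12: in
  g_few <- c(rep(5, 9), 12, rep(0, n - 10))            # count>=5 in 10 cells, max 12: in
  g_too_few <- c(rep(5, 8), 12, rep(0, n - 9))         # count>=5 in 9 cells: out
  cnt <- cbind(base, g_max9, g_edge, g_few, g_too_few)
  colnames(cnt) <- paste0("g", 1:7)
  m <- make_cells(cnt)
  keep <- spatlas:::subcluster_gene_filter(m)
  expect_false("g4" %in% keep)
  expect_true(all(c("g5", "g6") %in% keep))
  expect_false("g7" %in% keep)
  expect_error(subcluster(subset_cells(m, cells = 1:10)), "20 cells")
})

test_that("subclustering recovers three latent subtypes (ARI >= 0.8)", {
  set.seed(28)
  n <- 600; G <- 40
  sub_t <- sample(1:3, n, replace = TRUE)
  mu <- matrix(3, 3, G)
  for (t in 1:3) mu[t, ((t - 1) * 10 + 1):(t * 10)] <- 6   # 2x on 10 genes each
  cnt <- matrix(rnbinom(n * G, mu = mu[sub_t, ], size = 20), n, G)
  m <- make_cells(cnt)
  cl <- subcluster(m, seed = 0)
  expect_ari_at_least(as.integer(cl), sub_t, 0.8)
})

test_that("marker ranking finds exclusive genes and is null under permutation", {
  set.seed(29)
  n <- 120
  lab <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * 10), n, 10)
  x[lab == "A", 4] <- x[lab == "A", 4] + 4    # strong exclusive marker for A
  colnames(x) <- paste0("g", 1:10)
  cells <- data.frame(cell_id = sprintf("c%03d", 1:n), x = 0, y = 0, z = 0,
                      sample_id = "S1", batch_id = "B1")
  p <- processed_matrix(x, cells, genes = colnames(x))
  mk <- rank_markers(p, lab, n_top = 3)
  expect_equal(mk$gene[mk$cluster == "A" & mk$rank == 1], "g4")
  true_top <- max(mk$score[mk$cluster == "A"])
  # permutation null: the true top score is rarely attained
  beat <- 0
  for (i in 1:50) {
    pm <- rank_markers(p, sample(lab), n_top = 1)
    if (max(pm$score) >= true_top) beat <- beat + 1
  }
  expect_lte(beat / 50, 0.05)
  # two identical clusters: no large scores
  y <- matrix(rnorm(n * 6), n, 6); colnames(y) <- paste0("h", 1:6)
  p2 <- processed_matrix(y, cells, genes = colnames(y))
  mk2 <- rank_markers(p2, lab, n_top = 6)
  expect_lt(max(abs(mk2$score)), 3.5)
})
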