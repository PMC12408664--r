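test_that("mmd vanishes on identical point sets and matches closed forms", {
  set.seed(14)
  Z <- matrix(rnorm(30), 10, 3)
  expect_lt(abs(mmd(Z, Z, "rbf_multiscale")), 1e-10)
  expect_lt(abs(mmd(Z, Z, "linear")), 1e-10)
  # linear kernel equals squared distance of the means
  A <- matrix(rnorm(24), 8, 3); B <- matrix(rnorm(36), 12, 3)
  expect_equal(mmd(A, B, "linear"),
               sum((colMeans(A) - colMeans(B))^2), tolerance = 1e-10)
  expect_error(mmd(A, B[, 1:2]), "width")
  expect_error(mmd(A[1, , drop = FALSE], B), "at least 2")
})

test_that("rbf mmd equals the O(n^2) double-sum oracle", {
  set.seed(15)
  X <- matrix(rnorm(30), 10, 3); Y <- matrix(rnorm(36), 12, 3)
  bw <- c(0.7, 1.3)
  oracle <- 0
  for (s in bw) {
    kxx <- kyy <- kxy <- 0
    for (i in 1:10) for (j in 1:10)
      kxx <- kxx + exp(-sum((X[i, ] - X[j, ])^2) / (2 * s^2))
    for (i in 1:12) for (j in 1:12)
      kyy <- kyy + exp(-sum((Y[i, ] - Y[j, ])^2) / (2 * s^2))
    for (i in 1:10) for (j in 1:12)
      kxy <- kxy + exp(-sum((X[i, ] - Y[j, ])^2) / (2 * s^2))
    oracle <- oracle + kxx / 100 + kyy / 144 - 2 * kxy / 120
  }
  expect_equal(mmd(X, Y, "rbf_multiscale", bandwidths = bw), oracle / 2,
               tolerance = 1e-10)
})

test_that("cluster_cells separates well-separated blobs and is seeded", {
  set.seed(16)
  Z <- rbind(matrix(rnorm(20 * 2), 20, 2),
             matrix(rnorm(20 * 2, mean = 10), 20, 2))
  cl <- cluster_cells(Z, resolution = 1, n_neighbors = 10, seed = 2)
  expect_length(cl, 40)
  # blob identity is recovered exactly (adjusted Rand = 1 <=> perfect
  # agreement up to label switching)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:20])), 1)
  expect_equal(length(unique(cl[21:40])), 1)
  expect_true(cl[1] != cl[21])
  expect_identical(cluster_cells(Z, n_neighbors = 10, seed = 2), cl)
  expect_error(cluster_cells(Z[1:5, ], n_neighbors = 10), "at least")
})

test_that("identical cells fall into one cluster", {
  Z <- matrix(1, 20, 3) + 0   # identical rows
  cl <- cluster_cells(Z, n_neighbors = 5, seed = 1)
  expect_equal(length(unique(cl)), 1)
})

test_that("cluster_regularizer measures cosine coherence", {
  # identical members: coherence perfect, penalty 0
  Z <- matrix(rep(c(1, 2), each = 5), 5, 2)
  expect_equal(cluster_regularizer(Z, rep(1, 5)), 0, tolerance = 1e-12)
  # two orthogonal cells: centroid at 45 degrees, penalty 1 - cos(45)
  Z2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(cluster_regularizer(Z2, c(1, 1)), 1 - cos(pi / 4),
               tolerance = 1e-12)
  # scale invariance
  set.seed(17)
  Z3 <- matrix(rnorm(40), 10, 4)
  cl <- rep(1:2, 5)
  expect_equal(cluster_regularizer(Z3, cl),
               cluster_regularizer(Z3 * 7, cl), tolerance = 1e-12)
  expect_true(cluster_regularizer(Z3, cl) >= 0 &&
                cluster_regularizer(Z3, cl) <= 2)
  # zero-norm embedding warns and scores similarity 0
  Z4 <- rbind(c(0, 0), c(1, 1))
  expect_warning(v <- cluster_regularizer(Z4, c(1, 1)), "zero-norm")
  expect_gte(v, 0)
})

test_that("dann_loss is the stated affine combination", {
  cfg <- dann_config(omega = 0.5, theta = 0.1)
  expect_equal(dann_loss(1, 2, 3, cfg), 2.3)
  cfg0 <- dann_config(omega = 0, theta = 0)
  expect_equal(dann_loss(1.7, 99, 99, cfg0), 1.7)
  # linearity in each component
  expect_equal(dann_loss(1, 4, 3, cfg) - dann_loss(1, 2, 3, cfg), 1)
})

test_that("binarize_scores thresholds with ties going to sensitive", {
  expect_equal(binarize_scores(c(0.3, 0.7, 0.5)), c(0L, 1L, 1L))
  expect_equal(binarize_scores(c(0.49999, 0.50001)), c(0L, 1L))
  expect_error(binarize_scores(c(-0.1, 0.5)), "0, 1")
})

test_that("fit_transfer wires the stages together coherently", {
  run <- tiny_transfer_run()
  res <- run$res
  n_cells <- length(run$sim$sc$y$labels)
  expect_length(res$scores$scores, n_cells)
  expect_true(all(res$scores$scores >= 0 & res$scores$scores <= 1))
  expect_identical(res$scores$labels,
                   binarize_scores(res$scores$scores))
  # loss trace decomposes exactly at every logged epoch
  tr <- res$loss_trace
  cfg <- res$model$configs$dann
  expect_true(all(abs(tr$total - (tr$class + cfg$omega * tr$mmd +
                                    cfg$theta * tr$regularizer)) < 1e-9))
  # bulk pre-training reduced the cross-entropy
  hist <- res$model$predictor$training_history
  expect_lt(tail(hist, 1), hist[1])
  # predict_transfer reproduces the stored scores on the same data
  y2 <- predict_transfer(res$model, run$sc_ln)
  expect_equal(y2$scores, res$scores$scores, tolerance = 1e-12)
})

test_that("fit_transfer errors on disjoint gene sets", {
  sim <- simulate_paired(sim_config(n_genes = 40, n_bulk = 60,
                                    n_cells = 60, seed = 3))
  sc_ln <- normalize_log(sim$sc$X)
  bulk <- sim$bulk$X
  bulk$gene_ids <- paste0("other_", bulk$gene_ids)
  colnames(bulk$values) <- bulk$gene_ids
  dae <- dae_config(40, encoder_dims = 8, bottleneck = 4, epochs = 2)
  expect_error(
    fit_transfer(bulk, sim$bulk$y, sc_ln, dae, dae,
                 attention_config(4, n_heads = 1, n_tokens = 2), dann_config()),
    "gene intersection")
})
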