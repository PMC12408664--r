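test_that("expression_matrix validates ids, shape and layer", {
  m <- matrix(1:6, 2, 3)
  X <- expression_matrix(m, c("a", "b"), c("g1", "g2", "g3"),
                         domain = "bulk", layer = "counts")
  expect_equal(dim(X), c(2L, 3L))
  expect_error(expression_matrix(m, c("a", "a"), c("g1", "g2", "g3")),
               "duplicate sample_ids")
  expect_error(expression_matrix(m, c("a", "b"), c("g1", "g1", "g3")),
               "duplicate gene_ids")
  expect_error(expression_matrix(-m, c("a", "b"), c("g1", "g2", "g3")),
               "non-negative")
  expect_error(expression_matrix(m + 0.5, c("a", "b"), c("g1", "g2", "g3"),
                                 layer = "counts"),
               "integer-valued")
})

test_that("response_labels enforce binary labels and score consistency", {
  expect_error(response_labels(c("a", "b"), c(0, 2)), "0/1")
  y <- response_labels(c("a", "b", "c"), c(1, 0, 1),
                       provenance = "predicted",
                       scores = c(0.9, 0.2, 0.5))
  expect_equal(y$labels, c(1L, 0L, 1L))
  expect_error(response_labels(c("a", "b"), c(1, 0),
                               provenance = "predicted",
                               scores = c(0.2, 0.9)),
               "inconsistent")
})

test_that("csv and mtx round-trips preserve values and identifiers", {
  X <- make_counts(3, 4, seed = 7)
  for (fmt in c("csv", "tsv", "mtx")) {
    path <- file.path(withr::local_tempdir(), paste0("m.", fmt))
    write_expression(X, path, fmt)
    X2 <- read_expression(path, fmt, domain = "single_cell",
                          layer = "counts")
    expect_equal(X2$values, X$values, ignore_attr = FALSE)
    expect_identical(X2$sample_ids, X$sample_ids)
    expect_identical(X2$gene_ids, X$gene_ids)
  }
})

test_that("mtx triplets expand to the right number of zeros", {
  # 5 nonzeros over 4x3 leaves 7 zero entries
  m <- matrix(0, 4, 3)
  m[cbind(c(1, 2, 3, 4, 1), c(1, 2, 3, 1, 2))] <- c(3, 1, 4, 1, 5)
  X <- expression_matrix(m, paste0("c", 1:4), paste0("g", 1:3),
                         layer = "counts")
  path <- file.path(withr::local_tempdir(), "m.mtx")
  write_expression(X, path, "mtx")
  X2 <- read_expression(path, "mtx", layer = "counts")
  expect_equal(sum(X2$values == 0), 4 * 3 - 5)
  expect_equal(X2$values, X$values)
})

test_that("h5ad input is rejected with advice, missing sidecars error", {
  expect_error(read_expression("x.h5ad", "h5ad"), "not supported")
  d <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(diag(3), sparse = TRUE),
                  file.path(d, "bare.mtx"))
  expect_error(read_expression(file.path(d, "bare.mtx"), "mtx"),
               "sidecars")
})

test_that("transposed inputs are normalized to samples x genes", {
  X <- make_counts(3, 5, seed = 2)
  path <- file.path(withr::local_tempdir(), "t.csv")
  tX <- expression_matrix(t(X$values), X$gene_ids, X$sample_ids,
                          layer = "counts")
  write_expression(tX, path, "csv")
  X2 <- read_expression(path, "csv", transpose = TRUE, layer = "counts")
  expect_equal(X2$values, X$values)
})

test_that("qc_filter applies the three rules strictly and in order", {
  # 5 cells x 6 genes; gene g6 is mitochondrial
  m <- rbind(
    c(5, 5, 5, 5, 5, 2),    # fine (mito 2/27)
    c(9, 0, 0, 0, 0, 0),    # only 1 gene detected -> removed by rule 1
    c(5, 5, 5, 5, 5, 1),    # fine (mito 1/26); keeps MT-1 in >= 3 cells
    c(4, 4, 4, 4, 4, 0),    # fine
    c(44, 22, 11, 11, 0, 12))  # mito 12/100 = 0.12 > 0.10 -> removed
  X <- expression_matrix(m, paste0("c", 1:5),
                         c("g1", "g2", "g3", "g4", "g5", "MT-1"),
                         layer = "counts")
  out <- qc_filter(X, min_genes_per_cell = 2, min_cells_per_gene = 3,
                   max_mito_frac = 0.10)
  expect_identical(out$X$sample_ids, c("c1", "c3", "c4"))
  expect_equal(out$report$cells_removed_low_genes, 1)
  expect_equal(out$report$cells_removed_mito, 1)
  # g5 is detected in exactly 3 cells after rule 1 -> retained (strict "<")
  expect_true("g5" %in% out$X$gene_ids)
  expect_equal(out$report$order, c("cells_by_genes", "genes_by_cells",
                                   "mito"))
})

test_that("a cell under the detected-gene threshold is removed", {
  # cell 1 expresses 150 genes, threshold 200
  set.seed(3)
  m <- matrix(rpois(2 * 300, 3) + 1, 2, 300)
  m[1, 151:300] <- 0
  X <- expression_matrix(m, c("low", "ok"), paste0("g", 1:300),
                         layer = "counts")
  out <- qc_filter(X, min_genes_per_cell = 200, min_cells_per_gene = 0,
                   max_mito_frac = 1)
  expect_identical(out$X$sample_ids, "ok")
})

test_that("qc_filter errors when everything is removed", {
  X <- make_counts(3, 5)
  expect_error(qc_filter(X, min_genes_per_cell = 100), "empty matrix")
})

test_that("normalize_log rescales cells and log-transforms", {
  m <- rbind(c(10, 0, 10), c(4, 4, 2))
  X <- expression_matrix(m, c("a", "b"), c("g1", "g2", "g3"),
                         layer = "counts")
  out <- normalize_log(X, target_sum = 20)
  expect_equal(out$values[1, ], c(g1 = log(11), g2 = 0, g3 = log(11)))
  expect_equal(out$layer, "lognorm")
  # row sums of expm1 equal target_sum
  set.seed(9)
  X2 <- make_counts(5, 8, seed = 9)
  out2 <- normalize_log(X2, target_sum = 1e4)
  expect_true(all(abs(rowSums(expm1(out2$values)) - 1e4) < 1e-8))
  # zero-total cell errors
  m3 <- rbind(c(0, 0), c(1, 2))
  X3 <- expression_matrix(m3, c("z", "a"), c("g1", "g2"), layer = "counts")
  expect_error(normalize_log(X3), "qc_filter")
})

test_that("oversampling equalizes counts using only original minority rows", {
  set.seed(4)
  m <- matrix(rpois(100 * 5, 8), 100, 5)
  X <- expression_matrix(m, paste0("s", 1:100), paste0("g", 1:5),
                         layer = "counts")
  y <- response_labels(X$sample_ids, c(rep(0, 90), rep(1, 10)))
  out <- balance_classes(X, y, "oversample", seed = 5)
  expect_equal(as.vector(table(out$y$labels)), c(90, 90))
  new_rows <- out$X$values[101:180, , drop = FALSE]
  orig_min <- m[91:100, , drop = FALSE]
  for (i in seq_len(nrow(new_rows)))
    expect_true(any(apply(orig_min, 1, function(r)
      all(r == new_rows[i, ]))))
  # majority rows untouched
  expect_equal(out$X$values[1:90, ], X$values[1:90, ])
})

test_that("balanced input is returned unchanged", {
  X <- make_counts(6, 4)
  y <- response_labels(X$sample_ids, rep(c(0, 1), 3))
  out <- balance_classes(X, y, "smote", seed = 1)
  expect_identical(out$X$values, X$values)
})

test_that("SMOTE synthesizes points on segments between minority samples", {
  # minority at (0,0) and (1,1) with k = 1: synthetics lie on the segment
  m <- rbind(matrix(5 + 0:19, 20, 2), c(0, 0), c(1, 1))
  X <- expression_matrix(pmax(m, 0), paste0("s", 1:22), c("g1", "g2"),
                         layer = "lognorm")
  y <- response_labels(X$sample_ids, c(rep(0, 20), 1, 1))
  out <- balance_classes(X, y, "smote", k_neighbors = 1, seed = 3)
  synth <- out$X$values[23:nrow(out$X$values), , drop = FALSE]
  expect_true(all(abs(synth[, 1] - synth[, 2]) < 1e-10))
  expect_true(all(synth >= 0 & synth <= 1))
})

test_that("SMOTE demands minority count above k_neighbors", {
  Xc <- make_counts(10, 3)
  X <- make_lognorm(Xc$values)
  y <- response_labels(X$sample_ids, c(rep(0, 7), 1, 1, 1))
  expect_error(balance_classes(X, y, "smote", k_neighbors = 5, seed = 1),
               "k_neighbors")
  y1 <- response_labels(X$sample_ids, rep(1, 10))
  expect_error(balance_classes(X, y1, "smote", seed = 1), "both classes")
})

test_that("balancing is reproducible under a seed", {
  set.seed(8)
  m <- matrix(round(rexp(60 * 4, 1 / 3), 3), 60, 4)
  X <- expression_matrix(m, paste0("s", 1:60), paste0("g", 1:4),
                         layer = "lognorm")
  y <- response_labels(X$sample_ids, c(rep(0, 45), rep(1, 15)))
  a <- balance_classes(X, y, "smote", k_neighbors = 5, seed = 42)
  b <- balance_classes(X, y, "smote", k_neighbors = 5, seed = 42)
  expect_identical(a$X$values, b$X$values)
  # SMOTE refuses a raw counts layer (interpolation breaks integrality)
  Xc <- expression_matrix(matrix(rpois(240, 6), 60, 4),
                          paste0("s", 1:60), paste0("g", 1:4),
                          layer = "counts")
  expect_error(balance_classes(Xc, y, "smote", seed = 1), "normalize")
})

test_that("split_train_test partitions with exact stratified counts", {
  set.seed(10)
  m <- matrix(rpois(100 * 3, 5), 100, 3)
  X <- expression_matrix(m, paste0("s", 1:100), paste0("g", 1:3),
                         layer = "counts")
  y <- response_labels(X$sample_ids, rep(c(0, 1), each = 50))
  sp <- split_train_test(X, y, test_frac = 0.2, seed = 1)
  expect_equal(length(sp$test$y$labels), 20)
  expect_equal(length(sp$train$y$labels), 80)
  expect_equal(as.vector(table(sp$test$y$labels)), c(10, 10))
  # partition property
  expect_setequal(c(sp$train$y$sample_ids, sp$test$y$sample_ids),
                  y$sample_ids)
  expect_length(intersect(sp$train$y$sample_ids, sp$test$y$sample_ids), 0)
  expect_error(split_train_test(X, y, test_frac = 1.2), "test_frac")
})
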