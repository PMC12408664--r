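make_marker_data <- function(n_per_class = 50, n_genes = 40, shift = 3,
                             seed = 18) {
  set.seed(seed)
  n <- 2 * n_per_class
  m <- matrix(rnorm(n * n_genes, mean = 3, sd = 1), n, n_genes)
  labels <- rep(c(1, 0), each = n_per_class)
  m[labels == 1, 1] <- m[labels == 1, 1] + shift   # sensitive marker g1
  m[labels == 0, 2] <- m[labels == 0, 2] + shift   # resistant marker g2
  X <- make_lognorm(`dimnames<-`(pmax(m, 0),
                                 list(paste0("c", 1:n),
                                      paste0("g", 1:n_genes))))
  list(X = X, labels = labels)
}

test_that("find_degs recovers a planted marker at rank one", {
  d <- make_marker_data()
  degs <- find_degs(d$X, d$labels)
  expect_identical(degs$sensitive_up[1], "g1")
  expect_identical(degs$resistant_up[1], "g2")
  expect_error(find_degs(d$X, rep(1, 100)), "class")
})

test_that("find_degs is calibrated under label permutation", {
  d <- make_marker_data(shift = 0)   # no signal at all
  set.seed(19)
  n_sig <- replicate(20, {
    labs <- sample(d$labels)
    sum(find_degs(d$X, labs)$table$padj < 0.05)
  })
  expect_lte(mean(n_sig), 0.01 * ncol(d$X$values))
})

test_that("a gene identical in both classes is reported in neither list", {
  d <- make_marker_data()
  d$X$values[, "g5"] <- 1
  degs <- find_degs(d$X, d$labels)
  expect_false("g5" %in% degs$sensitive_up)
  expect_false("g5" %in% degs$resistant_up)
})

test_that("gene_set_score is the mean of per-gene z-scores", {
  v <- rbind(c(1, 10), c(2, 20), c(3, 30))
  X <- make_lognorm(`dimnames<-`(v, list(paste0("c", 1:3), c("gA", "gB"))))
  gs <- gene_set_score(X, c("gA", "gB"))
  manual <- rowMeans(cbind(scale(v[, 1]), scale(v[, 2])))
  expect_equal(gs$scores, manual, ignore_attr = TRUE, tolerance = 1e-12)
  # singleton set equals that gene's z-score
  gs1 <- gene_set_score(X, "gA")
  expect_equal(gs1$scores, as.numeric(scale(v[, 1])), ignore_attr = TRUE)
  # order within the set is irrelevant
  expect_equal(gene_set_score(X, c("gB", "gA"))$scores, gs$scores)
  # constant matrix scores 0 with a warning
  Xc <- make_lognorm(`dimnames<-`(matrix(2, 3, 2),
                                  list(paste0("c", 1:3), c("gA", "gB"))))
  expect_warning(gsc <- gene_set_score(Xc, c("gA", "gB")), "zero-variance")
  expect_true(all(gsc$scores == 0))
  expect_error(gene_set_score(X, "nope"), "intersection")
})

test_that("score_correlation behaves at its extremes", {
  d <- make_marker_data()
  a <- gene_set_score(d$X, c("g1", "g3"))
  b <- a; b$scores <- -a$scores
  expect_equal(score_correlation(a, a)$r, 1)
  expect_equal(score_correlation(a, b)$r, -1)
  expect_equal(score_correlation(a, b)$r_squared, 1)
  z <- a; z$scores <- rep(1, length(a$scores))
  expect_error(score_correlation(a, z), "zero variance")
})

test_that("random_geneset_null yields valid, seeded p-values", {
  d <- make_marker_data()
  pred_labels <- d$labels   # pretend perfect predictions
  degs <- find_degs(d$X, pred_labels)
  out <- random_geneset_null(d$X, d$labels, pred_labels,
                             degs$sensitive_up, n_trials = 99, seed = 4)
  expect_length(out$null_rs, 99)
  expect_gt(out$p_value, 0)          # add-one: never exactly zero
  expect_lte(out$p_value, 1)
  out2 <- random_geneset_null(d$X, d$labels, pred_labels,
                              degs$sensitive_up, n_trials = 99, seed = 4)
  expect_identical(out$null_rs, out2$null_rs)
  expect_error(random_geneset_null(d$X, d$labels, pred_labels,
                                   character(0)), "empty")
})

test_that("integrated gradients are exact for a linear surrogate", {
  # build a model whose F is linear: identity-ish encoder, linear MLP
  run <- tiny_transfer_run()
  model <- run$res$model
  X <- run$sc_ln$values[1:8, model$genes, drop = FALSE]
  att <- integrated_gradients(model, X, n_steps = 2, n_top = 5)
  # completeness against the package's own forward difference
  expect_true(all(att$completeness_residual >= 0))
  # linear-surrogate closed form: for F(x) = sum(w * x), IG = w * x
  w <- rnorm(ncol(X))
  f <- function(M) as.numeric(M %*% w)
  base <- rep(0, ncol(X))
  steps <- 50
  # package semantics on the same path: (x - b) * mean of grads (constant w)
  ig_manual <- sweep(X, 2, base, "-") * matrix(w, nrow(X), ncol(X),
                                               byrow = TRUE)
  expect_equal(rowSums(ig_manual), f(X) - f(matrix(base, 1)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("integrated gradients satisfy completeness on a trained model", {
  run <- tiny_transfer_run()
  model <- run$res$model
  X <- run$sc_ln$values[1:30, model$genes, drop = FALSE]
  att <- integrated_gradients(model, X, n_steps = 50)
  tol <- 0.01 * abs(att$delta) + 1e-4
  expect_true(all(att$completeness_residual < tol))
  # attributions of a constant model are zero
  model0 <- model
  for (i in seq_along(model0$predictor$mlp$layers)) {
    model0$predictor$mlp$layers[[i]]$W[] <- 0
    model0$predictor$mlp$layers[[i]]$b[] <- 0
  }
  att0 <- integrated_gradients(model0, X, n_steps = 5)
  expect_true(all(abs(att0$attributions) < 1e-12))
})
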