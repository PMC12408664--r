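test_that("attention_config enforces token and head divisibility", {
  cfg <- attention_config(64, n_heads = 8, n_tokens = 8)
  expect_equal(cfg$token_dim, 8L)
  expect_equal(cfg$d_k, 1L)
  expect_error(attention_config(64, n_heads = 3, n_tokens = 8),
               "divisible")
  expect_error(attention_config(63, n_heads = 1, n_tokens = 8),
               "divisible")
  cfg0 <- attention_config(16, n_heads = 0, n_tokens = 4)
  expect_true(is.na(cfg0$d_k))
})

test_that("scaled_dot_attention matches its closed forms and oracle", {
  # single token: softmax of a scalar is 1, output = V
  Q <- matrix(rnorm(3), 1); K <- matrix(rnorm(3), 1)
  V <- matrix(rnorm(5), 1)
  expect_equal(scaled_dot_attention(Q, K, V), V)
  # identical keys: uniform weights, output = column means of V
  K2 <- matrix(1, 4, 3); V2 <- matrix(rnorm(8), 4, 2)
  out <- scaled_dot_attention(matrix(rnorm(3), 1), K2, V2)
  expect_equal(as.numeric(out), colMeans(V2))
  # brute-force softmax oracle on a random 4-token case
  set.seed(6)
  Q <- matrix(rnorm(12), 4); K <- matrix(rnorm(12), 4)
  V <- matrix(rnorm(8), 4)
  S <- Q %*% t(K) / sqrt(3)
  A <- exp(S) / rowSums(exp(S))
  expect_equal(scaled_dot_attention(Q, K, V), A %*% V, tolerance = 1e-10)
  expect_true(all(abs(rowSums(A) - 1) < 1e-8))
  expect_error(scaled_dot_attention(Q[, 1:2], K, V), "column count")
})

test_that("single-head identity projections reduce to scaled_dot_attention", {
  cfg <- attention_config(12, n_heads = 1, n_tokens = 3)
  P <- predictor_init(cfg)
  I4 <- diag(4)
  P$attention$Wq[[1]] <- I4; P$attention$Wk[[1]] <- I4
  P$attention$Wv[[1]] <- I4; P$attention$Wo <- I4
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(multi_head_attention(X, P),
               scaled_dot_attention(X, X, X), tolerance = 1e-12)
})

test_that("attention is permutation-equivariant across tokens", {
  set.seed(8)
  cfg <- attention_config(24, n_heads = 2, n_tokens = 4)
  P <- predictor_init(cfg)
  X <- matrix(rnorm(24), 4, 6)
  perm <- c(3, 1, 4, 2)
  expect_equal(multi_head_attention(X[perm, ], P),
               multi_head_attention(X, P)[perm, ], tolerance = 1e-12)
})

test_that("two-head attention matches a manual per-head assembly", {
  set.seed(9)
  cfg <- attention_config(24, n_heads = 2, n_tokens = 4)
  P <- predictor_init(cfg)
  X <- matrix(rnorm(24), 4, 6)
  d_k <- cfg$d_k
  heads <- lapply(1:2, function(h) {
    Q <- X %*% P$attention$Wq[[h]]
    K <- X %*% P$attention$Wk[[h]]
    V <- X %*% P$attention$Wv[[h]]
    S <- Q %*% t(K) / sqrt(d_k)
    A <- exp(S) / rowSums(exp(S))
    A %*% V
  })
  manual <- do.call(cbind, heads) %*% P$attention$Wo
  expect_equal(multi_head_attention(X, P), manual, tolerance = 1e-10)
})

test_that("predict_proba emits calibrated-range scores and honours shapes", {
  set.seed(10)
  cfg <- attention_config(12, n_heads = 2, n_tokens = 3,
                          predictor_dims = c(8), seed = 4)
  P <- predictor_init(cfg)
  Z <- matrix(rnorm(60), 5, 12)
  p <- predict_proba(P, Z)
  expect_length(p, 5)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict_proba(P, Z[, 1:7]), "bottleneck")
  # zero-weight MLP: sigmoid(0) = 0.5 everywhere
  for (i in seq_along(P$mlp$layers)) {
    P$mlp$layers[[i]]$W[] <- 0; P$mlp$layers[[i]]$b[] <- 0
  }
  expect_equal(predict_proba(P, Z), rep(0.5, 5))
})

test_that("zero heads bypass attention exactly", {
  set.seed(11)
  cfg0 <- attention_config(12, n_heads = 0, n_tokens = 3,
                           predictor_dims = c(8), seed = 5)
  P0 <- predictor_init(cfg0)
  Z <- matrix(rnorm(48), 4, 12)
  # manual MLP on the flat latent with the same weights
  H <- pmax(sweep(Z %*% P0$mlp$layers[[1]]$W, 2, P0$mlp$layers[[1]]$b,
                  "+"), 0)
  logit <- sweep(H %*% P0$mlp$layers[[2]]$W, 2, P0$mlp$layers[[2]]$b, "+")
  expect_equal(predict_proba(P0, Z), as.numeric(1 / (1 + exp(-logit))),
               tolerance = 1e-12)
  expect_error(multi_head_attention(matrix(rnorm(12), 3, 4), P0),
               "n_heads = 0")
})

test_that("classification_loss matches closed forms and an oracle", {
  expect_lt(classification_loss(c(1, 0, 1), c(1, 0, 1)), 1.1e-7)
  expect_equal(classification_loss(rep(0.5, 4), c(0, 1, 0, 1)), log(2))
  set.seed(12)
  s <- runif(20); y <- rbinom(20, 1, 0.5)
  oracle <- -mean(y * log(s) + (1 - y) * log(1 - s))
  expect_equal(classification_loss(s, y), oracle, tolerance = 1e-12)
  expect_error(classification_loss(s, y[1:5]), "lengths")
  # stationarity at a perfect fit: gradient p - y is ~0 elementwise
  expect_true(all(abs(c(1, 0) - c(1, 0)) < 1e-12))
})

test_that("predictor training reduces cross-entropy and is seeded", {
  set.seed(13)
  n <- 60
  Z <- matrix(rnorm(n * 8), n, 8)
  y <- as.integer(Z[, 1] + 0.3 * rnorm(n) > 0)
  cfg <- attention_config(8, n_heads = 2, n_tokens = 2,
                          predictor_dims = c(8), dropout = 0, seed = 3)
  P1 <- fit_predictor(predictor_init(cfg), Z, y, epochs = 80, seed = 5)
  expect_lt(tail(P1$training_history, 1), P1$training_history[1])
  P2 <- fit_predictor(predictor_init(cfg), Z, y, epochs = 80, seed = 5)
  expect_identical(P1$mlp$layers, P2$mlp$layers)
  expect_gt(auc_roc(predict_proba(P1, Z), y), 0.8)
})
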