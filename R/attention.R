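# Multi-head self-attention over the latent embedding, followed by an MLP
# head that emits a drug-sensitivity probability.
#
# A per-sample latent vector (length bottleneck) is reshaped into
# n_tokens x token_dim tokens; attention mixes the tokens; the mixed tokens
# are flattened back and fed to the MLP. There is no positional encoding:
# latent coordinates carry no order, and the attention output is
# permutation-equivariant in the tokens.
#
# Internally tokens are kept as a list of T matrices (n_samples x token_dim)
# so every operation is vectorized over the batch.

#' Attention-predictor configuration
#'
#' @param bottleneck Latent width the predictor consumes; must equal
#'   `n_tokens * token_dim`.
#' @param n_heads Number of attention heads; `0` disables attention and the
#'   predictor becomes a plain MLP on the flattened latent.
#' @param n_tokens Number of tokens the latent vector is reshaped into
#'   (default 8).
#' @param predictor_dims Hidden widths of the MLP head
#'   (default `c(128, 64)`).
#' @param dropout Dropout fraction for the MLP hiddens during training
#'   (default 0.3).
#' @param seed Integer seed for initialization.
#' @return An `attention_config` list; `token_dim` is derived and the
#'   per-head key dimension `d_k = token_dim / n_heads` must be a positive
#'   integer when `n_heads > 0`.
#' @export
attention_config <- function(bottleneck, n_heads = 8, n_tokens = 8,
                             predictor_dims = c(128, 64), dropout = 0.3,
                             seed = 1) {
  stopifnot(bottleneck >= 1, n_heads >= 0, n_tokens >= 1,
            all(predictor_dims >= 1), dropout >= 0, dropout < 1)
  if (bottleneck %% n_tokens != 0)
    stop("bottleneck (", bottleneck, ") must be divisible by n_tokens (",
         n_tokens, ")")
  token_dim <- bottleneck %/% n_tokens
  if (n_heads > 0 && token_dim %% n_heads != 0)
    stop("token_dim (", token_dim, ") must be divisible by n_heads (",
         n_heads, ") so that d_k = token_dim / n_heads is a positive integer")
  structure(list(bottleneck = as.integer(bottleneck),
                 n_heads = as.integer(n_heads),
                 n_tokens = as.integer(n_tokens),
                 token_dim = as.integer(token_dim),
                 d_k = if (n_heads > 0) token_dim %/% n_heads else NA_integer_,
                 predictor_dims = as.integer(predictor_dims),
                 dropout = dropout, seed = as.integer(seed)),
            class = "attention_config")
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, the attention primitive: every softmax row
#' sums to one and the output rows are convex combinations of the rows
#' of `V`.
#'
#' @param Q,K Query/key matrices with the same column count `d_k`.
#' @param V Value matrix with as many rows as `K`.
#' @return Matrix of shape `nrow(Q) x ncol(V)`.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must have the same column count")
  if (nrow(K) != nrow(V)) stop("K and V must have the same row count")
  S <- Q %*% t(K) / sqrt(ncol(K))
  S <- S - apply(S, 1, max)            # row-wise stabilization
  A <- exp(S); A <- A / rowSums(A)
  A %*% V
}

# ---- internal batched multi-head attention -------------------------------

# tokens: list of T matrices (n x d). Returns list(out = token list,
# cache) for backward.
.mha_forward <- function(tokens, weights, d_k) {
  T_ <- length(tokens); n <- nrow(tokens[[1]]); d <- ncol(tokens[[1]])
  H <- length(weights$Wq)
  head_out <- vector("list", H)
  cache <- list(tokens = tokens, A = vector("list", H),
                Q = vector("list", H), K = vector("list", H),
                V = vector("list", H))
  for (h in seq_len(H)) {
    Q <- lapply(tokens, function(x) x %*% weights$Wq[[h]])
    K <- lapply(tokens, function(x) x %*% weights$Wk[[h]])
    V <- lapply(tokens, function(x) x %*% weights$Wv[[h]])
    # scores S[[i]][, j] over n samples
    A <- vector("list", T_)
    for (i in seq_len(T_)) {
      S <- matrix(0, n, T_)
      for (j in seq_len(T_)) S[, j] <- rowSums(Q[[i]] * K[[j]]) / sqrt(d_k)
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A[[i]] <- E / rowSums(E)
    }
    O <- vector("list", T_)
    for (i in seq_len(T_)) {
      acc <- matrix(0, n, d_k)
      for (j in seq_len(T_)) acc <- acc + A[[i]][, j] * V[[j]]
      O[[i]] <- acc
    }
    head_out[[h]] <- O
    cache$A[[h]] <- A; cache$Q[[h]] <- Q; cache$K[[h]] <- K; cache$V[[h]] <- V
  }
  # concat heads per token, then output projection
  concat <- lapply(seq_len(T_), function(i)
    do.call(cbind, lapply(head_out, `[[`, i)))
  out <- lapply(concat, function(x) x %*% weights$Wo)
  cache$concat <- concat
  list(out = out, cache = cache)
}

# dout: list of T matrices (n x d). Returns grads (same shape as weights)
# and dtokens.
.mha_backward <- function(dout, weights, cache, d_k) {
  T_ <- length(dout); n <- nrow(dout[[1]])
  H <- length(weights$Wq)
  d <- ncol(weights$Wo)
  dWo <- matrix(0, nrow(weights$Wo), d)
  dconcat <- vector("list", T_)
  for (i in seq_len(T_)) {
    dWo <- dWo + crossprod(cache$concat[[i]], dout[[i]])
    dconcat[[i]] <- dout[[i]] %*% t(weights$Wo)
  }
  dtokens <- lapply(seq_len(T_), function(i)
    matrix(0, n, ncol(cache$tokens[[1]])))
  dWq <- dWk <- dWv <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * d_k + 1):(h * d_k)
    dO <- lapply(dconcat, function(x) x[, cols, drop = FALSE])
    A <- cache$A[[h]]; Q <- cache$Q[[h]]; K <- cache$K[[h]]; V <- cache$V[[h]]
    dV <- lapply(seq_len(T_), function(j) matrix(0, n, d_k))
    dA <- vector("list", T_)
    for (i in seq_len(T_)) {
      dAi <- matrix(0, n, T_)
      for (j in seq_len(T_)) {
        dAi[, j] <- rowSums(dO[[i]] * V[[j]])
        dV[[j]] <- dV[[j]] + A[[i]][, j] * dO[[i]]
      }
      dA[[i]] <- dAi
    }
    dQ <- lapply(seq_len(T_), function(i) matrix(0, n, d_k))
    dK <- lapply(seq_len(T_), function(j) matrix(0, n, d_k))
    for (i in seq_len(T_)) {
      # softmax backward per row: dS = A * (dA - rowSums(A * dA))
      rs <- rowSums(A[[i]] * dA[[i]])
      dS <- A[[i]] * (dA[[i]] - rs)
      dS <- dS / sqrt(d_k)
      for (j in seq_len(T_)) {
        dQ[[i]] <- dQ[[i]] + dS[, j] * K[[j]]
        dK[[j]] <- dK[[j]] + dS[, j] * Q[[i]]
      }
    }
    gq <- matrix(0, ncol(cache$tokens[[1]]), d_k)
    gk <- gq; gv <- gq
    for (t in seq_len(T_)) {
      gq <- gq + crossprod(cache$tokens[[t]], dQ[[t]])
      gk <- gk + crossprod(cache$tokens[[t]], dK[[t]])
      gv <- gv + crossprod(cache$tokens[[t]], dV[[t]])
      dtokens[[t]] <- dtokens[[t]] +
        dQ[[t]] %*% t(weights$Wq[[h]]) +
        dK[[t]] %*% t(weights$Wk[[h]]) +
        dV[[t]] %*% t(weights$Wv[[h]])
    }
    dWq[[h]] <- gq; dWk[[h]] <- gk; dWv[[h]] <- gv
  }
  list(grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo),
       dtokens = dtokens)
}

# ---- predictor ------------------------------------------------------------

.predictor_build <- function(config) {
  H <- config$n_heads
  att <- NULL
  if (H > 0) {
    d <- config$token_dim; dk <- config$d_k
    init <- function() matrix(stats::rnorm(d * dk, sd = sqrt(1 / d)), d, dk)
    att <- list(Wq = replicate(H, init(), simplify = FALSE),
                Wk = replicate(H, init(), simplify = FALSE),
                Wv = replicate(H, init(), simplify = FALSE),
                Wo = matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d))
  }
  mlp <- .mlp_new(c(config$bottleneck, config$predictor_dims, 1), "sigmoid")
  list(attention = att, mlp = mlp)
}

#' Initialize an attention predictor
#'
#' @param config An [attention_config()].
#' @return A `predictor_model` (untrained).
#' @export
predictor_init <- function(config) {
  stopifnot(inherits(config, "attention_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  net <- .predictor_build(config)
  structure(list(attention = net$attention, mlp = net$mlp, config = config),
            class = "predictor_model")
}

# split a latent matrix (n x bottleneck) into a token list
.to_tokens <- function(Z, n_tokens, token_dim) {
  lapply(seq_len(n_tokens), function(t)
    Z[, ((t - 1) * token_dim + 1):(t * token_dim), drop = FALSE])
}
.from_tokens <- function(tokens) do.call(cbind, tokens)

#' Multi-head self-attention over a token matrix
#'
#' Applies the model's attention block to a single sample's token matrix:
#' per head `i`, `Attention(X Wq_i, X Wk_i, X Wv_i)`; the head outputs are
#' concatenated and projected by `Wo`. Output shape equals the input shape.
#'
#' @param X_tokens Matrix of shape `n_tokens x token_dim`.
#' @param model A `predictor_model` with `n_heads >= 1`.
#' @return Matrix `n_tokens x token_dim`.
#' @export
multi_head_attention <- function(X_tokens, model) {
  stopifnot(inherits(model, "predictor_model"))
  if (is.null(model$attention))
    stop("model has n_heads = 0: no attention block")
  cfg <- model$config
  X_tokens <- as.matrix(X_tokens)
  if (nrow(X_tokens) != cfg$n_tokens || ncol(X_tokens) != cfg$token_dim)
    stop("X_tokens must be ", cfg$n_tokens, " x ", cfg$token_dim)
  tokens <- lapply(seq_len(cfg$n_tokens),
                   function(t) X_tokens[t, , drop = FALSE])
  out <- .mha_forward(tokens, model$attention, cfg$d_k)$out
  do.call(rbind, out)
}

# full forward: latent matrix -> probability vector; returns caches
.predictor_forward <- function(model, Z, train = FALSE) {
  cfg <- model$config
  att_cache <- NULL
  if (cfg$n_heads > 0) {
    tokens <- .to_tokens(Z, cfg$n_tokens, cfg$token_dim)
    fa <- .mha_forward(tokens, model$attention, cfg$d_k)
    Zmix <- .from_tokens(fa$out)
    att_cache <- fa$cache
  } else {
    Zmix <- Z
  }
  fm <- .mlp_forward(model$mlp, Zmix, train = train,
                     dropout = if (train) cfg$dropout else 0)
  list(p = as.numeric(fm$out), mlp_cache = fm, att_cache = att_cache)
}

# backward from d(pre-sigmoid logit) vector; returns grads + dZ
.predictor_backward <- function(model, cache, dlogit) {
  cfg <- model$config
  bm <- .mlp_backward(model$mlp, cache$mlp_cache,
                      matrix(dlogit, ncol = 1), dout_is_preact = TRUE)
  if (cfg$n_heads > 0) {
    dtok <- .to_tokens(bm$dX, cfg$n_tokens, cfg$token_dim)
    ba <- .mha_backward(dtok, model$attention, cache$att_cache, cfg$d_k)
    dZ <- .from_tokens(ba$dtokens)
    list(grads = list(attention = ba$grads, mlp = bm$grads), dZ = dZ)
  } else {
    list(grads = list(mlp = bm$grads), dZ = bm$dX)
  }
}

#' Predict drug-sensitivity probabilities from latent embeddings
#'
#' Deterministic forward pass (dropout off): each latent vector is
#' tokenized, passed through multi-head attention (skipped when
#' `n_heads = 0`), flattened, and scored by the sigmoid-output MLP.
#'
#' @param model A `predictor_model`.
#' @param Z A `latent_embedding` or numeric matrix with `bottleneck`
#'   columns.
#' @return Numeric vector of probabilities in `[0, 1]`, one per sample.
#' @export
predict_proba <- function(model, Z) {
  stopifnot(inherits(model, "predictor_model"))
  Zm <- if (inherits(Z, "latent_embedding")) Z$values else as.matrix(Z)
  if (ncol(Zm) != model$config$bottleneck)
    stop("ncol(Z) (", ncol(Zm), ") != bottleneck (",
         model$config$bottleneck, ")")
  .predictor_forward(model, Zm)$p
}

#' Binary cross-entropy classification loss
#'
#' Mean of `-(y log s + (1 - y) log(1 - s))` with scores clipped to
#' `[eps, 1 - eps]`, `eps = 1e-7`.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels Binary labels aligned with `scores`.
#' @return Non-negative scalar.
#' @export
classification_loss <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  eps <- 1e-7
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

#' Train the predictor on labelled latent embeddings
#'
#' Minimizes binary cross-entropy with Adam. This is the bulk pre-training
#' step; the same parameters are later refined during joint transfer
#' training. When an `encoder` and its input matrix `X` are supplied, the
#' embeddings are recomputed every epoch from a freshly noise-corrupted
#' input (the predictor consumes the encoder's noisy pass, so the decision
#' boundary is trained under the same corruption the autoencoder denoises
#' — this also makes it robust to the heavier dropout noise of single-cell
#' profiles).
#'
#' @param model A `predictor_model` (e.g. fresh from [predictor_init()]).
#' @param Z Latent matrix / `latent_embedding` (samples x bottleneck).
#'   Ignored when `encoder` is given.
#' @param labels Binary response labels aligned with the samples.
#' @param epochs Training epochs (default 200).
#' @param learning_rate Adam learning rate (default `1e-3`).
#' @param batch_size Mini-batch size; `Inf` (default) is full-batch.
#' @param seed Integer seed for dropout masks, noise and batch order.
#' @param encoder Optional `dae_model` for noise-augmented training.
#' @param X Input matrix for `encoder` (samples x genes).
#' @param aug_noise Masking probability for the per-epoch corruption
#'   (default: the encoder config's `noise_rate`).
#' @return The trained `predictor_model` with a `training_history` of
#'   per-epoch cross-entropy.
#' @export
fit_predictor <- function(model, Z, labels, epochs = 200,
                          learning_rate = 1e-3, batch_size = Inf, seed = 1,
                          encoder = NULL, X = NULL, aug_noise = NULL) {
  stopifnot(inherits(model, "predictor_model"))
  augmented <- !is.null(encoder)
  if (augmented) {
    stopifnot(inherits(encoder, "dae_model"), !is.null(X))
    X <- as.matrix(X)
    if (is.null(aug_noise)) aug_noise <- encoder$config$noise_rate
    Zm <- encode(encoder, X)$values
  } else {
    Zm <- if (inherits(Z, "latent_embedding")) Z$values else as.matrix(Z)
  }
  labels <- as.numeric(labels)
  stopifnot(nrow(Zm) == length(labels))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  params <- .predictor_params(model)
  opt <- .adam_new(params, lr = learning_rate)
  n <- nrow(Zm)
  bs <- if (is.finite(batch_size)) min(batch_size, n) else n
  history <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    if (augmented && aug_noise > 0)
      Zm <- encode(encoder, noise_inject(X, aug_noise))$values
    ord <- if (bs < n) sample(n) else seq_len(n)
    tot <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      zb <- Zm[idx, , drop = FALSE]; yb <- labels[idx]
      fw <- .predictor_forward(model, zb, train = TRUE)
      loss <- classification_loss(fw$p, yb)
      if (!is.finite(loss)) stop("predictor training diverged at epoch ", epoch)
      tot <- tot + loss * length(idx)
      dlogit <- (fw$p - yb) / length(idx)
      bw <- .predictor_backward(model, fw, dlogit)
      step <- .adam_step(opt, .predictor_params(model), bw$grads)
      opt <- step$opt
      model <- .predictor_set_params(model, step$params)
    }
    history[epoch] <- tot / n
  }
  model$training_history <- history
  model
}

.predictor_params <- function(model) {
  if (!is.null(model$attention))
    list(attention = model$attention, mlp = model$mlp$layers)
  else list(mlp = model$mlp$layers)
}
.predictor_set_params <- function(model, params) {
  if (!is.null(model$attention)) model$attention <- params$attention
  model$mlp$layers <- params$mlp
  model
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("<predictor_model> bottleneck %d = %d tokens x %d | heads %d | MLP [%s]\n",
              x$config$bottleneck, x$config$n_tokens, x$config$token_dim,
              x$config$n_heads, paste(x$config$predictor_dims, collapse = ",")))
  invisible(x)
}
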