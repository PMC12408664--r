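# Minimal feed-forward network engine: dense layers with ReLU hidden
# activations, inverted dropout, hand-derived backprop and Adam updates.
# All forward/backward functions are pure matrix code; batching is over rows.
# Parameter initialization draws from the *current* RNG stream, so callers
# seed once at model construction and everything downstream is reproducible.

.nn_init_dense <- function(n_in, n_out) {
  # He initialization (ReLU-friendly)
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                  n_in, n_out),
       b = rep(0, n_out))
}

# An MLP is a list of dense layers plus an activation spec:
# hidden layers ReLU, output activation one of "identity", "sigmoid".
.mlp_new <- function(dims, out_activation = "identity") {
  stopifnot(length(dims) >= 2)
  layers <- vector("list", length(dims) - 1)
  for (i in seq_along(layers)) layers[[i]] <- .nn_init_dense(dims[i], dims[i + 1])
  list(layers = layers, dims = dims, out_activation = out_activation)
}

# Forward pass. When train = TRUE and dropout > 0, inverted dropout is
# applied after every hidden ReLU (never after the output).
.mlp_forward <- function(net, X, train = FALSE, dropout = 0) {
  L <- length(net$layers)
  acts <- vector("list", L + 1)   # layer inputs
  masks <- vector("list", L)
  acts[[1]] <- X
  H <- X
  for (i in seq_len(L)) {
    H <- sweep(H %*% net$layers[[i]]$W, 2, net$layers[[i]]$b, "+")
    if (i < L) {
      H <- pmax(H, 0)
      if (train && dropout > 0) {
        mask <- matrix(stats::rbinom(length(H), 1, 1 - dropout) / (1 - dropout),
                       nrow(H), ncol(H))
        H <- H * mask
        masks[[i]] <- mask
      }
    } else if (net$out_activation == "sigmoid") {
      H <- 1 / (1 + exp(-H))
    }
    acts[[i + 1]] <- H
  }
  list(out = H, acts = acts, masks = masks)
}

# Backward pass from d(out). For "sigmoid" output, pass dZ directly via
# `dout_is_preact = TRUE` (e.g. BCE gradient p - y), which is both simpler
# and numerically stable. Returns parameter grads and the input gradient.
.mlp_backward <- function(net, cache, dout, dout_is_preact = FALSE) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- dout
  if (!dout_is_preact && net$out_activation == "sigmoid") {
    s <- cache$acts[[L + 1]]
    delta <- delta * s * (1 - s)
  }
  for (i in rev(seq_len(L))) {
    inp <- cache$acts[[i]]
    grads[[i]] <- list(W = crossprod(inp, delta), b = colSums(delta))
    delta <- delta %*% t(net$layers[[i]]$W)
    if (i > 1) {
      # back through dropout then ReLU of layer i-1
      if (!is.null(cache$masks[[i - 1]])) delta <- delta * cache$masks[[i - 1]]
      delta <- delta * (cache$acts[[i]] > 0)
    }
  }
  list(grads = grads, dX = delta)
}

# Adam optimizer over an arbitrary nested list of numeric arrays.
.adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps)
}

.adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  walk <- function(p, g, m, v) {
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g * g
    mh <- m / (1 - opt$beta1^opt$t)
    vh <- v / (1 - opt$beta2^opt$t)
    list(p = p - opt$lr * mh / (sqrt(vh) + opt$eps), m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(rec, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else walk(p, g, m, v)
  }
  out <- rec(params, grads, opt$m, opt$v)
  opt$m <- out$m; opt$v <- out$v
  list(opt = opt, params = out$p)
}
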