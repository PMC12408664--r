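#' Denoising-autoencoder configuration
#'
#' @param input_dim Number of input features (genes).
#' @param encoder_dims Integer vector of encoder hidden-layer widths
#'   (default `c(256, 128)`).
#' @param bottleneck Latent dimensionality (default 512 is the bulk-scale
#'   default; small synthetic runs use far less).
#' @param noise_rate Probability that an input entry is masked to zero
#'   during training (binomial corruption), in `[0, 1]` (default 0.2).
#' @param dropout Dropout fraction applied after each hidden layer during
#'   training, in `[0, 1)` (default 0.3).
#' @param epochs Training epochs (default 500).
#' @param learning_rate Adam learning rate (default `1e-3`).
#' @param batch_size Mini-batch size; `Inf` (default) trains full-batch.
#' @param seed Integer seed controlling initialization, noise masks and
#'   batch order.
#' @return A `dae_config` list.
#' @export
dae_config <- function(input_dim, encoder_dims = c(256, 128),
                       bottleneck = 512, noise_rate = 0.2, dropout = 0.3,
                       epochs = 500, learning_rate = 1e-3,
                       batch_size = Inf, seed = 1) {
  stopifnot(input_dim >= 1, bottleneck >= 1, all(encoder_dims >= 1),
            noise_rate >= 0, noise_rate <= 1, dropout >= 0, dropout < 1,
            epochs >= 1, learning_rate > 0)
  structure(list(input_dim = as.integer(input_dim),
                 encoder_dims = as.integer(encoder_dims),
                 bottleneck = as.integer(bottleneck),
                 noise_rate = noise_rate, dropout = dropout,
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "dae_config")
}

#' Binomial masking noise
#'
#' Corrupts a matrix for denoising-autoencoder training: each entry is
#' independently set to zero with probability `rate` and kept unchanged
#' otherwise. Never invents values; only existing entries are masked.
#'
#' @param X Numeric matrix.
#' @param rate Masking probability in `[0, 1]`.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A matrix of the same shape.
#' @export
noise_inject <- function(X, rate, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1)
    stop("rate must be a single number in [0, 1]")
  X <- as.matrix(X)
  if (rate == 0) return(X)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  mask <- matrix(stats::rbinom(length(X), 1, 1 - rate), nrow(X), ncol(X))
  X * mask
}

#' Mean-squared-error reconstruction loss
#'
#' @param X,X_recon Numeric matrices of identical shape.
#' @return Mean over all entries of the squared difference.
#' @export
reconstruction_loss <- function(X, X_recon) {
  X <- as.matrix(X); X_recon <- as.matrix(X_recon)
  if (!identical(dim(X), dim(X_recon)))
    stop("shape mismatch: ", paste(dim(X), collapse = "x"), " vs ",
         paste(dim(X_recon), collapse = "x"))
  mean((X - X_recon)^2)
}

# Build encoder + decoder MLPs for a config. Encoder: input -> hidden dims
# (ReLU) -> linear bottleneck. Decoder mirrors the encoder widths in
# reverse with ReLU hiddens and a linear output.
.dae_build <- function(config) {
  enc_dims <- c(config$input_dim, config$encoder_dims, config$bottleneck)
  dec_dims <- rev(enc_dims)
  list(encoder = .mlp_new(enc_dims, "identity"),
       decoder = .mlp_new(dec_dims, "identity"))
}

#' Fit a denoising autoencoder
#'
#' Trains encoder/decoder by minimizing the mean squared error between the
#' clean input and the reconstruction of its noise-corrupted version
#' (a fresh binomial mask each epoch). Hidden layers use ReLU; the
#' bottleneck and the reconstruction output are linear.
#'
#' @param X An [expression_matrix()] or plain numeric matrix
#'   (samples x genes).
#' @param config A [dae_config()]; `config$input_dim` must equal the gene
#'   count.
#' @param init A `dae_model` with identical layer dimensions whose weights
#'   warm-start training (default `NULL`: fresh seeded initialization).
#'   Used to initialize the single-cell autoencoder from the bulk one so
#'   the two latent spaces share a coordinate frame.
#' @return A `dae_model` with `encoder`, `decoder`, `config` and
#'   `training_history` (per-epoch reconstruction MSE against clean input).
#' @export
fit_dae <- function(X, config, init = NULL) {
  Xm <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  if (any(!is.finite(Xm))) stop("X must be finite")
  stopifnot(inherits(config, "dae_config"))
  if (ncol(Xm) != config$input_dim)
    stop("config$input_dim (", config$input_dim, ") != ncol(X) (",
         ncol(Xm), ")")

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  net <- .dae_build(config)
  if (!is.null(init)) {
    stopifnot(inherits(init, "dae_model"))
    same_dims <- identical(init$encoder$dims, net$encoder$dims) &&
      identical(init$decoder$dims, net$decoder$dims)
    if (!same_dims) stop("init model dimensions do not match config")
    net$encoder$layers <- init$encoder$layers
    net$decoder$layers <- init$decoder$layers
  }
  params <- list(enc = lapply(net$encoder$layers, identity),
                 dec = lapply(net$decoder$layers, identity))
  opt <- .adam_new(params, lr = config$learning_rate)
  n <- nrow(Xm)
  bs <- if (is.finite(config$batch_size)) min(config$batch_size, n) else n
  history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- if (bs < n) sample(n) else seq_len(n)
    epoch_loss <- 0; n_seen <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      xb <- Xm[idx, , drop = FALSE]
      xn <- noise_inject(xb, config$noise_rate)
      fe <- .mlp_forward(net$encoder, xn, train = TRUE,
                         dropout = config$dropout)
      fd <- .mlp_forward(net$decoder, fe$out, train = TRUE,
                         dropout = config$dropout)
      diffm <- fd$out - xb
      loss <- mean(diffm^2)
      if (!is.finite(loss))
        stop("DAE training diverged (non-finite loss) at epoch ", epoch,
             "; reduce learning_rate (", config$learning_rate, ")")
      epoch_loss <- epoch_loss + loss * length(idx); n_seen <- n_seen + length(idx)
      dout <- 2 * diffm / length(diffm)
      bd <- .mlp_backward(net$decoder, fd, dout)
      be <- .mlp_backward(net$encoder, fe, bd$dX)
      step <- .adam_step(opt, list(enc = net$encoder$layers,
                                   dec = net$decoder$layers),
                         list(enc = be$grads, dec = bd$grads))
      opt <- step$opt
      net$encoder$layers <- step$params$enc
      net$decoder$layers <- step$params$dec
    }
    history[epoch] <- epoch_loss / n_seen
  }
  structure(list(encoder = net$encoder, decoder = net$decoder,
                 config = config, training_history = history),
            class = "dae_model")
}

#' @export
print.dae_model <- function(x, ...) {
  cat(sprintf("<dae_model> %d -> [%s] -> %d | final MSE %.4g (%d epochs)\n",
              x$config$input_dim, paste(x$config$encoder_dims, collapse = ","),
              x$config$bottleneck, utils::tail(x$training_history, 1),
              x$config$epochs))
  invisible(x)
}

#' Encode samples into the latent space
#'
#' Deterministic inference pass: no noise, no dropout.
#'
#' @param model A `dae_model` from [fit_dae()].
#' @param X Numeric matrix or [expression_matrix()] with
#'   `input_dim` columns.
#' @return A `latent_embedding`: list with `values`
#'   (samples x bottleneck matrix) and `encoder` (`"bulk"` or the domain of
#'   origin is up to the caller; stored as the config used).
#' @export
encode <- function(model, X) {
  stopifnot(inherits(model, "dae_model"))
  Xm <- if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
  if (ncol(Xm) != model$config$input_dim)
    stop("ncol(X) (", ncol(Xm), ") != input_dim (", model$config$input_dim, ")")
  out <- .mlp_forward(model$encoder, Xm)$out
  rownames(out) <- rownames(Xm)
  structure(list(values = out, bottleneck = model$config$bottleneck),
            class = "latent_embedding")
}

#' Decode latent embeddings back to gene space
#'
#' @param model A `dae_model`.
#' @param Z A `latent_embedding` or numeric matrix with `bottleneck` columns.
#' @return Numeric matrix (samples x genes).
#' @export
decode <- function(model, Z) {
  stopifnot(inherits(model, "dae_model"))
  Zm <- if (inherits(Z, "latent_embedding")) Z$values else as.matrix(Z)
  if (ncol(Zm) != model$config$bottleneck)
    stop("ncol(Z) != bottleneck")
  .mlp_forward(model$decoder, Zm)$out
}

#' Save / load a model bundle
#'
#' Serializes any model object of this package (DAE, predictor, transfer
#' bundle) together with its configuration and seed; `load_model` restores
#' it bit-exactly.
#'
#' @param model Model object.
#' @param path Destination file.
#' @return `path` (`save_model`) or the restored object (`load_model`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model bundle not found: ", path)
  readRDS(path)
}
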