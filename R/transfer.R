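#' Joint domain-adaptation training configuration
#'
#' Weights and schedule for the composite objective
#' `class + omega * MMD + theta * regularizer` minimized over the bulk
#' encoder, the single-cell encoder and the predictor (decoders stay frozen
#' after their autoencoder stages).
#'
#' @param omega Weight of the MMD alignment term (default 0.25).
#' @param theta Weight of the cluster-coherence regularizer (default 0.1).
#' @param epochs Joint training epochs (default 30).
#' @param batch_size Mini-batch size per domain per step (default 64);
#'   bulk and single-cell batches are drawn independently with the same
#'   size.
#' @param learning_rate Adam learning rate (default `1e-3`).
#' @param cluster_resolution Louvain resolution for the one-off clustering
#'   of single-cell latents (default 1).
#' @param cluster_neighbors kNN graph size for clustering (default 15).
#' @param kernel,bandwidths MMD kernel options, see [mmd()].
#' @param seed Integer seed.
#' @return A `dann_config` list.
#' @export
dann_config <- function(omega = 0.25, theta = 0.1, epochs = 30,
                        batch_size = 64, learning_rate = 1e-3,
                        cluster_resolution = 1, cluster_neighbors = 15,
                        kernel = "rbf_multiscale",
                        bandwidths = "median-heuristic", seed = 1) {
  stopifnot(is.finite(omega), omega >= 0, is.finite(theta), theta >= 0,
            epochs >= 0, batch_size >= 2, learning_rate > 0)
  structure(list(omega = omega, theta = theta, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 cluster_resolution = cluster_resolution,
                 cluster_neighbors = as.integer(cluster_neighbors),
                 kernel = kernel, bandwidths = bandwidths,
                 seed = as.integer(seed)),
            class = "dann_config")
}

#' Composite domain-adaptation loss
#'
#' @param class_loss Cross-entropy term.
#' @param mmd_value MMD alignment term.
#' @param reg_value Cluster-regularizer term.
#' @param config A [dann_config()] providing `omega` and `theta`.
#' @return `class_loss + omega * mmd_value + theta * reg_value`.
#' @export
dann_loss <- function(class_loss, mmd_value, reg_value, config) {
  stopifnot(is.finite(class_loss), is.finite(mmd_value), is.finite(reg_value))
  class_loss + config$omega * mmd_value + config$theta * reg_value
}

#' Binarize continuous sensitivity scores
#'
#' Post-hoc thresholding for downstream interpretation only: scores at or
#' above the threshold map to 1 (sensitive), below it to 0 (resistant).
#' Threshold-free metrics (AUC, AP) and training never use this.
#'
#' @param scores Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5; ties go to sensitive).
#' @return Integer vector of 0/1 labels.
#' @export
binarize_scores <- function(scores, threshold = 0.5) {
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  as.integer(scores >= threshold)
}

# Per-gene standardization within a domain; zero-variance genes map to 0.
# mode "center" subtracts the gene mean only (keeps variance structure);
# "zscore" also divides by the gene sd.
.gene_scale <- function(X, mode = "center") {
  center <- colMeans(X)
  s <- if (mode == "zscore") {
    sd_ <- apply(X, 2, stats::sd); sd_[sd_ == 0] <- 1; sd_
  } else rep(1, ncol(X))
  list(X = sweep(sweep(X, 2, center, "-"), 2, s, "/"), center = center,
       scale = s)
}

.apply_scaling <- function(X, sc_params) {
  if (is.null(sc_params)) return(X)
  sweep(sweep(X, 2, sc_params$center, "-"), 2, sc_params$scale, "/")
}

# Align bulk and single-cell matrices on their shared genes (exact id
# match, bulk ordering).
.align_genes <- function(bulk, sc) {
  shared <- intersect(bulk$gene_ids, sc$gene_ids)
  if (length(shared) == 0) stop("empty gene intersection between domains")
  list(bulk = bulk[seq_along(bulk$sample_ids), match(shared, bulk$gene_ids)],
       sc = sc[seq_along(sc$sample_ids), match(shared, sc$gene_ids)],
       genes = shared)
}

#' Stage-wise transfer training: bulk pre-training to single-cell scoring
#'
#' Runs the full three-stage procedure:
#' \enumerate{
#'   \item Fit the bulk denoising autoencoder; train the attention predictor
#'     on the bulk latents against the bulk response labels (cross-entropy).
#'   \item Fit the single-cell denoising autoencoder; Louvain-cluster the
#'     single-cell latents once; then jointly refine the two encoders and
#'     the predictor over mini-batches, minimizing
#'     `class + omega * MMD + theta * regularizer` (decoders frozen).
#'   \item Score every cell: `predict_proba(P, E_t(sc))`.
#' }
#'
#' @param bulk An [expression_matrix()] (bulk domain, log-scale values).
#' @param bulk_labels A [response_labels()] aligned with `bulk`.
#' @param sc An [expression_matrix()] (single-cell domain, `lognorm` layer).
#' @param dae_bulk,dae_sc [dae_config()]s for the two autoencoders;
#'   `input_dim` fields are overwritten with the shared gene count.
#' @param pred An [attention_config()]; its `bottleneck` must equal
#'   `dae_bulk$bottleneck` (which must equal `dae_sc$bottleneck`).
#' @param dann A [dann_config()].
#' @param pretrain_epochs,pretrain_lr Predictor pre-training schedule on the
#'   bulk latents (defaults 200 epochs, Adam `1e-3`).
#' @param warm_start_sc Initialize the single-cell autoencoder from the
#'   trained bulk one before its own denoising fit (default `TRUE`). This
#'   anchors the two latent spaces in a shared coordinate frame, which the
#'   MMD alignment then only has to refine; with independent initialization
#'   the two latent spaces differ by an arbitrary rotation that a
#'   distribution-matching penalty cannot reliably undo.
#' @param scale_genes Per-gene standardization within each domain before
#'   the autoencoders: `"zscore"` (default) subtracts each gene's mean and
#'   divides by its sd, removing the per-gene affine component of the
#'   bulk/single-cell gap; `"center"` subtracts the mean only; `"none"`
#'   disables it (useful when the domain gap itself is under study, e.g.
#'   in alignment ablations). The parameters are stored in the bundle and
#'   re-applied at prediction and attribution time.
#' @return A `transfer_result`: `model` (bundle with both DAEs, the
#'   predictor, configs, clusters and seed), `loss_trace` (per-epoch
#'   data.frame with class/mmd/regularizer/total), and `scores`
#'   (a predicted [response_labels()] for the cells).
#' @export
fit_transfer <- function(bulk, bulk_labels, sc, dae_bulk, dae_sc, pred, dann,
                         pretrain_epochs = 200, pretrain_lr = 1e-3,
                         warm_start_sc = TRUE,
                         scale_genes = c("zscore", "center", "none")) {
  scale_genes <- if (is.logical(scale_genes))
    (if (scale_genes) "zscore" else "none") else match.arg(scale_genes)
  stopifnot(inherits(bulk, "expression_matrix"),
            inherits(bulk_labels, "response_labels"),
            inherits(sc, "expression_matrix"),
            inherits(dae_bulk, "dae_config"), inherits(dae_sc, "dae_config"),
            inherits(pred, "attention_config"), inherits(dann, "dann_config"))
  if (dae_bulk$bottleneck != dae_sc$bottleneck ||
      pred$bottleneck != dae_bulk$bottleneck)
    stop("bottlenecks of both DAEs and the predictor must agree")
  al <- .align_genes(bulk, sc)
  Xg <- al$bulk$values; Xt <- al$sc$values
  scaling <- NULL
  if (scale_genes != "none") {
    sg <- .gene_scale(Xg, scale_genes); st <- .gene_scale(Xt, scale_genes)
    Xg <- sg$X; Xt <- st$X
    scaling <- list(bulk = sg[c("center", "scale")],
                    sc = st[c("center", "scale")])
  }
  yb <- bulk_labels$labels[match(rownames(Xg), bulk_labels$sample_ids)]
  if (any(is.na(yb))) stop("bulk_labels do not cover all bulk samples")
  dae_bulk$input_dim <- ncol(Xg); dae_sc$input_dim <- ncol(Xt)

  # Stage 1: bulk DAE + predictor pre-training
  mg <- fit_dae(Xg, dae_bulk)
  P <- predictor_init(pred)
  # the predictor learns from the encoder's noisy pass, matching the
  # corruption the autoencoder is trained to undo
  P <- fit_predictor(P, NULL, yb, epochs = pretrain_epochs,
                     learning_rate = pretrain_lr,
                     batch_size = dann$batch_size, seed = pred$seed,
                     encoder = mg, X = Xg)

  # Stage 2: single-cell DAE, one-off clustering, joint refinement
  mt <- fit_dae(Xt, dae_sc, init = if (warm_start_sc) mg else NULL)
  Zt <- encode(mt, Xt)$values
  clusters <- cluster_cells(Zt, resolution = dann$cluster_resolution,
                            n_neighbors = min(dann$cluster_neighbors,
                                              nrow(Zt) - 1),
                            seed = dann$seed)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(dann$seed)
  params <- list(enc_g = mg$encoder$layers, enc_t = mt$encoder$layers,
                 pred = .predictor_params(P))
  opt <- .adam_new(params, lr = dann$learning_rate)
  n_g <- nrow(Xg); n_t <- nrow(Xt)
  bs <- min(dann$batch_size, n_g, n_t)
  trace <- data.frame(epoch = integer(0), class = numeric(0),
                      mmd = numeric(0), regularizer = numeric(0),
                      total = numeric(0))

  for (epoch in seq_len(dann$epochs)) {
    ord_g <- sample(n_g); ord_t <- sample(n_t)
    n_steps <- max(1, floor(min(n_g, n_t) / bs))
    ep <- c(class = 0, mmd = 0, reg = 0, total = 0)
    for (step_i in seq_len(n_steps)) {
      ig <- ord_g[((step_i - 1) * bs + 1):(step_i * bs)]
      it <- ord_t[((step_i - 1) * bs + 1):(step_i * bs)]
      xb <- Xg[ig, , drop = FALSE]; yb_b <- yb[ig]
      xs <- Xt[it, , drop = FALSE]

      fe_g <- .mlp_forward(mg$encoder, xb)
      fe_t <- .mlp_forward(mt$encoder, xs)
      zb <- fe_g$out; zs <- fe_t$out

      fw <- .predictor_forward(P, zb, train = FALSE)
      class_loss <- classification_loss(fw$p, yb_b)
      mm <- .mmd_grad(zb, zs, kernel = dann$kernel,
                      bandwidths = dann$bandwidths)
      rg <- .cluster_reg_grad(zs, clusters[it])
      total <- dann_loss(class_loss, mm$value, rg$value, dann)
      if (!is.finite(total))
        stop("joint training diverged at epoch ", epoch,
             " (class=", class_loss, ", mmd=", mm$value,
             ", reg=", rg$value, ")")
      ep <- ep + c(class_loss, mm$value, rg$value, total)

      # gradients
      dlogit <- (fw$p - yb_b) / length(yb_b)
      bw <- .predictor_backward(P, fw, dlogit)
      dzb <- bw$dZ + dann$omega * mm$dX
      dzs <- dann$omega * mm$dY + dann$theta * rg$dZ
      bg <- .mlp_backward(mg$encoder, fe_g, dzb)
      bt <- .mlp_backward(mt$encoder, fe_t, dzs)
      stepr <- .adam_step(opt,
                          list(enc_g = mg$encoder$layers,
                               enc_t = mt$encoder$layers,
                               pred = .predictor_params(P)),
                          list(enc_g = bg$grads, enc_t = bt$grads,
                               pred = bw$grads))
      opt <- stepr$opt
      mg$encoder$layers <- stepr$params$enc_g
      mt$encoder$layers <- stepr$params$enc_t
      P <- .predictor_set_params(P, stepr$params$pred)
    }
    ep <- ep / n_steps
    trace <- rbind(trace, data.frame(epoch = epoch, class = ep[["class"]],
                                     mmd = ep[["mmd"]],
                                     regularizer = ep[["reg"]],
                                     total = ep[["total"]]))
  }

  # Stage 3: transfer inference on all cells
  scores <- predict_proba(P, encode(mt, Xt)$values)
  labels <- binarize_scores(scores)
  pred_labels <- response_labels(rownames(Xt), labels,
                                 provenance = "predicted", scores = scores)

  model <- structure(list(dae_bulk = mg, dae_sc = mt, predictor = P,
                          genes = al$genes, clusters = clusters,
                          scaling = scaling,
                          configs = list(dae_bulk = dae_bulk,
                                         dae_sc = dae_sc, pred = pred,
                                         dann = dann),
                          seed = dann$seed),
                     class = "model_bundle")
  structure(list(model = model, loss_trace = trace, scores = pred_labels),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %d cells scored | %d joint epochs | final total loss %.4g\n",
              length(x$scores$labels), nrow(x$loss_trace),
              if (nrow(x$loss_trace)) utils::tail(x$loss_trace$total, 1) else NA))
  invisible(x)
}

#' Score new cells with a trained transfer model
#'
#' @param model A `model_bundle` from [fit_transfer()].
#' @param sc An [expression_matrix()] whose genes cover the model's gene
#'   list (aligned by exact id match).
#' @return A predicted [response_labels()] with continuous scores.
#' @export
predict_transfer <- function(model, sc) {
  stopifnot(inherits(model, "model_bundle"), inherits(sc, "expression_matrix"))
  idx <- match(model$genes, sc$gene_ids)
  if (any(is.na(idx)))
    stop("single-cell matrix is missing ", sum(is.na(idx)),
         " of the model's genes")
  Xt <- sc$values[, idx, drop = FALSE]
  Xt <- .apply_scaling(Xt, model$scaling$sc)
  scores <- predict_proba(model$predictor, encode(model$dae_sc, Xt)$values)
  response_labels(sc$sample_ids, binarize_scores(scores),
                  provenance = "predicted", scores = scores)
}
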