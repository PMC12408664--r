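# Shared fixtures and a cache for trained pipelines (several tests probe
# different properties of the same trained model; training it once keeps
# the suite fast without coupling the tests).

.test_cache <- new.env(parent = emptyenv())

# Small counts matrix with controllable per-cell gene detection.
make_counts <- function(n_cells = 6, n_genes = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, 5), n_cells, n_genes)
  expression_matrix(m, paste0("c", seq_len(n_cells)),
                    paste0("g", seq_len(n_genes)),
                    domain = "single_cell", layer = "counts")
}

make_lognorm <- function(values, domain = "single_cell") {
  expression_matrix(values, rownames(values), colnames(values),
                    domain = domain, layer = "lognorm")
}

# Study conditions for the end-to-end recovery checks: the generator
# settings come from the recovery scenario (strong effect, unit domain
# shift); the training schedule is the package's small-study default.
train_transfer_run <- function(seed, domain_shift = 1, omega = 0.25,
                               scale_genes = "zscore") {
  key <- sprintf("run_%d_%g_%g_%s", seed, domain_shift, omega, scale_genes)
  if (!is.null(.test_cache[[key]])) return(.test_cache[[key]])
  sim <- simulate_paired(sim_config(n_genes = 300, n_bulk = 400,
                                    n_cells = 400, effect_size = 3,
                                    domain_shift = domain_shift,
                                    seed = seed))
  sc_ln <- normalize_log(sim$sc$X)
  bal <- balance_classes(sim$bulk$X, sim$bulk$y, method = "oversample",
                         seed = seed)
  dae_b <- dae_config(300, encoder_dims = 128, bottleneck = 16,
                      noise_rate = 0.3, dropout = 0.1, epochs = 150,
                      learning_rate = 1e-3, batch_size = 64, seed = seed)
  dae_s <- dae_config(300, encoder_dims = 128, bottleneck = 16,
                      noise_rate = 0.3, dropout = 0.1, epochs = 5,
                      learning_rate = 1e-4, batch_size = 64,
                      seed = seed + 1000)
  pred <- attention_config(16, n_heads = 2, n_tokens = 4,
                           predictor_dims = c(32), dropout = 0.1,
                           seed = seed)
  dann <- dann_config(omega = omega, theta = 0.1, epochs = 100,
                      batch_size = 256, learning_rate = 1e-4, seed = seed)
  res <- fit_transfer(bal$X, bal$y, sc_ln, dae_b, dae_s, pred, dann,
                      pretrain_epochs = 300, scale_genes = scale_genes)
  out <- list(sim = sim, sc_ln = sc_ln, res = res,
              auc = auc_roc(res$scores$scores, sim$sc$y$labels))
  .test_cache[[key]] <- out
  out
}

# A tiny trained model on easy data for fast structural tests.
tiny_transfer_run <- function() {
  if (!is.null(.test_cache$tiny)) return(.test_cache$tiny)
  sim <- simulate_paired(sim_config(n_genes = 60, n_bulk = 120,
                                    n_cells = 120, effect_size = 3,
                                    n_markers_per_class = 5,
                                    domain_shift = 0.5, seed = 11))
  sc_ln <- normalize_log(sim$sc$X)
  dae_b <- dae_config(60, encoder_dims = 32, bottleneck = 8,
                      noise_rate = 0.2, dropout = 0, epochs = 60,
                      learning_rate = 1e-3, batch_size = 32, seed = 11)
  dae_s <- dae_config(60, encoder_dims = 32, bottleneck = 8,
                      noise_rate = 0.2, dropout = 0, epochs = 10,
                      learning_rate = 1e-4, batch_size = 32, seed = 12)
  pred <- attention_config(8, n_heads = 2, n_tokens = 2,
                           predictor_dims = c(16), dropout = 0, seed = 11)
  dann <- dann_config(omega = 0.25, theta = 0.1, epochs = 20,
                      batch_size = 64, learning_rate = 1e-4, seed = 11)
  res <- fit_transfer(sim$bulk$X, sim$bulk$y, sc_ln, dae_b, dae_s, pred,
                      dann, pretrain_epochs = 120)
  .test_cache$tiny <- list(sim = sim, sc_ln = sc_ln, res = res)
  .test_cache$tiny
}
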