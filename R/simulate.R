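#' Simulation configuration for paired bulk / single-cell data
#'
#' Defines a linear-Gaussian latent model shared by the two domains: latent
#' factors drive gene expression through sparse loadings; one factor (the
#' sensitivity axis) determines the binary drug-response label; marker
#' genes load only on that axis. The single-cell domain adds a per-gene
#' affine domain shift, Bernoulli dropout and Poisson count noise, yielding
#' raw UMI-like counts that exercise QC and normalization.
#'
#' @param n_genes Number of genes (default 300).
#' @param n_bulk Number of bulk samples (default 400).
#' @param n_cells Number of single cells (default 400).
#' @param n_latent Latent factors, including the sensitivity axis
#'   (default 6).
#' @param effect_size Loading magnitude of marker genes on the sensitivity
#'   axis; separation of class means (default 3).
#' @param domain_shift Scale of the per-gene mean offset and log-scale
#'   distortion between domains (default 1).
#' @param imbalance Minority (sensitive) class share in `(0, 0.5]`
#'   (default 0.3).
#' @param n_markers_per_class Marker genes per class (default 10).
#' @param dropout_rate Single-cell zero-inflation probability (default 0.3).
#' @param seed Integer seed (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 300, n_bulk = 400, n_cells = 400,
                       n_latent = 6, effect_size = 3, domain_shift = 1,
                       imbalance = 0.3, n_markers_per_class = 10,
                       dropout_rate = 0.3, seed = 1) {
  stopifnot(n_genes >= 1, n_bulk >= 1, n_cells >= 1, n_latent >= 1,
            effect_size >= 0, domain_shift >= 0,
            imbalance > 0, imbalance < 1,
            n_markers_per_class >= 1,
            2 * n_markers_per_class <= n_genes,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_genes = as.integer(n_genes), n_bulk = as.integer(n_bulk),
                 n_cells = as.integer(n_cells),
                 n_latent = as.integer(n_latent),
                 effect_size = effect_size, domain_shift = domain_shift,
                 imbalance = imbalance,
                 n_markers_per_class = as.integer(n_markers_per_class),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a paired bulk / single-cell dataset with planted truth
#'
#' Both domains draw latent factors from the same standard-normal law; the
#' label is 1 (sensitive) when the sensitivity factor plus annotation noise
#' exceeds the threshold that yields the configured minority share.
#' Bulk expression is `baseline + loadings x factors + Gaussian noise` on a
#' log-like scale (clamped at zero). Single-cell expression applies the
#' same generative law, then a per-gene affine domain shift, and is
#' converted to counts via Poisson sampling with Bernoulli dropout.
#'
#' @param config A [sim_config()]. `simulate_imbalanced()` is a
#'   convenience wrapper fixing `imbalance = 0.1`.
#' @return A list with `bulk` (`X` lognorm-layer [expression_matrix()],
#'   `y` [response_labels()]), `sc` (`X` counts-layer matrix, `y` true
#'   labels), and `truth` (latent factors, marker lists, domain-shift
#'   parameters, label threshold).
#' @export
simulate_paired <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  G <- config$n_genes; L <- config$n_latent
  nb <- config$n_bulk; nc <- config$n_cells

  # planted markers: first axis = sensitivity; disjoint marker lists
  genes <- sprintf("g%03d", seq_len(G))
  sens_markers <- genes[seq_len(config$n_markers_per_class)]
  res_markers <- genes[config$n_markers_per_class +
                         seq_len(config$n_markers_per_class)]

  # sparse loadings: non-marker genes load on 1-2 of the nuisance factors
  # (2..L); the sensitivity axis (factor 1) reaches expression only through
  # the planted markers, so effect_size = 0 removes all label signal
  if (L < 2) stop("n_latent must be >= 2 (one sensitivity + nuisance axes)")
  W <- matrix(0, G, L)
  for (g in seq_len(G)) {
    k <- sample(1:2, 1)
    f <- if (L == 2) 2L else sample(2:L, k)
    W[g, f] <- stats::rnorm(length(f))
  }
  W[match(sens_markers, genes), ] <- 0
  W[match(res_markers, genes), ] <- 0
  W[match(sens_markers, genes), 1] <- config$effect_size
  W[match(res_markers, genes), 1] <- -config$effect_size

  baseline <- stats::rnorm(G, mean = 4, sd = 0.5)

  # labels from the sensitivity factor plus a little annotation noise (the
  # label is determined by the factor up to rare boundary flips); the
  # threshold is the empirical quantile, so class counts hit the target
  # share tightly
  tau <- 0.1
  draw_domain <- function(n, prefix) {
    Z <- matrix(stats::rnorm(n * L), n, L)
    score <- Z[, 1] + stats::rnorm(n, sd = tau)
    thr <- stats::quantile(score, 1 - config$imbalance, type = 1,
                           names = FALSE)
    y <- as.integer(score > thr)
    S <- sweep(Z %*% t(W), 2, baseline, "+") +
      matrix(stats::rnorm(n * G, sd = 0.5), n, G)
    rownames(S) <- sprintf("%s%04d", prefix, seq_len(n))
    list(Z = Z, y = y, S = S, thr = thr)
  }
  b <- draw_domain(nb, "cl")
  s <- draw_domain(nc, "cell")
  if (length(unique(b$y)) < 2 || length(unique(s$y)) < 2)
    stop("simulated labels collapsed to one class; infeasible imbalance ",
         "for this sample size")

  # per-gene affine domain shift applied to the single-cell signal
  shift_mu <- stats::rnorm(G, sd = config$domain_shift * 0.5)
  shift_sc <- exp(stats::rnorm(G, sd = config$domain_shift * 0.2))
  S_sc <- sweep(sweep(s$S, 2, shift_sc, "*"), 2, shift_mu, "+")

  # counts: Poisson around the exponentiated log-signal, with dropout
  lambda <- expm1(pmax(S_sc, 0)) / 20
  counts <- matrix(stats::rpois(nc * G, lambda), nc, G)
  if (config$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(nc * G, 1, 1 - config$dropout_rate), nc, G)
    counts <- counts * keep
  }
  rownames(counts) <- rownames(s$S)

  bulk_X <- expression_matrix(pmax(b$S, 0), rownames(b$S), genes,
                              domain = "bulk", layer = "lognorm")
  bulk_y <- response_labels(rownames(b$S), b$y, provenance = "ground_truth")
  sc_X <- expression_matrix(counts, rownames(counts), genes,
                            domain = "single_cell", layer = "counts")
  sc_y <- response_labels(rownames(counts), s$y,
                          provenance = "ground_truth")
  truth <- list(bulk_factors = b$Z, sc_factors = s$Z,
                sens_markers = sens_markers, res_markers = res_markers,
                loadings = W, baseline = baseline,
                shift_mu = shift_mu, shift_scale = shift_sc,
                label_threshold = c(bulk = b$thr, sc = s$thr))
  list(bulk = list(X = bulk_X, y = bulk_y),
       sc = list(X = sc_X, y = sc_y),
       truth = truth)
}

#' @rdname simulate_paired
#' @param ... Overrides forwarded to [sim_config()] (besides `imbalance`).
#' @export
simulate_imbalanced <- function(...) {
  simulate_paired(sim_config(imbalance = 0.1, ...))
}
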