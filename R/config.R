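#' Default configuration tree
#'
#' Nested defaults for every stage. The autoencoder/predictor defaults are
#' the bulk-scale settings (bottleneck 512, encoder 256/128, predictor
#' 128/64, dropout 0.3, 500 epochs); small studies override them.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    io = list(orientation = "samples_x_genes"),
    qc = list(min_genes = 200L, min_cells = 3L, max_mito_frac = 0.10,
              mito_prefix = "MT-"),
    balance = list(method = "smote", k_neighbors = 5L),
    split = list(test_frac = 0.20, seed = 1L),
    dae = list(bottleneck = 512L, encoder_dims = c(256L, 128L),
               noise_rate = 0.2, dropout = 0.3, epochs = 500L,
               learning_rate = 1e-3),
    model = list(n_heads = 8L, n_tokens = 8L,
                 predictor_dims = c(128L, 64L), dropout = 0.3,
                 epochs = 200L, learning_rate = 1e-3),
    dann = list(omega = 0.25, theta = 0.1, epochs = 30L, batch_size = 64L,
                learning_rate = 1e-3, cluster_resolution = 1,
                cluster_neighbors = 15L),
    sim = list(n_genes = 300L, n_bulk = 400L, n_cells = 400L,
               n_latent = 6L, effect_size = 3, domain_shift = 1,
               imbalance = 0.3, n_markers_per_class = 10L,
               dropout_rate = 0.3),
    seed = 1L
  )
}

#' Load and validate a configuration file
#'
#' Reads YAML (or JSON, a YAML subset), overlays it on [default_config()],
#' rejects unknown keys, and enforces cross-field constraints (the
#' bottleneck must factor into tokens, and the token width into heads).
#' An empty file yields the full defaults.
#'
#' @param path Path to a YAML/JSON config file, or `NULL` for pure
#'   defaults.
#' @return The validated nested config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- .merge_config(cfg, user, prefix = character(0))
  }
  .validate_config(cfg)
  cfg
}

.merge_config <- function(base, user, prefix) {
  if (!is.list(user)) stop("config section '", paste(prefix, collapse = "."),
                           "' must be a mapping")
  for (key in names(user)) {
    full <- paste(c(prefix, key), collapse = ".")
    if (!key %in% names(base))
      stop("unknown config key: '", full, "'")
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- .merge_config(base[[key]], user[[key]], c(prefix, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

.validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("config invalid: ", msg)
  chk(cfg$qc$min_genes >= 0, "qc.min_genes must be >= 0")
  chk(cfg$qc$min_cells >= 0, "qc.min_cells must be >= 0")
  chk(cfg$qc$max_mito_frac >= 0 && cfg$qc$max_mito_frac <= 1,
      "qc.max_mito_frac must lie in [0, 1]")
  chk(cfg$balance$method %in% c("smote", "oversample", "none"),
      "balance.method must be smote/oversample/none")
  chk(cfg$split$test_frac > 0 && cfg$split$test_frac < 1,
      "split.test_frac must lie in (0, 1)")
  chk(cfg$dae$bottleneck >= 1, "dae.bottleneck must be >= 1")
  chk(cfg$dae$noise_rate >= 0 && cfg$dae$noise_rate <= 1,
      "dae.noise_rate must lie in [0, 1]")
  chk(cfg$model$n_heads >= 0, "model.n_heads must be >= 0")
  chk(cfg$dae$bottleneck %% cfg$model$n_tokens == 0,
      paste0("dae.bottleneck (", cfg$dae$bottleneck,
             ") must be divisible by model.n_tokens (",
             cfg$model$n_tokens, ")"))
  token_dim <- cfg$dae$bottleneck %/% cfg$model$n_tokens
  if (cfg$model$n_heads > 0)
    chk(token_dim %% cfg$model$n_heads == 0,
        paste0("token width (", token_dim,
               ") must be divisible by model.n_heads (",
               cfg$model$n_heads, ")"))
  chk(cfg$dann$omega >= 0 && cfg$dann$theta >= 0,
      "dann.omega and dann.theta must be >= 0")
  invisible(cfg)
}

#' Deterministic per-stage seed derived from the master seed
#'
#' Every randomized stage consumes `stage_seed(master, "<stage>")`, so
#' stages can be re-run independently and still reproduce the pipeline.
#'
#' @param master Master integer seed.
#' @param stage Stage name (character).
#' @return An integer in `[0, 2^31)`.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}
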