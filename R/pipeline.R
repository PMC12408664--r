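# Pipeline runner behind the command-line wrapper (inst/cli/scdrp.R).
# Each command reads/writes plain files, so a run is fully described by its
# manifest (command + args + config + seeds + input checksums) and can be
# replayed bit-for-bit.

#' Run a pipeline command
#'
#' File-level entry points mirroring the package functions:
#' \describe{
#'   \item{simulate}{Write a synthetic paired dataset (`bulk.csv`,
#'     `bulk_labels.csv`, `sc.csv`, `sc_labels.csv`, `truth.json`).}
#'   \item{transfer}{Full training: bulk DAE + predictor pre-training,
#'     single-cell DAE, joint refinement; writes `model.rds`,
#'     `scores.csv`, `loss_trace.csv`.}
#'   \item{predict}{Score a single-cell matrix with a saved model; writes
#'     `scores.csv` (cell_id, score, label).}
#'   \item{score-genes}{DEG-based per-cell gene scores from predicted and
#'     true labels; writes `genescores.csv`.}
#'   \item{keygenes}{Integrated-gradient key genes; writes `keygenes.csv`
#'     (gene, class, rank).}
#'   \item{evaluate}{Metrics of a score file against truth labels; writes
#'     `report.json`.}
#'   \item{sweep}{Attention-head sweep on the bulk latents; writes
#'     `sweep.csv`.}
#' }
#'
#' @param command One of the commands above.
#' @param args Named list of file paths and overrides; see details of each
#'   command in the CLI help. Common keys: `out` (output directory),
#'   `config` (YAML path), `seed` (master seed overriding the config).
#' @return Invisibly, a list of written artifact paths (plus the manifest).
#' @export
run_pipeline <- function(command = c("simulate", "transfer", "predict",
                                     "score-genes", "keygenes", "evaluate",
                                     "sweep"),
                         args = list()) {
  command <- match.arg(command)
  cfg <- load_config(args$config)
  if (!is.null(args$seed)) cfg$seed <- as.integer(args$seed)
  out_dir <- args$out
  if (is.null(out_dir)) stop("args$out (output directory) is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  artifacts <- switch(
    command,
    "simulate" = .cmd_simulate(cfg, args, out_dir),
    "transfer" = .cmd_transfer(cfg, args, out_dir),
    "predict" = .cmd_predict(cfg, args, out_dir),
    "score-genes" = .cmd_score_genes(cfg, args, out_dir),
    "keygenes" = .cmd_keygenes(cfg, args, out_dir),
    "evaluate" = .cmd_evaluate(cfg, args, out_dir),
    "sweep" = .cmd_sweep(cfg, args, out_dir))

  manifest <- write_manifest(out_dir, command, args, cfg,
                             elapsed = as.numeric(difftime(Sys.time(), t0,
                                                           units = "secs")))
  invisible(c(artifacts, manifest = manifest))
}

.read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  response_labels(df[[1]], df[[2]], provenance = "ground_truth")
}

.write_labels_csv <- function(y, path) {
  utils::write.csv(data.frame(sample_id = y$sample_ids, label = y$labels),
                   path, row.names = FALSE, quote = FALSE)
}

.cmd_simulate <- function(cfg, args, out_dir) {
  sc_cfg <- do.call(sim_config, c(cfg$sim, list(seed = stage_seed(cfg$seed,
                                                                  "simulate"))))
  sim <- simulate_paired(sc_cfg)
  paths <- file.path(out_dir, c("bulk.csv", "bulk_labels.csv", "sc.csv",
                                "sc_labels.csv", "truth.json"))
  write_expression(sim$bulk$X, paths[1], "csv")
  .write_labels_csv(sim$bulk$y, paths[2])
  write_expression(sim$sc$X, paths[3], "csv")
  .write_labels_csv(sim$sc$y, paths[4])
  jsonlite::write_json(list(sens_markers = sim$truth$sens_markers,
                            res_markers = sim$truth$res_markers,
                            label_threshold = sim$truth$label_threshold),
                       paths[5], auto_unbox = TRUE, digits = NA)
  as.list(paths)
}

# shared preprocessing: read bulk (lognorm layer) and sc (counts), QC +
# normalize sc, balance the bulk training data
.load_pair <- function(cfg, args) {
  bulk <- read_expression(args$bulk, domain = "bulk", layer = "lognorm")
  bulk_y <- .read_labels_csv(args$bulk_labels)
  sc <- read_expression(args$sc, domain = "single_cell", layer = "counts")
  qc <- qc_filter(sc, min_genes_per_cell = cfg$qc$min_genes,
                  min_cells_per_gene = cfg$qc$min_cells,
                  max_mito_frac = cfg$qc$max_mito_frac,
                  mito_gene_prefix = cfg$qc$mito_prefix)
  sc_ln <- normalize_log(qc$X)
  list(bulk = bulk, bulk_y = bulk_y, sc = sc_ln, qc_report = qc$report)
}

.cmd_transfer <- function(cfg, args, out_dir) {
  dat <- .load_pair(cfg, args)
  bal <- balance_classes(dat$bulk, dat$bulk_y, method = cfg$balance$method,
                         k_neighbors = cfg$balance$k_neighbors,
                         seed = stage_seed(cfg$seed, "balance"))
  genes <- intersect(bal$X$gene_ids, dat$sc$gene_ids)
  dae_b <- do.call(dae_config,
                   c(list(input_dim = length(genes)), cfg$dae,
                     list(seed = stage_seed(cfg$seed, "dae_bulk"))))
  dae_s <- do.call(dae_config,
                   c(list(input_dim = length(genes)), cfg$dae,
                     list(seed = stage_seed(cfg$seed, "dae_sc"))))
  pred <- attention_config(cfg$dae$bottleneck, n_heads = cfg$model$n_heads,
                           n_tokens = cfg$model$n_tokens,
                           predictor_dims = cfg$model$predictor_dims,
                           dropout = cfg$model$dropout,
                           seed = stage_seed(cfg$seed, "predictor"))
  dann <- do.call(dann_config,
                  c(cfg$dann, list(seed = stage_seed(cfg$seed, "dann"))))
  res <- fit_transfer(bal$X, bal$y, dat$sc, dae_b, dae_s, pred, dann,
                      pretrain_epochs = cfg$model$epochs,
                      pretrain_lr = cfg$model$learning_rate)
  paths <- file.path(out_dir, c("model.rds", "scores.csv",
                                "loss_trace.csv"))
  save_model(res$model, paths[1])
  utils::write.csv(data.frame(cell_id = res$scores$sample_ids,
                              score = res$scores$scores,
                              label = res$scores$labels),
                   paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(res$loss_trace, paths[3], row.names = FALSE,
                   quote = FALSE)
  as.list(paths)
}

.load_scored_sc <- function(cfg, args) {
  sc <- read_expression(args$sc, domain = "single_cell", layer = "counts")
  qc <- qc_filter(sc, min_genes_per_cell = cfg$qc$min_genes,
                  min_cells_per_gene = cfg$qc$min_cells,
                  max_mito_frac = cfg$qc$max_mito_frac,
                  mito_gene_prefix = cfg$qc$mito_prefix)
  normalize_log(qc$X)
}

.cmd_predict <- function(cfg, args, out_dir) {
  if (is.null(args$model) || !file.exists(args$model))
    stop("model bundle not found: ",
         if (is.null(args$model)) "(no --model given)" else args$model)
  model <- load_model(args$model)
  sc <- .load_scored_sc(cfg, args)
  y <- predict_transfer(model, sc)
  path <- file.path(out_dir, "scores.csv")
  utils::write.csv(data.frame(cell_id = y$sample_ids, score = y$scores,
                              label = y$labels),
                   path, row.names = FALSE, quote = FALSE)
  list(path)
}

.cmd_score_genes <- function(cfg, args, out_dir) {
  sc <- .load_scored_sc(cfg, args)
  scores_df <- utils::read.csv(args$scores, stringsAsFactors = FALSE)
  keep <- match(sc$sample_ids, scores_df$cell_id)
  if (any(is.na(keep))) stop("scores.csv does not cover all QC-passing cells")
  pred_labels <- scores_df$label[keep]
  degs <- find_degs(sc, pred_labels)
  sens <- gene_set_score(sc, degs$sensitive_up, basis = "predicted_labels")
  res <- gene_set_score(sc, degs$resistant_up, basis = "predicted_labels")
  path <- file.path(out_dir, "genescores.csv")
  utils::write.csv(data.frame(cell_id = sc$sample_ids,
                              sensitive_score = sens$scores,
                              resistant_score = res$scores),
                   path, row.names = FALSE, quote = FALSE)
  list(path)
}

.cmd_keygenes <- function(cfg, args, out_dir) {
  if (is.null(args$model) || !file.exists(args$model))
    stop("model bundle not found")
  model <- load_model(args$model)
  sc <- .load_scored_sc(cfg, args)
  n_top <- if (is.null(args$top)) 100L else as.integer(args$top)
  att <- integrated_gradients(model, sc, n_top = n_top)
  kg <- rbind(
    data.frame(gene = att$key_genes$sensitive, class = "sensitive",
               rank = seq_along(att$key_genes$sensitive)),
    data.frame(gene = att$key_genes$resistant, class = "resistant",
               rank = seq_along(att$key_genes$resistant)))
  path <- file.path(out_dir, "keygenes.csv")
  utils::write.csv(kg, path, row.names = FALSE, quote = FALSE)
  list(path)
}

.cmd_evaluate <- function(cfg, args, out_dir) {
  scores_df <- utils::read.csv(args$scores, stringsAsFactors = FALSE)
  truth <- .read_labels_csv(args$truth)
  keep <- match(scores_df$cell_id, truth$sample_ids)
  if (any(is.na(keep))) stop("truth labels do not cover all scored cells")
  ev <- evaluate_scores(scores_df$score, truth$labels[keep])
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(ev, path, auto_unbox = TRUE, digits = NA)
  list(path)
}

.cmd_sweep <- function(cfg, args, out_dir) {
  dat <- .load_pair(cfg, args)
  genes <- intersect(dat$bulk$gene_ids, dat$sc$gene_ids)
  dae_b <- do.call(dae_config,
                   c(list(input_dim = length(genes)), cfg$dae,
                     list(seed = stage_seed(cfg$seed, "dae_bulk"))))
  al <- .align_genes(dat$bulk, dat$sc)
  mg <- fit_dae(al$bulk$values, dae_b)
  Z <- encode(mg, al$bulk$values)$values
  yb <- dat$bulk_y$labels[match(rownames(Z), dat$bulk_y$sample_ids)]
  heads <- if (is.null(args$heads)) c(0, 2, 4, 8, 16, 32) else args$heads
  tab <- head_sweep(Z, yb, heads = heads, n_tokens = cfg$model$n_tokens,
                    predictor_dims = cfg$model$predictor_dims,
                    dropout = cfg$model$dropout,
                    epochs = cfg$model$epochs,
                    learning_rate = cfg$model$learning_rate,
                    seed = stage_seed(cfg$seed, "sweep"))
  path <- file.path(out_dir, "sweep.csv")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  list(path)
}

#' Write a reproducibility manifest
#'
#' Records everything needed to replay a run: command, arguments, the full
#' config snapshot, master seed, package version, and md5 checksums of the
#' input files.
#'
#' @param out_dir Output directory of the run.
#' @param command,args,cfg The command executed with its arguments and
#'   validated config.
#' @param elapsed Wall-clock seconds.
#' @return Path of the written `manifest.json`.
#' @export
write_manifest <- function(out_dir, command, args, cfg, elapsed = NA) {
  file_args <- args[vapply(args, function(a)
    is.character(a) && length(a) == 1 && file.exists(a) && !dir.exists(a),
    logical(1))]
  checksums <- if (length(file_args))
    as.list(tools::md5sum(unlist(file_args))) else list()
  manifest <- list(command = command,
                   args = args[setdiff(names(args), "config_obj")],
                   config = cfg,
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("scdrp")),
                   input_checksums = checksums,
                   elapsed_seconds = elapsed)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

#' Replay a run from its manifest
#'
#' Re-executes the recorded command with the recorded arguments and config
#' into `out_dir`; with the original inputs this reproduces the artifacts
#' bit-for-bit.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Output directory for the replay (default: a fresh
#'   directory next to the manifest).
#' @return Invisibly, the artifact list from [run_pipeline()].
#' @export
replay_manifest <- function(manifest_path, out_dir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(out_dir))
    out_dir <- file.path(dirname(manifest_path), "replay")
  args <- as.list(m$args)
  args$out <- out_dir
  # write the recorded config snapshot and point the run at it
  cfg_path <- file.path(out_dir, "config_snapshot.yaml")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(m$config, cfg_path)
  args$config <- cfg_path
  args$seed <- m$seed
  run_pipeline(m$command, args)
}
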