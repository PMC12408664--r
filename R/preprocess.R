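#' Quality-control filtering of a single-cell count matrix
#'
#' Applies the standard droplet-QC rules, in a fixed order: (1) remove cells
#' with fewer than `min_genes_per_cell` detected genes (empty droplets),
#' (2) remove genes detected in fewer than `min_cells_per_gene` of the
#' remaining cells, (3) remove cells whose mitochondrial share of total
#' counts exceeds `max_mito_frac` (stressed or dying cells). All thresholds
#' use strict inequalities: a cell with exactly `min_genes_per_cell` genes,
#' or a gene present in exactly `min_cells_per_gene` cells, is retained; a
#' cell at exactly `max_mito_frac` mitochondrial share is retained.
#'
#' @param X An [expression_matrix()] with `layer == "counts"`.
#' @param min_genes_per_cell Cells with detected-gene count below this are
#'   removed (default 200).
#' @param min_cells_per_gene Genes detected in fewer than this many cells
#'   are removed (default 3).
#' @param max_mito_frac Cells with mitochondrial count fraction above this
#'   are removed (default 0.10).
#' @param mito_gene_prefix Gene-id prefix identifying mitochondrial genes,
#'   matched case-insensitively (default `"MT-"`; use `"mt-"` conventions
#'   freely, matching ignores case).
#' @return A list with `X` (filtered [expression_matrix()]) and `report`,
#'   a `qc_report` recording removals per rule and the thresholds used.
#' @export
qc_filter <- function(X, min_genes_per_cell = 200, min_cells_per_gene = 3,
                      max_mito_frac = 0.10, mito_gene_prefix = "MT-") {
  stopifnot(inherits(X, "expression_matrix"))
  if (X$layer != "counts")
    stop("qc_filter expects the raw 'counts' layer, got '", X$layer, "'")
  v <- X$values
  n_in_cells <- nrow(v); n_in_genes <- ncol(v)

  # (1) cells by detected genes
  genes_per_cell <- rowSums(v > 0)
  keep_cells <- genes_per_cell >= min_genes_per_cell
  removed_low_genes <- sum(!keep_cells)
  v <- v[keep_cells, , drop = FALSE]

  # (2) genes by detecting cells
  cells_per_gene <- colSums(v > 0)
  keep_genes <- cells_per_gene >= min_cells_per_gene
  removed_low_cells <- sum(!keep_genes)
  v <- v[, keep_genes, drop = FALSE]

  # (3) cells by mitochondrial fraction
  is_mito <- startsWith(toupper(colnames(v)), toupper(mito_gene_prefix))
  totals <- rowSums(v)
  mito_frac <- if (any(is_mito))
    rowSums(v[, is_mito, drop = FALSE]) / pmax(totals, 1) else
    rep(0, nrow(v))
  keep_mito <- mito_frac <= max_mito_frac
  removed_mito <- sum(!keep_mito)
  v <- v[keep_mito, , drop = FALSE]

  if (nrow(v) == 0) stop("empty matrix after QC: all cells removed")

  report <- structure(list(
    cells_removed_low_genes = removed_low_genes,
    genes_removed_low_cells = removed_low_cells,
    cells_removed_mito = removed_mito,
    n_cells_in = n_in_cells, n_genes_in = n_in_genes,
    n_cells_out = nrow(v), n_genes_out = ncol(v),
    thresholds = list(min_genes_per_cell = min_genes_per_cell,
                      min_cells_per_gene = min_cells_per_gene,
                      max_mito_frac = max_mito_frac,
                      mito_gene_prefix = mito_gene_prefix),
    order = c("cells_by_genes", "genes_by_cells", "mito")),
    class = "qc_report")

  list(X = expression_matrix(v, rownames(v), colnames(v),
                             domain = X$domain, layer = "counts"),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> cells %d -> %d, genes %d -> %d\n",
                     "  removed: %d low-gene cells, %d low-cell genes, ",
                     "%d high-mito cells\n"),
              x$n_cells_in, x$n_cells_out, x$n_genes_in, x$n_genes_out,
              x$cells_removed_low_genes, x$genes_removed_low_cells,
              x$cells_removed_mito))
  invisible(x)
}

#' Library-size normalization and log transform
#'
#' Scales each cell to `target_sum` total counts, then applies
#' `log1p` elementwise. This is the usual UMI depth normalization: after
#' the transform, `rowSums(expm1(out))` equals `target_sum` for every cell.
#'
#' @param X An [expression_matrix()] with `layer == "counts"`; every cell
#'   must have a positive total (run [qc_filter()] first).
#' @param target_sum Per-cell total after scaling (default `1e4`).
#' @return An [expression_matrix()] with `layer == "lognorm"`.
#' @export
normalize_log <- function(X, target_sum = 1e4) {
  stopifnot(inherits(X, "expression_matrix"))
  if (X$layer != "counts")
    stop("normalize_log expects the raw 'counts' layer")
  totals <- rowSums(X$values)
  if (any(totals <= 0))
    stop("cells with zero total counts present; run qc_filter() first")
  v <- log1p(X$values / totals * target_sum)
  expression_matrix(v, X$sample_ids, X$gene_ids, domain = X$domain,
                    layer = "lognorm")
}

#' Balance class sizes by SMOTE or random oversampling
#'
#' Augments the minority class until both classes have equal counts.
#' `"oversample"` duplicates minority rows drawn uniformly with replacement.
#' `"smote"` synthesizes new minority samples by interpolation: for a random
#' minority sample x with a neighbour x_nn drawn from its `k_neighbors`
#' nearest minority neighbours (Euclidean distance), the synthetic sample is
#' `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`. Majority rows are never
#' touched; balancing belongs on training data only.
#'
#' @param X An [expression_matrix()].
#' @param y A [response_labels()] aligned with `X` (same sample order).
#' @param method `"smote"`, `"oversample"` or `"none"`.
#' @param k_neighbors Neighbourhood size for SMOTE (default 5); the minority
#'   class must have more than `k_neighbors` members.
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @return A list with balanced `X` and `y` (synthetic/duplicated samples get
#'   suffixed ids).
#' @export
balance_classes <- function(X, y, method = c("smote", "oversample", "none"),
                            k_neighbors = 5, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(X, "expression_matrix"), inherits(y, "response_labels"))
  if (!identical(X$sample_ids, y$sample_ids))
    stop("X and y sample_ids must be aligned")
  counts <- table(factor(y$labels, levels = c(0, 1)))
  if (any(counts == 0)) stop("both classes must be present to balance")
  if (method == "none" || counts[1] == counts[2]) return(list(X = X, y = y))

  if (method == "smote" && X$layer == "counts")
    stop("SMOTE interpolates expression values and cannot produce a raw ",
         "counts layer; normalize first (normalize_log) or use ",
         "method = 'oversample'")
  minority <- as.integer(names(counts)[which.min(counts)])
  n_new <- abs(diff(as.integer(counts)))
  idx_min <- which(y$labels == minority)
  Xm <- X$values[idx_min, , drop = FALSE]

  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  if (method == "oversample") {
    pick <- sample(length(idx_min), n_new, replace = TRUE)
    new_rows <- Xm[pick, , drop = FALSE]
  } else {
    if (length(idx_min) <= k_neighbors)
      stop("SMOTE needs minority count > k_neighbors (", k_neighbors,
           "); use a smaller k or method = 'oversample'")
    d <- as.matrix(stats::dist(Xm))
    diag(d) <- Inf
    # k nearest minority neighbours of each minority sample
    nn_idx <- apply(d, 1, function(r) order(r)[seq_len(k_neighbors)])
    nn_idx <- matrix(nn_idx, nrow = k_neighbors)
    base <- sample(length(idx_min), n_new, replace = TRUE)
    which_nn <- sample(k_neighbors, n_new, replace = TRUE)
    u <- stats::runif(n_new)
    nn <- nn_idx[cbind(which_nn, base)]
    new_rows <- Xm[base, , drop = FALSE] +
      u * (Xm[nn, , drop = FALSE] - Xm[base, , drop = FALSE])
  }
  rownames(new_rows) <- sprintf("%s_%s%d", X$sample_ids[idx_min][
    if (method == "oversample") pick else base],
    if (method == "oversample") "dup" else "syn", seq_len(n_new))

  v <- rbind(X$values, new_rows)
  labs <- c(y$labels, rep(minority, n_new))
  Xb <- expression_matrix(pmax(v, 0), rownames(v), X$gene_ids,
                          domain = X$domain, layer = X$layer)
  yb <- response_labels(rownames(v), labs, provenance = y$provenance)
  list(X = Xb, y = yb)
}

#' Stratified train/test split
#'
#' @param X An [expression_matrix()].
#' @param y A [response_labels()] aligned with `X`.
#' @param test_frac Fraction of samples assigned to the test set
#'   (default 0.20); the test size is `round(test_frac * n)`.
#' @param stratified Preserve the class ratio within rounding (default TRUE).
#' @param seed Integer seed.
#' @return A list with `train` and `test`, each a list of `X` and `y`, plus
#'   the index vectors `train_idx` / `test_idx`.
#' @export
split_train_test <- function(X, y, test_frac = 0.20, stratified = TRUE,
                             seed = 1) {
  stopifnot(inherits(X, "expression_matrix"), inherits(y, "response_labels"))
  if (!identical(X$sample_ids, y$sample_ids))
    stop("X and y sample_ids must be aligned")
  n <- length(y$labels)
  if (test_frac <= 0 || test_frac >= 1)
    stop("test_frac must lie strictly in (0, 1)")
  if (n < 5) stop("need at least 5 samples to split")
  n_test <- round(test_frac * n)

  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  if (stratified) {
    if (length(unique(y$labels)) < 2)
      stop("stratified split needs both classes present")
    idx0 <- which(y$labels == 0); idx1 <- which(y$labels == 1)
    # allocate per-class test counts proportionally, fixing the total
    n1 <- round(test_frac * length(idx1))
    n0 <- n_test - n1
    n0 <- max(0, min(n0, length(idx0)))
    test_idx <- sort(c(sample(idx0, n0), sample(idx1, n1)))
  } else {
    test_idx <- sort(sample(n, n_test))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  subset_xy <- function(idx) {
    list(X = X[idx, seq_along(X$gene_ids)],
         y = response_labels(y$sample_ids[idx], y$labels[idx],
                             provenance = y$provenance))
  }
  c(list(train = subset_xy(train_idx), test = subset_xy(test_idx)),
    list(train_idx = train_idx, test_idx = test_idx))
}

# Save/restore .Random.seed so seeded operations do not disturb the
# caller's RNG stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
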