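#' Differentially expressed genes between predicted response classes
#'
#' Two-sided Wilcoxon rank-sum test per gene between the two label groups,
#' Benjamini-Hochberg adjusted; genes are ranked by adjusted p-value, ties
#' broken by absolute effect size (difference of class means on the log
#' scale). Returns the top genes per direction passing the effect-size
#' floor.
#'
#' @param X An [expression_matrix()] with `layer == "lognorm"`.
#' @param labels Binary vector aligned with rows of `X` (1 = sensitive).
#' @param n_top Maximum genes per direction (default 100).
#' @param min_abs_lfc Minimum absolute log-fold-change (class-mean
#'   difference) to report (default 0.25).
#' @return A list with `sensitive_up` and `resistant_up` (character
#'   vectors, ranked) and `table` (per-gene statistics).
#' @export
find_degs <- function(X, labels, n_top = 100, min_abs_lfc = 0.25) {
  stopifnot(inherits(X, "expression_matrix"))
  labels <- as.integer(labels)
  if (length(labels) != nrow(X$values)) stop("labels must align with rows")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 < 3 || n0 < 3)
    stop("each class needs at least 3 cells (got ", n1, " / ", n0, ")")
  v <- X$values
  i1 <- labels == 1
  lfc <- colMeans(v[i1, , drop = FALSE]) - colMeans(v[!i1, , drop = FALSE])
  pval <- vapply(seq_len(ncol(v)), function(j) {
    x1 <- v[i1, j]; x0 <- v[!i1, j]
    if (all(x1 == x1[1]) && all(x0 == x0[1]) && x1[1] == x0[1]) return(1)
    stats::wilcox.test(x1, x0, exact = FALSE)$p.value
  }, numeric(1))
  padj <- stats::p.adjust(pval, method = "BH")
  tab <- data.frame(gene = X$gene_ids, lfc = lfc, p = pval, padj = padj,
                    row.names = NULL)
  pick <- function(dir) {
    keep <- if (dir > 0) tab$lfc >= min_abs_lfc else tab$lfc <= -min_abs_lfc
    sub <- tab[keep, , drop = FALSE]
    sub <- sub[order(sub$padj, -abs(sub$lfc)), , drop = FALSE]
    utils::head(sub$gene, n_top)
  }
  list(sensitive_up = pick(+1), resistant_up = pick(-1), table = tab)
}

#' Per-cell gene-set score
#'
#' Summarizes a gene list per cell as the mean of per-gene z-scored
#' expression (z-scoring across cells). Constant genes get a z-score of 0.
#'
#' @param X An [expression_matrix()] with `layer == "lognorm"`.
#' @param gene_set Character vector of gene ids; must intersect the matrix
#'   genes.
#' @param basis Label provenance the set was derived from (recorded only):
#'   `"predicted_labels"` or `"true_labels"`.
#' @return A `gene_set_score` list: `cell_ids`, `scores` (one per cell),
#'   `gene_set` (the intersected set), `basis`.
#' @export
gene_set_score <- function(X, gene_set,
                           basis = c("predicted_labels", "true_labels")) {
  basis <- match.arg(basis)
  stopifnot(inherits(X, "expression_matrix"))
  gene_set <- intersect(as.character(gene_set), X$gene_ids)
  if (length(gene_set) == 0) stop("gene_set has empty intersection with matrix genes")
  v <- X$values[, gene_set, drop = FALSE]
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  zero_var <- sdv == 0
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance gene(s) scored as 0")
  sdv[zero_var] <- 1
  z <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  z[, zero_var] <- 0
  structure(list(cell_ids = X$sample_ids, scores = rowMeans(z),
                 gene_set = gene_set, basis = basis),
            class = "gene_set_score")
}

#' Pearson correlation between two per-cell score vectors
#'
#' @param pred_scores,true_scores `gene_set_score` objects over the same
#'   cells in the same order.
#' @return A list with `r` and `r_squared`.
#' @export
score_correlation <- function(pred_scores, true_scores) {
  stopifnot(inherits(pred_scores, "gene_set_score"),
            inherits(true_scores, "gene_set_score"))
  if (!identical(pred_scores$cell_ids, true_scores$cell_ids))
    stop("score vectors must cover the same cells in the same order")
  a <- pred_scores$scores; b <- true_scores$scores
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance in a score vector")
  r <- stats::cor(a, b)
  list(r = r, r_squared = r^2)
}

#' Random-gene-set null test for the predicted-vs-true score correlation
#'
#' The observed statistic is the Pearson correlation between per-cell
#' scores of the predicted-label DEG list and per-cell scores of the
#' true-label DEG list (same direction). Each of `n_trials` null draws
#' replaces the predicted list with a uniform random gene set of identical
#' size and recomputes the correlation against the same true-label scores.
#' The p-value uses the add-one permutation estimator
#' `p = (1 + #\{null_r >= observed_r\}) / (1 + n_trials)`, so it is never
#' exactly zero and `p < 0.001` is attainable with 1,000 trials.
#'
#' @param X An [expression_matrix()] (`lognorm`).
#' @param true_labels Binary ground-truth labels aligned with rows of `X`.
#' @param pred_labels Binary predicted labels aligned with rows of `X`
#'   (recorded; the predicted DEG list is passed as `deg_list`).
#' @param deg_list Character vector: the predicted-label DEG list under
#'   test (non-empty).
#' @param direction `"sensitive"` or `"resistant"`: which true-label DEG
#'   direction to correlate against.
#' @param n_trials Number of random gene sets (default 1000).
#' @param seed Integer seed.
#' @param n_top,min_abs_lfc Passed to [find_degs()] for the true-label list.
#' @return A list with `observed_r`, `null_rs` (length `n_trials`) and
#'   `p_value`.
#' @export
random_geneset_null <- function(X, true_labels, pred_labels, deg_list,
                                direction = c("sensitive", "resistant"),
                                n_trials = 1000, seed = 1,
                                n_top = 100, min_abs_lfc = 0.25) {
  direction <- match.arg(direction)
  deg_list <- intersect(as.character(deg_list), X$gene_ids)
  if (length(deg_list) == 0) stop("deg_list is empty")
  if (n_trials < 1) stop("n_trials must be >= 1")
  true_degs <- find_degs(X, true_labels, n_top = n_top,
                         min_abs_lfc = min_abs_lfc)
  ref_set <- if (direction == "sensitive") true_degs$sensitive_up else
    true_degs$resistant_up
  if (length(ref_set) == 0) stop("true-label DEG list is empty")
  true_vec <- gene_set_score(X, ref_set, basis = "true_labels")
  obs <- score_correlation(
    gene_set_score(X, deg_list, basis = "predicted_labels"), true_vec)$r

  # pre-compute the z-score matrix once; each trial is a column-mean
  v <- X$values
  mu <- colMeans(v); sdv <- apply(v, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  tv <- true_vec$scores
  k <- length(deg_list)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null_rs <- vapply(seq_len(n_trials), function(i) {
    g <- sample(ncol(z), k)
    s <- rowMeans(z[, g, drop = FALSE])
    if (stats::sd(s) == 0) 0 else stats::cor(s, tv)
  }, numeric(1))
  p <- (1 + sum(null_rs >= obs)) / (1 + n_trials)
  list(observed_r = obs, null_rs = null_rs, p_value = p)
}

#' Integrated-gradients attribution of the transfer model
#'
#' Path-integral attribution of the cell-level sensitivity score
#' `F(x) = P(E_t(x))` to each input gene:
#' `IG_i = (x_i - b_i) * mean_k dF/dx_i` evaluated along the straight path
#' from the baseline `b` to the cell `x` (Riemann approximation; the
#' default midpoint rule evaluates at `b + ((k - 0.5)/n)(x - b)`).
#' Satisfies completeness: the attributions of a cell sum to
#' `F(x) - F(b)` up to the discretization residual, which is checked and
#' stored per cell.
#'
#' @param model A `model_bundle` from [fit_transfer()].
#' @param X_cells Numeric matrix (cells x genes, aligned with the model's
#'   gene list) or an [expression_matrix()] covering those genes.
#' @param baseline Baseline expression vector in raw (unscaled) expression
#'   units, or `NULL` (default) for the origin of the model's input space:
#'   zero expression when the model does no gene standardization, the
#'   per-gene average profile when it standardizes (an "average cell"
#'   reference, which also keeps the integration path on-manifold so the
#'   completeness check converges at the default step count).
#' @param n_steps Riemann steps along the path (default 50). With
#'   `adaptive = TRUE` this is the starting resolution; cells whose
#'   completeness residual exceeds the tolerance are re-integrated at
#'   doubled step counts (up to `max_steps`), the standard adaptive
#'   refinement for a piecewise-smooth integrand (ReLU kinks).
#' @param adaptive Refine per cell until completeness holds
#'   (default TRUE).
#' @param max_steps Refinement cap per cell (default 12800).
#' @param rule `"midpoint"` (default), `"left"` or `"right"` Riemann rule.
#' @param n_top Key genes reported per class (default 100).
#' @return An `attribution_result`: `attributions` (cells x genes),
#'   `completeness_residual` (per cell, relative), `key_genes` (a list with
#'   ranked `sensitive` and `resistant` character vectors, by mean
#'   attribution magnitude within each predicted class), `n_steps`,
#'   `baseline`.
#' @export
integrated_gradients <- function(model, X_cells, baseline = NULL,
                                 n_steps = 50, adaptive = TRUE,
                                 max_steps = 12800,
                                 rule = c("midpoint", "left", "right"),
                                 n_top = 100) {
  rule <- match.arg(rule)
  stopifnot(inherits(model, "model_bundle"), n_steps >= 1)
  if (inherits(X_cells, "expression_matrix")) {
    idx <- match(model$genes, X_cells$gene_ids)
    if (any(is.na(idx))) stop("X_cells is missing model genes")
    Xm <- X_cells$values[, idx, drop = FALSE]
  } else {
    Xm <- as.matrix(X_cells)
    if (ncol(Xm) != length(model$genes))
      stop("ncol(X_cells) != number of model genes")
  }
  n <- nrow(Xm); p <- ncol(Xm)
  # the model may standardize genes internally; IG along the straight path
  # is invariant to this affine map, so work in the model's input space
  if (!is.null(baseline) && length(baseline) != p)
    stop("baseline width must equal gene count")
  if (!is.null(model$scaling)) {
    Xm <- .apply_scaling(Xm, model$scaling$sc)
    baseline <- if (is.null(baseline)) rep(0, p) else
      as.numeric((baseline - model$scaling$sc$center) /
                   model$scaling$sc$scale)
  } else if (is.null(baseline)) {
    baseline <- rep(0, p)
  }

  enc <- model$dae_sc$encoder
  P <- model$predictor
  f_and_grad <- function(M) {
    fe <- .mlp_forward(enc, M)
    fw <- .predictor_forward(P, fe$out, train = FALSE)
    dlogit <- fw$p * (1 - fw$p)          # dF/dlogit through the sigmoid
    bw <- .predictor_backward(P, fw, dlogit)
    be <- .mlp_backward(enc, fe, bw$dZ)
    list(f = fw$p, g = be$dX)
  }

  path_offsets <- function(k) switch(rule,
                                     midpoint = (seq_len(k) - 0.5) / k,
                                     left = (seq_len(k) - 1) / k,
                                     right = seq_len(k) / k)
  diffm <- sweep(Xm, 2, baseline, "-")
  integrate_cells <- function(rows, k) {
    acc <- matrix(0, length(rows), p)
    bm <- matrix(baseline, length(rows), p, byrow = TRUE)
    dm <- diffm[rows, , drop = FALSE]
    for (a in path_offsets(k)) acc <- acc + f_and_grad(bm + a * dm)$g
    dm * acc / k
  }
  fx <- f_and_grad(Xm)$f
  fb <- f_and_grad(matrix(baseline, 1, p))$f
  delta <- fx - fb
  tol <- 0.01 * abs(delta) + 1e-4

  ig <- integrate_cells(seq_len(n), n_steps)
  steps_used <- rep(n_steps, n)
  resid <- abs(rowSums(ig) - delta)
  if (adaptive) {
    k <- n_steps
    while (any(resid >= tol) && k < max_steps) {
      k <- 2 * k
      redo <- which(resid >= tol)
      ig[redo, ] <- integrate_cells(redo, k)
      steps_used[redo] <- k
      resid[redo] <- abs(rowSums(ig[redo, , drop = FALSE]) - delta[redo])
    }
  }
  rel_resid <- resid / pmax(abs(delta), 1e-12)

  pred_class <- binarize_scores(fx)
  rank_genes <- function(cls) {
    rows <- pred_class == cls
    if (!any(rows)) return(character(0))
    mag <- colMeans(abs(ig[rows, , drop = FALSE]))
    model$genes[order(mag, decreasing = TRUE)][seq_len(min(n_top, p))]
  }
  structure(list(attributions = `dimnames<-`(ig, list(rownames(Xm),
                                                      model$genes)),
                 completeness_residual = resid,
                 completeness_relative = rel_resid,
                 delta = delta,
                 key_genes = list(sensitive = rank_genes(1L),
                                  resistant = rank_genes(0L)),
                 n_steps = n_steps, steps_used = steps_used, rule = rule,
                 baseline = baseline),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %d cells x %d genes | %d %s steps | max |residual| %.3g\n",
              nrow(x$attributions), ncol(x$attributions), x$n_steps, x$rule,
              max(x$completeness_residual)))
  invisible(x)
}
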