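#' Thresholded classification metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 `2TP/(2TP+FP+FN)` for
#' the positive (sensitive) class at a fixed score threshold, plus the
#' confusion counts. Zero-denominator cases return 0 with a warning.
#'
#' @param scores Probabilities in `[0, 1]`.
#' @param labels Binary ground-truth labels aligned with `scores`.
#' @param threshold Decision threshold (default 0.5, ties to positive).
#' @return A list with `precision`, `recall`, `f1`, `tp`, `fp`, `fn`, `tn`,
#'   `threshold`.
#' @export
thresholded_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (0/0); reported as 0"); 0 }
    else num / den
  }
  list(precision = safe(tp, tp + fp, "precision"),
       recall = safe(tp, tp + fn, "recall"),
       f1 = safe(2 * tp, 2 * tp + fp + fn, "f1"),
       tp = tp, fp = fp, fn = fn, tn = tn, threshold = threshold)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie correction: the
#' probability that a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param scores Numeric scores (any monotone scale).
#' @param labels Binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision
#'
#' Step-wise area under the precision-recall curve,
#' `AP = sum_k (R_k - R_{k-1}) P_k` over descending-score thresholds with
#' `R_0 = 0`; tied scores are grouped at a single threshold.
#'
#' @inheritParams auc_roc
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels))
    stop("both classes must be present")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; r_prev <- 0
  for (t in thresholds) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

#' Full evaluation report
#'
#' @inheritParams thresholded_metrics
#' @return A list combining [thresholded_metrics()], [auc_roc()] and
#'   [average_precision()].
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  tm <- thresholded_metrics(scores, labels, threshold)
  c(tm, list(auc_roc = auc_roc(scores, labels),
             average_precision = average_precision(scores, labels)))
}

#' Repeated stratified cross-validation harness
#'
#' Splits samples into stratified folds, trains via a caller-supplied
#' closure, and reports per-metric mean and standard deviation across
#' independently seeded repeats.
#'
#' @param X An [expression_matrix()].
#' @param y A [response_labels()] aligned with `X`.
#' @param train_fn `function(X_train, y_train, seed)` returning a scorer
#'   `function(X_test)` that emits probabilities.
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Independent repeats with distinct seeds (default 10).
#' @param seed Master seed; repeat `r` uses `seed + r - 1`.
#' @param threshold Threshold for the thresholded metrics.
#' @return A list with `summary` (data.frame of metric, mean, sd) and
#'   `per_repeat` (matrix of repeat x metric means over folds).
#' @export
cross_validate <- function(X, y, train_fn, n_folds = 10, n_repeats = 10,
                           seed = 1, threshold = 0.5) {
  stopifnot(inherits(X, "expression_matrix"), inherits(y, "response_labels"))
  n <- length(y$labels)
  if (n < n_folds) stop("n < n_folds")
  if (min(table(y$labels)) < n_folds)
    stop("stratification infeasible: a class has fewer samples than folds")
  metric_names <- c("precision", "recall", "f1", "auc_roc",
                    "average_precision")
  per_repeat <- matrix(NA_real_, n_repeats, length(metric_names),
                       dimnames = list(NULL, metric_names))
  old <- .save_rng(); on.exit(.restore_rng(old))
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r - 1)
    fold <- integer(n)
    for (cls in unique(y$labels)) {
      idx <- sample(which(y$labels == cls))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
    fold_metrics <- matrix(NA_real_, n_folds, length(metric_names))
    for (f in seq_len(n_folds)) {
      te <- which(fold == f); tr <- which(fold != f)
      scorer <- train_fn(X[tr, seq_along(X$gene_ids)],
                         response_labels(y$sample_ids[tr], y$labels[tr],
                                         provenance = y$provenance),
                         seed = seed + r - 1)
      s <- scorer(X[te, seq_along(X$gene_ids)])
      ev <- evaluate_scores(s, y$labels[te], threshold)
      fold_metrics[f, ] <- unlist(ev[metric_names])
    }
    per_repeat[r, ] <- colMeans(fold_metrics)
  }
  summary <- data.frame(metric = metric_names,
                        mean = colMeans(per_repeat),
                        sd = apply(per_repeat, 2, stats::sd),
                        row.names = NULL)
  list(summary = summary, per_repeat = per_repeat)
}

#' Attention-head sweep
#'
#' Trains and evaluates one predictor pipeline per attention-head count on
#' identical data splits and seeds, so metric differences are attributable
#' to the head count alone. Head counts that do not divide the token width
#' are skipped with a warning and marked in the table.
#'
#' @param Z Latent matrix (samples x bottleneck) to train on, e.g. from
#'   [encode()].
#' @param labels Binary labels aligned with rows of `Z`.
#' @param heads Head counts to sweep (default `c(0, 2, 4, 8, 16, 32)`).
#' @param n_tokens Tokenization of the latent vector (default 8).
#' @param predictor_dims,dropout,epochs,learning_rate,test_frac,seed
#'   Pipeline settings shared by every arm.
#' @return A data.frame with one row per requested head count: metrics on
#'   the held-out split, or `NA` with `skipped = TRUE` for invalid counts.
#' @export
head_sweep <- function(Z, labels, heads = c(0, 2, 4, 8, 16, 32),
                       n_tokens = 8, predictor_dims = c(64, 32),
                       dropout = 0.2, epochs = 150, learning_rate = 1e-3,
                       test_frac = 0.2, seed = 1) {
  Zm <- .as_latent(Z)
  labels <- as.integer(labels)
  stopifnot(nrow(Zm) == length(labels))
  bottleneck <- ncol(Zm)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- nrow(Zm)
  te <- sort(sample(n, round(test_frac * n)))
  tr <- setdiff(seq_len(n), te)
  rows <- lapply(heads, function(h) {
    cfg <- tryCatch(attention_config(bottleneck, n_heads = h,
                                     n_tokens = n_tokens,
                                     predictor_dims = predictor_dims,
                                     dropout = dropout, seed = seed),
                    error = function(e) e)
    if (inherits(cfg, "error")) {
      warning("head count ", h, " skipped: ", conditionMessage(cfg))
      return(data.frame(n_heads = h, precision = NA, recall = NA, f1 = NA,
                        auc_roc = NA, average_precision = NA,
                        skipped = TRUE))
    }
    P <- predictor_init(cfg)
    P <- fit_predictor(P, Zm[tr, , drop = FALSE], labels[tr],
                       epochs = epochs, learning_rate = learning_rate,
                       seed = seed)
    s <- predict_proba(P, Zm[te, , drop = FALSE])
    ev <- evaluate_scores(s, labels[te])
    data.frame(n_heads = h, precision = ev$precision, recall = ev$recall,
               f1 = ev$f1, auc_roc = ev$auc_roc,
               average_precision = ev$average_precision, skipped = FALSE)
  })
  do.call(rbind, rows)
}
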