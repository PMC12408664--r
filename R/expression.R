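#' Construct an expression matrix
#'
#' Container for a samples x genes expression matrix with identifiers, a
#' domain tag (bulk cell lines vs single cells) and a layer tag recording
#' what the values are (raw counts or log-normalized expression).
#'
#' @param values Numeric matrix, samples in rows, genes in columns. Must be
#'   non-negative; the `"counts"` layer must additionally be integer-valued.
#' @param sample_ids Character vector of unique sample/cell identifiers,
#'   one per row. Defaults to rownames of `values`.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column. Defaults to colnames of `values`.
#' @param domain `"bulk"` or `"single_cell"`.
#' @param layer `"counts"` (raw) or `"lognorm"` (library-size normalized,
#'   log1p transformed).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values),
                              domain = c("bulk", "single_cell"),
                              layer = c("counts", "lognorm")) {
  domain <- match.arg(domain)
  layer <- match.arg(layer)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != nrow(values)")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) != ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (layer == "counts" && any(abs(values - round(values)) > 1e-8))
    stop("'counts' layer must be integer-valued")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_ids = gene_ids, domain = domain, layer = layer),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes | domain=%s layer=%s\n",
              nrow(x$values), ncol(x$values), x$domain, x$layer))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Subset samples (i) and/or genes (j) keeping metadata consistent.
#' @export
`[.expression_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  expression_matrix(v, rownames(v), colnames(v), domain = x$domain,
                    layer = x$layer)
}

#' Construct per-sample binary response labels
#'
#' @param sample_ids Character vector of sample/cell identifiers.
#' @param labels Binary vector (0 = resistant, 1 = sensitive).
#' @param provenance `"ground_truth"` or `"predicted"`.
#' @param scores Optional continuous sensitivity probabilities in `[0, 1]`,
#'   aligned with `sample_ids`.
#' @param threshold Binarization threshold used when `scores` are present;
#'   labels must equal `as.integer(scores >= threshold)`.
#' @return An object of class `response_labels`.
#' @export
response_labels <- function(sample_ids, labels,
                            provenance = c("ground_truth", "predicted"),
                            scores = NULL, threshold = 0.5) {
  provenance <- match.arg(provenance)
  sample_ids <- as.character(sample_ids)
  labels <- as.integer(labels)
  if (length(sample_ids) != length(labels))
    stop("sample_ids and labels lengths differ")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!is.null(scores)) {
    scores <- as.numeric(scores)
    if (length(scores) != length(labels))
      stop("scores must align with sample_ids")
    if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
    if (!all(labels == as.integer(scores >= threshold)))
      stop("labels inconsistent with scores under threshold ", threshold)
  }
  structure(list(sample_ids = sample_ids, labels = labels,
                 provenance = provenance, scores = scores,
                 threshold = if (is.null(scores)) NULL else threshold),
            class = "response_labels")
}

#' @export
print.response_labels <- function(x, ...) {
  cat(sprintf("<response_labels> n=%d (%d sensitive / %d resistant) [%s]%s\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
              x$provenance,
              if (is.null(x$scores)) "" else " with scores"))
  invisible(x)
}

#' Read an expression matrix from disk
#'
#' Supported formats: dense delimited tables (`csv`, `tsv`; first column =
#' sample ids, header = gene ids) and MatrixMarket triplets (`mtx`, with
#' `<stem>_rows.txt` / `<stem>_cols.txt` sidecar files carrying the row and
#' column identifiers). AnnData `h5ad` containers are not supported by this
#' package; convert to MTX or CSV first (e.g. with anndata in Python).
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`. Default guesses from the
#'   file extension.
#' @param transpose Set `TRUE` when the file stores genes x samples; the
#'   matrix is transposed so the result is always samples x genes.
#' @param domain,layer Passed to [expression_matrix()].
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "mtx", "h5ad"),
                            transpose = FALSE,
                            domain = "single_cell", layer = "counts") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx", h5ad = "h5ad",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format == "h5ad")
    stop("h5ad input is not supported; export the AnnData object to ",
         "MatrixMarket (X + obs/var indices) or CSV and re-read")
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e)))
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric values in ", path)
  } else {
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop("failed to parse MTX ", path, ": ",
                                           conditionMessage(e)))
    stem <- sub("\\.mtx$", "", path)
    rows_file <- paste0(stem, "_rows.txt")
    cols_file <- paste0(stem, "_cols.txt")
    if (!file.exists(rows_file) || !file.exists(cols_file))
      stop("MTX sidecars missing: expected ", rows_file, " and ", cols_file)
    rn <- readLines(rows_file)
    cn <- readLines(cols_file)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar lengths do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  }
  if (transpose) m <- t(m)
  expression_matrix(m, rownames(m), colnames(m), domain = domain,
                    layer = layer)
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()] for the same formats; round-trips values
#' and identifiers.
#'
#' @param X An [expression_matrix()].
#' @param path Destination path.
#' @param format `"csv"`, `"tsv"` or `"mtx"` (MTX writes the two id sidecars
#'   next to the matrix file).
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(X, "expression_matrix"))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(sample_id = X$sample_ids, X$values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(X$values, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(X$sample_ids, paste0(stem, "_rows.txt"))
    writeLines(X$gene_ids, paste0(stem, "_cols.txt"))
  }
  invisible(path)
}
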