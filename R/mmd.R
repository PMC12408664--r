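#' Maximum mean discrepancy between two embedding sets
#'
#' Squared-MMD estimate via kernel means (biased V-statistic):
#' `mean k(x, x') + mean k(y, y') - 2 mean k(x, y)`, which is exactly zero
#' when the two point sets coincide. The `"linear"` kernel gives the squared
#' Euclidean distance between the two sample means; `"rbf_multiscale"`
#' (default) averages Gaussian kernels `exp(-||x - y||^2 / (2 s^2))` over
#' bandwidths `s = median pairwise distance x {0.25, 0.5, 1, 2, 4}`
#' (median heuristic on the pooled sample).
#'
#' @param Z_bulk,Z_sc Latent matrices / `latent_embedding`s with equal
#'   column counts and at least 2 rows each.
#' @param kernel `"rbf_multiscale"` or `"linear"`.
#' @param bandwidths `"median-heuristic"` (default) or an explicit positive
#'   numeric vector of bandwidths for the RBF kernel.
#' @return Non-negative scalar (up to float tolerance).
#' @export
mmd <- function(Z_bulk, Z_sc, kernel = c("rbf_multiscale", "linear"),
                bandwidths = "median-heuristic") {
  kernel <- match.arg(kernel)
  X <- .as_latent(Z_bulk); Y <- .as_latent(Z_sc)
  if (ncol(X) != ncol(Y)) stop("embedding widths differ")
  if (nrow(X) < 2 || nrow(Y) < 2) stop("need at least 2 samples per side")
  if (kernel == "linear") {
    d <- colMeans(X) - colMeans(Y)
    return(sum(d * d))
  }
  sig <- .mmd_bandwidths(X, Y, bandwidths)
  Dxx <- .sqdist(X, X); Dyy <- .sqdist(Y, Y); Dxy <- .sqdist(X, Y)
  val <- 0
  for (s in sig)
    val <- val + mean(exp(-Dxx / (2 * s^2))) + mean(exp(-Dyy / (2 * s^2))) -
      2 * mean(exp(-Dxy / (2 * s^2)))
  val / length(sig)
}

.as_latent <- function(Z) {
  if (inherits(Z, "latent_embedding")) Z$values else as.matrix(Z)
}

.sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * A %*% t(B)
  pmax(d, 0)
}

.mmd_bandwidths <- function(X, Y, bandwidths) {
  if (is.numeric(bandwidths)) {
    if (any(bandwidths <= 0)) stop("bandwidths must be positive")
    return(bandwidths)
  }
  P <- rbind(X, Y)
  D <- .sqdist(P, P)
  med <- stats::median(sqrt(D[upper.tri(D)]))
  if (!is.finite(med) || med <= 0) med <- 1
  med * c(0.25, 0.5, 1, 2, 4)
}

# MMD value + gradients w.r.t. both embeddings, for joint training.
# Same estimator as mmd(); bandwidths are treated as constants
# (no gradient through the median heuristic).
.mmd_grad <- function(X, Y, kernel = "rbf_multiscale",
                      bandwidths = "median-heuristic") {
  n <- nrow(X); m <- nrow(Y)
  if (kernel == "linear") {
    d <- colMeans(X) - colMeans(Y)
    gX <- matrix(2 * d / n, n, length(d), byrow = TRUE)
    gY <- matrix(-2 * d / m, m, length(d), byrow = TRUE)
    return(list(value = sum(d * d), dX = gX, dY = gY))
  }
  sig <- .mmd_bandwidths(X, Y, bandwidths)
  Dxx <- .sqdist(X, X); Dyy <- .sqdist(Y, Y); Dxy <- .sqdist(X, Y)
  val <- 0
  gX <- matrix(0, n, ncol(X)); gY <- matrix(0, m, ncol(Y))
  for (s in sig) {
    s2 <- s^2
    Kxx <- exp(-Dxx / (2 * s2)); Kyy <- exp(-Dyy / (2 * s2))
    Kxy <- exp(-Dxy / (2 * s2))
    val <- val + mean(Kxx) + mean(Kyy) - 2 * mean(Kxy)
    # d/dx_i of mean(Kxx): entries (i,j) and (j,i) both contribute
    # k'(d2) * 2 (x_i - x_j), with k'(d2) = -k / (2 s2)
    gX <- gX + (-2 / (n^2 * s2)) * (rowSums(Kxx) * X - Kxx %*% X) -
      (-2 / (n * m * s2)) * (rowSums(Kxy) * X - Kxy %*% Y)
    gY <- gY + (-2 / (m^2 * s2)) * (rowSums(Kyy) * Y - Kyy %*% Y) -
      (-2 / (n * m * s2)) * (colSums(Kxy) * Y - t(Kxy) %*% X)
  }
  list(value = val / length(sig), dX = gX / length(sig),
       dY = gY / length(sig))
}

#' Louvain clustering of cells in latent space
#'
#' Builds a k-nearest-neighbour graph on the embeddings (Euclidean
#' distance, symmetrized) and runs Louvain community detection.
#'
#' @param Z_sc Latent matrix / `latent_embedding` of single cells.
#' @param resolution Louvain resolution parameter (default 1).
#' @param n_neighbors Neighbourhood size for the kNN graph (default 15).
#' @param seed Integer seed (Louvain is seeded for reproducibility).
#' @return Integer vector of cluster labels (1-based), one per cell.
#' @export
cluster_cells <- function(Z_sc, resolution = 1, n_neighbors = 15, seed = 1) {
  Z <- .as_latent(Z_sc)
  n <- nrow(Z)
  if (n < n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1, " cells")
  D <- .sqdist(Z, Z)
  diag(D) <- Inf
  edges <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(n_neighbors)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::simplify(igraph::make_graph(edges, n = n, directed = FALSE))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(comm))
}

#' Cluster-coherence regularizer
#'
#' Penalizes single-cell embeddings that stray from their Louvain cluster:
#' the mean over cells of `1 - cosine(z_i, centroid of cluster(i))`. Lies in
#' `[0, 2]`; zero when every cell is colinear with its centroid, so the
#' penalty pushes the latent space to keep the cluster structure found in
#' the data.
#'
#' @param Z_sc Latent matrix / `latent_embedding`.
#' @param clusters Integer cluster assignment, one per cell
#'   (from [cluster_cells()]); every cluster must be non-empty.
#' @return Scalar in `[0, 2]`.
#' @export
cluster_regularizer <- function(Z_sc, clusters) {
  Z <- .as_latent(Z_sc)
  if (nrow(Z) != length(clusters)) stop("clusters must align with rows of Z_sc")
  .cluster_reg_grad(Z, clusters)$value
}

# value + gradient w.r.t. Z (centroids treated as constants for the
# gradient; they are recomputed from the current embeddings each call).
.cluster_reg_grad <- function(Z, clusters) {
  cl <- as.integer(factor(clusters))
  n <- nrow(Z)
  cent <- rowsum(Z, cl) / as.vector(table(cl))
  C <- cent[cl, , drop = FALSE]
  zn <- sqrt(rowSums(Z^2)); cn <- sqrt(rowSums(C^2))
  ok <- zn > 0 & cn > 0
  if (any(!ok))
    warning(sum(!ok), " zero-norm embedding(s); cosine treated as 0")
  dot <- rowSums(Z * C)
  cossim <- ifelse(ok, dot / (zn * cn), 0)
  value <- mean(1 - cossim)
  # d(1 - cos)/dz = -(c / (|z||c|) - cos * z / |z|^2)
  g <- matrix(0, n, ncol(Z))
  if (any(ok)) {
    zi <- which(ok)
    g[zi, ] <- -(C[zi, , drop = FALSE] / (zn[zi] * cn[zi]) -
                   (cossim[zi] / zn[zi]^2) * Z[zi, , drop = FALSE])
  }
  list(value = value, dZ = g / n)
}
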