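#' Reduce a score matrix to principal components and a 2-D embedding
#'
#' Runs PCA on the (residualised) score matrix for noise and dimensionality
#' control, then a 2-D UMAP of the retained components for visualisation.
#' All randomness is governed by `seed`; re-running with identical inputs
#' reproduces the embedding exactly.
#'
#' @param scores a `ScoreMatrix`.
#' @param use `"scaled"` or `"residuals"`; residuals require a prior
#'   [regress_out()] and a complete matrix.
#' @param n_pcs principal components to keep (default 20; clipped with a
#'   warning when the matrix is smaller).
#' @param seed integer random seed, recorded in the result.
#' @param n_neighbors UMAP neighbourhood size (default 15; clipped for tiny
#'   data).
#' @return list with `components` (cells x n_pcs), `embedding` (cells x 2),
#'   `sdev` (component standard deviations) and `params`.
#' @export
reduce_scores <- function(scores, use = c("scaled", "residuals"),
                          n_pcs = 20L, seed = 1L, n_neighbors = 15L) {
  stopifnot(inherits(scores, "ScoreMatrix"))
  use <- match.arg(use)
  m <- if (use == "residuals") {
    if (is.null(scores$residuals))
      stop("no residuals present; run regress_out() first")
    scores$residuals
  } else scores$scaled
  if (any(!is.finite(m)))
    stop("score matrix has missing values; run knn_impute()/regress_out() first")
  max_pcs <- min(nrow(m) - 1L, ncol(m))
  if (n_pcs > max_pcs) {
    warning(sprintf("n_pcs clipped from %d to %d", n_pcs, max_pcs))
    n_pcs <- max_pcs
  }
  pca <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)
  comp <- pca$x[, seq_len(n_pcs), drop = FALSE]
  total_var <- sum(apply(m, 2, stats::var))
  if (total_var < 1e-12) {
    # degenerate: all cells identical; embed at the origin
    emb <- matrix(0, nrow(m), 2)
  } else {
    nb <- max(2L, min(n_neighbors, nrow(m) - 1L))
    set.seed(derive_seed(seed, 1L))
    emb <- uwot::umap(comp, n_neighbors = nb, n_threads = 1,
                      n_sgd_threads = 0)
  }
  dimnames(emb) <- list(rownames(m), c("UMAP1", "UMAP2"))
  list(components = comp, embedding = emb, sdev = pca$sdev,
       params = list(use = use, n_pcs = n_pcs, seed = seed,
                     n_neighbors = if (total_var < 1e-12) NA else
                       max(2L, min(n_neighbors, nrow(m) - 1L))))
}

#' Find therapeutic clusters
#'
#' Groups cells by their score profiles — a therapeutic cluster is a set of
#' cells sharing a common response to the analysed drugs — using either
#' community detection on a k-nearest-neighbour graph of the principal
#' components (default) or k-means as a deterministic fallback. Cluster ids
#' are relabelled by decreasing size, so cluster 1 is always the largest.
#'
#' @param reduction result of [reduce_scores()].
#' @param method `"graph_community"` (Louvain on a kNN graph) or `"kmeans"`.
#' @param resolution community-detection resolution (default 0.4); higher
#'   values tend to yield more clusters.
#' @param k number of clusters for `method = "kmeans"`.
#' @param knn neighbours for the graph (default 15, clipped for tiny data).
#' @param seed integer random seed.
#' @return a `TherapeuticClusters`: list with `labels` (named integer
#'   vector, ids 1..K by decreasing size), `embedding`, and `params`.
#' @export
find_clusters <- function(reduction, method = c("graph_community", "kmeans"),
                          resolution = 0.4, k = NULL, knn = 15L, seed = 1L) {
  method <- match.arg(method)
  comp <- reduction$components
  n <- nrow(comp)
  if (method == "kmeans") {
    if (is.null(k)) stop("method 'kmeans' requires k")
    if (k > n) stop("k cannot exceed the number of cells")
    set.seed(derive_seed(seed, 2L))
    km <- stats::kmeans(comp, centers = k, nstart = 10L, iter.max = 100L)
    labels <- km$cluster
  } else {
    knn <- max(1L, min(knn, n - 1L))
    nn <- FNN::get.knn(comp, k = knn)
    # shared-nearest-neighbour graph: Jaccard overlap of (self-inclusive)
    # neighbourhoods, pruned at 1/15 — the standard construction for
    # community detection on single-cell-like data
    A <- Matrix::sparseMatrix(
      i = rep(seq_len(n), knn + 1L),
      j = as.vector(cbind(seq_len(n), nn$nn.index)),
      x = 1, dims = c(n, n))
    shared <- Matrix::tcrossprod(A)
    jac <- as.matrix(shared) / (2 * (knn + 1L) - as.matrix(shared))
    jac[jac < 1 / 15] <- 0
    diag(jac) <- 0
    g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                             weighted = TRUE)
    set.seed(derive_seed(seed, 2L))
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- igraph::membership(cl)
  }
  # relabel by decreasing size; ties by original id for determinism
  tab <- sort(table(labels), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(tab), names(tab))
  labels <- as.integer(relabel[as.character(labels)])
  names(labels) <- rownames(comp)
  structure(list(labels = labels, embedding = reduction$embedding,
                 params = c(reduction$params,
                            list(method = method, resolution = resolution,
                                 k = k, knn = knn, seed = seed))),
            class = "TherapeuticClusters")
}

#' Plot the therapeutic-cluster embedding
#'
#' Scatter plot of the 2-D embedding coloured by cluster, by a signature's
#' scaled score, or by a metadata column.
#'
#' @param tc a `TherapeuticClusters`.
#' @param colour_by `NULL` (cluster labels), a numeric vector, or a factor
#'   aligned with cells.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `tc`.
#' @export
plot_clusters <- function(tc, colour_by = NULL, main = "Therapeutic clusters",
                          ...) {
  stopifnot(inherits(tc, "TherapeuticClusters"))
  val <- if (is.null(colour_by)) factor(tc$labels) else colour_by
  if (is.numeric(val)) {
    pal <- grDevices::hcl.colors(100, "viridis")
    idx <- cut(val, breaks = 100, labels = FALSE, include.lowest = TRUE)
    cols <- pal[idx]
  } else {
    val <- factor(val)
    pal <- grDevices::hcl.colors(max(2L, nlevels(val)), "Dark 3")
    cols <- pal[as.integer(val)]
  }
  graphics::plot(tc$embedding, col = cols, pch = 16, cex = 0.6,
                 main = main, ...)
  invisible(tc)
}
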