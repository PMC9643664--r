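# Internal cluster-validity indices. Average silhouette width comes from the
# `cluster` package; Dunn, Calinski-Harabasz and connectivity are computed
# from their definitions; the gap statistic lives in run_grid() because it
# needs the clustering procedure itself.

#' Cluster validity measures for one partition
#'
#' Computes average silhouette width, Dunn index, Calinski-Harabasz index and
#' (negated) connectivity for a partition of samples, using Euclidean
#' distance. Connectivity (Handl et al.) penalises samples whose nearest
#' neighbours fall in other clusters; it is returned negated so that higher
#' is better for every measure.
#'
#' @param X samples x features numeric matrix.
#' @param labels integer cluster labels in 1..k.
#' @param dist_obj optional precomputed `dist(X)`.
#' @param neighbours neighbourhood size for connectivity (default 10,
#'   truncated to n - 1).
#' @return named numeric vector: `silhouette`, `dunn`, `calinski_harabasz`,
#'   `neg_connectivity`.
#' @export
cluster_validity_measures <- function(X, labels, dist_obj = NULL, neighbours = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(labels) != n) stop_fmt("labels must match rows of X")
  k <- length(unique(labels))
  if (k < 2) stop_fmt("need at least 2 clusters")
  if (is.null(dist_obj)) dist_obj <- stats::dist(X)
  dm <- as.matrix(dist_obj)

  sil <- mean(cluster::silhouette(labels, dist_obj)[, "sil_width"])

  # Dunn: min between-cluster distance / max within-cluster diameter
  min_between <- Inf
  max_diam <- 0
  for (a in unique(labels)) {
    ia <- which(labels == a)
    if (length(ia) > 1) max_diam <- max(max_diam, max(dm[ia, ia]))
    for (b in unique(labels)) {
      if (b <= a) next
      ib <- which(labels == b)
      min_between <- min(min_between, min(dm[ia, ib]))
    }
  }
  dunn <- if (max_diam > 0) min_between / max_diam else Inf

  # Calinski-Harabasz from Euclidean sums of squares
  grand <- colMeans(X)
  Bss <- 0; Wss <- 0
  for (a in unique(labels)) {
    ia <- which(labels == a)
    cen <- colMeans(X[ia, , drop = FALSE])
    Bss <- Bss + length(ia) * sum((cen - grand)^2)
    Wss <- Wss + sum(sweep(X[ia, , drop = FALSE], 2, cen)^2)
  }
  ch <- if (Wss > 0) (Bss / (k - 1)) / (Wss / (n - k)) else Inf

  # connectivity over the L nearest neighbours
  L <- min(neighbours, n - 1)
  conn <- 0
  for (i in seq_len(n)) {
    nn <- order(dm[i, -i])  # indices into the reduced vector
    others <- seq_len(n)[-i]
    nn_idx <- others[nn[seq_len(L)]]
    mismatch <- labels[nn_idx] != labels[i]
    conn <- conn + sum(mismatch / seq_len(L))
  }

  c(silhouette = sil, dunn = dunn, calinski_harabasz = ch,
    neg_connectivity = -conn)
}

# pooled within-cluster sum of squares about cluster centroids
within_ss <- function(X, labels) {
  w <- 0
  for (a in unique(labels)) {
    ia <- which(labels == a)
    cen <- colMeans(X[ia, , drop = FALSE])
    w <- w + sum(sweep(X[ia, , drop = FALSE], 2, cen)^2)
  }
  w
}
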