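#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Jonker/Volgenant-style shortest-augmenting-path implementation of the
#' Kuhn-Munkres algorithm, O(n^3). Used to match cluster labels between
#' algorithms by maximising agreement over the k x k contingency table.
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `m` with `m[i]` the column assigned to row i.
#' @export
hungarian_min <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop_fmt("cost must be a square matrix")
  n <- nrow(cost)
  if (n == 1) return(1L)
  # columns are indexed 1..n+1 with 1 the virtual start column
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  m <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) m[p[j]] <- j - 1L
  m
}

#' Match one labelling's clusters to another by maximum agreement
#'
#' Solves the one-to-one label matching over the k x k contingency table
#' (Hungarian algorithm on negated counts) and returns `labels` relabelled
#' into the reference labelling's identities.
#'
#' @param reference integer labels 1..k (the identities to match onto).
#' @param labels integer labels 1..k to be relabelled.
#' @return list with `matched` (relabelled `labels`), `mapping` (integer
#'   vector: `mapping[old] = new`), and `agreement` (matched sample count).
#' @export
match_cluster_labels <- function(reference, labels) {
  if (length(reference) != length(labels))
    stop_fmt("labellings must have equal length")
  k <- max(reference, labels)
  tab <- matrix(0, k, k)
  for (i in seq_along(reference)) {
    tab[labels[i], reference[i]] <- tab[labels[i], reference[i]] + 1
  }
  assign <- hungarian_min(max(tab) - tab)
  matched <- assign[labels]
  list(matched = matched, mapping = assign,
       agreement = sum(matched == reference))
}
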