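#' Select the most variable genes
#'
#' Returns the `n` genes with largest variance across samples (intended for
#' case samples), ties broken by gene id order. When `n` exceeds the number
#' of genes, all genes are returned.
#'
#' @param values genes x samples matrix.
#' @param n number of genes (>= 2).
#' @return character vector of gene ids.
#' @export
select_variable_genes <- function(values, n) {
  if (!is_count(n) || n < 2) stop_fmt("n must be an integer >= 2")
  v <- row_vars(values)
  ord <- order(-v, rownames(values))
  rownames(values)[ord][seq_len(min(n, nrow(values)))]
}

#' Run the consensus-clustering validity grid
#'
#' For each gene-subset size, takes the most variable genes, standardises
#' them, and clusters the samples with k-means (multiple random restarts)
#' and PAM (Euclidean) for each candidate k. Five validity measures are
#' computed per cell: average silhouette width, Dunn index,
#' Calinski-Harabasz, negated connectivity, and the gap statistic
#' (Tibshirani; `gap_B` uniform reference sets drawn over the range of each
#' standardised feature). Deterministic given `seed`.
#'
#' @param values genes x samples matrix (case samples).
#' @param k_values integer cluster numbers >= 2 (default 2:8).
#' @param gene_counts gene-subset ladder (default
#'   `c(100, 250, 500, 1000, 2500, 5000)`), truncated with a warning to the
#'   available gene count.
#' @param n_restarts k-means restarts for the data partitions (default 20).
#' @param gap_B number of gap-statistic reference sets (default 50).
#' @param ref_nstart k-means restarts on reference sets (default 5).
#' @param neighbours connectivity neighbourhood size (default 10).
#' @param seed integer seed controlling every random draw.
#' @return object of class `validity_grid`: `cells` data frame (algorithm,
#'   k, gene_count, the five measures, gap SE, `failed` flag) and the
#'   per-cell assignment vectors.
#' @export
run_grid <- function(values, k_values = 2:8,
                     gene_counts = c(100, 250, 500, 1000, 2500, 5000),
                     n_restarts = 20, gap_B = 50, ref_nstart = 5,
                     neighbours = 10, seed = 1) {
  validate_expression(values, "clustering matrix")
  n <- ncol(values)
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 2)) stop_fmt("k_values must be >= 2")
  if (n <= max(k_values)) stop_fmt("need more samples (%d) than max k (%d)", n, max(k_values))
  gene_counts <- sort(unique(as.integer(gene_counts)))
  if (any(gene_counts > nrow(values))) {
    warn_fmt("gene_counts above available genes (%d) truncated", nrow(values))
    gene_counts <- unique(pmin(gene_counts, nrow(values)))
  }

  cells <- list(); assignments <- list()
  for (gi in seq_along(gene_counts)) {
    gc_ <- gene_counts[gi]
    genes <- select_variable_genes(values, gc_)
    X <- t(zscore_rows(values[genes, , drop = FALSE]))
    D <- stats::dist(X)

    # per-(k, algorithm) partitions of the data
    labs <- list()
    for (k in k_values) {
      set.seed(derive_seed(seed, 131 * gi + k))
      km <- tryCatch(stats::kmeans(X, centers = k, nstart = n_restarts, iter.max = 100),
                     error = function(e) e)
      pm <- tryCatch(cluster::pam(D, k = k, diss = TRUE, cluster.only = TRUE),
                     error = function(e) e)
      labs[[paste0("kmeans:", k)]] <- if (inherits(km, "error")) km else km$cluster
      labs[[paste0("pam:", k)]] <- pm
    }

    # gap-statistic references shared across k and algorithms for this ladder
    rng <- apply(X, 2, range)
    log_w_ref <- array(NA_real_, c(gap_B, length(k_values), 2),
                       dimnames = list(NULL, k_values, c("kmeans", "pam")))
    for (b in seq_len(gap_B)) {
      set.seed(derive_seed(seed, 7919 * gi + b))
      ref <- matrix(stats::runif(n * ncol(X), min = rep(rng[1, ], each = n),
                                 max = rep(rng[2, ], each = n)), nrow = n)
      Dref <- stats::dist(ref)
      for (ki in seq_along(k_values)) {
        k <- k_values[ki]
        kmr <- tryCatch(stats::kmeans(ref, centers = k, nstart = ref_nstart, iter.max = 100),
                        error = function(e) NULL)
        if (!is.null(kmr)) log_w_ref[b, ki, "kmeans"] <- log(kmr$tot.withinss)
        pmr <- tryCatch(cluster::pam(Dref, k = k, diss = TRUE, cluster.only = TRUE),
                        error = function(e) NULL)
        if (!is.null(pmr)) log_w_ref[b, ki, "pam"] <- log(within_ss(ref, pmr))
      }
    }

    for (ki in seq_along(k_values)) {
      k <- k_values[ki]
      for (alg in c("kmeans", "pam")) {
        lab <- labs[[paste0(alg, ":", k)]]
        row <- data.frame(algorithm = alg, k = k, gene_count = gc_,
                          silhouette = NA_real_, dunn = NA_real_,
                          calinski_harabasz = NA_real_, neg_connectivity = NA_real_,
                          gap_statistic = NA_real_, gap_se = NA_real_,
                          failed = TRUE, stringsAsFactors = FALSE)
        if (!inherits(lab, "error") && length(unique(lab)) == k) {
          meas <- tryCatch(
            cluster_validity_measures(X, lab, dist_obj = D, neighbours = neighbours),
            error = function(e) NULL)
          if (!is.null(meas)) {
            lw <- log(within_ss(X, lab))
            lwr <- log_w_ref[, ki, alg]
            lwr <- lwr[is.finite(lwr)]
            row$silhouette <- meas[["silhouette"]]
            row$dunn <- meas[["dunn"]]
            row$calinski_harabasz <- meas[["calinski_harabasz"]]
            row$neg_connectivity <- meas[["neg_connectivity"]]
            if (length(lwr) >= 2) {
              row$gap_statistic <- mean(lwr) - lw
              row$gap_se <- stats::sd(lwr) * sqrt(1 + 1 / length(lwr))
            }
            row$failed <- FALSE
            names(lab) <- colnames(values)
            assignments[[sprintf("%s:%d:%d", alg, k, gc_)]] <- lab
          }
        }
        cells[[length(cells) + 1L]] <- row
      }
    }
  }
  structure(list(
    cells = do.call(rbind, cells),
    assignments = assignments,
    sample_ids = colnames(values),
    k_values = k_values, gene_counts = gene_counts,
    params = list(n_restarts = n_restarts, gap_B = gap_B,
                  ref_nstart = ref_nstart, neighbours = neighbours, seed = seed)
  ), class = "validity_grid")
}

#' @export
print.validity_grid <- function(x, ...) {
  cat(sprintf("<validity_grid> k in {%s}, genes in {%s}; %d/%d cells succeeded\n",
              paste(x$k_values, collapse = ","), paste(x$gene_counts, collapse = ","),
              sum(!x$cells$failed), nrow(x$cells)))
  invisible(x)
}

#' Build the optimality map from a validity grid
#'
#' Each validity measure is z-scored across all successful
#' (algorithm, k, gene_count) cells, the per-cell aggregate is the mean of
#' the five z-scores, and the map entry for (k, gene_count) averages the two
#' algorithms. The chosen cell maximises the aggregate; ties break toward
#' smaller k, then smaller gene count.
#'
#' @param grid a [run_grid()] result with at least 2 successful cells.
#' @return object of class `optimality_map`: `scores` data frame
#'   (k, gene_count, aggregate), the map `matrix` (k x gene_count), and
#'   `chosen_k` / `chosen_gene_count`.
#' @export
build_optimality_map <- function(grid) {
  stopifnot(inherits(grid, "validity_grid"))
  ok <- !grid$cells$failed
  if (sum(ok) < 2) stop_fmt("need at least 2 successful grid cells")
  cells <- grid$cells[ok, , drop = FALSE]
  measures <- c("silhouette", "dunn", "calinski_harabasz",
                "neg_connectivity", "gap_statistic")
  zs <- sapply(measures, function(m) {
    v <- cells[[m]]
    s <- stats::sd(v[is.finite(v)])
    mu <- mean(v[is.finite(v)])
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    z <- (v - mu) / s
    z[!is.finite(z)] <- 0
    z
  })
  cells$cell_score <- rowMeans(zs)
  agg <- stats::aggregate(cell_score ~ k + gene_count, data = cells, FUN = mean)
  names(agg)[3] <- "aggregate"
  agg <- agg[order(agg$k, agg$gene_count), , drop = FALSE]
  rownames(agg) <- NULL
  best <- which(agg$aggregate == max(agg$aggregate))
  chosen <- best[1]  # agg is ordered by (k, gene_count): first max is the tie-break
  mat <- matrix(NA_real_, length(grid$k_values), length(grid$gene_counts),
                dimnames = list(grid$k_values, grid$gene_counts))
  for (i in seq_len(nrow(agg)))
    mat[as.character(agg$k[i]), as.character(agg$gene_count[i])] <- agg$aggregate[i]
  structure(list(scores = agg, matrix = mat,
                 chosen_k = agg$k[chosen],
                 chosen_gene_count = agg$gene_count[chosen]),
            class = "optimality_map")
}

#' @export
print.optimality_map <- function(x, ...) {
  cat(sprintf("<optimality_map> chosen k = %d at %d genes\n",
              x$chosen_k, x$chosen_gene_count))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Agreement-based consensus assignment with unclustered calls
#'
#' Matches the PAM labels to the k-means labels at the chosen grid cell by
#' maximum-agreement one-to-one matching (Hungarian algorithm over the k x k
#' contingency table). Samples on which the matched labels agree receive
#' that label; disagreeing samples are called UNCLUSTERED (NA).
#'
#' @param grid a [run_grid()] result.
#' @param k chosen number of clusters.
#' @param gene_count chosen gene-subset size.
#' @return object of class `cluster_solution`: `labels` (named integer, NA =
#'   unclustered), per-algorithm matched assignments, `unclustered_fraction`,
#'   `k`, `gene_count`.
#' @export
consensus_assign <- function(grid, k, gene_count) {
  stopifnot(inherits(grid, "validity_grid"))
  km <- grid$assignments[[sprintf("kmeans:%d:%d", k, gene_count)]]
  pm <- grid$assignments[[sprintf("pam:%d:%d", k, gene_count)]]
  if (is.null(km) || is.null(pm))
    stop_fmt("chosen cell (k=%d, genes=%d) did not succeed for both algorithms",
             k, gene_count)
  if (length(unique(km)) != length(unique(pm)))
    stop_fmt("algorithms produced different cluster counts at the chosen cell")
  m <- match_cluster_labels(reference = km, labels = pm)
  agree <- m$matched == km
  labels <- ifelse(agree, km, NA_integer_)
  names(labels) <- grid$sample_ids
  structure(list(
    labels = labels, k = as.integer(k), gene_count = as.integer(gene_count),
    kmeans_labels = km, pam_labels_matched = m$matched,
    unclustered_fraction = mean(!agree)
  ), class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  tab <- table(factor(x$labels, levels = seq_len(x$k)))
  cat(sprintf("<cluster_solution> k = %d (%d genes): sizes %s; unclustered %d (%.1f%%)\n",
              x$k, x$gene_count, paste(tab, collapse = "/"),
              sum(is.na(x$labels)), 100 * x$unclustered_fraction))
  invisible(x)
}

#' Turn a cluster solution into a writable table
#'
#' @param x a `cluster_solution`.
#' @param ... unused.
#' @return data frame with `sample_id` and `label` ("1".."k" or
#'   "UNCLUSTERED").
#' @export
as.data.frame.cluster_solution <- function(x, ...) {
  data.frame(sample_id = names(x$labels),
             label = ifelse(is.na(x$labels), "UNCLUSTERED", as.character(x$labels)),
             stringsAsFactors = FALSE)
}
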