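#' Differentially expressed candidate genes per cluster (one-vs-rest)
#'
#' For each cluster, performs a per-gene Welch two-sample test of that
#' cluster against the remaining clustered samples, adjusts p-values across
#' genes by Benjamini-Hochberg, and keeps genes with FDR below `alpha_fdr`
#' and absolute mean difference of at least `min_effect` (log2 units).
#' Candidates are split into up/down lists by the sign of the difference and
#' ranked by absolute effect. Unclustered samples (NA labels) are excluded.
#'
#' @param values genes x samples matrix.
#' @param labels named integer cluster labels (NA = unclustered) or a
#'   `cluster_solution`.
#' @param alpha_fdr FDR threshold (default 0.01).
#' @param min_effect minimum absolute mean difference (default 0.5).
#' @return object of class `gene_signature`: `clusters` (per cluster:
#'   `up`/`down` gene id vectors, ranked) and `table` (gene, cluster,
#'   direction, effect, p, fdr).
#' @export
derive_candidate_genes <- function(values, labels, alpha_fdr = 0.01, min_effect = 0.5) {
  labels <- solution_labels(labels)
  labels <- labels[!is.na(labels)]
  keep <- intersect(colnames(values), names(labels))
  values <- values[, keep, drop = FALSE]
  labels <- labels[keep]
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 3))
    stop_fmt("need >= 2 clusters with >= 3 samples each (sizes: %s)",
             paste(tab, collapse = "/"))
  rows <- list()
  clusters <- sort(unique(labels))
  for (cl in clusters) {
    in_cl <- labels == cl
    w <- welch_rows(values[, in_cl, drop = FALSE], values[, !in_cl, drop = FALSE])
    fdr <- stats::p.adjust(w$p, method = "BH")
    hit <- fdr < alpha_fdr & abs(w$diff) >= min_effect
    if (any(hit)) {
      rows[[as.character(cl)]] <- data.frame(
        cluster = cl, gene = rownames(values)[hit],
        direction = ifelse(w$diff[hit] > 0, "up", "down"),
        effect = w$diff[hit], p = w$p[hit], fdr = fdr[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop_fmt(paste("no candidate genes for any cluster at FDR < %.3g and |effect| >= %.3g;",
                   "consider raising alpha_fdr or lowering min_effect"),
             alpha_fdr, min_effect)
  empty <- setdiff(as.character(clusters), names(rows))
  if (length(empty))
    warn_fmt("no candidate genes for cluster(s) %s", paste(empty, collapse = ", "))
  tbl <- do.call(rbind, rows)
  tbl <- tbl[order(tbl$cluster, -abs(tbl$effect)), , drop = FALSE]
  rownames(tbl) <- NULL
  cl_list <- lapply(as.character(clusters), function(cl) {
    sub <- tbl[tbl$cluster == as.integer(cl), , drop = FALSE]
    list(up = sub$gene[sub$direction == "up"], down = sub$gene[sub$direction == "down"])
  })
  names(cl_list) <- as.character(clusters)
  structure(list(clusters = cl_list, table = tbl), class = "gene_signature")
}

# vectorised Welch two-sample t-test per row
welch_rows <- function(x1, x0) {
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- row_vars(x1); v0 <- row_vars(x0)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(p)] <- 1  # constant genes in both groups
  list(diff = m1 - m0, t = t, df = df, p = p)
}

solution_labels <- function(labels) {
  if (inherits(labels, "cluster_solution")) return(labels$labels)
  if (is.null(names(labels))) stop_fmt("labels must be named by sample id")
  labels
}

# per-sample, per-cluster signature scores from standardised expression:
# mean z over the cluster's up genes minus mean z over its down genes.
signature_scores <- function(z, signature) {
  ks <- names(signature)
  scores <- matrix(0, ncol(z), length(ks), dimnames = list(colnames(z), ks))
  for (cl in ks) {
    up <- intersect(signature[[cl]]$up, rownames(z))
    dn <- intersect(signature[[cl]]$down, rownames(z))
    s <- 0
    if (length(up)) s <- s + colMeans(z[up, , drop = FALSE])
    if (length(dn)) s <- s - colMeans(z[dn, , drop = FALSE])
    scores[, cl] <- s
  }
  scores
}

predict_from_scores <- function(scores) {
  cl <- as.integer(colnames(scores))
  cl[max.col(scores, ties.method = "first")]
}

balanced_accuracy <- function(truth, pred) {
  cls <- sort(unique(truth))
  mean(vapply(cls, function(cl) mean(pred[truth == cl] == cl), 0))
}

#' Train a compact cluster classifier by greedy forward search
#'
#' Builds a small up/down gene-signature classifier in the style used for
#' multi-cohort sepsis signatures: each sample's score for cluster c is the
#' mean within-dataset z-scored expression over c's up genes minus the mean
#' over its down genes, and the predicted cluster is the argmax (ties to the
#' lowest cluster index). Starting from an empty signature, the candidate
#' gene (with its cluster and direction) that maximally increases
#' cross-validated balanced accuracy is added at each step; the search stops
#' when the improvement falls below `improvement` or `max_genes` genes are
#' selected. Fold assignment is stratified by cluster and seeded.
#'
#' @param values genes x samples training matrix.
#' @param labels named cluster labels (NA = unclustered) or a
#'   `cluster_solution`.
#' @param candidates a [derive_candidate_genes()] result.
#' @param max_genes signature size cap (default 30).
#' @param cv_folds cross-validation folds (default 5); must not exceed the
#'   smallest cluster.
#' @param improvement minimum CV balanced-accuracy gain to continue
#'   (default 0.001).
#' @param seed integer seed for fold assignment.
#' @return object of class `cluster_classifier`: `k`, `signature` (per
#'   cluster up/down lists), `selected_genes` (in selection order),
#'   `training_accuracy` (refit on all training samples), `cv_accuracy`,
#'   `policy`, `low_risk_cluster` (NA until set) and `seed`.
#' @export
greedy_train <- function(values, labels, candidates, max_genes = 30,
                         cv_folds = 5, improvement = 0.001, seed = 1) {
  stopifnot(inherits(candidates, "gene_signature"))
  labels <- solution_labels(labels)
  labels <- labels[!is.na(labels)]
  keep <- intersect(colnames(values), names(labels))
  values <- values[, keep, drop = FALSE]
  labels <- labels[keep]
  tab <- table(labels)
  if (sum(vapply(candidates$clusters, function(x) length(x$up) + length(x$down), 0L) > 0) < 2)
    stop_fmt("candidates must be non-empty for at least 2 clusters")
  if (cv_folds > min(tab))
    stop_fmt("cv_folds (%d) exceeds the smallest cluster size (%d)", cv_folds, min(tab))

  pool <- candidates$table[candidates$table$gene %in% rownames(values), , drop = FALSE]
  if (!nrow(pool)) stop_fmt("no candidate genes present in the training matrix")
  z <- zscore_rows(values[unique(pool$gene), , drop = FALSE])
  n <- ncol(z)
  truth <- labels

  set.seed(seed)
  fold <- integer(n)
  for (cl in names(tab)) {
    idx <- sample(which(truth == as.integer(cl)))
    fold[idx] <- rep_len(seq_len(cv_folds), length(idx))
  }

  cv_balacc <- function(pred) {
    mean(vapply(seq_len(cv_folds), function(f) {
      held <- fold == f
      balanced_accuracy(truth[held], pred[held])
    }, 0))
  }

  ks <- sort(unique(truth))
  sig <- lapply(ks, function(cl) list(up = character(0), down = character(0)))
  names(sig) <- as.character(ks)
  # incremental state: score_c = sum_up/c_up - sum_dn/c_dn
  n_up <- n_dn <- stats::setNames(integer(length(ks)), as.character(ks))
  sum_up <- sum_dn <- matrix(0, n, length(ks),
                             dimnames = list(colnames(z), as.character(ks)))

  current_scores <- function() {
    s <- matrix(0, n, length(ks), dimnames = dimnames(sum_up))
    for (j in seq_along(ks)) {
      cl <- as.character(ks[j])
      if (n_up[cl] > 0) s[, j] <- s[, j] + sum_up[, j] / n_up[cl]
      if (n_dn[cl] > 0) s[, j] <- s[, j] - sum_dn[, j] / n_dn[cl]
    }
    s
  }

  selected <- character(0)
  best_cv <- cv_balacc(predict_from_scores(current_scores()))
  pool$used <- FALSE
  repeat {
    if (length(selected) >= max_genes) break
    best_gain <- -Inf; best_i <- NA_integer_; best_cv_trial <- NA_real_
    base_up <- sum_up; base_dn <- sum_dn
    for (i in which(!pool$used)) {
      g <- pool$gene[i]; cl <- as.character(pool$cluster[i]); j <- match(cl, names(sig))
      zu <- z[g, ]
      t_up <- n_up; t_dn <- n_dn
      s_up <- base_up; s_dn <- base_dn
      if (pool$direction[i] == "up") { s_up[, j] <- s_up[, j] + zu; t_up[cl] <- t_up[cl] + 1L }
      else { s_dn[, j] <- s_dn[, j] + zu; t_dn[cl] <- t_dn[cl] + 1L }
      s <- matrix(0, n, length(ks), dimnames = dimnames(sum_up))
      for (jj in seq_along(ks)) {
        c2 <- as.character(ks[jj])
        if (t_up[c2] > 0) s[, jj] <- s[, jj] + s_up[, jj] / t_up[c2]
        if (t_dn[c2] > 0) s[, jj] <- s[, jj] - s_dn[, jj] / t_dn[c2]
      }
      acc <- cv_balacc(predict_from_scores(s))
      if (acc - best_cv > best_gain + 1e-12) {
        best_gain <- acc - best_cv; best_i <- i; best_cv_trial <- acc
      }
    }
    if (!is.finite(best_gain) || best_gain < improvement) break
    i <- best_i
    g <- pool$gene[i]; cl <- as.character(pool$cluster[i]); j <- match(cl, names(sig))
    if (pool$direction[i] == "up") {
      sum_up[, j] <- sum_up[, j] + z[g, ]; n_up[cl] <- n_up[cl] + 1L
      sig[[cl]]$up <- c(sig[[cl]]$up, g)
    } else {
      sum_dn[, j] <- sum_dn[, j] + z[g, ]; n_dn[cl] <- n_dn[cl] + 1L
      sig[[cl]]$down <- c(sig[[cl]]$down, g)
    }
    pool$used[i] <- TRUE
    if (!(g %in% selected)) selected <- c(selected, g)  # a gene may serve two clusters
    best_cv <- best_cv_trial
  }
  if (!length(selected))
    stop_fmt("greedy search selected no genes; check candidate quality")

  final_scores <- current_scores()
  pred <- predict_from_scores(final_scores)
  training_accuracy <- mean(pred == truth)

  structure(list(
    k = length(ks), signature = sig,
    selected_genes = selected,
    policy = "within-dataset z-score",
    training_accuracy = training_accuracy,
    cv_accuracy = best_cv,
    low_risk_cluster = NA_integer_,
    seed = as.integer(seed)
  ), class = "cluster_classifier")
}

#' @export
print.cluster_classifier <- function(x, ...) {
  cat(sprintf("<cluster_classifier> k = %d, %d genes; training accuracy %.1f%%; low-risk cluster: %s\n",
              x$k, length(x$selected_genes), 100 * x$training_accuracy,
              ifelse(is.na(x$low_risk_cluster), "unset", x$low_risk_cluster)))
  invisible(x)
}

#' Assign new samples to discovery clusters
#'
#' Z-scores each classifier gene within the supplied dataset (validation
#' cohorts are never co-normalised with discovery data), computes the
#' up-minus-down signature score per cluster and returns the argmax label.
#' Classifier genes absent from the matrix are dropped from their lists with
#' a warning, provided at least `min_present` of them are present.
#'
#' @param classifier a [greedy_train()] result.
#' @param values genes x samples matrix for one dataset.
#' @param min_present minimum fraction of classifier genes required
#'   (default 0.8); below this the call refuses rather than degrade.
#' @return named integer vector of cluster labels.
#' @export
classify_samples <- function(classifier, values, min_present = 0.8) {
  stopifnot(inherits(classifier, "cluster_classifier"))
  present <- intersect(classifier$selected_genes, rownames(values))
  frac <- length(present) / length(classifier$selected_genes)
  if (frac < min_present)
    stop_fmt("only %.0f%% of classifier genes present (minimum %.0f%%)",
             100 * frac, 100 * min_present)
  if (frac < 1)
    warn_fmt("%d classifier gene(s) missing from the dataset; scoring on the rest",
             length(classifier$selected_genes) - length(present))
  z <- zscore_rows(values[present, , drop = FALSE])
  scores <- signature_scores(z, classifier$signature)
  labels <- predict_from_scores(scores)
  names(labels) <- colnames(values)
  labels
}

#' Up/down-signature risk scores (SAMS-style)
#'
#' Z-scores each available signature gene within the dataset, then computes
#' per sample the mean z over up genes (`up_score`), the mean z over down
#' genes (`down_score`) and `combined = up_score - down_score`. Samples with
#' a combined score strictly above the cohort median are called high risk;
#' ties go to low risk. Missing signature genes are dropped with a warning.
#'
#' @param up_genes,down_genes gene id vectors (one may be empty).
#' @param values genes x samples matrix.
#' @param standardise if `FALSE`, `values` are taken as already standardised
#'   (useful for worked examples and precomputed z-matrices).
#' @return data frame: `sample_id`, `up_score`, `down_score`,
#'   `combined_score`, `risk` ("high"/"low").
#' @export
sams_score <- function(up_genes, down_genes, values, standardise = TRUE) {
  up <- intersect(up_genes, rownames(values))
  dn <- intersect(down_genes, rownames(values))
  n_missing <- (length(up_genes) - length(up)) + (length(down_genes) - length(dn))
  if (length(up) + length(dn) == 0)
    stop_fmt("no signature genes present in the dataset")
  if (n_missing > 0)
    warn_fmt("%d signature gene(s) absent; scoring on the %d present",
             n_missing, length(up) + length(dn))
  z <- if (standardise) zscore_rows(values[c(up, dn), , drop = FALSE])
       else values[c(up, dn), , drop = FALSE]
  up_score <- if (length(up)) colMeans(z[up, , drop = FALSE]) else rep(0, ncol(values))
  down_score <- if (length(dn)) colMeans(z[dn, , drop = FALSE]) else rep(0, ncol(values))
  combined <- up_score - down_score
  risk <- ifelse(combined > stats::median(combined), "high", "low")
  data.frame(sample_id = colnames(values), up_score = up_score,
             down_score = down_score, combined_score = combined,
             risk = risk, row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent agreement between two binary risk assignments
#'
#' @param labels_a,labels_b vectors of risk calls named by sample id (or
#'   unnamed and aligned).
#' @return percent of samples with equal calls (0-100).
#' @export
method_agreement <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (!length(common)) stop_fmt("risk assignments share no samples")
    labels_a <- labels_a[common]; labels_b <- labels_b[common]
  } else if (length(labels_a) != length(labels_b)) {
    stop_fmt("unnamed risk assignments must have equal length")
  }
  100 * mean(labels_a == labels_b)
}

#' Identify the low-risk cluster from training survival data
#'
#' The low-risk cluster is the one with the best observed survival,
#' measured by the smallest crude event rate (events per person-time); all
#' other clusters are treated as equally high risk downstream.
#'
#' @param labels named cluster labels (NA ignored).
#' @param time,event survival follow-up and event indicator, aligned with
#'   `labels` by name or position.
#' @return integer cluster id.
#' @export
pick_low_risk_cluster <- function(labels, time, event) {
  labels <- solution_labels(labels)
  ok <- !is.na(labels) & !is.na(time) & !is.na(event)
  if (!any(ok)) stop_fmt("no survival data among clustered samples")
  labels <- labels[ok]; time <- time[ok]; event <- event[ok]
  rates <- tapply(seq_along(labels), labels, function(i) sum(event[i]) / sum(time[i]))
  as.integer(names(rates)[which.min(rates)])
}

#' Map cluster labels to high/low risk groups
#'
#' @param labels cluster labels (NA allowed).
#' @param low_risk_cluster the single low-risk cluster id.
#' @return character vector "high"/"low" (NA preserved), named like
#'   `labels`.
#' @export
risk_from_clusters <- function(labels, low_risk_cluster) {
  labels <- solution_labels(labels)
  out <- ifelse(is.na(labels), NA_character_,
                ifelse(labels == low_risk_cluster, "low", "high"))
  names(out) <- names(labels)
  out
}
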