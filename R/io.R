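# Plain-text I/O: expression TSV (genes x samples, first column gene id),
# phenotype CSV, classifier / signature / params JSON.

#' Write an expression matrix as tab-delimited text
#'
#' @param values genes x samples matrix.
#' @param path output file; first column `gene_id`, header row of sample ids.
#' @export
write_expression_tsv <- function(values, path) {
  df <- data.frame(gene_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited expression matrix
#'
#' Non-numeric expression cells raise an error naming the offending gene and
#' sample; duplicated gene rows are collapsed by their mean with a warning.
#'
#' @param path TSV with gene ids in the first column.
#' @return genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_fmt("expression file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_fmt("expression file %s has no sample columns", path)
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v))
      if (length(bad))
        stop_fmt("non-numeric expression value '%s' at gene %s, sample %s",
                 v[bad[1]], genes[bad[1]], colnames(vals)[j])
      vals[[j]] <- suppress
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warn_fmt("%d duplicated gene id(s) collapsed by mean: %s%s", length(dup),
             paste(utils::head(dup, 5), collapse = ", "),
             if (length(dup) > 5) ", ..." else "")
    m <- rowsum(m, group = genes) / as.vector(table(genes)[unique(genes)])
    m <- m[order(rownames(m)), , drop = FALSE]
  }
  m
}

#' Load one cohort from expression TSV + phenotype CSV
#'
#' @param expr_path tab-delimited genes x samples expression file.
#' @param pheno_path CSV with one row per sample (`sample_id`,
#'   `disease_status`, optional clinical fields).
#' @param cohort_id batch label for the cohort.
#' @return a [cohort_data()].
#' @export
load_cohort <- function(expr_path, pheno_path, cohort_id) {
  if (!file.exists(pheno_path)) stop_fmt("phenotype file not found: %s", pheno_path)
  expr <- read_expression_tsv(expr_path)
  pheno <- utils::read.csv(pheno_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(pheno)) stop_fmt("phenotype file lacks sample_id")
  pheno$cohort_id <- cohort_id
  only_expr <- setdiff(colnames(expr), pheno$sample_id)
  only_pheno <- setdiff(pheno$sample_id, colnames(expr))
  if (length(only_expr) || length(only_pheno))
    stop_fmt("sample id mismatch for cohort '%s': missing phenotype for [%s]; missing expression for [%s]",
             cohort_id, paste(only_expr, collapse = ", "),
             paste(only_pheno, collapse = ", "))
  cohort_data(expr, pheno, cohort_id)
}

#' Write a phenotype table as CSV
#' @param annotations data frame of per-sample phenotypes.
#' @param path output CSV path.
#' @export
write_pheno_csv <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a cluster classifier to JSON
#'
#' Layout: `{k, clusters: {c: {up: [...], down: [...]}}, policy,
#' training_accuracy, low_risk_cluster, selected_genes, seed}`.
#'
#' @param classifier a `cluster_classifier`.
#' @param path output JSON path.
#' @export
write_classifier_json <- function(classifier, path) {
  stopifnot(inherits(classifier, "cluster_classifier"))
  obj <- list(
    k = classifier$k,
    clusters = lapply(classifier$signature, function(s)
      list(up = as.list(s$up), down = as.list(s$down))),
    policy = classifier$policy,
    training_accuracy = classifier$training_accuracy,
    cv_accuracy = classifier$cv_accuracy,
    low_risk_cluster = if (is.na(classifier$low_risk_cluster)) NULL
                       else classifier$low_risk_cluster,
    selected_genes = as.list(classifier$selected_genes),
    seed = classifier$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cluster classifier from JSON
#' @param path JSON produced by [write_classifier_json()].
#' @return a `cluster_classifier`.
#' @export
read_classifier_json <- function(path) {
  obj <- jsonlite::read_json(path)
  sig <- lapply(obj$clusters, function(s)
    list(up = unlist(s$up) %||% character(0), down = unlist(s$down) %||% character(0)))
  structure(list(
    k = obj$k, signature = sig,
    selected_genes = unlist(obj$selected_genes) %||% character(0),
    policy = obj$policy,
    training_accuracy = obj$training_accuracy,
    cv_accuracy = obj$cv_accuracy,
    low_risk_cluster = if (is.null(obj$low_risk_cluster)) NA_integer_
                       else as.integer(obj$low_risk_cluster),
    seed = as.integer(obj$seed %||% NA_integer_)
  ), class = "cluster_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the simulated study to disk
#'
#' Emits `expr_<cohort>.tsv` per cohort, a pooled `pheno.csv` and
#' `truth.json` (latent clusters, signature genes, hazards).
#'
#' @param sim result of [simulate_multi_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (co in sim$cohorts)
    write_expression_tsv(co$expression, file.path(out_dir, sprintf("expr_%s.tsv", co$cohort_id)))
  ann <- do.call(rbind, lapply(sim$cohorts, function(co) co$annotations))
  write_pheno_csv(ann, file.path(out_dir, "pheno.csv"))
  truth <- list(
    latent_cluster = as.list(sim$truth$latent_cluster),
    signature_genes = sim$truth$signature_genes,
    true_hazard = sim$truth$true_hazard
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
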