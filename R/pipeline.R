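#' Assemble and validate a run configuration
#'
#' A run configuration names the cohorts (in-memory [cohort_data()] objects
#' or `expr`/`pheno` file paths with roles), the output directory, the seed,
#' and one parameter block per stage. A discovery run requires at least two
#' discovery cohorts, each containing healthy controls.
#'
#' @param cohorts list of [cohort_data()] (or lists with `expr`, `pheno`,
#'   `cohort_id` paths).
#' @param roles character vector, one of "discovery"/"validation" per
#'   cohort.
#' @param out_dir artifact directory.
#' @param seed integer master seed.
#' @param conorm,cluster,classifier named lists overriding stage defaults.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohorts, roles, out_dir, seed = 1,
                       conorm = list(), cluster = list(), classifier = list()) {
  if (length(cohorts) != length(roles))
    stop_fmt("roles must be given for every cohort")
  if (!all(roles %in% c("discovery", "validation")))
    stop_fmt("roles must be 'discovery' or 'validation'")
  conorm_def <- list(min_controls = 3, tol = 1e-4, max_iter = 100)
  cluster_def <- list(k_values = 2:8,
                      gene_counts = c(100, 250, 500, 1000, 2500, 5000),
                      n_restarts = 20, gap_B = 50, ref_nstart = 5, neighbours = 10)
  classifier_def <- list(alpha_fdr = 0.01, min_effect = 0.5, max_genes = 30,
                         cv_folds = 5, improvement = 0.001, min_present = 0.8)
  structure(list(
    cohorts = cohorts, roles = roles, out_dir = out_dir, seed = as.integer(seed),
    conorm = utils::modifyList(conorm_def, conorm),
    cluster = utils::modifyList(cluster_def, cluster),
    classifier = utils::modifyList(classifier_def, classifier)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` needs the yaml package, `.json`
#'   uses jsonlite). Fields mirror [run_config()], with cohorts given as
#'   `{expr, pheno, cohort_id, role}` entries.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_fmt("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path)
  flatten_block <- function(b)
    lapply(b, function(v) if (is.list(v)) unlist(v) else v)
  cohorts <- lapply(obj$cohorts, function(co) co[c("expr", "pheno", "cohort_id")])
  roles <- vapply(obj$cohorts, function(co) co$role, "")
  run_config(cohorts, roles, out_dir = obj$out_dir, seed = obj$seed %||% 1,
             conorm = flatten_block(obj$conorm %||% list()),
             cluster = flatten_block(obj$cluster %||% list()),
             classifier = flatten_block(obj$classifier %||% list()))
}

resolve_cohorts <- function(config, role) {
  idx <- which(config$roles == role)
  lapply(idx, function(i) {
    co <- config$cohorts[[i]]
    if (inherits(co, "cohort_data")) co
    else load_cohort(co$expr, co$pheno, co$cohort_id)
  })
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_fmt("stage '%s' failed: %s", name, conditionMessage(e)))
}

write_manifest <- function(out_dir, entries, seed, params) {
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  hashes <- as.list(tools::md5sum(sort(files)))
  names(hashes) <- basename(names(hashes))
  manifest <- list(package = "fibrotype",
                   version = as.character(utils::packageVersion("fibrotype")),
                   seed = seed, params = params, results = entries,
                   artifact_md5 = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Run the discovery stage end to end
#'
#' Pools the discovery cohorts on common genes, co-normalises them with
#' controls-only ComBat, removes the controls, runs the clustering validity
#' grid and optimality map, derives the consensus assignment with
#' unclustered calls, compares clinical traits across clusters, derives
#' candidate genes and trains the greedy classifier. When survival data are
#' available among clustered training samples the low-risk cluster (best
#' observed survival) is recorded in the classifier. All artifacts plus a
#' manifest (seed, parameter blocks, artifact checksums) are written under
#' `config$out_dir`; a rerun with the same config and seed is byte-identical.
#'
#' @param config a [run_config()] with >= 2 discovery cohorts, each with
#'   controls.
#' @return list: `pooled` (co-normalised case matrix), `annotations`,
#'   `params` ([fit_control_combat()]), `grid`, `map`, `solution`,
#'   `traits`, `candidates`, `classifier`, `mixing` (pre/post scores),
#'   `manifest`.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "run_config"))
  discovery <- stage("load", resolve_cohorts(config, "discovery"))
  if (length(discovery) < 2) stop_fmt("a discovery run needs >= 2 discovery cohorts")
  for (co in discovery) {
    n_ctrl <- sum(co$annotations$disease_status == "control")
    if (n_ctrl < config$conorm$min_controls)
      stop_fmt("discovery cohort '%s' has %d controls (< %d): cannot co-normalise",
               co$cohort_id, n_ctrl, config$conorm$min_controls)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  pooled <- stage("pool", intersect_and_pool(discovery))
  params <- stage("conorm_fit", fit_control_combat(
    pooled$expression, pooled$annotations,
    min_controls = config$conorm$min_controls,
    tol = config$conorm$tol, max_iter = config$conorm$max_iter))
  adjusted <- stage("conorm_apply", apply_conormalization(
    pooled$expression, pooled$annotations, params))

  is_case <- pooled$annotations$disease_status == "case"
  batch <- pooled$annotations$cohort_id
  mixing <- c(
    pre = batch_mixing_score(pooled$expression[params$genes, is_case, drop = FALSE],
                             batch[is_case]),
    post = batch_mixing_score(adjusted[, is_case, drop = FALSE], batch[is_case]))

  # healthy controls are removed from all further analysis
  cases <- adjusted[, is_case, drop = FALSE]
  case_ann <- pooled$annotations[is_case, , drop = FALSE]

  cl <- config$cluster
  grid <- stage("grid", run_grid(cases, k_values = cl$k_values,
                                 gene_counts = cl$gene_counts,
                                 n_restarts = cl$n_restarts, gap_B = cl$gap_B,
                                 ref_nstart = cl$ref_nstart,
                                 neighbours = cl$neighbours, seed = config$seed))
  map <- stage("optimality_map", build_optimality_map(grid))
  solution <- stage("consensus", consensus_assign(grid, map$chosen_k,
                                                  map$chosen_gene_count))
  traits <- stage("traits", compare_traits(case_ann, solution))

  cf <- config$classifier
  candidates <- stage("candidates", derive_candidate_genes(
    cases, solution, alpha_fdr = cf$alpha_fdr, min_effect = cf$min_effect))
  classifier <- stage("classifier", greedy_train(
    cases, solution, candidates, max_genes = cf$max_genes,
    cv_folds = cf$cv_folds, improvement = cf$improvement,
    seed = derive_seed(config$seed, 17)))
  surv_ok <- !is.na(case_ann$time) & !is.na(case_ann$event) &
    !is.na(solution$labels[case_ann$sample_id])
  if (any(surv_ok)) {
    classifier$low_risk_cluster <- pick_low_risk_cluster(
      solution$labels[case_ann$sample_id[surv_ok]],
      case_ann$time[surv_ok], case_ann$event[surv_ok])
  }

  # artifacts
  write_expression_tsv(cases, file.path(config$out_dir, "conorm_cases.tsv"))
  write_pheno_csv(case_ann, file.path(config$out_dir, "pheno_cases.csv"))
  utils::write.table(grid$cells, file.path(config$out_dir, "validity_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(map$scores, file.path(config$out_dir, "optimality_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(solution), file.path(config$out_dir, "solution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(traits, file.path(config$out_dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_classifier_json(classifier, file.path(config$out_dir, "classifier.json"))

  manifest <- write_manifest(
    config$out_dir,
    entries = list(
      n_common_genes = length(params$genes),
      n_cases = sum(is_case), n_controls = sum(!is_case),
      mixing_pre = unname(mixing["pre"]), mixing_post = unname(mixing["post"]),
      chosen_k = map$chosen_k, chosen_gene_count = map$chosen_gene_count,
      unclustered_fraction = solution$unclustered_fraction,
      cluster_sizes = as.list(table(factor(solution$labels, levels = seq_len(solution$k)))),
      n_classifier_genes = length(classifier$selected_genes),
      training_accuracy = classifier$training_accuracy,
      low_risk_cluster = if (is.na(classifier$low_risk_cluster)) NULL
                         else classifier$low_risk_cluster),
    seed = config$seed,
    params = config[c("conorm", "cluster", "classifier")])

  list(pooled = cases, annotations = case_ann, params = params, grid = grid,
       map = map, solution = solution, traits = traits,
       candidates = candidates, classifier = classifier,
       mixing = mixing, manifest = manifest)
}

#' Run the validation stage
#'
#' Applies a trained classifier to each validation cohort (within-dataset
#' z-scoring; cohorts are never co-normalised with discovery data), scores
#' an optional up/down risk signature (SAMS-style) per cohort, compares
#' clinical traits across predicted clusters, and — where survival data
#' exist — fits Kaplan-Meier/log-rank and Cox models for classifier risk
#' (univariate and covariate-adjusted, with a nested LRT) and, when a
#' signature is supplied, for signature risk, plus the percent agreement
#' between the two risk assignments.
#'
#' @param config a [run_config()] with >= 1 validation cohort.
#' @param classifier a trained `cluster_classifier` with
#'   `low_risk_cluster` set (required for risk analyses).
#' @param sams_signature optional list with `up` and `down` gene id vectors.
#' @param covariates covariate columns for the adjusted Cox model
#'   (default `c("age", "sex", "fvc_pct", "dlco_pct")`).
#' @return list: `labels`, `risk`, `sams`, `traits`, `agreement`,
#'   `survival` (cluster/risk log-rank + Cox models + LRT; NULL when no
#'   survival data), `manifest`.
#' @export
run_validation <- function(config, classifier, sams_signature = NULL,
                           covariates = c("age", "sex", "fvc_pct", "dlco_pct")) {
  stopifnot(inherits(config, "run_config"), inherits(classifier, "cluster_classifier"))
  cohorts <- stage("load", resolve_cohorts(config, "validation"))
  if (!length(cohorts)) stop_fmt("no validation cohorts in config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  labels <- integer(0); sams_all <- NULL
  for (co in cohorts) {
    lab <- stage(paste0("classify_", co$cohort_id),
                 classify_samples(classifier, co$expression,
                                  min_present = config$classifier$min_present))
    labels <- c(labels, lab)
    if (!is.null(sams_signature)) {
      sc <- stage(paste0("sams_", co$cohort_id),
                  sams_score(sams_signature$up, sams_signature$down, co$expression))
      sc$cohort_id <- co$cohort_id
      sams_all <- rbind(sams_all, sc)
    }
  }
  ann <- do.call(rbind, lapply(cohorts, function(co) co$annotations))
  traits <- stage("traits", compare_traits(ann, labels))

  risk <- NULL; survival_out <- NULL; agreement <- NULL
  if (!is.na(classifier$low_risk_cluster)) {
    risk <- risk_from_clusters(labels, classifier$low_risk_cluster)
  }
  if (!is.null(sams_all) && !is.null(risk)) {
    sams_risk <- stats::setNames(sams_all$risk, sams_all$sample_id)
    agreement <- method_agreement(risk, sams_risk)
  }

  has_surv <- all(c("time", "event") %in% names(ann)) &&
    any(!is.na(ann$time) & !is.na(ann$event))
  if (!has_surv) {
    warn_fmt("no survival data in any validation cohort; survival section skipped")
  } else {
    d <- ann[!is.na(ann$time) & !is.na(ann$event), , drop = FALSE]
    d$cluster <- factor(labels[d$sample_id])
    survival_out <- list()
    survival_out$km_cluster <- km_logrank(d$time, d$event, d$cluster)
    if (!is.null(risk)) {
      d$risk <- factor(risk[d$sample_id], levels = c("low", "high"))
      survival_out$km_risk <- km_logrank(d$time, d$event, d$risk)
      survival_out$cox_risk <- stage("cox_risk", cox_fit(d, "risk"))
      cc <- covariates[covariates %in% names(d)]
      cc_ok <- cc[vapply(cc, function(v) {
        x <- d[[v]][stats::complete.cases(d[, c("time", "event", "risk", cc)])]
        length(unique(x)) > 1
      }, TRUE)]
      dc <- d[stats::complete.cases(d[, c("time", "event", "risk", cc_ok)]), , drop = FALSE]
      if (length(cc_ok) && nrow(dc) > 5 * (length(cc_ok) + 1)) {
        survival_out$cox_risk_adjusted <- stage("cox_adj",
          cox_fit(dc, "risk", covariates = cc_ok))
        survival_out$cox_covariates_only <- stage("cox_cov",
          cox_fit(dc, cc_ok[1], covariates = cc_ok[-1]))
        survival_out$lrt_risk <- lrt_nested(survival_out$cox_risk_adjusted,
                                            survival_out$cox_covariates_only)
      }
      if (!is.null(sams_all)) {
        ds <- merge(d, sams_all[, c("sample_id", "risk")], by = "sample_id",
                    suffixes = c("", "_sams"))
        ds$risk_sams <- factor(ds$risk_sams, levels = c("low", "high"))
        if (nlevels(droplevels(ds$risk_sams)) == 2) {
          survival_out$km_sams <- km_logrank(ds$time, ds$event, ds$risk_sams)
          survival_out$cox_sams <- stage("cox_sams", cox_fit(ds, "risk_sams"))
        }
      }
    }
  }

  lab_df <- data.frame(sample_id = names(labels), label = labels,
                       risk = if (is.null(risk)) NA_character_ else risk[names(labels)],
                       stringsAsFactors = FALSE)
  utils::write.table(lab_df, file.path(config$out_dir, "validation_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sams_all))
    utils::write.table(sams_all, file.path(config$out_dir, "validation_sams.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(traits, file.path(config$out_dir, "validation_traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  entries <- list(
    n_validation = length(labels),
    cluster_sizes = as.list(table(factor(labels, levels = seq_len(classifier$k)))),
    agreement_pct = agreement)
  if (!is.null(survival_out$cox_risk)) {
    entries$hr_high_vs_low <- unname(survival_out$cox_risk$hr[1])
    entries$c_index_risk <- survival_out$cox_risk$c_index
  }
  if (!is.null(survival_out$lrt_risk)) entries$lrt_p <- survival_out$lrt_risk$p
  manifest <- write_manifest(config$out_dir, entries, config$seed,
                             config[c("classifier")])

  list(labels = labels, risk = risk, sams = sams_all, traits = traits,
       agreement = agreement, survival = survival_out, manifest = manifest)
}
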