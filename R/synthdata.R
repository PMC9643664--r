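#' Simulation configuration for the multi-cohort generator
#'
#' Bundles and validates every knob of the synthetic multi-cohort study:
#' cohort sizes, the latent case-subgroup structure, the batch-effect model,
#' survival hazards and clinical covariate shifts. Defaults emulate a
#' three-cohort blood-transcriptome discovery design: cases 70/93/57 with
#' healthy controls 45/30/20, three latent case subgroups in proportions
#' roughly 0.33/0.48/0.19, and one low-risk subgroup (cluster 2) with a much
#' lower event hazard than the other two.
#'
#' The batch model matches the ComBat generative form: for batch b and gene g,
#' `x = mu_g + shift + gamma_bg + delta_bg * eps`, with `gamma_bg ~
#' Normal(0, batch_additive_sd)` and `delta2_bg ~ InvGamma(shape, shape - 1)`
#' (mean 1; smaller shape = wider multiplicative spread). Case samples are
#' additionally shifted by `±effect_size * noise_sd` on their subgroup's
#' signature genes.
#'
#' @param n_cohorts number of cohorts (batches).
#' @param n_cases integer vector (length `n_cohorts`) of cases per cohort.
#' @param n_controls integer vector of healthy controls per cohort (0 allowed,
#'   for validation-style cohorts).
#' @param n_genes_total number of genes in the simulated universe.
#' @param common_fraction fraction of genes shared by every cohort's platform
#'   (1 = identical panels).
#' @param K number of latent case subgroups (>= 2).
#' @param cluster_proportions simplex vector of length `K`.
#' @param n_signature_genes signature genes per subgroup (disjoint sets).
#' @param effect_size mean shift on signature genes, in units of `noise_sd`.
#' @param batch_additive_sd SD of per-batch additive offsets `gamma_bg`.
#' @param batch_scale_shape inverse-gamma shape (> 2) of the per-batch
#'   multiplicative variance factors `delta2_bg`; the default 5 gives
#'   multiplicative factors with SD about 0.3 around 1.
#' @param noise_sd residual SD on the log2 scale.
#' @param hazard_per_cluster positive event rates (per year) per subgroup.
#' @param censoring_rate exponential censoring rate (per year).
#' @param covariate_shift named list of per-subgroup additive shifts for
#'   `fvc_pct`, `dlco_pct`, `fev1_pct` (each a length-`K` numeric). `NULL`
#'   gives defaults in which the low-hazard subgroup has relatively preserved
#'   lung function.
#' @param weibull_shape Weibull shape for event times; 1 (default) gives
#'   exponential survival with closed-form oracles.
#' @param mask_phenotypes if `TRUE`, randomly mask ~20% of lung-function and
#'   genotype fields to emulate partially reported clinical tables.
#' @param cohort_prefix prefix for cohort (and sample) identifiers; use a
#'   distinct prefix (e.g. `"val"`) when simulating validation cohorts so
#'   sample ids do not collide with a discovery simulation.
#' @param seed integer RNG seed; the same seed reproduces the data exactly.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 3,
                       n_cases = c(70, 93, 57),
                       n_controls = c(45, 30, 20),
                       n_genes_total = 2000,
                       common_fraction = 1,
                       K = 3,
                       cluster_proportions = c(0.33, 0.48, 0.19),
                       n_signature_genes = 150,
                       effect_size = 1.5,
                       batch_additive_sd = 2,
                       batch_scale_shape = 5,
                       noise_sd = 1,
                       hazard_per_cluster = c(0.25, 0.08, 0.30),
                       censoring_rate = 0.10,
                       covariate_shift = NULL,
                       weibull_shape = 1,
                       mask_phenotypes = FALSE,
                       cohort_prefix = "cohort",
                       seed = 1) {
  if (length(n_cases) == 1) n_cases <- rep(n_cases, n_cohorts)
  if (length(n_controls) == 1) n_controls <- rep(n_controls, n_cohorts)
  if (length(n_cases) != n_cohorts || length(n_controls) != n_cohorts)
    stop_fmt("n_cases / n_controls must have length n_cohorts (%d)", n_cohorts)
  if (any(n_cases < 0) || any(n_controls < 0)) stop_fmt("cohort sizes must be >= 0")
  if (!is_count(K) || K < 2) stop_fmt("K must be an integer >= 2")
  if (length(cluster_proportions) != K)
    stop_fmt("cluster_proportions must have length K = %d", K)
  if (any(cluster_proportions < 0) || abs(sum(cluster_proportions) - 1) > 1e-9)
    stop_fmt("cluster_proportions must be non-negative and sum to 1 (within 1e-9)")
  if (length(hazard_per_cluster) != K || any(hazard_per_cluster <= 0))
    stop_fmt("hazard_per_cluster must be %d positive rates", K)
  if (effect_size < 0) stop_fmt("effect_size must be >= 0")
  if (common_fraction <= 0 || common_fraction > 1)
    stop_fmt("common_fraction must be in (0, 1]")
  if (batch_scale_shape <= 2)
    stop_fmt("batch_scale_shape must be > 2 (finite variance of scale factors)")
  if (censoring_rate <= 0) stop_fmt("censoring_rate must be positive")
  if (K * n_signature_genes > n_genes_total)
    stop_fmt("signature genes (%d x %d) exceed n_genes_total", K, n_signature_genes)
  expected <- sum(n_cases) * cluster_proportions
  if (any(expected < 2))
    stop_fmt("expected case count < 2 in cluster(s) %s; enlarge cohorts or proportions",
             paste(which(expected < 2), collapse = ", "))
  if (is.null(covariate_shift)) {
    covariate_shift <- default_covariate_shift(K, hazard_per_cluster)
  }
  for (nm in names(covariate_shift)) {
    if (length(covariate_shift[[nm]]) != K)
      stop_fmt("covariate_shift$%s must have length K = %d", nm, K)
  }
  structure(list(
    n_cohorts = n_cohorts, n_cases = n_cases, n_controls = n_controls,
    n_genes_total = n_genes_total, common_fraction = common_fraction,
    K = K, cluster_proportions = cluster_proportions,
    n_signature_genes = n_signature_genes, effect_size = effect_size,
    batch_additive_sd = batch_additive_sd, batch_scale_shape = batch_scale_shape,
    noise_sd = noise_sd, hazard_per_cluster = hazard_per_cluster,
    censoring_rate = censoring_rate, covariate_shift = covariate_shift,
    weibull_shape = weibull_shape, mask_phenotypes = mask_phenotypes,
    cohort_prefix = cohort_prefix, seed = as.integer(seed)
  ), class = "sim_config")
}

# Lung function is relatively preserved in the lowest-hazard subgroup.
default_covariate_shift <- function(K, hazards) {
  low <- which.min(hazards)
  mk <- function(good, bad) {
    s <- rep(bad, K); s[low] <- good; s
  }
  list(fvc_pct = mk(4, -2), dlco_pct = mk(6, -4), fev1_pct = mk(3, -2))
}

#' Container for one simulated or loaded cohort
#'
#' @param expression genes x samples log2 expression matrix.
#' @param annotations data frame of per-sample phenotypes; must contain
#'   `sample_id`, `cohort_id` and `disease_status` (`"case"`/`"control"`).
#' @param cohort_id cohort (batch) label.
#' @return object of class `cohort_data`.
#' @export
cohort_data <- function(expression, annotations, cohort_id) {
  validate_expression(expression, sprintf("cohort '%s' expression", cohort_id))
  if (!all(c("sample_id", "cohort_id", "disease_status") %in% names(annotations)))
    stop_fmt("annotations need sample_id, cohort_id, disease_status columns")
  if (!setequal(colnames(expression), annotations$sample_id))
    stop_fmt("cohort '%s': expression and annotation sample sets differ", cohort_id)
  if (!all(annotations$disease_status %in% c("case", "control")))
    stop_fmt("disease_status must be 'case' or 'control'")
  annotations <- annotations[match(colnames(expression), annotations$sample_id), , drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(expression = expression, annotations = annotations,
                 cohort_id = cohort_id), class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data '%s'> %d genes x %d samples (%d cases, %d controls)\n",
              x$cohort_id, nrow(x$expression), ncol(x$expression),
              sum(x$annotations$disease_status == "case"),
              sum(x$annotations$disease_status == "control")))
  invisible(x)
}

#' Simulate a multi-cohort expression study with known ground truth
#'
#' Generates `n_cohorts` cohorts of log2-scale expression with per-batch
#' additive/multiplicative effects, `K` latent case subgroups carrying
#' disjoint up/down gene signatures, subgroup-dependent exponential (or
#' Weibull) survival and clinical covariate shifts, plus healthy controls
#' that carry no subgroup signal. Platform differences (partially
#' overlapping gene panels) are injected when `common_fraction < 1`.
#'
#' @param config a [sim_config()].
#' @param truth optional `synthetic_truth` from a previous simulation: its
#'   baseline means, signature genes and directions are reused (so a
#'   classifier trained on the earlier study applies), while batch effects,
#'   samples, covariates and survival are drawn fresh — the natural way to
#'   simulate independent validation cohorts.
#' @return list with elements `cohorts` (list of [cohort_data()]) and
#'   `truth` (class `synthetic_truth`: `latent_cluster` named by case sample,
#'   `signature_genes` per subgroup with `up`/`down` gene sets, the batch
#'   effect matrices `gamma` and `delta2`, and the true hazards).
#' @export
simulate_multi_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes_total
  if (is.null(truth)) {
    genes <- sprintf("G%05d", seq_len(G))
    mu <- stats::rnorm(G, mean = 8, sd = 2)
    names(mu) <- genes

    # disjoint signature gene sets with random up/down directions
    sig_pool <- sample(genes, config$K * config$n_signature_genes)
    signature_genes <- vector("list", config$K)
    shift_mat <- matrix(0, G, config$K, dimnames = list(genes, NULL))
    for (k in seq_len(config$K)) {
      gk <- sig_pool[((k - 1) * config$n_signature_genes + 1):(k * config$n_signature_genes)]
      dir_up <- as.logical(stats::rbinom(length(gk), 1, 0.5))
      signature_genes[[k]] <- list(up = sort(gk[dir_up]), down = sort(gk[!dir_up]))
      shift_mat[gk, k] <- ifelse(dir_up, 1, -1) * config$effect_size * config$noise_sd
    }
    names(signature_genes) <- as.character(seq_len(config$K))
  } else {
    stopifnot(inherits(truth, "synthetic_truth"))
    if (length(truth$baseline_mean) != G || length(truth$signature_genes) != config$K)
      stop_fmt("config is incompatible with the supplied truth (genes/K differ)")
    mu <- truth$baseline_mean
    genes <- names(mu)
    signature_genes <- truth$signature_genes
    shift_mat <- matrix(0, G, config$K, dimnames = list(genes, NULL))
    for (k in seq_len(config$K)) {
      sg <- signature_genes[[k]]
      shift_mat[sg$up, k] <- config$effect_size * config$noise_sd
      shift_mat[sg$down, k] <- -config$effect_size * config$noise_sd
    }
  }

  B <- config$n_cohorts
  cohort_ids <- sprintf("%s%d", config$cohort_prefix, seq_len(B))
  gamma <- matrix(stats::rnorm(B * G, 0, config$batch_additive_sd), B, G,
                  dimnames = list(cohort_ids, genes))
  a <- config$batch_scale_shape
  delta2 <- matrix(1 / stats::rgamma(B * G, shape = a, rate = a - 1), B, G,
                   dimnames = list(cohort_ids, genes))

  cohorts <- vector("list", B)
  latent <- integer(0)
  for (b in seq_len(B)) {
    nca <- config$n_cases[b]; nco <- config$n_controls[b]
    n <- nca + nco
    ids <- sprintf("%s_S%03d", cohort_ids[b], seq_len(n))
    status <- c(rep("case", nca), rep("control", nco))
    cl <- if (nca > 0) sample(seq_len(config$K), nca, replace = TRUE,
                              prob = config$cluster_proportions) else integer(0)
    base <- matrix(mu, G, n, dimnames = list(genes, ids))
    if (nca > 0) base[, seq_len(nca)] <- base[, seq_len(nca), drop = FALSE] + shift_mat[, cl, drop = FALSE]
    eps <- matrix(stats::rnorm(G * n, 0, config$noise_sd), G, n)
    x <- base + gamma[b, ] + sqrt(delta2[b, ]) * eps

    age <- stats::rnorm(n, 67, 8)
    sex <- ifelse(stats::rbinom(n, 1, 0.7) == 1, "male", "female")
    ancestry <- ifelse(stats::rbinom(n, 1, 0.85) == 1, "European", "other")
    smoking <- stats::rbinom(n, 1, 0.65) == 1
    muc5b <- sample(c("GG", "GT", "TT"), n, replace = TRUE, prob = c(0.3, 0.6, 0.1))
    cs <- config$covariate_shift
    sh <- function(field) c(cs[[field]][cl], rep(0, nco))
    fvc <- stats::rnorm(n, 65, 15) + sh("fvc_pct")
    dlco <- stats::rnorm(n, 45, 12) + sh("dlco_pct")
    fev1 <- stats::rnorm(n, 74, 15) + sh("fev1_pct")
    fvc <- pmin(pmax(fvc, 15), 140); dlco <- pmin(pmax(dlco, 10), 140)
    fev1 <- pmin(pmax(fev1, 15), 140)

    time <- rep(NA_real_, n); event <- rep(NA_integer_, n)
    if (nca > 0) {
      haz <- config$hazard_per_cluster[cl]
      t_event <- stats::rweibull(nca, shape = config$weibull_shape, scale = 1 / haz)
      t_cens <- stats::rexp(nca, rate = config$censoring_rate)
      time[seq_len(nca)] <- pmin(t_event, t_cens)
      event[seq_len(nca)] <- as.integer(t_event <= t_cens)
    }

    ann <- data.frame(
      sample_id = ids, cohort_id = cohort_ids[b], disease_status = status,
      age = age, sex = sex, ancestry = ancestry,
      fvc_pct = fvc, dlco_pct = dlco, fev1_pct = fev1,
      smoking_ever = smoking, muc5b = muc5b,
      time = time, event = event, stringsAsFactors = FALSE
    )
    if (config$mask_phenotypes) {
      for (f in c("fvc_pct", "dlco_pct", "fev1_pct", "muc5b", "smoking_ever")) {
        mask <- stats::rbinom(n, 1, 0.2) == 1
        ann[[f]][mask] <- NA
      }
    }
    cohorts[[b]] <- cohort_data(x, ann, cohort_ids[b])
    if (nca > 0) {
      v <- cl; names(v) <- ids[seq_len(nca)]
      latent <- c(latent, v)
    }
  }

  truth <- structure(list(
    latent_cluster = latent,
    signature_genes = signature_genes,
    true_gamma = gamma,
    true_delta2 = delta2,
    true_hazard = config$hazard_per_cluster,
    baseline_mean = mu,
    config = config
  ), class = "synthetic_truth")

  if (config$common_fraction < 1) {
    keep <- unlist(lapply(signature_genes, unlist), use.names = FALSE)
    cohorts <- inject_platform_differences(cohorts, config$common_fraction,
                                           keep_genes = keep)
  }
  list(cohorts = cohorts, truth = truth)
}

#' Emulate partially overlapping gene panels across cohorts
#'
#' Designates a common gene set (a `common_fraction` share of the gene
#' universe, always containing `keep_genes`) that every cohort retains; each
#' cohort additionally keeps a random private subset of the remaining genes.
#' The intersection of the returned gene lists equals the designated common
#' set exactly.
#'
#' @param cohorts list of [cohort_data()] sharing one gene universe.
#' @param common_fraction fraction of genes in the common set, in (0, 1].
#' @param keep_genes genes that must be part of the common set (e.g. planted
#'   signature genes).
#' @param seed optional seed; by default the current RNG stream is used.
#' @return list of [cohort_data()] with reduced gene panels.
#' @export
inject_platform_differences <- function(cohorts, common_fraction,
                                        keep_genes = NULL, seed = NULL) {
  if (common_fraction <= 0 || common_fraction > 1)
    stop_fmt("common_fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (common_fraction == 1) return(cohorts)
  universe <- sort(unique(unlist(lapply(cohorts, function(co) rownames(co$expression)))))
  n_common <- round(common_fraction * length(universe))
  if (n_common < 1) stop_fmt("common gene set would be empty")
  keep_genes <- intersect(keep_genes, universe)
  if (length(keep_genes) > n_common)
    stop_fmt("keep_genes (%d) exceed the common set size (%d)", length(keep_genes), n_common)
  common <- c(keep_genes, sample(setdiff(universe, keep_genes), n_common - length(keep_genes)))
  rest <- setdiff(universe, common)
  panels <- lapply(seq_along(cohorts), function(i) {
    priv <- rest[stats::rbinom(length(rest), 1, 0.5) == 1]
    c(common, priv)
  })
  # a non-common gene must be absent from at least one cohort
  if (length(rest)) {
    everywhere <- rest[vapply(rest, function(g) all(vapply(panels, function(p) g %in% p, TRUE)), TRUE)]
    for (g in everywhere) {
      drop_from <- sample(length(panels), 1)
      panels[[drop_from]] <- setdiff(panels[[drop_from]], g)
    }
  }
  out <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    keep <- intersect(rownames(co$expression), panels[[i]])
    out[[i]] <- cohort_data(co$expression[keep, , drop = FALSE], co$annotations, co$cohort_id)
  }
  out
}
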