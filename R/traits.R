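#' Compare clinical traits across clusters
#'
#' Routes each trait to the appropriate test: categorical traits
#' (character / factor / logical) to a chi-square test, falling back to
#' Fisher's exact test when any expected cell count is below 5; continuous
#' traits to one-way ANOVA when the overall sample skewness |g1| <= 1 and to
#' Kruskal-Wallis otherwise; and, when `time`/`event` columns are present, a
#' k-group log-rank test for survival. Missing values (including the string
#' "missing") are dropped per trait and the number of observations actually
#' used is reported. A trait represented in fewer than 2 groups is marked
#' untestable rather than raising an error.
#'
#' @param annotations data frame with `sample_id` and trait columns.
#' @param labels named cluster labels (NA = unclustered, excluded) or a
#'   `cluster_solution`.
#' @param traits trait columns to test; defaults to every column except
#'   identifiers and the survival pair.
#' @return data frame: trait, test, statistic, p, n_used, note.
#' @export
compare_traits <- function(annotations, labels, traits = NULL) {
  labels <- solution_labels(labels)
  labels <- labels[!is.na(labels)]
  ann <- annotations[match(names(labels), annotations$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) stop_fmt("annotations missing for some labelled samples")
  g <- factor(labels)
  if (nlevels(g) < 2) stop_fmt("need at least 2 clusters")
  if (is.null(traits))
    traits <- setdiff(names(ann), c("sample_id", "cohort_id", "disease_status",
                                    "time", "event"))
  out <- list()
  for (tr in traits) {
    x <- ann[[tr]]
    if (is.character(x)) x[x %in% c("", "missing")] <- NA
    ok <- !is.na(x)
    n_used <- sum(ok)
    gi <- droplevels(g[ok])
    row <- data.frame(trait = tr, test = NA_character_, statistic = NA_real_,
                      p = NA_real_, n_used = n_used, note = "",
                      stringsAsFactors = FALSE)
    counts <- table(gi)
    if (nlevels(gi) < 2 || sum(counts >= 2) < 2) {
      row$note <- "untestable: fewer than 2 groups with >= 2 observations"
      out[[tr]] <- row
      next
    }
    xi <- x[ok]
    res <- tryCatch({
      if (is.numeric(xi)) {
        sk <- sample_skewness(xi)
        if (is.na(sk) || abs(sk) <= 1) {
          fit <- stats::anova(stats::aov(xi ~ gi))
          list(test = "anova", statistic = fit$`F value`[1], p = fit$`Pr(>F)`[1])
        } else {
          kw <- stats::kruskal.test(xi, gi)
          list(test = "kruskal_wallis", statistic = unname(kw$statistic), p = kw$p.value)
        }
      } else {
        tab <- table(gi, xi)
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
          ft <- stats::fisher.test(tab, workspace = 2e6)
          list(test = "fisher_exact", statistic = NA_real_, p = ft$p.value)
        } else {
          ct <- stats::chisq.test(tab, correct = FALSE)
          list(test = "chi_square", statistic = unname(ct$statistic), p = ct$p.value)
        }
      }
    }, error = function(e) list(test = "failed", statistic = NA_real_,
                                p = NA_real_, note = conditionMessage(e)))
    row$test <- res$test
    row$statistic <- res$statistic
    row$p <- res$p
    if (!is.null(res$note)) row$note <- res$note
    out[[tr]] <- row
  }
  if (all(c("time", "event") %in% names(ann))) {
    ok <- !is.na(ann$time) & !is.na(ann$event)
    row <- data.frame(trait = "survival", test = "log_rank", statistic = NA_real_,
                      p = NA_real_, n_used = sum(ok), note = "",
                      stringsAsFactors = FALSE)
    gi <- droplevels(g[ok])
    if (nlevels(gi) >= 2 && sum(ann$event[ok]) >= 1) {
      lr <- km_logrank(ann$time[ok], ann$event[ok], gi)
      row$statistic <- lr$chisq; row$p <- lr$p
    } else {
      row$note <- "untestable: no events or fewer than 2 groups"
    }
    out[["survival"]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' GAP index (gender-age-physiology) for IPF mortality
#'
#' Point score 0-8 from the published staging table: sex (female 0, male 1);
#' age (<=60: 0, 61-65: 1, >65: 2); FVC % predicted (>=75: 0, 50-74: 1,
#' <50: 2); DLCO % predicted (>55: 0, 36-55: 1, <=35: 2, cannot perform: 3).
#'
#' @param sex "male"/"female" (or "M"/"F", case-insensitive).
#' @param age_years age in years.
#' @param fvc_pct FVC percent predicted, in (0, 150].
#' @param dlco_pct DLCO percent predicted, in (0, 150]; ignored where
#'   `dlco_unmeasurable` is TRUE.
#' @param dlco_unmeasurable logical: patient cannot perform the DLCO
#'   manoeuvre (scores 3 points).
#' @return integer vector of GAP scores (0-8).
#' @export
gap_index <- function(sex, age_years, fvc_pct, dlco_pct,
                      dlco_unmeasurable = FALSE) {
  n <- max(length(sex), length(age_years), length(fvc_pct), length(dlco_pct))
  sex <- rep_len(sex, n); age_years <- rep_len(age_years, n)
  fvc_pct <- rep_len(fvc_pct, n); dlco_pct <- rep_len(dlco_pct, n)
  dlco_unmeasurable <- rep_len(dlco_unmeasurable, n)
  s <- tolower(as.character(sex))
  if (!all(s %in% c("male", "female", "m", "f")))
    stop_fmt("sex must be male/female")
  if (any(fvc_pct <= 0 | fvc_pct > 150, na.rm = TRUE))
    stop_fmt("FVC%% out of physiologic range (0, 150]")
  if (any(!dlco_unmeasurable & (dlco_pct <= 0 | dlco_pct > 150), na.rm = TRUE))
    stop_fmt("DLCO%% out of physiologic range (0, 150]")
  p_sex <- ifelse(s %in% c("male", "m"), 1L, 0L)
  p_age <- ifelse(age_years <= 60, 0L, ifelse(age_years <= 65, 1L, 2L))
  p_fvc <- ifelse(fvc_pct >= 75, 0L, ifelse(fvc_pct >= 50, 1L, 2L))
  p_dlco <- ifelse(dlco_unmeasurable, 3L,
                   ifelse(dlco_pct > 55, 0L, ifelse(dlco_pct >= 36, 1L, 2L)))
  as.integer(p_sex + p_age + p_fvc + p_dlco)
}

#' Hypergeometric over-representation test for gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between a query gene list and each gene set, within a fixed universe;
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param query_genes character vector (subset of `universe`).
#' @param gene_sets named list of gene id vectors (each a subset of
#'   `universe`), or a single vector.
#' @param universe character vector of all testable genes.
#' @return data frame: set, set_size, overlap, p, p_adjusted.
#' @export
ora_hypergeometric <- function(query_genes, gene_sets, universe) {
  if (!length(universe)) stop_fmt("universe is empty")
  universe <- unique(universe)
  query_genes <- unique(query_genes)
  if (!all(query_genes %in% universe))
    stop_fmt("query genes outside the universe")
  if (!is.list(gene_sets)) gene_sets <- list(set1 = gene_sets)
  if (is.null(names(gene_sets))) names(gene_sets) <- paste0("set", seq_along(gene_sets))
  N <- length(universe); nq <- length(query_genes)
  res <- lapply(names(gene_sets), function(nm) {
    gs <- unique(gene_sets[[nm]])
    if (!all(gs %in% universe)) stop_fmt("gene set '%s' outside the universe", nm)
    m <- length(gs)
    k <- length(intersect(query_genes, gs))
    p <- if (k == 0) 1 else stats::phyper(k - 1, m, N - m, nq, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
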