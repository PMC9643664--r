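#' Pool cohorts on their common genes
#'
#' Restricts every cohort to the intersection of gene panels (canonical
#' sorted order) and column-concatenates the expression matrices. Sample
#' annotations are stacked, with `cohort_id` acting as the batch label.
#'
#' @param cohorts list of at least two [cohort_data()] with pairwise-disjoint
#'   sample ids.
#' @return list with `expression` (pooled genes x samples matrix) and
#'   `annotations` (stacked data frame).
#' @export
intersect_and_pool <- function(cohorts) {
  if (length(cohorts) < 2) stop_fmt("need at least 2 cohorts to pool")
  ids <- unlist(lapply(cohorts, function(co) colnames(co$expression)))
  if (anyDuplicated(ids))
    stop_fmt("duplicate sample ids across cohorts: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gene_lists <- lapply(cohorts, function(co) rownames(co$expression))
  common <- Reduce(intersect, gene_lists)
  if (length(common) == 0) {
    labs <- vapply(cohorts, function(co) co$cohort_id, "")
    stop_fmt("empty gene intersection across cohorts: %s", paste(labs, collapse = ", "))
  }
  common <- sort(common)
  mats <- lapply(cohorts, function(co) co$expression[common, , drop = FALSE])
  pooled <- do.call(cbind, mats)
  ann <- do.call(rbind, lapply(cohorts, function(co) co$annotations))
  rownames(ann) <- NULL
  list(expression = pooled, annotations = ann)
}

#' Fit controls-only ComBat batch parameters (COCONUT)
#'
#' Estimates per-batch location/scale batch effects from *healthy control*
#' samples only, with parametric empirical-Bayes shrinkage, so that the
#' adjustment can later be applied to every sample (cases included) of the
#' same batches. Per gene g the grand mean `alpha_g` is the unweighted mean
#' over all controls and `sigma_g` is the pooled *within-batch* control SD
#' (location batch effects must not inflate the standardisation scale, or
#' the adjustment would distort case-control contrasts); controls are
#' standardised
#' to `z = (x - alpha_g) / sigma_g`; per batch b the raw effects are the
#' control mean `gamma_hat_bg` and variance `delta2_hat_bg` of z. Batch-level
#' priors (Normal for gamma, inverse-gamma for delta2) are fitted by method
#' of moments across genes, and the standard ComBat fixed-point iteration
#' shrinks the raw effects until the maximum absolute change is below `tol`.
#'
#' Case samples never contribute to any estimate: refitting after modifying
#' case values returns bit-identical parameters.
#'
#' @param pooled genes x samples matrix from [intersect_and_pool()].
#' @param annotations matching annotation data frame (`sample_id`,
#'   `cohort_id`, `disease_status`).
#' @param min_controls minimum controls per batch (default 3).
#' @param tol fixed-point convergence tolerance (default 1e-4).
#' @param max_iter maximum fixed-point iterations (default 100).
#' @return object of class `combat_params` with per-gene `alpha`, `sigma`,
#'   per-batch x gene `gamma_star`, `delta2_star`, the raw effects, prior
#'   hyperparameters, control counts and iterations used. Genes whose control
#'   variance is below 1e-8 in any batch are dropped with a warning (they
#'   cannot be standardised) and listed in `dropped_genes`.
#' @export
fit_control_combat <- function(pooled, annotations, min_controls = 3,
                               tol = 1e-4, max_iter = 100) {
  validate_expression(pooled, "pooled matrix")
  ann <- annotations[match(colnames(pooled), annotations$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) stop_fmt("annotations missing for some pooled samples")
  is_ctrl <- ann$disease_status == "control"
  batches <- unique(ann$cohort_id)
  n_ctrl <- vapply(batches, function(b) sum(is_ctrl & ann$cohort_id == b), 0L)
  names(n_ctrl) <- batches
  if (any(n_ctrl < min_controls))
    stop_fmt("batch(es) with fewer than %d controls: %s", min_controls,
             paste(batches[n_ctrl < min_controls], collapse = ", "))

  ctrl <- pooled[, is_ctrl, drop = FALSE]
  ctrl_batch <- ann$cohort_id[is_ctrl]

  # genes that cannot be standardised (near-zero control variance in any batch)
  bad <- rep(FALSE, nrow(pooled))
  for (b in batches) {
    v <- row_vars(ctrl[, ctrl_batch == b, drop = FALSE])
    bad <- bad | !is.finite(v) | v < 1e-8
  }
  dropped <- rownames(pooled)[bad]
  if (length(dropped)) {
    warn_fmt("dropping %d gene(s) with near-zero control variance: %s%s",
             length(dropped), paste(utils::head(dropped, 5), collapse = ", "),
             if (length(dropped) > 5) ", ..." else "")
    ctrl <- ctrl[!bad, , drop = FALSE]
  }
  genes <- rownames(ctrl)

  alpha <- rowMeans(ctrl)
  ss <- 0; dfree <- 0L
  for (b in batches) {
    xb <- ctrl[, ctrl_batch == b, drop = FALSE]
    ss <- ss + rowSums((xb - rowMeans(xb))^2)
    dfree <- dfree + ncol(xb) - 1L
  }
  sigma <- sqrt(ss / dfree)
  z <- (ctrl - alpha) / sigma

  nb <- length(batches)
  gamma_hat <- delta2_hat <- gamma_star <- delta2_star <-
    matrix(NA_real_, nb, length(genes), dimnames = list(batches, genes))
  gamma_bar <- tau2 <- lambda <- theta <- stats::setNames(numeric(nb), batches)
  iterations <- stats::setNames(integer(nb), batches)

  for (b in batches) {
    zb <- z[, ctrl_batch == b, drop = FALSE]
    n_b <- ncol(zb)
    g_hat <- rowMeans(zb)
    d_hat <- row_vars(zb)
    gamma_hat[b, ] <- g_hat
    delta2_hat[b, ] <- d_hat

    gamma_bar[b] <- mean(g_hat)
    tau2[b] <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    # inverse-gamma moment estimators (shape lambda, scale theta)
    if (is.finite(s2) && s2 > 1e-12) {
      lambda[b] <- (2 * s2 + m^2) / s2
      theta[b] <- (m * s2 + m^3) / s2
    } else {
      lambda[b] <- NA_real_; theta[b] <- NA_real_
    }

    g_star <- g_hat
    d_star <- d_hat
    ssq_base <- rowSums(zb^2)
    zb_sum <- rowSums(zb)
    shrink_gamma <- is.finite(tau2[b]) && tau2[b] > 1e-12
    shrink_delta <- is.finite(lambda[b])
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- if (shrink_gamma) {
        (n_b * tau2[b] * g_hat + d_star * gamma_bar[b]) / (n_b * tau2[b] + d_star)
      } else g_hat
      d_new <- if (shrink_delta) {
        ssq <- ssq_base - 2 * g_new * zb_sum + n_b * g_new^2
        (theta[b] + 0.5 * ssq) / (n_b / 2 + lambda[b] - 1)
      } else d_hat
      delta <- max(abs(g_new - g_star), abs(d_new - d_star))
      g_star <- g_new; d_star <- d_new
      if (delta < tol) break
      if (it >= max_iter)
        stop_fmt("EB fixed point did not converge for batch '%s' after %d iterations (last change %.3g)",
                 b, max_iter, delta)
    }
    iterations[b] <- it
    gamma_star[b, ] <- g_star
    delta2_star[b, ] <- d_star
  }
  if (any(delta2_star <= 0)) stop_fmt("non-positive shrunk scale effect encountered")

  structure(list(
    genes = genes, batches = batches, alpha = alpha, sigma = sigma,
    gamma_hat = gamma_hat, delta2_hat = delta2_hat,
    gamma_star = gamma_star, delta2_star = delta2_star,
    gamma_bar = gamma_bar, tau2 = tau2, lambda = lambda, theta = theta,
    n_controls = n_ctrl, iterations = iterations,
    dropped_genes = dropped, min_controls = min_controls, tol = tol
  ), class = "combat_params")
}

#' @export
print.combat_params <- function(x, ...) {
  cat(sprintf("<combat_params> %d genes, %d batches (%s); controls: %s; dropped genes: %d\n",
              length(x$genes), length(x$batches), paste(x$batches, collapse = ", "),
              paste(x$n_controls, collapse = "/"), length(x$dropped_genes)))
  invisible(x)
}

#' Apply the controls-estimated batch adjustment to all samples
#'
#' For every sample (case and control) of batch b:
#' `y = sigma_g * ((x - alpha_g)/sigma_g - gamma_star_bg) / sqrt(delta2_star_bg) + alpha_g`.
#' Genes dropped during fitting are removed from the output.
#'
#' @param pooled genes x samples matrix (superset of `params$genes` allowed).
#' @param annotations annotation data frame carrying each sample's batch.
#' @param params a [fit_control_combat()] result.
#' @return adjusted matrix over `params$genes`, same samples and order.
#' @export
apply_conormalization <- function(pooled, annotations, params) {
  validate_expression(pooled, "pooled matrix")
  stopifnot(inherits(params, "combat_params"))
  missing_genes <- setdiff(params$genes, rownames(pooled))
  if (length(missing_genes))
    stop_fmt("pooled matrix lacks %d gene(s) used by the fit", length(missing_genes))
  ann <- annotations[match(colnames(pooled), annotations$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) stop_fmt("annotations missing for some pooled samples")
  unknown <- setdiff(unique(ann$cohort_id), params$batches)
  if (length(unknown))
    stop_fmt("batch(es) without fitted parameters: %s", paste(unknown, collapse = ", "))
  x <- pooled[params$genes, , drop = FALSE]
  out <- x
  for (b in params$batches) {
    cols <- which(ann$cohort_id == b)
    if (!length(cols)) next
    z <- (x[, cols, drop = FALSE] - params$alpha) / params$sigma
    z <- (z - params$gamma_star[b, ]) / sqrt(params$delta2_star[b, ])
    out[, cols] <- z * params$sigma + params$alpha
  }
  out
}

#' Batch-mixing score in the first two principal components
#'
#' Projects samples onto the first two gene-centred principal components and
#' returns the ratio of between-batch centroid dispersion to total dispersion
#' in that plane: 0 means batches are perfectly mixed, values toward 1 mean
#' the batches are fully separated. Sign-invariant, hence deterministic.
#'
#' @param values genes x samples matrix.
#' @param batch batch label per sample (length = ncol(values)).
#' @return scalar in \[0, 1\].
#' @export
batch_mixing_score <- function(values, batch) {
  if (length(batch) != ncol(values)) stop_fmt("batch labels must match samples")
  tab <- table(batch)
  if (length(tab) < 2) stop_fmt("need at least 2 batches")
  if (any(tab < 3)) stop_fmt("need at least 3 samples per batch")
  if (min(ncol(values) - 1L, nrow(values)) < 2)
    stop_fmt("fewer than 2 principal components computable")
  pc <- stats::prcomp(t(values), center = TRUE, scale. = FALSE, rank. = 2)
  sc <- pc$x[, 1:2, drop = FALSE]
  grand <- colMeans(sc)
  total <- sum(sweep(sc, 2, grand)^2)
  if (total <= 0) return(0)
  between <- 0
  for (b in names(tab)) {
    m <- colMeans(sc[batch == b, , drop = FALSE])
    between <- between + tab[[b]] * sum((m - grand)^2)
  }
  as.numeric(between / total)
}
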