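#' Kaplan-Meier curves, medians and a k-group log-rank test
#'
#' Median survival per group follows the convention "smallest observed time
#' with S(t) <= 0.5"; groups whose curve never crosses 0.5 are reported as
#' not reached (NA). With every record censored the log-rank statistic is
#' undefined and reported as such rather than raising an error.
#'
#' @param time positive follow-up times.
#' @param event event indicators (0/1).
#' @param group group labels (>= 2 groups).
#' @return list of class `km_logrank`: `curves` (group, time, n_risk,
#'   n_event, surv), `medians` (named, NA = not reached), `chisq`, `df`,
#'   `p`, `n`, `note`.
#' @export
km_logrank <- function(time, event, group) {
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[ok]; event <- event[ok]; group <- droplevels(factor(group[ok]))
  if (any(time <= 0)) stop_fmt("survival times must be positive")
  if (nlevels(group) < 2) stop_fmt("need at least 2 groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_lab <- sub("^group=", "", rep(names(fit$strata), fit$strata))
  curves <- data.frame(group = strata_lab, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  medians <- vapply(levels(group), function(gl) {
    cu <- curves[curves$group == gl, , drop = FALSE]
    hit <- which(cu$surv <= 0.5)
    if (length(hit)) cu$time[min(hit)] else NA_real_
  }, 0)
  if (sum(event) == 0) {
    return(structure(list(curves = curves, medians = medians,
                          chisq = NA_real_, df = nlevels(group) - 1L,
                          p = NA_real_, n = length(time),
                          note = "log-rank undefined: all records censored"),
                     class = "km_logrank"))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  structure(list(curves = curves, medians = medians,
                 chisq = unname(sd_$chisq), df = df,
                 p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
                 n = length(time), note = ""),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  med <- ifelse(is.na(x$medians), "not reached", format(x$medians, digits = 3))
  cat(sprintf("<km_logrank> n = %d; log-rank chisq = %s (df %d), p = %s\n",
              x$n, format(x$chisq, digits = 4), x$df, format(x$p, digits = 3)))
  cat("  median survival:", paste(names(x$medians), med, sep = " = ", collapse = "; "), "\n")
  if (nzchar(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Cox proportional-hazards fit with concordance
#'
#' Fits a Cox model (Efron tie handling) of survival on a group variable
#' plus optional covariates, on complete cases for the included variables.
#' Reports hazard ratios with Wald 95% CIs and p-values, the partial
#' log-likelihood, and Harrell's C on the fitted risk scores with a
#' Noether-type CI. Monotone likelihood (complete separation, infinite
#' coefficients) and zero events raise errors.
#'
#' @param data data frame containing `time`, `event` and model variables.
#' @param group name of the primary grouping variable (coerced to factor if
#'   character); its first level is the reference.
#' @param covariates optional covariate column names.
#' @param time,event column names for follow-up and event indicator.
#' @return object of class `survival_model`: `coefficients`, `hr`, `ci`
#'   (2-column matrix), `p` (Wald), `loglik`, `c_index`, `c_ci`, `n_used`,
#'   `n_events`, `group`, `covariates`, `fit`.
#' @export
cox_fit <- function(data, group, covariates = character(),
                    time = "time", event = "event") {
  vars <- c(time, event, group, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop_fmt("columns not found: %s", paste(missing_cols, collapse = ", "))
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  if (!nrow(d)) stop_fmt("no complete cases for the requested model")
  if (any(d[[time]] <= 0)) stop_fmt("survival times must be positive")
  if (sum(d[[event]]) == 0) stop_fmt("zero events: Cox model undefined")
  if (is.character(d[[group]])) d[[group]] <- factor(d[[group]])
  rhs <- paste(c(group, covariates), collapse = " + ")
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event, rhs))
  mono <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|Loglik converged before", conditionMessage(w))) {
        mono <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    })
  if (!is.null(mono))
    stop_fmt("monotone likelihood / non-identifiable coefficient: %s", mono)
  co <- summary(fit)
  ci <- co$conf.int[, c("lower .95", "upper .95"), drop = FALSE]
  conc <- survival::concordance(fit)
  c_se <- sqrt(conc$var)
  structure(list(
    coefficients = stats::coef(fit),
    hr = exp(stats::coef(fit)),
    ci = ci,
    p = co$coefficients[, "Pr(>|z|)"],
    loglik = fit$loglik[2],
    loglik_null = fit$loglik[1],
    c_index = unname(conc$concordance),
    c_ci = unname(conc$concordance + c(-1, 1) * stats::qnorm(0.975) * c_se),
    n_used = nrow(d), n_events = sum(d[[event]]),
    group = group, covariates = covariates, fit = fit
  ), class = "survival_model")
}

#' @export
print.survival_model <- function(x, ...) {
  cat(sprintf("<survival_model> n = %d (%d events); C = %.3f (95%% CI %.3f-%.3f)\n",
              x$n_used, x$n_events, x$c_index, x$c_ci[1], x$c_ci[2]))
  tab <- data.frame(HR = round(x$hr, 3), lower = round(x$ci[, 1], 3),
                    upper = round(x$ci[, 2], 3), p = signif(x$p, 3))
  print(tab)
  invisible(x)
}

#' Harrell's concordance index for a risk score
#'
#' Probability that, of a usable pair, the subject with the higher risk
#' score fails earlier (Harrell's C; pairs unusable under censoring are
#' excluded by the standard rule, tied scores count 1/2). The 95% CI uses a
#' Noether-type normal approximation on the concordance SE.
#'
#' @param risk numeric risk scores (higher = riskier).
#' @param time,event survival outcome.
#' @return list: `c_index`, `se`, `ci` (length 2), `n`.
#' @export
concordance_index <- function(risk, time, event) {
  ok <- !is.na(risk) & !is.na(time) & !is.na(event)
  risk <- risk[ok]; time <- time[ok]; event <- event[ok]
  if (sum(event) == 0) stop_fmt("no events: no comparable pairs")
  cc <- survival::concordance(survival::Surv(time, event) ~ risk, reverse = TRUE)
  n_pairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) stop_fmt("no comparable pairs")
  se <- sqrt(cc$var)
  list(c_index = unname(cc$concordance), se = se,
       ci = unname(cc$concordance + c(-1, 1) * stats::qnorm(0.975) * se),
       n = length(risk))
}

#' Likelihood-ratio test between nested Cox models
#'
#' @param model_full,model_reduced [cox_fit()] results on the same records;
#'   the reduced model's variables must be a subset of the full model's.
#' @return list: `statistic`, `df`, `p`.
#' @export
lrt_nested <- function(model_full, model_reduced) {
  stopifnot(inherits(model_full, "survival_model"),
            inherits(model_reduced, "survival_model"))
  full_vars <- c(model_full$group, model_full$covariates)
  red_vars <- c(model_reduced$group, model_reduced$covariates)
  if (!all(red_vars %in% full_vars))
    stop_fmt("models are not nested (reduced variables not a subset)")
  if (model_full$n_used != model_reduced$n_used)
    stop_fmt("models were fitted on different record sets (n %d vs %d)",
             model_full$n_used, model_reduced$n_used)
  stat <- 2 * (model_full$loglik - model_reduced$loglik)
  df <- length(model_full$coefficients) - length(model_reduced$coefficients)
  if (df < 0) stop_fmt("full model has fewer parameters than reduced model")
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}
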