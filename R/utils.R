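# Internal numeric helpers shared across modules.

row_means <- function(x) rowMeans(x)

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

row_sds <- function(x) sqrt(row_vars(x))

#' Standardise each gene (row) to zero mean and unit variance
#'
#' Constant rows (variance below `eps`) are mapped to zero rather than NaN.
#'
#' @param x numeric matrix, genes x samples.
#' @param eps variance floor below which a row is treated as constant.
#' @return matrix of the same shape.
#' @keywords internal
zscore_rows <- function(x, eps = 1e-12) {
  m <- rowMeans(x)
  s <- row_sds(x)
  s[!is.finite(s) | s < sqrt(eps)] <- Inf  # constant row -> z = 0
  (x - m) / s
}

col_zscore <- function(x) scale(x)

#' Sample skewness (g1)
#'
#' Moment-based skewness `m3 / m2^(3/2)` with n denominators, used to route
#' continuous traits between ANOVA and Kruskal-Wallis.
#'
#' @param x numeric vector; NAs dropped.
#' @return scalar skewness (NA if fewer than 3 values or zero variance).
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)

#' Validate a genes x samples expression matrix
#'
#' Checks for a numeric matrix with unique, non-missing gene and sample
#' identifiers and no missing values.
#'
#' @param x candidate matrix.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_fmt("%s must be a numeric matrix (genes x samples)", what)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop_fmt("%s must have unique gene row names", what)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop_fmt("%s must have unique sample column names", what)
  if (anyNA(x)) stop_fmt("%s contains missing values", what)
  invisible(x)
}

# Deterministic integer sub-seed derived from a base seed, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}
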