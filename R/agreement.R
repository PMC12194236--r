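#' Subjects-by-measurements ratings matrix
#'
#' Complete rectangular grid of angle values feeding the reliability
#' statistics: rows are subjects, columns are the repeated measurements
#' (raters, readings or sessions). Incomplete rows are rejected; the study
#' designs supported here are complete-case by construction.
#'
#' @param values numeric matrix (or data frame) of angles in degrees,
#'   `n_subjects x k_measurements`, `n >= 3`, `k >= 2`, no missing cells.
#' @param subject_ids optional row labels.
#' @param measurement_labels optional column labels.
#' @return An object of class `ratings_matrix`.
#' @export
ratings_matrix <- function(values, subject_ids = NULL, measurement_labels = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 3L) stop("ratings matrix needs at least 3 subjects", call. = FALSE)
  if (ncol(m) < 2L) stop("ratings matrix needs at least 2 measurements", call. = FALSE)
  if (anyNA(m) || !all(is.finite(m))) {
    stop("ratings matrix must be complete (no missing or non-finite cells)",
         call. = FALSE)
  }
  rownames(m) <- subject_ids %||% rownames(m) %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- measurement_labels %||% colnames(m) %||% paste0("M", seq_len(ncol(m)))
  structure(list(values = m), class = "ratings_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ratings_matrix <- function(x, ...) {
  cat(sprintf("<ratings_matrix> %d subjects x %d measurements\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

as_ratings <- function(m) {
  if (inherits(m, "ratings_matrix")) m else ratings_matrix(m)
}

#' Two-way ANOVA mean squares of a ratings matrix
#'
#' Decomposes the total sum of squares about the grand mean into
#' between-subjects (rows), between-measurements (columns) and residual
#' components, without replication. This is the kernel of the
#' absolute-agreement intraclass correlation.
#'
#' @param m a [ratings_matrix()] or coercible matrix.
#' @return List with `ms_rows` (df `n-1`), `ms_cols` (df `k-1`) and
#'   `ms_error` (df `(n-1)(k-1)`), all in squared degrees.
#' @export
anova_mean_squares <- function(m) {
  v <- as_ratings(m)$values
  n <- nrow(v)
  k <- ncol(v)
  grand <- mean(v)
  ss_rows <- k * sum((rowMeans(v) - grand)^2)
  ss_cols <- n * sum((colMeans(v) - grand)^2)
  ss_total <- sum((v - grand)^2)
  ss_error <- ss_total - ss_rows - ss_cols
  list(ms_rows = ss_rows / (n - 1),
       ms_cols = ss_cols / (k - 1),
       ms_error = ss_error / ((n - 1) * (k - 1)))
}

#' Absolute-agreement average-measures intraclass correlation ICC(2,k)
#'
#' Two-way random-effects, absolute-agreement ICC for the mean of k
#' measurements (McGraw & Wong's ICC(A,k)), with its confidence interval from
#' the McGraw-Wong procedure: the single-measure bounds use F quantiles with a
#' Satterthwaite-approximated denominator degrees of freedom and are stepped
#' up to average measures by the Spearman-Brown relation. The point estimate
#' is `(MSR - MSE) / (MSR + (MSC - MSE) / n)`.
#'
#' @param m a [ratings_matrix()] or coercible matrix.
#' @param confidence confidence level of the interval (default 0.95).
#' @return An object of class `icc_result`: estimate, `ci_low`, `ci_high`,
#'   the three mean squares, `n`, `k`, and the Koo-Li `interpretation`.
#' @export
icc2k <- function(m, confidence = 0.95) {
  v <- as_ratings(m)$values
  n <- nrow(v)
  k <- ncol(v)
  stopifnot(confidence > 0, confidence < 1)
  ms <- anova_mean_squares(v)
  msr <- ms$ms_rows
  msc <- ms$ms_cols
  mse <- ms$ms_error
  if (msr + abs(msc) + abs(mse) < .Machine$double.eps * mean(abs(v) + 1)) {
    stop("ICC is undefined for a constant ratings matrix (zero total variance)",
         call. = FALSE)
  }
  est <- (msr - mse) / (msr + (msc - mse) / n)

  # single-measure ICC(A,1) and its McGraw-Wong interval
  r1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - confidence
  if (abs(1 - r1) < 1e-14) {
    lo1 <- hi1 <- 1
  } else {
    a <- k * r1 / (n * (1 - r1))
    b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
    v_df <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    # the F quantile is at its large-df asymptote long before 1e6; capping
    # keeps qf away from its inaccurate extreme-df region
    v_df <- min(v_df, 1e6)
    # degenerate samples can drive the approximated df below 1, where qf
    # emits precision notes while still returning its best-effort quantile
    f1 <- suppressWarnings(stats::qf(1 - alpha / 2, n - 1, v_df))
    f2 <- suppressWarnings(stats::qf(1 - alpha / 2, v_df, n - 1))
    lo1 <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi1 <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  }
  sb <- function(r) k * r / (1 + (k - 1) * r)
  out <- structure(
    list(estimate = est, ci_low = sb(lo1), ci_high = sb(hi1),
         confidence = confidence, ms_rows = msr, ms_cols = msc, ms_error = mse,
         # degenerate samples (negative variance components) can push the
         # point estimate above 1; the band label clamps, the estimate stays
         n = n, k = k, interpretation = interpret_icc(min(est, 1))),
    class = "icc_result"
  )
  out
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,%d) = %.3f (%d%% CI %.3f, %.3f) - %s agreement, n = %d\n",
              x$k, x$estimate, round(100 * x$confidence), x$ci_low, x$ci_high,
              x$interpretation, x$n))
  invisible(x)
}

#' Interpret an ICC estimate on the Koo-Li bands
#'
#' Below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, above 0.9 excellent;
#' the boundary values 0.5, 0.75 and 0.9 belong to the interval they close
#' (0.5 and 0.75 are moderate's endpoints, 0.9 is good's upper endpoint).
#'
#' @param estimate ICC value, at most 1.
#' @return `"poor"`, `"moderate"`, `"good"` or `"excellent"`.
#' @export
interpret_icc <- function(estimate) {
  stopifnot(is.numeric(estimate), length(estimate) == 1L, estimate <= 1 + 1e-12)
  if (estimate < 0.5) "poor"
  else if (estimate <= 0.75) "moderate"
  else if (estimate <= 0.9) "good"
  else "excellent"
}

#' Bland-Altman agreement analysis
#'
#' Mean difference (bias) and limits of agreement for paired measurements.
#' Differences are taken as `x - y`; the function is orientation-agnostic and
#' the caller fixes which method is `x`. The accuracy pipeline uses HKA - PKA,
#' which is negative when the radiographic angle is the more varus one.
#'
#' @param x,y paired numeric vectors of equal length (at least 2 pairs).
#' @param multiplier half-width of the limits in standard deviations
#'   (default 1.96, the two-sided normal 95% value).
#' @return An object of class `bland_altman_result`: `bias`, `sd_diff`
#'   (sample SD, n-1 denominator), `loa_low`, `loa_high`, `multiplier`, `n`.
#' @export
bland_altman <- function(x, y, multiplier = 1.96) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in paired measurements", call. = FALSE)
  stopifnot(multiplier > 0)
  d <- x - y
  bias <- mean(d)
  sd_diff <- sqrt(sum((d - bias)^2) / (length(d) - 1))
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - multiplier * sd_diff,
         loa_high = bias + multiplier * sd_diff,
         multiplier = multiplier, n = length(d)),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f (LoA %.3f, %.3f), n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' The p-value comes from the exact t transform `r * sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, both non-constant.
#' @return List with `r`, `p_value` and `n`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("correlation needs at least 3 pairs", call. = FALSE)
  cx <- x - mean(x)
  cy <- y - mean(y)
  sxx <- sum(cx^2)
  syy <- sum(cy^2)
  if (sxx == 0 || syy == 0) {
    stop("correlation is undefined for a constant vector", call. = FALSE)
  }
  r <- sum(cx * cy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Simple linear regression with R-squared and standard error of the estimate
#'
#' Ordinary least squares of `y` on `x`, solved from the closed-form normal
#' equations. The standard error of the estimate (SEE) is the residual
#' standard deviation `sqrt(SSE / (n - 2))`, the paper-standard summary of
#' calibration precision.
#'
#' @param x predictor values (non-constant, `n >= 3`).
#' @param y response values.
#' @return An object of class `regression_result`: `intercept`, `slope`,
#'   `r2`, `see`, `r`, `p_value`, `n`.
#' @export
ols_fit <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("regression needs at least 3 pairs", call. = FALSE)
  cx <- x - mean(x)
  sxx <- sum(cx^2)
  if (sxx == 0) stop("regression is undefined for a constant predictor", call. = FALSE)
  slope <- sum(cx * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  see <- sqrt(sse / (n - 2))
  cor_part <- if (sst == 0) {
    list(r = 0, p_value = 1)
  } else {
    pearson_r(x, y)
  }
  structure(
    list(intercept = intercept, slope = slope, r2 = r2, see = see,
         r = cor_part$r, p_value = cor_part$p_value, n = n),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: y = %.4f + %.4f x,  R2 = %.3f, SEE = %.4f, n = %d\n",
              x$intercept, x$slope, x$r2, x$see, x$n))
  invisible(x)
}
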