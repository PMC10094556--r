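#' Correlation structure of components and one activity
#'
#' Holds \eqn{\hat R_{xx}} (the m x m Pearson correlation matrix of the
#' components) and \eqn{\hat R_{xy}} (the vector of component-activity
#' correlations, i.e. the total effects \eqn{r_{jy}}).
#'
#' @param r_xx m x m correlation matrix; must be symmetric within 1e-10 with
#'   unit diagonal and entries in [-1, 1].
#' @param r_xy length-m vector of total effects.
#' @param units character vector of unit names.
#' @param n_samples number of samples the estimate is based on, or `NULL`
#'   when the structure was reconstructed from a published table.
#' @param check_psd require the smallest eigenvalue of `r_xx` to be
#'   >= -1e-8; defaults to `TRUE` when `n_samples` is given (sample
#'   correlation matrices are PSD up to roundoff).
#' @return object of class `correlation_structure` with the fields above
#'   plus `condition_number` (2-norm) and a logical `singular` flag set when
#'   `r_xx` is numerically singular (perfectly collinear columns).
#' @export
correlation_structure <- function(r_xx, r_xy, units = NULL, n_samples = NULL,
                                  check_psd = !is.null(n_samples)) {
  r_xx <- as.matrix(r_xx)
  m <- nrow(r_xx)
  units <- units %||% colnames(r_xx) %||% paste0("x", seq_len(m))
  if (ncol(r_xx) != m || length(r_xy) != m || length(units) != m) {
    pathsar_abort("r_xx, r_xy and units have inconsistent dimensions",
                  "pathsar_contract_error")
  }
  if (max(abs(r_xx - t(r_xx))) > 1e-10) {
    pathsar_abort("r_xx is not symmetric (tolerance 1e-10)",
                  "pathsar_contract_error")
  }
  if (max(abs(diag(r_xx) - 1)) > 1e-8) {
    pathsar_abort("r_xx diagonal must be 1", "pathsar_contract_error")
  }
  if (max(abs(r_xx)) > 1 + 1e-8 || max(abs(r_xy)) > 1 + 1e-8) {
    pathsar_abort("correlations must lie in [-1, 1]", "pathsar_contract_error")
  }
  # snap to the exact contract
  r_xx <- (r_xx + t(r_xx)) / 2
  diag(r_xx) <- 1
  r_xx[r_xx > 1] <- 1
  r_xx[r_xx < -1] <- -1
  r_xy <- pmin(1, pmax(-1, as.numeric(r_xy)))

  ev <- eigen(r_xx, symmetric = TRUE, only.values = TRUE)$values
  if (check_psd && min(ev) < -1e-8) {
    pathsar_abort(sprintf("r_xx is not PSD (min eigenvalue %.3g)", min(ev)),
                  "pathsar_contract_error")
  }
  singular <- min(abs(ev)) < 1e-12 * max(abs(ev))
  if (singular) {
    warning("r_xx is numerically singular (perfectly collinear columns)",
            call. = FALSE)
  }
  cond <- if (singular) Inf else max(abs(ev)) / min(abs(ev))

  dimnames(r_xx) <- list(units, units)
  names(r_xy) <- units
  structure(
    list(r_xx = r_xx, r_xy = r_xy, units = units, n_samples = n_samples,
         condition_number = cond, singular = singular),
    class = "correlation_structure")
}

#' @export
print.correlation_structure <- function(x, ...) {
  cat(sprintf("<correlation_structure> m = %d units%s; condition number %.3g\n",
              length(x$units),
              if (is.null(x$n_samples)) "" else sprintf(", n = %d", x$n_samples),
              x$condition_number))
  invisible(x)
}

#' Estimate the correlation structure from standardized data
#'
#' @param z_units n x m matrix of (standardized) component columns.
#' @param z_activity length-n (standardized) activity vector.
#' @param units optional unit names; defaults to `colnames(z_units)`.
#' @return a [correlation_structure()].
#' @export
estimate_correlations <- function(z_units, z_activity, units = NULL) {
  z_units <- as.matrix(z_units)
  n <- nrow(z_units)
  if (n < 3L) {
    pathsar_abort(sprintf("need n >= 3 samples to estimate correlations, got %d", n),
                  "pathsar_insufficient_data")
  }
  if (length(z_activity) != n) {
    pathsar_abort("activity length does not match the number of rows",
                  "pathsar_contract_error")
  }
  r_xx <- cor(z_units)
  r_xy <- as.numeric(cor(z_units, z_activity))
  correlation_structure(r_xx, r_xy,
                        units = units %||% colnames(z_units),
                        n_samples = n)
}

#' Solve the canonical equations for the path coefficients
#'
#' Solves \eqn{\hat R_{xx} b^* = \hat R_{xy}} by a symmetric factorization
#' (Cholesky when positive definite). Path-analysis systems for strongly
#' intercorrelated mixtures are often severely ill-conditioned, so the
#' condition number is always checked first; above `cond_threshold` the
#' solve aborts and names the most nearly dependent column pair, unless an
#' explicit `ridge` is supplied (reported in the result attributes, never
#' silent).
#'
#' @param corr a [correlation_structure()].
#' @param cond_threshold refuse to solve above this 2-norm condition number.
#' @param ridge optional explicit Tikhonov constant added to the diagonal;
#'   `NULL` (default) means plain solve.
#' @return named numeric vector of direct effects \eqn{b_j^*}, with
#'   attributes `condition_number`, `residual` (relative residual norm) and
#'   `ridge`.
#' @export
solve_canonical <- function(corr, cond_threshold = 1e10, ridge = NULL) {
  stopifnot(inherits(corr, "correlation_structure"))
  R <- corr$r_xx
  y <- corr$r_xy
  if (is.null(ridge) && (corr$singular || corr$condition_number > cond_threshold)) {
    off <- abs(R)
    diag(off) <- 0
    idx <- which(off == max(off), arr.ind = TRUE)[1L, ]
    pathsar_abort(
      sprintf(paste0("canonical system is ill-conditioned (condition number %.3g",
                     " > %.3g); most nearly dependent columns: %s ~ %s (|r| = %.4f).",
                     " Consider removing a column or passing an explicit ridge."),
              corr$condition_number, cond_threshold,
              corr$units[idx[1L]], corr$units[idx[2L]], max(off)),
      "pathsar_ill_conditioned")
  }
  A <- if (is.null(ridge)) R else R + diag(ridge, nrow(R))
  b <- tryCatch(
    drop(chol2inv(chol(A)) %*% y),
    error = function(e) drop(solve(A, y)))
  resid <- sqrt(sum((A %*% b - y)^2)) / max(sqrt(sum(y^2)), .Machine$double.eps)
  if (is.null(ridge) && resid > 1e-8) {
    pathsar_abort(sprintf("solve residual %.3g exceeds 1e-8", resid),
                  "pathsar_ill_conditioned")
  }
  names(b) <- corr$units
  attr(b, "condition_number") <- corr$condition_number
  attr(b, "residual") <- resid
  attr(b, "ridge") <- ridge
  b
}

#' Decompose total effects into direct and indirect effects
#'
#' Entry \eqn{(t, j)} of the indirect matrix is \eqn{r_{jt} b_t^*}: the part
#' of unit \eqn{j}'s correlation with the activity routed through unit
#' \eqn{t}. The diagonal is stored as 0 (reports render the direct effect
#' there instead).
#'
#' @param corr a [correlation_structure()].
#' @param b_star length-m vector of path coefficients.
#' @param activity activity name carried along for reporting.
#' @return object of class `path_decomposition` with fields `direct`,
#'   `indirect` (m x m, zero diagonal), `indirect_sum`, `total`
#'   (\eqn{r_{jy}}), `units`, `activity`.
#' @export
decompose_effects <- function(corr, b_star, activity = "activity") {
  stopifnot(inherits(corr, "correlation_structure"))
  m <- length(corr$units)
  if (length(b_star) != m) {
    pathsar_abort("b_star length does not match the correlation structure",
                  "pathsar_contract_error")
  }
  b <- as.numeric(b_star)
  # indirect[t, j] = r_jt * b_t ; r_xx symmetric so row t is r_xx[t, ]
  indirect <- diag(b, m) %*% corr$r_xx
  diag(indirect) <- 0
  dimnames(indirect) <- list(corr$units, corr$units)
  indirect_sum <- colSums(indirect)
  structure(
    list(direct = stats::setNames(b, corr$units),
         indirect = indirect,
         indirect_sum = indirect_sum,
         total = corr$r_xy,
         units = corr$units,
         activity = activity),
    class = "path_decomposition")
}

#' @export
print.path_decomposition <- function(x, digits = 4, ...) {
  cat(sprintf("<path_decomposition> activity '%s', %d units\n",
              x$activity, length(x$units)))
  print(round(as.data.frame(x), digits))
  invisible(x)
}

#' Render a decomposition in the standard table layout
#'
#' Rows are the m "through" units (with the direct effect on the diagonal),
#' then `Sum of indirect effects`, then `Total effect (rjy)`; columns are
#' the units. Column sums of the body reproduce the total effects.
#'
#' @param x a `path_decomposition`.
#' @param ... unused.
#' @return data frame with m + 2 rows.
#' @export
as.data.frame.path_decomposition <- function(x, ...) {
  body <- x$indirect
  diag(body) <- x$direct
  out <- rbind(body,
               `Sum of indirect effects` = x$indirect_sum,
               `Total effect (rjy)` = x$total)
  as.data.frame(out, check.names = FALSE)
}

#' Fit summary: coefficient of determination and F test
#'
#' \eqn{R^2 = \sum_j b_j^* r_{jy}};
#' \eqn{F = (R^2/m) / ((1 - R^2)/(n - m - 1))} with an exact upper-tail
#' F p-value. When the inputs come from a rounded published table the raw
#' \eqn{R^2} may stray slightly outside [0, 1]; the raw value is kept in
#' `r_squared_raw` and the clipped one is used for the F statistic.
#'
#' @param corr a [correlation_structure()].
#' @param b_star path coefficients.
#' @param n number of samples (defaults to `corr$n_samples`).
#' @param alpha significance level for the gate (default 0.01, an
#'   "extremely significant" threshold).
#' @return object of class `fit_summary`: `r_squared`, `r_squared_raw`,
#'   `f_statistic`, `df` (c(m, n - m - 1)), `p_value`, `alpha`,
#'   `significant`.
#' @export
fit_summary <- function(corr, b_star, n = corr$n_samples, alpha = 0.01) {
  stopifnot(inherits(corr, "correlation_structure"))
  m <- length(corr$units)
  if (is.null(n) || !is.finite(n) || n <= m + 1) {
    pathsar_abort(
      sprintf("F test needs n > m + 1 (n = %s, m = %d); decomposition is still valid, significance is not testable",
              toString(n), m),
      "pathsar_dof_error")
  }
  r2_raw <- sum(as.numeric(b_star) * corr$r_xy)
  r2 <- min(1, max(0, r2_raw))
  df1 <- m
  df2 <- n - m - 1
  f <- if (r2 >= 1) Inf else (r2 / df1) / ((1 - r2) / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  structure(
    list(r_squared = r2, r_squared_raw = r2_raw, f_statistic = f,
         df = c(df1, df2), p_value = p, alpha = alpha,
         significant = p <= alpha),
    class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("R^2 = %.4f, F(%d, %d) = %.4g, p = %.3g -> %s at alpha = %g\n",
              x$r_squared, x$df[1L], x$df[2L], x$f_statistic, x$p_value,
              if (x$significant) "significant" else "NOT significant",
              x$alpha))
  invisible(x)
}

#' Full path-analysis pipeline for one activity
#'
#' Standardizes the table, estimates the correlation structure, solves the
#' canonical equations, decomposes the total effects and runs the F test.
#'
#' @param table a [sample_table()].
#' @param activity activity name.
#' @param alpha F-test significance level.
#' @param cond_threshold,ridge passed to [solve_canonical()].
#' @return object of class `path_analysis`: `corr`, `b_star`, `decomposition`,
#'   `fit`, `activity`.
#' @export
path_analysis <- function(table, activity, alpha = 0.01,
                          cond_threshold = 1e10, ridge = NULL) {
  z <- standardize_table(table, activity)
  corr <- estimate_correlations(z$z_values, z$z_activity,
                                units = table$units$name)
  b <- solve_canonical(corr, cond_threshold = cond_threshold, ridge = ridge)
  decomp <- decompose_effects(corr, b, activity = activity)
  fit <- fit_summary(corr, b, alpha = alpha)
  structure(
    list(corr = corr, b_star = b, decomposition = decomp, fit = fit,
         activity = activity),
    class = "path_analysis")
}

#' @export
print.path_analysis <- function(x, ...) {
  cat(sprintf("Path analysis of activity '%s'\n", x$activity))
  print(x$fit)
  print(x$decomposition)
  invisible(x)
}
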