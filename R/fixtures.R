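#' Published decomposition table
#'
#' Container for a decomposition table as printed in a report or article:
#' an m x m block whose diagonal holds the direct effects and whose cell
#' (t, j) holds the indirect effect \eqn{r_{jt} b_t^*}, plus the printed
#' "Sum of indirect effects" and "Total effect" rows. Such tables are
#' typically rounded (often to 4 decimals), which matters for everything
#' reconstructed from them.
#'
#' @param block m x m numeric matrix (direct effects on the diagonal).
#' @param indirect_sum printed length-m sum-of-indirect row.
#' @param total printed length-m total-effect row.
#' @param units unit names.
#' @param activity activity name.
#' @return object of class `published_decomposition_table`.
#' @export
published_table <- function(block, indirect_sum, total, units = NULL,
                            activity = "activity") {
  block <- as.matrix(block)
  m <- nrow(block)
  units <- units %||% colnames(block) %||% paste0("x", seq_len(m))
  if (ncol(block) != m || length(indirect_sum) != m || length(total) != m ||
      length(units) != m) {
    pathsar_abort("published table parts have inconsistent dimensions",
                  "pathsar_contract_error")
  }
  if (!all(is.finite(block)) || !all(is.finite(indirect_sum)) ||
      !all(is.finite(total))) {
    pathsar_abort("published table entries must all be finite",
                  "pathsar_contract_error")
  }
  dimnames(block) <- list(units, units)
  structure(
    list(block = block,
         indirect_sum = stats::setNames(as.numeric(indirect_sum), units),
         total = stats::setNames(as.numeric(total), units),
         units = units, activity = activity),
    class = "published_decomposition_table")
}

#' @export
print.published_decomposition_table <- function(x, ...) {
  cat(sprintf("<published_decomposition_table> activity '%s', %d units\n",
              x$activity, length(x$units)))
  invisible(x)
}

#' Read a published decomposition table from CSV
#'
#' Expected layout: a `row` column with the m unit names followed by
#' `Sum of indirect effects` and `Total effect (rjy)`, then one numeric
#' column per unit.
#'
#' @param path CSV path.
#' @param activity activity name to attach.
#' @return a [published_table()].
#' @export
read_published_table <- function(path, activity = "activity") {
  if (!file.exists(path)) {
    pathsar_abort(sprintf("published table not found: %s", path),
                  "pathsar_io_error")
  }
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  units <- setdiff(names(df), "row")
  m <- length(units)
  if (nrow(df) != m + 2L) {
    pathsar_abort(sprintf("expected %d rows (m units + 2 summary rows), got %d",
                          m + 2L, nrow(df)),
                  "pathsar_parse_error")
  }
  mat <- as.matrix(df[, units])
  published_table(block = mat[seq_len(m), , drop = FALSE],
                  indirect_sum = mat[m + 1L, ],
                  total = mat[m + 2L, ],
                  units = units, activity = activity)
}

#' Write a published decomposition table to CSV
#'
#' @param tab a [published_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_published_table <- function(tab, path) {
  stopifnot(inherits(tab, "published_decomposition_table"))
  df <- data.frame(row = c(tab$units, "Sum of indirect effects",
                           "Total effect (rjy)"),
                   rbind(tab$block, tab$indirect_sum, tab$total),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("row", tab$units)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled case-study decomposition tables
#'
#' The two published decomposition tables of the Rhodiola crenulata
#' proanthocyanidin case study that motivated this package: 10 monomer
#' units (terminal ECt, CGt, ECGt; extension GCe, EGCe, GCGe, EGCGe, Ce,
#' ECe, ECGe) against antioxidant and anti-diabetes activity, printed to 4
#' decimals. They let the headline results be reproduced at desk scale even
#' though the underlying 36-sample raw data were never published.
#'
#' @return named list with elements `antioxidant` and `antidiabetes`, each a
#'   [published_table()].
#' @export
bundled_paper_tables <- function() {
  f <- function(file, activity) {
    read_published_table(
      system.file("extdata", file, package = "pathsar", mustWork = TRUE),
      activity = activity)
  }
  list(antioxidant = f("antioxidant_decomposition.csv", "antioxidant"),
       antidiabetes = f("antidiabetes_decomposition.csv", "antidiabetes"))
}

#' Reconstruct a correlation structure from a published table
#'
#' Each off-diagonal cell is \eqn{r_{jt} b_t^*}, so dividing cell (t, j) by
#' the diagonal entry \eqn{b_t^*} estimates \eqn{r_{jt}}, and the
#' transposed cell divided by \eqn{b_j^*} estimates the same quantity.
#' The two quotients are symmetrized by a reliability-weighted mean with
#' weights proportional to \eqn{|b^*|} (quotients through tiny direct
#' effects are rounding-dominated); this reduces to using only the
#' counterpart quotient when one diagonal entry is numerically zero.
#' Entries are clipped to [-1, 1]; if the result has eigenvalues below
#' -1e-6 it is projected to the nearest correlation matrix (eigenvalue
#' clipping plus diagonal rescaling) and the projection distance recorded.
#'
#' @param tab a [published_table()].
#' @param weighting `"reliability"` (default, weights proportional to
#'   |b*|) or `"equal"` (plain mean of the two quotients).
#' @return a [correlation_structure()] (with `n_samples = NULL`), carrying
#'   attributes `asymmetry` (max |quotient difference| over pairs where both
#'   quotients are reliable) and `projection_distance` (Frobenius distance
#'   moved by the PSD projection, 0 when not needed).
#' @export
reconstruct_from_published_table <- function(tab,
                                             weighting = c("reliability", "equal")) {
  stopifnot(inherits(tab, "published_decomposition_table"))
  weighting <- match.arg(weighting)
  b <- diag(tab$block)
  m <- length(b)
  tiny <- abs(b) < 1e-6
  if (sum(!tiny) < 2L) {
    pathsar_abort("too many near-zero direct effects to reconstruct",
                  "pathsar_reconstruction_error")
  }
  R <- diag(m)
  asym <- 0
  for (j in seq_len(m - 1L)) {
    for (t in seq(j + 1L, m)) {
      if (tiny[j] && tiny[t]) {
        pathsar_abort(
          sprintf("cannot reconstruct r(%s, %s): both direct effects are near zero (%s: %.3g, %s: %.3g)",
                  tab$units[j], tab$units[t], tab$units[j], b[j],
                  tab$units[t], b[t]),
          "pathsar_reconstruction_error")
      }
      # quotient through b_t: cell (t, j) = r_jt * b_t; through b_j likewise
      if (weighting == "reliability") {
        # weighted mean with weights |b_t|, |b_j|; algebraically
        # (sign(b_t) cell_tj + sign(b_j) cell_jt) / (|b_t| + |b_j|),
        # which never divides by a small diagonal
        r <- (sign(b[t]) * tab$block[t, j] + sign(b[j]) * tab$block[j, t]) /
          (abs(b[t]) + abs(b[j]))
      } else {
        q <- c(if (!tiny[t]) tab$block[t, j] / b[t],
               if (!tiny[j]) tab$block[j, t] / b[j])
        r <- mean(q)
      }
      if (!tiny[j] && !tiny[t]) {
        asym <- max(asym, abs(tab$block[t, j] / b[t] - tab$block[j, t] / b[j]))
      }
      R[j, t] <- R[t, j] <- min(1, max(-1, r))
    }
  }
  proj <- 0
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-6) {
    lam <- pmax(ev$values, 0)
    R2 <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(R2))
    R2 <- R2 / tcrossprod(d)
    diag(R2) <- 1
    proj <- sqrt(sum((R2 - R)^2))
    message(sprintf("projected reconstruction to nearest correlation matrix (distance %.3g)",
                    proj))
    R <- R2
  }
  out <- correlation_structure(R, tab$total, units = tab$units,
                               n_samples = NULL, check_psd = FALSE)
  attr(out, "asymmetry") <- asym
  attr(out, "projection_distance") <- proj
  out
}

#' Recover direct effects from a rounded published table
#'
#' Solving the canonical equations on a quotient-reconstructed correlation
#' matrix is numerically hopeless for strongly collinear mixtures: the
#' system's condition number (~1e5 for the bundled case study) amplifies
#' 4-decimal rounding into order-one coefficient errors. This routine
#' solves the *same* equations in a diagonally preconditioned homogeneous
#' form that never divides by a direct effect: since the printed block
#' satisfies \eqn{C = diag(b^*) R_{xx}} exactly before rounding,
#' \eqn{R_{xx} b^* = R_{xy}} is equivalent to
#' \eqn{(C - diag(R_{xy}))\, b^* = 0}, so \eqn{b^*} is the null vector of
#' \eqn{K = C - diag(R_{xy})}. Rounding perturbs K by only ~1e-4 while its
#' second-smallest singular value is O(0.1), so the null direction is
#' stable. The scale is fixed by least squares of
#' \eqn{\hat R_{xx} (\alpha v) \approx \hat R_{xy}} against the
#' quotient-reconstructed matrix; the printed diagonal is never consulted.
#'
#' @param tab a [published_table()].
#' @return named numeric vector of recovered direct effects, with
#'   attributes `spectral_gap` (ratio of the two smallest singular values
#'   of K; large means a well-identified null direction) and
#'   `null_residual` (smallest singular value).
#' @export
recover_direct_effects <- function(tab) {
  stopifnot(inherits(tab, "published_decomposition_table"))
  K <- tab$block - diag(unname(tab$total))
  sv <- svd(K)
  m <- length(tab$units)
  v <- sv$v[, m]
  gap <- if (m > 1L) sv$d[m - 1L] / max(sv$d[m], .Machine$double.eps) else Inf
  if (is.finite(gap) && gap < 10) {
    warning(sprintf("null direction poorly identified (spectral gap %.2f)", gap),
            call. = FALSE)
  }
  corr <- reconstruct_from_published_table(tab)
  Rv <- drop(corr$r_xx %*% v)
  alpha <- sum(Rv * corr$r_xy) / sum(Rv^2)
  b <- alpha * v
  names(b) <- tab$units
  attr(b, "spectral_gap") <- gap
  attr(b, "null_residual") <- sv$d[m]
  b
}

#' Generate a published-style table from a known structure
#'
#' Forward direction of [reconstruct_from_published_table()]: lays out
#' direct effects on the diagonal and \eqn{r_{jt} b_t^*} off it, with the
#' summary rows. Useful for exact round-trip checks and for emulating the
#' rounding of printed tables.
#'
#' @param corr a [correlation_structure()].
#' @param b_star direct effects.
#' @param activity activity name.
#' @param digits optional rounding (e.g. 4 to emulate a printed table);
#'   `NULL` keeps full precision.
#' @return a [published_table()].
#' @export
make_published_table <- function(corr, b_star, activity = "activity",
                                 digits = NULL) {
  stopifnot(inherits(corr, "correlation_structure"))
  b <- as.numeric(b_star)
  block <- diag(b, length(b)) %*% corr$r_xx  # row t: b_t * r_tj
  diag(block) <- b
  off <- block
  diag(off) <- 0
  indirect_sum <- colSums(off)
  total <- corr$r_xy
  if (!is.null(digits)) {
    block <- round(block, digits)
    indirect_sum <- round(indirect_sum, digits)
    total <- round(total, digits)
  }
  published_table(block, indirect_sum, total, units = corr$units,
                  activity = activity)
}

#' Specification of a synthetic dataset
#'
#' The generative model the package assumes: components
#' \eqn{x \sim N(0, R_{xx})} and activity \eqn{y = \sum_j b_j x_j +
#' \varepsilon}, \eqn{\varepsilon \sim N(0, \sigma^2)} i.i.d.
#'
#' @param r_xx target correlation matrix (symmetric, unit diagonal, PSD).
#' @param b true coefficients on the unstandardized-x scale.
#' @param noise_sd error standard deviation, >= 0.
#' @param n number of samples, at least m + 2.
#' @param seed RNG seed (integer).
#' @param units optional unit names.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(r_xx, b, noise_sd, n, seed, units = NULL) {
  r_xx <- as.matrix(r_xx)
  m <- nrow(r_xx)
  units <- units %||% colnames(r_xx) %||% paste0("x", seq_len(m))
  if (length(b) != m) {
    pathsar_abort("coefficient vector length must match r_xx",
                  "pathsar_spec_error")
  }
  if (max(abs(r_xx - t(r_xx))) > 1e-10 || max(abs(diag(r_xx) - 1)) > 1e-10) {
    pathsar_abort("r_xx must be symmetric with unit diagonal",
                  "pathsar_spec_error")
  }
  ev <- eigen(r_xx, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    pathsar_abort(sprintf("r_xx is not PSD (min eigenvalue %.3g)", min(ev)),
                  "pathsar_spec_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    pathsar_abort("noise_sd must be >= 0", "pathsar_spec_error")
  }
  if (n < m + 2L) {
    pathsar_abort(sprintf("need n >= m + 2 (= %d), got %d", m + 2L, n),
                  "pathsar_spec_error")
  }
  structure(
    list(r_xx = r_xx, b = as.numeric(b), noise_sd = noise_sd,
         n = as.integer(n), seed = as.integer(seed), units = units),
    class = "synthetic_spec")
}

#' Simulate a dataset from a synthetic specification
#'
#' Multivariate normal components are generated through an eigenvalue
#' factorization of the target correlation matrix (negative roundoff
#' eigenvalues are clipped to 0), so exactly singular targets degrade
#' gracefully. Identical seeds give identical tables.
#'
#' @param spec a [synthetic_spec()].
#' @param activity name for the generated activity column.
#' @return a [sample_table()] with one activity.
#' @export
simulate_dataset <- function(spec, activity = "activity") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- length(spec$b)
  ev <- eigen(spec$r_xx, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), m)
  x <- matrix(rnorm(spec$n * m), spec$n, m) %*% t(A)
  colnames(x) <- spec$units
  y <- drop(x %*% spec$b) + rnorm(spec$n, sd = spec$noise_sd)
  sample_table(x, units = spec$units,
               activities = stats::setNames(list(y), activity))
}

#' Exchangeable (compound-symmetry) correlation matrix
#'
#' @param m dimension.
#' @param rho common off-diagonal correlation; must keep the matrix PSD,
#'   i.e. `rho >= -1/(m-1)`.
#' @return m x m correlation matrix.
#' @export
exchangeable_corr <- function(m, rho) {
  if (m > 1L && (rho < -1 / (m - 1) || rho > 1)) {
    pathsar_abort("rho outside the PSD range for an exchangeable matrix",
                  "pathsar_spec_error")
  }
  R <- matrix(rho, m, m)
  diag(R) <- 1
  R
}
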