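test_that("estimate_correlations matches the brute-force pairwise oracle", {
  set.seed(17)
  x <- matrix(rnorm(250), 50, 5, dimnames = list(NULL, paste0("u", 1:5)))
  y <- rnorm(50)
  z <- apply(x, 2, standardize)
  zy <- standardize(y)
  corr <- estimate_correlations(z, zy)

  # independent oracle: sum(z_j z_t) / (n - 1) on explicitly standardized columns
  n <- nrow(z)
  oracle_xx <- matrix(0, 5, 5)
  for (j in 1:5) for (t in 1:5) oracle_xx[j, t] <- sum(z[, j] * z[, t]) / (n - 1)
  oracle_xy <- vapply(1:5, function(j) sum(z[, j] * zy) / (n - 1), numeric(1))
  expect_equal(unname(corr$r_xx), oracle_xx, tolerance = 1e-12)
  expect_equal(unname(corr$r_xy), oracle_xy, tolerance = 1e-12)
  expect_true(corr$condition_number >= 1)
})

test_that("degenerate correlation inputs are handled", {
  # m = 1: trivially [[1]]
  z1 <- matrix(standardize(rnorm(10)), ncol = 1, dimnames = list(NULL, "a"))
  corr <- estimate_correlations(z1, standardize(rnorm(10)))
  expect_equal(unname(corr$r_xx), matrix(1, 1, 1))

  # duplicated column: off-diagonal 1 and a singularity flag
  x <- rnorm(10)
  z <- cbind(a = standardize(x), b = standardize(x))
  expect_warning(corr2 <- estimate_correlations(z, standardize(rnorm(10))),
                 "singular")
  expect_equal(corr2$r_xx["a", "b"], 1)
  expect_true(corr2$singular)

  expect_error(estimate_correlations(matrix(1:4, 2, 2), 1:2),
               class = "pathsar_insufficient_data")
})

test_that("solve_canonical: orthogonal predictors and the OLS oracle", {
  corr <- correlation_structure(diag(2), c(0.3, -0.5), units = c("a", "b"))
  expect_equal(as.numeric(solve_canonical(corr)), c(0.3, -0.5))

  # simulated standardized data: must agree with an independent least-squares fit
  spec <- synthetic_spec(exchangeable_corr(4, 0.4), b = c(2, -1, 0.5, 0.1),
                         noise_sd = 1, n = 200, seed = 23)
  tab <- simulate_dataset(spec)
  z <- standardize_table(tab, "activity")
  corr <- estimate_correlations(z$z_values, z$z_activity)
  b <- solve_canonical(corr)
  expect_equal(as.numeric(b), ols_oracle(z$z_values, z$z_activity),
               tolerance = 1e-8)
})

test_that("ill-conditioned systems abort with a named diagnosis unless ridged", {
  R <- exchangeable_corr(3, 0.2)
  R[1, 2] <- R[2, 1] <- 0.999999
  corr <- correlation_structure(R, c(0.5, 0.5, 0.2), units = c("u1", "u2", "u3"),
                                check_psd = FALSE)
  err <- expect_error(solve_canonical(corr, cond_threshold = 1e4),
                      class = "pathsar_ill_conditioned")
  expect_match(conditionMessage(err), "u[12] ~ u[12]")

  b <- solve_canonical(corr, cond_threshold = 1e4, ridge = 1e-4)
  expect_equal(attr(b, "ridge"), 1e-4)
  expect_length(b, 3)
})

test_that("decompose_effects: identity, orthogonal case, contract errors", {
  tab <- demo_table(seed = 31)
  pa <- path_analysis(tab, "antioxidant")
  d <- pa$decomposition
  # row-wise canonical identity: r_jy = b_j* + sum_{t != j} r_jt b_t*
  expect_equal(d$total, d$direct + d$indirect_sum, tolerance = 1e-10)
  expect_equal(d$indirect_sum, colSums(d$indirect), tolerance = 1e-12)
  expect_equal(unname(diag(d$indirect)), rep(0, 4))
  # indirect[t, j] = r_jt * b_t
  expect_equal(d$indirect["CGt", "ECt"],
               pa$corr$r_xx["ECt", "CGt"] * pa$b_star[["CGt"]],
               tolerance = 1e-12)

  corr <- correlation_structure(diag(3), c(0.2, -0.1, 0.4))
  d0 <- decompose_effects(corr, c(0.2, -0.1, 0.4))
  expect_equal(unname(d0$indirect), matrix(0, 3, 3))
  expect_equal(d0$total, d0$direct, tolerance = 1e-12)

  expect_error(decompose_effects(corr, 1:2), class = "pathsar_contract_error")
})

test_that("fit_summary: closed-form F, monotonicity, dof gate", {
  corr <- correlation_structure(diag(2), c(0.5, 0.5))
  fs <- fit_summary(corr, b_star = c(0.5, 0.5), n = 13)
  expect_equal(fs$r_squared, 0.5)
  expect_equal(fs$f_statistic, 5)          # (0.5/2) / (0.5/10)
  expect_equal(fs$df, c(2, 10))
  expect_equal(fs$p_value, pf(5, 2, 10, lower.tail = FALSE))
  expect_identical(fs$significant, fs$p_value <= fs$alpha)

  # p monotone decreasing in F at fixed df
  r2 <- seq(0.1, 0.9, by = 0.1)
  ps <- vapply(r2, function(r) {
    fit_summary(corr, c(r, 0), n = 13)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  expect_error(fit_summary(corr, c(0.5, 0.5), n = 3),
               class = "pathsar_dof_error")
})

test_that("R^2 from the decomposition equals 1 - SSE/SST of the regression", {
  spec <- synthetic_spec(exchangeable_corr(5, 0.3), b = c(1, -0.7, 0.4, 0.2, 0),
                         noise_sd = 0.8, n = 120, seed = 41)
  tab <- simulate_dataset(spec)
  z <- standardize_table(tab, "activity")
  corr <- estimate_correlations(z$z_values, z$z_activity)
  b <- solve_canonical(corr)
  fs <- fit_summary(corr, b)

  fitted <- z$z_values %*% b
  sse <- sum((z$z_activity - fitted)^2)
  sst <- sum(z$z_activity^2)
  expect_equal(fs$r_squared, 1 - sse / sst, tolerance = 1e-8)
})

test_that("permuting unit columns permutes the whole decomposition identically", {
  tab <- demo_table(seed = 51)
  pa <- path_analysis(tab, "antioxidant")

  perm <- c(3, 1, 4, 2)
  tab2 <- tab
  tab2$values <- tab$values[, perm]
  tab2$units <- tab$units[perm, ]
  pa2 <- path_analysis(tab2, "antioxidant")

  expect_equal(pa2$b_star, pa$b_star[perm], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(pa2$decomposition$total),
               unname(pa$decomposition$total[perm]), tolerance = 1e-12)
  expect_equal(unname(pa2$decomposition$indirect),
               unname(pa$decomposition$indirect[perm, perm]), tolerance = 1e-10)
  expect_equal(pa2$fit$r_squared, pa$fit$r_squared, tolerance = 1e-10)
})

test_that("computed R^2 stays in [0, 1] for PSD nonsingular structures", {
  set.seed(61)
  for (i in 1:10) {
    m <- sample(2:6, 1)
    spec <- synthetic_spec(exchangeable_corr(m, runif(1, -0.1, 0.6)),
                           b = rnorm(m), noise_sd = runif(1, 0.1, 2),
                           n = 50, seed = i)
    tab <- simulate_dataset(spec)
    pa <- path_analysis(tab, "activity")
    expect_gte(pa$fit$r_squared_raw, 0)
    expect_lte(pa$fit$r_squared_raw, 1 + 1e-8)
  }
})
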