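tabs <- bundled_paper_tables()

test_that("bundled decomposition tables have the published shape and anchor cells", {
  for (tab in tabs) {
    expect_s3_class(tab, "published_decomposition_table")
    expect_equal(dim(tab$block), c(10, 10))
    expect_length(tab$indirect_sum, 10)
    expect_length(tab$total, 10)
  }
  expect_equal(tabs$antioxidant$block["ECGe", "ECGe"], 1.1117)
  expect_equal(tabs$antioxidant$block["ECGe", "ECGt"], -1.1053)
  expect_equal(tabs$antidiabetes$total[["EGCGe"]], -0.2828)
  expect_equal(tabs$antidiabetes$block["ECGt", "ECGt"], -1.1364)
  # transcription cross-check: column sums of the off-diagonal block must
  # reproduce the printed sum-of-indirect row to printed precision
  for (tab in tabs) {
    off <- tab$block
    diag(off) <- 0
    expect_equal(unname(colSums(off)), unname(tab$indirect_sum),
                 tolerance = 2.5e-4)
  }
})

test_that("published-table CSV round trip is exact", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_published_table(tabs$antioxidant, path)
  back <- read_published_table(path, activity = "antioxidant")
  expect_equal(back$block, tabs$antioxidant$block)
  expect_equal(back$total, tabs$antioxidant$total)
})

test_that("reconstruction: quotient example, exact r_xy, asymmetry diagnostic", {
  corr <- reconstruct_from_published_table(tabs$antioxidant)
  # r(ECGt, ECGe): quotients -1.1053/1.1117 and 0.0273/-0.0274, both ~ -0.994
  expect_equal(corr$r_xx["ECGt", "ECGe"], -0.994, tolerance = 0.005)
  expect_equal(corr$r_xy, tabs$antioxidant$total)
  expect_equal(unname(diag(corr$r_xx)), rep(1, 10))
  expect_lt(max(abs(corr$r_xx)), 1 + 1e-12)
  expect_gte(attr(corr, "asymmetry"), 0)
  expect_equal(attr(corr, "projection_distance"), 0)
})

test_that("reconstruction is exact on a full-precision generated table", {
  set.seed(101)
  spec <- synthetic_spec(exchangeable_corr(5, 0.4), b = c(1, -0.5, 0.3, 0.2, -0.1),
                         noise_sd = 0.5, n = 400, seed = 101)
  tab <- simulate_dataset(spec)
  pa <- path_analysis(tab, "activity")
  pub <- make_published_table(pa$corr, pa$b_star, digits = NULL)

  rec <- reconstruct_from_published_table(pub)
  expect_equal(rec$r_xx, pa$corr$r_xx, tolerance = 1e-12)
  expect_equal(rec$r_xy, pa$corr$r_xy, tolerance = 1e-12)

  b <- recover_direct_effects(pub)
  expect_equal(as.numeric(b), as.numeric(pa$b_star), tolerance = 1e-8)
})

test_that("printed-table round trip honours the rounding budget", {
  for (tab in tabs) {
    corr <- reconstruct_from_published_table(tab)
    d <- decompose_effects(corr, diag(tab$block), tab$activity)
    cells <- d$indirect
    diag(cells) <- d$direct
    expect_lt(max(abs(cells - tab$block)), 0.02)
    expect_lt(max(abs(d$direct + d$indirect_sum - tab$total)), 0.01)
    expect_lt(max(abs(d$indirect_sum - tab$indirect_sum)), 0.01)
  }
})

test_that("direct effects are recovered from both rounded tables within 0.05", {
  for (tab in tabs) {
    b <- recover_direct_effects(tab)
    expect_lt(max(abs(b - diag(tab$block))), 0.05)
    expect_gt(attr(b, "spectral_gap"), 10)
  }
})

test_that("reconstruction refuses a pair of near-zero direct effects", {
  corr <- correlation_structure(exchangeable_corr(4, 0.5), c(0.5, 0.4, 0.3, 0.2),
                                units = c("a", "b", "c", "d"))
  pub <- make_published_table(corr, c(1e-9, 2e-9, 0.5, 0.4))
  err <- expect_error(reconstruct_from_published_table(pub),
                      class = "pathsar_reconstruction_error")
  expect_match(conditionMessage(err), "a.*b")
})

test_that("simulate_dataset is seed-deterministic and respects the model", {
  spec <- demo_spec(seed = 13)
  expect_identical(simulate_dataset(spec), simulate_dataset(spec))
  expect_false(identical(simulate_dataset(spec),
                         simulate_dataset(demo_spec(seed = 14))))

  # noiseless activity is an exact linear combination: R^2 = 1
  spec0 <- synthetic_spec(exchangeable_corr(3, 0.2), b = c(1, -1, 0.5),
                          noise_sd = 0, n = 50, seed = 7)
  pa <- path_analysis(simulate_dataset(spec0), "activity")
  expect_equal(pa$fit$r_squared_raw, 1, tolerance = 1e-10)
})

test_that("large-sample empirical correlations concentrate on the target", {
  # Monte-Carlo concentration check, run at n = 40000 (tolerance 0.01 is
  # already comfortable there; larger n only burns test time)
  m <- 5
  spec <- synthetic_spec(exchangeable_corr(m, 0.5), b = rep(1, m),
                         noise_sd = 1, n = 40000, seed = 3)
  tab <- simulate_dataset(spec)
  emp <- cor(tab$values)
  expect_lt(max(abs(emp - exchangeable_corr(m, 0.5))), 0.01)
})

test_that("singular targets degrade gracefully", {
  R <- matrix(1, 2, 2)  # exactly singular but a valid correlation matrix
  spec <- synthetic_spec(R, b = c(1, 1), noise_sd = 0.1, n = 50, seed = 5)
  tab <- simulate_dataset(spec)
  expect_equal(cor(tab$values)[1, 2], 1, tolerance = 1e-12)
})

test_that("synthetic_spec validates its invariants", {
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(synthetic_spec(bad, rep(1, 3), 1, 50, 1),
               class = "pathsar_spec_error")
  expect_error(synthetic_spec(diag(3), rep(1, 3), 1, 4, 1),
               class = "pathsar_spec_error")
  expect_error(synthetic_spec(diag(3), rep(1, 3), -1, 50, 1),
               class = "pathsar_spec_error")
  expect_error(exchangeable_corr(5, -0.5), class = "pathsar_spec_error")
})
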