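# shared fixtures, all built in code

# a path_decomposition carrying exactly the printed rows of a published
# table (direct on the diagonal, printed sums and totals), for testing the
# interpretation layer against the published statements verbatim
decomp_from_published <- function(tab) {
  indirect <- tab$block
  diag(indirect) <- 0
  structure(
    list(direct = stats::setNames(diag(tab$block), tab$units),
         indirect = indirect,
         indirect_sum = tab$indirect_sum,
         total = tab$total,
         units = tab$units,
         activity = tab$activity),
    class = "path_decomposition")
}

# small well-conditioned simulated table with known ground truth
demo_spec <- function(seed = 11, n = 200, noise_sd = 0.3) {
  synthetic_spec(exchangeable_corr(4, 0.3), b = c(1, -0.5, 0.3, 0),
                 noise_sd = noise_sd, n = n, seed = seed,
                 units = c("ECt", "CGt", "Ce", "ECe"))
}

demo_table <- function(...) simulate_dataset(demo_spec(...), activity = "antioxidant")

# independent OLS oracle: lm() on standardized columns, no intercept
ols_oracle <- function(z, zy) {
  unname(stats::coef(stats::lm(zy ~ z - 1)))
}
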