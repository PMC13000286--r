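test_that("Spearman rho matches the closed form and base R", {
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_equal(spearman_rho(1:7, (1:7)^3), 1)
  expect_equal(spearman_rho(1:7, -(1:7)), -1)
  # ties: agrees with stats::cor mid-rank handling
  set.seed(1)
  x <- sample(1:4, 30, replace = TRUE)
  y <- rnorm(30)
  expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
  # zero rank variance: undefined
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
})

test_that("single-feature adjusted p matches exhaustive enumeration", {
  set.seed(11)
  x <- rnorm(7); y <- rnorm(7)
  obs <- abs(spearman_rho(x, y))
  P <- all_perms(7)
  rho_all <- apply(P, 1, function(p) abs(spearman_rho(x, y[p])))
  p_exact <- mean(rho_all >= obs - 1e-12)
  res <- permutation_adjusted(matrix(x, 1), y, n_permutations = 20000,
                              seed = 3)
  mcse <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(tidy(res)$p_adj - p_exact), 2 * mcse + 1 / 20001)
})

test_that("adjusted p floors, monotonicity and family dominance", {
  set.seed(12)
  F <- matrix(rnorm(5 * 15), 5)
  y <- rnorm(15)
  res <- tidy(permutation_adjusted(F, y, 2000, seed = 4))
  expect_true(all(res$p_adj >= 1 / 2001 & res$p_adj <= 1))
  # |rho| ordering implies p ordering within the family
  o <- order(-abs(res$rho))
  expect_true(all(diff(res$p_adj[o]) >= 0))
  # family-adjusted p dominates the single-feature p
  for (k in 1:5) {
    single <- tidy(permutation_adjusted(F[k, , drop = FALSE], y, 2000,
                                        seed = 4))
    expect_gte(res$p_adj[k], single$p_adj)
  }
  # perfectly monotone feature at n = 13: p near the floor
  r2 <- tidy(permutation_adjusted(matrix(1:13, 1), (1:13)^2, 1e5, seed = 5))
  expect_lte(r2$p_adj, 3 / (1e5 + 1))

  # reproducibility
  a <- tidy(permutation_adjusted(F, y, 1000, seed = 9))
  b <- tidy(permutation_adjusted(F, y, 1000, seed = 9))
  expect_identical(a, b)
})

test_that("family-wise error is controlled on null cohorts", {
  flags <- vapply(1:200, function(s) {
    set.seed(s + 9000)
    F <- matrix(rnorm(8 * 13), 8)
    y <- rnorm(13)
    any(tidy(permutation_adjusted(F, y, 500, seed = s))$flag)
  }, logical(1))
  # 200 cohorts at nominal 0.05: 2 se band
  expect_gt(mean(flags), 0.05 - 2 * sqrt(0.05 * 0.95 / 200))
  expect_lt(mean(flags), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("partial Spearman reduces, nullifies and matches plain rank correlation", {
  set.seed(13)
  # empty covariate set: identical to the unadjusted family
  F <- matrix(rnorm(3 * 14), 3)
  y <- rnorm(14)
  plain <- tidy(permutation_adjusted(F, y, 500, seed = 2))
  viapartial <- tidy(partial_spearman_adjusted(F, y, NULL, 500, seed = 2))
  expect_identical(plain, viapartial)

  # y equal to the covariate: partial rho collapses to 0
  pr <- tidy(partial_spearman_adjusted(F, y, cbind(z = y), 200, seed = 3))
  expect_lt(max(abs(pr$rho)), 1e-6)

  # covariate whose ranks are exactly orthogonal to the ranks of x and y:
  # partial == plain (search the permutations of 1:8 for exact zeros)
  xf <- 1:8
  yy <- c(2, 1, 4, 3, 6, 5, 8, 7)
  ctr <- function(v) v - mean(v)
  perms <- all_perms(8)
  hit <- which(apply(perms, 1, function(p) {
    sum(ctr(p) * ctr(xf)) == 0 && sum(ctr(p) * ctr(yy)) == 0
  }))[1]
  z <- perms[hit, ]
  pp <- tidy(partial_spearman_adjusted(matrix(xf, 1), yy, cbind(z = z),
                                       50, seed = 1))
  expect_lt(abs(pp$rho - spearman_rho(xf, yy)), 1e-6)

  # collinear covariates are rejected by name
  Z <- cbind(a = y, b = 2 * y)
  expect_error(partial_spearman_adjusted(F, rnorm(14), Z, 100), "collinear")
})

test_that("group comparisons: Mann-Whitney and chi-square contracts", {
  # identical groups: p near 1
  g <- c(1, 2, 3, 4, 5, 6, 7, 8)
  r <- group_compare(g, g, "continuous")
  expect_gt(r$p_value, 0.9)
  expect_false(r$marginal)

  # complete separation at n = 8 + 8: tiny p
  r2 <- group_compare(1:8, 101:108, "continuous")
  expect_lt(r2$p_value, 0.001)
  expect_true(r2$marginal)

  # balanced 2x2 table: statistic 0, p = 1
  a <- rep(c("x", "y"), each = 5)
  b <- rep(c("x", "y"), each = 5)
  r3 <- group_compare(a, b, "categorical")
  expect_equal(unname(r3$statistic), 0)
  expect_equal(r3$p_value, 1)
})

test_that("planted physiology-gain effects are recovered end to end", {
  # scaled-down version of the parameter-recovery study (full version in
  # the acceptance suite)
  hits <- vapply(1:25, function(s) {
    cs <- generate_cohort_summaries(13, true_spearman = 0.8, seed = s)
    any(tidy(permutation_adjusted(cs$features, cs$gain, 2000, seed = s))$flag)
  }, logical(1))
  nulls <- vapply(1:25, function(s) {
    cs <- generate_cohort_summaries(13, true_spearman = 0, seed = 100 + s)
    any(tidy(permutation_adjusted(cs$features, cs$gain, 2000,
                                  seed = 100 + s))$flag)
  }, logical(1))
  expect_gte(mean(hits), 0.7)
  expect_lte(mean(nulls), 0.12)
})

test_that("tidy, glance and autoplot work on topography objects", {
  set.seed(14)
  F <- matrix(rnorm(8 * 13), 8, dimnames = list(montage_8(), NULL))
  res <- permutation_adjusted(F, rnorm(13), 500, seed = 6, family = "demo")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("family", "feature", "n", "rho", "p_adj", "flag"))
  gl <- glance(res)
  expect_equal(gl$n_features, 8)
  expect_equal(gl$n_permutations, 500)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
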