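test_that("marginal test finds exact signals and flags degenerate input", {
  set.seed(5)
  a_w <- runif(10)
  res <- marginal_test(a_w, 2 + 3 * a_w)  # exact linear, no noise
  expect_lt(res$p, 1e-10)
  expect_equal(res$beta, 3, tolerance = 1e-8)

  resc <- marginal_test(rep(0.3, 10), rnorm(10))
  expect_equal(resc$p, 1)
  expect_equal(resc$flags, "degenerate")

  # dichotomous phenotypes go through logistic regression
  y <- rep(c(0, 1), each = 10)
  x <- c(rnorm(10, 0), rnorm(10, 1))
  resd <- marginal_test(x, y)
  expect_equal(resd$model, "dichotomous")
  expect_true(resd$p >= 0 && resd$p <= 1)

  # complete separation is flagged, not silently dropped
  ressep <- marginal_test(c(1:10, 21:30), rep(c(0, 1), each = 10))
  expect_match(ressep$flags, "separation")
})

test_that("marginal p-values are uniform under the null", {
  set.seed(6)
  n <- 30
  x <- runif(n)
  p <- vapply(seq_len(1000),
              function(b) marginal_test(x, rnorm(n))$p, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("corrected test adds K-1 component covariates", {
  set.seed(7)
  n <- 40
  a_w <- runif(n)
  y <- rnorm(n)
  P1 <- matrix(1, n, 1)
  # single component adds no covariates: identical to the marginal test
  expect_equal(corrected_test(a_w, y, P1), marginal_test(a_w, y))

  # duplicating the abundance as a covariate trips the collinearity flag
  P_dup <- cbind(a_w, 1 - a_w)
  res <- corrected_test(a_w, y, P_dup)
  expect_match(res$flags, "collinear")

  # signal fully carried by the components is absorbed by the correction
  P <- random_stochastic_matrix(n, 3, seed = 8)
  y2 <- drop(P %*% c(1, 2, 3)) + rnorm(n, 0, 0.05)
  aw2 <- drop(P %*% c(0.9, 0.05, 0.05)) + rnorm(n, 0, 0.002)
  expect_lt(marginal_test(aw2, y2)$p, 0.01)
  expect_gt(corrected_test(aw2, y2, P)$p, 0.01)
})

test_that("component-phenotype test behaves at both extremes", {
  set.seed(9)
  p_k <- runif(30)
  expect_lt(component_phenotype_test(p_k, p_k)$p, 1e-10)

  p <- vapply(seq_len(1000),
              function(b) component_phenotype_test(p_k, rnorm(30))$p,
              numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)

  # a covariate equal to the phenotype explains everything
  y <- rnorm(30)
  res <- component_phenotype_test(p_k, y, covariates = cbind(y))
  expect_true(res$p > 0.9 || grepl("collinear", res$flags))
})

test_that("permutation p-values use the +1 correction and are reproducible", {
  y <- 1:10
  x <- c(1, 1, 1, 1, 1, 2, 2, 2, 2, 10)
  stat <- function(yy) sum(yy * x)
  res <- permutation_test(stat, y, n_perms = 99, seed = 1)
  expect_equal(res$p, permutation_test(stat, y, n_perms = 99, seed = 1)$p)
  # observed y is the unique maximizer here: boundary value 1/(n+1)
  expect_equal(res$p, 1 / 100)
  # p is monotone in the observed statistic for a fixed permutation set
  p_at <- function(obs) (1 + sum(res$permuted >= obs)) / 100
  grid <- sort(res$permuted)
  expect_true(all(diff(p_at(grid)) <= 0) ||
              all(diff(vapply(grid, p_at, numeric(1))) <= 0))

  # statistic independent of labels gives roughly uniform p
  set.seed(2)
  ps <- replicate(200, {
    yy <- rnorm(8)
    permutation_test(function(z) rnorm(1), yy, n_perms = 19)$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("rejected fraction is calibrated under the null and detects shifts", {
  set.seed(10)
  W <- 25
  fracs <- replicate(400, {
    a <- matrix(runif(W * 12), W, 12)
    fraction_rejected(a, rep(c("a", "b"), each = 6), alpha = 0.05)$fraction
  })
  expect_lt(abs(mean(fracs) - 0.05), 0.02)

  # groups drawn from different component mixtures reject broadly
  F <- random_stochastic_matrix(2, W, seed = 11)
  P <- rbind(matrix(c(.9, .1), 8, 2, byrow = TRUE),
             matrix(c(.1, .9), 8, 2, byrow = TRUE))
  R <- sample_counts(P, F, 5000, seed = 12)
  a <- relative_abundance(R)
  fr <- fraction_rejected(a, rep(c("g1", "g2"), each = 8), alpha = 0.05)
  expect_gt(fr$fraction, 0.5)

  expect_equal(fraction_rejected(a, rep(c("g1", "g2"), each = 8),
                                 alpha = 1)$fraction, 1)
  expect_error(fraction_rejected(a, c("g1", rep("g2", 15))), "2 samples")
})

test_that("qq points pair sorted p-values with uniform quantiles", {
  n <- 7
  grid <- (seq_len(n) - 0.5) / n
  qq <- qq_points(sample(grid))
  expect_equal(qq$observed, qq$expected)  # identity line
  qq1 <- qq_points(rep(1, 5))
  expect_true(all(qq1$observed == 1))
  expect_equal(nrow(qq_points(runif(13))), 13)
  expect_error(qq_points(c(0.5, 1.2)), "0, 1|\\[0, 1\\]")
})
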