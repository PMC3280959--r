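test_that("random initialization is row-stochastic and reproducible", {
  m <- init_params(5, 3, 7, seed = 11)
  expect_equal(rowSums(m$P), rep(1, 5), tolerance = 1e-12)
  expect_equal(rowSums(m$F), rep(1, 3), tolerance = 1e-12)
  expect_equal(init_params(5, 3, 7, seed = 11), m)
  expect_equal(unname(init_params(4, 1, 6, seed = 2)$P), matrix(1, 4, 1))
})

test_that("aggregate log-likelihood matches the brute-force oracle", {
  set.seed(21)
  R <- matrix(rpois(12, 8), 3, 4)
  m <- init_params(3, 2, 4, seed = 5)
  expect_equal(loglik_aggregate(m, R), loglik_bruteforce(m$P, m$F, R))

  # uniform F rows collapse the mixture regardless of P
  mu <- m; mu$F <- matrix(1 / 4, 2, 4)
  expect_equal(loglik_aggregate(mu, R), sum(R) * log(1 / 4))

  # identity factorization carries zero log-likelihood
  mi <- list(P = diag(2), F = diag(2))
  expect_equal(loglik_aggregate(mi, matrix(c(3, 0, 0, 3), 2, 2)), 0)

  expect_error(loglik_aggregate(m, R[, 1:3]), "mismatch")
})

test_that("aggregate EM is monotone and reaches the grid-search optimum", {
  # monotone likelihood on random instances (M=5, W=6, K=2)
  for (s in 1:3) {
    set.seed(100 + s)
    R <- matrix(rpois(30, 12), 5, 6)
    fit <- em_aggregate(R, fit_options(K = 2, restarts = 2, seed = s))
    expect_true(all(diff(fit$trace) >= -1e-8 * abs(fit$trace[-1])))
  }

  # fixed point matches an independent two-stage simplex grid search
  set.seed(42)
  for (s in 1:3) {
    R <- matrix(rpois(4, 30) + 1, 2, 2)
    fit <- em_aggregate(R, fit_options(K = 2, restarts = 8, seed = s))
    expect_equal(fit$loglik, grid_loglik_max(R), tolerance = 1e-3)
  }

  # separable counts recover the identity factorization up to relabeling
  fit <- em_aggregate(matrix(c(100, 0, 0, 100), 2, 2),
                      fit_options(K = 2, restarts = 5, seed = 1))
  expect_lt(estimation_error(fit$P, diag(2), margin = 2), 1e-3)

  # K = 1 collapses to pooled frequencies
  R <- matrix(c(3, 2, 1, 2), 2, 2)
  f1 <- em_aggregate(R, fit_options(K = 1, restarts = 1, seed = 1))
  expect_equal(unname(f1$F[1, ]), colSums(R) / sum(R))
  expect_equal(unname(f1$P), matrix(1, 2, 1))
})

test_that("both EM variants keep P and F row-stochastic at every iteration", {
  set.seed(31)
  R <- matrix(rpois(30, 9) + 1, 5, 6)
  for (iters in c(1, 3, 7)) {
    fit <- em_aggregate(R, fit_options(K = 2, restarts = 1, max_iters = iters,
                                       seed = 9))
    expect_equal(rowSums(fit$P), rep(1, 5), tolerance = 1e-9)
    expect_equal(rowSums(fit$F), rep(1, 2), tolerance = 1e-9)
  }
  reads <- list(a = c("AAAAA", "CCCCC", "GGGGG"),
                b = c("CCCCC", "GGGGG", "AAAAA"))
  bags <- read_kmer_bags(reads, 4, "first")
  for (iters in c(1, 3)) {
    fit <- em_refined(bags, fit_options(K = 2, restarts = 1,
                                        max_iters = iters, seed = 9))
    expect_equal(unname(rowSums(fit$P)), rep(1, 2), tolerance = 1e-9)
    expect_equal(unname(rowSums(fit$F)), rep(1, 2), tolerance = 1e-9)
  }
})

test_that("refined EM with one k-mer per read reduces to the aggregate model", {
  set.seed(61)
  # three samples with one 4-mer per read: the two likelihoods coincide
  words <- c("AAAA", "CCCC", "GGGG", "TTTT")
  reads <- list(
    s1 = sample(words, 40, replace = TRUE, prob = c(.6, .2, .1, .1)),
    s2 = sample(words, 40, replace = TRUE, prob = c(.1, .6, .2, .1)),
    s3 = sample(words, 40, replace = TRUE, prob = c(.1, .1, .2, .6)))
  bags <- read_kmer_bags(reads, 4, "first")
  cm <- count_matrix(reads, 4, "first")
  fa <- em_aggregate(cm, fit_options(K = 2, restarts = 6, seed = 3))
  fr <- em_refined(bags, fit_options(K = 2, restarts = 6, seed = 3))
  expect_equal(fr$loglik, fa$loglik, tolerance = 1e-6)
  expect_lt(estimation_error(fr$P, fa$P, margin = 2), 1e-4)
  expect_lt(estimation_error(fr$F, fa$F, margin = 1), 1e-4)

  # monotone likelihood for the refined model too
  expect_true(all(diff(fr$trace) >= -1e-8 * abs(fr$trace[-1])))
})

test_that("refined EM separates reads whose bags use disjoint class sets", {
  # reads over {AAAA} vs {CCCC}: with K=2 the components specialize
  reads <- list(s1 = c(rep("AAAAAAAA", 4), rep("CCCCCCCC", 4)))
  bags <- read_kmer_bags(reads, 4, "overlapping")
  fit <- em_refined(bags, fit_options(K = 2, restarts = 5, seed = 2))
  # each component puts essentially all mass on one class
  expect_equal(sort(apply(fit$F, 1, max)), c(1, 1), tolerance = 1e-6)
  expect_equal(sort(unname(apply(fit$F, 1, which.max))),
               sort(match(c("AAAA", "CCCC"), bags$classes)))
})

test_that("estimation error is permutation-matched", {
  F_true <- random_stochastic_matrix(3, 5, seed = 4)
  expect_equal(estimation_error(F_true, F_true), 0)
  expect_equal(estimation_error(F_true[c(2, 3, 1), ], F_true), 0)

  # known perturbation against the exhaustive two-permutation oracle
  F2 <- random_stochastic_matrix(2, 4, seed = 5)
  eps <- c(0.01, -0.01, 0.02, -0.02)
  Fp <- F2; Fp[1, ] <- Fp[1, ] + eps
  direct <- min(sum((Fp - F2)^2), sum((Fp[2:1, ] - F2)^2))
  expect_equal(estimation_error(Fp, F2), direct)
  expect_equal(estimation_error(Fp, F2), sum(eps^2))

  expect_error(estimation_error(F_true, F2), "mismatch")
})

test_that("exact factorizations are approached as counts grow", {
  P <- random_stochastic_matrix(20, 2, seed = 71)
  F <- random_stochastic_matrix(2, 136, seed = 72)
  errs <- vapply(c(1e2, 1e4, 1e6), function(n) {
    R <- sample_counts(P, F, n, seed = 73)
    fit <- em_aggregate(R, fit_options(K = 2, restarts = 8, seed = 74))
    estimation_error(fit$P, P, margin = 2)
  }, numeric(1))
  # decreasing on the ladder, down to the small identifiability floor of the
  # factorization (interior F rows admit a wedge of equivalent solutions, so
  # the error saturates near zero rather than vanishing)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05 * errs[1])
  expect_lt(errs[3], 0.1)
})

test_that("squared-correlation score maxes over orderings and handles noise", {
  P <- random_stochastic_matrix(500, 3, seed = 81)
  sc <- compare_to_pca(P, list(exact = P, shuffled = P[, c(3, 1, 2)]))
  expect_equal(unname(sc), c(1, 1), tolerance = 1e-12)

  noise <- matrix(rnorm(1500), 500, 3)
  expect_lt(compare_to_pca(P, list(n = noise))[["n"]], 0.05)

  const <- matrix(1, 500, 3)
  expect_equal(unname(compare_to_pca(P, list(c = const))[["c"]]), 0)
})
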