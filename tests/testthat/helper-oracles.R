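# Independent oracles and small fixtures used across test files.

# Brute-force mixture log-likelihood by explicit per-cell summation.
loglik_bruteforce <- function(P, F, R) {
  ll <- 0
  for (i in seq_len(nrow(R))) for (w in seq_len(ncol(R))) {
    if (R[i, w] == 0) next
    mass <- 0
    for (k in seq_len(ncol(P))) mass <- mass + P[i, k] * F[k, w]
    ll <- ll + R[i, w] * log(mass)
  }
  ll
}

# Maximum log-likelihood of the K=2, 2x2 model by two-stage grid search over
# the four free simplex parameters (p1, p2, f1, f2). Independent of EM.
grid_loglik_max <- function(R, coarse = 0.025, fine = 0.002, halo = 0.03) {
  ll_grid <- function(p1, p2, f1, f2) {
    g <- expand.grid(p1 = p1, p2 = p2, f1 = f1, f2 = f2)
    A11 <- g$p1 * g$f1 + (1 - g$p1) * g$f2
    A21 <- g$p2 * g$f1 + (1 - g$p2) * g$f2
    eps <- 1e-300
    ll <- R[1, 1] * log(pmax(A11, eps)) + R[1, 2] * log(pmax(1 - A11, eps)) +
          R[2, 1] * log(pmax(A21, eps)) + R[2, 2] * log(pmax(1 - A21, eps))
    list(best = max(ll), at = g[which.max(ll), ])
  }
  s <- seq(0, 1, by = coarse)
  c1 <- ll_grid(s, s, s, s)
  w <- function(x) seq(max(0, x - halo), min(1, x + halo), by = fine)
  a <- c1$at
  c2 <- ll_grid(w(a$p1), w(a$p2), w(a$f1), w(a$f2))
  max(c1$best, c2$best)
}

# Exhaustive k-medoids oracle: best medoid subset of size S by full
# enumeration (tiny n only).
kmedoids_oracle <- function(X, S, metric = "l1") {
  n <- nrow(X)
  d <- if (metric == "l1") function(a, b) sum(abs(a - b))
       else function(a, b) sqrt(sum((a - b)^2))
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- d(X[i, ], X[j, ])
  combos <- utils::combn(n, S)
  costs <- apply(combos, 2, function(med)
    sum(apply(D[, med, drop = FALSE], 1, min)))
  list(cost = min(costs), medoids = combos[, which.min(costs)])
}

# Sequence overlap oracle: explicit check of all four suffix-prefix
# arrangements of two reads at every overlap length (exact matching).
overlap_oracle_pair <- function(a, b, min_overlap) {
  rc <- function(s) metajoint::revcomp(s)
  suf <- function(s, m) substr(s, nchar(s) - m + 1, nchar(s))
  pre <- function(s, m) substr(s, 1, m)
  for (left in list(c(a, b), c(b, a), c(a, rc(b)), c(rc(a), b))) {
    L <- left[1]; Rr <- left[2]
    for (m in min_overlap:min(nchar(L), nchar(Rr))) {
      if (suf(L, m) == pre(Rr, m)) return(TRUE)
    }
  }
  FALSE
}

# Random small community shared by binning tests: high per-tag coverage so
# that clustering is essentially noiseless.
make_test_community <- function(n_species = 2, n_samples = 5,
                                genome_len = 5e4, reads_per_sample = 3000,
                                read_len = 400, proportions = NULL,
                                seed = 1) {
  genomes <- vapply(seq_len(n_species),
                    function(s) random_genome(genome_len, seed + s),
                    character(1))
  names(genomes) <- paste0("sp", seq_len(n_species))
  if (is.null(proportions))
    proportions <- incremental_proportions(max(n_species, 2), n_samples,
                                           seed = seed + 50)[[n_species]]
  simulate_reads(genomes, proportions, reads_per_sample, read_len,
                 seed = seed + 100)
}
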