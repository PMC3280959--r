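test_that("sequence overlap detection honors threshold, strand and N rules", {
  a <- random_genome(400, 1)
  # exact 50-base suffix-prefix overlap -> edge
  b50 <- paste0(substr(a, 351, 400), random_genome(350, 2))
  expect_length(detect_overlaps_sequence(c(a, b50))$from, 1)
  # 49 exact bases -> no edge
  b49 <- paste0(substr(a, 352, 400), random_genome(351, 3))
  expect_length(detect_overlaps_sequence(c(a, b49))$from, 0)
  # reverse-complement arrangement of a 60-base suffix -> edge, matching the
  # explicit four-orientation oracle
  brc <- revcomp(paste0(substr(a, 341, 400), random_genome(340, 4)))
  expect_length(detect_overlaps_sequence(c(a, brc))$from, 1)
  expect_true(overlap_oracle_pair(a, brc, 50))
  expect_false(overlap_oracle_pair(a, b49, 50))
  # N never matches
  bn <- b50
  substr(bn, 25, 25) <- "N"
  expect_length(detect_overlaps_sequence(c(a, bn))$from, 0)
  # but the permissive mode tolerates it as a mismatch
  expect_length(detect_overlaps_sequence(c(a, bn),
                                         max_mismatch_rate = 0.05)$from, 1)
})

test_that("sequence overlaps agree with the pairwise oracle on random pools", {
  set.seed(14)
  genome <- random_genome(3000, 15)
  starts <- sample(0:(3000 - 150), 30)
  reads <- substring(genome, starts + 1, starts + 150)
  flip <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  reads[flip] <- revcomp(reads[flip])
  G <- detect_overlaps_sequence(reads, min_overlap = 50)
  got <- sort(paste(pmin(G$from, G$to), pmax(G$from, G$to)))
  want <- character(0)
  for (i in 1:29) for (j in (i + 1):30)
    if (overlap_oracle_pair(reads[i], reads[j], 50))
      want <- c(want, paste(i, j))
  expect_equal(got, sort(want))
})

test_that("positional overlaps use a strict threshold and respect genomes", {
  lay <- data.frame(sample = 1, genome = c("g", "g", "g", "h"),
                    start = c(0, 250, 300, 0), length = 400)
  G <- detect_overlaps_positional(lay, min_overlap = 100)
  edges <- paste(G$from, G$to)
  expect_true("1 2" %in% edges)        # overlap 150 > 100
  expect_false("1 3" %in% edges)       # overlap exactly 100: excluded
  expect_false(any(grepl("4", edges))) # other genome, same coordinates
})

test_that("greedy MIS produces valid maximal tag sets with affiliations", {
  edgeless <- metajoint:::new_overlap_graph(4, integer(0), integer(0),
                                            rep(1, 4), "1")
  expect_equal(greedy_mis(edgeless)$tags, 1:4)

  cedges <- t(utils::combn(5, 2))
  complete <- metajoint:::new_overlap_graph(5, cedges[, 1], cedges[, 2],
                                            rep(1, 5), "1")
  Tc <- greedy_mis(complete)
  expect_equal(Tc$tags, 1)
  expect_equal(Tc$affiliation, rep(1, 5))

  # path a-b-c scanned in order: tags {a, c}, b affiliated with a
  path <- metajoint:::new_overlap_graph(3, c(1, 2), c(2, 3), rep(1, 3), "1")
  Tp <- greedy_mis(path)
  expect_equal(Tp$tags, c(1, 3))
  expect_equal(Tp$affiliation, c(1, 1, 3))

  # property: independence and maximality on random graphs
  for (s in 1:5) {
    set.seed(s)
    n <- 60
    e <- unique(t(replicate(120, sort(sample.int(n, 2)))))
    G <- metajoint:::new_overlap_graph(n, e[, 1], e[, 2],
                                       sample(1:3, n, TRUE), as.character(1:3))
    T <- greedy_mis(G)
    is_tag <- seq_len(n) %in% T$tags
    # no two tags adjacent
    expect_false(any(is_tag[e[, 1]] & is_tag[e[, 2]]))
    # every non-tag has a tagged neighbour (its affiliation)
    nt <- which(!is_tag)
    expect_true(all(T$affiliation[nt] %in% T$tags))
    adj_ok <- vapply(nt, function(v) {
      any((e[, 1] == v & e[, 2] == T$affiliation[v]) |
          (e[, 2] == v & e[, 1] == T$affiliation[v]))
    }, logical(1))
    expect_true(all(adj_ok))
  }
})

test_that("coverage vectors count per-sample neighbours plus self", {
  # isolated tag from sample 2 of 3
  iso <- metajoint:::new_overlap_graph(1, integer(0), integer(0), 2L,
                                       as.character(1:3))
  Ti <- greedy_mis(iso)
  expect_equal(unname(coverage_vectors(Ti, iso)[1, ]), c(0, 1, 0))

  # star: tag t (sample 1) overlapped by 3 reads of sample 1 and 2 of sample 2
  G <- metajoint:::new_overlap_graph(6, rep(1, 5), 2:6,
                                     c(1, 1, 1, 1, 2, 2), as.character(1:2))
  T <- greedy_mis(G)
  expect_equal(T$tags, 1)
  V <- coverage_vectors(T, G)
  expect_equal(unname(V[1, ]), c(4, 2))
  # conservation: row sum = degree + 1
  expect_equal(sum(V[1, ]), 5 + 1)
})

test_that("k-medoids matches exhaustive search on small instances", {
  set.seed(16)
  X <- rbind(matrix(rnorm(16, 0, 0.5), 8, 2),
             matrix(rnorm(16, 8, 0.5), 8, 2))
  km <- kmedoids(X, 2, seed = 3, n_starts = 5)
  oracle <- kmedoids_oracle(X, 2)
  expect_equal(km$cost, oracle$cost, tolerance = 1e-12)
  expect_equal(length(unique(km$labels[1:8])), 1)
  expect_equal(length(unique(km$labels[9:16])), 1)

  # S = 1: medoid is the cost-minimizing vector
  km1 <- kmedoids(X[1:8, ], 1, seed = 2)
  expect_equal(km1$cost, kmedoids_oracle(X[1:8, ], 1)$cost)

  # determinism per seed
  expect_equal(kmedoids(X, 2, seed = 9)$cost, kmedoids(X, 2, seed = 9)$cost)

  # duplicate-collapse leaves the solution intact
  Xd <- X[rep(1:16, each = 3), ]
  kmd <- kmedoids(Xd, 2, seed = 4, n_starts = 5)
  expect_equal(kmd$cost, 3 * oracle$cost, tolerance = 1e-9)
  expect_error(kmedoids(X, 17), "exceeds")
})

test_that("bins propagate from tags and precision scores match definitions", {
  path <- metajoint:::new_overlap_graph(3, c(1, 2), c(2, 3), rep(1, 3), "1")
  T <- greedy_mis(path)
  bins <- assign_bins(T, c(1, 2))
  expect_equal(bins$labels, c(1, 1, 2))  # b inherits tag a's label

  expect_equal(binning_precision(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(binning_precision(c(2, 2, 1, 1), c("x", "x", "y", "y")), 1)
  expect_equal(binning_precision(c(1, 1, 1, 1), c("x", "x", "y", "y")), 0.5)
  # more species than bins: unmatched species scores 0
  expect_equal(binning_precision(c(1, 1, 1, 1), c("x", "x", "y", "z")),
               1 / 3, tolerance = 1e-12)
})

test_that("sequence overlap edges contain positional edges on clean reads", {
  set.seed(18)
  genome <- random_genome(20000, 19)
  n <- 120
  starts <- sample(0:(20000 - 300), n)
  strands <- sample(c("+", "-"), n, TRUE)
  reads <- substring(genome, starts + 1, starts + 300)
  reads[strands == "-"] <- revcomp(reads[strands == "-"])
  Gs <- detect_overlaps_sequence(reads, min_overlap = 80)
  Gp <- detect_overlaps_positional(
    data.frame(sample = 1, genome = "g", start = starts, length = 300),
    min_overlap = 80)
  seq_edges <- paste(pmin(Gs$from, Gs$to), pmax(Gs$from, Gs$to))
  pos_edges <- paste(pmin(Gp$from, Gp$to), pmax(Gp$from, Gp$to))
  expect_true(all(pos_edges %in% seq_edges))
})

test_that("end-to-end binning recovers two species at high coverage", {
  # distinct abundance profiles and >= 20x coverage: near-perfect recovery
  props <- cbind(c(0.8, 0.3, 0.6, 0.2, 0.7), c(0.2, 0.7, 0.4, 0.8, 0.3))
  precisions <- vapply(1:3, function(s) {
    com <- make_test_community(n_species = 2, genome_len = 5e4,
                               reads_per_sample = 3000,
                               proportions = props, seed = 100 * s)
    G <- detect_overlaps_sequence(split(com$reads$seq, com$reads$sample),
                                  min_overlap = 50)
    bins <- multibin(G, S = 2, seed = s, n_starts = 3)
    binning_precision(bins$labels, com$reads$species)
  }, numeric(1))
  expect_true(all(precisions >= 0.99))
})

test_that("joint multi-sample binning beats per-sample binning when nearly balanced", {
  p_major <- c(0.57, 0.55, 0.70, 0.53, 0.56)
  com <- make_test_community(n_species = 2, genome_len = 5e4,
                             reads_per_sample = 3000,
                             proportions = cbind(p_major, 1 - p_major),
                             seed = 77)
  lay <- data.frame(sample = com$reads$sample, genome = com$reads$species,
                    start = com$reads$start, length = com$reads$length)
  G <- detect_overlaps_positional(lay, min_overlap = 100)
  joint <- multibin(G, S = 2, seed = 5, n_starts = 5)
  joint_prec <- binning_precision(joint$labels, com$reads$species)

  per_sample <- vapply(unique(com$reads$sample), function(sm) {
    sel <- lay$sample == sm
    Gs <- detect_overlaps_positional(lay[sel, ], min_overlap = 100)
    bins <- multibin(Gs, S = 2, seed = 5, n_starts = 5)
    binning_precision(bins$labels, com$reads$species[sel])
  }, numeric(1))
  expect_gt(joint_prec, mean(per_sample))
})

test_that("Hartigan curve has the documented shape and selects 3 clusters", {
  set.seed(23)
  X <- rbind(matrix(rpois(120 * 3, 5), 120, 3),
             matrix(rpois(120 * 3, 30), 120, 3),
             matrix(rpois(120 * 3, 80), 120, 3))
  sel <- select_num_bins(X, S_max = 6, seed = 2, n_starts = 5)
  expect_equal(sel$S, 3)
  expect_length(sel$H, 5)
  expect_length(sel$W, 6)
  expect_true(all(is.finite(sel$H)))
  # H follows its defining formula from the W curve
  S_grid <- 1:5
  expect_equal(sel$H, (sel$W[S_grid] / sel$W[S_grid + 1] - 1) *
                        (nrow(X) - S_grid - 1))
})
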