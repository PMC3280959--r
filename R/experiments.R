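#' @name experiments
#' @title Simulation experiments
#'
#' @description
#' Self-contained drivers for the package's evaluation experiments: k-mer
#' extraction strategy comparison under the two likelihood models, the
#' mixture model versus PCA, stratification-corrected association, joint
#' binning benchmarks, and the design-phase tradeoff between the number of
#' samples and per-sample depth. Each takes a seed and regenerates everything
#' it needs.
NULL

# k-mer class frequencies of each genome: the true F matrix for communities
genome_class_freqs <- function(genomes, k, index = NULL) {
  if (is.null(index)) index <- kmer_index(k)
  cm <- count_matrix(as.list(genomes), k = k, strategy = "overlapping",
                     index = index)
  cm$R / rowSums(cm$R)
}

#' Strategy comparison under the two likelihood models
#'
#' Simulates communities of synthetic genomes mixed in random proportions,
#' extracts k-mers under several strategies, fits the aggregate model to the
#' pooled counts and the refined model to the per-read bags, and scores the
#' permutation-matched sum of squared differences between the true and
#' estimated mixture-proportion matrix P.
#'
#' @param n_rep replicates.
#' @param n_samples samples (mixtures) per replicate.
#' @param n_species synthetic genomes per community (also the K fitted).
#' @param genome_len genome length in bases.
#' @param reads_per_sample,read_len sequencing depth and read length.
#' @param k word length.
#' @param restarts,max_iters,tol EM settings.
#' @param seed integer seed.
#' @return matrix of P-estimation errors, `n_rep` x 4, columns
#'   `aggregate_first`, `aggregate_overlapping`, `refined_nonoverlapping`,
#'   `refined_sparse9`.
#' @export
experiment_strategy_comparison <- function(n_rep = 20, n_samples = 10,
                                           n_species = 4, genome_len = 1e5,
                                           reads_per_sample = 1000,
                                           read_len = 100, k = 4,
                                           restarts = 3, max_iters = 300,
                                           tol = 1e-7, seed = 1) {
  idx <- kmer_index(k)
  combos <- c("aggregate_first", "aggregate_overlapping",
              "refined_nonoverlapping", "refined_sparse9")
  errs <- matrix(NA_real_, n_rep, length(combos),
                 dimnames = list(NULL, combos))
  for (rep in seq_len(n_rep)) {
    s <- seed + 1000L * rep
    # species differ in base composition, as real taxa do: without that, all
    # genomes share one k-mer profile and there is nothing to estimate
    comp <- random_base_compositions(n_species, seed = s + 99L)
    genomes <- vapply(seq_len(n_species),
                      function(g) random_genome(genome_len, s + g, comp[g, ]),
                      character(1))
    names(genomes) <- paste0("sp", seq_len(n_species))
    P_true <- random_stochastic_matrix(n_samples, n_species, s + 100L)
    com <- simulate_reads(genomes, P_true, reads_per_sample, read_len,
                          seed = s + 200L)
    sets <- split(com$reads$seq, com$reads$sample)
    fit_err <- function(model, strategy, sparse_n = 9L) {
      opts <- fit_options(K = n_species, restarts = restarts,
                          max_iters = max_iters, tol = tol, seed = s + 300L)
      fit <- if (model == "aggregate") {
        em_aggregate(count_matrix(sets, k, strategy, sparse_n, index = idx),
                     opts)
      } else {
        em_refined(read_kmer_bags(sets, k, strategy, sparse_n, index = idx),
                   opts)
      }
      estimation_error(fit$P, P_true[match(names(sets), rownames(P_true) %||%
                                             paste0("sample", seq_len(n_samples))),
                                     , drop = FALSE], margin = 2L)
    }
    errs[rep, "aggregate_first"] <- fit_err("aggregate", "first")
    errs[rep, "aggregate_overlapping"] <- fit_err("aggregate", "overlapping")
    errs[rep, "refined_nonoverlapping"] <- fit_err("refined", "nonoverlapping")
    errs[rep, "refined_sparse9"] <- fit_err("refined", "sparse", 9L)
  }
  errs
}

#' Mixture model versus PCA on simulated multinomial mixtures
#'
#' Draws P and F uniformly (row-normalized), samples counts at several
#' per-sample depths, and scores how well the fitted mixture proportions and
#' the leading principal components recover the true columns of P (mean
#' squared correlation, best component ordering).
#'
#' @param counts_levels per-sample count depths to test.
#' @param n_exp experiments per depth.
#' @param M,K,W problem dimensions.
#' @param restarts,seed EM restarts and seed.
#' @return array `length(counts_levels) x n_exp x 2` (methods `plsa`, `pca`).
#' @export
experiment_plsa_vs_pca <- function(counts_levels = c(100, 1000, 10000),
                                   n_exp = 20, M = 100, K = 3, W = 136,
                                   restarts = 5, seed = 1) {
  out <- array(NA_real_, c(length(counts_levels), n_exp, 2),
               dimnames = list(as.character(counts_levels), NULL,
                               c("plsa", "pca")))
  for (li in seq_along(counts_levels)) {
    for (e in seq_len(n_exp)) {
      s <- seed + 10000L * li + 10L * e
      P <- random_stochastic_matrix(M, K, s)
      F <- random_stochastic_matrix(K, W, s + 1L)
      R <- sample_counts(P, F, counts_levels[li], s + 2L)
      fit <- em_aggregate(R, fit_options(K = K, restarts = restarts,
                                         max_iters = 300, tol = 1e-7,
                                         seed = s + 3L))
      sc <- compare_to_pca(P, list(plsa = fit$P, pca = pca_components(R, K)))
      out[li, e, ] <- sc[c("plsa", "pca")]
    }
  }
  out
}

#' Stratified-cohort association experiment
#'
#' Builds a synthetic stratified cohort whose phenotype is a noisy linear
#' function of the true component proportions only, fits the mixture model to
#' the observed counts, and tests every k-mer class marginally and with the
#' estimated component proportions as covariates.
#'
#' @param M,K,W,counts_per_sample,noise_sd cohort parameters (see
#'   [make_stratified_cohort()]).
#' @param restarts,seed EM restarts and seed.
#' @return list with p-value vectors `marginal` and `corrected`, the cohort,
#'   and the fitted model.
#' @export
experiment_stratified_qq <- function(M = 100, K = 3, W = 136,
                                     counts_per_sample = 10000,
                                     noise_sd = 0.1, restarts = 5, seed = 1) {
  cohort <- make_stratified_cohort(M, K, W, counts_per_sample,
                                   link = "linear", noise_sd = noise_sd,
                                   seed = seed)
  fit <- em_aggregate(cohort$R, fit_options(K = K, restarts = restarts,
                                            max_iters = 300, tol = 1e-7,
                                            seed = seed + 1L))
  a <- cohort$a
  marginal <- vapply(seq_len(nrow(a)),
                     function(w) marginal_test(a[w, ], cohort$y)$p, numeric(1))
  corrected <- vapply(seq_len(nrow(a)),
                      function(w) corrected_test(a[w, ], cohort$y, fit$P)$p,
                      numeric(1))
  list(marginal = marginal, corrected = corrected, cohort = cohort, fit = fit)
}

#' Joint multi-sample binning benchmark
#'
#' Generates a community of synthetic genomes shared by all samples in
#' different proportions, builds the overlap graph (from sequences, or from
#' positions in positional mode), and runs the binning pipeline once per
#' random clustering start, scoring species-averaged precision against the
#' truth labels.
#'
#' @param n_species,n_samples community shape.
#' @param genome_len genome length in bases.
#' @param reads_per_sample,read_len depth and read length.
#' @param proportions optional samples x species matrix; default is the
#'   incremental uniform scheme.
#' @param sub_rate substitution error rate applied to the reads.
#' @param mode `"sequence"` or `"positional"`.
#' @param min_overlap overlap threshold (sequence: >= bases; positional:
#'   strictly more than).
#' @param max_mismatch_rate mismatch tolerance for the sequence overlap.
#' @param S number of bins (default `n_species`).
#' @param n_starts clustering starts, each scored separately.
#' @param metric k-medoids distance.
#' @param seed integer seed.
#' @return list: `precisions` (per start), `mean`, `best`, `n_tags`,
#'   `n_edges`, and the `community`.
#' @export
experiment_binning <- function(n_species = 5, n_samples = 5, genome_len = 1e6,
                               reads_per_sample = 20000, read_len = 400,
                               proportions = NULL, sub_rate = 0,
                               mode = c("sequence", "positional"),
                               min_overlap = if (mode[1] == "sequence") 50 else 100,
                               max_mismatch_rate = 0, S = n_species,
                               n_starts = 10, metric = "l1", seed = 1) {
  mode <- match.arg(mode)
  if (is.null(proportions)) {
    proportions <- if (n_species == 1) matrix(1, n_samples, 1) else
      incremental_proportions(max(n_species, 2), n_samples,
                              seed = seed)[[n_species]]
  }
  genomes <- if (mode == "sequence") {
    g <- vapply(seq_len(n_species),
                function(s) random_genome(genome_len, seed + 7000L + s),
                character(1))
    names(g) <- paste0("sp", seq_len(n_species)); g
  } else {
    stats::setNames(rep(as.integer(genome_len), n_species),
                    paste0("sp", seq_len(n_species)))
  }
  com <- simulate_reads(genomes, proportions, reads_per_sample, read_len,
                        seed = seed + 8000L)
  if (mode == "sequence") {
    reads <- com$reads$seq
    if (sub_rate > 0)
      reads <- add_substitutions(reads, sub_rate, seed = seed + 9000L)
    G <- detect_overlaps_sequence(reads,
                                  sample = com$reads$sample,
                                  min_overlap = min_overlap,
                                  max_mismatch_rate = max_mismatch_rate)
  } else {
    G <- detect_overlaps_positional(
      data.frame(sample = com$reads$sample, genome = com$reads$species,
                 start = com$reads$start, length = com$reads$length),
      min_overlap = min_overlap)
  }
  T <- greedy_mis(G)
  V <- coverage_vectors(T, G)
  precisions <- vapply(seq_len(n_starts), function(st) {
    km <- kmedoids(V, S, seed = seed + 100L + st, n_starts = 1L,
                   metric = metric)
    binning_precision(assign_bins(T, km$labels), com$reads$species)
  }, numeric(1))
  list(precisions = precisions, mean = mean(precisions),
       best = max(precisions), n_tags = length(T$tags),
       n_edges = length(G$from), community = com, graph = G, tags = T,
       coverage = V)
}

#' Design-phase tradeoff for component estimation
#'
#' Splits a fixed total number of multinomial counts among different numbers
#' of samples: a base population of `base_samples` samples with
#' `total_counts / base_samples` counts each is drawn once per trial, and
#' coarser datasets are formed by merging adjacent samples (summing their
#' counts and averaging their true mixture rows). The model is refit at every
#' size and scored by the permutation-matched sum of squared differences
#' between the estimated and true F.
#'
#' @param n_trials trials to average over.
#' @param total_counts total multinomial counts per trial.
#' @param base_samples size of the finest split.
#' @param sizes sample counts to evaluate (divisors of `base_samples`).
#' @param K,W model dimensions.
#' @param restarts,max_iters,tol EM settings.
#' @param seed integer seed.
#' @return list: `errors` (trials x sizes matrix of F errors), `mean_error`,
#'   `best_size` (argmin of the mean error).
#' @export
experiment_design_components <- function(n_trials = 20, total_counts = 1e6,
                                         base_samples = 1000,
                                         sizes = c(1000, 500, 200, 100, 50,
                                                   20, 10, 5, 2, 1),
                                         K = 3, W = 136, restarts = 5,
                                         max_iters = 300, tol = 1e-7,
                                         seed = 1) {
  stopifnot(all(base_samples %% sizes == 0))
  per <- total_counts / base_samples
  errors <- matrix(NA_real_, n_trials, length(sizes),
                   dimnames = list(NULL, as.character(sizes)))
  for (tr in seq_len(n_trials)) {
    s <- seed + 1000L * tr
    P <- random_stochastic_matrix(base_samples, K, s)
    F <- random_stochastic_matrix(K, W, s + 1L)
    R_base <- sample_counts(P, F, per, s + 2L)
    for (si in seq_along(sizes)) {
      m <- sizes[si]
      grp <- rep(seq_len(m), each = base_samples / m)
      R <- rowsum(R_base, grp)
      fit <- em_aggregate(R, fit_options(K = K, restarts = restarts,
                                         max_iters = max_iters, tol = tol,
                                         seed = s + 10L * si))
      errors[tr, si] <- estimation_error(fit$F, F, margin = 1L)
    }
  }
  mean_error <- colMeans(errors)
  list(errors = errors, mean_error = mean_error,
       best_size = sizes[which.min(mean_error)])
}

#' Design-phase tradeoff for binning
#'
#' Allocates a fixed total number of reads to an increasing number of samples
#' (species proportions drawn uniformly per sample), bins the pooled reads in
#' positional-overlap mode, and reports the mean per-sample species-averaged
#' precision at every split.
#'
#' @param n_samples_grid sample counts to evaluate.
#' @param total_reads total reads, shared equally by the samples.
#' @param n_species,genome_len,read_len community shape.
#' @param min_overlap positional overlap threshold (strictly more than).
#' @param n_starts clustering starts (best-cost start is scored).
#' @param seed integer seed.
#' @return data.frame with `n_samples` and mean per-sample `precision`.
#' @export
experiment_design_binning <- function(n_samples_grid = c(1, 2, 4, 8, 16, 32),
                                      total_reads = 65536, n_species = 15,
                                      genome_len = 1e5, read_len = 400,
                                      min_overlap = 100, n_starts = 5,
                                      seed = 1) {
  genomes <- stats::setNames(rep(as.integer(genome_len), n_species),
                             paste0("sp", seq_len(n_species)))
  precision <- vapply(seq_along(n_samples_grid), function(gi) {
    m <- n_samples_grid[gi]
    s <- seed + 500L * gi
    props <- random_stochastic_matrix(m, n_species, s)
    com <- simulate_reads(genomes, props, round(total_reads / m), read_len,
                          seed = s + 1L)
    G <- detect_overlaps_positional(
      data.frame(sample = com$reads$sample, genome = com$reads$species,
                 start = com$reads$start, length = com$reads$length),
      min_overlap = min_overlap)
    bins <- multibin(G, S = n_species, seed = s + 2L, n_starts = n_starts)
    samples <- unique(com$reads$sample)
    mean(vapply(samples, function(sm) {
      sel <- com$reads$sample == sm
      binning_precision(bins$labels[sel], com$reads$species[sel])
    }, numeric(1)))
  }, numeric(1))
  data.frame(n_samples = n_samples_grid, precision = precision)
}
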