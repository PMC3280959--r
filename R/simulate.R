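#' @name simulate
#' @title Synthetic data generators
#'
#' @description
#' Generators for the two data-generating processes the toolkit is evaluated
#' on: (i) mixture-of-multinomials counts drawn from uniform-random
#' row-stochastic P and F matrices, and (ii) multi-sample shotgun communities
#' in which every sample contains the same synthetic species in different,
#' randomly drawn proportions, with per-read truth labels and start
#' positions. All generators are fully reproducible from their parameters and
#' seed.
NULL

#' Random row-stochastic matrix
#'
#' Entries i.i.d. uniform(0,1), each row normalized to sum to one.
#'
#' @param rows,cols dimensions.
#' @param seed integer seed.
#' @return rows x cols row-stochastic matrix.
#' @export
random_stochastic_matrix <- function(rows, cols, seed = NULL) {
  stopifnot(rows >= 1, cols >= 1)
  with_seed(seed, row_normalize(matrix(stats::runif(rows * cols), rows, cols)))
}

#' Multinomial counts from a mixture model
#'
#' Draws row `i` of the counts matrix as
#' `Multinomial(counts_per_sample, (P %*% F)[i, ])`.
#'
#' @param P samples x components row-stochastic matrix.
#' @param F components x classes row-stochastic matrix.
#' @param counts_per_sample counts drawn per sample (scalar or per-sample
#'   vector).
#' @param seed integer seed.
#' @return samples x classes integer matrix; row sums equal
#'   `counts_per_sample` exactly.
#' @export
sample_counts <- function(P, F, counts_per_sample, seed = NULL) {
  A <- P %*% F
  M <- nrow(A)
  nn <- rep_len(counts_per_sample, M)
  stopifnot(all(nn >= 1))
  with_seed(seed, {
    R <- t(vapply(seq_len(M),
                  function(i) stats::rmultinom(1, nn[i], A[i, ])[, 1],
                  integer(ncol(A))))
    dimnames(R) <- list(rownames(P), colnames(F))
    R
  })
}

#' Nested per-sample species proportions
#'
#' Generates, for every species count S = 1..S_max, a samples x S
#' row-stochastic proportions matrix, where each sample's S-species vector
#' extends its (S-1)-species vector by one fresh uniform(0,1) draw followed
#' by renormalization. Ratios between pre-existing species are preserved
#' across S, so the datasets of increasing complexity are nested.
#'
#' @param S_max largest species count (>= 2).
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return named list `"1"`..`"S_max"` of proportion matrices.
#' @export
incremental_proportions <- function(S_max, n_samples, seed = NULL) {
  stopifnot(S_max >= 2, n_samples >= 1)
  with_seed(seed, {
    out <- vector("list", S_max)
    names(out) <- as.character(seq_len(S_max))
    prev <- matrix(1, n_samples, 1)
    out[[1]] <- prev
    for (S in 2:S_max) {
      u <- stats::runif(n_samples)
      raw <- cbind(prev, u)          # append the fresh draw, renormalize
      prev <- raw / (1 + u)
      out[[S]] <- prev
    }
    out
  })
}

#' Random genome sequence
#'
#' Linear genome with i.i.d. bases over A/C/G/T. The default composition is
#' uniform; supplying `base_probs` biases the composition, which is how
#' synthetic species are given the distinct k-mer signatures real taxa carry
#' (bacterial GC content alone spans roughly 25--75%).
#'
#' @param length genome length in bases.
#' @param seed integer seed.
#' @param base_probs length-4 probability vector for A, C, G, T.
#' @return a single DNA string.
#' @export
random_genome <- function(length, seed = NULL,
                          base_probs = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(length(base_probs) == 4, all(base_probs >= 0))
  with_seed(seed,
            paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                         prob = base_probs),
                  collapse = ""))
}

#' Random base compositions for a set of species
#'
#' Draws one A/C/G/T probability vector per species from a symmetric
#' Dirichlet; moderate concentration gives the compositional spread between
#' taxa that makes k-mer profiles informative.
#'
#' @param n_species number of species.
#' @param concentration symmetric Dirichlet concentration (default 10).
#' @param seed integer seed.
#' @return `n_species` x 4 matrix of base probabilities.
#' @export
random_base_compositions <- function(n_species, concentration = 10,
                                     seed = NULL) {
  with_seed(seed, {
    g <- matrix(stats::rgamma(n_species * 4, shape = concentration),
                n_species, 4)
    g / rowSums(g)
  })
}

#' Simulate a multi-sample shotgun community
#'
#' Draws, for every read of every sample, a species according to the sample's
#' proportions row, a start position uniform on `[0, L - read_len]` along that
#' species' genome, and a strand uniform on +/-; the read sequence is the
#' (reverse-complemented) substring. In positional mode (`genomes` given as
#' integer lengths) no sequences are produced, only layouts -- the design-phase
#' shortcut where overlap is later decided from coordinates alone.
#'
#' @param genomes named character vector of genome sequences, or a named
#'   integer vector of genome lengths (positional mode).
#' @param proportions samples x species row-stochastic matrix; column order
#'   follows `genomes`.
#' @param reads_per_sample reads drawn per sample.
#' @param read_len read length in bases.
#' @param seed integer seed.
#' @return `mj_community`: list with `genomes`, `proportions`, and `reads`, a
#'   data.frame with columns `read_id`, `sample`, `species`, `start`
#'   (0-based), `strand`, `length`, and `seq` (NA in positional mode).
#' @export
simulate_reads <- function(genomes, proportions, reads_per_sample, read_len,
                           seed = NULL) {
  positional <- is.numeric(genomes)
  glen <- if (positional) as.integer(genomes) else nchar(genomes)
  if (any(glen < read_len)) stop("genome shorter than the read length")
  species_ids <- names(genomes) %||% paste0("species", seq_along(genomes))
  P <- as.matrix(proportions)
  stopifnot(ncol(P) == length(genomes))
  M <- nrow(P)
  sample_ids <- rownames(P) %||% paste0("sample", seq_len(M))
  with_seed(seed, {
    per <- rep_len(reads_per_sample, M)
    rows <- vector("list", M)
    for (i in seq_len(M)) {
      n <- per[i]
      sp <- sample.int(length(genomes), n, replace = TRUE, prob = P[i, ])
      start <- floor(stats::runif(n) * (glen[sp] - read_len + 1L))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      rows[[i]] <- data.frame(
        read_id = sprintf("%s_r%06d", sample_ids[i], seq_len(n)),
        sample = sample_ids[i],
        species = species_ids[sp],
        start = as.integer(start),
        strand = strand,
        length = read_len,
        stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, rows)
    if (positional) {
      reads$seq <- NA_character_
    } else {
      seqs <- character(nrow(reads))
      for (s in seq_along(genomes)) {
        sel <- reads$species == species_ids[s]
        if (!any(sel)) next
        seqs[sel] <- substring(genomes[[s]], reads$start[sel] + 1L,
                               reads$start[sel] + read_len)
      }
      minus <- reads$strand == "-"
      if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
      reads$seq <- seqs
    }
    structure(list(genomes = genomes, proportions = P, reads = reads,
                   read_len = read_len),
              class = "mj_community")
  })
}

#' Inject base substitutions
#'
#' Every base is independently substituted with probability `rate` by a base
#' chosen uniformly among the three alternatives (never the original).
#'
#' @param reads character vector of reads.
#' @param rate substitution probability per base, in `[0, 1)`.
#' @param seed integer seed.
#' @return character vector of mutated reads.
#' @export
add_substitutions <- function(reads, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || length(reads) == 0) return(reads)
  with_seed(seed, {
    lens <- nchar(reads)
    big <- charToRaw(paste(reads, collapse = ""))
    hits <- which(stats::runif(length(big)) < rate)
    if (length(hits)) {
      bases <- charToRaw("ACGT")
      orig <- big[hits]
      # draw one of the 3 other bases: offset 1..3 from the original's index
      oidx <- match(orig, bases)            # NA for non-ACGT: leave untouched
      ok <- !is.na(oidx)
      off <- sample.int(3L, sum(ok), replace = TRUE)
      big[hits[ok]] <- bases[((oidx[ok] - 1L + off) %% 4L) + 1L]
    }
    all <- rawToChar(big)
    ends <- cumsum(lens)
    substring(all, c(1L, utils::head(ends, -1L) + 1L), ends)
  })
}

#' Synthetic stratified cohort
#'
#' Fixture for stratification-correction experiments: draws uniform-random
#' row-stochastic P (samples x K) and F (K x W), samples multinomial counts
#' per sample, and generates a phenotype from the true component proportions
#' -- `linear`: `y = P %*% beta + N(0, noise_sd)`; `logistic`: Bernoulli with
#' logit `P %*% beta`. The phenotype depends on the data only through P, so
#' marginal k-mer tests are confounded while component-corrected tests are
#' calibrated.
#'
#' @param M,K,W samples, components, classes.
#' @param counts_per_sample multinomial counts per sample.
#' @param link `"linear"` or `"logistic"`.
#' @param beta length-K effect vector of the components on the phenotype.
#' @param noise_sd residual standard deviation (linear link).
#' @param seed integer seed.
#' @return list of class `mj_cohort`: `P`, `F`, `R` (counts), `a` (relative
#'   abundances), `y` (phenotype).
#' @export
make_stratified_cohort <- function(M, K, W, counts_per_sample = 10000,
                                   link = c("linear", "logistic"),
                                   beta = NULL, noise_sd = 0.1, seed = NULL) {
  link <- match.arg(link)
  if (is.null(beta)) beta <- seq_len(K)  # distinct component effects
  stopifnot(length(beta) == K)
  with_seed(seed, {
    P <- random_stochastic_matrix(M, K)
    F <- random_stochastic_matrix(K, W)
    R <- sample_counts(P, F, counts_per_sample)
    eta <- drop(P %*% beta)
    y <- switch(link,
      linear = eta + stats::rnorm(M, 0, noise_sd),
      logistic = stats::rbinom(M, 1, stats::plogis(drop(scale(eta)))))
    structure(list(P = P, F = F, R = R, a = t(R / rowSums(R)), y = y,
                   link = link, beta = beta),
              class = "mj_cohort")
  })
}
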