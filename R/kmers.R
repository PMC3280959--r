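#' Canonical k-mer index
#'
#' Enumerates all k-mers over \{A,C,G,T\} and collapses each with its reverse
#' complement into a single canonical class, represented by the
#' lexicographically smaller member of the pair. Strands are indistinguishable
#' in shotgun sequencing data, so complementary k-mer counts are always summed.
#' For `k = 4` there are 136 classes (120 complementary pairs plus 16
#' reverse-complement palindromes).
#'
#' @param k word length in bases (1--10).
#' @return An object of class `mj_kmer_index`: a list with elements `k`,
#'   `classes` (ordered character vector of class representatives), `kmers`
#'   (all `4^k` words) and `class_of` (integer class index per word).
#' @examples
#' idx <- kmer_index(4)
#' length(idx$classes)  # 136
#' @export
kmer_index <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k <= 10)
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(bases), k),
                                 list(KEEP.OUT.ATTRS = FALSE,
                                      stringsAsFactors = FALSE)))
  # column 1 varies fastest; reverse so words come out in lexicographic order
  kmers <- do.call(paste0, rev(grid))
  kmers <- sort(kmers)
  rc <- revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  classes <- sort(unique(canon))
  structure(list(k = k, classes = classes, kmers = kmers,
                 class_of = match(canon, classes)),
            class = "mj_kmer_index")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T; other letters map to N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonicalize k-mers
#'
#' Maps each k-mer to the lexicographically smaller of the word and its
#' reverse complement. Words containing characters outside A/C/G/T are
#' rejected and returned as `NA` (callers skip them).
#'
#' @param kmer character vector of equal-length DNA words.
#' @return character vector of canonical class representatives (`NA` for
#'   rejected words). Idempotent.
#' @examples
#' canonicalize(c("TTTT", "ACGT"))  # "AAAA" "ACGT"
#' @export
canonicalize <- function(kmer) {
  bad <- grepl("[^ACGT]", kmer)
  out <- rep(NA_character_, length(kmer))
  if (any(!bad)) {
    x <- kmer[!bad]
    rc <- revcomp(x)
    out[!bad] <- ifelse(x <= rc, x, rc)
  }
  out
}

# 0-based k-mer start positions along a read of length L under a strategy.
kmer_positions <- function(L, k, strategy, sparse_n = 9L) {
  if (L < k) return(integer(0))
  last <- L - k
  switch(strategy,
    first = 0L,
    overlapping = 0:last,
    nonoverlapping = seq.int(0L, last, by = k),
    sparse = {
      n <- min(sparse_n, last + 1L)
      unique(as.integer(round(seq(0, last, length.out = n))))
    },
    stop("unknown strategy: ", strategy))
}

# Resolve a strategy spec: "sparse:9" -> list(strategy = "sparse", n = 9).
parse_strategy <- function(strategy, sparse_n = 9L) {
  if (grepl("^sparse:", strategy)) {
    sparse_n <- as.integer(sub("^sparse:", "", strategy))
    strategy <- "sparse"
  }
  strategy <- match.arg(strategy,
                        c("first", "sparse", "nonoverlapping", "overlapping"))
  list(strategy = strategy, sparse_n = as.integer(sparse_n))
}

# Internal workhorse: (read index, class index) pairs for a vector of reads.
# k-mers containing non-ACGT characters do not match any indexed word and are
# silently dropped.
extract_pairs <- function(reads, index, strategy, sparse_n = 9L) {
  k <- index$k
  L <- nchar(reads)
  ri <- list(); ci <- list(); nb <- 0L
  for (len in unique(L[L >= k])) {
    rid <- which(L == len)
    pos <- kmer_positions(len, k, strategy, sparse_n)
    for (p in pos) {
      words <- substr(reads[rid], p + 1L, p + k)
      idx <- index$class_of[match(words, index$kmers)]
      ok <- !is.na(idx)
      nb <- nb + 1L
      ri[[nb]] <- rid[ok]
      ci[[nb]] <- idx[ok]
    }
  }
  list(read = unlist(ri) %||% integer(0), class = unlist(ci) %||% integer(0))
}

#' Extract canonical k-mers from a read
#'
#' Four extraction strategies are supported for a read of length `L`:
#' `"first"` takes the single k-mer at position 0; `"sparse"` takes
#' `sparse_n` k-mers at evenly spaced start positions spanning the read
#' (including both ends); `"nonoverlapping"` takes k-mers at positions 0, k,
#' 2k, ...; `"overlapping"` takes all `L - k + 1` positions. k-mers containing
#' non-ACGT bases are dropped.
#'
#' @param read a single DNA string.
#' @param k word length.
#' @param strategy one of `"first"`, `"sparse"` (or `"sparse:n"`),
#'   `"nonoverlapping"`, `"overlapping"`.
#' @param sparse_n number of k-mers for the sparse strategy (default 9).
#' @return character vector (multiset) of canonical k-mer classes; empty when
#'   the read is shorter than `k`.
#' @export
extract_kmers <- function(read, k, strategy = "first", sparse_n = 9L) {
  stopifnot(length(read) == 1L)
  st <- parse_strategy(strategy, sparse_n)
  idx <- kmer_index(k)
  pr <- extract_pairs(read, idx, st$strategy, st$sparse_n)
  idx$classes[pr$class]
}

#' Per-sample canonical k-mer counts matrix
#'
#' Counts canonical k-mer classes extracted from each sample's reads under a
#' common extraction strategy, producing the samples x classes counts matrix
#' that the mixture model and the association tests consume.
#'
#' @param read_sets named list of character vectors, one vector of reads per
#'   sample.
#' @param k word length.
#' @inheritParams extract_kmers
#' @param index optionally, a prebuilt [kmer_index()] for `k`.
#' @return An object of class `mj_counts`: list with `R` (integer matrix,
#'   samples x classes, dimnames set), `samples`, `totals` (row sums), `k` and
#'   `strategy`.
#' @export
count_matrix <- function(read_sets, k, strategy = "first", sparse_n = 9L,
                         index = NULL) {
  stopifnot(length(read_sets) >= 1L)
  st <- parse_strategy(strategy, sparse_n)
  if (is.null(index)) index <- kmer_index(k)
  stopifnot(index$k == k)
  samples <- names(read_sets) %||% paste0("sample", seq_along(read_sets))
  W <- length(index$classes)
  R <- matrix(0L, length(read_sets), W,
              dimnames = list(samples, index$classes))
  for (i in seq_along(read_sets)) {
    if (length(read_sets[[i]]) == 0L) {
      warning("sample '", samples[i], "' has no reads; zero row")
      next
    }
    pr <- extract_pairs(read_sets[[i]], index, st$strategy, st$sparse_n)
    R[i, ] <- tabulate(pr$class, nbins = W)
  }
  structure(list(R = R, samples = samples, totals = rowSums(R), k = k,
                 strategy = st$strategy),
            class = "mj_counts")
}

#' Per-read k-mer bags
#'
#' Builds, for every read in every sample, the multiset of canonical k-mer
#' classes extracted under a strategy. Bags are stored as one sparse
#' reads x classes count matrix plus a sample index, the input consumed by the
#' per-read (refined) mixture model.
#'
#' @inheritParams count_matrix
#' @return An object of class `mj_bags`: list with `C` (sparse dgCMatrix,
#'   reads x classes), `sample` (integer sample index per read), `samples`,
#'   `classes`, `k`, `strategy`.
#' @export
read_kmer_bags <- function(read_sets, k, strategy = "sparse", sparse_n = 9L,
                           index = NULL) {
  st <- parse_strategy(strategy, sparse_n)
  if (is.null(index)) index <- kmer_index(k)
  samples <- names(read_sets) %||% paste0("sample", seq_along(read_sets))
  W <- length(index$classes)
  ri <- list(); ci <- list(); si <- list()
  offset <- 0L
  for (i in seq_along(read_sets)) {
    reads <- read_sets[[i]]
    pr <- extract_pairs(reads, index, st$strategy, st$sparse_n)
    ri[[i]] <- pr$read + offset
    ci[[i]] <- pr$class
    si[[i]] <- rep.int(i, length(reads))
    offset <- offset + length(reads)
  }
  C <- Matrix::sparseMatrix(i = unlist(ri), j = unlist(ci), x = 1,
                            dims = c(offset, W),
                            dimnames = list(NULL, index$classes))
  sample <- unlist(si)
  nk <- Matrix::rowSums(C)
  if (any(nk == 0))
    warning(sum(nk == 0), " read(s) yielded no k-mers and carry no evidence")
  structure(list(C = C, sample = sample, samples = samples,
                 classes = index$classes, k = k, strategy = st$strategy),
            class = "mj_bags")
}

#' Relative k-mer abundances
#'
#' Normalizes a counts matrix into per-sample relative abundances
#' `a[w, i] = R[i, w] / totals[i]`; columns (samples) sum to one.
#'
#' @param counts an `mj_counts` object or a plain samples x classes matrix.
#' @return numeric matrix, classes x samples, columns summing to 1.
#' @export
relative_abundance <- function(counts) {
  R <- if (inherits(counts, "mj_counts")) counts$R else as.matrix(counts)
  tot <- rowSums(R)
  if (any(tot <= 0)) {
    bad <- rownames(R)[tot <= 0] %||% which(tot <= 0)
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  t(R / tot)
}

# Coerce to a plain counts matrix (samples x classes).
as_counts_matrix <- function(counts) {
  if (inherits(counts, "mj_counts")) counts$R else as.matrix(counts)
}
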