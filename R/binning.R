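#' @name multibin
#' @title MultiBin: coverage-based read binning across multiple samples
#'
#' @description
#' MultiBin pools the reads of all samples, connects pairs of reads with a
#' substantial sequence overlap into a graph, greedily extracts a maximal
#' independent set of *tag* reads, summarizes each tag by its per-sample
#' coverage vector (how many reads of each sample overlap it), clusters the
#' tag vectors by k-medoids, and propagates each tag's bin to the reads
#' affiliated with it. Tags of one species share an expected coverage vector
#' determined by the species' abundance profile across samples, which is what
#' makes the joint multi-sample clustering informative even when abundances
#' within any single sample are nearly balanced.
NULL

new_overlap_graph <- function(n, from, to, sample, sample_ids) {
  structure(list(n = n, from = as.integer(from), to = as.integer(to),
                 sample = as.integer(sample), sample_ids = sample_ids),
            class = "mj_overlap_graph")
}

#' Sequence-overlap graph of pooled reads
#'
#' Connects two reads when some suffix-prefix arrangement of the pair (either
#' read first, either strand) aligns over at least `min_overlap` bases with a
#' mismatch fraction at most `max_mismatch_rate` (0 demands an exact match).
#' Detection uses exact-seed indexing of read end-words followed by full
#' verification of every candidate, and is deterministic.
#'
#' @param reads character vector of pooled reads (A/C/G/T; N never matches),
#'   or a named list of per-sample read vectors.
#' @param sample integer/factor sample of origin per read (ignored when
#'   `reads` is a per-sample list).
#' @param min_overlap minimum overlap length in bases (default 50).
#' @param max_mismatch_rate maximum fraction of mismatches tolerated inside
#'   the overlap (default 0 = exact; use ~0.05 for error-tolerant mode).
#' @return `mj_overlap_graph`: vertex count `n`, symmetric edge list
#'   `from`/`to` (1-based, no self-edges), `sample` index per read,
#'   `sample_ids`.
#' @export
detect_overlaps_sequence <- function(reads, sample = NULL, min_overlap = 50L,
                                     max_mismatch_rate = 0) {
  if (is.list(reads)) {
    sample_ids <- names(reads) %||% paste0("sample", seq_along(reads))
    sample <- rep(seq_along(reads), lengths(reads))
    reads <- unlist(reads, use.names = FALSE)
  } else {
    if (is.null(sample)) sample <- rep(1L, length(reads))
    sample <- as.integer(as.factor(sample))
    sample_ids <- as.character(sort(unique(sample)))
  }
  e <- overlap_edges_seq_cpp(reads, as.integer(min_overlap),
                             as.numeric(max_mismatch_rate))
  new_overlap_graph(length(reads), e$from, e$to, sample, sample_ids)
}

#' Positional overlap graph from read layouts
#'
#' Design-phase variant that skips sequences entirely: reads are given as
#' (genome, start, length) layouts and two reads are connected when they lie
#' on the same genome and physically overlap by strictly more than
#' `min_overlap` bases. Computed by a per-genome sorted sweep.
#'
#' @param layouts data.frame with columns `sample`, `genome`, `start`
#'   (0-based), `length`.
#' @param min_overlap overlap must exceed this many bases (default 100).
#' @return `mj_overlap_graph`.
#' @export
detect_overlaps_positional <- function(layouts, min_overlap = 100L) {
  stopifnot(all(c("sample", "genome", "start", "length") %in% names(layouts)),
            all(layouts$start >= 0))
  g <- as.integer(as.factor(layouts$genome))
  e <- overlap_edges_pos_cpp(g, as.integer(layouts$start),
                             as.integer(layouts$length),
                             as.integer(min_overlap))
  sample <- as.integer(as.factor(layouts$sample))
  new_overlap_graph(nrow(layouts), e$from, e$to, sample,
                    levels(as.factor(layouts$sample)))
}

#' Greedy maximal independent set of tag reads
#'
#' Scans the vertices in a deterministic order, adding a read to the tag set
#' whenever none of its neighbours is already tagged; the result is a maximal
#' independent set. Every non-tag read is then affiliated with its
#' earliest-scanned tagged neighbour (tags affiliate with themselves).
#'
#' @param G `mj_overlap_graph`.
#' @param order optional scan order (permutation of vertex indices); default
#'   is input pool order.
#' @return `mj_tags`: integer `tags` (read indices), `affiliation` (owning
#'   tag read per read), and the scan `order`.
#' @export
greedy_mis <- function(G, order = NULL) {
  stopifnot(inherits(G, "mj_overlap_graph"))
  if (is.null(order)) order <- seq_len(G$n)
  res <- greedy_mis_cpp(G$n, G$from, G$to, as.integer(order))
  structure(list(tags = which(res$is_tag), affiliation = res$affiliation,
                 order = order),
            class = "mj_tags")
}

#' Per-tag coverage vectors
#'
#' For each tag t, `v_t[i]` counts the reads of sample i that substantially
#' overlap t (its graph neighbours), plus one for the tag itself in its own
#' sample, so that isolated tags still carry their sample of origin.
#'
#' @param T `mj_tags` from [greedy_mis()].
#' @param G the `mj_overlap_graph` the tags came from.
#' @return integer matrix, tags x samples; row order follows `T$tags`.
#' @export
coverage_vectors <- function(T, G) {
  stopifnot(inherits(T, "mj_tags"), inherits(G, "mj_overlap_graph"))
  cov <- coverage_cpp(G$n, G$from, G$to, T$tags, G$sample,
                      length(G$sample_ids))
  colnames(cov) <- G$sample_ids
  cov
}

#' k-medoids clustering by local search
#'
#' Starting from a random choice of S medoids, assigns every vector to its
#' nearest medoid and repeatedly applies the best cost-improving swap of a
#' medoid with a non-medoid until no swap improves the total within-cluster
#' distance; the best of `n_starts` random starts is returned. The default
#' distance is L1 on the raw coverage vectors; `"norml1"` normalizes each
#' vector to sum to one first.
#'
#' @param vectors numeric matrix (points x dimensions).
#' @param S number of clusters (1 <= S <= number of points).
#' @param seed integer seed for the random starts.
#' @param n_starts number of random starts (default 10).
#' @param metric `"l1"` (default), `"l2"`, or `"norml1"`.
#' @param max_iter cap on accepted swaps per start (default 100).
#' @return list: `medoids` (row indices), `labels` (cluster per point),
#'   `cost` (total distance to medoids).
#' @export
kmedoids <- function(vectors, S, seed = NULL, n_starts = 10L,
                     metric = c("l1", "l2", "norml1"), max_iter = 100L) {
  metric <- match.arg(metric)
  X <- as.matrix(vectors)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (S > n) stop("S exceeds the number of vectors")
  if (metric == "norml1") {
    s <- rowSums(abs(X))
    X <- X / ifelse(s > 0, s, 1)
  }
  # identical vectors are interchangeable: collapse them to weighted points
  # (clustering is unchanged; n shrinks substantially for integer counts)
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  uidx <- which(!duplicated(key))
  group <- match(key, key[uidx])
  Xu <- X[uidx, , drop = FALSE]
  wu <- as.numeric(tabulate(group, nbins = length(uidx)))
  nu <- nrow(Xu)
  if (S >= nu) {
    # every distinct vector can be its own medoid: zero-cost solution
    return(list(medoids = uidx[seq_len(min(S, nu))], labels = group,
                cost = 0))
  }
  starts <- with_seed(seed, t(vapply(seq_len(n_starts),
                                     function(b) sample.int(nu, S),
                                     integer(S))))
  if (S == 1L) starts <- matrix(starts, ncol = 1L)
  res <- kmedoids_cpp(Xu, wu, starts, metric = if (metric == "l2") 1L else 0L,
                      max_iter = as.integer(max_iter))
  list(medoids = uidx[res$medoids], labels = res$labels[group],
       cost = res$cost)
}

#' Propagate tag labels to all reads
#'
#' Every read inherits the bin of the tag it is affiliated with; tags keep
#' their own label.
#'
#' @param T `mj_tags`.
#' @param tag_labels integer cluster labels, one per tag (aligned with
#'   `T$tags`).
#' @return `mj_binning`: `labels` (bin per read), `S` (number of bins).
#' @export
assign_bins <- function(T, tag_labels) {
  stopifnot(inherits(T, "mj_tags"), length(tag_labels) == length(T$tags))
  if (any(T$affiliation == 0))
    stop("unaffiliated non-tag read: tag set is not maximal")
  label_of_read <- integer(max(T$affiliation))
  label_of_read[T$tags] <- as.integer(tag_labels)
  structure(list(labels = label_of_read[T$affiliation],
                 S = length(unique(tag_labels))),
            class = "mj_binning")
}

#' Species-averaged binning precision
#'
#' Chooses the bin-to-species assignment (optimal bipartite matching on the
#' correct-read count matrix) that maximizes the mean over species of the
#' fraction of each species' reads placed in its matched bin. Invariant under
#' bin relabeling; species left unmatched (more species than bins) score 0.
#'
#' @param bins `mj_binning` or an integer label vector per read.
#' @param truth species of origin per read (factor/character/integer).
#' @return scalar precision in `[0, 1]`.
#' @export
binning_precision <- function(bins, truth) {
  labels <- if (inherits(bins, "mj_binning")) bins$labels else bins
  stopifnot(length(labels) == length(truth))
  truth <- as.factor(truth)
  tab <- table(factor(labels), truth)                # bins x species counts
  frac <- sweep(as.matrix(tab), 2L, colSums(tab), "/")  # per-species recall
  n <- max(dim(frac))
  score <- matrix(0, n, n)
  score[seq_len(nrow(frac)), seq_len(ncol(frac))] <- frac
  match_col <- hungarian_cpp(-score)                 # maximize total recall
  # mean over true species of the recall in each species' matched bin
  # (padding rows carry score 0, covering species left without a bin)
  per_species <- vapply(seq_len(ncol(frac)), function(b) {
    score[which(match_col == b), b]
  }, numeric(1))
  mean(per_species)
}

#' Select the number of bins with the Hartigan index
#'
#' Runs k-medoids for S = 1..S_max clusters and computes the Hartigan index
#' `H(S) = (W(S)/W(S+1) - 1) * (n - S - 1)` on the within-cluster cost curve
#' W. The chosen S is where H "decreases sharply and reaches a plateau": the
#' default `rule = "drop"` picks the largest S whose relative drop
#' `H(S-1)/H(S)` exceeds `sharp` -- the last halving of the index before the
#' plateau -- falling back to the single largest drop when none qualifies.
#' The rule is scale-free in the number of points; `rule = "threshold"`
#' instead picks the smallest S with `H(S) <= threshold` (the classical
#' absolute rule, value 10). The full curve is returned for inspection.
#'
#' @param vectors points x dimensions matrix (tag coverage vectors).
#' @param S_max largest cluster count considered (>= 2); needs at least
#'   `S_max + 1` vectors.
#' @param seed,n_starts,metric passed to [kmedoids()].
#' @param rule `"drop"` (default) or `"threshold"`.
#' @param sharp minimum `H(S-1)/H(S)` ratio counting as a sharp decrease.
#' @param threshold plateau threshold on H for `rule = "threshold"`.
#' @return list: chosen `S`, `H` (length `S_max - 1`), `W` (length `S_max`).
#' @export
select_num_bins <- function(vectors, S_max, seed = NULL, n_starts = 10L,
                            metric = "l1", rule = c("drop", "threshold"),
                            sharp = 2, threshold = 10) {
  rule <- match.arg(rule)
  n <- nrow(vectors)
  stopifnot(S_max >= 2)
  if (n < S_max + 1) stop("need at least S_max + 1 vectors")
  W <- vapply(seq_len(S_max), function(S) {
    seed_S <- if (is.null(seed)) NULL else seed + S
    kmedoids(vectors, S, seed = seed_S, n_starts = n_starts,
             metric = metric)$cost
  }, numeric(1))
  S_grid <- seq_len(S_max - 1L)
  H <- (W[S_grid] / pmax(W[S_grid + 1L], .Machine$double.eps) - 1) *
    (n - S_grid - 1)
  H[W[S_grid] == 0] <- 0  # perfect fit already; adding clusters buys nothing
  S <- if (rule == "threshold") {
    below <- which(H <= threshold)
    if (length(below)) below[1] else which.min(H)
  } else {
    eps <- .Machine$double.eps
    drops <- pmax(H[-length(H)], eps) / pmax(H[-1], eps)  # H(S-1)/H(S)
    cand <- which(drops > sharp)
    if (length(cand)) max(cand) + 1L else which.max(drops) + 1L
  }
  list(S = S, H = H, W = W)
}

#' Run the full MultiBin pipeline on an overlap graph
#'
#' Tags via [greedy_mis()], coverage vectors, k-medoids with `n_starts`
#' random starts, and label propagation, in one call.
#'
#' @param G `mj_overlap_graph`.
#' @param S number of bins.
#' @inheritParams kmedoids
#' @return `mj_binning` with the tag-level clustering attached as attributes
#'   `tags`, `coverage`, `cost`.
#' @export
multibin <- function(G, S, seed = NULL, n_starts = 10L, metric = "l1") {
  T <- greedy_mis(G)
  V <- coverage_vectors(T, G)
  km <- kmedoids(V, S, seed = seed, n_starts = n_starts, metric = metric)
  bins <- assign_bins(T, km$labels)
  attr(bins, "tags") <- T
  attr(bins, "coverage") <- V
  attr(bins, "cost") <- km$cost
  bins
}
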