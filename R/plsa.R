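#' Options for mixture-model fitting
#'
#' @param K number of latent components.
#' @param restarts number of independent random restarts (best kept).
#' @param max_iters iteration cap per restart.
#' @param tol convergence threshold on the relative log-likelihood change.
#' @param seed integer seed; restart `r` is initialized from `seed + r - 1`.
#' @param floor optional lower floor applied to F entries during the refined
#'   E-step (0 disables; useful for degenerate data where components lose all
#'   mass on observed classes).
#' @return list of class `mj_fit_options`.
#' @export
fit_options <- function(K, restarts = 10L, max_iters = 500L, tol = 1e-8,
                        seed = NULL, floor = 0) {
  stopifnot(K >= 1, restarts >= 1, max_iters >= 1, tol > 0)
  structure(list(K = as.integer(K), restarts = as.integer(restarts),
                 max_iters = as.integer(max_iters), tol = tol, seed = seed,
                 floor = floor),
            class = "mj_fit_options")
}

#' Random row-stochastic initialization
#'
#' Draws every entry of P (samples x components) and F (components x classes)
#' i.i.d. uniform(0,1) and normalizes each row to sum to one.
#'
#' @param M,K,W numbers of samples, components and k-mer classes.
#' @param seed integer seed (reproducible); NULL uses the current RNG stream.
#' @return list of class `mj_plsa` with elements `P`, `F`, `K`,
#'   `loglik = NA` (unfitted).
#' @export
init_params <- function(M, K, W, seed = NULL) {
  stopifnot(M >= 1, K >= 1, W >= 1)
  with_seed(seed, {
    P <- row_normalize(matrix(stats::runif(M * K), M, K))
    F <- row_normalize(matrix(stats::runif(K * W), K, W))
    new_plsa(P, F)
  })
}

new_plsa <- function(P, F, loglik = NA_real_, trace = numeric(0)) {
  structure(list(P = P, F = F, K = ncol(P), loglik = loglik, trace = trace),
            class = "mj_plsa")
}

#' Aggregate-counts log-likelihood
#'
#' The log-likelihood of a counts matrix under the mixture of multinomials:
#' `sum_i sum_w R[i,w] * log(sum_k P[i,k] F[k,w])`. Cells with `R[i,w] = 0`
#' contribute nothing; a positive count over zero mixture mass yields `-Inf`.
#'
#' @param model an `mj_plsa` object (or list with `P`, `F`).
#' @param counts `mj_counts` or samples x classes matrix.
#' @return scalar log-likelihood.
#' @export
loglik_aggregate <- function(model, counts) {
  R <- as_counts_matrix(counts)
  P <- model$P; F <- model$F
  if (nrow(R) != nrow(P) || ncol(R) != ncol(F) || ncol(P) != nrow(F))
    stop("dimension mismatch between model and counts")
  A <- P %*% F
  pos <- R > 0
  sum(R[pos] * log(A[pos]))
}

# One full EM run on aggregate counts from a given starting point.
em_aggregate_run <- function(R, P, F, max_iters, tol) {
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iters)) {
    A <- P %*% F
    pos <- R > 0
    ll <- sum(R[pos] * log(A[pos]))
    trace[it] <- ll
    if (is.finite(prev) && abs(ll - prev) <= tol * abs(prev)) break
    prev <- ll
    Rat <- R / A
    Rat[!pos] <- 0
    Pn <- row_normalize(P * (Rat %*% t(F)))
    Fn <- row_normalize(F * (t(P) %*% Rat))
    P <- Pn; F <- Fn
  }
  new_plsa(P, F, loglik = trace[length(trace)], trace = trace)
}

#' Fit the mixture model to aggregate counts (EM)
#'
#' Expectation-maximization for the shared-component mixture of multinomials
#' on a samples x classes counts matrix. The E-step computes the posterior of
#' the component for every (sample, k-mer) pair,
#' `Q(k | i, w) \propto P[i,k] F[k,w]`; the M-step re-estimates
#' `P[i,k] \propto sum_w R[i,w] Q(k|i,w)` and
#' `F[k,w] \propto sum_i R[i,w] Q(k|i,w)`. The log-likelihood is
#' non-decreasing across iterations; the best of `restarts` random starts is
#' returned (ties broken by the lowest restart index).
#'
#' @param counts `mj_counts` or samples x classes matrix with positive row
#'   totals.
#' @param opts an [fit_options()] object.
#' @return fitted `mj_plsa` with `loglik` and the per-iteration `trace` of the
#'   winning restart.
#' @export
em_aggregate <- function(counts, opts) {
  R <- as_counts_matrix(counts)
  if (all(R == 0)) stop("all-zero counts matrix")
  if (any(rowSums(R) <= 0)) stop("every sample needs positive total counts")
  M <- nrow(R); W <- ncol(R); K <- opts$K
  best <- NULL
  for (r in seq_len(opts$restarts)) {
    seed_r <- if (is.null(opts$seed)) NULL else opts$seed + r - 1L
    init <- init_params(M, K, W, seed = seed_r)
    fit <- em_aggregate_run(R, init$P, init$F, opts$max_iters, opts$tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  dimnames(best$F) <- list(NULL, colnames(R))
  rownames(best$P) <- rownames(R)
  best
}

# One full EM run on per-read bags. C: sparse reads x classes, sample: integer
# index per read.
em_refined_run <- function(C, sample, M, P, F, max_iters, tol, floor = 0) {
  trace <- numeric(0)
  prev <- -Inf
  n <- nrow(C)
  for (it in seq_len(max_iters)) {
    Fe <- if (floor > 0) pmax(F, floor) else F
    logF <- log(pmax(Fe, .Machine$double.xmin))  # -745 stands in for log(0)
    B <- as.matrix(C %*% t(logF))                # n x K read-level evidence
    LQ <- B + log(P)[sample, , drop = FALSE]
    m <- do.call(pmax, as.data.frame(LQ))
    Q <- exp(LQ - m)
    s <- rowSums(Q)
    ll <- sum(m + log(s))
    trace[it] <- ll
    if (is.finite(prev) && abs(ll - prev) <= tol * abs(prev)) break
    prev <- ll
    Q <- Q / s
    Pn <- row_normalize(rowsum(Q, sample, reorder = TRUE))
    if (nrow(Pn) != M) stop("every sample needs at least one read")
    Fn <- row_normalize(t(as.matrix(Matrix::crossprod(C, Q))))
    P <- Pn; F <- Fn
  }
  new_plsa(P, F, loglik = trace[length(trace)], trace = trace)
}

#' Fit the refined (per-read) mixture model (EM)
#'
#' The refined model assigns one latent component to every read rather than to
#' every extracted k-mer: reads from sample `i` draw a component `k` with
#' probability `P[i,k]` and then all their k-mers i.i.d. from `F[k,]`. The
#' E-step posterior is `Q(k|r) \propto P[i(r),k] prod_w F[k,w]^{c[r,w]}`,
#' evaluated in log space with max-subtraction; the M-step sets
#' `P[i,k] \propto sum_{r in i} Q(k|r)` and
#' `F[k,w] \propto sum_r Q(k|r) c[r,w]`.
#'
#' @param bags an `mj_bags` object from [read_kmer_bags()]; every read must
#'   have a non-empty bag.
#' @param opts an [fit_options()] object.
#' @return fitted `mj_plsa`.
#' @export
em_refined <- function(bags, opts) {
  stopifnot(inherits(bags, "mj_bags"))
  C <- bags$C
  keep <- Matrix::rowSums(C) > 0
  if (!all(keep)) stop(sum(!keep), " read(s) have empty k-mer bags")
  M <- length(bags$samples)
  W <- ncol(C); K <- opts$K
  best <- NULL
  for (r in seq_len(opts$restarts)) {
    seed_r <- if (is.null(opts$seed)) NULL else opts$seed + r - 1L
    init <- init_params(M, K, W, seed = seed_r)
    fit <- em_refined_run(C, bags$sample, M, init$P, init$F,
                          opts$max_iters, opts$tol, opts$floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  dimnames(best$F) <- list(NULL, bags$classes)
  rownames(best$P) <- bags$samples
  best
}

#' Permutation-matched estimation error
#'
#' Sum of squared entry differences between an estimated and a true matrix,
#' minimized over relabelings of the components (rows of F, columns of P).
#' Exhaustive over all permutations for K <= 8, greedy matching above.
#'
#' @param est,truth matrices of identical shape; components along `margin`
#'   (1 = rows, as in F; 2 = columns, as in P).
#' @param margin which dimension indexes components.
#' @return non-negative scalar; 0 iff the matrices agree up to a component
#'   permutation.
#' @export
estimation_error <- function(est, truth, margin = 1L) {
  if (!all(dim(est) == dim(truth))) stop("shape mismatch")
  if (margin == 2L) { est <- t(est); truth <- t(truth) }
  K <- nrow(est)
  if (K <= 8L) {
    perms <- all_perms(K)
    errs <- apply(perms, 1L, function(p) sum((est[p, , drop = FALSE] - truth)^2))
    min(errs)
  } else {
    # greedy: repeatedly match the closest (estimated, true) component pair
    D <- as.matrix(stats::dist(rbind(est, truth)))[seq_len(K), K + seq_len(K)]^2
    tot <- 0
    for (step in seq_len(K)) {
      ij <- arrayInd(which.min(D), dim(D))
      tot <- tot + D[ij[1], ij[2]]
      D[ij[1], ] <- Inf
      D[, ij[2]] <- Inf
    }
    tot
  }
}

#' Sample scores of the leading principal components
#'
#' Convenience wrapper extracting the first `K` principal-component scores of
#' a (centered) counts matrix, the standard dimensionality-reduction baseline
#' the mixture model is compared against.
#'
#' @param counts `mj_counts` or samples x classes matrix.
#' @param K number of components.
#' @return samples x K matrix of scores.
#' @export
pca_components <- function(counts, K) {
  R <- as_counts_matrix(counts)
  stats::prcomp(R, center = TRUE, scale. = FALSE)$x[, seq_len(K), drop = FALSE]
}

#' Mean squared correlation with the true mixture proportions
#'
#' For each method's K estimated component score vectors, computes the mean
#' over components of the squared Pearson correlation with the true columns
#' of P, maximized over the assignment of estimated to true components.
#' Pairings involving a constant vector (undefined correlation) score 0.
#'
#' @param P_true samples x K matrix of true mixture proportions.
#' @param estimates named list of samples x K matrices (one per method).
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
compare_to_pca <- function(P_true, estimates) {
  K <- ncol(P_true)
  score_one <- function(E) {
    stopifnot(ncol(E) == K, nrow(E) == nrow(P_true))
    r2 <- matrix(0, K, K)  # r2[a, b] = cor(E[, a], P_true[, b])^2
    for (a in seq_len(K)) for (b in seq_len(K)) {
      if (stats::sd(E[, a]) == 0 || stats::sd(P_true[, b]) == 0) next
      r2[a, b] <- stats::cor(E[, a], P_true[, b])^2
    }
    perms <- all_perms(K)
    max(apply(perms, 1L, function(p) mean(r2[cbind(p, seq_len(K))])))
  }
  vapply(estimates, score_one, numeric(1))
}
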