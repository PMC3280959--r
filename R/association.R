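#' @name association
#' @title Metagenome-wide k-mer association testing
#'
#' @description
#' Association between the relative abundance of a k-mer class and a
#' per-sample phenotype is assessed by regressing the phenotype on the
#' abundance: simple linear regression for continuous phenotypes and logistic
#' regression for dichotomous ones. When samples are mixtures of shared
#' components in different proportions (stratification), wide swaths of
#' k-mers correlate spuriously with component-linked phenotypes; the
#' corrected test adds the first K-1 estimated component proportions as
#' covariates (the last is omitted because the proportions sum to one), which
#' restores the null distribution for k-mers whose signal the components
#' explain.
NULL

# Regress y on x (plus optional covariate matrix Z) and report the x
# coefficient. Handles both phenotype types and flags degenerate fits.
reg_test <- function(x, y, Z = NULL,
                     type = c("auto", "continuous", "dichotomous")) {
  type <- match.arg(type)
  n <- length(y)
  stopifnot(length(x) == n, n >= 3)
  if (type == "auto")
    type <- if (length(unique(y)) == 2L) "dichotomous" else "continuous"
  flags <- character(0)
  if (stats::sd(x) == 0) {
    return(assoc_row(NA_real_, NA_real_, 1, type, "degenerate"))
  }
  dat <- data.frame(.y = if (type == "dichotomous") as.numeric(factor(y)) - 1
                    else y,
                    .x = x)
  form <- .y ~ .x
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    colnames(Z) <- paste0(".z", seq_len(ncol(Z)))
    dat <- cbind(dat, Z)
    form <- stats::as.formula(paste(".y ~ .x +",
                                    paste(colnames(Z), collapse = " + ")))
  }
  if (type == "continuous") {
    fit <- stats::lm(form, data = dat)
    co <- summary(fit)$coefficients
  } else {
    warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm(form, family = stats::binomial(), data = dat),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (warned || !fit$converged) flags <- c(flags, "separation")
    co <- summary(fit)$coefficients
  }
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) flags <- c(flags, "collinear")
  if (!(".x" %in% rownames(co)) || aliased[".x"])
    return(assoc_row(NA_real_, NA_real_, NA_real_, type,
                     paste(unique(c(flags, "collinear")), collapse = ";")))
  assoc_row(co[".x", 1], co[".x", 2], co[".x", 4], type,
            paste(flags, collapse = ";"))
}

assoc_row <- function(beta, se, p, model, flags) {
  data.frame(beta = beta, se = se, p = p, model = model, flags = flags,
             stringsAsFactors = FALSE)
}

#' Marginal k-mer association test
#'
#' Regresses the phenotype on a single k-mer's relative abundance vector and
#' reports the abundance coefficient with its Wald two-sided p-value.
#' Constant abundance vectors are flagged `degenerate` with p = 1; logistic
#' separation or non-convergence is flagged, never silently dropped.
#'
#' @param a_w numeric abundance vector, one value per sample.
#' @param y phenotype vector (continuous, or dichotomous with two levels).
#' @param type phenotype type; `"auto"` treats two-level vectors as
#'   dichotomous.
#' @return one-row data.frame: `beta`, `se`, `p`, `model`, `flags`.
#' @export
marginal_test <- function(a_w, y, type = "auto") {
  reg_test(a_w, y, Z = NULL, type = type)
}

#' Component-corrected k-mer association test
#'
#' As [marginal_test()], but with the first K-1 columns of the sample x
#' component proportion matrix entered as covariates; the K-th is dropped
#' because proportions sum to one. The reported test is for the abundance
#' coefficient after this correction.
#'
#' @inheritParams marginal_test
#' @param P samples x K row-stochastic component proportion matrix (typically
#'   the `P` of a fitted mixture model).
#' @return one-row data.frame as in [marginal_test()].
#' @export
corrected_test <- function(a_w, y, P, type = "auto") {
  P <- as.matrix(P)
  stopifnot(nrow(P) == length(y))
  K <- ncol(P)
  Z <- if (K >= 2) P[, -K, drop = FALSE] else NULL
  reg_test(a_w, y, Z = Z, type = type)
}

#' Component-phenotype association test
#'
#' Tests one component's proportion vector for association with a phenotype,
#' optionally correcting for other measured phenotypes entered as covariates.
#'
#' @param p_k numeric vector of one component's proportions across samples.
#' @inheritParams marginal_test
#' @param covariates optional matrix/data.frame of additional covariates.
#' @return one-row data.frame as in [marginal_test()].
#' @export
component_phenotype_test <- function(p_k, y, covariates = NULL,
                                     type = "auto") {
  reg_test(p_k, y, Z = covariates, type = type)
}

#' Label-permutation empirical p-value
#'
#' Recomputes a statistic under uniformly random permutations of the
#' phenotype labels and reports `p = (1 + #{permuted >= observed}) /
#' (n_perms + 1)` (the +1 correction keeps p away from zero).
#'
#' @param statistic_fn function mapping a phenotype vector to a scalar
#'   statistic (larger = more extreme).
#' @param y phenotype vector to permute.
#' @param n_perms number of permutations (>= 1).
#' @param seed integer seed for reproducible permutations.
#' @return list with `p`, `observed`, and the vector `permuted`.
#' @export
permutation_test <- function(statistic_fn, y, n_perms, seed = NULL) {
  stopifnot(n_perms >= 1)
  observed <- statistic_fn(y)
  permuted <- with_seed(seed, {
    vapply(seq_len(n_perms),
           function(b) statistic_fn(sample(y)), numeric(1))
  })
  p <- (1 + sum(permuted >= observed)) / (n_perms + 1)
  list(p = p, observed = observed, permuted = permuted)
}

#' Fraction of k-mers rejected by a two-sample t-test
#'
#' For every k-mer class, compares its relative abundance between two
#' phenotype groups with a Welch two-sample t-test and reports the fraction
#' of classes rejected at level `alpha`. Composable with
#' [permutation_test()] for an empirical calibration of that fraction.
#'
#' @param a classes x samples abundance matrix (see [relative_abundance()]).
#' @param groups dichotomous label vector, one per sample; both groups need
#'   at least two samples.
#' @param alpha nominal significance level.
#' @return list with `fraction`, the per-class `pvalues`, and `alpha`.
#' @export
fraction_rejected <- function(a, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, ncol(a) == length(groups))
  if (any(table(groups) < 2)) stop("both groups need at least 2 samples")
  g1 <- groups == levels(groups)[1]
  pvals <- apply(a, 1L, function(row) {
    if (stats::sd(row) == 0) return(1)
    stats::t.test(row[g1], row[!g1])$p.value
  })
  list(fraction = mean(pvals <= alpha), pvalues = pvals, alpha = alpha)
}

#' Quantile-quantile points against the uniform distribution
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @return data.frame with `expected` = (j - 0.5)/n uniform quantiles and
#'   `observed` = sorted p-values; suitable for a QQ plot.
#' @export
qq_points <- function(pvals) {
  stopifnot(length(pvals) > 0)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  n <- length(pvals)
  data.frame(expected = (seq_len(n) - 0.5) / n, observed = sort(pvals))
}
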