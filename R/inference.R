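#' Residualize a measure on covariates
#'
#' Ordinary least-squares residuals of a measure on an intercept plus the
#' given covariates.
#'
#' @param values Numeric vector.
#' @param covariates Numeric matrix/data frame of covariate columns (or
#'   `NULL`, in which case the result is the mean-centered input).
#' @return Numeric residual vector.
#' @export
residualize <- function(values, covariates = NULL) {
  values <- as.numeric(values)
  Z <- .covariate_matrix(covariates, length(values))
  X <- cbind(rep(1, length(values)), Z)
  .check_rank(X)
  as.vector(values - X %*% solve(crossprod(X), crossprod(X, values)))
}

#' Covariate-adjusted two-sample t statistic
#'
#' The t statistic of the group coefficient in the linear model
#' `measure ~ intercept + group + covariates`, with group coded
#' patient = 1, control = 0, so positive t means patients > controls.
#' Without covariates this equals the classical pooled-variance two-sample t.
#'
#' @param values Numeric measure vector, one entry per subject.
#' @param group Vector of `"patient"`/`"control"` labels (or 0/1).
#' @param covariates Optional numeric covariate columns (e.g. age, sex code).
#' @return The t statistic (numeric scalar) with attribute `"df"`.
#' @export
adjusted_group_ttest <- function(values, group, covariates = NULL) {
  g <- .code_group(group)
  if (sum(g == 1) == 0 || sum(g == 0) == 0) stop("both groups must be nonempty")
  Z <- .covariate_matrix(covariates, length(g))
  eng <- .t_engine(g, Z)
  t <- eng$tfun(as.matrix(as.numeric(values)))
  if (!is.finite(t) && stats::var(as.numeric(values)) == 0)
    stop("measure is constant: degenerate variance")
  structure(t, df = eng$df)
}

#' Permutation p-values for group differences across measures
#'
#' For each measure column, tests the covariate-adjusted group difference by
#' permutation. With covariates the Freedman-Lane scheme is used: residuals
#' of the reduced model (intercept + covariates) are row-permuted, the
#' reduced fit is added back, and the full-model group t is recomputed; the
#' same permutation applies to every measure within one draw. Without
#' covariates this reduces to permuting group labels. When the number of
#' distinct label assignments `choose(n, n_patients)` does not exceed `B`,
#' exhaustive enumeration over assignments replaces sampling and the result
#' is deterministic (independent of `seed`).
#'
#' Sampled p-values use the add-one convention `(1 + b) / (1 + B)` by
#' default, so p is never 0; `p_convention = "strict"` gives the plain
#' proportion `b / B`. Exhaustive p-values are the proportion over all
#' assignments (the identity is included, so they are never 0 either).
#'
#' @param measures Subjects x measures numeric matrix (or a vector for a
#'   single measure).
#' @param group Vector of `"patient"`/`"control"` labels (or 0/1).
#' @param covariates Optional numeric covariate columns.
#' @param B Number of permutations; default 5000.
#' @param seed RNG seed; required when sampling is used.
#' @param alternative `"two.sided"` (default), `"greater"` (patients >
#'   controls) or `"less"`.
#' @param p_convention `"add_one"` (default) or `"strict"`.
#' @param exhaustive `"auto"` (default: enumerate when feasible) or
#'   `"never"`.
#' @return Data frame with columns `measure`, `t`, `p_perm`; attribute
#'   `"exhaustive"` records which path was used.
#' @export
permutation_pvalues <- function(measures, group, covariates = NULL, B = 5000,
                                seed = NULL,
                                alternative = c("two.sided", "greater", "less"),
                                p_convention = c("add_one", "strict"),
                                exhaustive = c("auto", "never")) {
  alternative <- match.arg(alternative)
  p_convention <- match.arg(p_convention)
  exhaustive <- match.arg(exhaustive)
  Y <- as.matrix(measures)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("m", seq_len(ncol(Y)))
  g <- .code_group(group)
  if (nrow(Y) != length(g)) stop("measures and group lengths differ")
  Z <- .covariate_matrix(covariates, length(g))
  if (B < 1) stop("B must be at least 1")

  const <- apply(Y, 2, function(y) stats::var(y) == 0)
  if (any(const))
    warning("constant measure(s) assigned p = 1: ",
            paste(colnames(Y)[const], collapse = ", "))

  use_exhaustive <- exhaustive == "auto" && choose(length(g), sum(g == 1)) <= B
  if (use_exhaustive) {
    t_all <- .exhaustive_t(Y, g, Z)
    t_obs <- .t_engine(g, Z)$tfun(Y)
    p <- .tail_count(t_obs, t_all, alternative) / nrow(t_all)
  } else {
    if (is.null(seed)) stop("seed is required for sampled permutations")
    res <- .fl_perm_t(Y, g, Z, B, seed)
    t_obs <- res$t_obs
    b <- .tail_count(t_obs, res$t_perm, alternative)
    p <- if (p_convention == "add_one") (1 + b) / (1 + B) else b / B
  }
  p[const] <- 1
  t_obs[const] <- 0
  out <- data.frame(measure = colnames(Y), t = t_obs, p_perm = p,
                    row.names = NULL)
  attr(out, "exhaustive") <- use_exhaustive
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment with monotone adjusted p-values and rejection flags
#' at level `alpha`.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @param alpha FDR level; default 0.05.
#' @return List with `adjusted` (BH-adjusted p) and `reject` (logical).
#' @export
fdr_bh <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0)
    return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Group comparison of a family of summary measures
#'
#' Runs the covariate-adjusted permutation test on every measure column and
#' applies Benjamini-Hochberg FDR within the family, also flagging the
#' lenient uncorrected tier.
#'
#' @inheritParams permutation_pvalues
#' @param alpha Significance level for both tiers; default 0.05.
#' @return Data frame `measure t p_perm p_fdr sig_fdr sig_unc`.
#' @export
group_comparison <- function(measures, group, covariates = NULL, B = 5000,
                             seed = NULL, alpha = 0.05,
                             alternative = "two.sided",
                             p_convention = "add_one") {
  res <- permutation_pvalues(measures, group, covariates, B = B, seed = seed,
                             alternative = alternative,
                             p_convention = p_convention)
  fdr <- fdr_bh(res$p_perm, alpha)
  res$p_fdr <- fdr$adjusted
  res$sig_fdr <- fdr$reject
  res$sig_unc <- res$p_perm < alpha
  res
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact conditional test: with all margins fixed, the two-sided p-value is
#' the sum of hypergeometric probabilities of every table whose point
#' probability does not exceed that of the observed table (within relative
#' tolerance 1e-7, so equal-probability tables are not misclassified by
#' floating-point noise).
#'
#' @param counts 2x2 matrix (or length-4 vector, row-major) of nonnegative
#'   integer counts.
#' @return List with `p.value` and `odds_ratio` (sample odds ratio).
#' @examples
#' fisher_exact_2x2(matrix(c(7, 8, 5, 10), 2, byrow = TRUE))$p.value  # 0.7104
#' @export
fisher_exact_2x2 <- function(counts) {
  x <- matrix(as.numeric(counts), 2, 2,
              byrow = is.vector(counts) && !is.matrix(counts))
  if (any(x < 0) || any(x != round(x))) stop("counts must be nonnegative integers")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("a margin of the 2x2 table is zero")
  m <- sum(x[1, ])          # white balls: row 1
  n <- sum(x[2, ])          # black balls: row 2
  k <- sum(x[, 1])          # drawn: column 1
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(x[1, 1], m, n, k)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  list(p.value = min(1, p),
       odds_ratio = (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1]))
}

#' Welch's two-sample two-tailed t-test
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return List with `t`, `df` (Welch-Satterthwaite) and `p.value`.
#' @export
welch_ttest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("both samples have zero variance")
  res <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact p-value by enumeration when the pooled sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param a,b Numeric samples.
#' @return List with `U` (number of (a, b) pairs with a > b, plus half the
#'   ties) and `p.value`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b)) <= 12 && !ties
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- res$p.value
  if (is.nan(p)) p <- 1   # all observations tied in tiny samples
  list(U = unname(res$statistic), p.value = min(1, p))
}
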