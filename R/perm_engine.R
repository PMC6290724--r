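# Internal linear-model / permutation machinery shared by the summary-level
# group tests and the edge-wise NBS. All tests reduce to the t statistic of
# the group coefficient in  y ~ intercept + group + covariates,  computed
# simultaneously for many measure columns.

.code_group <- function(group) {
  if (is.numeric(group)) {
    u <- sort(unique(group))
    if (!all(u %in% c(0, 1))) stop("numeric group must be coded 0/1")
    return(as.numeric(group))
  }
  g <- as.character(group)
  if (!all(g %in% c("patient", "control")))
    stop("group must be 'patient'/'control' or 0/1")
  as.numeric(g == "patient")
}

.covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  z <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(z)) stop("covariates must be numeric (code factors beforehand)")
  if (nrow(z) != n) stop("covariates have ", nrow(z), " rows, expected ", n)
  z
}

.check_rank <- function(X) {
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  invisible(X)
}

# Precompute everything needed to get the group-coefficient t statistic from
# a response matrix with the design held fixed: t_m = a'y_m / sqrt(RSS_m/df * c_gg).
.t_engine <- function(g, Z) {
  n <- length(g)
  X <- cbind(intercept = 1, group = g, Z)
  .check_rank(X)
  XtXinv <- solve(crossprod(X))
  a <- (XtXinv %*% t(X))[2, ]
  Q <- qr.Q(qr(X))
  df <- n - ncol(X)
  if (df < 1) stop("too few subjects for the covariate-adjusted model")
  cgg <- XtXinv[2, 2]
  tfun <- function(Y) {
    Y <- as.matrix(Y)
    num <- as.vector(a %*% Y)
    QtY <- crossprod(Q, Y)
    rss <- pmax(colSums(Y * Y) - colSums(QtY * QtY), 0)
    num / sqrt(rss / df * cgg)
  }
  list(tfun = tfun, df = df, p = ncol(X))
}

# Freedman-Lane: fit the reduced model (intercept + covariates), permute its
# residual rows, add the reduced fit back, and re-test the full model. The
# same row permutation is applied to every measure column.
.fl_perm_t <- function(Y, g, Z, B, seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  eng <- .t_engine(g, Z)
  X0 <- cbind(rep(1, n), Z)
  fit0 <- X0 %*% solve(crossprod(X0), crossprod(X0, Y))
  R <- Y - fit0
  if (!is.null(seed)) set.seed(seed)
  t_obs <- eng$tfun(Y)
  t_perm <- matrix(NA_real_, B, ncol(Y))
  for (b in seq_len(B)) {
    idx <- sample.int(n)
    t_perm[b, ] <- eng$tfun(fit0 + R[idx, , drop = FALSE])
  }
  list(t_obs = t_obs, t_perm = t_perm, df = eng$df)
}

# Exhaustive enumeration of group-label assignments (all subsets of size n1
# as the patient group), refitting the full model with the permuted group
# regressor. Used when choose(n, n1) is small; includes the identity
# assignment, so the resulting p is never 0.
.exhaustive_t <- function(Y, g, Z) {
  Y <- as.matrix(Y)
  n <- length(g)
  assign <- utils::combn(n, sum(g == 1))
  t_all <- matrix(NA_real_, ncol(assign), ncol(Y))
  for (k in seq_len(ncol(assign))) {
    gk <- numeric(n)
    gk[assign[, k]] <- 1
    t_all[k, ] <- .t_engine(gk, Z)$tfun(Y)
  }
  t_all
}

.tail_count <- function(t_obs, t_mat, alternative) {
  # tolerance keeps exactly-tied statistics (up to float noise) in the tail
  tol <- 1e-8 * (1 + abs(t_obs))
  tol[!is.finite(tol)] <- 0
  switch(alternative,
    two.sided = colSums(sweep(abs(t_mat), 2, abs(t_obs) - tol, `>=`)),
    greater   = colSums(sweep(t_mat, 2, t_obs - tol, `>=`)),
    less      = colSums(sweep(t_mat, 2, t_obs + tol, `<=`))
  )
}
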