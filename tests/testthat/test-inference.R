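test_that("residualization matches closed-form least squares", {
  # covariate orthogonal to the measure: residuals are the centered measure
  y <- c(4, 6, 8, 10)
  z <- c(1, -1, -1, 1)
  expect_equal(residualize(y, z), y - mean(y))

  # perfect fit: measure = 2 * age
  age <- c(50, 55, 60, 65, 70)
  expect_equal(residualize(2 * age, age), rep(0, 5), tolerance = 1e-10)

  # small worked case against the normal equations solved by hand
  y <- c(1, 3, 2, 5, 4)
  x <- c(0, 1, 2, 3, 4)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize(y, x), as.vector(y - X %*% beta))

  expect_error(residualize(y, cbind(x, 2 * x)), "rank deficient")
})

test_that("adjusted group t equals the classical pooled t without covariates", {
  set.seed(8)
  a <- rnorm(10, 1); b <- rnorm(12)
  values <- c(a, b)
  group <- rep(c("patient", "control"), c(10, 12))
  t_pkg <- adjusted_group_ttest(values, group)
  t_cls <- stats::t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(as.numeric(t_pkg), unname(t_cls), tolerance = 1e-10)
  expect_equal(attr(t_pkg, "df"), 20)

  # identical groups -> t = 0
  expect_equal(as.numeric(adjusted_group_ttest(c(1, 2, 3, 1, 2, 3),
                                               rep(c("patient", "control"), each = 3))),
               0)
  # sign convention: patients minus controls
  set.seed(9)
  v <- c(rnorm(6, 5), rnorm(6, 0))
  expect_gt(as.numeric(adjusted_group_ttest(v, rep(c("patient", "control"), each = 6))), 3)
})

test_that("covariate-adjusted t matches an independent lm() fit", {
  set.seed(10)
  n <- 8
  g <- rep(c(1, 0), each = 4)
  age <- rnorm(n, 60, 5); sex <- c(1, 0, 1, 0, 0, 1, 0, 1)
  y <- 0.3 * g + 0.01 * age + rnorm(n, sd = 0.5)
  t_pkg <- as.numeric(adjusted_group_ttest(y, g, cbind(age, sex)))
  fit <- summary(lm(y ~ g + age + sex))
  expect_equal(t_pkg, fit$coefficients["g", "t value"], tolerance = 1e-9)
})

test_that("exhaustive permutation p matches hand enumeration on 2+2 subjects", {
  values <- c(1, 1, 0, 0)
  group <- c("patient", "patient", "control", "control")
  # independent enumeration over the 6 assignments of 2 patient slots:
  # only the identity gives t = +Inf, only the mirror gives -Inf, others 0
  one <- permutation_pvalues(values, group, B = 100, alternative = "greater")
  expect_true(attr(one, "exhaustive"))
  expect_equal(one$p_perm, 1 / 6)
  two <- permutation_pvalues(values, group, B = 100, alternative = "two.sided")
  expect_equal(two$p_perm, 2 / 6)
  # deterministic: no seed needed, repeated calls identical
  expect_identical(two$p_perm,
                   permutation_pvalues(values, group, B = 100)$p_perm)
})

test_that("exhaustive and sampled permutation p agree on the same data", {
  set.seed(12)
  y <- rnorm(10)
  group <- rep(c("patient", "control"), each = 5)   # choose(10,5) = 252
  pe <- permutation_pvalues(y, group, B = 300)$p_perm
  ps <- permutation_pvalues(y, group, B = 4000, seed = 5,
                            exhaustive = "never")$p_perm
  expect_lt(abs(pe - ps), 0.03)
})

test_that("constant measures get p = 1 with a warning", {
  y <- cbind(m1 = rnorm(10), m2 = rep(3, 10))
  group <- rep(c("patient", "control"), 5)
  expect_warning(res <- permutation_pvalues(y, group, B = 200, seed = 1),
                 "constant")
  expect_equal(res$p_perm[res$measure == "m2"], 1)
})

test_that("sampled permutation p-values are calibrated under the null", {
  set.seed(42)
  n <- 16
  group <- rep(c("patient", "control"), each = 8)
  pvals <- replicate(300, {
    y <- rnorm(n)
    covs <- cbind(age = rnorm(n, 60, 5), sex = rbinom(n, 1, 0.5))
    permutation_pvalues(y, group, covs, B = 499, seed = sample.int(1e6, 1),
                        exhaustive = "never")$p_perm
  })
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("BH control matches the step-up thresholds and dominates Bonferroni", {
  res <- fdr_bh(c(0.01, 0.02, 0.03), alpha = 0.05)
  expect_true(all(res$reject))                       # i * alpha / m = .0167/.0333/.05
  expect_equal(res$adjusted, rep(0.03, 3))
  expect_false(any(fdr_bh(rep(1, 5))$reject))
  expect_true(fdr_bh(0.04)$reject)
  expect_equal(fdr_bh(numeric(0))$adjusted, numeric(0))
  expect_true(all(diff(sort(fdr_bh(runif(20))$adjusted)) >= 0))

  set.seed(13)
  for (i in 1:20) {
    p <- runif(15)^2
    bh <- fdr_bh(p)$reject
    bonf <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(which(bonf) %in% which(bh)))
  }
})

test_that("Fisher exact p reproduces the demographic tables", {
  expect_equal(fisher_exact_2x2(matrix(c(7, 8, 5, 10), 2, byrow = TRUE))$p.value,
               0.7104, tolerance = 1e-4)
  expect_equal(fisher_exact_2x2(matrix(c(6, 9, 3, 12), 2, byrow = TRUE))$p.value,
               0.4270, tolerance = 1e-4)
  expect_gt(fisher_exact_2x2(matrix(c(7, 8, 8, 7), 2, byrow = TRUE))$p.value,
            0.9999)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Fisher exact agrees with stats::fisher.test on random tables", {
  set.seed(14)
  for (i in 1:50) {
    x <- matrix(rpois(4, 6) + 1, 2, 2)
    expect_equal(fisher_exact_2x2(x)$p.value, fisher.test(x)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Welch t follows the closed-form statistic and df", {
  a <- c(1.1, 2.3, 3.2, 4.8); b <- c(2.0, 2.2, 6.1)
  res <- welch_ttest(a, b)
  se2a <- var(a) / 4; se2b <- var(b) / 3
  expect_equal(res$t, (mean(a) - mean(b)) / sqrt(se2a + se2b), tolerance = 1e-12)
  expect_equal(res$df, (se2a + se2b)^2 / (se2a^2 / 3 + se2b^2 / 2),
               tolerance = 1e-12)

  expect_lt(welch_ttest(c(1, 2, 3), c(11, 12, 13))$p.value, 0.01)
  set.seed(15)
  x <- rnorm(6)
  expect_equal(welch_ttest(x, x)$t, 0)
  expect_error(welch_ttest(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Mann-Whitney U is exact for small untied samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p.value, 0.1)    # 2/20 arrangements as extreme
  expect_equal(mann_whitney_u(1, 1)$p.value, 1)

  # at the exact/approximate boundary the two routes agree closely
  set.seed(16)
  diffs <- replicate(25, {
    a <- rnorm(6); b <- rnorm(6) + 0.5
    exact_p <- mann_whitney_u(a, b)$p.value
    approx_p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    abs(exact_p - approx_p)
  })
  expect_lt(mean(diffs), 0.01)
  expect_lt(max(diffs), 0.03)
})

test_that("demographics table runs the documented test per characteristic", {
  cfg <- synthetic_study_config(seed = 77)
  st <- simulate_study(cfg)
  tab <- demographics_table(st$manifest)
  expect_setequal(tab$characteristic,
                  c("age", "sex", "education", "MMSE", "MoCA", "head motion"))
  expect_equal(tab$test[tab$characteristic == "sex"], "Fisher exact")
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  # planted cognitive deficit in patients is detectable
  expect_lt(tab$p[tab$characteristic == "MoCA"], 0.01)
})
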