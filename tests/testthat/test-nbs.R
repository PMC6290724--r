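# small helper: subjects x edges matrix of iid noise on a complete graph
iid_edges <- function(n_sub, n_nodes, seed) {
  set.seed(seed)
  e <- choose(n_nodes, 2)
  Y <- matrix(rnorm(n_sub * e), n_sub, e)
  attr(Y, "edge_index") <- unname(which(upper.tri(matrix(0, n_nodes, n_nodes)),
                                        arr.ind = TRUE))
  Y
}

test_that("edge F equals t squared and matches an RSS-ratio oracle", {
  set.seed(20)
  n <- 8
  g <- rep(c(1, 0), each = 4)
  age <- rnorm(n, 60, 4); sex <- rbinom(n, 1, 0.5)
  Y <- matrix(rnorm(n * 10), n, 10)
  es <- edge_statistics(Y, g, cbind(age, sex))
  expect_equal(es$F, es$t^2, tolerance = 1e-9)

  # reduced-vs-full residual-sum-of-squares F for each edge
  for (k in 1:10) {
    full <- lm(Y[, k] ~ g + age + sex)
    red <- lm(Y[, k] ~ age + sex)
    rss_f <- sum(resid(full)^2); rss_r <- sum(resid(red)^2)
    f_oracle <- (rss_r - rss_f) / (rss_f / full$df.residual)
    expect_equal(es$F[k], f_oracle, tolerance = 1e-9)
  }
})

test_that("edge statistics reflect group structure", {
  set.seed(21)
  Y <- matrix(rnorm(20 * 15, sd = 0.2), 20, 15)
  g <- rep(c("patient", "control"), each = 10)
  es0 <- edge_statistics(Y, g)
  expect_lt(max(abs(es0$t)), 5)            # no real effect

  Y[g == "patient", 7] <- Y[g == "patient", 7] + 5   # planted shift
  es1 <- edge_statistics(Y, g)
  expect_equal(which.max(es1$F), 7L)
  expect_gt(es1$t[7], 0)
})

test_that("suprathreshold components match hand-built graphs", {
  # chain (1,2),(2,3) above threshold -> one component of 2 links
  st <- structure(list(F = c(9, 9, 1), t = c(2, 2, 0.5),
                       edge_index = rbind(c(1, 2), c(2, 3), c(4, 5)),
                       roi_abbrev = NULL, df = 10), class = "edge_stats")
  comp <- suprathreshold_components(st, f_threshold = 5.3, direction = "greater")
  expect_equal(nrow(comp), 2)
  expect_equal(unique(comp$component_size), 2L)

  # disjoint edges -> two components of one link each
  st$edge_index <- rbind(c(1, 2), c(3, 4), c(5, 6))
  comp <- suprathreshold_components(st, 5.3, "greater")
  expect_equal(sort(comp$component_size), c(1L, 1L))
  expect_equal(length(unique(comp$component_id)), 2)

  # direction filter: negative edges only appear under "less"
  st$t <- c(2, -2, 2)
  expect_equal(nrow(suprathreshold_components(st, 5.3, "less")), 1)
  # ties at the threshold are excluded (strict >)
  st$F <- c(5.3, 9, 9)
  expect_equal(nrow(suprathreshold_components(st, 5.3, "greater")), 1)
})

test_that("component finding agrees with a BFS oracle on 1000 random graphs", {
  set.seed(22)
  for (i in 1:1000) {
    n_edges <- sample(0:12, 1)
    ea <- sample(10, n_edges, replace = TRUE)
    eb <- sample(10, n_edges, replace = TRUE)
    keep <- ea != eb
    ea <- ea[keep]; eb <- eb[keep]
    expect_identical(rsnconn:::.max_component_edges(ea, eb),
                     bfs_max_component_edges(ea, eb))
  }
})

test_that("NBS finds a planted component and bounds its p-value", {
  Y <- iid_edges(30, 10, seed = 23)
  g <- rep(c("patient", "control"), each = 15)
  # dense 5-edge connected block with a strong shift in patients
  planted <- 1:5   # edges (1,2),(1,3),(2,3),(1,4),(2,4): one connected block
  Y[g == "patient", planted] <- Y[g == "patient", planted] + 3
  res <- nbs_test(Y, g, B = 1000, seed = 3)
  gre <- res$components[res$components$direction == "greater", ]
  expect_gte(max(gre$size), 5)
  expect_lte(min(gre$p_corrected), 0.05)
  # corrected p is self-consistent with the reported null distribution
  M <- max(gre$size)
  expect_equal(min(gre$p_corrected),
               (1 + sum(res$null_max[, "greater"] >= M)) / 1001)

  # with a component-forming threshold no permutation reaches, the observed
  # planted component sits at the boundary: p = 1/(B+1), strict convention 0
  res_hi <- nbs_test(Y, g, B = 1000, seed = 3, f_threshold = 50)
  gre_hi <- res_hi$components[res_hi$components$direction == "greater", ]
  expect_equal(gre_hi$size, 5L)
  expect_equal(gre_hi$p_corrected, 1 / 1001)
  res_s <- nbs_test(Y, g, B = 1000, seed = 3, f_threshold = 50,
                    p_convention = "strict")
  gre_s <- res_s$components[res_s$components$direction == "greater", ]
  expect_equal(gre_s$p_corrected, 0)
})

test_that("corrected p is monotone nonincreasing in component size", {
  Y <- iid_edges(24, 12, seed = 24)
  g <- rep(c("patient", "control"), each = 12)
  res <- nbs_test(Y, g, B = 500, seed = 9, f_threshold = 2)
  for (d in unique(res$components$direction)) {
    cc <- res$components[res$components$direction == d, ]
    cc <- cc[order(cc$size), ]
    expect_true(all(diff(cc$p_corrected) <= 1e-12))
  }
})

test_that("no suprathreshold edges yields an empty result with a null distribution", {
  Y <- iid_edges(20, 8, seed = 25)
  g <- rep(c("patient", "control"), each = 10)
  res <- nbs_test(Y, g, B = 200, seed = 4, f_threshold = 1e6)
  expect_equal(nrow(res$components), 0)
  expect_equal(nrow(res$edges), 0)
  expect_equal(dim(res$null_max), c(200L, 2L))
  expect_true(all(res$null_max == 0))
})

test_that("Freedman-Lane covariate adjustment keeps the edge test calibrated", {
  set.seed(26)
  rejections <- replicate(60, {
    n <- 24
    g <- rep(c(1, 0), each = n / 2)
    age <- rnorm(n, 60, 6)
    Y <- iid_edges(n, 8, seed = sample.int(1e6, 1)) + 0.05 * age
    res <- nbs_test(Y, g, covariates = cbind(age), B = 199,
                    seed = sample.int(1e6, 1))
    nrow(res$components) > 0 && any(res$components$p_corrected < 0.05)
  })
  expect_lt(mean(rejections), 0.15)
})
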