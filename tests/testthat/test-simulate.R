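test_that("group targets differ exactly where effects are planted", {
  cfg_null <- synthetic_study_config(seed = 1, planted_effects = NULL,
                                     score_model = NULL)
  expect_identical(build_target_covariance(cfg_null, "patient"),
                   build_target_covariance(cfg_null, "control"))

  eff <- list(list(networks = c("AN", "SMN"), delta = -0.15, group = "patient"))
  cfg <- synthetic_study_config(seed = 1, planted_effects = eff)
  tp <- build_target_covariance(cfg, "patient")
  tc <- build_target_covariance(cfg, "control")
  rois <- cfg$rois
  diffmask <- unclass(tp) != unclass(tc)
  an <- rois$network == "AN"; smn <- rois$network == "SMN"
  expected <- outer(an, smn) | outer(smn, an)
  expect_equal(unname(diffmask), unname(expected))   # exactly the 2x20 entries
  expect_equal(sum(diffmask), 2 * sum(an) * sum(smn))
  expect_equal(unique(as.vector(tp[an, smn] - tc[an, smn])), -0.15)

  expect_gt(min(eigen(tp, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gt(min(eigen(tc, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("over-aggressive configurations are rejected", {
  expect_error(
    synthetic_study_config(seed = 1, base_r_within = 0.9, base_r_between = -0.4),
    "aggressive|outside")
})

test_that("simulated series converge to the target correlation", {
  target <- matrix(c(1, 0.4, 0, 0.4, 1, 0, 0, 0, 1), 3, 3)
  x <- simulate_subject(target, 10000, ar1 = 0, seed = 2)
  r <- cor(x)
  expect_gt(r[1, 2], 0.37); expect_lt(r[1, 2], 0.43)
  expect_lt(max(abs(r[cbind(c(1, 2), c(3, 3))])), 0.04)

  xid <- simulate_subject(diag(4), 10000, ar1 = 0, seed = 3)
  rid <- cor(xid)
  expect_lt(mean(abs(rid[upper.tri(rid)])), 0.04)

  expect_identical(simulate_subject(target, 100, 0.3, seed = 5),
                   simulate_subject(target, 100, 0.3, seed = 5))
  expect_false(identical(simulate_subject(target, 100, 0.3, seed = 5),
                         simulate_subject(target, 100, 0.3, seed = 6)))
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulate_subject(bad, 50), "positive definite")
})

test_that("scores respect coupling, clipping and the 0-30 range", {
  set.seed(6)
  eta <- runif(20, 0.05, 0.3)
  group <- rep(c("patient", "control"), each = 10)
  model <- list(intercept = c(patient = 24, control = 28), slope = 0,
                sd = c(patient = 2, control = 1))
  s0 <- simulate_scores(eta, group, model, seed = 7)
  expect_true(all(s0 >= 0 & s0 <= 30))
  expect_lt(abs(cor(eta, s0)), 0.6)   # slope 0: no systematic coupling

  model$slope <- 200; model$sd <- c(patient = 0.1, control = 0.1)
  s1 <- simulate_scores(eta, group, model, seed = 8)
  expect_gt(cor(eta[1:10], s1[1:10], method = "spearman"), 0.9)
  expect_true(all(s1 >= 0 & s1 <= 30))

  model$intercept <- c(patient = 100, control = -40); model$slope <- 0
  s2 <- simulate_scores(eta, group, model, seed = 9)
  expect_true(all(s2[group == "patient"] == 30))
  expect_true(all(s2[group == "control"] == 0))
})

test_that("a default study has the documented shape and layout", {
  cfg <- synthetic_study_config(seed = 11)
  st <- simulate_study(cfg)
  expect_length(st$timeseries, 30)
  expect_true(all(vapply(st$timeseries, function(x)
    identical(dim(x), c(220L, 36L)), logical(1))))
  expect_equal(sum(st$manifest$group == "patient"), 15)
  expect_equal(sum(st$manifest$sex == "male"), 15)   # 7 + 8
  expect_true(all(st$manifest$mmse >= 0 & st$manifest$mmse <= 30))

  d <- tempfile(); dir.create(d)
  simulate_study(cfg, out_dir = d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  expect_length(list.files(file.path(d, "ts")), 30)

  # byte-identical manifest across runs with the same seed
  d2 <- tempfile(); dir.create(d2)
  simulate_study(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))

  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_length(gt$planted_effects, 1)
  null_cfg <- synthetic_study_config(seed = 11, planted_effects = NULL)
  expect_length(simulate_study(null_cfg)$ground_truth$planted_effects, 0)
})

test_that("a written study reloads into the simulated series", {
  cfg <- synthetic_study_config(seed = 12, n_patients = 2, n_controls = 2,
                                n_timepoints = 40)
  d <- tempfile(); dir.create(d)
  st <- simulate_study(cfg, out_dir = d)
  reloaded <- load_study(file.path(d, "manifest.csv"), cfg$rois)
  expect_equal(reloaded$manifest$id, st$manifest$id)
  expect_equal(unname(reloaded$timeseries[["pat01"]]),
               unname(st$timeseries[["pat01"]]), tolerance = 1e-6)
})
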