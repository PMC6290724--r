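#' Configuration for a synthetic two-group connectivity study
#'
#' Defines the generative model used throughout the test suite: two groups of
#' subjects, each with a T x N ROI time series drawn from a block-structured
#' target correlation matrix (within-network correlations `base_r_within`,
#' between-network `base_r_between`), temporally smoothed with an AR(1)
#' filter, with group effects planted on chosen edges or network pairs, and
#' cognitive scores linearly coupled to a designated edge's transformed
#' connectivity.
#'
#' The defaults emulate a small clinical case-control study: 15 patients and
#' 15 controls, 220 timepoints, the packaged 36-ROI six-network atlas,
#' within/between-network correlations 0.4/0 (between-network 0 because the
#' emulated preprocessing includes global-mean-signal regression, which
#' centers off-diagonal correlations near zero), AR(1) 0.3, a planted
#' connectivity reduction (delta = -0.25 in correlation units) on a connected
#' 6-edge component spanning the auditory and sensorimotor networks in the
#' patient group, and MMSE/MoCA scores coupled to the first planted edge.
#'
#' @param n_patients,n_controls Group sizes; default 15 each.
#' @param n_timepoints Series length T; default 220.
#' @param rois A `roi_set`; default the packaged atlas.
#' @param base_r_within,base_r_between Block correlations; defaults 0.4, 0.
#' @param ar1 Temporal AR(1) coefficient; default 0.3. Sample-correlation
#'   targets are exact in expectation at `ar1 = 0` and approximate otherwise.
#' @param planted_effects List of effects, each a list with `delta`
#'   (correlation-unit shift), `group` (`"patient"`, `"control"` or
#'   `"both"`), and either `edges` (list of abbreviation pairs) or
#'   `networks` (two labels: all cross-network pairs). `NULL` disables all
#'   effects (pure null study).
#' @param score_model `NULL` for scores independent of connectivity, or a
#'   list with `target` (abbreviation pair), per-score `intercept`
#'   (named patient/control), `slope` (score units per eta unit) and `sd`
#'   (noise, named patient/control). See defaults in the function body.
#' @param seed Study seed; all randomness flows from it.
#' @return List of class `rsn_study_config`.
#' @export
synthetic_study_config <- function(n_patients = 15, n_controls = 15,
                                   n_timepoints = 220,
                                   rois = default_roi_set(),
                                   base_r_within = 0.4, base_r_between = 0,
                                   ar1 = 0.3,
                                   planted_effects = default_planted_effects(),
                                   score_model = default_score_model(),
                                   seed = 1) {
  stopifnot(n_patients >= 1, n_controls >= 1, n_timepoints >= 3,
            inherits(rois, "roi_set"), abs(ar1) < 1)
  cfg <- list(n_patients = n_patients, n_controls = n_controls,
              n_timepoints = n_timepoints, rois = rois,
              base_r_within = base_r_within, base_r_between = base_r_between,
              ar1 = ar1, planted_effects = planted_effects,
              score_model = score_model, seed = seed)
  class(cfg) <- "rsn_study_config"
  # validate: both group targets must be (repairably) positive definite
  build_target_covariance(cfg, "patient")
  build_target_covariance(cfg, "control")
  cfg
}

#' Default planted group effect
#'
#' A connected component of six auditory-sensorimotor edges (SMA to all four
#' auditory ROIs, plus lSTG to lPreC and lPoC) whose correlation is reduced
#' by 0.25 in the patient group.
#'
#' @return A one-element planted-effects list.
#' @export
default_planted_effects <- function() {
  list(list(
    edges = list(c("SMA", "lSTG"), c("SMA", "rSTG"), c("SMA", "lHes"),
                 c("SMA", "rHes"), c("lPreC", "lSTG"), c("lPoC", "lSTG")),
    delta = -0.25, group = "patient"
  ))
}

#' Default cognitive-score coupling
#'
#' MMSE and MoCA are linear in the transformed connectivity of the SMA-lSTG
#' edge (the first planted edge), with group-specific intercepts and noise
#' chosen to land in realistic score ranges: patients around 24 (MMSE) / 19
#' (MoCA) with SD near 3.5, controls around 28 / 27 with SD 1.
#'
#' @return A score-model list.
#' @export
default_score_model <- function() {
  list(target = c("SMA", "lSTG"),
       mmse = list(intercept = c(patient = 24, control = 28), slope = 25,
                   sd = c(patient = 3.5, control = 1.0)),
       moca = list(intercept = c(patient = 19, control = 27), slope = 25,
                   sd = c(patient = 3.5, control = 1.0)))
}

.edge_indices <- function(rois, pair) {
  i <- match(pair, rois$abbrev)
  if (anyNA(i)) stop("unknown ROI abbreviation: ", pair[is.na(i)][1])
  sort(i)
}

#' Target correlation matrix for one group
#'
#' Builds the block-structured target: unit diagonal, `base_r_within` inside
#' each network, `base_r_between` across networks, with the configured
#' planted effects added for the requested group. If the result is not
#' positive definite it is repaired by clipping eigenvalues at a small
#' positive floor and rescaling to unit diagonal; a repair that moves any
#' entry by more than 0.05 aborts (the configuration is too aggressive).
#'
#' @param config An `rsn_study_config`.
#' @param group `"patient"` or `"control"`.
#' @return N x N correlation matrix with attribute `"repaired"` (logical) and
#'   `"max_repair_change"`.
#' @export
build_target_covariance <- function(config, group = c("patient", "control")) {
  group <- match.arg(group)
  rois <- config$rois
  n <- nrow(rois)
  same_net <- outer(rois$network, rois$network, "==")
  R <- ifelse(same_net, config$base_r_within, config$base_r_between)
  diag(R) <- 1
  for (eff in config$planted_effects) {
    if (!(eff$group %in% c(group, "both"))) next
    if (!is.null(eff$networks)) {
      ix <- which(rois$network == eff$networks[1])
      iy <- which(rois$network == eff$networks[2])
      R[ix, iy] <- R[ix, iy] + eff$delta
      R[iy, ix] <- R[iy, ix] + eff$delta
    } else {
      for (pair in eff$edges) {
        ij <- .edge_indices(rois, pair)
        R[ij[1], ij[2]] <- R[ij[1], ij[2]] + eff$delta
        R[ij[2], ij[1]] <- R[ij[2], ij[1]] + eff$delta
      }
    }
  }
  if (any(abs(R[upper.tri(R)]) >= 1))
    stop("planted effects push a target correlation outside (-1, 1)")
  dimnames(R) <- list(rois$abbrev, rois$abbrev)
  ev <- eigen(R, symmetric = TRUE)
  repaired <- FALSE
  max_change <- 0
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-6)
    R2 <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R2))
    R2 <- R2 / outer(d, d)
    diag(R2) <- 1
    max_change <- max(abs(R2 - R))
    if (max_change > 0.05)
      stop("positive-definiteness repair changes an entry by ",
           format(max_change, digits = 3), " (> 0.05): config too aggressive")
    R <- R2
    dimnames(R) <- list(rois$abbrev, rois$abbrev)
    repaired <- TRUE
  }
  attr(R, "repaired") <- repaired
  attr(R, "max_repair_change") <- max_change
  R
}

#' Simulate one subject's ROI time series
#'
#' Draws a zero-mean stationary T x N series whose innovations have the
#' target cross-correlation: i.i.d. Gaussian innovations are passed through a
#' stationary AR(1) filter per column (identical coefficient, so the
#' cross-correlation structure is preserved) and mixed with the Cholesky
#' factor of the target. At `ar1 = 0` the expected sample correlation equals
#' the target exactly.
#'
#' @param target Positive-definite N x N correlation matrix.
#' @param n_timepoints Series length T.
#' @param ar1 AR(1) coefficient in (-1, 1).
#' @param seed Optional RNG seed.
#' @return T x N numeric matrix, columns named like `target`.
#' @export
simulate_subject <- function(target, n_timepoints, ar1 = 0, seed = NULL) {
  ev <- min(eigen(target, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("target correlation matrix is not positive definite")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(target)
  L <- chol(target)
  E <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
  if (ar1 != 0) {
    E[1, ] <- E[1, ] / sqrt(1 - ar1^2)   # stationary start
    for (t in 2:n_timepoints) E[t, ] <- ar1 * E[t - 1, ] + E[t, ]
  }
  X <- E %*% L
  colnames(X) <- colnames(target)
  X
}

#' Simulate cognitive scores coupled to a connectivity measure
#'
#' `score = intercept[group] + slope * (measure - ref) + noise`, rounded to
#' integers and clipped to \[0, 30\] (the MMSE/MoCA range). `ref` centers the
#' coupling on a reference measure value so the intercepts are interpretable
#' as group means.
#'
#' @param measure Per-subject connectivity measure (e.g. a target edge eta).
#' @param group Per-subject `"patient"`/`"control"` labels.
#' @param model One score's model: list with `intercept` (named vector),
#'   `slope`, `sd` (named vector).
#' @param ref Reference measure value subtracted before applying the slope;
#'   default the overall mean of `measure`.
#' @param seed Optional RNG seed.
#' @return Integer score vector in \[0, 30\].
#' @export
simulate_scores <- function(measure, group, model, ref = mean(measure),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raw <- model$intercept[group] + model$slope * (measure - ref) +
    stats::rnorm(length(measure), 0, model$sd[group])
  pmin(30L, pmax(0L, as.integer(round(raw))))
}

#' Simulate a complete synthetic study
#'
#' Generates the full study: per-subject time series from the group targets,
#' demographics (age, sex, education), head-motion summaries and cognitive
#' scores, plus a ground-truth record of everything planted. With `out_dir`
#' the study is written in the on-disk layout consumed by [load_study()]
#' (manifest.csv, one TSV per subject, ground_truth.json).
#'
#' @param config An `rsn_study_config`.
#' @param out_dir Optional output directory.
#' @return List of class `rsn_study` with `manifest`, `timeseries` (named
#'   list of T x N matrices) and `ground_truth`.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "rsn_study_config"))
  rois <- config$rois
  n_p <- config$n_patients
  n_c <- config$n_controls
  n_tot <- n_p + n_c
  group <- c(rep("patient", n_p), rep("control", n_c))
  ids <- sprintf("%s%02d", ifelse(group == "patient", "pat", "con"),
                 c(seq_len(n_p), seq_len(n_c)))

  set.seed(config$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1, n_tot)
  score_seed <- sample.int(.Machine$integer.max - 1, 1)

  # demographics emulating an elderly case-control sample
  age <- round(ifelse(group == "patient",
                      stats::rnorm(n_tot, 61.7, 6.3),
                      stats::rnorm(n_tot, 61.4, 5.4)))
  age <- pmin(72, pmax(49, age))
  # fixed male counts of 7/15 (patients) and 8/15 (controls), scaled to group size
  n_male_p <- round(n_p * 7 / 15); n_male_c <- round(n_c * 8 / 15)
  sex <- c(sample(rep(c("male", "female"), c(n_male_p, n_p - n_male_p))),
           sample(rep(c("male", "female"), c(n_male_c, n_c - n_male_c))))
  education <- round(ifelse(group == "patient",
                            stats::rnorm(n_tot, 8.5, 2.9),
                            stats::rnorm(n_tot, 8.1, 2.0)))
  education <- pmax(6, pmin(15, education))
  mean_fd <- ifelse(group == "patient",
                    stats::rnorm(n_tot, 0.0857, 0.0425),
                    stats::rnorm(n_tot, 0.0725, 0.0294))
  mean_fd <- round(pmax(0.01, mean_fd), 4)

  targets <- list(patient = build_target_covariance(config, "patient"),
                  control = build_target_covariance(config, "control"))
  ts <- lapply(seq_len(n_tot), function(i)
    simulate_subject(targets[[group[i]]], config$n_timepoints, config$ar1,
                     seed = subj_seeds[i]))
  names(ts) <- ids

  if (!is.null(config$score_model)) {
    pair <- .edge_indices(rois, config$score_model$target)
    target_eta <- vapply(ts, function(x) {
      eta_transform(stats::cor(x[, pair[1]], x[, pair[2]]))
    }, numeric(1))
    ref <- eta_transform(config$base_r_between)
    set.seed(score_seed)
    mmse <- simulate_scores(target_eta, group, config$score_model$mmse, ref = ref)
    moca <- simulate_scores(target_eta, group, config$score_model$moca, ref = ref)
  } else {
    set.seed(score_seed)
    mmse <- pmin(30L, pmax(0L, as.integer(round(
      ifelse(group == "patient", stats::rnorm(n_tot, 23.7, 4.0),
             stats::rnorm(n_tot, 28.1, 1.0))))))
    moca <- pmin(30L, pmax(0L, as.integer(round(
      ifelse(group == "patient", stats::rnorm(n_tot, 18.6, 4.1),
             stats::rnorm(n_tot, 27.1, 1.0))))))
  }

  manifest <- data.frame(id = ids, group = group, age = age, sex = sex,
                         education = education, mmse = mmse, moca = moca,
                         mean_fd = mean_fd,
                         path = paste0("ts/", ids, ".tsv"),
                         stringsAsFactors = FALSE)
  class(manifest) <- c("subject_manifest", "data.frame")

  ground_truth <- list(
    planted_effects = config$planted_effects,
    score_model = config$score_model,
    seed = config$seed,
    base_r_within = config$base_r_within,
    base_r_between = config$base_r_between,
    ar1 = config$ar1,
    target_patient = unclass(targets$patient),
    target_control = unclass(targets$control)
  )

  study <- structure(list(manifest = manifest, timeseries = ts,
                          ground_truth = ground_truth, config = config),
                     class = "rsn_study")
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "ts"), showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    for (id in ids)
      utils::write.table(ts[[id]], file.path(out_dir, "ts", paste0(id, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    write_roi_set(rois, file.path(out_dir, "rois.tsv"))
    jsonlite::write_json(ground_truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  study
}
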