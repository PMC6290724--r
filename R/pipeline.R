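#' Run the full three-level connectivity analysis
#'
#' Executes the whole pipeline on a study: head-motion QC, per-subject
#' correlation and eta matrices, the three analysis levels — (1) nodal
#' integration, (2) intra-/inter-network composite scores, both tested with
#' covariate-adjusted Freedman-Lane permutation tests and FDR control, and
#' (3) edge-wise NBS — followed by Spearman brain-behavior association of the
#' altered measures with MMSE/MoCA in the patient group. Age and sex (coded
#' male = 1) are the adjustment covariates throughout.
#'
#' @param study An `rsn_study` (from [load_study()] or [simulate_study()]),
#'   or a path to a manifest CSV.
#' @param rois A `roi_set`; default the packaged atlas. Ignored when `study`
#'   already carries time series.
#' @param out_dir Optional output directory for all stage CSVs, the NBS null
#'   distribution, a JSON provenance record and a plain-text summary.
#' @param xi Eta-transform decay constant; default 2.
#' @param f_threshold NBS component-forming threshold; default 5.3.
#' @param B Permutation count for both the summary tests and the NBS;
#'   default 5000.
#' @param alpha Significance level for all tiers; default 0.05.
#' @param seed RNG seed (required).
#' @param p_convention `"add_one"` (default) or `"strict"` (see
#'   [permutation_pvalues()] and [nbs_test()]).
#' @param outlier_k Tukey fence multiplier for the behavior association;
#'   `NULL` disables outlier removal.
#' @param qc Apply the mean-FD exclusion rule? Default `TRUE` (skipped when
#'   the manifest has no usable `mean_fd`).
#' @param qc_by_group Compute the motion threshold per group instead of
#'   pooled; default `FALSE`.
#' @return List of class `rsn_run` with elements `manifest` (post-QC),
#'   `qc_dropped`, `measures`, `nodal_results`, `network_results`,
#'   `nbs`, `associations`, `altered_ids`, `demographics` and `params`.
#' @export
run_study <- function(study, rois = default_roi_set(), out_dir = NULL,
                      xi = 2, f_threshold = 5.3, B = 5000, alpha = 0.05,
                      seed = NULL, p_convention = "add_one",
                      outlier_k = 1.5, qc = TRUE, qc_by_group = FALSE) {
  if (is.null(seed)) stop("seed is required")
  if (is.character(study)) study <- load_study(study, rois)
  if (!is.null(study$config)) rois <- study$config$rois
  manifest <- study$manifest
  ts <- study$timeseries

  # -- quality control ------------------------------------------------------
  qc_dropped <- character(0)
  if (qc && !is.null(manifest$mean_fd) && all(is.finite(manifest$mean_fd))) {
    keep <- qc_exclude_high_motion(manifest$mean_fd,
                                   by_group = if (qc_by_group) manifest$group)
    qc_dropped <- manifest$id[!keep]
    manifest <- manifest[keep, , drop = FALSE]
    ts <- ts[manifest$id]
  }
  if (length(unique(manifest$group)) < 2)
    stop("after QC, one of the groups is empty")

  # -- connectivity ---------------------------------------------------------
  etas <- lapply(manifest$id, function(id) {
    r <- correlation_matrix(ts[[id]], rois)
    eta_transform(r, xi = xi)
  })
  names(etas) <- manifest$id

  # -- summary levels -------------------------------------------------------
  measures <- summarize_cohort(etas, rois)
  edges <- edge_matrix(etas, rois)
  covariates <- cbind(age = manifest$age,
                      sex = as.numeric(manifest$sex == "male"))

  nodal_cols <- grep("^gamma_", names(measures), value = TRUE)
  network_cols <- grep("^(intra|inter)_", names(measures), value = TRUE)

  # -- group inference (two FDR families: nodal, network composites) -------
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 3)
  nodal_results <- group_comparison(as.matrix(measures[nodal_cols]),
                                    manifest$group, covariates, B = B,
                                    seed = seeds[1], alpha = alpha,
                                    p_convention = p_convention)
  network_results <- group_comparison(as.matrix(measures[network_cols]),
                                      manifest$group, covariates, B = B,
                                      seed = seeds[2], alpha = alpha,
                                      p_convention = p_convention)

  # -- NBS ------------------------------------------------------------------
  nbs <- nbs_test(edges, manifest$group, covariates,
                  f_threshold = f_threshold, B = B, seed = seeds[3],
                  p_convention = p_convention)

  # -- brain-behavior association (patients only) --------------------------
  sig_comp <- nbs$components[nbs$components$p_corrected < alpha, ,
                             drop = FALSE]
  sig_edges <- merge(nbs$edges, sig_comp[, c("direction", "component_id")],
                     by = c("direction", "component_id"))
  altered_ids <- unique(c(
    nodal_results$measure[nodal_results$sig_unc],
    network_results$measure[network_results$sig_unc],
    if (nrow(sig_edges) > 0) paste0(sig_edges$roi_a, "|", sig_edges$roi_b)
  ))
  pat <- manifest$group == "patient"
  pat_data <- data.frame(measures[pat, , drop = FALSE],
                         as.data.frame(edges[pat, , drop = FALSE]),
                         check.names = FALSE)
  altered_ids <- intersect(altered_ids, names(pat_data))
  associations <- associate_alterations(
    pat_data, manifest[pat, c("mmse", "moca")], altered_ids,
    outlier_k = outlier_k, alpha = alpha)

  demographics <- demographics_table(manifest)

  params <- list(xi = xi, f_threshold = f_threshold, B = B, alpha = alpha,
                 seed = seed, p_convention = p_convention,
                 outlier_k = outlier_k, qc = qc, qc_by_group = qc_by_group,
                 n_rois = nrow(rois), n_networks = length(roi_networks(rois)),
                 n_summary_measures = length(nodal_cols) + length(network_cols),
                 n_edges = ncol(edges))

  run <- structure(list(manifest = manifest, qc_dropped = qc_dropped,
                        measures = measures, nodal_results = nodal_results,
                        network_results = network_results, nbs = nbs,
                        associations = associations,
                        altered_ids = altered_ids,
                        demographics = demographics, params = params),
                   class = "rsn_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write a pipeline run to disk
#'
#' @param run An `rsn_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$measures, file.path(out_dir, "summary_measures.csv"),
                   row.names = FALSE)
  utils::write.csv(run$nodal_results, file.path(out_dir, "nodal_results.csv"),
                   row.names = FALSE)
  utils::write.csv(run$network_results,
                   file.path(out_dir, "network_results.csv"), row.names = FALSE)
  utils::write.csv(run$associations, file.path(out_dir, "associations.csv"),
                   row.names = FALSE)
  utils::write.csv(run$demographics, file.path(out_dir, "demographics.csv"),
                   row.names = FALSE)
  write_nbs_result(run$nbs, out_dir)
  prov <- c(run$params,
            list(qc_dropped = run$qc_dropped,
                 n_subjects = nrow(run$manifest),
                 r_version = as.character(getRversion()),
                 package_version = as.character(utils::packageVersion("rsnconn"))))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(run)),
             file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.rsn_run <- function(x, ...) {
  p <- x$params
  cat("Three-level RSN connectivity analysis\n")
  cat(sprintf("  subjects: %d (%d dropped by motion QC)\n",
              nrow(x$manifest), length(x$qc_dropped)))
  cat(sprintf("  measures: %d summary (%d nodal + %d composites), %d edges\n",
              p$n_summary_measures, sum(grepl("^gamma_", x$nodal_results$measure)),
              nrow(x$network_results), p$n_edges))
  cat(sprintf("  params: xi = %g, F threshold = %g, B = %d, alpha = %g, seed = %d\n",
              p$xi, p$f_threshold, p$B, p$alpha, p$seed))
  cat(sprintf("  nodal tier: %d FDR-significant, %d uncorrected\n",
              sum(x$nodal_results$sig_fdr), sum(x$nodal_results$sig_unc)))
  cat(sprintf("  network tier: %d FDR-significant, %d uncorrected\n",
              sum(x$network_results$sig_fdr), sum(x$network_results$sig_unc)))
  sig <- x$nbs$components$p_corrected < p$alpha
  cat(sprintf("  NBS: %d component(s), %d significant (min p = %s)\n",
              nrow(x$nbs$components), sum(sig),
              if (nrow(x$nbs$components)) format(min(x$nbs$components$p_corrected),
                                                 digits = 3) else "NA"))
  cat(sprintf("  behavior: %d (measure, score) pairs tested, %d at p < %g\n",
              nrow(x$associations), sum(x$associations$sig_unc), p$alpha))
  invisible(x)
}
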