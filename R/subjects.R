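#' Read a subject manifest
#'
#' The manifest is a CSV with one row per subject and columns
#' `id group age sex education mmse moca mean_fd path`. `group` must be
#' "patient" or "control"; `sex` "male" or "female"; `path` points to the
#' subject's time-series TSV (relative paths are resolved against the
#' manifest's directory). `education`, `mmse`, `moca` and `mean_fd` may be
#' empty (NA).
#'
#' @param path Path to the manifest CSV.
#' @return A data frame of subject metadata with class `subject_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "group", "path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate subject ids in manifest")
  if (!all(df$group %in% c("patient", "control")))
    stop("manifest group must be 'patient' or 'control'")
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  class(df) <- c("subject_manifest", "data.frame")
  df
}

#' Load a study: manifest plus per-subject ROI time series
#'
#' Reads every subject's T x N time-series TSV (no header, columns in ROI
#' order) and validates it against the ROI set.
#'
#' @param manifest A `subject_manifest` (see [read_manifest()]) or a path to
#'   a manifest CSV.
#' @param rois A `roi_set`; column counts are checked against it.
#' @return A list of class `rsn_study` with elements `manifest` and
#'   `timeseries` (named list of T x N matrices, one per subject id).
#' @export
load_study <- function(manifest, rois) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(rois, "roi_set"))
  ts <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(utils::read.table(manifest$path[i], sep = "\t"))
    dimnames(m) <- NULL
    validate_timeseries(m, rois, id = manifest$id[i])
    m
  })
  names(ts) <- manifest$id
  structure(list(manifest = manifest, timeseries = ts), class = "rsn_study")
}

#' Validate a subject time-series matrix
#'
#' @param x Numeric T x N matrix.
#' @param rois A `roi_set`.
#' @param id Subject id used in error messages.
#' @return `x`, invisibly; errors on violations (too few timepoints, wrong
#'   column count, missing values) and warns on zero-variance columns.
#' @export
validate_timeseries <- function(x, rois, id = "subject") {
  if (!is.matrix(x) || !is.numeric(x)) stop(id, ": time series must be a numeric matrix")
  if (nrow(x) < 3) stop(id, ": time series has fewer than 3 timepoints")
  if (ncol(x) != nrow(rois))
    stop(id, ": time series has ", ncol(x), " columns but ROI set has ", nrow(rois))
  if (anyNA(x)) stop(id, ": time series contains missing values")
  v <- apply(x, 2, stats::var)
  if (any(v == 0))
    warning(id, ": zero-variance ROI column(s): ",
            paste(rois$abbrev[v == 0], collapse = ", "))
  invisible(x)
}

#' Frame-wise displacement (Power formulation)
#'
#' FD at frame t is the sum of absolute frame-to-frame changes of the six
#' rigid-body realignment parameters, with the three rotations converted from
#' radians to arc length on a sphere of radius `head_radius`. FD of the first
#' frame is 0 by convention.
#'
#' @param motion_params T x 6 numeric matrix: three translations (mm) then
#'   three rotations (radians).
#' @param head_radius Head radius in mm used for the rotation arc length;
#'   default 50.
#' @return Numeric vector of length T.
#' @examples
#' mp <- matrix(0, 10, 6); mp[5:10, 1] <- 0.1
#' compute_fd_power(mp)   # 0.1 at frame 5, 0 elsewhere
#' @export
compute_fd_power <- function(motion_params, head_radius = 50) {
  mp <- as.matrix(motion_params)
  if (ncol(mp) != 6) stop("motion_params must have 6 columns")
  if (nrow(mp) < 2) stop("need at least 2 frames to compute FD")
  if (anyNA(mp)) stop("motion parameters contain missing values")
  d <- abs(diff(mp))
  d[, 4:6] <- d[, 4:6] * head_radius
  c(0, rowSums(d))
}

#' Exclude subjects with high head motion
#'
#' A subject is dropped when their mean frame-wise displacement exceeds the
#' group mean by more than `k` sample standard deviations. The threshold is
#' computed in a single pass over all input subjects (it is not recomputed
#' after exclusions). With `by_group`, mean and SD are computed within each
#' group separately.
#'
#' @param mean_fd Numeric vector of per-subject mean FD (mm).
#' @param k Number of SDs above the mean; default 2.
#' @param by_group Optional grouping vector of the same length; when given,
#'   thresholds are per group.
#' @return Logical vector: `TRUE` = keep. The threshold(s) are attached as
#'   attribute `"threshold"`.
#' @examples
#' keep <- qc_exclude_high_motion(c(rep(0.05, 9), 0.5))
#' which(!keep)   # subject 10
#' @export
qc_exclude_high_motion <- function(mean_fd, k = 2, by_group = NULL) {
  if (!all(is.finite(mean_fd))) stop("mean FD values must be finite")
  if (length(mean_fd) < 3) stop("need at least 3 subjects for motion QC")
  if (is.null(by_group)) {
    thr <- mean(mean_fd) + k * stats::sd(mean_fd)
    keep <- mean_fd <= thr
  } else {
    stopifnot(length(by_group) == length(mean_fd))
    thr <- tapply(mean_fd, by_group, function(v) mean(v) + k * stats::sd(v))
    keep <- mean_fd <= thr[as.character(by_group)]
    names(keep) <- NULL
  }
  attr(keep, "threshold") <- thr
  keep
}

#' Demographic and clinical group comparison table
#'
#' Reproduces the standard case-control characteristics table: two-sample
#' two-tailed t-test for age, Fisher's exact test for sex (and any binary
#' count variables), Mann-Whitney U for education and head motion, and
#' Welch's t-test for the cognitive scores (MMSE, MoCA).
#'
#' @param manifest A `subject_manifest` data frame.
#' @return Data frame with columns `characteristic`, `test`, `statistic`,
#'   `p`.
#' @export
demographics_table <- function(manifest) {
  pat <- manifest$group == "patient"
  rows <- list()
  add <- function(name, test, statistic, p)
    rows[[length(rows) + 1]] <<- data.frame(characteristic = name, test = test,
                                            statistic = statistic, p = p)
  tt <- stats::t.test(manifest$age[pat], manifest$age[!pat], var.equal = TRUE)
  add("age", "two-sample t", unname(tt$statistic), tt$p.value)
  counts <- table(factor(manifest$group, c("patient", "control")),
                  factor(manifest$sex, c("male", "female")))
  fis <- fisher_exact_2x2(counts)
  add("sex", "Fisher exact", NA_real_, fis$p.value)
  if (!is.null(manifest$education) && any(!is.na(manifest$education))) {
    mw <- mann_whitney_u(manifest$education[pat], manifest$education[!pat])
    add("education", "Mann-Whitney U", mw$U, mw$p.value)
  }
  for (score in c(mmse = "MMSE", moca = "MoCA")) {
    col <- tolower(score)
    if (!is.null(manifest[[col]]) && any(!is.na(manifest[[col]]))) {
      wt <- welch_ttest(manifest[[col]][pat], manifest[[col]][!pat])
      add(score, "Welch t", wt$t, wt$p.value)
    }
  }
  if (!is.null(manifest$mean_fd) && any(!is.na(manifest$mean_fd))) {
    mw <- mann_whitney_u(manifest$mean_fd[pat], manifest$mean_fd[!pat])
    add("head motion", "Mann-Whitney U", mw$U, mw$p.value)
  }
  do.call(rbind, rows)
}
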