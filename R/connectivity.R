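#' Pearson ROI-pair correlation matrix
#'
#' Computes the sample Pearson correlation between every pair of ROI time
#' series, giving the square N x N connectivity matrix whose diagonal is
#' exactly 1.
#'
#' @param timeseries T x N numeric matrix (one column per ROI), or a list
#'   with a `timeseries` element.
#' @param rois Optional `roi_set` used to name rows/columns and to report the
#'   offending ROI on zero-variance errors.
#' @return N x N symmetric matrix of class `corr_matrix` with unit diagonal.
#' @export
correlation_matrix <- function(timeseries, rois = NULL) {
  x <- if (is.list(timeseries) && !is.null(timeseries$timeseries))
    timeseries$timeseries else timeseries
  x <- as.matrix(x)
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    lab <- if (!is.null(rois)) rois$abbrev[v == 0] else which(v == 0)
    stop("zero-variance ROI column(s): ", paste(lab, collapse = ", "))
  }
  r <- stats::cor(x)
  r[r > 1] <- 1
  r[r < -1] <- -1
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (!is.null(rois)) dimnames(r) <- list(rois$abbrev, rois$abbrev)
  class(r) <- c("corr_matrix", "matrix", "array")
  r
}

#' Exponential transform of the hyperbolic correlation distance
#'
#' Maps each Pearson correlation r to a positive similarity
#' \deqn{\eta = \exp(-\xi \, d), \quad d = (1 - r) / (1 + r),}
#' where d is the hyperbolic correlation distance and \eqn{\xi > 0} sets how
#' fast similarity decays with distance (default 2). The transform is
#' strictly increasing in r, maps r = 1 to 1 and r = 0 to exp(-xi), and
#' tends to 0 as r approaches -1. Since d diverges at r = -1, correlations
#' are clamped to at least `-1 + clamp_eps` first; clamped entries trigger a
#' warning (or an error with `on_minus_one = "error"`). At the default
#' clamp the transformed value underflows to 0.
#'
#' @param corr A `corr_matrix` (or any numeric matrix/vector of correlations
#'   in \[-1, 1\]).
#' @param xi Positive decay constant; default 2.
#' @param clamp_eps Clamp offset at r = -1; default 1e-12.
#' @param on_minus_one `"clamp"` (default) or `"error"`.
#' @return Object of the same shape with class `eta_matrix` (for matrix
#'   input); attribute `"xi"` records the constant. Matrix diagonals are set
#'   to exactly 1.
#' @examples
#' eta_transform(0)          # exp(-2)
#' eta_transform(1/3)        # exp(-1)
#' @export
eta_transform <- function(corr, xi = 2, clamp_eps = 1e-12,
                          on_minus_one = c("clamp", "error")) {
  on_minus_one <- match.arg(on_minus_one)
  if (!is.numeric(xi) || length(xi) != 1 || xi <= 0) stop("xi must be a positive scalar")
  r <- unclass(corr)
  if (any(r < -1 - 1e-9 | r > 1 + 1e-9, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  lo <- -1 + clamp_eps
  if (any(r < lo, na.rm = TRUE)) {
    if (on_minus_one == "error") stop("correlation at -1: eta transform diverges")
    warning("correlation(s) at -1 clamped to -1 + ", format(clamp_eps))
    r[r < lo] <- lo
  }
  r[r > 1] <- 1
  eta <- exp(-xi * (1 - r) / (1 + r))
  if (is.matrix(eta)) {
    diag(eta) <- 1
    class(eta) <- c("eta_matrix", "matrix", "array")
  }
  attr(eta, "xi") <- xi
  eta
}

#' Invert the eta transform
#'
#' Recovers r from \eqn{\eta = \exp(-\xi (1-r)/(1+r))}:
#' r = (1 - d) / (1 + d) with d = -log(eta)/xi.
#'
#' @param eta Transformed values in (0, 1].
#' @param xi Positive decay constant used in the forward transform.
#' @return Correlations.
#' @export
eta_inverse <- function(eta, xi = 2) {
  d <- -log(unclass(eta)) / xi
  r <- (1 - d) / (1 + d)
  attr(r, "xi") <- NULL
  r
}

#' Write a connectivity matrix and its edge list
#'
#' Writes the square matrix as a TSV with ROI abbreviations as header and row
#' names, and (optionally) a long-format edge list CSV with columns
#' `roi_a roi_b r eta`.
#'
#' @param r A `corr_matrix`.
#' @param eta The matching `eta_matrix` (optional; required for the edge
#'   list).
#' @param matrix_path Output TSV path for the matrix (`r`).
#' @param edges_path Optional output CSV path for the edge list.
#' @return Invisibly, the edge list data frame (or `NULL`).
#' @export
write_connectivity <- function(r, eta = NULL, matrix_path, edges_path = NULL) {
  utils::write.table(as.matrix(unclass(r)), matrix_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  edges <- NULL
  if (!is.null(edges_path)) {
    if (is.null(eta)) stop("edge list output requires the eta matrix")
    ut <- upper.tri(r)
    ij <- which(ut, arr.ind = TRUE)
    nm <- rownames(r)
    if (is.null(nm)) nm <- as.character(seq_len(nrow(r)))
    edges <- data.frame(roi_a = nm[ij[, 1]], roi_b = nm[ij[, 2]],
                        r = r[ut], eta = unclass(eta)[ut])
    utils::write.csv(edges, edges_path, row.names = FALSE)
  }
  invisible(edges)
}
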