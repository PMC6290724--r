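#' Nodal integration
#'
#' The integration of node i is the sum of its transformed connectivities to
#' the other nodes, \eqn{\Gamma_i = \sum_{j \ne i} \eta_{ij}} — a
#' total-connectivity-degree measure. The diagonal (self-similarity, 1 by
#' definition) is excluded by default; `include_diagonal = TRUE` adds it,
#' shifting every value up by exactly 1.
#'
#' @param eta An `eta_matrix`.
#' @param include_diagonal Include the j = i term? Default `FALSE`.
#' @return Numeric vector of length N, named like the matrix rows.
#' @export
nodal_integration <- function(eta, include_diagonal = FALSE) {
  m <- as.matrix(unclass(eta))
  g <- rowSums(m) - if (include_diagonal) 0 else diag(m)
  stats::setNames(as.vector(g), rownames(m))
}

#' Intra-network composite score
#'
#' Mean transformed connectivity over the C(m, 2) unordered ROI pairs inside
#' one network (diagonal excluded, each pair counted once).
#'
#' @param eta An `eta_matrix` in ROI-set order.
#' @param rois The matching `roi_set`.
#' @param network A network label present in `rois`.
#' @return Scalar composite score.
#' @export
intra_composite <- function(eta, rois, network) {
  idx <- which(rois$network == network)
  if (length(idx) == 0) stop("unknown network: ", network)
  if (length(idx) < 2) stop("network ", network, " has fewer than 2 ROIs")
  m <- as.matrix(unclass(eta))[idx, idx]
  mean(m[upper.tri(m)])
}

#' Inter-network composite score
#'
#' Mean transformed connectivity over all |X| x |Y| ROI pairs whose endpoints
#' lie in two different networks.
#'
#' @inheritParams intra_composite
#' @param network_x,network_y Two distinct network labels.
#' @return Scalar composite score; symmetric in its two network arguments.
#' @export
inter_composite <- function(eta, rois, network_x, network_y) {
  if (identical(network_x, network_y)) stop("inter-network composite needs two distinct networks")
  ix <- which(rois$network == network_x)
  iy <- which(rois$network == network_y)
  if (length(ix) == 0) stop("unknown network: ", network_x)
  if (length(iy) == 0) stop("unknown network: ", network_y)
  mean(as.matrix(unclass(eta))[ix, iy])
}

#' All summary measures for one subject
#'
#' @param eta An `eta_matrix`.
#' @param rois The matching `roi_set`.
#' @return Named numeric vector: `gamma_<abbrev>` (N values),
#'   `intra_<net>` (one per network), `inter_<netA>_<netB>` (one per
#'   unordered pair, networks in alphabetical order within the key).
#' @export
summary_measures <- function(eta, rois) {
  nets <- roi_networks(rois)
  g <- nodal_integration(eta)
  names(g) <- paste0("gamma_", rois$abbrev)
  intra <- vapply(nets, function(k) intra_composite(eta, rois, k), numeric(1))
  names(intra) <- paste0("intra_", nets)
  pairs <- utils::combn(sort(nets), 2)
  inter <- apply(pairs, 2, function(p) inter_composite(eta, rois, p[1], p[2]))
  names(inter) <- paste0("inter_", pairs[1, ], "_", pairs[2, ])
  c(g, intra, inter)
}

#' Summary-measure table for a cohort
#'
#' One row per subject with the N nodal integrations and the intra-/inter-
#' network composites (N + 6 + 15 = 57 columns for the default 36-ROI,
#' six-network atlas).
#'
#' @param etas Named list of per-subject `eta_matrix` objects, all in the
#'   same ROI order.
#' @param rois The shared `roi_set`.
#' @return Data frame with an `id` column followed by the measures.
#' @export
summarize_cohort <- function(etas, rois) {
  cols <- c("id", names(summary_measures(.constant_eta(rois), rois)))
  if (length(etas) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$id <- character(0)
    return(out)
  }
  nms <- lapply(etas, function(e) rownames(unclass(e)))
  nms <- nms[!vapply(nms, is.null, logical(1))]
  if (length(nms) > 0 && !all(vapply(nms, identical, logical(1), y = rois$abbrev)))
    stop("eta matrices do not all share the ROI set ordering")
  rows <- t(vapply(etas, summary_measures, numeric(length(cols) - 1), rois = rois))
  ids <- names(etas)
  if (is.null(ids)) ids <- as.character(seq_along(etas))
  data.frame(id = ids, rows, row.names = NULL, check.names = FALSE)
}

.constant_eta <- function(rois, value = 0.5) {
  n <- nrow(rois)
  m <- matrix(value, n, n, dimnames = list(rois$abbrev, rois$abbrev))
  diag(m) <- 1
  class(m) <- c("eta_matrix", "matrix", "array")
  m
}

#' Edge-wise eta matrix for a cohort
#'
#' Stacks the upper triangle of every subject's eta matrix into a subjects x
#' edges matrix (N(N-1)/2 columns) for edge-wise inference. Edge order is the
#' column-major upper triangle; columns are named `<roiA>|<roiB>`.
#'
#' @inheritParams summarize_cohort
#' @return S x E numeric matrix with attribute `"edge_index"` (E x 2 matrix
#'   of ROI row indices) and attribute `"roi_abbrev"`.
#' @export
edge_matrix <- function(etas, rois) {
  n <- nrow(rois)
  ut <- upper.tri(matrix(0, n, n))
  ij <- which(ut, arr.ind = TRUE)
  x <- t(vapply(etas, function(e) as.matrix(unclass(e))[ut], numeric(nrow(ij))))
  colnames(x) <- paste0(rois$abbrev[ij[, 1]], "|", rois$abbrev[ij[, 2]])
  ids <- names(etas)
  if (!is.null(ids)) rownames(x) <- ids
  attr(x, "edge_index") <- unname(ij)
  attr(x, "roi_abbrev") <- rois$abbrev
  x
}
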