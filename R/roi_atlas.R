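#' Resting-state network ROI atlases
#'
#' An ROI set is an ordered table of spherical regions of interest, each with
#' an anatomical name, a short unique abbreviation, a resting-state network
#' (RSN) label, an MNI center (mm) and a radius (mm). The row order is
#' significant: it defines the row/column indices of every connectivity
#' matrix downstream.
#'
#' @name roi_set
NULL

.rsn_networks <- c("DMN", "DAN", "FPCN", "AN", "SMN", "VN")

#' Load an ROI definition table
#'
#' Reads a tab-separated ROI table with columns `network`, `name`, `abbrev`,
#' `x`, `y`, `z` (MNI mm) and `radius` (mm), preserving row order.
#'
#' @param path Path to a tab-separated ROI table.
#' @param networks Allowed network labels. Defaults to the six RSNs
#'   (DMN, DAN, FPCN, AN, SMN, VN).
#' @return An object of class `roi_set`: a data frame with the columns above,
#'   one row per ROI.
#' @examples
#' rois <- load_roi_set(system.file("extdata", "rsn_rois.tsv", package = "rsnconn"))
#' nrow(rois)              # 36
#' table(rois$network)
#' @export
load_roi_set <- function(path, networks = .rsn_networks) {
  if (!file.exists(path)) stop("ROI table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_roi_set(df, networks = networks)
}

#' Construct an ROI set from a data frame
#'
#' @param df Data frame with columns `network`, `name`, `abbrev`, `x`, `y`,
#'   `z`, `radius`.
#' @inheritParams load_roi_set
#' @return A `roi_set`.
#' @export
as_roi_set <- function(df, networks = .rsn_networks) {
  required <- c("network", "name", "abbrev", "x", "y", "z", "radius")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("ROI table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("ROI table is empty")
  df <- df[, required]
  for (col in c("x", "y", "z", "radius")) df[[col]] <- as.numeric(df[[col]])
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z) || anyNA(df$radius))
    stop("ROI table contains non-numeric coordinates or radii")
  if (any(df$radius <= 0)) stop("ROI radii must be positive")
  dup <- duplicated(df$abbrev)
  if (any(dup))
    stop("duplicate ROI abbreviations: ", paste(unique(df$abbrev[dup]), collapse = ", "))
  bad <- !(df$network %in% networks)
  if (any(bad))
    stop("unknown network label '", df$network[which(bad)[1]], "' in ROI table row ",
         which(bad)[1])
  rownames(df) <- NULL
  class(df) <- c("roi_set", "data.frame")
  df
}

#' Write an ROI set back to a tab-separated table
#'
#' Round-trips with [load_roi_set()]: reloading the written file reproduces
#' the ROI set exactly.
#'
#' @param rois A `roi_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  utils::write.table(rois, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged six-network ROI atlas
#'
#' 36 spherical ROIs (6 mm radius) covering the default mode (DMN), dorsal
#' attention (DAN), frontal-parietal control (FPCN), auditory (AN),
#' sensorimotor (SMN) and visual (VN) networks, with MNI mm centers.
#'
#' @return A `roi_set` with 36 rows.
#' @export
default_roi_set <- function() {
  load_roi_set(system.file("extdata", "rsn_rois.tsv", package = "rsnconn"))
}

#' @export
print.roi_set <- function(x, ...) {
  cat("ROI set:", nrow(x), "ROIs in", length(unique(x$network)), "networks (",
      paste(unique(x$network), collapse = ", "), ")\n")
  NextMethod()
}

#' Networks of an ROI set
#'
#' @param rois A `roi_set`.
#' @return Character vector of unique network labels, in order of first
#'   appearance.
#' @export
roi_networks <- function(rois) unique(rois$network)
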