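#' Edge-wise covariate-adjusted statistics
#'
#' Fits `eta ~ intercept + group + covariates` to every edge and returns the
#' signed t of the group coefficient (patients minus controls) and the
#' corresponding F = t^2 (the one-degree-of-freedom F of dropping group from
#' the model).
#'
#' @param eta_edges Subjects x edges matrix (see [edge_matrix()]); must carry
#'   the `"edge_index"` attribute or have N(N-1)/2 columns of a known N.
#' @param group Vector of `"patient"`/`"control"` labels (or 0/1).
#' @param covariates Optional numeric covariate columns (age, sex code).
#' @return Object of class `edge_stats`: list with `t`, `F` (length-E
#'   vectors), `edge_index` (E x 2), `roi_abbrev`, `df`.
#' @export
edge_statistics <- function(eta_edges, group, covariates = NULL) {
  Y <- as.matrix(eta_edges)
  g <- .code_group(group)
  if (nrow(Y) != length(g)) stop("edge matrix rows and group length differ")
  Z <- .covariate_matrix(covariates, length(g))
  if (length(g) < (if (is.null(Z)) 0 else ncol(Z)) + 3)
    stop("too few subjects for the edge-wise model")
  eng <- .t_engine(g, Z)
  t <- eng$tfun(Y)
  structure(list(t = t, F = t^2,
                 edge_index = .edge_index_of(eta_edges),
                 roi_abbrev = attr(eta_edges, "roi_abbrev"),
                 df = eng$df),
            class = "edge_stats")
}

.edge_index_of <- function(eta_edges) {
  ei <- attr(eta_edges, "edge_index")
  if (!is.null(ei)) return(ei)
  e <- ncol(as.matrix(eta_edges))
  n <- (1 + sqrt(1 + 8 * e)) / 2
  if (n != round(n)) stop("edge count is not N(N-1)/2 for any integer N")
  unname(which(upper.tri(matrix(0, n, n)), arr.ind = TRUE))
}

#' Connected components of the suprathreshold edge graph
#'
#' Keeps edges whose F statistic strictly exceeds the threshold and whose
#' signed t matches the requested direction, builds the undirected graph on
#' the ROIs, and returns its connected components (each with at least one
#' edge). Component size is the number of links, not nodes.
#'
#' @param stats An `edge_stats` object.
#' @param f_threshold Primary component-forming threshold on F; default 5.3.
#' @param direction `"greater"` (patients > controls, t > 0) or `"less"`.
#' @param use_direction If `FALSE`, all suprathreshold edges are kept
#'   regardless of sign (combined-direction graph).
#' @return Data frame of suprathreshold edges with columns `roi_a`, `roi_b`
#'   (indices), `F`, `t`, `component_id`, `component_size`; zero rows when no
#'   edge survives.
#' @export
suprathreshold_components <- function(stats, f_threshold = 5.3,
                                      direction = c("greater", "less"),
                                      use_direction = TRUE) {
  direction <- match.arg(direction)
  if (f_threshold <= 0) stop("f_threshold must be positive")
  keep <- stats$F > f_threshold
  if (use_direction)
    keep <- keep & if (direction == "greater") stats$t > 0 else stats$t < 0
  ei <- stats$edge_index[keep, , drop = FALSE]
  out <- data.frame(roi_a = ei[, 1], roi_b = ei[, 2],
                    F = stats$F[keep], t = stats$t[keep],
                    component_id = integer(sum(keep)),
                    component_size = integer(sum(keep)))
  if (nrow(out) == 0) return(out)
  gr <- igraph::graph_from_edgelist(cbind(as.character(ei[, 1]),
                                          as.character(ei[, 2])),
                                    directed = FALSE)
  comp <- igraph::components(gr)
  node_comp <- comp$membership[as.character(ei[, 1])]
  out$component_id <- as.integer(node_comp)
  out$component_size <- as.integer(table(node_comp)[as.character(node_comp)])
  out
}

# Max component size (edge count) of an undirected graph given as endpoint
# index vectors; plain union-find, fast enough for the permutation loop.
.max_component_edges <- function(ea, eb) {
  if (length(ea) == 0) return(0L)
  nodes <- unique(c(ea, eb))
  parent <- seq_along(nodes)
  ia <- match(ea, nodes); ib <- match(eb, nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  max(tabulate(roots[ia], nbins = length(nodes)))
}

#' Network-based statistic (NBS)
#'
#' Edge-wise group inference with family-wise error control by the maximal
#' connected-component size. Each edge gets a covariate-adjusted group t
#' (and F = t^2); edges with F above `f_threshold` are split by the sign of
#' t into two one-directional graphs ("greater": patients > controls;
#' "less": patients < controls) whose connected components are the candidate
#' effects. Group labels are then permuted `B` times (Freedman-Lane when
#' covariates are present) and the maximal component size is recorded per
#' permutation and direction; the corrected p of an observed component of
#' size M is, under the default convention,
#' `(1 + #permutations with max size >= M) / (B + 1)`. The `"strict"`
#' convention instead counts permutations with max size strictly greater
#' than M and divides by B (this can yield p = 0).
#'
#' @param eta_edges Subjects x edges matrix (see [edge_matrix()]).
#' @param group Vector of `"patient"`/`"control"` labels (or 0/1).
#' @param covariates Optional numeric covariate columns.
#' @param f_threshold Component-forming threshold on F; default 5.3.
#' @param B Number of permutations; default 5000 (at least 100 for a
#'   reportable p).
#' @param seed RNG seed (required).
#' @param directions Directions to test; default both.
#' @param use_direction Split suprathreshold edges by t sign (default). With
#'   `FALSE` a single combined-direction analysis is run under
#'   direction label `"both"`.
#' @param p_convention `"add_one"` (default) or `"strict"`.
#' @return Object of class `nbs_result`: list with `components` (data frame
#'   `direction component_id size p_corrected`), `edges` (suprathreshold edge
#'   table with ROI names), `null_max` (B x directions matrix of permutation
#'   maximal component sizes) and the call parameters.
#' @export
nbs_test <- function(eta_edges, group, covariates = NULL, f_threshold = 5.3,
                     B = 5000, seed = NULL,
                     directions = c("greater", "less"), use_direction = TRUE,
                     p_convention = c("add_one", "strict")) {
  p_convention <- match.arg(p_convention)
  if (is.null(seed)) stop("seed is required")
  if (B < 100) warning("fewer than 100 permutations: corrected p is unreliable")
  Y <- as.matrix(eta_edges)
  g <- .code_group(group)
  Z <- .covariate_matrix(covariates, length(g))
  obs <- edge_statistics(eta_edges, group, covariates)
  if (!use_direction) directions <- "both"

  perm <- .fl_perm_t(Y, g, Z, B, seed)
  ei <- obs$edge_index
  null_max <- matrix(0L, B, length(directions),
                     dimnames = list(NULL, directions))
  thr_t <- sqrt(f_threshold)
  for (b in seq_len(B)) {
    tb <- perm$t_perm[b, ]
    for (d in directions) {
      keep <- switch(d,
        greater = tb > thr_t,
        less    = tb < -thr_t,
        both    = abs(tb) > thr_t)
      null_max[b, d] <- .max_component_edges(ei[keep, 1], ei[keep, 2])
    }
  }

  comp_rows <- list()
  edge_rows <- list()
  for (d in directions) {
    sc <- suprathreshold_components(obs, f_threshold,
                                    direction = if (d == "both") "greater" else d,
                                    use_direction = d != "both")
    if (nrow(sc) > 0) {
      sizes <- tapply(sc$component_size, sc$component_id, unique)
      ids <- as.integer(names(sizes))
      p <- vapply(as.integer(sizes), function(M) {
        hits <- null_max[, d]
        if (p_convention == "add_one") (1 + sum(hits >= M)) / (B + 1)
        else sum(hits > M) / B
      }, numeric(1))
      comp_rows[[d]] <- data.frame(direction = d, component_id = ids,
                                   size = as.integer(sizes), p_corrected = p)
      sc$direction <- d
      edge_rows[[d]] <- sc
    }
  }
  components <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(direction = character(0), component_id = integer(0),
               size = integer(0), p_corrected = numeric(0))
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(roi_a = integer(0), roi_b = integer(0), F = numeric(0),
               t = numeric(0), component_id = integer(0),
               component_size = integer(0), direction = character(0))
  if (!is.null(obs$roi_abbrev) && nrow(edges) > 0) {
    edges$roi_a <- obs$roi_abbrev[edges$roi_a]
    edges$roi_b <- obs$roi_abbrev[edges$roi_b]
  }
  rownames(components) <- rownames(edges) <- NULL
  structure(list(components = components, edges = edges, null_max = null_max,
                 f_threshold = f_threshold, B = B,
                 p_convention = p_convention, edge_stats = obs),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("Network-based statistic: F threshold", x$f_threshold, ",", x$B,
      "permutations\n")
  if (nrow(x$components) == 0) cat("No suprathreshold components.\n")
  else print(x$components)
  invisible(x)
}

#' Write NBS outputs
#'
#' Writes the component table, the suprathreshold edge table, the null
#' distribution of maximal component sizes, and a simple weighted edge-list
#' graph file (`roi_a roi_b weight`, weight = F).
#'
#' @param x An `nbs_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_nbs_result <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$components, file.path(dir, "nbs_components.csv"),
                   row.names = FALSE)
  utils::write.csv(x$edges, file.path(dir, "nbs_edges.csv"), row.names = FALSE)
  nm <- as.data.frame(x$null_max)
  utils::write.csv(nm, file.path(dir, "nbs_null_max.csv"), row.names = FALSE)
  if (nrow(x$edges) > 0)
    utils::write.table(x$edges[, c("roi_a", "roi_b", "F")],
                       file.path(dir, "nbs_graph.txt"),
                       sep = " ", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(dir)
}
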