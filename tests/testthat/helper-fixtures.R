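# Shared fixtures built in code.

# a tiny two-network atlas for hand-checkable summaries
tiny_roi_set <- function() {
  as_roi_set(data.frame(
    network = c("AN", "AN", "AN", "SMN", "SMN"),
    name = c("a1", "a2", "a3", "s1", "s2"),
    abbrev = c("a1", "a2", "a3", "s1", "s2"),
    x = c(0, 10, 20, 30, 40), y = 0, z = 0, radius = 6
  ))
}

# symmetric eta-like matrix with unit diagonal and entries in (0, 1)
random_eta <- function(n, seed = NULL, labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::runif(n * n, 0.05, 0.95), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  class(m) <- c("eta_matrix", "matrix", "array")
  m
}

constant_eta <- function(n, c, labels = NULL) {
  m <- matrix(c, n, n)
  diag(m) <- 1
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  class(m) <- c("eta_matrix", "matrix", "array")
  m
}

# breadth-first-search connected components, independent of igraph and of the
# package's union-find: returns max component edge count
bfs_max_component_edges <- function(ea, eb) {
  if (length(ea) == 0) return(0L)
  nodes <- unique(c(ea, eb))
  best <- 0L
  unvisited <- nodes
  while (length(unvisited) > 0) {
    queue <- unvisited[1]
    comp <- queue
    unvisited <- setdiff(unvisited, queue)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(eb[ea == v], ea[eb == v])
      new <- intersect(nb, unvisited)
      unvisited <- setdiff(unvisited, new)
      queue <- c(queue, new)
      comp <- c(comp, new)
    }
    best <- max(best, sum(ea %in% comp & eb %in% comp))
  }
  as.integer(best)
}
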