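#' Binary-graph attributes and degree-preserving null models
#'
#' All topological attributes are computed on simple undirected binary
#' graphs: clustering index (segregation), characteristic path length
#' (integration), global and local efficiency, betweenness centrality with
#' its normalized form, connected components, Maslov-Sneppen rewired null
#' graphs, and the small-world coefficient sigma. Graph algorithms are
#' delegated to igraph; the definitions fixed here (treatment of low-degree
#' nodes, disconnected pairs, normalization by mean betweenness) are the
#' package's contract and are verified against brute-force oracles in the
#' test suite.
#'
#' @name graph_metrics
NULL

# Accept a binary_graph, an adjacency matrix, or an igraph object.
.as_igraph <- function(g) {
  if (inherits(g, "igraph")) return(g)
  A <- if (inherits(g, "binary_graph")) g$adjacency else as.matrix(g)
  igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected", diag = FALSE)
}

.as_adjacency <- function(g) {
  if (inherits(g, "binary_graph")) return(g$adjacency)
  if (inherits(g, "igraph"))
    return(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
  as.matrix(g)
}

#' Clustering index
#'
#' Per node: the number of existing edges among the node's neighbors divided
#' by the number possible, `C_i = 2 e_i / (k_i (k_i - 1))`; nodes with fewer
#' than two neighbors contribute 0. The graph-level index is the mean over
#' all N nodes; it is 1 exactly for a complete graph.
#'
#' @param g A `binary_graph`, adjacency matrix, or igraph object.
#' @return List with `C_i` (per node) and `C` (mean).
#' @export
clustering_index <- function(g) {
  ig <- .as_igraph(g)
  ci <- igraph::transitivity(ig, type = "local", isolates = "zero")
  list(C_i = ci, C = mean(ci))
}

#' Characteristic path length and geodesic matrix
#'
#' `L` is the mean geodesic (hop) distance over connected ordered pairs
#' `i != j`. On fragmented graphs the mean is over connected pairs only
#' unless `strict = TRUE`, in which case disconnection is an error.
#'
#' @param g Graph input as in [clustering_index()].
#' @param strict Error on disconnected graphs instead of averaging over
#'   connected pairs.
#' @return List with `L` and `d` (the N x N geodesic matrix; `Inf` marks
#'   disconnected pairs).
#' @export
path_length <- function(g, strict = FALSE) {
  ig <- .as_igraph(g)
  if (igraph::ecount(ig) == 0) stop("path length undefined on an empty graph")
  d <- igraph::distances(ig)
  off <- d[upper.tri(d) | lower.tri(d)]
  if (any(is.infinite(off))) {
    if (strict) stop("graph is disconnected (strict mode)")
    off <- off[is.finite(off)]
  }
  list(L = mean(off), d = d)
}

#' Global efficiency
#'
#' Mean over ordered pairs `i != j` of `1 / d_ij`, with disconnected pairs
#' contributing 0. Equals 1 exactly for a complete graph.
#'
#' @param g Graph input as in [clustering_index()].
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  ig <- .as_igraph(g)
  n <- igraph::vcount(ig)
  if (n < 2) return(0)
  d <- igraph::distances(ig)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbors (the node itself removed); nodes with fewer than two
#' neighbors contribute 0.
#'
#' @param g Graph input as in [clustering_index()].
#' @return Scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  ig <- .as_igraph(g)
  n <- igraph::vcount(ig)
  vals <- vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(ig, v))
    if (length(nb) < 2) return(0)
    global_efficiency(igraph::induced_subgraph(ig, nb))
  }, numeric(1))
  mean(vals)
}

#' Betweenness centrality and its normalized form
#'
#' Shortest-path betweenness `B_i` with fractional credit across equally
#' short paths (Freeman/Brandes), counting each unordered pair once. The
#' normalized betweenness is `b_i = B_i / <B>` where `<B>` is the network
#' mean, so `mean(b_i) = 1` whenever `<B> > 0`; when every `B_i` is zero
#' (e.g. a complete graph) `b_i` is undefined and returned as `NA` with
#' `defined = FALSE`.
#'
#' @param g Graph input as in [clustering_index()].
#' @return List with `B` (per node), `nbc` (`b_i`), `mean_B`, `defined`.
#' @export
betweenness_centrality <- function(g) {
  ig <- .as_igraph(g)
  B <- igraph::betweenness(ig, directed = FALSE, weights = NULL)
  mB <- mean(B)
  if (mB > 0) list(B = B, nbc = B / mB, mean_B = mB, defined = TRUE)
  else list(B = B, nbc = rep(NA_real_, length(B)), mean_B = mB, defined = FALSE)
}

#' Largest connected component
#'
#' @param g Graph input as in [clustering_index()].
#' @return List with `members` (1-based node indices, ascending) and `size`.
#'   Among equally large components the one containing the smallest node
#'   index is returned.
#' @export
largest_component <- function(g) {
  ig <- .as_igraph(g)
  comp <- igraph::components(ig)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    first_member <- vapply(best, function(b) min(which(comp$membership == b)),
                           numeric(1))
    best <- best[which.min(first_member)]
  }
  members <- which(comp$membership == best)
  list(members = members, size = length(members))
}

#' Degree-preserving rewired null graph
#'
#' Applies `n_iter_per_edge * K` attempted double-edge swaps (Maslov-Sneppen
#' rewiring); every draw has exactly the degree sequence of the input and
#' remains a simple graph.
#'
#' @param g Graph input as in [clustering_index()] with at least 2 edges.
#' @param n_iter_per_edge Attempted swaps per edge (default 10).
#' @param seed Optional RNG seed.
#' @return Adjacency matrix of the rewired graph.
#' @export
rewire_null <- function(g, n_iter_per_edge = 10, seed = NULL) {
  ig <- .as_igraph(g)
  k <- igraph::ecount(ig)
  if (k < 2) stop("rewiring needs at least 2 edges")
  if (!is.null(seed)) set.seed(seed)
  rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = n_iter_per_edge * k))
  as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
}

#' Small-world coefficient sigma
#'
#' `sigma = gamma / lambda` with `gamma = C_real / mean(C_rand)` and
#' `lambda = L_real / mean(L_rand)` over an ensemble of degree-preserving
#' rewired null graphs. A small-world graph has clustering much larger than
#' its nulls at comparable path length, i.e. `sigma > 1`. When the
#' thresholded graph is fragmented, the computation is restricted to its
#' largest component.
#'
#' @param g Graph input as in [clustering_index()].
#' @param n_null Null-ensemble size (default 100).
#' @param n_iter_per_edge Swap budget per edge for each null draw.
#' @param seed Optional RNG seed.
#' @return A `small_world_result`: list with `sigma`, `gamma`, `lambda`,
#'   `C_real`, `L_real`, `C_rand`, `L_rand`, `n_null`.
#' @export
small_world_sigma <- function(g, n_null = 100, n_iter_per_edge = 10,
                              seed = NULL) {
  ig <- .as_igraph(g)
  lc <- largest_component(ig)
  if (lc$size < igraph::vcount(ig))
    ig <- igraph::induced_subgraph(ig, lc$members)
  if (!is.null(seed)) set.seed(seed)
  C_real <- clustering_index(ig)$C
  L_real <- path_length(ig)$L
  k <- igraph::ecount(ig)
  nulls <- vapply(seq_len(n_null), function(i) {
    rg <- igraph::rewire(ig, igraph::keeping_degseq(niter = n_iter_per_edge * k))
    c(clustering_index(rg)$C, path_length(rg)$L)
  }, numeric(2))
  C_rand <- mean(nulls[1, ]); L_rand <- mean(nulls[2, ])
  if (C_rand <= 0)
    stop("null ensemble has zero mean clustering; sigma undefined")
  gamma <- C_real / C_rand
  lambda <- L_real / L_rand
  structure(list(sigma = gamma / lambda, gamma = gamma, lambda = lambda,
                 C_real = C_real, L_real = L_real,
                 C_rand = C_rand, L_rand = L_rand, n_null = n_null),
            class = "small_world_result")
}

#' Evaluate one global attribute on a binary graph
#'
#' Dispatcher used by the attribute-curve machinery.
#'
#' @param g Graph input as in [clustering_index()].
#' @param metric One of `"C"`, `"L"`, `"Eglob"`, `"Eloc"`, `"sigma"`.
#' @param n_null,seed Passed to [small_world_sigma()] when
#'   `metric = "sigma"`.
#' @return Scalar attribute value.
#' @export
graph_attribute <- function(g, metric, n_null = 20, seed = NULL) {
  switch(match.arg(metric, c("C", "L", "Eglob", "Eloc", "sigma")),
         C = clustering_index(g)$C,
         L = path_length(g)$L,
         Eglob = global_efficiency(g),
         Eloc = local_efficiency(g),
         sigma = small_world_sigma(g, n_null = n_null, seed = seed)$sigma)
}

#' Node degrees
#' @param g Graph input as in [clustering_index()].
#' @return Integer vector of degrees.
#' @export
node_degrees <- function(g) {
  as.integer(igraph::degree(.as_igraph(g)))
}
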