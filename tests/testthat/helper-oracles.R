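# Brute-force graph-metric oracles, independent of the package's igraph route.
# All operate on dense 0/1 adjacency matrices.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      new_d <- D[i, k] + D[k, ]
      D[i, ] <- pmin(D[i, ], new_d)
    }
  }
  D
}

oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  off <- D[upper.tri(D) | lower.tri(D)]
  mean(off[is.finite(off)])
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))  # sum counts each neighbor edge twice
  }, numeric(1))
  list(C_i = ci, C = mean(ci))
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# Geodesic counting via adjacency powers: every s-t walk of length d(s,t) is a
# shortest path, so sigma_st = (A^d)[s,t]; paths through v decompose at v.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  maxd <- max(c(1, D[is.finite(D) & D > 0]))
  W <- vector("list", maxd)
  W[[1]] <- A
  if (maxd > 1) for (l in 2:maxd) W[[l]] <- W[[l - 1]] %*% A
  sig <- function(s, t) if (s == t) 1 else W[[D[s, t]]][s, t]
  B <- numeric(n)
  if (n < 3) return(B)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      dst <- D[s, t]
      if (!is.finite(dst) || dst < 2) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == dst)
          B[v] <- B[v] + sig(s, v) * sig(v, t) / sig(s, t)
      }
    }
  }
  B
}

oracle_components <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    frontier <- s
    members <- s
    seen[s] <- TRUE
    while (length(frontier) > 0) {
      nb <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      members <- c(members, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# --- graph generators --------------------------------------------------------

random_adjacency <- function(n, p = 0.3) {
  A <- matrix(0L, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- as.integer(stats::runif(length(ut)) < p)
  A + t(A)
}

# all labeled simple graphs on n nodes, as adjacency matrices
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(0:(2^m - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- bits
    A + t(A)
  })
}

complete_graph <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}

path_graph <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

star_graph <- function(n_leaves) {
  A <- matrix(0L, n_leaves + 1, n_leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1L
  A
}

cycle_graph <- function(n) {
  A <- path_graph(n)
  A[1, n] <- A[n, 1] <- 1L
  A
}

watts_strogatz <- function(n = 90, nei = 5, p = 0.1) {
  g <- igraph::sample_smallworld(1, n, nei, p)
  as.matrix(igraph::as_adjacency_matrix(igraph::simplify(g), sparse = FALSE))
}
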