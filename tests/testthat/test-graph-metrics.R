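test_that("closed-form attribute values on canonical graphs", {
  k5 <- complete_graph(5)
  expect_equal(clustering_index(k5)$C, 1)
  expect_equal(path_length(k5)$L, 1)
  expect_equal(global_efficiency(k5), 1)
  expect_equal(local_efficiency(complete_graph(4)), 1)

  star <- star_graph(4)  # K_{1,4}, center is node 1
  expect_equal(clustering_index(star)$C, 0)
  expect_equal(local_efficiency(star), 0)
  bc <- betweenness_centrality(star)
  expect_equal(bc$B[1], 6)          # choose(4, 2) leaf pairs
  expect_equal(bc$B[-1], rep(0, 4))

  p3 <- path_graph(3)
  expect_equal(path_length(p3)$L, 4 / 3)
  expect_equal(betweenness_centrality(p3)$B[2], 1)

  # two isolated nodes: efficiency 0, path length undefined
  expect_equal(global_efficiency(matrix(0, 2, 2)), 0)
  expect_error(path_length(matrix(0, 2, 2)), "empty")

  # complete graph: all betweenness zero, normalization undefined but flagged
  bc_k <- betweenness_centrality(k5)
  expect_false(bc_k$defined)
  expect_true(all(is.na(bc_k$nbc)))
})

test_that("metrics equal brute-force oracles exhaustively on small graphs", {
  for (n in 2:5) {
    for (A in all_graphs(n)) {
      expect_equal(clustering_index(A)$C_i, oracle_clustering(A)$C_i)
      expect_equal(global_efficiency(A), oracle_global_efficiency(A))
      expect_equal(betweenness_centrality(A)$B, oracle_betweenness(A),
                   tolerance = 1e-10)
      if (sum(A) > 0) {
        expect_equal(path_length(A)$L, oracle_path_length(A))
      }
    }
  }
})

test_that("metrics equal brute-force oracles on 200 random graphs up to N=25", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:25, 1)
    A <- random_adjacency(n, p = runif(1, 0.1, 0.6))
    expect_equal(clustering_index(A)$C_i, oracle_clustering(A)$C_i,
                 tolerance = 1e-12)
    expect_equal(global_efficiency(A), oracle_global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(A), oracle_local_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(betweenness_centrality(A)$B, oracle_betweenness(A),
                 tolerance = 1e-9)
    if (sum(A) > 0)
      expect_equal(path_length(A)$L, oracle_path_length(A), tolerance = 1e-12)
    # normalized betweenness averages to 1 when defined
    bc <- betweenness_centrality(A)
    if (bc$defined) expect_equal(mean(bc$nbc), 1, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(12)
  for (i in 1:10) {
    A <- random_adjacency(15, 0.3)
    perm <- sample(15)
    Ap <- A[perm, perm]
    expect_equal(clustering_index(Ap)$C, clustering_index(A)$C)
    expect_equal(global_efficiency(Ap), global_efficiency(A))
    expect_equal(local_efficiency(Ap), local_efficiency(A))
    expect_equal(sort(betweenness_centrality(Ap)$B),
                 sort(betweenness_centrality(A)$B), tolerance = 1e-9)
  }
})

test_that("global efficiency dominates 1/L on connected graphs", {
  set.seed(13)
  found <- 0
  while (found < 20) {
    A <- random_adjacency(12, 0.4)
    if (largest_component(A)$size < 12) next
    found <- found + 1
    expect_gte(global_efficiency(A) + 1e-12, 1 / path_length(A)$L)
  }
})

test_that("largest component matches a BFS oracle with deterministic ties", {
  set.seed(14)
  for (i in 1:20) {
    A <- random_adjacency(15, 0.12)
    comps <- oracle_components(A)
    sizes <- lengths(comps)
    lc <- largest_component(A)
    expect_equal(lc$size, max(sizes))
    best <- comps[sizes == max(sizes)]
    firsts <- vapply(best, min, numeric(1))
    expect_equal(lc$members, best[[which.min(firsts)]])
  }
  # explicit tie: components {1,2} and {3,4} -> the one holding node 1
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  expect_equal(largest_component(A)$members, c(1, 2))
})

test_that("rewiring preserves the exact degree sequence and simplicity", {
  set.seed(15)
  A <- random_adjacency(30, 0.2)
  deg <- rowSums(A)
  for (i in 1:25) {
    R <- rewire_null(A, n_iter_per_edge = 10)
    expect_identical(rowSums(R), deg)
    expect_true(all(diag(R) == 0))
    expect_true(all(R %in% c(0, 1)))
    expect_true(isSymmetric(R))
  }
  # a cycle stays 2-regular no matter how long we swap
  C6 <- cycle_graph(6)
  R <- rewire_null(C6, n_iter_per_edge = 100, seed = 3)
  expect_equal(unname(rowSums(R)), rep(2, 6))
  expect_error(rewire_null(matrix(0, 3, 3)), "at least 2 edges")
})

test_that("rewiring actually randomizes triangle structure", {
  # a clique-rich graph loses triangles under degree-preserving rewiring
  set.seed(16)
  A <- kronecker(diag(6), matrix(1, 5, 5) - diag(5))  # six 5-cliques
  # connect blocks in a ring so swaps can mix across blocks
  for (b in 1:6) {
    i <- (b - 1) * 5 + 1; j <- (b %% 6) * 5 + 2
    A[i, j] <- A[j, i] <- 1
  }
  tri <- function(M) sum(diag(M %*% M %*% M)) / 6
  t0 <- tri(A)
  t_null <- vapply(1:30, function(i) tri(rewire_null(A, 10)), numeric(1))
  expect_lt(max(t_null), t0)
})

test_that("small-world sigma behaves on canonical inputs", {
  # complete graph: its only degree-preserving rewiring is itself
  k6 <- complete_graph(6)
  sw <- small_world_sigma(k6, n_null = 5, seed = 1)
  expect_equal(sw$sigma, 1)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)

  # a lattice with shortcuts is small-world: sigma > 1
  ws <- watts_strogatz(60, 4, 0.1)
  set.seed(2)
  sw2 <- small_world_sigma(ws, n_null = 30)
  expect_gt(sw2$sigma, 1)
})

test_that("attribute dispatcher and degrees agree with the primitives", {
  set.seed(17)
  A <- random_adjacency(15, 0.4)
  expect_equal(graph_attribute(A, "C"), clustering_index(A)$C)
  expect_equal(graph_attribute(A, "Eglob"), global_efficiency(A))
  expect_equal(graph_attribute(A, "Eloc"), local_efficiency(A))
  expect_equal(node_degrees(A), unname(rowSums(A)))
  expect_error(graph_attribute(A, "modularity"), "arg")
})
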