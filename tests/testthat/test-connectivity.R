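test_that("pearson matrix matches the direct covariance formula", {
  set.seed(2)
  v <- matrix(rnorm(10 * 5), 10, 5)
  C <- pearson_matrix(v)
  expect_equal(diag(C), rep(0, 5), ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(C)))
  # textbook cov / (sd sd) oracle
  for (i in 1:4) for (j in (i + 1):5) {
    num <- sum((v[, i] - mean(v[, i])) * (v[, j] - mean(v[, j])))
    den <- sqrt(sum((v[, i] - mean(v[, i]))^2) * sum((v[, j] - mean(v[, j]))^2))
    expect_equal(C[i, j], num / den, tolerance = 1e-12)
  }

  # identical columns correlate at 1, planted anticorrelation recovers sign
  v2 <- cbind(v[, 1], v[, 1], -v[, 2], v[, 2])
  C2 <- pearson_matrix(v2)
  expect_equal(C2[1, 2], 1)
  expect_equal(C2[3, 4], -1)

  v3 <- v; v3[, 2] <- 7
  colnames(v3) <- paste0("reg", 1:5)
  expect_error(pearson_matrix(v3), "constant.*reg2")
  expect_error(pearson_matrix(v[1:3, ]), "at least 4")
})

test_that("pearson matrix is invariant to affine rescaling of a column", {
  set.seed(3)
  v <- matrix(rnorm(20 * 6), 20, 6)
  C <- pearson_matrix(v)
  v2 <- v
  v2[, 3] <- 5 * v[, 3] + 2
  expect_equal(unclass(pearson_matrix(v2)), unclass(C), tolerance = 1e-12)
  v2[, 3] <- -v[, 3]
  expect_equal(pearson_matrix(v2)[3, ], -C[3, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("bootstrap draws are reproducible, sized, and degenerate to the full sample", {
  set.seed(4)
  v <- matrix(rnorm(100 * 8), 100, 8)
  b1 <- bootstrap_matrices(v, n_boot = 5, fraction = 0.8, seed = 9)
  b2 <- bootstrap_matrices(v, n_boot = 5, fraction = 0.8, seed = 9)
  expect_identical(lapply(b1, unclass), lapply(b2, unclass))
  expect_equal(attr(b1, "config")$subset_size, 80)
  expect_equal(attr(b1[[1]], "n_subjects"), 80)

  full <- pearson_matrix(v)
  b3 <- bootstrap_matrices(v, n_boot = 3, fraction = 1.0, seed = 1)
  for (C in b3) expect_equal(unclass(C), unclass(full), tolerance = 1e-12)

  expect_error(bootstrap_matrices(v[1:4, ], fraction = 0.5), "too small")
})

test_that("sparsity grid has the documented endpoints and length", {
  g <- sparsity_grid()
  expect_length(g, 21)
  expect_equal(g[1], 0.5)
  expect_equal(g[21], 0.9)
  expect_equal(diff(g), rep(0.02, 20), tolerance = 1e-9)
  expect_equal(sparsity_grid(0.7, 0.7, 0.02), 0.7)
  expect_equal(sparsity_grid(0.5, 0.6, 0.05), c(0.5, 0.55, 0.6))
  expect_error(sparsity_grid(step = 0), "positive")
  expect_error(sparsity_grid(0.9, 0.5), "start")
})

test_that("binarization keeps exactly the K largest |r| with nested edge sets", {
  set.seed(5)
  n <- 20
  C <- pearson_matrix(matrix(rnorm(50 * n), 50, n))
  e_total <- n * (n - 1) / 2
  for (s in c(0.5, 0.7, 0.9)) {
    g <- binarize(C, s)
    k_expected <- floor((1 - s) * e_total)
    expect_equal(g$k_edges, k_expected)
    expect_equal(sum(g$adjacency) / 2, k_expected)
    expect_equal(diag(g$adjacency), rep(0, n), ignore_attr = TRUE)
    # sort oracle: every retained |r| >= every discarded |r|
    absr <- abs(C[upper.tri(C)])
    kept <- g$adjacency[upper.tri(C)] == 1
    expect_gte(min(absr[kept]), max(absr[!kept]))
    expect_equal(g$threshold, min(absr[kept]))
  }
  # monotone nesting along the grid
  prev <- NULL
  for (s in sparsity_grid(0.5, 0.9, 0.1)) {
    g <- binarize(C, s)
    if (!is.null(prev)) expect_true(all(g$adjacency <= prev))
    prev <- g$adjacency
  }
  # K = 1 retains the single argmax pair
  s1 <- 1 - 1.5 / e_total
  g1 <- binarize(C, s1)
  expect_equal(g1$k_edges, 1)
  expect_equal(g1$threshold, max(abs(C[upper.tri(C)])))
  expect_error(binarize(pearson_matrix(matrix(rnorm(40), 10, 4)), 0.9),
               "retains no edges")
})

test_that("Fisher transform obeys its closed form and odd symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(0.5), 0.5 * log((1 + 0.5) / (1 - 0.5)))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("edge-wise Z comparison matches its closed form and is antisymmetric", {
  # scalar oracle at r1 = 0.8, r2 = 0.2, n1 = n2 = 69
  z1 <- 0.5 * log(1.8 / 0.2); z2 <- 0.5 * log(1.2 / 0.8)
  z_expected <- (z1 - z2) / sqrt(1 / 66 + 1 / 66)
  C1 <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  C2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  cmp <- compare_matrices(C1, C2, n1 = 69, n2 = 69)
  expect_equal(cmp$Z, z_expected, tolerance = 1e-12)

  set.seed(6)
  A <- pearson_matrix(matrix(rnorm(60 * 10), 60, 10))
  B <- pearson_matrix(matrix(rnorm(50 * 10), 50, 10))
  ab <- compare_matrices(A, B)
  ba <- compare_matrices(B, A)
  expect_equal(ab$Z, -ba$Z)
  expect_identical(ab$significant, ba$significant)

  same <- compare_matrices(A, A)
  expect_true(all(same$Z == 0))
  expect_false(any(same$significant))

  expect_error(compare_matrices(A, B, n1 = 3, n2 = 50), "exceed 3")
})

test_that("involvement counts tally endpoints of significant edges", {
  cmp <- data.frame(region_a = c("a", "a", "b"), region_b = c("b", "c", "c"),
                    significant = c(TRUE, TRUE, FALSE))
  counts <- edge_involvement_counts(cmp)
  expect_equal(as.integer(counts[c("a", "b", "c")]), c(2, 1, 1))
})
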