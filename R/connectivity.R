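#' Connectivity matrices, bootstraps, binarization, and edge-wise comparison
#'
#' The metabolic network edge weight between two regions is the Pearson
#' correlation of their confound-adjusted uptake across subjects. Matrices
#' are resampled by subject bootstraps, binarized over a grid of sparsity
#' degrees by keeping the largest absolute correlations, and compared between
#' groups edge by edge with Fisher's r-to-z and the normal Z statistic under
#' Benjamini-Hochberg false discovery rate control.
#'
#' @name connectivity
NULL

.residual_values <- function(x) {
  if (inherits(x, "residual_matrix")) x$values else as.matrix(x)
}

#' Interregional Pearson correlation matrix
#'
#' @param residuals A `residual_matrix` or a plain subjects x N matrix.
#' @return A `conn_matrix`: symmetric N x N Pearson correlation matrix with
#'   the diagonal forced to zero (self-connections excluded) and attribute
#'   `n_subjects`.
#' @export
pearson_matrix <- function(residuals) {
  v <- .residual_values(residuals)
  if (nrow(v) < 4) stop("need at least 4 subjects to estimate correlations")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(v)[sds == 0]
    if (is.null(nm)) nm <- which(sds == 0)
    stop("constant residual column for region(s): ", paste(nm, collapse = ", "))
  }
  C <- stats::cor(v)
  diag(C) <- 0
  C <- (C + t(C)) / 2
  attr(C, "n_subjects") <- nrow(v)
  class(C) <- c("conn_matrix", class(C))
  C
}

#' Bootstrap connectivity matrices
#'
#' Draws `n_boot` subject subsets of size `round(fraction * n)` — by default
#' distinct subjects within each sample, independently across samples — and
#' returns one Pearson matrix per draw.
#'
#' @param residuals A `residual_matrix` or subjects x N matrix.
#' @param n_boot Number of bootstrap samples (study default 300).
#' @param fraction Subset fraction of the group's subjects (study default 0.8).
#' @param seed RNG seed; the sequence of draws is reproducible.
#' @param replace Draw subjects with replacement within a sample.
#' @return List of `conn_matrix`, with attribute `config` recording the draw
#'   parameters.
#' @export
bootstrap_matrices <- function(residuals, n_boot = 300, fraction = 0.8,
                               seed = 1L, replace = FALSE) {
  v <- .residual_values(residuals)
  n <- nrow(v)
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (n_boot < 1) stop("n_boot must be >= 1")
  m <- round(fraction * n)
  if (m < 4) stop("bootstrap subset size ", m, " is too small (need >= 4)")
  set.seed(seed)
  out <- lapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, m, replace = replace)
    pearson_matrix(v[idx, , drop = FALSE])
  })
  attr(out, "config") <- list(n_boot = n_boot, fraction = fraction,
                              seed = seed, replace = replace, subset_size = m)
  out
}

#' Sparsity-degree grid
#'
#' @param start,stop,step Inclusive arithmetic grid parameters; the defaults
#'   give the standard 21 values from 0.5 to 0.9 in steps of 0.02.
#' @return Numeric vector of sparsity degrees.
#' @export
sparsity_grid <- function(start = 0.5, stop = 0.9, step = 0.02) {
  if (step <= 0) stop("step must be positive")
  if (start <= 0 || stop >= 1 || start > stop)
    stop("need 0 < start <= stop < 1")
  g <- seq(start, stop + step * 1e-8, by = step)
  round(g[g <= stop + step * 1e-8], 10)
}

#' Binarize a connectivity matrix at a sparsity degree
#'
#' Keeps the `K = floor((1 - s) * N(N-1)/2)` unordered pairs of largest
#' absolute correlation (a sparsity degree of 0.9 discards 90% of candidate
#' edges). Ties at the threshold are broken deterministically by atlas-order
#' pair index. The realized threshold is the smallest retained absolute
#' correlation.
#'
#' @param C A `conn_matrix` (or symmetric matrix, diagonal ignored).
#' @param s Sparsity degree in (0, 1).
#' @return A `binary_graph`: list with `adjacency` (0/1 symmetric, zero
#'   diagonal), `sparsity`, `threshold` (realized R_k), `k_edges`,
#'   `n_nodes`.
#' @export
binarize <- function(C, s) {
  if (s <= 0 || s >= 1) stop("sparsity degree must lie in (0, 1)")
  n <- nrow(C)
  ut <- which(upper.tri(C))
  e_total <- length(ut)
  k <- floor((1 - s) * e_total)
  if (k < 1) stop("sparsity degree ", s, " retains no edges")
  absr <- abs(C[ut])
  ord <- order(-absr, seq_along(absr))  # ties -> lower atlas pair index wins
  keep <- ut[ord[seq_len(k)]]
  A <- matrix(0L, n, n, dimnames = dimnames(C))
  A[keep] <- 1L
  A <- A + t(A)
  structure(list(adjacency = A, sparsity = s,
                 threshold = absr[ord[k]], k_edges = k, n_nodes = n),
            class = "binary_graph")
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, which makes correlation
#' differences approximately normal with variance `1/(n - 3)`.
#'
#' @param r Numeric vector of correlations with `|r| < 1`.
#' @return Transformed values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' Edge-wise comparison of two connectivity matrices
#'
#' For every unordered region pair, computes
#' `Z = (z1 - z2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))` on the Fisher-transformed
#' correlations, a two-sided normal p-value, and a Benjamini-Hochberg
#' decision at rate `q` over all pairs.
#'
#' @param C1,C2 `conn_matrix` objects (same dimension, atlas order).
#' @param n1,n2 Numbers of subjects behind each matrix (default: their
#'   `n_subjects` attributes). Must exceed 3.
#' @param q False discovery rate.
#' @param atlas Optional `region_atlas` for labelling pairs.
#' @return An `edge_comparison`: data.frame with one row per pair
#'   (`region_a`, `region_b`, `r1`, `r2`, `z1`, `z2`, `Z`, `p`,
#'   `significant`), plus attributes `n1`, `n2`, `q`.
#' @export
compare_matrices <- function(C1, C2, n1 = attr(C1, "n_subjects"),
                             n2 = attr(C2, "n_subjects"), q = 0.05,
                             atlas = NULL) {
  if (is.null(n1) || is.null(n2)) stop("n1 and n2 must be supplied")
  if (n1 <= 3 || n2 <= 3) stop("group sizes must exceed 3 (z variance undefined)")
  if (!all(dim(C1) == dim(C2))) stop("matrices must have identical dimensions")
  idx <- which(upper.tri(C1), arr.ind = TRUE)
  r1 <- C1[upper.tri(C1)]; r2 <- C2[upper.tri(C2)]
  z1 <- fisher_z(r1); z2 <- fisher_z(r2)
  Z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(Z))
  sig <- stats::p.adjust(p, method = "BH") <= q
  lab <- if (!is.null(atlas)) atlas$regions$abbreviation
         else if (!is.null(rownames(C1))) rownames(C1)
         else as.character(seq_len(nrow(C1)))
  out <- data.frame(region_a = lab[idx[, 1]], region_b = lab[idx[, 2]],
                    r1 = r1, r2 = r2, z1 = z1, z2 = z2, Z = Z, p = p,
                    significant = sig)
  attr(out, "n1") <- n1; attr(out, "n2") <- n2; attr(out, "q") <- q
  class(out) <- c("edge_comparison", "data.frame")
  out
}

#' Per-region involvement counts in significant edge differences
#'
#' For each region, the number of significant pairs it participates in —
#' the quantity visualized as sphere diameter in connectivity-difference
#' figures.
#'
#' @param comparison An `edge_comparison`.
#' @return Named integer vector (regions with zero involvement included when
#'   the comparison carries labels for them).
#' @export
edge_involvement_counts <- function(comparison) {
  sig <- comparison[comparison$significant, ]
  table(factor(c(sig$region_a, sig$region_b),
               levels = unique(c(comparison$region_a, comparison$region_b))))
}

#' Write a connectivity matrix as square CSV with region labels
#' @param C Matrix in atlas order.
#' @param atlas A `region_atlas`.
#' @param path Output CSV path.
#' @export
write_conn_matrix <- function(C, atlas, path) {
  M <- as.matrix(C)
  dimnames(M) <- list(atlas$regions$abbreviation, atlas$regions$abbreviation)
  utils::write.csv(M, path)
  invisible(path)
}
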