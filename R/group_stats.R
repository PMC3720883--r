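#' Cross-group statistics: attribute curves, AUC contrasts, NBC profiling
#'
#' Global attributes are summarized per bootstrap by the area under their
#' curve over the sparsity grid (the curves are monotone-ish in sparsity, so
#' the area is a stable one-number summary), and groups are contrasted by
#' Kruskal-Wallis tests on the bootstrap AUC distributions with pairwise
#' post-hoc comparisons. Nodal normalized betweenness (NBC) is profiled over
#' bootstraps and sparsity degrees, tested per grid point across groups, and
#' thresholded at 1.5 for hub selection.
#'
#' @name group_stats
NULL

#' Attribute curves over the sparsity grid
#'
#' Evaluates a global attribute on the binarized graph of every bootstrap
#' matrix at every sparsity degree.
#'
#' @param matrices List of `conn_matrix` (one per bootstrap).
#' @param grid Sparsity grid from [sparsity_grid()].
#' @param metric One of `"C"`, `"L"`, `"Eglob"`, `"Eloc"`, `"sigma"`.
#' @param strict Propagate strict disconnection handling for `"L"`; in
#'   strict mode undefined grid points are recorded as `NA`, not dropped.
#' @param n_null Null-ensemble size per graph when `metric = "sigma"`.
#' @param seed Base seed for sigma's null draws (deterministic per cell).
#' @return An `attribute_curve`: list with `metric`, `grid`, `values`
#'   (n_boot x n_grid matrix), `auc` (per-bootstrap trapezoidal area).
#' @export
attribute_curves <- function(matrices, grid, metric, strict = FALSE,
                             n_null = 20, seed = 1L) {
  metric <- match.arg(metric, c("C", "L", "Eglob", "Eloc", "sigma"))
  vals <- matrix(NA_real_, length(matrices), length(grid))
  for (b in seq_along(matrices)) {
    for (j in seq_along(grid)) {
      g <- binarize(matrices[[b]], grid[j])
      vals[b, j] <- tryCatch({
        if (metric == "L") path_length(g, strict = strict)$L
        else graph_attribute(g, metric, n_null = n_null,
                             seed = seed + 1000L * b + j)
      }, error = function(e) NA_real_)
    }
  }
  structure(list(metric = metric, grid = grid, values = vals,
                 auc = curve_auc(vals, grid)),
            class = "attribute_curve")
}

#' Trapezoidal area under attribute curves
#'
#' @param values Matrix (bootstraps x grid points) or vector of attribute
#'   values.
#' @param grid Sparsity degrees (>= 2 points).
#' @param interpolate Linearly interpolate over interior missing values
#'   instead of erroring.
#' @return Per-bootstrap AUC.
#' @export
curve_auc <- function(values, grid, interpolate = FALSE) {
  if (length(grid) < 2) stop("AUC needs at least 2 grid points")
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (ncol(values) != length(grid)) stop("values/grid length mismatch")
  apply(values, 1, function(y) {
    if (anyNA(y)) {
      if (!interpolate) stop("missing attribute values; set interpolate=TRUE")
      y <- stats::approx(grid[!is.na(y)], y[!is.na(y)], xout = grid,
                         rule = 2)$y
    }
    pracma::trapz(grid, y)
  })
}

#' Kruskal-Wallis comparison of per-group AUC samples
#'
#' Tests the bootstrap AUC distributions across groups, then runs pairwise
#' rank-sum post-hoc tests with Bonferroni correction over the number of
#' pairs. The bootstrap AUCs are treated as exchangeable samples, so the
#' p-values describe bootstrap separation between group networks, not
#' subject-level inference.
#'
#' @param auc_by_group Named list of numeric AUC vectors (>= 2 groups, each
#'   >= 2 values).
#' @param alpha Significance level for the post-hoc decisions.
#' @return An `auc_comparison`: list with `kw` (statistic, df, p),
#'   `posthoc` (data.frame per pair: `groups`, `p`, `p_bonferroni`,
#'   `significant`, `higher`), `group_means`.
#' @export
compare_auc <- function(auc_by_group, alpha = 0.05) {
  if (length(auc_by_group) < 2) stop("need at least 2 groups")
  if (any(vapply(auc_by_group, length, integer(1)) < 2))
    stop("every group needs at least 2 AUC values")
  all_vals <- unlist(auc_by_group)
  if (stats::sd(all_vals) == 0) {
    kw <- list(statistic = 0, df = length(auc_by_group) - 1, p = 1)
    posthoc <- NULL
  } else {
    kt <- stats::kruskal.test(auc_by_group)
    kw <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
               p = kt$p.value)
    cmb <- utils::combn(names(auc_by_group), 2)
    n_pairs <- ncol(cmb)
    posthoc <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
      a <- cmb[1, i]; b <- cmb[2, i]
      wt <- suppressWarnings(stats::wilcox.test(auc_by_group[[a]],
                                                auc_by_group[[b]]))
      data.frame(groups = paste(a, b, sep = "-"), p = wt$p.value,
                 p_bonferroni = min(1, wt$p.value * n_pairs))
    }))
    posthoc$significant <- posthoc$p_bonferroni <= alpha
    means <- vapply(auc_by_group, mean, numeric(1))
    posthoc$higher <- vapply(seq_len(n_pairs), function(i) {
      pr <- strsplit(posthoc$groups[i], "-")[[1]]
      pr[which.max(means[pr])]
    }, character(1))
  }
  structure(list(kw = kw, posthoc = posthoc,
                 group_means = vapply(auc_by_group, mean, numeric(1))),
            class = "auc_comparison")
}

#' Nodal NBC profile across groups
#'
#' Finds the sparsity upper bound — the largest contiguous run of grid values
#' (from the densest end) at which every bootstrap graph of every group is
#' fully connected — computes normalized betweenness per region, bootstrap
#' and retained grid point, tests each region at each grid point across
#' groups with Kruskal-Wallis (Bonferroni-corrected over the N regions), and
#' flags a region as different when corrected-significant at >= 99% of the
#' retained grid points. Mean NBC per region (over bootstraps and grid) is
#' the hub statistic.
#'
#' @param boot_by_group Named list: group -> list of `conn_matrix`.
#' @param grid Sparsity grid (ascending).
#' @param atlas A `region_atlas`.
#' @param alpha Family-wise level after Bonferroni correction.
#' @param significance_fraction Fraction of grid points that must be
#'   corrected-significant (default 0.99).
#' @return An `nbc_profile`: list with `mean_nbc` (region x group), `flags`,
#'   `significant_fraction`, `p_bonferroni` (region x grid), `grid_used`,
#'   `upper_bound`, `nbc` (group -> boot x grid x region array).
#' @export
nbc_profile <- function(boot_by_group, grid, atlas, alpha = 0.05,
                        significance_fraction = 0.99) {
  groups <- names(boot_by_group)
  if (length(groups) < 2) stop("need bootstraps for at least 2 groups")
  n <- atlas$n_regions

  # connectivity check per grid point; retain the contiguous prefix
  connected_at <- vapply(seq_along(grid), function(j) {
    all(vapply(groups, function(g) {
      all(vapply(boot_by_group[[g]], function(C) {
        largest_component(binarize(C, grid[j]))$size == n
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  if (!connected_at[1])
    stop("no sparsity degree yields fully connected graphs in every ",
         "bootstrap; use a denser (lower-sparsity) grid")
  n_used <- if (all(connected_at)) length(grid) else which(!connected_at)[1] - 1L
  grid_used <- grid[seq_len(n_used)]

  nbc <- lapply(groups, function(g) {
    boots <- boot_by_group[[g]]
    arr <- array(NA_real_, dim = c(length(boots), n_used, n))
    for (b in seq_along(boots)) {
      for (j in seq_len(n_used)) {
        bc <- betweenness_centrality(binarize(boots[[b]], grid_used[j]))
        arr[b, j, ] <- if (bc$defined) bc$nbc else rep(NA_real_, n)
      }
    }
    arr
  })
  names(nbc) <- groups

  p_raw <- matrix(NA_real_, n, n_used)
  for (j in seq_len(n_used)) {
    for (r in seq_len(n)) {
      samples <- lapply(groups, function(g) nbc[[g]][, j, r])
      p_raw[r, j] <- if (stats::sd(unlist(samples)) == 0) 1
                     else stats::kruskal.test(samples)$p.value
    }
  }
  p_bonf <- pmin(p_raw * n, 1)  # pmin(matrix, scalar) keeps dim
  frac <- rowMeans(p_bonf <= alpha)
  mean_nbc <- vapply(groups, function(g) {
    apply(nbc[[g]], 3, mean, na.rm = TRUE)
  }, numeric(n))
  rownames(mean_nbc) <- rownames(p_bonf) <- atlas$regions$abbreviation
  names(frac) <- atlas$regions$abbreviation

  structure(list(mean_nbc = mean_nbc,
                 flags = frac >= significance_fraction,
                 significant_fraction = frac,
                 p_bonferroni = p_bonf,
                 grid_used = grid_used,
                 upper_bound = grid_used[n_used],
                 nbc = nbc, atlas = atlas),
            class = "nbc_profile")
}

#' Hub selection from an NBC profile
#'
#' Hubs are the regions whose mean NBC (over bootstraps and sparsity
#' degrees) exceeds 1.5 times the network mean, i.e. `b_i > 1.5`.
#'
#' @param profile An `nbc_profile`, or a region x group matrix of mean NBC
#'   with region rownames (then `atlas` must be given).
#' @param threshold Hub threshold on mean NBC (default 1.5).
#' @param atlas Required when `profile` is a bare matrix.
#' @return A `hub_table`: data.frame with `group`, `region`, `nbc`, `lobe`,
#'   `hemisphere`, sorted by group then descending NBC.
#' @export
select_hubs <- function(profile, threshold = 1.5, atlas = NULL) {
  if (inherits(profile, "nbc_profile")) {
    m <- profile$mean_nbc; atlas <- profile$atlas
  } else m <- profile
  if (is.null(atlas)) stop("atlas required")
  rows <- list()
  for (g in colnames(m)) {
    sel <- which(m[, g] > threshold)
    if (length(sel) == 0) next
    reg <- rownames(m)[sel]
    ai <- region_index(atlas, reg)
    df <- data.frame(group = g, region = reg, nbc = m[sel, g],
                     lobe = atlas$regions$lobe[ai],
                     hemisphere = atlas$regions$hemisphere[ai])
    rows[[g]] <- df[order(-df$nbc), ]
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(group = character(), region = character(),
                         nbc = numeric(), lobe = character(),
                         hemisphere = character())
  rownames(out) <- NULL
  class(out) <- c("hub_table", "data.frame")
  out
}
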