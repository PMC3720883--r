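#' Spatial analyses of the strongest covariations
#'
#' Where do the largest absolute correlations live? These analyses rank the
#' edge universe by |r|, count how many of the top-K edges fall within each
#' lobe, average |r| within and between region sets, and run the central
#' "Core" analysis: the ten bilateral pericentral structures (precentral,
#' supplementary motor, median cingulate, postcentral, paracentral) treated
#' as a unit and contrasted against the frontal and limbic lobes.
#'
#' @name lobe_core
NULL

#' The ten-region Core set
#'
#' @return Character vector of the Core abbreviations: PreCG, SMA, DCG,
#'   PoCG, PCL, each in both hemispheres (5 homologous pairs).
#' @export
core_regions <- function() {
  as.vector(outer(c("PreCG", "SMA", "DCG", "PoCG", "PCL"), c(".L", ".R"),
                  paste0))
}

#' Top-K edges by absolute correlation
#'
#' @param C A `conn_matrix` (or symmetric matrix; diagonal ignored).
#' @param k Number of edges (study default 1000, i.e. 24.96% of the 4005
#'   pairs of a 90-region atlas).
#' @param atlas Optional `region_atlas` for labels.
#' @param signed Rank by signed `r` (descending) instead of `|r|`.
#' @return Data.frame of `k` rows (`region_a`, `region_b`, `r`, `abs_r`),
#'   descending, ties broken by atlas pair index.
#' @export
top_k_edges <- function(C, k = 1000, atlas = NULL, signed = FALSE) {
  n <- nrow(C)
  e_total <- n * (n - 1) / 2
  if (k < 1 || k > e_total)
    stop("k must lie in [1, ", e_total, "] for ", n, " regions")
  idx <- which(upper.tri(C), arr.ind = TRUE)
  r <- C[upper.tri(C)]
  key <- if (signed) r else abs(r)
  ord <- order(-key, seq_along(key))[seq_len(k)]
  lab <- if (!is.null(atlas)) atlas$regions$abbreviation
         else if (!is.null(rownames(C))) rownames(C)
         else as.character(seq_len(n))
  data.frame(region_a = lab[idx[ord, 1]], region_b = lab[idx[ord, 2]],
             r = r[ord], abs_r = abs(r[ord]))
}

#' Intra-lobe counts of an edge list
#'
#' Counts how many listed edges have both endpoints in the same lobe, per
#' lobe. Regions outside the named lobes contribute to the cross-lobe
#' remainder only.
#'
#' @param edges Data.frame with `region_a`, `region_b` (abbreviations).
#' @param atlas A `region_atlas`.
#' @param lobes Lobes to report (default: the five named lobes).
#' @return Named integer vector over `lobes` plus a `cross` count; the total
#'   over all categories equals `nrow(edges)`.
#' @export
lobe_edge_counts <- function(edges, atlas,
                             lobes = c("Limbic", "Frontal", "Parietal",
                                       "Occipital", "Temporal")) {
  la <- atlas$regions$lobe[region_index(atlas, edges$region_a)]
  lb <- atlas$regions$lobe[region_index(atlas, edges$region_b)]
  intra <- la == lb & la %in% lobes
  counts <- table(factor(la[intra], levels = lobes))
  out <- c(as.integer(counts), nrow(edges) - sum(intra))
  names(out) <- c(lobes, "cross")
  out
}

#' Mean absolute correlation within or between region sets
#'
#' With one set: mean `|C_ij|` over unordered pairs within the set. With two
#' disjoint sets: mean over the full rectangle of between-set pairs.
#'
#' @param C A `conn_matrix` (or symmetric matrix).
#' @param set_a Character abbreviations or 1-based indices.
#' @param set_b Optional second set, disjoint from `set_a`.
#' @param atlas Required to resolve abbreviations.
#' @return Scalar mean absolute correlation.
#' @export
set_mean_abs_corr <- function(C, set_a, set_b = NULL, atlas = NULL) {
  resolve <- function(s) {
    if (is.character(s)) {
      if (is.null(atlas)) stop("atlas required to resolve abbreviations")
      region_index(atlas, s)
    } else as.integer(s)
  }
  ia <- resolve(set_a)
  if (is.null(set_b)) {
    if (length(ia) < 2) stop("need at least 2 regions for a within-set mean")
    sub <- abs(C[ia, ia])
    mean(sub[upper.tri(sub)])
  } else {
    ib <- resolve(set_b)
    if (length(ib) < 1 || length(ia) < 1) stop("sets must be non-empty")
    if (length(intersect(ia, ib)) > 0)
      stop("sets must be disjoint for a between-set mean")
    mean(abs(C[ia, ib]))
  }
}

# KW + pairwise post hoc on named lists of per-bootstrap statistics
.kw_posthoc <- function(samples_by_group, alpha = 0.05) {
  compare_auc(samples_by_group, alpha = alpha)
}

#' Core covariation analysis
#'
#' For every group and bootstrap matrix: mean |r| within the Core set
#' (45 intra-Core pairs), and between Core and the frontal / limbic lobes
#' with Core members first removed from those lobes. Groups are contrasted
#' per panel by Kruskal-Wallis with pairwise post-hoc tests.
#'
#' @param boot_by_group Named list: group -> list of `conn_matrix`.
#' @param atlas A `region_atlas`.
#' @param core Core abbreviations (default [core_regions()]).
#' @param alpha Post-hoc significance level.
#' @return A `core_analysis`: list with `distributions` (panel -> group ->
#'   per-bootstrap mean |r|), `tests` (panel -> `auc_comparison`),
#'   `group_means` (panel x group matrix).
#' @export
core_analysis <- function(boot_by_group, atlas, core = core_regions(),
                          alpha = 0.05) {
  core_i <- region_index(atlas, core)
  frontal <- setdiff(which(atlas$regions$lobe == "Frontal"), core_i)
  limbic <- setdiff(which(atlas$regions$lobe == "Limbic"), core_i)
  panels <- list(
    "Core-Core" = function(C) set_mean_abs_corr(C, core_i),
    "Core-Frontal" = function(C) set_mean_abs_corr(C, core_i, frontal),
    "Core-Limbic" = function(C) set_mean_abs_corr(C, core_i, limbic))
  dists <- lapply(panels, function(f) {
    lapply(boot_by_group, function(boots) vapply(boots, f, numeric(1)))
  })
  tests <- lapply(dists, .kw_posthoc, alpha = alpha)
  gm <- t(vapply(dists, function(d) vapply(d, mean, numeric(1)),
                 numeric(length(boot_by_group))))
  structure(list(distributions = dists, tests = tests, group_means = gm),
            class = "core_analysis")
}

#' Covariation among a hypometabolic region set
#'
#' Mean |r| within a supplied region set (typically the regions flagged
#' hypometabolic in the AD contrast) per bootstrap and group, with
#' Kruskal-Wallis and pairwise post-hoc tests across groups.
#'
#' @param boot_by_group Named list: group -> list of `conn_matrix`.
#' @param regions Character abbreviations or indices (>= 2).
#' @param atlas Required to resolve abbreviations.
#' @param alpha Post-hoc significance level.
#' @return List with `distributions`, `tests` (an `auc_comparison`),
#'   `group_means`.
#' @export
hypometabolic_set_covariation <- function(boot_by_group, regions, atlas = NULL,
                                          alpha = 0.05) {
  if (length(regions) < 2) stop("need at least 2 regions")
  dists <- lapply(boot_by_group, function(boots) {
    vapply(boots, function(C) set_mean_abs_corr(C, regions, atlas = atlas),
           numeric(1))
  })
  structure(list(distributions = dists,
                 tests = .kw_posthoc(dists, alpha = alpha),
                 group_means = vapply(dists, mean, numeric(1))),
            class = "hypometabolic_covariation")
}
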